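# Shared fixture builders for the test suite. All randomness is controlled
# through explicit seeds so every test is reproducible.

# One Wald-ratio replicate under a simulation config, in the two-sample
# design the method assumes (and real analyses use): the score-exposure
# association comes from one cohort, the score-metabolite association from
# an independent cohort of the same size. Plain allele-count score.
wald_replicate <- function(cfg, seed, metabolite = 1L) {
  cfg_m <- cfg; cfg_m$seed <- as.integer(seed)
  cfg_e <- cfg; cfg_e$seed <- as.integer(seed) + 500000L
  g_m <- simulate_genotypes(cfg$snps$raf, cfg$n_individuals, seed = cfg_m$seed,
                            rsid = cfg$snps$rsid)
  g_e <- simulate_genotypes(cfg$snps$raf, cfg$n_individuals, seed = cfg_e$seed,
                            rsid = cfg$snps$rsid)
  cs_m <- simulate_cohort(g_m, cfg_m)
  cs_e <- simulate_cohort(g_e, cfg_e)
  e <- fit_iv_assoc(rowSums(g_e$dosage), cs_e$cohort$exposure, role = "exposure")
  m <- fit_iv_assoc(rowSums(g_m$dosage), cs_m$metabolites[, metabolite],
                    role = "metabolite")
  wald_ratio(m, e)
}

# one per-SNP summary replicate, two-sample: exposure associations from a
# large external GWAS (summary level), outcome associations from marginal
# per-SNP regressions in the individual-level cohort
pairs_replicate <- function(cfg, seed, metabolite = 1L, n_gwas = 46186) {
  cfg$seed <- as.integer(seed)
  g <- simulate_genotypes(cfg$snps$raf, cfg$n_individuals, seed = cfg$seed,
                          rsid = cfg$snps$rsid)
  cs <- simulate_cohort(g, cfg)
  ax <- simulate_summary_stats(cfg, n_gwas = n_gwas, role = "exposure",
                               seed = cfg$seed + 700000L)
  ay <- snp_trait_assoc(g, cs$metabolites[, metabolite])
  snp_pairs(ax$rsid, ax$beta, ax$se, ay$beta, ay$se)
}

# random summary-level snp_pairs instance for algebraic/oracle checks
random_pairs <- function(seed, J = 10, theta = 0.5) {
  set.seed(seed)
  bx <- rnorm(J, 0.1, 0.04)
  sx <- runif(J, 0.005, 0.03)
  sy <- runif(J, 0.01, 0.05)
  by <- theta * bx + rnorm(J, 0, sy)
  snp_pairs(sprintf("rs%03d", seq_len(J)), bx, sx, by, sy)
}

# Independent brute-force oracle for the likelihood estimator: for each
# candidate theta on a refined grid, minimize the joint two-normal deviance
# over each nuisance ksi_j numerically (1-D optimize per SNP), then take the
# grid/bracket minimum in theta. Shares no code with mr_likelihood().
oracle_profile_mle <- function(pairs) {
  joint_dev <- function(theta) {
    tot <- 0
    for (j in seq_len(nrow(pairs))) {
      f <- function(ksi) {
        (pairs$bx[j] - ksi)^2 / pairs$sx[j]^2 +
          (pairs$by[j] - theta * ksi)^2 / pairs$sy[j]^2
      }
      lim <- max(abs(pairs$bx[j]), abs(pairs$by[j] / max(abs(theta), 1e-3))) + 1
      tot <- tot + optimize(f, c(-lim, lim), tol = 1e-12)$objective
    }
    tot
  }
  ratios <- pairs$by / pairs$bx
  lo <- min(ratios) - 2 * diff(range(c(ratios, 0))) - 1
  hi <- max(ratios) + 2 * diff(range(c(ratios, 0))) + 1
  grid <- seq(lo, hi, length.out = 60)
  vals <- vapply(grid, joint_dev, numeric(1))
  k <- which.min(vals)
  bracket <- c(grid[max(1, k - 1)], grid[min(length(grid), k + 1)])
  optimize(joint_dev, bracket, tol = 1e-10)$minimum
}
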