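#' Simulation configuration for the synthetic cohort generator
#'
#' Defines the generative model used throughout the test surface: a set of
#' independent Hardy-Weinberg SNPs driving an exposure (insulin resistance or
#' impaired insulin secretion, in SD-units), a single standard-normal
#' confounder entering both exposure and metabolites, metabolites with a
#' causal exposure effect and optional per-SNP direct (pleiotropic) effects,
#' and plate/drift batch structure for LC/MS-like feature intensities.
#'
#' Residual standard deviations default to `NULL`, meaning they are chosen so
#' the exposure and each metabolite have unit population variance; effects
#' are then directly interpretable in SD-units.
#'
#' @param n_individuals number of samples.
#' @param snps data frame with columns `rsid`, `raf` (risk-allele frequency,
#'   strictly inside (0,1)), `effect` (per-allele exposure effect, SD-units),
#'   and optionally `risk_allele`, `other_allele`. Defaults to a 10-SNP
#'   instrument with frequencies 0.2-0.5 and per-allele effects 0.05-0.15.
#' @param theta true causal effect(s) of the exposure on the metabolite(s),
#'   SD-unit change per SD exposure; length gives the number of metabolites.
#' @param b_u,c_m confounder effects on exposure and metabolite.
#' @param pleiotropy per-SNP direct metabolite effects: a scalar, a vector of
#'   length `nrow(snps)`, or a matrix SNPs x metabolites. Default 0.
#' @param noise_sd_exposure,noise_sd_metabolite residual SDs; `NULL` requests
#'   the unit-variance calibration described above.
#' @param batch list with `n_plates`, `plate_effect_sd`, `drift_slope`
#'   (log-intensity drift per injection) for [simulate_feature_table()].
#' @param seed integer seed; fixing it reproduces every output bit-exactly.
#'
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, seed = 7)
#' cfg$snps$raf
sim_config <- function(n_individuals = 5000,
                       snps = NULL,
                       theta = -0.4,
                       b_u = 0.3,
                       c_m = 0.3,
                       pleiotropy = 0,
                       noise_sd_exposure = NULL,
                       noise_sd_metabolite = NULL,
                       batch = list(n_plates = 8, plate_effect_sd = 0.15,
                                    drift_slope = 0.002),
                       seed = 1L) {
  if (is.null(snps)) {
    snps <- data.frame(
      rsid = sprintf("rs%04d", seq_len(10L)),
      risk_allele = rep(c("A", "C"), 5L),
      other_allele = rep(c("G", "T"), 5L),
      raf = seq(0.2, 0.5, length.out = 10L),
      effect = seq(0.05, 0.15, length.out = 10L),
      stringsAsFactors = FALSE
    )
  }
  .assert(is.data.frame(snps) && all(c("rsid", "raf", "effect") %in% names(snps)),
          "`snps` must be a data frame with columns rsid, raf, effect",
          "mrmetab_invalid_parameter")
  .assert(n_individuals >= 1, "n_individuals must be >= 1",
          "mrmetab_invalid_parameter")
  .assert(all(snps$raf > 0 & snps$raf < 1),
          "all risk-allele frequencies must lie strictly in (0, 1)",
          "mrmetab_invalid_parameter")
  if (is.null(snps$risk_allele)) snps$risk_allele <- rep("A", nrow(snps))
  if (is.null(snps$other_allele)) snps$other_allele <- rep("G", nrow(snps))

  n_met <- length(theta)
  d <- pleiotropy
  if (is.matrix(d)) {
    .assert(nrow(d) == nrow(snps) && ncol(d) == n_met,
            "pleiotropy matrix must be n_snps x n_metabolites",
            "mrmetab_structural_error")
  } else {
    d <- matrix(rep_len(d, nrow(snps)), nrow(snps), n_met)
  }

  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    snps = snps,
    theta = theta,
    b_u = b_u,
    c_m = c_m,
    pleiotropy = d,
    noise_sd_exposure = noise_sd_exposure,
    noise_sd_metabolite = noise_sd_metabolite,
    batch = batch,
    seed = as.integer(seed)
  ), class = "sim_config")
  # fail early if the variance budget is impossible
  .exposure_sd_raw(cfg)
  .metabolite_sd_raw(cfg)
  cfg
}

# population SD of the raw (unstandardized) exposure
.exposure_sd_raw <- function(cfg) {
  v <- 2 * cfg$snps$raf * (1 - cfg$snps$raf)
  gen <- sum(cfg$snps$effect^2 * v) + cfg$b_u^2
  s2 <- if (is.null(cfg$noise_sd_exposure)) {
    .assert(gen < 0.99,
            "genetic + confounder variance exceeds the unit-variance budget for the exposure",
            "mrmetab_invalid_parameter")
    1 - gen
  } else {
    cfg$noise_sd_exposure^2
  }
  sqrt(gen + s2)
}

# population SDs of the raw metabolites (one per element of theta)
.metabolite_sd_raw <- function(cfg) {
  v <- 2 * cfg$snps$raf * (1 - cfg$snps$raf)
  sx <- .exposure_sd_raw(cfg)
  a <- cfg$snps$effect
  vapply(seq_along(cfg$theta), function(k) {
    th <- cfg$theta[k]
    d <- cfg$pleiotropy[, k]
    core <- th^2 + cfg$c_m^2 + 2 * th * cfg$c_m * cfg$b_u / sx +
      sum(d^2 * v) + 2 * (th / sx) * sum(a * d * v)
    s2 <- if (is.null(cfg$noise_sd_metabolite)) {
      .assert(core < 0.99,
              "causal + confounder + pleiotropic variance exceeds the unit-variance budget for a metabolite",
              "mrmetab_invalid_parameter")
      1 - core
    } else {
      cfg$noise_sd_metabolite^2
    }
    sqrt(core + s2)
  }, numeric(1))
}

#' Construct a genotype dosage matrix
#'
#' Container for risk-allele dosages (0/1/2 or `NA`) with optional per-SNP
#' allele labels declaring which allele the dosage counts.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns.
#' @param sample_ids,snp_ids row/column identifiers.
#' @param counted_allele,other_allele optional named character vectors (one
#'   entry per SNP) giving the allele the dosage counts and the alternate
#'   allele, as in PLINK RAW-style exports.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            snp_ids = colnames(dosage),
                            counted_allele = NULL, other_allele = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(dosage)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%03d", seq_len(ncol(dosage)))
  .assert(length(sample_ids) == nrow(dosage) && length(snp_ids) == ncol(dosage),
          "id lists must match dosage dimensions", "mrmetab_structural_error")
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  .assert(all(ok), "dosages must be 0, 1, 2 or missing",
          "mrmetab_structural_error")
  dimnames(dosage) <- list(sample_ids, snp_ids)
  if (!is.null(counted_allele)) counted_allele <- setNames(as.character(counted_allele), snp_ids)
  if (!is.null(other_allele)) other_allele <- setNames(as.character(other_allele), snp_ids)
  structure(list(dosage = dosage, sample_ids = sample_ids, snp_ids = snp_ids,
                 counted_allele = counted_allele, other_allele = other_allele),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs; %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Dosages are drawn independently as Binomial(2, raf) per SNP: independent
#' loci in Hardy-Weinberg equilibrium, with no linkage disequilibrium.
#'
#' @param raf vector of risk-allele frequencies, each strictly in (0, 1).
#' @param n number of individuals.
#' @param seed integer seed.
#' @param rsid optional SNP identifiers.
#' @param risk_allele,other_allele optional allele labels; when supplied the
#'   returned matrix declares the risk allele as its counted allele.
#' @return a [genotype_matrix()].
#' @export
#' @examples
#' g <- simulate_genotypes(rep(0.3, 5), n = 100, seed = 1)
#' colMeans(g$dosage) / 2   # close to 0.3
simulate_genotypes <- function(raf, n, seed = 1L, rsid = NULL,
                               risk_allele = NULL, other_allele = NULL) {
  .assert(all(raf > 0 & raf < 1), "each raf must lie strictly in (0, 1)",
          "mrmetab_invalid_parameter")
  .assert(n >= 1, "n must be >= 1", "mrmetab_invalid_parameter")
  set.seed(seed)
  J <- length(raf)
  dosage <- matrix(rbinom(n * J, 2L, rep(raf, each = n)), nrow = n, ncol = J)
  if (is.null(rsid)) rsid <- sprintf("rs%04d", seq_len(J))
  genotype_matrix(dosage, sample_ids = sprintf("S%05d", seq_len(n)),
                  snp_ids = rsid, counted_allele = risk_allele,
                  other_allele = other_allele)
}

#' Set genotype entries missing at random
#'
#' @param g a [genotype_matrix()].
#' @param rate per-entry missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the matrix with entries masked to `NA`.
#' @export
inject_missingness <- function(g, rate, seed = 1L) {
  .assert(inherits(g, "genotype_matrix"), "g must be a genotype_matrix")
  .assert(rate >= 0 && rate < 1, "rate must lie in [0, 1)",
          "mrmetab_invalid_parameter")
  if (rate == 0) return(g)
  set.seed(seed)
  mask <- matrix(runif(length(g$dosage)) < rate, nrow = nrow(g$dosage))
  g$dosage[mask] <- NA
  g
}

#' Simulate a cohort with known causal structure
#'
#' Generates, per individual: a standard-normal confounder `U`; an exposure
#' `X = sum_j a_j G_j + b_u U + e` standardized to SD-units; metabolites
#' `M_k = theta_k X + c_m U + sum_j d_jk G_j + eps_k`, also standardized;
#' covariates (age, sex, three genetic PCs, cohort label, BMI); and OGTT
#' insulin/glucose at 0 and 30 minutes plus clamp M/I as monotone transforms
#' of latent insulin sensitivity and secretion, so that the derived IGI30 and
#' disposition index carry the assumed sign structure (higher exposure =
#' worse insulin sensitivity = lower clamp M/I).
#'
#' @param genotypes a [genotype_matrix()] whose columns align with
#'   `config$snps`.
#' @param config a [sim_config()].
#' @return a list of class `cohort_sim` with elements `cohort` (data frame),
#'   `metabolites` (samples x metabolites matrix, SD-units) and `truth`
#'   (the generative parameters actually used).
#' @export
simulate_cohort <- function(genotypes, config) {
  .assert(inherits(genotypes, "genotype_matrix"), "genotypes must be a genotype_matrix")
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  G <- genotypes$dosage
  .assert(ncol(G) == nrow(config$snps),
          "genotype columns do not align with config$snps",
          "mrmetab_structural_error")
  n <- nrow(G)
  set.seed(config$seed + 1L)

  sx_raw <- .exposure_sd_raw(config)
  sm_raw <- .metabolite_sd_raw(config)
  v <- 2 * config$snps$raf * (1 - config$snps$raf)
  s_e <- sqrt(max(sx_raw^2 - sum(config$snps$effect^2 * v) - config$b_u^2, 1e-12))

  U <- rnorm(n)
  X_raw <- drop(G %*% config$snps$effect) + config$b_u * U + rnorm(n, sd = s_e)
  X <- (X_raw - mean(X_raw)) / sd(X_raw)

  K <- length(config$theta)
  M <- matrix(NA_real_, n, K,
              dimnames = list(genotypes$sample_ids, sprintf("met%03d", seq_len(K))))
  for (k in seq_len(K)) {
    th <- config$theta[k]
    d <- config$pleiotropy[, k]
    core_var <- th^2 + config$c_m^2 + 2 * th * config$c_m * config$b_u / sx_raw +
      sum(d^2 * v) + 2 * (th / sx_raw) * sum(config$snps$effect * d * v)
    s_eps <- sqrt(max(sm_raw[k]^2 - core_var, 1e-12))
    m_raw <- th * X + config$c_m * U + drop(G %*% d) + rnorm(n, sd = s_eps)
    M[, k] <- (m_raw - mean(m_raw)) / sd(m_raw)
  }

  # OGTT and clamp variables: monotone transforms of latent sensitivity
  # (-X, since higher exposure means worse insulin sensitivity) and a latent
  # secretion trait; scales follow typical elderly non-diabetic cohorts
  # (clamp M/I around 5.4, disposition index around 2.5)
  sens <- -X
  secr <- -0.5 * X + rnorm(n, sd = 0.8)
  glu0 <- 5.0 + 0.3 * rnorm(n)
  dglu <- pmax(2.5 + 0.6 * rnorm(n), 0.5)
  glu30 <- glu0 + dglu
  ins0 <- pmax(8 + 2 * rnorm(n), 2)
  igi_true <- exp(log(0.463) + 0.5 * secr)
  ins30 <- ins0 + igi_true * dglu
  clamp_mi <- exp(log(5.4) + 0.45 * sens)

  cohort <- data.frame(
    sample_id = genotypes$sample_ids,
    age = round(70 + 2 * rnorm(n), 1),
    sex = rbinom(n, 1L, 0.5),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
    cohort = sample(c("cohortA", "cohortB"), n, replace = TRUE),
    bmi = round(26 + 3.5 * rnorm(n), 1),
    exposure = X,
    confounder = U,
    ins0 = ins0, ins30 = ins30, glu0 = glu0, glu30 = glu30,
    clamp_mi = clamp_mi,
    stringsAsFactors = FALSE
  )

  structure(list(cohort = cohort, metabolites = M,
                 truth = list(theta = config$theta,
                              pleiotropy = config$pleiotropy,
                              exposure_sd_raw = sx_raw,
                              metabolite_sd_raw = sm_raw)),
            class = "cohort_sim")
}

#' Simulate GWAS summary statistics under the generative model
#'
#' Per-SNP true marginal effects follow from the cohort model: for the
#' exposure role, `a_j / sd(X_raw)` per allele; for the outcome (metabolite)
#' role, `theta * a_j / sd(X_raw) + d_j`. Reported effects add sampling noise
#' `Normal(0, se_j)` with `se_j = 1 / sqrt(2 f_j (1 - f_j) n_gwas)` (unit
#' trait SD). Allele labels and frequencies are emitted so that downstream
#' harmonization can be exercised. `n_gwas = Inf` gives the zero-noise limit.
#'
#' @param config a [sim_config()].
#' @param n_gwas GWAS sample size (may be `Inf`).
#' @param role `"exposure"` or `"outcome"`.
#' @param seed integer seed.
#' @param metabolite index of the metabolite used for the outcome role.
#' @return a data frame of class `summary_stats` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`.
#' @export
simulate_summary_stats <- function(config, n_gwas, role = c("exposure", "outcome"),
                                   seed = 1L, metabolite = 1L) {
  role <- match.arg(role)
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  .assert(n_gwas >= 1, "n_gwas must be >= 1", "mrmetab_invalid_parameter")
  sx <- .exposure_sd_raw(config)
  a_marg <- config$snps$effect / sx
  true_beta <- switch(role,
    exposure = a_marg,
    outcome = config$theta[metabolite] * a_marg + config$pleiotropy[, metabolite]
  )
  se <- 1 / sqrt(2 * config$snps$raf * (1 - config$snps$raf) * n_gwas)
  set.seed(seed)
  beta <- if (is.infinite(n_gwas)) true_beta else rnorm(length(true_beta), true_beta, se)
  out <- data.frame(
    rsid = config$snps$rsid,
    effect_allele = config$snps$risk_allele,
    other_allele = config$snps$other_allele,
    eaf = config$snps$raf,
    beta = beta,
    se = se,
    n = rep(n_gwas, nrow(config$snps)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Wrap simulated metabolites into an LC/MS-like feature table
#'
#' Converts SD-unit metabolite values into batch-structured log-normal
#' feature intensities: `log(I) = mu_k + 0.5 * M_k + plate effect +
#' drift * injection order + noise`, with plate-level random intercepts and a
#' linear run-order drift. Optionally appends pure-noise features and
#' duplicate injections (for duplicate-correlation filtering).
#'
#' @param sim a `cohort_sim` from [simulate_cohort()].
#' @param config the [sim_config()] used to generate it (for `batch` and
#'   `seed`).
#' @param n_noise_features extra features unrelated to any signal.
#' @param duplicates if `TRUE`, every sample is injected twice and
#'   `sample_meta$dup_pair` links the two injections.
#' @param rt_range retention-time range (seconds) that feature retention
#'   times are drawn from.
#' @return a [feature_table()] on the raw intensity scale.
#' @export
simulate_feature_table <- function(sim, config, n_noise_features = 20L,
                                   duplicates = FALSE, rt_range = c(20, 600)) {
  .assert(inherits(sim, "cohort_sim"), "sim must be a cohort_sim")
  set.seed(config$seed + 2L)
  M <- sim$metabolites
  n <- nrow(M)
  K <- ncol(M) + n_noise_features
  feat_id <- sprintf("F%04d", seq_len(K))
  signal <- cbind(M, matrix(rnorm(n * n_noise_features), n, n_noise_features))

  reps <- if (duplicates) 2L else 1L
  idx <- rep(seq_len(n), each = reps)
  n_inj <- length(idx)
  order_ <- seq_len(n_inj)
  n_plates <- config$batch$n_plates
  plate <- paste0("P", ((order_ - 1L) %/% ceiling(n_inj / n_plates)) + 1L)
  plate_eff <- setNames(rnorm(n_plates, sd = config$batch$plate_effect_sd),
                        paste0("P", seq_len(n_plates)))

  mu <- rnorm(K, mean = 12, sd = 1.5)
  logI <- matrix(mu, n_inj, K, byrow = TRUE) +
    0.5 * signal[idx, , drop = FALSE] +
    plate_eff[plate] +
    config$batch$drift_slope * order_ +
    matrix(rnorm(n_inj * K, sd = 0.1), n_inj, K)

  inj_id <- if (duplicates) {
    paste0(rownames(M)[idx], "_r", rep(1:2, times = n))
  } else rownames(M)
  sample_meta <- data.frame(
    sample_id = inj_id,
    source_sample = rownames(M)[idx],
    plate = plate,
    order = order_,
    stringsAsFactors = FALSE
  )
  if (duplicates) sample_meta$dup_pair <- rownames(M)[idx]
  feature_meta <- data.frame(
    id = feat_id,
    mz = round(runif(K, 50, 1200), 4),
    rt_seconds = round(runif(K, rt_range[1], rt_range[2]), 1),
    annotation = c(colnames(M), rep(NA_character_, n_noise_features)),
    stringsAsFactors = FALSE
  )
  intens <- exp(logI)
  dimnames(intens) <- list(inj_id, feat_id)
  feature_table(intens, feature_meta, sample_meta)
}
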