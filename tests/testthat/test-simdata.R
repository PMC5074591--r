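test_that("genotype simulation follows the binomial HWE model", {
  g <- simulate_genotypes(rep(0.5, 10), n = 4, seed = 42)
  expect_equal(dim(g$dosage), c(4L, 10L))
  expect_true(all(g$dosage %in% 0:2))

  # empirical mean dosage converges to 2f (binomial law)
  g2 <- simulate_genotypes(0.2, n = 50000, seed = 1)
  mc_se <- sqrt(2 * 0.2 * 0.8 / 50000)
  expect_lt(abs(mean(g2$dosage) - 0.4), 3 * mc_se)

  # degenerate limit near fixation
  g3 <- simulate_genotypes(0.999999, n = 10, seed = 1)
  expect_true(all(g3$dosage == 2L))

  expect_error(simulate_genotypes(1.2, n = 5), class = "mrmetab_invalid_parameter")
  expect_error(simulate_genotypes(0, n = 5), class = "mrmetab_invalid_parameter")
})

test_that("fixing the seed reproduces outputs bit-exactly", {
  cfg <- sim_config(n_individuals = 200, seed = 9)
  g1 <- simulate_genotypes(cfg$snps$raf, 200, seed = 9)
  g2 <- simulate_genotypes(cfg$snps$raf, 200, seed = 9)
  expect_identical(g1$dosage, g2$dosage)
  c1 <- simulate_cohort(g1, cfg)
  c2 <- simulate_cohort(g2, cfg)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$metabolites, c2$metabolites)
  s1 <- simulate_summary_stats(cfg, 10000, "outcome", seed = 3)
  s2 <- simulate_summary_stats(cfg, 10000, "outcome", seed = 3)
  expect_identical(s1, s2)
})

test_that("cohort generator has the stated causal structure", {
  # null model: score-metabolite slope within 3 SEs of zero
  cfg0 <- sim_config(n_individuals = 4000, theta = 0, b_u = 0, seed = 21)
  g <- simulate_genotypes(cfg0$snps$raf, cfg0$n_individuals, seed = 21)
  cs <- simulate_cohort(g, cfg0)
  fit <- fit_iv_assoc(rowSums(g$dosage), cs$metabolites[, 1], role = "metabolite")
  expect_lt(abs(fit$beta), 3 * fit$se)

  # exposure and metabolites come back in SD-units
  cfg <- sim_config(n_individuals = 3000, seed = 22)
  cs2 <- simulate_cohort(simulate_genotypes(cfg$snps$raf, 3000, seed = 22), cfg)
  expect_equal(sd(cs2$cohort$exposure), 1, tolerance = 1e-12)
  expect_equal(mean(cs2$metabolites[, 1]), 0, tolerance = 1e-12)

  # physiologic variables respect their invariants and sign structure:
  # clamp M/I positive and decreasing in the exposure
  expect_true(all(cs2$cohort$clamp_mi > 0))
  expect_true(all(cs2$cohort$glu30 != cs2$cohort$glu0))
  expect_lt(cor(cs2$cohort$exposure, cs2$cohort$clamp_mi), -0.5)
  igi <- compute_igi30(cs2$cohort$ins0, cs2$cohort$ins30,
                       cs2$cohort$glu0, cs2$cohort$glu30)
  expect_true(all(igi > 0))
})

test_that("two-stage Wald ratio recovers the simulated causal effect", {
  cfg <- sim_config(n_individuals = 5000, theta = -0.4, seed = 1)
  est <- vapply(1:25, function(i) wald_replicate(cfg, 1000 + i)$beta, numeric(1))
  expect_lt(abs(mean(est) + 0.4), 3 * sd(est) / sqrt(length(est)))
})

test_that("summary statistics reflect the generative marginal effects", {
  cfg <- sim_config(n_individuals = 1000, theta = -0.4, seed = 5)
  # zero-noise limit: betas equal the true marginal effects
  ex0 <- simulate_summary_stats(cfg, Inf, "exposure", seed = 1)
  ou0 <- simulate_summary_stats(cfg, Inf, "outcome", seed = 1)
  expect_true(all(ex0$se == 0))
  expect_equal(ou0$beta / ex0$beta, rep(-0.4, 10), tolerance = 1e-12)

  # consistency: ratio approaches theta as n_gwas grows
  ou <- simulate_summary_stats(cfg, 1e8, "outcome", seed = 7)
  expect_equal(ou$beta / ex0$beta, rep(-0.4, 10), tolerance = 0.05)

  # se follows 1 / sqrt(2 f (1-f) n)
  ou2 <- simulate_summary_stats(cfg, 10000, "outcome", seed = 2)
  expect_equal(ou2$se,
               1 / sqrt(2 * cfg$snps$raf * (1 - cfg$snps$raf) * 10000),
               tolerance = 1e-12)
})

test_that("relabelling effect/other alleles and negating beta is harmless", {
  cfg <- sim_config(n_individuals = 1000, seed = 5)
  ex <- simulate_summary_stats(cfg, 50000, "exposure", seed = 11)
  ou <- simulate_summary_stats(cfg, 50000, "outcome", seed = 12)
  flipped <- ou
  flipped$effect_allele <- ou$other_allele
  flipped$other_allele <- ou$effect_allele
  flipped$beta <- -ou$beta
  flipped$eaf <- 1 - ou$eaf
  p1 <- make_snp_pairs(ex, ou)
  p2 <- make_snp_pairs(ex, flipped)
  expect_equal(mr_ivw(p2)$estimate, mr_ivw(p1)$estimate, tolerance = 1e-12)
  expect_equal(summary_score_assoc(flipped)$beta,
               -summary_score_assoc(ou)$beta, tolerance = 1e-12)
})

test_that("missingness injection is Bernoulli at the requested rate", {
  g <- simulate_genotypes(rep(0.3, 10), n = 1000, seed = 3)
  expect_identical(inject_missingness(g, 0, seed = 1)$dosage, g$dosage)

  gm <- inject_missingness(g, 0.05, seed = 4)
  n_entries <- length(gm$dosage)
  mc_se <- sqrt(0.05 * 0.95 / n_entries)
  expect_lt(abs(mean(is.na(gm$dosage)) - 0.05), 3 * mc_se)

  # independence product: with 2 SNPs at rate 0.5, ~25% of rows stay complete
  g2 <- simulate_genotypes(rep(0.3, 2), n = 10000, seed = 5)
  g2m <- inject_missingness(g2, 0.5, seed = 6)
  frac_complete <- mean(rowSums(is.na(g2m$dosage)) == 0)
  expect_lt(abs(frac_complete - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))

  expect_error(inject_missingness(g, 1), class = "mrmetab_invalid_parameter")
})

test_that("batch-structured feature tables carry plate and drift effects", {
  cfg <- sim_config(n_individuals = 120, theta = c(-0.4, 0.2), seed = 8,
                    batch = list(n_plates = 4, plate_effect_sd = 1,
                                 drift_slope = 0.01))
  g <- simulate_genotypes(cfg$snps$raf, 120, seed = 8)
  cs <- simulate_cohort(g, cfg)
  ft <- simulate_feature_table(cs, cfg, n_noise_features = 5, duplicates = TRUE)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft$intensities), 240)  # duplicate injections
  expect_equal(ncol(ft$intensities), 7)
  expect_true(all(ft$intensities > 0))
  # injected plate variance is visible on the log scale
  lt <- log_transform(ft)
  fit <- lm(lt$intensities[, 1] ~ factor(lt$sample_meta$plate))
  expect_lt(anova(fit)[["Pr(>F)"]][1], 1e-6)
})
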