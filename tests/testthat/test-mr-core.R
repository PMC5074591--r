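test_that("Wald ratio and delta-method SE match hand evaluation", {
  m <- iv_assoc(-0.2, 0.05, role = "metabolite")
  e <- iv_assoc(0.5, 0.02, role = "exposure")
  r <- wald_ratio(m, e)
  expect_equal(r$beta, -0.4)
  expect_equal(r$se, 0.4 * sqrt(0.0625 + 0.0016), tolerance = 1e-12)
  expect_equal(r$se, 0.101272, tolerance = 1e-6)
  expect_equal(r$ci_lo, r$beta - qnorm(0.975) * r$se, tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-abs(r$beta / r$se)), tolerance = 1e-12)

  # self-ratio
  expect_equal(wald_ratio(e, e)$beta, 1)

  # scale equivariance: doubling the exposure association halves both
  e2 <- iv_assoc(1.0, 0.04, role = "exposure")
  r2 <- wald_ratio(m, e2)
  expect_equal(r2$beta, r$beta / 2, tolerance = 1e-12)
  expect_equal(r2$se, r$se / 2, tolerance = 1e-12)

  # degenerate numerators/denominators
  expect_error(wald_ratio(m, iv_assoc(0, 0.1, role = "exposure")),
               class = "mrmetab_weak_instrument")
  r0 <- wald_ratio(iv_assoc(0, 0.05, role = "metabolite"), e)
  expect_equal(r0$beta, 0)
  expect_equal(r0$se, 0.05 / 0.5)
  expect_equal(r0$flag, "zero_numerator_limit")
})

test_that("IV regression matches lm and tolerates constant covariates", {
  set.seed(20)
  n <- 300
  score <- rbinom(n, 20, 0.3)
  covars <- data.frame(age = rnorm(n, 70), sex = rbinom(n, 1, 0.5),
                       pc1 = rnorm(n))
  trait <- 0.1 * score + 0.05 * covars$age + rnorm(n)
  fit <- fit_iv_assoc(score, trait, covars)
  ref <- summary(lm(trait ~ score + age + sex + pc1, data = covars))$coefficients
  expect_equal(fit$beta, ref["score", 1], tolerance = 1e-10)
  expect_equal(fit$se, ref["score", 2], tolerance = 1e-10)

  # exact fit: se ~ 0
  exact <- fit_iv_assoc(score, 0.1 * score)
  expect_equal(exact$beta, 0.1, tolerance = 1e-12)
  expect_lt(exact$se, 1e-12)

  # constant covariate leaves the estimate unchanged
  fit2 <- fit_iv_assoc(score, trait, cbind(covars, k = 1))
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-12)

  # genuine collinearity errors, naming a column
  expect_error(fit_iv_assoc(score, trait, cbind(covars, age2 = covars$age * 2)),
               "age2", class = "mrmetab_structural_error")
})

test_that("null IV associations stay within 3 SEs almost always", {
  set.seed(21)
  n <- 200
  score <- rbinom(n, 20, 0.3)
  inside <- vapply(1:400, function(i) {
    f <- fit_iv_assoc(score, rnorm(n))
    abs(f$beta) < 3 * f$se
  }, logical(1))
  expect_gte(mean(inside), 0.99 - 3 * sqrt(0.01 * 0.99 / 400))
})

test_that("summary-score association reduces, pools and scales correctly", {
  one <- data.frame(beta = 0.3, se = 0.07)
  a1 <- summary_score_assoc(one)
  expect_equal(a1$beta, 0.3)
  expect_equal(a1$se, 0.07)

  two <- data.frame(beta = c(0.2, 0.4), se = c(0.1, 0.2))
  a2 <- summary_score_assoc(two)
  expect_equal(a2$beta, 0.24, tolerance = 1e-12)
  expect_equal(a2$se, 125^(-0.5), tolerance = 1e-12)
  expect_equal(a2$se, 0.089443, tolerance = 1e-5)

  # linearity in beta
  a3 <- summary_score_assoc(transform(two, beta = 3 * beta))
  expect_equal(a3$beta, 3 * a2$beta, tolerance = 1e-12)

  expect_error(summary_score_assoc(two[0, ]), class = "mrmetab_invalid_parameter")

  # zero-noise limit equals the exact linear-combination effect: equal SEs
  # give the plain mean of per-SNP effects (unweighted score, w = 1)
  betas <- c(0.1, 0.2, 0.3)
  lim <- summary_score_assoc(data.frame(beta = betas, se = rep(1e-8, 3)))
  expect_equal(lim$beta, mean(betas), tolerance = 1e-10)
})

test_that("fixed-effects meta-analysis obeys its algebraic laws", {
  r1 <- wald_ratio(iv_assoc(-0.2, 0.05, role = "metabolite"),
                   iv_assoc(0.5, 0.02, role = "exposure"))
  # single study: identity
  m1 <- meta_fixed(list(r1))
  expect_equal(m1$beta, r1$beta, tolerance = 1e-12)
  expect_equal(m1$se, r1$se, tolerance = 1e-12)

  # K identical studies shrink the SE by sqrt(K)
  m4 <- meta_fixed(list(r1, r1, r1, r1))
  expect_equal(m4$beta, r1$beta, tolerance = 1e-12)
  expect_equal(m4$se, r1$se / 2, tolerance = 1e-12)

  # hand-computed pooling
  mf <- meta_fixed(data.frame(beta = c(0.2, 0.4), se = c(0.1, 0.2)))
  expect_equal(mf$beta, 0.24, tolerance = 1e-12)
  expect_equal(mf$se, 0.089443, tolerance = 1e-5)

  # associativity: nested pooling equals flat pooling to 1e-12
  set.seed(22)
  studies <- lapply(1:6, function(i)
    data.frame(beta = rnorm(1), se = runif(1, 0.05, 0.3)))
  flat <- meta_fixed(do.call(rbind, studies))
  g1 <- meta_fixed(do.call(rbind, studies[1:3]))
  g2 <- meta_fixed(do.call(rbind, studies[4:6]))
  nested <- meta_fixed(data.frame(beta = c(g1$beta, g2$beta),
                                  se = c(g1$se, g2$se)))
  expect_equal(nested$beta, flat$beta, tolerance = 1e-12)
  expect_equal(nested$se, flat$se, tolerance = 1e-12)

  expect_error(meta_fixed(list()), class = "mrmetab_invalid_parameter")
})

test_that("meta-analysis agrees with metafor's fixed-effects model", {
  skip_if_not_installed("metafor")
  set.seed(23)
  b <- rnorm(5, -0.3, 0.2)
  s <- runif(5, 0.05, 0.3)
  mine <- meta_fixed(data.frame(beta = b, se = s))
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(mine$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(mine$se, as.numeric(ref$se), tolerance = 1e-8)
})

test_that("p-values reconstructed from printed estimate + CI behave", {
  # symmetric null-centred interval
  expect_equal(p_from_estimate_ci(0, -1, 1), 1)
  # reconstruction is the inverse of the normal CI construction
  r <- wald_ratio(iv_assoc(-0.2, 0.05, role = "metabolite"),
                  iv_assoc(0.5, 0.02, role = "exposure"))
  expect_equal(p_from_estimate_ci(r$beta, r$ci_lo, r$ci_hi), r$p,
               tolerance = 1e-10)
  expect_warning(p_from_estimate_ci(2, -1, 1), "outside")
  expect_error(p_from_estimate_ci(0, 1, -1), class = "mrmetab_invalid_parameter")
})
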