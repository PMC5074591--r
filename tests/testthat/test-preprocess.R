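# small hand-built feature table: 6 injections (3 duplicate pairs), 4 features
make_table <- function(intens, rt = c(40, 40, 30, 40), dup = TRUE) {
  n <- nrow(intens)
  sm <- data.frame(sample_id = paste0("I", seq_len(n)),
                   plate = rep(c("P1", "P2"), length.out = n),
                   order = seq_len(n))
  if (dup) sm$dup_pair <- rep(paste0("S", seq_len(n / 2)), each = 2)
  fm <- data.frame(id = paste0("F", seq_len(ncol(intens))),
                   mz = 100 + seq_len(ncol(intens)),
                   rt_seconds = rt[seq_len(ncol(intens))],
                   annotation = NA_character_)
  feature_table(intens, fm, sm)
}

test_that("log transform applies ln with the half-minimum pseudo-count rule", {
  x <- matrix(exp(1), 6, 4)
  t <- make_table(x)
  lt <- log_transform(t)
  expect_equal(unname(lt$intensities), matrix(1, 6, 4))

  expect_equal(unname(log_transform(make_table(matrix(1, 6, 4)))$intensities),
               matrix(0, 6, 4))

  # zeros replaced by half the feature's minimum positive value
  x2 <- matrix(4, 6, 4)
  x2[1, 2] <- 0
  lt2 <- log_transform(make_table(x2))
  expect_equal(lt2$intensities[1, 2], log(2))  # half of min positive (4) = 2
  # missing preserved
  x3 <- matrix(4, 6, 4); x3[2, 3] <- NA
  expect_true(is.na(log_transform(make_table(x3))$intensities[2, 3]))

  expect_error(feature_table(matrix(-1, 6, 4),
                             make_table(matrix(1, 6, 4))$feature_meta,
                             make_table(matrix(1, 6, 4))$sample_meta),
               class = "mrmetab_data_error")
})

test_that("ANOVA-type standardization removes plate offsets and drift", {
  set.seed(10)
  n <- 40
  base <- matrix(rnorm(n * 3, 10), n, 3)
  sm <- data.frame(sample_id = paste0("I", 1:n),
                   plate = rep(c("P1", "P2"), each = n / 2),
                   order = 1:n)
  fm <- data.frame(id = paste0("F", 1:3), mz = 1:3, rt_seconds = 60,
                   annotation = NA_character_)

  # no batch structure: output equals input (single plate, no drift signal)
  t0 <- feature_table(exp(base), fm, transform(sm, plate = "P1"))
  lt0 <- log_transform(t0)
  adj0 <- anova_standardize(lt0, drift = FALSE)
  expect_equal(adj0$intensities, lt0$intensities, tolerance = 1e-10)

  # injected +1/-1 plate offsets are removed: plate means equalized
  off <- ifelse(sm$plate == "P1", 1, -1)
  t1 <- feature_table(exp(base + off), fm, sm)
  adj1 <- anova_standardize(log_transform(t1))
  m1 <- colMeans(adj1$intensities[sm$plate == "P1", ])
  m2 <- colMeans(adj1$intensities[sm$plate == "P2", ])
  expect_equal(m1, m2, tolerance = 1e-8)

  # injected linear drift 0.01/injection: post-adjustment slope ~ 0
  t2 <- feature_table(exp(base + 0.01 * sm$order), fm, sm)
  adj2 <- anova_standardize(log_transform(t2))
  slope <- coef(lm(adj2$intensities[, 1] ~ sm$order))[2]
  expect_lt(abs(slope), 1e-10)

  # idempotence up to numerical tolerance
  adj1b <- anova_standardize(adj1)
  expect_equal(adj1b$intensities, adj1$intensities, tolerance = 1e-10)

  # single-sample factor level warns
  sm_bad <- transform(sm, plate = c("P9", sm$plate[-1]))
  expect_warning(anova_standardize(log_transform(feature_table(exp(base), fm, sm_bad))),
                 "single sample")
})

test_that("feature filtering applies RT, duplicate, outlier and count rules in order", {
  # duplicate injections (rows 1-2, 3-4, 5-6) agree closely for F1-F3,
  # disagree for F4
  pairsig <- c(5, 7, 9)
  base <- rep(pairsig, each = 2) + rep(c(0, 0.01), 3)
  x <- exp(cbind(F1 = base, F2 = base + 1, F3 = base - 1,
                 F4 = c(5, 9, 4, 8, 6, 2)))
  t <- log_transform(make_table(x, rt = c(40, 40, 30, 40)))

  res <- filter_features(t, min_rt = 35, min_dup_corr = 0.5)
  expect_false("F3" %in% res$table$feature_meta$id)  # RT 30 < 35
  expect_true("retention_time" %in% res$report$reason)
  expect_false("F4" %in% res$table$feature_meta$id)
  expect_true(any(res$report$reason == "duplicate_correlation"))
  # every removed feature accounted for exactly once
  removed <- setdiff(c("F3", "F4"), res$table$feature_meta$id)
  expect_equal(sort(res$report$feature_id[res$report$reason != "outlier_masked"]),
               sort(removed))

  # outlier masking: a value at mean + 4 SD becomes missing
  set.seed(12)
  y <- matrix(rnorm(200, 10, 1), 100, 2)
  mu <- mean(y[, 1]); s <- sd(y[, 1])
  y[1, 1] <- mu + 4 * s
  sm <- data.frame(sample_id = paste0("I", 1:100), plate = "P1", order = 1:100)
  fm <- data.frame(id = c("F1", "F2"), mz = 1:2, rt_seconds = 60,
                   annotation = NA_character_)
  tt <- feature_table(exp(y), fm, sm)
  tt <- log_transform(tt)
  res2 <- filter_features(tt, outlier_sd = 3)
  expect_true(is.na(res2$table$intensities[1, 1]))
  expect_true("F1" %in% res2$report$feature_id)

  # non-missing count applies after masking
  res3 <- filter_features(tt, outlier_sd = 3, min_nonmissing = 100)
  expect_false("F1" %in% res3$table$feature_meta$id)

  # all filters disabled: identity
  res4 <- filter_features(t)
  expect_identical(res4$table$intensities, t$intensities)
  expect_equal(nrow(res4$report), 0)

  # correlation filter without duplicates is a configuration error
  tnd <- log_transform(make_table(x, dup = FALSE))
  expect_error(filter_features(tnd, min_dup_corr = 0.5),
               class = "mrmetab_config_error")
})

test_that("standardization gives exact mean 0 / SD 1 and is idempotent", {
  m <- cbind(F1 = c(1, 2, 3), F2 = c(5, 6, 10))
  z <- standardize_features(m)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-14)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-14)
  expect_equal(standardize_features(z), z, tolerance = 1e-12)

  # constant feature dropped with warning
  m2 <- cbind(F1 = c(1, 2, 3), F2 = c(4, 4, 4))
  expect_warning(z2 <- standardize_features(m2), "zero-variance")
  expect_equal(colnames(z2), "F1")
})
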