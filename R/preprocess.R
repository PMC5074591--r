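#' Construct an LC/MS feature table
#'
#' @param intensities numeric matrix, samples in rows, features in columns;
#'   values must be non-negative or missing.
#' @param feature_meta data frame with columns `id`, `mz`, `rt_seconds`
#'   (>= 0) and optionally `annotation`.
#' @param sample_meta data frame with columns `sample_id`, `plate`, `order`,
#'   optionally `dup_pair` (identifier shared by duplicate injections).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(intensities, feature_meta, sample_meta) {
  intensities <- as.matrix(intensities)
  .assert(all(c("id", "rt_seconds") %in% names(feature_meta)),
          "feature_meta needs columns id and rt_seconds", "mrmetab_structural_error")
  .assert(all(c("sample_id", "plate", "order") %in% names(sample_meta)),
          "sample_meta needs columns sample_id, plate and order",
          "mrmetab_structural_error")
  .assert(nrow(sample_meta) == nrow(intensities) &&
            nrow(feature_meta) == ncol(intensities),
          "metadata dimensions do not match the intensity matrix",
          "mrmetab_structural_error")
  .assert(all(feature_meta$rt_seconds >= 0), "retention times must be >= 0",
          "mrmetab_data_error")
  .assert(all(intensities >= 0, na.rm = TRUE),
          "intensities must be non-negative or missing", "mrmetab_data_error")
  dimnames(intensities) <- list(sample_meta$sample_id, feature_meta$id)
  structure(list(intensities = intensities, feature_meta = feature_meta,
                 sample_meta = sample_meta, log_scale = FALSE),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d injections x %d features (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (isTRUE(x$log_scale)) "log" else "raw"))
  invisible(x)
}

#' Natural-log transform of feature intensities
#'
#' Zeros are replaced by half the feature's minimum positive value before
#' taking logs (a configurable pseudo-count; features with no positive value
#' stay missing). Negative intensities are a data error. Missing values are
#' preserved.
#'
#' @param t a [feature_table()].
#' @param zero_handling `"half_min"` (default pseudo-count rule) or
#'   `"error"`.
#' @return the table on the log scale.
#' @export
log_transform <- function(t, zero_handling = c("half_min", "error")) {
  zero_handling <- match.arg(zero_handling)
  .assert(inherits(t, "feature_table"), "t must be a feature_table")
  .assert(!isTRUE(t$log_scale), "table is already on the log scale",
          "mrmetab_data_error")
  x <- t$intensities
  .assert(all(x >= 0, na.rm = TRUE), "negative intensity encountered",
          "mrmetab_data_error")
  zero <- !is.na(x) & x == 0
  if (any(zero)) {
    if (zero_handling == "error") {
      stop(errorCondition("zero intensities present and zero_handling = 'error'",
                          class = c("mrmetab_data_error", "mrmetab_error")))
    }
    for (j in which(colSums(zero) > 0)) {
      pos <- x[, j][!is.na(x[, j]) & x[, j] > 0]
      x[zero[, j], j] <- if (length(pos)) min(pos) / 2 else NA_real_
    }
  }
  t$intensities <- log(x)
  t$log_scale <- TRUE
  t
}

#' ANOVA-type standardization of batch structure
#'
#' Per feature, fits a linear model of log-intensity on categorical batch
#' factors (plate by default, plus any other factor columns named) and a
#' linear acquisition-order drift term, and returns residuals plus the
#' feature's grand mean. After adjustment the per-plate means of each feature
#' agree to numerical precision, and re-applying the adjustment is a no-op.
#'
#' @param t a [feature_table()] on the log scale.
#' @param factors character vector of `sample_meta` columns treated as
#'   categorical batch factors (default `"plate"`).
#' @param drift include the linear injection-order term (default `TRUE`).
#' @return the adjusted table.
#' @export
anova_standardize <- function(t, factors = "plate", drift = TRUE) {
  .assert(inherits(t, "feature_table"), "t must be a feature_table")
  .assert(isTRUE(t$log_scale), "anova_standardize expects log-scale intensities",
          "mrmetab_data_error")
  .assert(all(factors %in% names(t$sample_meta)),
          "unknown batch factor column", "mrmetab_structural_error")
  terms <- lapply(factors, function(f) {
    lv <- factor(t$sample_meta[[f]])
    if (any(table(lv) == 1L)) {
      warning(sprintf("batch factor '%s' has a level with a single sample; its effect is estimated from that one observation", f))
    }
    lv
  })
  terms <- terms[vapply(terms, nlevels, integer(1)) >= 2L]  # constant factors add nothing
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(t$intensities))),
                        lapply(terms, function(lv) {
                          stats::model.matrix(~lv)[, -1, drop = FALSE]
                        })))
  if (drift) X <- cbind(X, order = t$sample_meta$order)

  Y <- t$intensities
  out <- Y
  cc_all <- !is.na(Y)
  for (j in seq_len(ncol(Y))) {
    obs <- cc_all[, j]
    y <- Y[obs, j]
    if (length(y) <= ncol(X)) next  # too few observations to adjust
    fit <- lm.fit(X[obs, , drop = FALSE], y)
    out[obs, j] <- fit$residuals + mean(y)
  }
  t$intensities <- out
  t
}

#' Feature and value filtering with a removal report
#'
#' Applies, in order: (1) removal of features with retention time below
#' `min_rt` seconds; (2) removal of features whose Pearson correlation
#' between duplicate injections (log scale, pairwise-complete) falls below
#' `min_dup_corr`; (3) masking of individual values further than
#' `outlier_sd` sample SDs from the feature mean; (4) removal of features
#' with fewer than `min_nonmissing` non-missing values (counted after
#' outlier masking). Each removal is recorded once in the report.
#'
#' @param t a [feature_table()].
#' @param min_rt minimum retention time in seconds, or `NULL` to skip.
#' @param min_dup_corr minimum inter-duplicate Pearson correlation, or
#'   `NULL`; requires `sample_meta$dup_pair`.
#' @param outlier_sd SD multiplier for value masking, or `NULL`.
#' @param min_nonmissing minimum non-missing count per feature, or `NULL`.
#' @return list with elements `table` (filtered) and `report` (data frame
#'   `feature_id`, `reason`, `value`; masked values are reported per feature
#'   with the count masked).
#' @export
filter_features <- function(t, min_rt = NULL, min_dup_corr = NULL,
                            outlier_sd = NULL, min_nonmissing = NULL) {
  .assert(inherits(t, "feature_table"), "t must be a feature_table")
  report <- data.frame(feature_id = character(), reason = character(),
                       value = numeric(), stringsAsFactors = FALSE)
  add <- function(ids, reason, values) {
    if (length(ids)) {
      report <<- rbind(report, data.frame(feature_id = ids, reason = reason,
                                          value = values, stringsAsFactors = FALSE))
    }
  }
  drop_features <- function(tab, ids) {
    keep <- !(tab$feature_meta$id %in% ids)
    tab$intensities <- tab$intensities[, keep, drop = FALSE]
    tab$feature_meta <- tab$feature_meta[keep, , drop = FALSE]
    tab
  }

  # 1. retention time
  if (!is.null(min_rt)) {
    bad <- t$feature_meta$id[t$feature_meta$rt_seconds < min_rt]
    add(bad, "retention_time",
        t$feature_meta$rt_seconds[match(bad, t$feature_meta$id)])
    t <- drop_features(t, bad)
  }

  # 2. duplicate correlation
  if (!is.null(min_dup_corr)) {
    .assert(!is.null(t$sample_meta$dup_pair),
            "duplicate-correlation filter requested but sample_meta has no dup_pair column",
            "mrmetab_config_error")
    pairs <- split(seq_len(nrow(t$intensities)), t$sample_meta$dup_pair)
    pairs <- pairs[vapply(pairs, length, integer(1)) == 2L]
    .assert(length(pairs) >= 3,
            "need at least 3 duplicate pairs to estimate correlations",
            "mrmetab_config_error")
    i1 <- vapply(pairs, `[`, integer(1), 1L)
    i2 <- vapply(pairs, `[`, integer(1), 2L)
    dc <- vapply(seq_len(ncol(t$intensities)), function(j) {
      suppressWarnings(cor(t$intensities[i1, j], t$intensities[i2, j],
                           use = "pairwise.complete.obs"))
    }, numeric(1))
    bad <- t$feature_meta$id[is.na(dc) | dc < min_dup_corr]
    add(bad, "duplicate_correlation", dc[match(bad, t$feature_meta$id)])
    t <- drop_features(t, bad)
  }

  # 3. outlier masking (sample SD, n-1 denominator)
  if (!is.null(outlier_sd)) {
    x <- t$intensities
    mu <- colMeans(x, na.rm = TRUE)
    s <- apply(x, 2, sd, na.rm = TRUE)
    lim_lo <- mu - outlier_sd * s
    lim_hi <- mu + outlier_sd * s
    mask <- sweep(x, 2, lim_lo, `<`) | sweep(x, 2, lim_hi, `>`)
    mask[is.na(mask)] <- FALSE
    n_masked <- colSums(mask)
    x[mask] <- NA
    t$intensities <- x
    add(t$feature_meta$id[n_masked > 0], "outlier_masked",
        n_masked[n_masked > 0])
  }

  # 4. non-missing count
  if (!is.null(min_nonmissing)) {
    nn <- colSums(!is.na(t$intensities))
    bad <- t$feature_meta$id[nn < min_nonmissing]
    add(bad, "non_missing", nn[match(bad, t$feature_meta$id)])
    t <- drop_features(t, bad)
  }

  list(table = t, report = report)
}

#' Standardize features to mean 0, SD 1
#'
#' Per-feature affine normalization computed on non-missing entries with the
#' sample SD (n-1 denominator). Zero-variance features are dropped with a
#' warning.
#'
#' @param x numeric matrix (samples x features) or a [feature_table()].
#' @return object of the same kind with standardized values.
#' @export
standardize_features <- function(x) {
  tab <- NULL
  if (inherits(x, "feature_table")) {
    tab <- x
    x <- x$intensities
  }
  .assert(is.matrix(x), "x must be a matrix or feature_table")
  nn <- colSums(!is.na(x))
  .assert(all(nn >= 2), "every feature needs at least 2 non-missing values",
          "mrmetab_data_error")
  s <- apply(x, 2, sd, na.rm = TRUE)
  const <- s == 0 | is.na(s)
  if (any(const)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(const), paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    s <- s[!const]
  }
  mu <- colMeans(x, na.rm = TRUE)
  z <- sweep(sweep(x, 2, mu, `-`), 2, s, `/`)
  if (!is.null(tab)) {
    keep <- colnames(z)
    tab$intensities <- z
    tab$feature_meta <- tab$feature_meta[tab$feature_meta$id %in% keep, , drop = FALSE]
    return(tab)
  }
  z
}
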