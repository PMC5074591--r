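#' Instrument-trait association container
#'
#' @param beta SD-unit trait change per score allele.
#' @param se standard error (> 0, except in exact-fit edge cases where it
#'   may be 0).
#' @param n sample size.
#' @param role `"exposure"` or `"metabolite"`.
#' @return object of class `iv_assoc`.
#' @export
iv_assoc <- function(beta, se, n = NA_integer_,
                     role = c("exposure", "metabolite")) {
  role <- match.arg(role)
  .assert(se >= 0, "se must be non-negative", "mrmetab_invalid_parameter")
  structure(list(beta = beta, se = se, n = n, role = role),
            class = "iv_assoc")
}

#' @export
print.iv_assoc <- function(x, ...) {
  cat(sprintf("<iv_assoc %s> beta %.4f (se %.4f), n = %s\n",
              x$role, x$beta, x$se, format(x$n)))
  invisible(x)
}

.mr_result <- function(beta, se, method, n_snps = NA_integer_,
                       study = NA_character_, flag = NA_character_) {
  z <- .z95()
  p <- if (se > 0) 2 * pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  out <- structure(list(beta = beta, se = se,
                        ci_lo = beta - z * se, ci_hi = beta + z * se,
                        p = p, method = method, n_snps = n_snps,
                        study = study, flag = flag),
                   class = "mr_result")
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result %s> beta %.4f (95%% CI %.4f to %.4f), p = %.4g%s\n",
              x$method, x$beta, x$ci_lo, x$ci_hi, x$p,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(beta = x$beta, se = x$se, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
             p = x$p, method = x$method, n_snps = x$n_snps, study = x$study,
             stringsAsFactors = FALSE)
}

#' Regression of a trait on a genetic risk score
#'
#' Ordinary least squares of the SD-unit trait on the score, adjusted for
#' covariates (by default the analysis uses age, sex, the first three
#' genetic principal components and cohort; pass them in `covariates`).
#' Constant covariate columns are dropped (they cannot affect the score
#' coefficient); any remaining rank deficiency is an error naming the
#' collinear columns.
#'
#' @param score numeric score vector or a `score_vector` from
#'   [build_score()] (excluded individuals are dropped).
#' @param trait SD-unit trait vector.
#' @param covariates optional data frame or matrix.
#' @param role stored on the result (`"exposure"` or `"metabolite"`).
#' @return an [iv_assoc()].
#' @export
fit_iv_assoc <- function(score, trait, covariates = NULL,
                         role = c("exposure", "metabolite")) {
  role <- match.arg(role)
  if (inherits(score, "score_vector")) score <- score$score
  .assert(length(score) == length(trait),
          "score and trait lengths disagree", "mrmetab_structural_error")
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.data.frame(covariates)
    # expand factors/characters to dummies
    C <- stats::model.matrix(~., data = C)[, -1, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, score = score, C)
  storage.mode(X) <- "double"
  cc <- complete.cases(X) & !is.na(trait)
  X <- X[cc, , drop = FALSE]
  y <- trait[cc]

  const <- apply(X[, -1, drop = FALSE], 2, function(col) var(col) == 0)
  if (any(const)) X <- X[, c(TRUE, !const), drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(errorCondition(
      sprintf("design is rank deficient; collinear column(s): %s",
              paste(bad, collapse = ", ")),
      class = c("mrmetab_structural_error", "mrmetab_error")))
  }
  fit <- lm.fit(X, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  k <- match("score", colnames(X))
  iv_assoc(beta = fit$coefficients[["score"]],
           se = sqrt(sigma2 * XtX_inv[k, k]),
           n = length(y), role = role)
}

#' Wald ratio causal estimator with delta-method standard error
#'
#' The causal effect of the exposure on the metabolite is the ratio of the
#' two instrument associations,
#' `beta_IV = beta_IV-Metabolite / beta_IV-Exposure`, with first-order
#' delta-method standard error
#' `SE_IV = |beta_IV| * sqrt((SE_m/beta_m)^2 + (SE_e/beta_e)^2)`.
#' The 95% CI and two-sided p use the normal approximation. A zero
#' metabolite association is handled as the analytic limit
#' `SE_IV = |SE_m / beta_e|` and flagged; a zero exposure association is a
#' weak-instrument error.
#'
#' @param m instrument-metabolite association ([iv_assoc()]).
#' @param e instrument-exposure association ([iv_assoc()]).
#' @param study optional study label.
#' @param n_snps number of score SNPs (metadata).
#' @return an `mr_result` with method `"wald"`.
#' @export
#' @examples
#' wald_ratio(iv_assoc(-0.2, 0.05, role = "metabolite"),
#'            iv_assoc(0.5, 0.02, role = "exposure"))
wald_ratio <- function(m, e, study = NA_character_, n_snps = NA_integer_) {
  .assert(inherits(m, "iv_assoc") && inherits(e, "iv_assoc"),
          "m and e must be iv_assoc objects")
  if (e$beta == 0) {
    stop(errorCondition("instrument-exposure association is zero (weak instrument)",
                        class = c("mrmetab_weak_instrument", "mrmetab_error")))
  }
  if (m$beta == 0) {
    se <- abs(m$se / e$beta)
    out <- .mr_result(0, se, "wald", n_snps, study,
                      flag = "zero_numerator_limit")
    return(out)
  }
  beta <- m$beta / e$beta
  se <- abs(beta) * sqrt((m$se / m$beta)^2 + (e$se / e$beta)^2)
  .mr_result(beta, se, "wald", n_snps, study)
}

#' Summary-statistic genetic score association
#'
#' Combines per-SNP GWAS effects into the association between an additive
#' (by default unweighted) allele score and the trait:
#' `alpha = sum(w b / s^2) / sum(w^2 / s^2)`, with
#' `se = 1 / sqrt(sum(w^2 / s^2))` — the summary-data analogue of
#' regressing the trait on the score, expressing SD-unit change per score
#' allele.
#'
#' @param stats `summary_stats` data frame (columns `beta`, `se`; effects
#'   harmonized to the risk alleles).
#' @param weights per-SNP weights (default all 1: unweighted score).
#' @param role stored on the result.
#' @return an [iv_assoc()].
#' @export
summary_score_assoc <- function(stats, weights = 1,
                                role = c("metabolite", "exposure")) {
  role <- match.arg(role)
  .assert(nrow(stats) > 0, "empty SNP set", "mrmetab_invalid_parameter")
  .assert(all(stats$se > 0), "all SNP SEs must be positive",
          "mrmetab_invalid_parameter")
  w <- rep_len(weights, nrow(stats))
  denom <- sum(w^2 / stats$se^2)
  alpha <- sum(w * stats$beta / stats$se^2) / denom
  iv_assoc(beta = alpha, se = 1 / sqrt(denom),
           n = if (!is.null(stats$n)) max(stats$n) else NA_integer_,
           role = role)
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools study-level causal estimates: `beta = sum(b_k / se_k^2) /
#' sum(1 / se_k^2)`, `se = 1 / sqrt(sum(1 / se_k^2))`, with normal CI and
#' p-value.
#'
#' @param results list of `mr_result` objects, or a data frame with columns
#'   `beta` and `se`.
#' @return an `mr_result` with method `"meta"`.
#' @export
meta_fixed <- function(results) {
  if (is.data.frame(results)) {
    b <- results$beta; s <- results$se
  } else if (inherits(results, "mr_result")) {
    b <- results$beta; s <- results$se
  } else {
    .assert(length(results) >= 1 && all(vapply(results, inherits, logical(1), "mr_result")),
            "results must be mr_result objects", "mrmetab_invalid_parameter")
    b <- vapply(results, `[[`, numeric(1), "beta")
    s <- vapply(results, `[[`, numeric(1), "se")
  }
  .assert(length(b) >= 1, "meta-analysis needs at least one study",
          "mrmetab_invalid_parameter")
  .assert(all(s > 0), "all study SEs must be positive",
          "mrmetab_invalid_parameter")
  w <- 1 / s^2
  .mr_result(sum(w * b) / sum(w), 1 / sqrt(sum(w)), "meta",
             n_snps = NA_integer_, study = "pooled")
}

#' Reconstruct a p-value from an estimate and its 95% CI
#'
#' Inverts the usual reporting convention: `se = (hi - lo) / (2 * 1.959964)`
#' and `p = 2 * (1 - Phi(|beta| / se))` under the normal approximation.
#' Warns when the point estimate lies outside the interval (asymmetric or
#' rounded CIs).
#'
#' @param beta point estimate.
#' @param lo,hi 95% confidence limits (`lo < hi`).
#' @return two-sided p-value.
#' @export
#' @examples
#' p_from_estimate_ci(-0.36, -0.68, -0.04)  # ~0.027
p_from_estimate_ci <- function(beta, lo, hi) {
  .assert(lo < hi, "lo must be below hi", "mrmetab_invalid_parameter")
  if (beta < lo || beta > hi) {
    warning("estimate lies outside its confidence interval (asymmetric or rounded CI)")
  }
  se <- (hi - lo) / (2 * .z95())
  2 * pnorm(-abs(beta / se))
}
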