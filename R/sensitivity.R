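#' Per-SNP exposure/outcome association pairs
#'
#' @param rsid SNP identifiers.
#' @param bx,sx per-allele exposure association and SE (SD-units).
#' @param by,sy per-allele outcome association and SE (SD-units).
#' @return data frame of class `snp_pairs`.
#' @export
snp_pairs <- function(rsid, bx, sx, by, sy) {
  .assert(all(sx > 0) && all(sy > 0), "sx and sy must be positive",
          "mrmetab_invalid_parameter")
  out <- data.frame(rsid = rsid, bx = bx, sx = sx, by = by, sy = sy,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_pairs", "data.frame")
  out
}

#' Pair two harmonized summary-statistic tables by rsid
#'
#' Joins exposure-role and outcome-role GWAS tables on `rsid` and aligns the
#' outcome effects to the exposure's effect allele, negating `by` when the
#' outcome table reports the opposite allele. Incompatible allele sets are
#' an error.
#'
#' @param exposure,outcome `summary_stats` data frames (columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`).
#' @return a [snp_pairs()] for the SNPs present in both tables.
#' @export
make_snp_pairs <- function(exposure, outcome) {
  common <- intersect(exposure$rsid, outcome$rsid)
  .assert(length(common) > 0, "no shared SNPs between the two tables",
          "mrmetab_structural_error")
  ex <- exposure[match(common, exposure$rsid), ]
  ou <- outcome[match(common, outcome$rsid), ]
  by <- ou$beta
  same <- toupper(ou$effect_allele) == toupper(ex$effect_allele) &
    toupper(ou$other_allele) == toupper(ex$other_allele)
  flipped <- toupper(ou$effect_allele) == toupper(ex$other_allele) &
    toupper(ou$other_allele) == toupper(ex$effect_allele)
  .assert(all(same | flipped),
          sprintf("allele sets incompatible for: %s",
                  paste(common[!(same | flipped)], collapse = ", ")),
          "mrmetab_harmonization_error")
  by[flipped] <- -by[flipped]
  snp_pairs(common, ex$beta, ex$se, by, ou$se)
}

#' Per-SNP Wald ratio estimates
#'
#' `theta_j = by_j / bx_j` with first-order standard error
#' `se_j = sy_j / |bx_j|`. SNPs with a zero exposure association are
#' excluded and listed in `attr(, "excluded")`.
#'
#' @param pairs a [snp_pairs()].
#' @return data frame with columns `rsid`, `estimate`, `se`.
#' @export
per_snp_ratios <- function(pairs) {
  keep <- pairs$bx != 0
  if (!any(keep)) {
    stop(errorCondition("all SNPs have zero exposure association",
                        class = c("mrmetab_weak_instrument", "mrmetab_error")))
  }
  out <- data.frame(rsid = pairs$rsid[keep],
                    estimate = pairs$by[keep] / pairs$bx[keep],
                    se = pairs$sy[keep] / abs(pairs$bx[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- pairs$rsid[!keep]
  out
}

.sens_result <- function(method, estimate, se, p, n_snps,
                         intercept = NULL, intercept_se = NULL,
                         intercept_p = NULL, q_statistic = NA_real_,
                         q_df = NA_integer_, q_p = NA_real_,
                         residual_scale = NA_real_) {
  structure(list(method = method, estimate = estimate, se = se, p = p,
                 n_snps = n_snps, intercept = intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p,
                 q_statistic = q_statistic, q_df = q_df, q_p = q_p,
                 residual_scale = residual_scale),
            class = "sens_result")
}

#' @export
print.sens_result <- function(x, ...) {
  cat(sprintf("<%s> estimate %.4f (se %.4f), p = %.4g", x$method,
              x$estimate, x$se, x$p))
  if (!is.null(x$intercept)) {
    cat(sprintf("; intercept %.4f (se %.4f), p = %.4g",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  if (!is.na(x$q_statistic)) {
    cat(sprintf("; Q = %.2f (df %d, p = %.3g)", x$q_statistic, x$q_df, x$q_p))
  }
  cat("\n")
  invisible(x)
}

#' Inverse-variance-weighted causal estimate from multiple SNPs
#'
#' `theta_IVW = sum(bx by / sy^2) / sum(bx^2 / sy^2)` with fixed-effect
#' standard error `(sum(bx^2 / sy^2))^(-1/2)`; algebraically identical to
#' inverse-variance pooling of the per-SNP Wald ratios. With
#' `scale = "multiplicative"` the SE is inflated by the residual scale
#' `max(1, sqrt(Q / (J - 1)))` when heterogeneity is present. Cochran's Q
#' against the IVW estimate is attached.
#'
#' @param pairs a [snp_pairs()] with at least 2 SNPs.
#' @param scale `"fixed"` (default) or `"multiplicative"` SE model.
#' @return a `sens_result` with method `"ivw"`.
#' @export
mr_ivw <- function(pairs, scale = c("fixed", "multiplicative")) {
  scale <- match.arg(scale)
  .assert(nrow(pairs) >= 1, "IVW needs at least 1 SNP",
          "mrmetab_invalid_parameter")
  w <- pairs$bx^2 / pairs$sy^2
  est <- sum(pairs$bx * pairs$by / pairs$sy^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (nrow(pairs) == 1L) {
    # single-SNP reduction: identical to that SNP's Wald ratio, no Q
    return(.sens_result("ivw", est, se, 2 * pnorm(-abs(est / se)), 1L))
  }
  q <- cochran_q(pairs, pooled = est)
  if (scale == "multiplicative") {
    se <- se * max(1, sqrt(q$Q / q$df))
  }
  .sens_result("ivw", est, se, 2 * pnorm(-abs(est / se)), nrow(pairs),
               q_statistic = q$Q, q_df = q$df, q_p = q$p,
               residual_scale = if (scale == "multiplicative")
                 max(1, sqrt(q$Q / q$df)) else 1)
}

#' MR-Egger regression
#'
#' Weighted least squares of the per-SNP outcome associations on the
#' exposure associations with an unconstrained intercept, weights
#' `1 / sy^2`, after re-orienting every pair so `bx > 0`. The slope is the
#' causal estimate; the intercept estimates average directional pleiotropy
#' (consistent under the InSIDE assumption). Standard errors use a
#' multiplicative residual scale bounded below by 1; p-values use the t
#' distribution with `J - 2` degrees of freedom (or the normal
#' approximation on request).
#'
#' @param pairs a [snp_pairs()] with at least 3 SNPs.
#' @param p_method `"t"` (default) or `"normal"`.
#' @param constrain_intercept fit with the intercept fixed at 0 (then the
#'   slope reproduces the IVW estimate; mainly for validation).
#' @return a `sens_result` with method `"egger"`.
#' @export
mr_egger <- function(pairs, p_method = c("t", "normal"),
                     constrain_intercept = FALSE) {
  p_method <- match.arg(p_method)
  .assert(nrow(pairs) >= 3 || constrain_intercept,
          "MR-Egger needs at least 3 SNPs (slope and intercept unidentifiable otherwise)",
          "mrmetab_invalid_parameter")
  flip <- sign(pairs$bx)
  flip[flip == 0] <- 1
  bx <- pairs$bx * flip
  by <- pairs$by * flip
  w <- 1 / pairs$sy^2
  X <- if (constrain_intercept) cbind(slope = bx) else
    cbind(intercept = 1, slope = bx)
  J <- nrow(pairs)
  df <- J - ncol(X)
  .assert(df >= 1, "not enough SNPs for residual degrees of freedom",
          "mrmetab_invalid_parameter")
  WX <- X * w
  XtWX <- crossprod(X, WX)
  V0 <- chol2inv(chol(XtWX))
  coefs <- drop(V0 %*% crossprod(WX, by))
  res <- by - drop(X %*% coefs)
  scale2 <- max(1, sum(w * res^2) / df)   # residual scale bounded below by 1
  se <- sqrt(diag(V0) * scale2)
  pfun <- if (p_method == "t") function(z) 2 * pt(-abs(z), df) else
    function(z) 2 * pnorm(-abs(z))
  k <- ncol(X)
  slope <- coefs[k]; slope_se <- se[k]
  if (constrain_intercept) {
    return(.sens_result("egger", slope, slope_se, pfun(slope / slope_se), J,
                        residual_scale = sqrt(scale2)))
  }
  .sens_result("egger", slope, slope_se, pfun(slope / slope_se), J,
               intercept = coefs[1], intercept_se = se[1],
               intercept_p = pfun(coefs[1] / se[1]),
               residual_scale = sqrt(scale2))
}

# profile negative log-likelihood in theta (ksi profiled out analytically):
# bx_j ~ N(ksi_j, sx_j^2), by_j ~ N(theta ksi_j, sy_j^2) independent.
.profile_nll <- function(theta, pairs) {
  sum((pairs$by - theta * pairs$bx)^2 / (pairs$sy^2 + theta^2 * pairs$sx^2)) / 2
}

#' Likelihood-based causal estimator
#'
#' Maximum-likelihood fit of the measurement model `bx_j ~ N(ksi_j, sx_j^2)`,
#' `by_j ~ N(theta * ksi_j, sy_j^2)` (independent across SNPs), which unlike
#' IVW accounts for sampling error in the exposure associations. The nuisance
#' per-SNP effects `ksi_j` are profiled out analytically, reducing the
#' problem to one-dimensional bounded optimization (run over three dispersed
#' bracketing intervals for robustness); the standard error comes from the
#' curvature of the profile log-likelihood at the maximum.
#'
#' @param pairs a [snp_pairs()] with at least 2 SNPs.
#' @param rho exposure-outcome sampling correlation; only the independent
#'   case `rho = 0` is supported.
#' @return a `sens_result` with method `"likelihood"`.
#' @export
mr_likelihood <- function(pairs, rho = 0) {
  .assert(nrow(pairs) >= 2, "likelihood method needs at least 2 SNPs",
          "mrmetab_invalid_parameter")
  .assert(rho == 0, "only independent sampling errors (rho = 0) are supported",
          "mrmetab_invalid_parameter")
  ratios <- per_snp_ratios(pairs)
  spread <- max(ratios$se, diff(range(ratios$estimate)), 1)
  center <- median(ratios$estimate)
  width <- 10 * spread
  # three dispersed bracketing intervals guard against local optima
  brackets <- list(c(center - width, center + width),
                   c(center - 3 * width, center),
                   c(center, center + 3 * width))
  best <- NULL
  for (b in brackets) {
    opt <- optimize(.profile_nll, interval = b, pairs = pairs,
                    tol = .Machine$double.eps^0.5)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  theta <- best$minimum
  if (abs(theta - center) > 0.999 * 3 * width) {
    stop(errorCondition(
      sprintf("likelihood optimizer did not converge (estimate %.3g at bracket boundary)", theta),
      class = c("mrmetab_optimizer_error", "mrmetab_error")))
  }
  # observed information from the profile curvature (central differences)
  h <- max(1e-5, 1e-5 * abs(theta))
  curv <- (.profile_nll(theta + h, pairs) - 2 * .profile_nll(theta, pairs) +
             .profile_nll(theta - h, pairs)) / h^2
  .assert(curv > 0, "non-positive curvature at the likelihood maximum",
          "mrmetab_optimizer_error")
  se <- 1 / sqrt(curv)
  .sens_result("likelihood", theta, se, 2 * pnorm(-abs(theta / se)),
               nrow(pairs))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((theta_j - theta_pooled)^2 / se_j^2)` over the per-SNP Wald
#' ratios, with `df = J - 1` and a chi-square p-value. By default the pooled
#' estimate is the IVW estimate.
#'
#' @param pairs a [snp_pairs()] with at least 2 SNPs.
#' @param pooled pooled causal estimate; default inverse-variance pooling of
#'   the per-SNP ratios.
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(pairs, pooled = NULL) {
  .assert(nrow(pairs) >= 2, "Cochran's Q needs at least 2 SNPs",
          "mrmetab_invalid_parameter")
  r <- per_snp_ratios(pairs)
  if (is.null(pooled)) {
    w <- 1 / r$se^2
    pooled <- sum(w * r$estimate) / sum(w)
  }
  Q <- sum((r$estimate - pooled)^2 / r$se^2)
  df <- nrow(r) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Scatter, funnel and leave-one-out diagnostics
#'
#' Produces plot-ready tables: the scatter table of per-SNP outcome vs
#' exposure associations (with SEs), the funnel table of per-SNP causal
#' estimate vs precision `1 / se`, and (optionally) leave-one-out IVW
#' re-estimates that surface single instruments driving the pooled result.
#'
#' @param pairs a [snp_pairs()].
#' @param leave_one_out include the leave-one-out table (needs >= 3 SNPs).
#' @return list with data frames `scatter`, `funnel` and (optionally)
#'   `leave_one_out`.
#' @export
mr_diagnostics <- function(pairs, leave_one_out = TRUE) {
  r <- per_snp_ratios(pairs)
  scatter <- data.frame(rsid = pairs$rsid, bx = pairs$bx, sx = pairs$sx,
                        by = pairs$by, sy = pairs$sy,
                        stringsAsFactors = FALSE)
  funnel <- data.frame(rsid = r$rsid, estimate = r$estimate,
                       precision = 1 / r$se, stringsAsFactors = FALSE)
  out <- list(scatter = scatter, funnel = funnel)
  if (leave_one_out && nrow(pairs) >= 3) {
    loo <- lapply(seq_len(nrow(pairs)), function(i) {
      fit <- mr_ivw(pairs[-i, , drop = FALSE])
      data.frame(excluded_rsid = pairs$rsid[i], estimate = fit$estimate,
                 se = fit$se, p = fit$p, stringsAsFactors = FALSE)
    })
    out$leave_one_out <- do.call(rbind, loo)
  }
  out
}

#' Per-SNP marginal trait associations
#'
#' Simple regression of a trait on each SNP dosage separately (intercept +
#' dosage), vectorized across SNPs with complete-case handling per SNP.
#' Produces the per-allele association tables consumed by the sensitivity
#' estimators.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @param trait numeric trait vector (SD-units).
#' @return data frame with columns `rsid`, `beta`, `se`, `n`.
#' @export
snp_trait_assoc <- function(g, trait) {
  G <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  .assert(nrow(G) == length(trait), "genotypes and trait lengths disagree",
          "mrmetab_structural_error")
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("snp%03d", seq_len(ncol(G)))
  if (!anyNA(G) && !anyNA(trait)) {
    n <- nrow(G)
    gc <- sweep(G, 2, colMeans(G))
    yc <- trait - mean(trait)
    sxx <- colSums(gc^2)
    beta <- colSums(gc * yc) / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    return(data.frame(rsid = ids, beta = beta, se = se, n = n,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(ncol(G)), function(j) {
    cc <- !is.na(G[, j]) & !is.na(trait)
    x <- G[cc, j]; y <- trait[cc]
    n <- sum(cc)
    sxx <- sum((x - mean(x))^2)
    beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
    rss <- sum((y - mean(y))^2) - beta^2 * sxx
    data.frame(rsid = ids[j], beta = beta,
               se = sqrt(max(rss, 0) / (n - 2) / sxx), n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
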