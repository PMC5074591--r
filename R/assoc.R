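#' Insulinogenic index over 0-30 minutes of an OGTT
#'
#' `IGI30 = (ins30 - ins0) / (glu30 - glu0)`: the insulin increment divided
#' by the glucose increment between 0 and 30 minutes. Samples with zero
#' glucose change are undefined and returned as `NA` (they are excluded, with
#' a logged reason, by [derive_outcomes()]).
#'
#' @param ins0,ins30 plasma insulin at 0 and 30 min.
#' @param glu0,glu30 plasma glucose at 0 and 30 min.
#' @return numeric vector of IGI30 values.
#' @export
#' @examples
#' compute_igi30(10, 60, 5.0, 7.5)  # 20
compute_igi30 <- function(ins0, ins30, glu0, glu30) {
  dglu <- glu30 - glu0
  out <- (ins30 - ins0) / dglu
  out[dglu == 0] <- NA_real_
  out
}

#' Disposition index
#'
#' The product of insulin sensitivity (clamp M/I) and the insulinogenic
#' index: beta-cell responsiveness adjusted for sensitivity. Log
#' transformation is applied downstream, only to positive values.
#'
#' @param clamp_mi clamp M/I (glucose disposal per unit insulin).
#' @param igi30 insulinogenic index.
#' @return numeric vector.
#' @export
compute_di <- function(clamp_mi, igi30) clamp_mi * igi30

#' Derive the physiologic outcome set
#'
#' Computes IGI30 and DI from OGTT and clamp measurements, their natural-log
#' transforms (samples with undefined IGI30 or non-positive IGI30/DI are
#' excluded from the log outcomes, with reasons recorded), and SD-unit
#' copies of clamp M/I, log-IGI30 and log-DI for analysis.
#'
#' @param pheno data frame with columns `ins0`, `ins30`, `glu0`, `glu30`,
#'   `clamp_mi` (all positive clamp values required).
#' @return data frame with the derived outcomes plus columns `clamp_mi_sd`,
#'   `log_igi30_sd`, `log_di_sd`; the exclusion log is in
#'   `attr(, "exclusions")`.
#' @export
derive_outcomes <- function(pheno) {
  need <- c("ins0", "ins30", "glu0", "glu30", "clamp_mi")
  .assert(all(need %in% names(pheno)),
          paste("pheno must contain", paste(need, collapse = ", ")),
          "mrmetab_structural_error")
  .assert(all(pheno$clamp_mi > 0, na.rm = TRUE), "clamp M/I must be positive",
          "mrmetab_data_error")
  igi <- compute_igi30(pheno$ins0, pheno$ins30, pheno$glu0, pheno$glu30)
  di <- compute_di(pheno$clamp_mi, igi)

  excl <- data.frame(row = integer(), reason = character(),
                     stringsAsFactors = FALSE)
  note <- function(rows, reason) {
    if (length(rows)) excl <<- rbind(excl, data.frame(row = rows, reason = reason,
                                                      stringsAsFactors = FALSE))
  }
  note(which(is.na(igi) & !is.na(pheno$glu0)), "zero_glucose_change")
  note(which(!is.na(igi) & igi <= 0), "non_positive_igi30")
  note(which(!is.na(di) & di <= 0 & igi > 0), "non_positive_di")

  log_igi <- log_di <- rep(NA_real_, length(igi))
  ok_igi <- !is.na(igi) & igi > 0
  ok_di <- !is.na(di) & di > 0
  log_igi[ok_igi] <- log(igi[ok_igi])
  log_di[ok_di] <- log(di[ok_di])

  z <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  out <- data.frame(pheno, igi30 = igi, di = di,
                    log_igi30 = log_igi, log_di = log_di,
                    clamp_mi_sd = z(pheno$clamp_mi),
                    log_igi30_sd = z(log_igi),
                    log_di_sd = z(log_di))
  attr(out, "exclusions") <- excl
  out
}

#' Benjamini-Hochberg FDR adjustment with rejection flags
#'
#' Step-up control of the false discovery rate: q-values are the standard
#' BH-adjusted p-values (via [stats::p.adjust()]); a hypothesis is rejected
#' when its q-value is at or below `q`.
#'
#' @param pvals p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return data frame with columns `p`, `fdr_q`, `reject`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.03, 0.9))  # four rejections
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(data.frame(p = numeric(), fdr_q = numeric(), reject = logical()))
  }
  .assert(all(pvals >= 0 & pvals <= 1), "p-values must lie in [0, 1]",
          "mrmetab_invalid_parameter")
  fdr_q <- p.adjust(pvals, method = "BH")
  data.frame(p = pvals, fdr_q = fdr_q, reject = fdr_q <= q)
}

#' Metabolome-wide association scan
#'
#' One ordinary least-squares fit per metabolite, with the (standardized)
#' metabolite as predictor and the SD-unit outcome as response, adjusted for
#' the supplied covariates (and BMI when requested). Two-sided p-values use
#' the t distribution with residual degrees of freedom; BH-FDR q-values are
#' appended over the scan. Rank-deficient designs skip the metabolite with a
#' logged reason. With `flip_sign = TRUE` coefficients are reported in the
#' direction of worsening insulin resistance / impaired secretion (i.e. the
#' sign of associations with clamp M/I and DI is flipped).
#'
#' @param metabolites samples x features matrix, standardized.
#' @param outcome SD-unit outcome vector.
#' @param covariates optional data frame or matrix of adjustment covariates.
#' @param bmi optional BMI vector, included when `adjust_bmi = TRUE`.
#' @param adjust_bmi include BMI in the model.
#' @param fdr_q FDR level for the rejection flags.
#' @param flip_sign report associations in the worsening direction.
#' @return data frame of class `assoc_scan` with one row per metabolite
#'   (`metabolite`, `beta`, `se`, `p`, `fdr_q`, `reject`, `n`,
#'   `adjusted_for_bmi`); skipped features are recorded in
#'   `attr(, "skipped")`.
#' @export
metabolome_scan <- function(metabolites, outcome, covariates = NULL,
                            bmi = NULL, adjust_bmi = FALSE, fdr_q = 0.05,
                            flip_sign = FALSE) {
  metabolites <- as.matrix(metabolites)
  .assert(nrow(metabolites) == length(outcome),
          "metabolite matrix and outcome length disagree",
          "mrmetab_structural_error")
  C <- NULL
  if (!is.null(covariates)) C <- as.matrix(as.data.frame(covariates))
  if (adjust_bmi) {
    .assert(!is.null(bmi), "adjust_bmi = TRUE requires a bmi vector",
            "mrmetab_config_error")
    C <- cbind(C, bmi = bmi)
  }
  base <- cbind(`(Intercept)` = rep(1, length(outcome)), C)
  storage.mode(base) <- "double"

  ids <- colnames(metabolites)
  if (is.null(ids)) ids <- sprintf("F%04d", seq_len(ncol(metabolites)))
  skipped <- character()
  res <- vector("list", ncol(metabolites))

  complete_base <- complete.cases(base) & !is.na(outcome)
  no_missing <- all(complete_base) && !anyNA(metabolites)

  if (no_missing) {
    # shared-design fast path: Frisch-Waugh partial regression
    qr_base <- qr(base)
    .assert(qr_base$rank == ncol(base),
            "covariate block is rank deficient", "mrmetab_structural_error")
    ry <- qr.resid(qr_base, outcome)
    RX <- qr.resid(qr_base, metabolites)
    sxx <- colSums(RX^2)
    sxy <- colSums(RX * ry)
    syy <- sum(ry^2)
    df <- length(outcome) - ncol(base) - 1L
    for (j in seq_along(ids)) {
      if (sxx[j] < 1e-12) {
        skipped <- c(skipped, ids[j]); res[[j]] <- NULL; next
      }
      beta <- sxy[j] / sxx[j]
      rss <- syy - beta^2 * sxx[j]
      se <- sqrt(max(rss, 0) / df / sxx[j])
      tval <- beta / se
      res[[j]] <- data.frame(metabolite = ids[j], beta = beta, se = se,
                             p = 2 * pt(-abs(tval), df), n = length(outcome),
                             stringsAsFactors = FALSE)
    }
  } else {
    for (j in seq_along(ids)) {
      x <- metabolites[, j]
      cc <- complete_base & !is.na(x)
      X <- cbind(base[cc, , drop = FALSE], metabolite = x[cc])
      y <- outcome[cc]
      if (sum(cc) <= ncol(X) || qr(X)$rank < ncol(X)) {
        skipped <- c(skipped, ids[j]); next
      }
      fit <- lm.fit(X, y)
      df <- sum(cc) - ncol(X)
      sigma2 <- sum(fit$residuals^2) / df
      XtX_inv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(sigma2 * XtX_inv[ncol(X), ncol(X)])
      beta <- fit$coefficients[["metabolite"]]
      res[[j]] <- data.frame(metabolite = ids[j], beta = beta, se = se,
                             p = 2 * pt(-abs(beta / se), df), n = sum(cc),
                             stringsAsFactors = FALSE)
    }
  }

  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  .assert(!is.null(out) && nrow(out) > 0, "no metabolite could be fitted",
          "mrmetab_data_error")
  if (flip_sign) out$beta <- -out$beta
  adj <- bh_fdr(out$p, q = fdr_q)
  out$fdr_q <- adj$fdr_q
  out$reject <- adj$reject
  out$adjusted_for_bmi <- adjust_bmi
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("assoc_scan", "data.frame")
  out
}
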