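#' Define an additive unweighted genetic risk score
#'
#' @param rsid SNP identifiers.
#' @param risk_allele,other_allele allele labels (must differ per SNP).
#' @param raf reference risk-allele frequency in (0, 1), used when a score
#'   SNP is absent from the genotype data (frequency imputation) and when
#'   resolving palindromic SNPs.
#' @param proxy_rsid,proxy_r2 optional proxy variant and its LD r-squared
#'   with the index SNP (must exceed 0.8 when used).
#' @param availability one of `"genotyped"`, `"proxy"`,
#'   `"frequency-imputed"` per SNP; defaults to `"genotyped"`.
#' @return data frame of class `score_definition`.
#' @export
score_definition <- function(rsid, risk_allele, other_allele, raf,
                             proxy_rsid = NA_character_, proxy_r2 = NA_real_,
                             availability = "genotyped") {
  .assert(all(raf > 0 & raf < 1), "raf must lie strictly in (0, 1)",
          "mrmetab_invalid_parameter")
  .assert(all(toupper(risk_allele) != toupper(other_allele)),
          "risk and other allele must differ", "mrmetab_invalid_parameter")
  used <- !is.na(proxy_rsid)
  .assert(all(proxy_r2[used] > 0.8),
          "proxies require LD r2 > 0.8", "mrmetab_invalid_parameter")
  out <- data.frame(rsid = rsid, risk_allele = toupper(risk_allele),
                    other_allele = toupper(other_allele), raf = raf,
                    proxy_rsid = proxy_rsid, proxy_r2 = proxy_r2,
                    availability = rep_len(availability, length(rsid)),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_definition", "data.frame")
  out
}

.is_palindromic <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}

#' Orient genotype dosages to the risk allele
#'
#' Flips dosages (`d -> 2 - d`) for SNPs whose file counts the other allele,
#' errors when allele sets are incompatible, and handles palindromic (A/T,
#' C/G) SNPs by comparing the counted-allele frequency in the file with the
#' declared risk-allele frequency: when either frequency is within
#' `ambiguity_window` of 0.5 the SNP cannot be oriented and is excluded with
#' a report, otherwise the orientation whose frequencies agree is chosen.
#'
#' @param g a [genotype_matrix()] with `counted_allele` (and, when available,
#'   `other_allele`) declared.
#' @param def a [score_definition()].
#' @param ambiguity_window half-width of the frequency zone around 0.5 in
#'   which palindromic SNPs are considered unresolvable (default 0.08).
#' @return list of class `harmonized_genotypes`: `genotypes` (oriented, with
#'   unresolvable SNPs dropped) and `report` (rsid, action, detail).
#' @export
harmonize_alleles <- function(g, def, ambiguity_window = 0.08) {
  .assert(inherits(g, "genotype_matrix"), "g must be a genotype_matrix")
  .assert(!is.null(g$counted_allele),
          "genotype matrix does not declare which allele its dosages count",
          "mrmetab_harmonization_error")
  report <- data.frame(rsid = character(), action = character(),
                       detail = character(), stringsAsFactors = FALSE)
  note <- function(rsid, action, detail = "") {
    report <<- rbind(report, data.frame(rsid = rsid, action = action,
                                        detail = detail, stringsAsFactors = FALSE))
  }
  drop <- character()
  for (i in seq_len(nrow(def))) {
    rs <- def$rsid[i]
    j <- match(rs, g$snp_ids)
    if (is.na(j)) next
    counted <- toupper(g$counted_allele[[j]])
    other <- if (!is.null(g$other_allele)) toupper(g$other_allele[[j]]) else NA
    risk <- def$risk_allele[i]
    oth <- def$other_allele[i]
    file_set <- sort(c(counted, if (!is.na(other)) other))
    def_set <- sort(c(risk, oth))
    if (!is.na(other) && !identical(file_set, def_set)) {
      stop(errorCondition(
        sprintf("allele sets incompatible for %s: file %s/%s vs definition %s/%s",
                rs, counted, other, risk, oth),
        class = c("mrmetab_harmonization_error", "mrmetab_error")))
    }
    if (.is_palindromic(risk, oth)) {
      f_file <- mean(g$dosage[, j], na.rm = TRUE) / 2
      if (abs(f_file - 0.5) < ambiguity_window ||
          abs(def$raf[i] - 0.5) < ambiguity_window) {
        note(rs, "excluded",
             sprintf("palindromic, unresolvable (file freq %.3f, definition raf %.3f)",
                     f_file, def$raf[i]))
        drop <- c(drop, rs)
        next
      }
      # orient by frequency agreement
      if (abs(f_file - def$raf[i]) <= abs(f_file - (1 - def$raf[i]))) {
        note(rs, "kept", "palindromic, frequency-matched as risk allele")
      } else {
        g$dosage[, j] <- 2L - g$dosage[, j]
        g$counted_allele[[j]] <- risk
        note(rs, "flipped", "palindromic, frequency-matched as other allele")
      }
      next
    }
    if (counted == risk) {
      note(rs, "kept", "already oriented")
    } else if (counted == oth) {
      g$dosage[, j] <- 2L - g$dosage[, j]
      tmp <- g$counted_allele[[j]]
      g$counted_allele[[j]] <- risk
      if (!is.null(g$other_allele)) g$other_allele[[j]] <- tmp
      note(rs, "flipped", "file counted the other allele")
    } else {
      stop(errorCondition(
        sprintf("allele sets incompatible for %s: counted %s vs definition %s/%s",
                rs, counted, risk, oth),
        class = c("mrmetab_harmonization_error", "mrmetab_error")))
    }
  }
  if (length(drop)) {
    keep <- !(g$snp_ids %in% drop)
    g$dosage <- g$dosage[, keep, drop = FALSE]
    g$snp_ids <- g$snp_ids[keep]
    g$counted_allele <- g$counted_allele[keep]
    if (!is.null(g$other_allele)) g$other_allele <- g$other_allele[keep]
  }
  structure(list(genotypes = g, report = report),
            class = "harmonized_genotypes")
}

#' Build an additive unweighted genetic risk score
#'
#' `score_i = sum_j dosage_ij` over the score SNPs, with three rules:
#' (a) SNPs absent from the genotype data contribute the constant
#' `2 * raf` (reference-frequency imputation) for every individual;
#' (b) an individual with exactly one missing genotyped value has it
#' replaced by that SNP's sample-mean dosage (computed from the
#' post-harmonization non-missing dosages in this cohort);
#' (c) individuals with more than one missing value are excluded.
#' Frequency-imputed SNPs are constants and do not count toward rule (c).
#' A warning names any SNP with call rate at or below `call_rate_warn`.
#'
#' @param g an oriented [genotype_matrix()] (e.g. from
#'   [harmonize_alleles()]).
#' @param def a [score_definition()].
#' @param call_rate_warn call-rate threshold for the warning (default 0.95).
#' @return data frame of class `score_vector` with columns `sample_id`,
#'   `score`, `n_missing`, `included`; the frequency-imputed constant is in
#'   `attr(, "imputed_constant")`.
#' @export
#' @examples
#' g <- genotype_matrix(rbind(c(2, 1, 0)), sample_ids = "S1",
#'                      snp_ids = c("rs1", "rs2", "rs3"))
#' def <- score_definition(c("rs1", "rs2", "rs3"), c("A", "A", "A"),
#'                         c("G", "G", "G"), raf = c(0.3, 0.3, 0.3))
#' build_score(g, def)$score  # 3
build_score <- function(g, def, call_rate_warn = 0.95) {
  if (inherits(g, "harmonized_genotypes")) g <- g$genotypes
  .assert(inherits(g, "genotype_matrix"), "g must be a genotype_matrix")
  present <- def$rsid[def$rsid %in% g$snp_ids]
  absent <- def$rsid[!(def$rsid %in% g$snp_ids)]
  .assert(length(present) > 0, "no score SNP present in the genotype data",
          "mrmetab_structural_error")
  D <- g$dosage[, present, drop = FALSE]

  call_rate <- colMeans(!is.na(D))
  low <- call_rate <= call_rate_warn
  if (any(low)) {
    warning(sprintf("call rate <= %.0f%% for SNP(s): %s",
                    100 * call_rate_warn,
                    paste(present[low], collapse = ", ")))
  }

  snp_mean <- colMeans(D, na.rm = TRUE)
  n_missing <- rowSums(is.na(D))
  imputed_constant <- sum(2 * def$raf[match(absent, def$rsid)])

  score <- rep(NA_real_, nrow(D))
  complete <- n_missing == 0L
  score[complete] <- rowSums(D[complete, , drop = FALSE])
  one <- which(n_missing == 1L)
  for (i in one) {
    row <- D[i, ]
    miss <- which(is.na(row))
    row[miss] <- snp_mean[miss]
    score[i] <- sum(row)
  }
  score <- score + imputed_constant
  included <- n_missing <= 1L
  score[!included] <- NA_real_

  out <- data.frame(sample_id = g$sample_ids, score = score,
                    n_missing = n_missing, included = included,
                    stringsAsFactors = FALSE)
  attr(out, "imputed_constant") <- imputed_constant
  attr(out, "snp_mean") <- snp_mean
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Summarize a score vector
#'
#' @param s a `score_vector` from [build_score()].
#' @param g optional [genotype_matrix()] for per-SNP missingness.
#' @return list with `n`, `n_excluded`, `mean`, `sd` of the score among
#'   included individuals, and `snp_missingness` when genotypes are given.
#' @export
score_summary <- function(s, g = NULL) {
  .assert(inherits(s, "score_vector"), "s must be a score_vector")
  inc <- s$included
  out <- list(n = nrow(s), n_excluded = sum(!inc),
              mean = mean(s$score[inc]), sd = sd(s$score[inc]))
  if (!is.null(g)) {
    .assert(inherits(g, "genotype_matrix"), "g must be a genotype_matrix")
    out$snp_missingness <- colMeans(is.na(g$dosage))
  }
  class(out) <- "score_summary"
  out
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("score over %d individuals (%d excluded): mean %.3f, SD %.3f\n",
              x$n, x$n_excluded, x$mean, x$sd))
  invisible(x)
}
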