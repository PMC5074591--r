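# TSV dialect shared by every table the package writes: UTF-8,
# tab-separated, '.' decimal, single header row, no quoting.

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path),
          "mrmetab_config_error")
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# parse a numeric column strictly, reporting 1-based data line numbers of
# malformed fields ("NA" and empty strings are genuine missing values)
.parse_numeric <- function(raw, column, path) {
  raw_chr <- as.character(raw)
  val <- suppressWarnings(as.numeric(raw_chr))
  bad <- which(is.na(val) & !(is.na(raw_chr) | raw_chr %in% c("NA", "")))
  if (length(bad)) {
    stop(errorCondition(
      sprintf("malformed numeric field in column '%s' of %s at line %s",
              column, path, paste(bad + 1L, collapse = ", ")),
      class = c("mrmetab_parse_error", "mrmetab_error")))
  }
  val
}

#' Read a GWAS summary-statistic table
#'
#' Expects a TSV with header columns `rsid`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `n`. Duplicated rsids are an error;
#' rows with missing SE are dropped with a warning; malformed numeric
#' fields raise a parse error naming the line.
#'
#' @param path file path.
#' @return a `summary_stats` data frame.
#' @export
read_summary_stats <- function(path) {
  x <- .read_tsv(path)
  need <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se", "n")
  .assert(all(need %in% names(x)),
          sprintf("summary-stat file must have columns: %s",
                  paste(need, collapse = ", ")),
          "mrmetab_parse_error")
  dup <- unique(x$rsid[duplicated(x$rsid)])
  if (length(dup)) {
    stop(errorCondition(sprintf("duplicated rsid(s): %s",
                                paste(dup, collapse = ", ")),
                        class = c("mrmetab_parse_error", "mrmetab_error")))
  }
  for (col in c("eaf", "beta", "se", "n")) {
    x[[col]] <- .parse_numeric(x[[col]], col, path)
  }
  drop <- is.na(x$se)
  if (any(drop)) {
    warning(sprintf("dropping %d record(s) with missing se: %s", sum(drop),
                    paste(x$rsid[drop], collapse = ", ")))
    x <- x[!drop, , drop = FALSE]
  }
  rownames(x) <- NULL
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Write a GWAS summary-statistic table
#' @param stats a `summary_stats` data frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_summary_stats <- function(stats, path) .write_tsv(stats, path)

#' Write / read genotype dosages (PLINK RAW-style headers)
#'
#' The genotype TSV has a `sample_id` column followed by one column per SNP
#' named `rsid_ALLELE`, where the suffix declares which allele the dosage
#' counts.
#'
#' @param g a [genotype_matrix()] with `counted_allele` declared.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(g, path) {
  .assert(inherits(g, "genotype_matrix"), "g must be a genotype_matrix")
  .assert(!is.null(g$counted_allele),
          "genotype matrix must declare counted alleles to be written",
          "mrmetab_config_error")
  df <- data.frame(sample_id = g$sample_ids, g$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- paste0(g$snp_ids, "_", g$counted_allele)
  .write_tsv(df, path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  x <- .read_tsv(path)
  .assert(names(x)[1] == "sample_id",
          "genotype file must start with a sample_id column",
          "mrmetab_parse_error")
  cols <- names(x)[-1]
  m <- regmatches(cols, regexec("^(.*)_([ACGT])$", cols))
  ok <- lengths(m) == 3L
  .assert(all(ok),
          sprintf("genotype columns without an _ALLELE suffix: %s",
                  paste(cols[!ok], collapse = ", ")),
          "mrmetab_parse_error")
  rsid <- vapply(m, `[`, character(1), 2L)
  allele <- vapply(m, `[`, character(1), 3L)
  dos <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  genotype_matrix(dos, sample_ids = x$sample_id, snp_ids = rsid,
                  counted_allele = allele)
}

#' Write / read a metabolite matrix with its feature sidecar
#'
#' The matrix TSV has features as columns and a `sample_id` first column;
#' feature metadata live in a sidecar TSV with columns `id`, `mz`,
#' `rt_seconds`, `annotation`.
#'
#' @param t a [feature_table()].
#' @param path matrix file path; the sidecar is `<path>.features.tsv` and
#'   the sample metadata `<path>.samples.tsv`.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(t, path) {
  .assert(inherits(t, "feature_table"), "t must be a feature_table")
  df <- data.frame(sample_id = rownames(t$intensities), t$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(t$feature_meta, paste0(path, ".features.tsv"))
  .write_tsv(t$sample_meta, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- .read_tsv(path)
  fm <- .read_tsv(paste0(path, ".features.tsv"))
  sm <- .read_tsv(paste0(path, ".samples.tsv"))
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$sample_id
  feature_table(m, fm, sm)
}

#' Write / read a score definition
#' @param def a [score_definition()].
#' @param path file path.
#' @return the path (write) or a `score_definition` (read).
#' @export
write_score_definition <- function(def, path) .write_tsv(def, path)

#' @rdname write_score_definition
#' @export
read_score_definition <- function(path) {
  x <- .read_tsv(path)
  need <- c("rsid", "risk_allele", "other_allele", "raf")
  .assert(all(need %in% names(x)),
          sprintf("score definition needs columns: %s",
                  paste(need, collapse = ", ")),
          "mrmetab_parse_error")
  score_definition(x$rsid, x$risk_allele, x$other_allele,
                   .parse_numeric(x$raf, "raf", path),
                   proxy_rsid = if (!is.null(x$proxy_rsid)) x$proxy_rsid else NA_character_,
                   proxy_r2 = if (!is.null(x$proxy_r2)) .parse_numeric(x$proxy_r2, "proxy_r2", path) else NA_real_,
                   availability = if (!is.null(x$availability)) x$availability else "genotyped")
}

#' Read a flat key-value run configuration
#'
#' One `key: value` pair per line; `#` starts a comment. Values are parsed
#' as logical (`true`/`false`), numeric when possible, otherwise character;
#' comma-separated values become vectors.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  .assert(file.exists(path), sprintf("config file not found: %s", path),
          "mrmetab_config_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    .assert(grepl(":", ln, fixed = TRUE),
            sprintf("malformed config line: '%s'", ln), "mrmetab_config_error")
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- lapply(parts, function(p) {
      if (tolower(p) %in% c("true", "false")) return(tolower(p) == "true")
      num <- suppressWarnings(as.numeric(p))
      if (!is.na(num)) num else p
    })
    out[[key]] <- unlist(parsed, use.names = FALSE)
  }
  out
}
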