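#' End-to-end synthetic analysis pipeline
#'
#' Runs the full two-stage analysis on synthetic data with known ground
#' truth: simulate genotypes, cohort, LC/MS-like feature intensities and
#' GWAS summary statistics; preprocess the feature table (log transform,
#' ANOVA-type batch standardization, retention-time / duplicate-correlation
#' / outlier / non-missing filtering, SD standardization); run the
#' metabolome-wide association scan against clamp M/I with FDR control;
#' build the genetic risk score; estimate Wald-ratio causal effects per
#' study; run the per-SNP sensitivity suite; and pool studies by
#' fixed-effects meta-analysis. All stage outputs are written as TSV in the
#' package's dialect, every threshold and seed is echoed to a plain-text log
#' with ISO-8601 timestamps, and the whole run is deterministic given the
#' seed.
#'
#' @param config a [sim_config()], or a named list of overrides for one
#'   (e.g. from [read_run_config()]): recognised keys are `n_individuals`,
#'   `theta`, `seed`, and the filter thresholds `min_rt`, `min_dup_corr`,
#'   `outlier_sd`, `min_nonmissing`, `fdr_q`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("mrmetab_run_")) {
  thresholds <- list(min_rt = 35, min_dup_corr = 0.5, outlier_sd = 3,
                     min_nonmissing = NULL, fdr_q = 0.05)
  if (inherits(config, "sim_config")) {
    cfg <- config
  } else {
    .assert(is.list(config), "config must be a sim_config or a named list",
            "mrmetab_config_error")
    for (k in names(thresholds)) {
      if (!is.null(config[[k]])) thresholds[[k]] <- config[[k]]
    }
    cfg_args <- config[names(config) %in% names(formals(sim_config))]
    cfg <- do.call(sim_config, cfg_args)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) {
    writeLines(sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                       sprintf(fmt, ...)), log_con)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      say("stage %s: ERROR %s", name, conditionMessage(e))
      stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                          class = c("mrmetab_stage_error", "mrmetab_error")))
    })
  }
  say("mrmetab %s", as.character(packageVersion("mrmetab")))
  say("seed: %d", cfg$seed)
  say("n_individuals: %d; n_snps: %d; theta: %s", cfg$n_individuals,
      nrow(cfg$snps), paste(signif(cfg$theta, 4), collapse = ", "))
  for (k in names(thresholds)) {
    say("threshold %s: %s", k,
        if (is.null(thresholds[[k]])) "disabled" else format(thresholds[[k]]))
  }

  paths <- list()

  # --- simulate -------------------------------------------------------
  sim <- stage("simulate", {
    g <- simulate_genotypes(cfg$snps$raf, cfg$n_individuals, seed = cfg$seed,
                            rsid = cfg$snps$rsid,
                            risk_allele = cfg$snps$risk_allele,
                            other_allele = cfg$snps$other_allele)
    cs <- simulate_cohort(g, cfg)
    ft <- simulate_feature_table(cs, cfg, duplicates = TRUE)
    paths$genotypes <- write_genotypes(g, file.path(out_dir, "genotypes.tsv"))
    paths$phenotypes <- .write_tsv(cs$cohort, file.path(out_dir, "phenotypes.tsv"))
    paths$features_raw <- write_feature_table(ft, file.path(out_dir, "features_raw.tsv"))
    list(genotypes = g, cohort_sim = cs, features = ft)
  })

  # --- preprocess -----------------------------------------------------
  prep <- stage("preprocess", {
    t1 <- log_transform(sim$features)
    t2 <- anova_standardize(t1)
    fl <- filter_features(t2, min_rt = thresholds$min_rt,
                          min_dup_corr = thresholds$min_dup_corr,
                          outlier_sd = thresholds$outlier_sd,
                          min_nonmissing = thresholds$min_nonmissing)
    say("preprocess: %d features removed/masked (see removal_report.tsv)",
        nrow(fl$report))
    paths$removal_report <- .write_tsv(fl$report,
                                        file.path(out_dir, "removal_report.tsv"))
    # collapse duplicate injections to one row per source sample
    tab <- fl$table
    src <- tab$sample_meta$source_sample
    if (is.null(src)) src <- tab$sample_meta$sample_id
    agg <- rowsum(tab$intensities, group = src, na.rm = TRUE) /
      rowsum((!is.na(tab$intensities)) * 1, group = src)
    agg[is.nan(agg)] <- NA
    agg <- agg[match(sim$cohort_sim$cohort$sample_id, rownames(agg)), , drop = FALSE]
    z <- standardize_features(agg)
    paths$features_processed <- .write_tsv(
      data.frame(sample_id = rownames(z), z, check.names = FALSE),
      file.path(out_dir, "features_processed.tsv"))
    z
  })

  # --- scan -----------------------------------------------------------
  scan_res <- stage("scan", {
    outc <- derive_outcomes(sim$cohort_sim$cohort)
    excl <- attr(outc, "exclusions")
    say("scan: %d sample(s) excluded from log outcomes", nrow(excl))
    res <- metabolome_scan(prep, outc$clamp_mi_sd,
                           covariates = outc[, "age", drop = FALSE],
                           fdr_q = thresholds$fdr_q, flip_sign = TRUE)
    say("scan: %d/%d metabolites significant at %.0f%% FDR",
        sum(res$reject), nrow(res), 100 * thresholds$fdr_q)
    paths$scan <- .write_tsv(res, file.path(out_dir, "scan_results.tsv"))
    res
  })

  # --- score ----------------------------------------------------------
  score <- stage("score", {
    def <- score_definition(cfg$snps$rsid, cfg$snps$risk_allele,
                            cfg$snps$other_allele, cfg$snps$raf)
    harm <- harmonize_alleles(sim$genotypes, def)
    sv <- build_score(harm, def)
    say("score: %d individual(s) excluded (>1 missing genotype)",
        sum(!sv$included))
    paths$score <- .write_tsv(sv, file.path(out_dir, "score.tsv"))
    sv
  })

  # --- mr: per-study Wald ratios on the first metabolite --------------
  mr_res <- stage("mr", {
    coh <- sim$cohort_sim$cohort
    met <- sim$cohort_sim$metabolites[, 1]
    covars <- coh[, c("age", "sex", "pc1", "pc2", "pc3")]
    per_study <- lapply(split(seq_len(nrow(coh)), coh$cohort), function(ix) {
      e <- fit_iv_assoc(score$score[ix], coh$exposure[ix], covars[ix, ],
                        role = "exposure")
      m <- fit_iv_assoc(score$score[ix], met[ix], covars[ix, ],
                        role = "metabolite")
      wald_ratio(m, e, study = coh$cohort[ix][1], n_snps = nrow(cfg$snps))
    })
    tab <- do.call(rbind, lapply(per_study, as.data.frame))
    paths$mr <- .write_tsv(tab, file.path(out_dir, "mr_results.tsv"))
    per_study
  })

  # --- sensitivity ----------------------------------------------------
  sens <- stage("sensitivity", {
    ex_stats <- simulate_summary_stats(cfg, n_gwas = 46186, role = "exposure",
                                       seed = cfg$seed + 3L)
    by <- snp_trait_assoc(sim$genotypes, sim$cohort_sim$metabolites[, 1])
    pairs <- snp_pairs(ex_stats$rsid, ex_stats$beta, ex_stats$se,
                       by$beta, by$se)
    fits <- list(ivw = mr_ivw(pairs), egger = mr_egger(pairs),
                 likelihood = mr_likelihood(pairs))
    tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(method = f$method, estimate = f$estimate, se = f$se, p = f$p,
                 intercept = if (is.null(f$intercept)) NA else f$intercept,
                 intercept_se = if (is.null(f$intercept_se)) NA else f$intercept_se,
                 intercept_p = if (is.null(f$intercept_p)) NA else f$intercept_p,
                 Q = f$q_statistic, Q_df = f$q_df, Q_p = f$q_p,
                 stringsAsFactors = FALSE)
    }))
    diag <- mr_diagnostics(pairs)
    paths$sensitivity <- .write_tsv(tab, file.path(out_dir, "sensitivity.tsv"))
    paths$scatter <- .write_tsv(diag$scatter, file.path(out_dir, "scatter.tsv"))
    paths$funnel <- .write_tsv(diag$funnel, file.path(out_dir, "funnel.tsv"))
    c(fits, list(diagnostics = diag))
  })

  # --- meta -----------------------------------------------------------
  meta <- stage("meta", {
    m <- meta_fixed(mr_res)
    paths$meta <- .write_tsv(as.data.frame(m), file.path(out_dir, "meta.tsv"))
    m
  })

  say("pipeline complete")
  invisible(list(config = cfg, thresholds = thresholds, paths = paths,
                 scan = scan_res, score = score, mr = mr_res,
                 sensitivity = sens, meta = meta, out_dir = out_dir,
                 log = log_path))
}
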