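Package: mrmetab
Title: Metabolome-Wide Association and Mendelian Randomization of Insulin
    Resistance and Insulin Secretion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage analysis pipeline for untargeted plasma metabolomics
    and glycemic physiology. Stage one derives insulin-sensitivity and
    insulin-secretion outcomes (euglycemic-clamp M/I, the insulinogenic index
    IGI30 and the disposition index) and runs a metabolome-wide linear
    association scan with Benjamini-Hochberg false-discovery-rate control.
    Stage two estimates causal effects of insulin resistance and impaired
    insulin secretion on metabolite levels by Mendelian randomization:
    additive unweighted genetic risk scores with allele harmonization,
    frequency imputation and missingness rules; the Wald ratio estimator with
    delta-method standard errors; summary-statistic genetic score association;
    inverse-variance-weighted fixed-effects meta-analysis; and a sensitivity
    suite (per-variant ratios, IVW, MR-Egger regression, a profile-likelihood
    estimator, Cochran's Q and scatter/funnel diagnostics). A synthetic-data
    module generates genotypes, cohorts, LC/MS-like feature tables and GWAS
    summary statistics with known causal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
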