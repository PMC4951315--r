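#' Pipeline configuration
#'
#' Collects the analysis choices shared by the [run_assoc()], [run_score()]
#' and [run_report()] stages.  The defaults are the conventional choices for
#' this kind of study: risk strata at score cutpoints 0.8 and 1.2 (a score
#' of 1 is the population-average risk), quartile stratification, LD pruning
#' at r-squared 0.5, family-wise alpha 0.05 Bonferroni-corrected over the
#' SNPs screened, and external (reference-panel) risk-allele frequencies
#' when the model provides them.
#'
#' @param cutpoints fixed score cutpoints for [assign_strata_fixed()].
#' @param quantile_k number of quantile strata.
#' @param ld_prune_r2 r-squared threshold for [build_score_model()].
#' @param alpha family-wise significance level.
#' @param maf_fisher minor-allele-frequency cutoff below which the Fisher
#'   exact test replaces the chi-square allelic test.
#' @param freq_source `"external"` or `"controls"`.
#' @param seed master RNG seed for stages that simulate.
#' @param out_dir optional directory; when set, stages write provenance-
#'   stamped TSVs there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cutpoints = c(0.8, 1.2), quantile_k = 4,
                            ld_prune_r2 = 0.5, alpha = 0.05,
                            maf_fisher = 0.05, freq_source = "external",
                            seed = 1, out_dir = NULL) {
  structure(list(cutpoints = cutpoints, quantile_k = quantile_k,
                 ld_prune_r2 = ld_prune_r2, alpha = alpha,
                 maf_fisher = maf_fisher, freq_source = freq_source,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

provenance_header <- function(config, extra = NULL) {
  c(sprintf("# genoscore %s",
            as.character(utils::packageVersion("genoscore"))),
    sprintf("# seed=%s cutpoints=%s quantile_k=%d ld_prune_r2=%g alpha=%g",
            config$seed, paste(config$cutpoints, collapse = ","),
            config$quantile_k, config$ld_prune_r2, config$alpha),
    extra)
}

write_stage_tsv <- function(df, path, config, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the per-SNP association stage
#'
#' Wraps [assoc_screen()]; when `config$out_dir` is set, writes `assoc.tsv`
#' in the Table-2-style column layout with a provenance header.
#'
#' @param gt a [genotype_table()] with status.
#' @param config a [pipeline_config()].
#' @return The `assoc_table`, invisibly printed.
#' @export
run_assoc <- function(gt, config = pipeline_config()) {
  res <- assoc_screen(gt, maf_fisher = config$maf_fisher,
                      alpha = config$alpha)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_tsv(as.data.frame(res),
                    file.path(config$out_dir, "assoc.tsv"), config,
                    sprintf("# bonferroni_threshold=%g",
                            attr(res, "bonferroni_threshold")))
  }
  res
}

#' Run the scoring stage
#'
#' Scores every subject with the model and summarizes the score
#' distribution per group (median and quartiles), with the Mann-Whitney
#' comparison and, when age is available, the age-adjusted logistic
#' p-value.
#'
#' @param gt a [genotype_table()].
#' @param model a [score_model()].
#' @param config a [pipeline_config()].
#' @return A list with `scores` (a `score_result`), `group_summary`, and
#'   `tests` (unadjusted and age-adjusted p-values).
#' @export
run_score <- function(gt, model, config = pipeline_config()) {
  missing_snps <- setdiff(model$entries$rsid, gt$snp_id)
  if (length(missing_snps))
    stop("genotype table lacks model SNPs: ",
         paste(missing_snps, collapse = ", "))
  sc <- predict(model, gt)
  out <- list(scores = sc)
  if (!is.null(gt$status)) {
    qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    qc <- qs(sc$score[sc$status == 1]); qu <- qs(sc$score[sc$status == 0])
    out$group_summary <- data.frame(
      group = c("case", "control"), n = c(sum(sc$status == 1),
                                          sum(sc$status == 0)),
      q1 = c(qc[1], qu[1]), median = c(qc[2], qu[2]), q3 = c(qc[3], qu[3]))
    mw <- group_compare(sc$score[sc$status == 1], sc$score[sc$status == 0],
                        method = "mann_whitney")
    out$tests <- list(mann_whitney_p = mw$p)
    if (!is.null(gt$age))
      out$tests$age_adjusted_p <- tryCatch(
        score_case_logistic(sc$score, sc$status, gt$age)$p,
        error = function(e) NA_real_)  # e.g. a degenerate constant score
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_tsv(as.data.frame(sc),
                    file.path(config$out_dir, "scores.tsv"), config)
  }
  out
}

#' Run the stratification and ROC reporting stage
#'
#' Produces the fixed-cutpoint stratum table, the quantile stratum table
#' (each with its Cochran-Armitage trend p), the top-versus-bottom stratum
#' OR for each, and the ROC summary with its confidence interval.
#'
#' @param scores a `score_result` with status (from [run_score()]'s
#'   `$scores` or [predict.snp_score_model()]).
#' @param config a [pipeline_config()].
#' @return A list of class `score_report` with `fixed`, `quantile`
#'   (`stratum_table`s), `fixed_or`, `quantile_or`, `roc`.
#' @export
run_report <- function(scores, config = pipeline_config()) {
  stopifnot(!is.null(scores$status))
  s <- scores$score; y <- scores$status
  fixed <- stratum_likelihood(assign_strata_fixed(s, config$cutpoints), y)
  quant <- stratum_likelihood(assign_strata_quantile(s, config$quantile_k), y)
  rep_ <- list(
    fixed = fixed, quantile = quant,
    fixed_or = tryCatch(stratum_or(fixed, ref = 1, target = nrow(fixed)),
                        error = function(e) NULL),
    quantile_or = tryCatch(stratum_or(quant, ref = 1, target = nrow(quant)),
                           error = function(e) NULL),
    roc = score_roc(s, y))
  class(rep_) <- "score_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_tsv(as.data.frame(fixed),
                    file.path(config$out_dir, "strata_fixed.tsv"), config,
                    sprintf("# trend_p=%.6g", attr(fixed, "trend_p")))
    write_stage_tsv(as.data.frame(quant),
                    file.path(config$out_dir, "strata_quantile.tsv"), config,
                    sprintf("# trend_p=%.6g", attr(quant, "trend_p")))
    write_stage_tsv(rep_$roc$curve,
                    file.path(config$out_dir, "roc_points.tsv"), config,
                    sprintf("# auc=%.6f ci=%.6f,%.6f", rep_$roc$auc,
                            rep_$roc$ci_low, rep_$roc$ci_high))
  }
  rep_
}

#' @export
print.score_report <- function(x, ...) {
  cat("Fixed-cutpoint strata:\n"); print(x$fixed)
  if (!is.null(x$fixed_or))
    cat(sprintf("  top vs bottom OR = %.2f [%.2f, %.2f]\n",
                x$fixed_or$or, x$fixed_or$ci_low, x$fixed_or$ci_high))
  cat("Quantile strata:\n"); print(x$quantile)
  if (!is.null(x$quantile_or))
    cat(sprintf("  top vs bottom OR = %.2f [%.2f, %.2f]\n",
                x$quantile_or$or, x$quantile_or$ci_low, x$quantile_or$ci_high))
  print(x$roc)
  invisible(x)
}

#' Run the whole pipeline
#'
#' Association screen, score-model building (risk-allele orientation and LD
#' pruning against the cohort), scoring, stratification and ROC, in one
#' call.
#'
#' @param gt a [genotype_table()] with status.
#' @param model optional prespecified [score_model()]; when `NULL` the model
#'   is built from the screen's significant SNPs (all SNPs if none pass)
#'   with control-estimated frequencies.
#' @param config a [pipeline_config()].
#' @return A list with `assoc`, `model`, `score`, `report`.
#' @export
run_all <- function(gt, model = NULL, config = pipeline_config()) {
  assoc <- run_assoc(gt, config)
  if (is.null(model)) {
    sel <- if (any(assoc$significant)) assoc[assoc$significant, ] else assoc
    model <- build_score_model(sel, gt = gt,
                               ld_threshold = config$ld_prune_r2)
  }
  sc <- run_score(gt, model, config)
  rep_ <- run_report(sc$scores, config)
  list(assoc = assoc, model = model, score = sc, report = rep_)
}
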