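#' Case/control allele-count table for one SNP
#'
#' Collapses additive dosages into the 2x2 table of counted-vs-other allele
#' counts in cases and controls.  Missing genotypes are excluded pairwise
#' (standard allelic-test practice).
#'
#' @param dosage numeric vector of 0/1/2/`NA` dosages of the counted allele.
#' @param status 0/1 vector, same length.
#' @return A 2x2 integer matrix with rows `case`, `control` and columns
#'   `counted`, `other`; allele frequencies are `cell / rowSums`.
#' @examples
#' allele_counts(c(2, 1, 0, 1), c(1, 1, 0, 0))
#' @export
allele_counts <- function(dosage, status) {
  stopifnot(length(dosage) == length(status))
  keep <- !is.na(dosage) & !is.na(status)
  dosage <- dosage[keep]; status <- status[keep]
  if (length(dosage) == 0)
    stop("no called genotypes for this SNP")
  if (!any(status == 1) || !any(status == 0))
    stop("both cases and controls are required")
  tab <- rbind(case = c(sum(dosage[status == 1]),
                        2 * sum(status == 1) - sum(dosage[status == 1])),
               control = c(sum(dosage[status == 0]),
                           2 * sum(status == 0) - sum(dosage[status == 0])))
  colnames(tab) <- c("counted", "other")
  storage.mode(tab) <- "integer"
  tab
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, enumerates the distribution of
#' the heterozygote count and returns the two-sided exact p-value: the sum of
#' probabilities of all heterozygote configurations no more probable than the
#' observed one.  A monomorphic SNP returns 1 by convention.  Mid-p variants
#' are not used.
#'
#' @param n_hom_minor,n_het,n_hom_major genotype counts.
#' @return The exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfect HWE proportions
#' hwe_exact_test(0, 100, 0)    # gross heterozygote excess
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  counts <- c(n_hom_minor, n_het, n_hom_major)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  n_a <- 2 * n_hom_minor + n_het           # rare-allele count
  n_b <- 2 * n_hom_major + n_het
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  if (n_a == 0) return(1)                   # monomorphic
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq(n_a %% 2, n_a, by = 2)
  # probabilities conditional on allele counts, by recurrence from h to h+2:
  # P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2)*(h+1))
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    naa <- (n_a - h) / 2; nbb <- (n_b - h) / 2
    lp[i] <- lp[i - 1] + log(4 * naa * nbb) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Allelic odds ratio with Woolf confidence interval
#'
#' The OR is the cross-product ratio of the case/control-by-allele table,
#' equivalently `(F_A/(1-F_A)) / (F_U/(1-F_U))` in allele frequencies.  The
#' 95% CI is `exp(log(OR) +/- 1.96 * SE)` with the Woolf standard error
#' `sqrt(sum(1/cell))`; the p-value is the chi-square test of the table
#' without continuity correction (the PLINK-style allelic test).  A zero cell
#' triggers the Haldane-Anscombe 0.5 correction, flagged in the result.
#'
#' @param table a 2x2 allele-count matrix as from [allele_counts()].
#' @return A list with `or`, `ci_low`, `ci_high`, `p`, and `corrected`
#'   (`TRUE` if the 0.5 correction was applied).
#' @examples
#' allelic_or_ci(rbind(case = c(249, 443), control = c(1107, 1153)))
#' @export
allelic_or_ci <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins of the allele table must be positive")
  corrected <- any(table == 0)
  tw <- table + if (corrected) 0.5 else 0
  or_ <- unname((tw[1, 1] * tw[2, 2]) / (tw[1, 2] * tw[2, 1]))
  se <- sqrt(sum(1 / tw))
  p <- suppressWarnings(stats::chisq.test(table, correct = FALSE)$p.value)
  list(or = or_, ci_low = or_ * exp(-1.959963984540054 * se),
       ci_high = or_ * exp(1.959963984540054 * se), p = p,
       corrected = corrected)
}

#' Allelic odds ratio from allele frequencies
#'
#' @param f_a,f_u counted-allele frequency in cases and controls.
#' @return `(f_a/(1-f_a)) / (f_u/(1-f_u))`.
#' @export
or_from_freqs <- function(f_a, f_u) {
  stopifnot(f_a > 0, f_a < 1, f_u > 0, f_u < 1)
  (f_a / (1 - f_a)) / (f_u / (1 - f_u))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than the observed table's,
#' conditional on the margins.  Used for the association test when the
#' minor-allele frequency is below the rare-allele cutoff.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided exact p-value.
#' @export
fisher_exact_p <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  stats::fisher.test(table)$p.value
}

#' Per-allele logistic association test
#'
#' Fits `status ~ dosage (+ covariates)` by binomial logistic regression and
#' reports the additive per-allele effect with its Wald p-value.
#'
#' @param dosage 0/1/2 dosage vector (`NA` dropped listwise).
#' @param status 0/1 vector.
#' @param covariates optional numeric matrix/data.frame of extra covariates.
#' @return A list with `beta`, `or`, `se`, `p`, `n`.
#' @export
logistic_assoc <- function(dosage, status, covariates = NULL) {
  dat <- data.frame(status = status, dosage = dosage)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$dosage)) < 2)
    stop("dosage is constant; no per-allele effect is estimable")
  fit <- stats::glm(status ~ ., data = dat, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    stop("logistic fit did not converge (possible separation); ",
         "use the exact/Fisher path")
  sm <- summary(fit)$coefficients
  list(beta = sm["dosage", 1], or = exp(sm["dosage", 1]),
       se = sm["dosage", 2], p = sm["dosage", 4], n = nrow(dat))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level.
#' @param m number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 10)
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Compare a continuous variable between cases and controls
#'
#' Two-sided t-test for approximately normal variables, or Mann-Whitney
#' U-test (Wilcoxon rank-sum on midranks with the tie-corrected normal
#' approximation) otherwise.
#'
#' @param values_case,values_control numeric vectors.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @return A list with `variable`, `stat`, `p`, `test`, and group summaries.
#' @export
group_compare <- function(values_case, values_control,
                          method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  values_case <- values_case[!is.na(values_case)]
  values_control <- values_control[!is.na(values_control)]
  if (length(values_case) == 0 || length(values_control) == 0)
    stop("both groups must be non-empty")
  if (method == "t_test") {
    if (length(values_case) < 2 || length(values_control) < 2)
      stop("t-test needs at least 2 values per group")
    ht <- stats::t.test(values_case, values_control)
  } else {
    ht <- stats::wilcox.test(values_case, values_control, exact = FALSE,
                             correct = FALSE)
  }
  list(variable = deparse(substitute(values_case)),
       stat = unname(ht$statistic), p = ht$p.value, test = method,
       mean_case = mean(values_case), mean_control = mean(values_control),
       median_case = stats::median(values_case),
       median_control = stats::median(values_control))
}

#' Age-adjusted association between a score and case status
#'
#' Logistic regression of status on the genetic score with age as covariate;
#' returns the Wald p-value of the score term.  A constant age column is
#' dropped with a warning (the model then degrades to the unadjusted test).
#'
#' @param scores per-subject genetic scores.
#' @param status 0/1 vector.
#' @param age ages in years.
#' @return A list with `beta`, `or`, `p` for the score term and `adjusted`
#'   (`FALSE` when age was constant and dropped).
#' @export
score_case_logistic <- function(scores, status, age) {
  keep <- stats::complete.cases(scores, status, age)
  scores <- scores[keep]; status <- status[keep]; age <- age[keep]
  adjusted <- TRUE
  if (length(unique(age)) < 2) {
    warning("age is constant; reporting the unadjusted test")
    adjusted <- FALSE
  }
  res <- if (adjusted) logistic_assoc(scores, status, data.frame(age = age))
         else logistic_assoc(scores, status)
  c(res[c("beta", "or", "p")], list(adjusted = adjusted))
}

#' Per-SNP association screen
#'
#' Runs the full per-SNP screen on a cohort: minor-allele frequencies in
#' cases (`f_a`) and controls (`f_u`), allelic OR with Woolf 95% CI, a
#' p-value from the chi-square allelic test — switched to Fisher's exact
#' test when the minor-allele frequency in the combined sample is below
#' `maf_fisher` — and the Hardy-Weinberg exact p in controls.  Frequencies
#' are reported for the minor allele in the combined sample, so ORs can fall
#' on either side of 1; orient them to risk alleles with
#' [build_score_model()].
#'
#' @param gt a [genotype_table()] with status.
#' @param maf_fisher rare-allele cutoff for the Fisher switch (default 0.05).
#' @param alpha,m_tests family-wise alpha and test count for the Bonferroni
#'   threshold column (`m_tests` defaults to the number of SNPs).
#' @return A data.frame of class `assoc_table`: one row per SNP with columns
#'   `rsid`, `minor`, `major`, `f_a`, `f_u`, `or`, `ci_low`, `ci_high`, `p`,
#'   `test`, `hwe_p_controls`, `significant`.
#' @export
assoc_screen <- function(gt, maf_fisher = 0.05, alpha = 0.05,
                         m_tests = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(gt$status)) stop("association screen needs case/control status")
  if (is.null(m_tests)) m_tests <- length(gt$snp_id)
  thr <- bonferroni_alpha(alpha, m_tests)
  rows <- lapply(seq_along(gt$snp_id), function(k) {
    g <- gt$dosage[, k]
    tab <- allele_counts(g, gt$status)
    # orient the table to the minor allele in the combined sample
    minor_is_counted <- sum(tab[, 1]) <= sum(tab[, 2])
    if (!minor_is_counted) tab <- tab[, 2:1]
    minor <- if (minor_is_counted) gt$counted_allele[k] else gt$other_allele[k]
    major <- if (minor_is_counted) gt$other_allele[k] else gt$counted_allele[k]
    f_a <- tab[1, 1] / sum(tab[1, ])
    f_u <- tab[2, 1] / sum(tab[2, ])
    maf <- sum(tab[, 1]) / sum(tab)
    orci <- allelic_or_ci(tab)
    use_fisher <- maf < maf_fisher
    p <- if (use_fisher) fisher_exact_p(tab) else orci$p
    gc <- g[gt$status == 0 & !is.na(g)]
    if (!minor_is_counted) gc <- 2 - gc
    hwe <- hwe_exact_test(sum(gc == 2), sum(gc == 1), sum(gc == 0))
    data.frame(rsid = gt$snp_id[k], minor = minor, major = major,
               f_a = f_a, f_u = f_u, or = orci$or, ci_low = orci$ci_low,
               ci_high = orci$ci_high, p = p,
               test = if (use_fisher) "fisher" else "chi2",
               hwe_p_controls = hwe, significant = p < thr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "m_tests") <- m_tests
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' @export
print.assoc_table <- function(x, digits = 3, ...) {
  cat("Per-SNP association screen (", nrow(x), " SNPs)\n", sep = "")
  cat(sprintf("Bonferroni threshold: %g (alpha %g / %d tests)\n",
              attr(x, "bonferroni_threshold"), attr(x, "alpha"),
              attr(x, "m_tests")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
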