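#' Assign scores to fixed risk strata
#'
#' Half-open binning at the given cutpoints: the first stratum is
#' `(-Inf, c1)`, interior strata are `[c_i, c_{i+1})`, and the top stratum
#' is `[c_k, Inf)`.  With the default cutpoints `(0.8, 1.2)` this is the
#' low / medium / high convention: a score of exactly 0.8 is medium and
#' exactly 1.2 is high.
#'
#' @param score numeric vector of genetic scores.
#' @param cutpoints strictly increasing cutpoints.
#' @param labels optional stratum labels (default `low`/`medium`/`high` for
#'   two cutpoints, else `S1..S(k+1)`).
#' @return An ordered factor of length `length(score)`.
#' @examples
#' assign_strata_fixed(c(0.79, 0.8, 1.19, 1.2), c(0.8, 1.2))
#' @export
assign_strata_fixed <- function(score, cutpoints = c(0.8, 1.2),
                                labels = NULL) {
  if (is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be strictly increasing")
  k <- length(cutpoints) + 1
  if (is.null(labels))
    labels <- if (k == 3) c("low", "medium", "high") else paste0("S", 1:k)
  idx <- findInterval(score, cutpoints) + 1L  # [c_i, c_{i+1}) convention
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Assign scores to quantile strata
#'
#' Splits the pooled cohort at its `k`-quantiles (quartiles for `k = 4`).
#' Boundaries are right-closed, so a score tied with a quantile boundary
#' goes to the lower group; with heavy ties group sizes can be unequal but
#' the assignment is deterministic.
#'
#' @param scores numeric vector.
#' @param k number of groups (>= 2).
#' @return An ordered factor (`Q1..Qk`).
#' @export
assign_strata_quantile <- function(scores, k = 4) {
  stopifnot(k >= 2, length(scores) >= k)
  if (length(unique(scores)) == 1)
    stop("all scores identical: quantile strata undefined")
  qs <- stats::quantile(scores, probs = seq_len(k - 1) / k, names = FALSE)
  idx <- .bincode(scores, breaks = c(-Inf, unique(qs), Inf), right = TRUE)
  labels <- paste0("Q", seq_len(length(unique(qs)) + 1))
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Per-stratum case counts, likelihood of disease, and trend test
#'
#' Tabulates cases and controls per ordered stratum and reports each
#' stratum's "likelihood" — the in-sample case proportion, as a percentage —
#' together with the Cochran-Armitage trend p-value across strata.  Note
#' this likelihood depends on the study's case:control sampling ratio; it is
#' not an absolute risk.
#'
#' @param strata ordered factor of stratum assignments.
#' @param status 0/1 case status, same length.
#' @return A data.frame of class `stratum_table` with columns `label`,
#'   `n_case`, `n_control`, `likelihood_pct`, and attributes `trend_chi2`,
#'   `trend_p`.
#' @export
stratum_likelihood <- function(strata, status) {
  stopifnot(length(strata) == length(status))
  strata <- as.factor(strata)
  n_case <- as.vector(table(strata[status == 1]))
  n_control <- as.vector(table(strata[status == 0]))
  tot <- n_case + n_control
  lik <- ifelse(tot > 0, 100 * n_case / tot, NA_real_)
  if (any(tot == 0)) warning("empty stratum: likelihood undefined there")
  out <- data.frame(label = levels(strata), n_case = n_case,
                    n_control = n_control, likelihood_pct = lik)
  ok <- tot > 0
  if (sum(ok) >= 2) {
    tr <- cochran_armitage_trend(cbind(n_case, n_control)[ok, , drop = FALSE])
    attr(out, "trend_chi2") <- tr$chi2
    attr(out, "trend_p") <- tr$p
  }
  class(out) <- c("stratum_table", "data.frame")
  out
}

#' @export
print.stratum_table <- function(x, ...) {
  print.data.frame(cbind(x[1:3],
                         likelihood_pct = round(x$likelihood_pct, 2)),
                   row.names = FALSE)
  if (!is.null(attr(x, "trend_p")))
    cat(sprintf("Trend: chi2 = %.3f (1 df), P-trend = %.3g\n",
                attr(x, "trend_chi2"), attr(x, "trend_p")))
  invisible(x)
}

#' Cochran-Armitage chi-square test for trend in proportions
#'
#' One-degree-of-freedom trend chi-square over ordered strata with integer
#' scores `0..k-1` (no continuity correction); for `k = 2` it coincides with
#' the uncorrected 2x2 chi-square test.  Invariant to affine rescaling of
#' the stratum scores.
#'
#' @param table k x 2 matrix of ordered counts, columns (cases, controls).
#' @param scores ordinal stratum scores (default `0:(k-1)`).
#' @return A list with `chi2` and two-sided `p`.
#' @export
cochran_armitage_trend <- function(table, scores = NULL) {
  table <- as.matrix(table)
  stopifnot(ncol(table) == 2, nrow(table) >= 2)
  if (any(colSums(table) == 0)) stop("a zero column total leaves no trend")
  if (is.null(scores)) scores <- seq_len(nrow(table)) - 1
  # prop.trend.test warns through its internal anova() on saturated tables
  ht <- suppressWarnings(stats::prop.trend.test(table[, 1], rowSums(table),
                                                score = scores))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Odds ratio between two strata
#'
#' Cross-product odds ratio of case/control counts in a target stratum
#' versus a reference stratum (e.g. high vs low genetic score).  A zero cell
#' triggers the 0.5 continuity correction, flagged in the result.
#'
#' @param table a `stratum_table` or a k x 2 matrix (cases, controls).
#' @param ref,target row labels or indices of the reference and target
#'   strata.
#' @return A list with `or`, `ci_low`, `ci_high` (Woolf) and `corrected`.
#' @export
stratum_or <- function(table, ref, target) {
  if (inherits(table, "stratum_table")) {
    m <- as.matrix(table[, c("n_case", "n_control")])
    rownames(m) <- table$label
  } else m <- as.matrix(table)
  if (is.character(ref)) ref <- match(ref, rownames(m))
  if (is.character(target)) target <- match(target, rownames(m))
  if (anyNA(c(ref, target))) stop("unknown stratum label")
  sub <- m[c(target, ref), ]
  if (any(rowSums(sub) == 0)) stop("empty stratum")
  allelic_or_ci(sub)[c("or", "ci_low", "ci_high", "corrected")]
}
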