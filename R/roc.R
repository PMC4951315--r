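#' AUC by the Mann-Whitney midrank estimator
#'
#' `AUC = P(score_case > score_control) + 0.5 P(tie)`, computed from
#' midranks; invariant under any strictly increasing transform of the
#' scores.
#'
#' @param scores numeric vector of scores (higher = more case-like).
#' @param status 0/1 vector.
#' @return The AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, status) {
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique score values (ties collapse into a
#' single step, so the trapezoidal area under the curve equals the midrank
#' AUC exactly).
#'
#' @inheritParams auc_mann_whitney
#' @return A data.frame with columns `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1), both coordinates non-decreasing; the trapezoidal AUC
#'   is attached as `attr(, "auc")`.
#' @export
roc_curve <- function(scores, status) {
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- status[o]
  last <- cumsum(rle(s)$lengths)        # one point per unique threshold
  tpr <- c(0, cumsum(y)[last] / n1)
  fpr <- c(0, cumsum(1 - y)[last] / n0)
  curve <- data.frame(fpr = fpr, tpr = tpr)
  attr(curve, "auc") <- sum(diff(fpr) * (utils::head(tpr, -1) +
                                           utils::tail(tpr, -1)) / 2)
  curve
}

#' Confidence interval for an AUC
#'
#' DeLong's paired-placement variance (default) or the Hanley-McNeil
#' binormal-free approximation; 95% by default.  A degenerate AUC of 0 or 1
#' yields a zero-width interval with a warning.
#'
#' @param scores,status the data the AUC was computed from.
#' @param method `"delong"` or `"hanley"`.
#' @param conf confidence level.
#' @return A list with `auc`, `ci_low`, `ci_high`, `se`, `method`.
#' @export
auc_ci <- function(scores, status, method = c("delong", "hanley"),
                   conf = 0.95) {
  method <- match.arg(method)
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  x <- scores[status == 1]; y <- scores[status == 0]
  n1 <- length(x); n0 <- length(y)
  if (n1 < 2 || n0 < 2) stop("need at least 2 subjects per class")
  auc <- auc_mann_whitney(scores, status)
  if (method == "delong") {
    # placements: V10_i = mean_j psi(x_i, y_j); V01_j symmetric
    psi_row <- function(xi) mean((xi > y) + 0.5 * (xi == y))
    psi_col <- function(yj) mean((x > yj) + 0.5 * (x == yj))
    v10 <- vapply(x, psi_row, numeric(1))
    v01 <- vapply(y, psi_col, numeric(1))
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  }
  if (auc %in% c(0, 1) && se == 0)
    warning("degenerate AUC of ", auc, ": zero-width interval")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = auc, ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se), se = se, method = method)
}

#' ROC evaluation of a genetic score
#'
#' Bundles the midrank AUC, its confidence interval and the ROC curve for a
#' scored cohort.
#'
#' @param scores,status as in [auc_mann_whitney()]; or pass a `score_result`
#'   from [predict.snp_score_model()] as `scores` (status taken from it).
#' @param method CI method, see [auc_ci()].
#' @param conf confidence level.
#' @return An object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `se`, `method`, `curve`, `n_case`, `n_control`.
#' @export
score_roc <- function(scores, status = NULL, method = c("delong", "hanley"),
                      conf = 0.95) {
  if (inherits(scores, "score_result")) {
    status <- scores$status
    scores <- scores$score
  }
  ci <- auc_ci(scores, status, method = method, conf = conf)
  out <- c(ci, list(curve = roc_curve(scores, status),
                    n_case = sum(status == 1, na.rm = TRUE),
                    n_control = sum(status == 0, na.rm = TRUE)))
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f [%.3f, %.3f] (%s; %d cases / %d controls)\n",
              x$auc, x$ci_low, x$ci_high, x$method, x$n_case, x$n_control))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x a `roc_result` from [score_roc()].
#' @param ... passed to [plot()].
#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l", xlab = "1 - specificity",
       ylab = "Sensitivity",
       main = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)", x$auc, x$ci_low,
                      x$ci_high), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
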