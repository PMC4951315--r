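#' Genotypic odds ratio under the multiplicative model
#'
#' Carrying two risk alleles gives `OR^2`, one gives `OR`, none gives 1.
#'
#' @param allelic_or per-allele odds ratio (> 0).
#' @param g risk-allele dosage in `{0, 1, 2}`.
#' @return `allelic_or ^ g`.
#' @examples
#' genotypic_or(1.41, 2)
#' @export
genotypic_or <- function(allelic_or, g) {
  stopifnot(all(allelic_or > 0))
  if (any(!is.na(g) & !(g %in% c(0, 1, 2))))
    stop("dosage must be 0, 1 or 2")
  allelic_or ^ g
}

#' Population-average genotypic risk
#'
#' The Hardy-Weinberg-genotype-frequency-weighted mean genotypic OR:
#' `p^2 OR^2 + 2 p (1-p) OR + (1-p)^2`.  Dividing a genotype's OR by this
#' quantity expresses its risk relative to the population average, which is
#' what makes the genetic score have population mean one.
#'
#' @param allelic_or per-allele odds ratio (> 0).
#' @param p risk-allele frequency, strictly inside `(0, 1)`.
#' @return The weighted mean genotypic OR.
#' @examples
#' population_average_risk(2, 0.5)   # 2.25
#' @export
population_average_risk <- function(allelic_or, p) {
  stopifnot(all(allelic_or > 0))
  if (any(p <= 0 | p >= 1)) stop("risk-allele frequency must be in (0, 1)")
  p^2 * allelic_or^2 + 2 * p * (1 - p) * allelic_or + (1 - p)^2
}

#' Relative risk of one genotype versus the population average
#'
#' @inheritParams population_average_risk
#' @inheritParams genotypic_or
#' @return `genotypic_or(allelic_or, g) / population_average_risk(allelic_or, p)`.
#' @examples
#' snp_relative_risk(2, 0.5, 2)   # 4 / 2.25
#' @export
snp_relative_risk <- function(allelic_or, p, g) {
  genotypic_or(allelic_or, g) / population_average_risk(allelic_or, p)
}

#' Construct a SNP score model
#'
#' A `snp_score_model` is the fitted object at the centre of the package: a
#' set of risk-oriented SNPs, each with its risk allele, per-allele odds
#' ratio and population risk-allele frequency.  [predict()][predict.snp_score_model]
#' applies it to a [genotype_table()] to produce per-subject genetic scores;
#' [simulate()][simulate.snp_score_model] draws synthetic case-control
#' cohorts from it.  Use [build_score_model()] to derive one from
#' association results (with re-orientation of protective alleles and LD
#' pruning); use `score_model()` directly when the entries are already
#' risk-oriented, as in a published table of risk SNPs.
#'
#' @param rsid SNP identifiers (unique).
#' @param risk_allele risk-allele base symbols.
#' @param allelic_or per-allele odds ratios; must all be >= 1 (re-orient
#'   protective SNPs first).
#' @param risk_allele_freq population risk-allele frequencies in `(0, 1)`.
#' @param other_allele optional non-risk allele symbols (needed to score
#'   tables whose counted allele is the non-risk one).
#' @param freq_source `"external"` (reference-panel frequencies) or
#'   `"controls"` (estimated from the cohort); recorded per SNP.
#' @param ld_prune_r2 the pairwise r-squared ceiling this model is asserted
#'   to satisfy.
#' @return An object of class `snp_score_model`.
#' @examples
#' m <- score_model(rsid = c("rs10054504", "rs7023329", "rs718314"),
#'                  risk_allele = c("T", "A", "G"),
#'                  allelic_or = c(1.41, 1.67, 1.79),
#'                  risk_allele_freq = c(0.35, 0.51, 0.25))
#' m
#' @export
score_model <- function(rsid, risk_allele, allelic_or, risk_allele_freq,
                        other_allele = NULL,
                        freq_source = "external", ld_prune_r2 = 0.5) {
  if (length(rsid) == 0) stop("a score model needs at least one SNP")
  entries <- data.frame(rsid = as.character(rsid),
                        risk_allele = toupper(as.character(risk_allele)),
                        allelic_or = as.numeric(allelic_or),
                        risk_allele_freq = as.numeric(risk_allele_freq),
                        other_allele = if (is.null(other_allele)) NA_character_
                                       else toupper(as.character(other_allele)),
                        freq_source = as.character(freq_source),
                        stringsAsFactors = FALSE)
  if (nrow(entries) == 0) stop("a score model needs at least one SNP")
  if (anyDuplicated(entries$rsid))
    stop("duplicate rsid in score model: ",
         entries$rsid[duplicated(entries$rsid)][1])
  if (any(entries$allelic_or < 1))
    stop("allelic_or < 1 for ", entries$rsid[entries$allelic_or < 1][1],
         ": score models are stated on the risk allele; invert the OR and ",
         "flip the allele (see build_score_model())")
  if (any(entries$risk_allele_freq <= 0 | entries$risk_allele_freq >= 1))
    stop("risk_allele_freq must be strictly inside (0, 1)")
  if (!all(entries$freq_source %in% c("external", "controls")))
    stop('freq_source must be "external" or "controls"')
  structure(list(entries = entries, ld_prune_r2 = ld_prune_r2),
            class = "snp_score_model")
}

#' Build a risk-oriented, LD-pruned score model from association results
#'
#' Takes per-SNP association output (an `assoc_table` from [assoc_screen()]
#' or any data.frame with columns `rsid`, `allele`/`minor`, `or` and
#' optionally `other`/`major` and `p`), re-orients protective entries — an
#' OR below 1 is inverted and its risk allele switched to the other allele —
#' and prunes SNP pairs in strong linkage disequilibrium so the model does
#' not double-count one signal.
#'
#' Of a pair with `r2 >= ld_threshold`, the SNP named in `keep` is retained;
#' without a designation the SNP with the smaller association p-value wins;
#' with no p-values available the pair is an error.
#'
#' @param assoc association results (see above).
#' @param freqs named vector of allele frequencies for each SNP's *effect*
#'   allele as listed in `assoc` (flipped to `1 - f` on re-orientation), or
#'   `NULL` to estimate risk-allele frequencies from the controls of `gt`.
#' @param gt optional [genotype_table()] used to estimate control
#'   frequencies and pairwise LD.
#' @param ld optional data.frame of precomputed pairs
#'   (`rsid_a`, `rsid_b`, `r2`); computed from `gt` when omitted.
#' @param ld_threshold r-squared at or above which a pair is pruned.
#' @param keep rsIDs to retain preferentially when pruning.
#' @return A [score_model()] whose retained entries all have `allelic_or >= 1`
#'   and pairwise `r2 < ld_threshold`.
#' @export
build_score_model <- function(assoc, freqs = NULL, gt = NULL, ld = NULL,
                              ld_threshold = 0.5, keep = NULL) {
  df <- as.data.frame(assoc)
  if (!"allele" %in% names(df) && "minor" %in% names(df)) df$allele <- df$minor
  if (!"other" %in% names(df) && "major" %in% names(df)) df$other <- df$major
  need <- c("rsid", "allele", "or")
  if (!all(need %in% names(df)))
    stop("assoc needs columns rsid, allele (or minor), or")
  if (any(df$or <= 0)) stop("odds ratios must be positive")
  if (is.null(df$other)) df$other <- NA_character_
  if (is.null(df$p)) df$p <- NA_real_

  freq_source <- "external"
  if (is.null(freqs)) {
    if (is.null(gt)) stop("supply effect-allele freqs or a genotype table")
    freq_source <- "controls"
    ctrl <- gt[gt$status == 0L, ]
    freqs <- vapply(df$rsid, function(r)
      mean(oriented_dosage(ctrl, r, df$allele[match(r, df$rsid)]),
           na.rm = TRUE) / 2, numeric(1))
  } else {
    freqs <- freqs[df$rsid]
    if (anyNA(freqs)) stop("freqs missing for: ",
                           paste(df$rsid[is.na(freqs)], collapse = ", "))
  }

  # risk-allele orientation: invert protective ORs, flip allele and frequency
  flip <- df$or < 1
  if (any(flip & is.na(df$other)))
    stop("cannot re-orient ", paste(df$rsid[flip & is.na(df$other)],
         collapse = ", "), ": other allele unknown")
  risk_allele <- ifelse(flip, df$other, df$allele)
  other_allele <- ifelse(flip, df$allele, df$other)
  allelic_or <- ifelse(flip, 1 / df$or, df$or)
  risk_freq <- ifelse(flip, 1 - freqs, freqs)

  # pairwise LD pruning
  if (is.null(ld) && !is.null(gt) && nrow(df) > 1) {
    pairs <- utils::combn(df$rsid, 2)
    ld <- data.frame(rsid_a = pairs[1, ], rsid_b = pairs[2, ],
                     r2 = apply(pairs, 2, function(pr)
                       as.numeric(ld_r2(oriented_dosage(gt, pr[1],
                                          df$allele[match(pr[1], df$rsid)]),
                                        oriented_dosage(gt, pr[2],
                                          df$allele[match(pr[2], df$rsid)])))))
  }
  drop <- character(0)
  if (!is.null(ld)) {
    hot <- ld[ld$r2 >= ld_threshold, , drop = FALSE]
    for (i in seq_len(nrow(hot))) {
      a <- hot$rsid_a[i]; b <- hot$rsid_b[i]
      if (!all(c(a, b) %in% df$rsid) || a %in% drop || b %in% drop) next
      if (a %in% keep && !b %in% keep) drop <- c(drop, b)
      else if (b %in% keep && !a %in% keep) drop <- c(drop, a)
      else {
        pa <- df$p[match(a, df$rsid)]; pb <- df$p[match(b, df$rsid)]
        if (is.na(pa) || is.na(pb))
          stop(sprintf(
            "LD pair %s / %s at r2 = %.2f >= %.2f: designate which to keep",
            a, b, hot$r2[i], ld_threshold))
        drop <- c(drop, if (pa <= pb) b else a)
      }
    }
  }
  sel <- !df$rsid %in% drop
  m <- score_model(rsid = df$rsid[sel], risk_allele = risk_allele[sel],
                   allelic_or = allelic_or[sel],
                   risk_allele_freq = risk_freq[sel],
                   other_allele = other_allele[sel],
                   freq_source = freq_source, ld_prune_r2 = ld_threshold)
  attr(m, "pruned") <- drop
  m
}

#' Genetic score for one or more subjects
#'
#' The score is the product over model SNPs of each genotype's relative risk
#' versus the population average: `OR^g / (p^2 OR^2 + 2p(1-p) OR + (1-p)^2)`.
#' A missing genotype contributes a factor of 1 (the population-average
#' risk) and is counted in `n_missing`; a subject missing every model SNP is
#' an error, since the score is then undefined.
#'
#' @param dosages a named risk-allele dosage vector for one subject, or a
#'   subjects-by-SNPs matrix with model rsIDs as column names.  Dosages must
#'   count the *risk* allele; [predict.snp_score_model()] handles
#'   orientation from a [genotype_table()].
#' @param model a [score_model()].
#' @return A data.frame of class `score_result` with columns `subject_id`,
#'   `score`, `n_missing`; the per-SNP relative-risk factors are in
#'   `attr(, "factors")`.
#' @examples
#' m <- score_model("rs1", "A", 2, 0.5)
#' genetic_score(c(rs1 = 2), m)$score   # 4 / 2.25
#' @export
genetic_score <- function(dosages, model) {
  stopifnot(inherits(model, "snp_score_model"))
  if (!is.matrix(dosages))
    dosages <- matrix(dosages, nrow = 1,
                      dimnames = list("S1", names(dosages)))
  e <- model$entries
  miss_snp <- setdiff(e$rsid, colnames(dosages))
  if (length(miss_snp))
    stop("dosages missing model SNPs: ", paste(miss_snp, collapse = ", "))
  g <- dosages[, e$rsid, drop = FALSE]
  if (any(!is.na(g) & !(g %in% c(0, 1, 2))))
    stop("dosage must be 0, 1, 2 or NA")
  denom <- population_average_risk(e$allelic_or, e$risk_allele_freq)
  factors <- sweep(outer(seq_len(nrow(g)), seq_len(ncol(g)),
                         function(i, j) e$allelic_or[j] ^ g[cbind(i, j)]),
                   2, denom, "/")
  n_missing <- rowSums(is.na(g))
  if (any(n_missing == ncol(g)))
    stop("subject(s) missing all model SNPs: score undefined: ",
         paste(rownames(g)[n_missing == ncol(g)], collapse = ", "))
  factors[is.na(factors)] <- 1
  dimnames(factors) <- dimnames(g)
  out <- data.frame(subject_id = rownames(g) %||% paste0("S", seq_len(nrow(g))),
                    score = apply(factors, 1, prod),
                    n_missing = as.integer(n_missing))
  rownames(out) <- NULL
  attr(out, "factors") <- factors
  class(out) <- c("score_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a cohort with a fitted SNP score model
#'
#' Orients each model SNP's risk allele against the table's counted/other
#' alleles (dosage `g` becomes `2 - g` when the table counts the non-risk
#' allele) and computes the multiplicative genetic score per subject.
#'
#' @param object a [score_model()].
#' @param newdata a [genotype_table()], or a risk-allele dosage matrix.
#' @param ... unused.
#' @return A `score_result` data.frame (see [genetic_score()]), with
#'   `status` and `age` columns when the table carries them.
#' @export
predict.snp_score_model <- function(object, newdata, ...) {
  e <- object$entries
  if (inherits(newdata, "genotype_table")) {
    dos <- vapply(seq_len(nrow(e)), function(k)
      oriented_dosage(newdata, e$rsid[k], e$risk_allele[k]),
      numeric(nrow(newdata$dosage)))
    dos <- matrix(dos, nrow = nrow(newdata$dosage),
                  dimnames = list(newdata$subject_id, e$rsid))
    res <- genetic_score(dos, object)
    if (!is.null(newdata$status)) res$status <- newdata$status
    if (!is.null(newdata$age)) res$age <- newdata$age
    res
  } else {
    genetic_score(newdata, object)
  }
}

#' @export
coef.snp_score_model <- function(object, ...) {
  stats::setNames(object$entries$allelic_or, object$entries$rsid)
}

#' @export
print.snp_score_model <- function(x, ...) {
  cat("SNP score model:", nrow(x$entries), "risk-oriented SNPs",
      sprintf("(LD pruned at r2 >= %.2f)\n", x$ld_prune_r2))
  print(x$entries, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarize a SNP score model
#'
#' Reports, per SNP, the three genotype relative-risk factors and the score
#' range attainable, plus the model-wide extremes.
#'
#' @param object a [score_model()].
#' @param ... unused.
#' @return A list with the per-SNP factor table and score range, printed
#'   compactly.
#' @export
summary.snp_score_model <- function(object, ...) {
  e <- object$entries
  denom <- population_average_risk(e$allelic_or, e$risk_allele_freq)
  fac <- cbind(g0 = 1 / denom, g1 = e$allelic_or / denom,
               g2 = e$allelic_or^2 / denom)
  rownames(fac) <- e$rsid
  out <- list(entries = e, factors = fac,
              score_range = c(min = prod(fac[, "g0"]),
                              max = prod(fac[, "g2"])))
  class(out) <- "summary.snp_score_model"
  out
}

#' @export
print.summary.snp_score_model <- function(x, ...) {
  cat("Per-genotype relative-risk factors (vs population average):\n")
  print(round(x$factors, 4))
  cat(sprintf("Attainable score range: [%.4f, %.4f]\n",
              x$score_range["min"], x$score_range["max"]))
  invisible(x)
}
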