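#' Pairwise linkage disequilibrium r-squared from unphased genotypes
#'
#' Estimates two-locus haplotype frequencies by the EM algorithm (phase is
#' ambiguous only for double heterozygotes) and returns
#' `r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))` where `D` is the haplotype-frequency
#' covariance.  Symmetric in its arguments and invariant to swapping allele
#' labels at either locus.
#'
#' @param dosage_a,dosage_b 0/1/2/`NA` dosage vectors; missing excluded
#'   pairwise.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @return r-squared in `[0, 1]`, with the estimated haplotype frequencies
#'   and `D` attached as attributes.
#' @examples
#' g <- rbinom(200, 2, 0.4)
#' ld_r2(g, g)  # 1: perfect LD with itself
#' @export
ld_r2 <- function(dosage_a, dosage_b, tol = 1e-10) {
  stopifnot(length(dosage_a) == length(dosage_b))
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  ga <- dosage_a[keep]; gb <- dosage_b[keep]
  if (length(ga) < 2) stop("need at least 2 pairwise-complete subjects")
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
    stop("monomorphic SNP: r2 undefined")
  n <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) n[i + 1, j + 1] <- sum(ga == i & gb == j)
  N <- sum(n)
  p_a <- mean(ga) / 2; p_b <- mean(gb) / 2
  # haplotypes: h11 = AB, h10 = Ab, h01 = aB, h00 = ab (A/B counted alleles)
  h11 <- p_a * p_b; h10 <- p_a * (1 - p_b); h01 <- (1 - p_a) * p_b
  h00 <- (1 - p_a) * (1 - p_b)
  ndh <- n[2, 2]  # double heterozygotes: phase unknown
  fixed11 <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  fixed10 <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  fixed01 <- 2 * n[1, 3] + n[2, 3] + n[1, 2]
  fixed00 <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  for (it in 1:1000) {
    denom <- h11 * h00 + h10 * h01
    w <- if (denom > 0) h11 * h00 / denom else 0.5
    new11 <- (fixed11 + w * ndh) / (2 * N)
    new10 <- (fixed10 + (1 - w) * ndh) / (2 * N)
    new01 <- (fixed01 + (1 - w) * ndh) / (2 * N)
    new00 <- (fixed00 + w * ndh) / (2 * N)
    delta <- max(abs(c(new11 - h11, new10 - h10, new01 - h01, new00 - h00)))
    h11 <- new11; h10 <- new10; h01 <- new01; h00 <- new00
    if (delta < tol) break
  }
  pa <- h11 + h10; pb <- h11 + h01
  D <- h11 - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  structure(min(max(r2, 0), 1), D = D,
            haplotypes = c(AB = h11, Ab = h10, aB = h01, ab = h00))
}

#' Haplotype frequencies achieving a target r-squared
#'
#' Given marginal counted-allele frequencies at two loci and a target
#' r-squared, solves `D = sign * sqrt(r2 * p_a(1-p_a) p_b(1-p_b))` and
#' returns the four haplotype frequencies `(AB, Ab, aB, ab)`.  Errors when
#' the triple is infeasible, reporting the maximum attainable r-squared for
#' those marginals.
#'
#' @param p_a,p_b counted-allele frequencies in `(0, 1)`.
#' @param r2 target r-squared in `[0, 1]`.
#' @param d_sign +1 (default) for positive D (counted alleles co-occur), -1
#'   for repulsion.
#' @return Named numeric vector `(AB, Ab, aB, ab)` summing to 1, whose
#'   recomputed r-squared equals `r2`.
#' @examples
#' haplotype_freqs_for_r2(0.3, 0.4, 0.58)
#' @export
haplotype_freqs_for_r2 <- function(p_a, p_b, r2, d_sign = 1) {
  stopifnot(p_a > 0, p_a < 1, p_b > 0, p_b < 1, r2 >= 0, r2 <= 1,
            d_sign %in% c(-1, 1))
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  D <- d_sign * sqrt(r2 * denom)
  h <- c(AB = p_a * p_b + D, Ab = p_a * (1 - p_b) - D,
         aB = (1 - p_a) * p_b - D, ab = (1 - p_a) * (1 - p_b) + D)
  if (any(h < -1e-12)) {
    d_max <- if (d_sign > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
             else min(p_a * p_b, (1 - p_a) * (1 - p_b))
    stop(sprintf(
      "infeasible: r2 = %.3f unreachable for freqs (%.3f, %.3f); max r2 = %.4f",
      r2, p_a, p_b, d_max^2 / denom))
  }
  pmax(h, 0)
}
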