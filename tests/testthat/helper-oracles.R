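# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the package implementations they check.

# two-sided Fisher p by complete enumeration of tables with fixed margins
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lp <- function(a) lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1)
  as <- max(0, c1 - (n - r1)):min(r1, c1)
  p <- exp(lp(as))
  sum(p[p <= exp(lp(tab[1, 1])) * (1 + 1e-7)])
}

# AUC by exhaustive case-control pair counting
auc_brute <- function(scores, status) {
  x <- scores[status == 1]; y <- scores[status == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# HWE exact p from first principles: P(h | n, n_minor) via multinomial /
# hypergeometric counting over all parity-compatible heterozygote counts
hwe_brute <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  if (min(na, 2 * n - na) == 0) return(1)
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  lp <- vapply(hs, function(h) {
    n1 <- (na - h) / 2; n2 <- (2 * n - na - h) / 2
    lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n2) +
      h * log(2) - (lchoose(2 * n, na))
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- match(nab, hs)
  sum(p[p <= p[obs] * (1 + 1e-9)])
}

# deterministic rank-based quantile grouping oracle (right-closed boundaries)
quantile_groups_brute <- function(x, k) {
  qs <- unique(stats::quantile(x, seq_len(k - 1) / k, names = FALSE))
  vapply(x, function(v) sum(v > qs) + 1L, integer(1))
}

# tiny hand-built cohort: 4 subjects x 2 SNPs
tiny_table <- function() {
  genotype_table(matrix(c(2, 1, 0, 1,
                          0, 1, 2, 2), 4, 2,
                        dimnames = list(paste0("P", 1:4), c("rs1", "rs2"))),
                 status = c(1, 1, 0, 0),
                 counted_allele = c("A", "T"), other_allele = c("G", "C"),
                 age = c(60, 55, 50, 48))
}
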