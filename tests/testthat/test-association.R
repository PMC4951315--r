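test_that("allele counts collapse dosages correctly and drop missing", {
  tab <- allele_counts(c(2, 1, 0, 0), c(1, 1, 1, 0))
  expect_equal(unname(tab["case", ]), c(3, 3))  # 3 counted of 6 case alleles
  tab2 <- allele_counts(c(2, 1, NA, 0), c(1, 1, 1, 0))
  expect_equal(sum(tab2["case", ]), 4)  # missing case excluded pairwise
  expect_error(allele_counts(c(1, 1), c(1, 1)), "cases and controls")
  expect_error(allele_counts(c(NA, NA), c(1, 0)), "genotypes")
})

test_that("reconstructed allele counts at study size match the frequency", {
  # 346 cases at F_A = 0.36 carry round(0.36 * 692) = 249 minor alleles
  n_minor <- round(0.36 * 2 * 346)
  expect_equal(n_minor, 249)
  g <- c(rep(2, 100), rep(1, 49), rep(0, 197))  # 249 of 692 alleles
  tab <- allele_counts(c(g, 0, 2), c(rep(1, 346), 0, 0))
  expect_equal(unname(tab["case", 1]), 249)
  expect_equal(round(unname(tab["case", 1] / sum(tab["case", ])), 2), 0.36)
})

test_that("HWE exact p agrees with first-principles enumeration", {
  cases <- list(c(25, 50, 25), c(0, 100, 0), c(3, 4, 100), c(10, 1, 2),
                c(1, 1, 1), c(7, 20, 40))
  for (cc in cases)
    expect_equal(hwe_exact_test(cc[1], cc[2], cc[3]),
                 hwe_brute(cc[1], cc[2], cc[3]), tolerance = 1e-9)
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 0.05)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-6)
  expect_identical(hwe_exact_test(0, 0, 50), 1)   # monomorphic convention
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("allelic OR and CI reproduce published screen rows from freqs", {
  # printed (F_A, F_U) pairs and the ORs they reconstruct to 2 dp
  expect_equal(round(or_from_freqs(0.375, 0.409), 2), 0.87)
  expect_equal(round(or_from_freqs(0.094, 0.087), 2), 1.09)
  expect_equal(or_from_freqs(0.3, 0.3), 1)
  # table path and frequency path agree to machine precision
  tab <- rbind(case = c(240, 460), control = c(1100, 1160))
  res <- allelic_or_ci(tab)
  expect_equal(res$or, or_from_freqs(240 / 700, 1100 / 2260),
               tolerance = 1e-12)
  expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
  # p matches the uncorrected chi-square of the table
  expect_equal(res$p, chisq.test(tab, correct = FALSE)$p.value)
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  res <- allelic_or_ci(rbind(c(10, 5), c(0, 12)))
  expect_true(res$corrected)
  expect_true(is.finite(res$or) && res$or > 0)
  expect_error(allelic_or_ci(rbind(c(0, 5), c(0, 12))), "margins")
})

test_that("Fisher exact p equals complete enumeration on small margins", {
  expect_equal(fisher_exact_p(rbind(c(1, 9), c(1, 9))), 1)
  expect_equal(fisher_exact_p(rbind(c(10, 0), c(0, 10))), 2 / choose(20, 10),
               tolerance = 1e-9)
  set.seed(42)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_p(tab), fisher_brute(tab), tolerance = 1e-7)
  }
})

test_that("rare-allele association at reconstructed counts is significant", {
  # 0.029 vs 0.016 minor-allele frequency at 346 / 1130 subjects
  a <- round(0.029 * 692); b <- round(0.016 * 2260)
  tab <- rbind(case = c(a, 692 - a), control = c(b, 2260 - b))
  expect_lt(fisher_exact_p(tab), 0.05)
})

test_that("logistic association recovers a null and a simulated effect", {
  set.seed(5)
  g <- rbinom(1500, 2, 0.4)
  y <- rbinom(1500, 1, 0.25)
  null_fit <- logistic_assoc(g, y)
  expect_equal(null_fit$or, 1, tolerance = 0.3)
  # known per-allele effect
  y2 <- rbinom(1500, 1, plogis(-1.5 + g * log(1.67)))
  fit <- logistic_assoc(g, y2)
  expect_equal(fit$or, 1.67, tolerance = 0.35)
  expect_lt(fit$p, 0.01)
  expect_error(logistic_assoc(rep(1, 100), rbinom(100, 1, 0.5)), "constant")
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("ld_r2 is 1 for identical SNPs, ~0 under independence, symmetric", {
  set.seed(9)
  g <- rbinom(500, 2, 0.3)
  expect_equal(as.numeric(ld_r2(g, g)), 1, tolerance = 1e-6)
  a <- rbinom(10000, 2, 0.3); b <- rbinom(10000, 2, 0.45)
  expect_lt(as.numeric(ld_r2(a, b)), 0.01)
  expect_equal(as.numeric(ld_r2(a, b)), as.numeric(ld_r2(b, a)),
               tolerance = 1e-10)
  # allele-label swap invariance at either locus
  expect_equal(as.numeric(ld_r2(2 - a, b)), as.numeric(ld_r2(a, b)),
               tolerance = 1e-8)
  expect_error(ld_r2(rep(0, 50), rbinom(50, 2, 0.5)), "monomorphic")
})

test_that("ld_r2 recovers the target r2 of a generative haplotype pair", {
  h <- haplotype_freqs_for_r2(0.3, 0.4, 0.58)
  set.seed(31)
  n <- 20000
  hap <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = h), ncol = 2)
  ga <- rowSums(hap <= 2)
  gb <- rowSums(hap == 1 | hap == 3)
  expect_equal(as.numeric(ld_r2(ga, gb)), 0.58, tolerance = 0.03)
})

test_that("group comparisons behave under identity, shift and label swap", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(group_compare(x, x, "t_test")$p, 1)
  set.seed(13)
  ctrl <- rnorm(1000); case <- rnorm(300, 0.4)
  res <- group_compare(case, ctrl, "mann_whitney")
  expect_lt(res$p, 0.001)
  expect_equal(group_compare(ctrl, case, "mann_whitney")$p, res$p,
               tolerance = 1e-12)
  expect_error(group_compare(1, c(1, 2), "t_test"), "at least 2")
})

test_that("age-adjusted score association finds a real effect and warns on
           constant age", {
  set.seed(17)
  n <- 1476
  score <- rlnorm(n, 0, 0.5)
  age <- rnorm(n, 52, 10)
  y <- rbinom(n, 1, plogis(-2 + log(2) * score))
  res <- score_case_logistic(score, y, age)
  expect_lt(res$p, 1e-4)
  expect_true(res$adjusted)
  expect_warning(res2 <- score_case_logistic(score, y, rep(50, n)),
                 "constant")
  expect_false(res2$adjusted)
})

test_that("the per-SNP screen flags only true effects at the Bonferroni
           threshold", {
  fx <- make_fixture("null", n_case = 80, n_control = 250, seed = 23)
  res <- assoc_screen(fx$genotypes)
  expect_equal(attr(res, "bonferroni_threshold"), 0.05 / 3)
  expect_s3_class(res, "assoc_table")
  expect_true(all(res$f_a >= 0 & res$f_a <= 0.5 + 1e-9))
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high))
  # rare SNP routes to Fisher: force one by subsetting a rare simulated SNP
  cfg <- sim_config(data.frame(rsid = "rsRare", risk_allele_freq = 0.02,
                               allelic_or = 1), n_case = 50, n_control = 150)
  gt <- simulate_case_control(cfg, seed = 3)
  res2 <- assoc_screen(gt)
  expect_equal(res2$test, "fisher")
})
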