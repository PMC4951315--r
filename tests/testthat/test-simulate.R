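test_that("haplotype frequencies hit the target r2 algebraically", {
  # linkage equilibrium: products of marginals
  h0 <- haplotype_freqs_for_r2(0.3, 0.4, 0)
  expect_equal(unname(h0), c(0.12, 0.18, 0.28, 0.42))
  # perfect LD at matched frequencies
  h1 <- haplotype_freqs_for_r2(0.5, 0.5, 1)
  expect_equal(unname(h1), c(0.5, 0, 0, 0.5))
  # round-trip: recomputed r2 equals the target to 1e-12
  for (r2 in c(0.1, 0.3, 0.58)) {
    h <- haplotype_freqs_for_r2(0.3, 0.4, r2)
    pa <- h["AB"] + h["Ab"]; pb <- h["AB"] + h["aB"]
    D <- h["AB"] - pa * pb
    expect_equal(unname(D^2 / (pa * (1 - pa) * pb * (1 - pb))), r2,
                 tolerance = 1e-12)
    expect_equal(sum(h), 1, tolerance = 1e-12)
  }
  # infeasible triple errors with the attainable maximum
  expect_error(haplotype_freqs_for_r2(0.05, 0.95, 0.9), "max r2")
  # negative-D variant is also supported
  hn <- haplotype_freqs_for_r2(0.5, 0.5, 0.25, d_sign = -1)
  expect_lt(hn["AB"], 0.25)
})

test_that("population sampling is HWE-consistent and seed-reproducible", {
  cfg <- sim_config(data.frame(rsid = "rs1", risk_allele_freq = 0.5,
                               allelic_or = 1.5))
  pop <- simulate_population(cfg, 50000, seed = 4)
  g <- pop$dosage[, 1]
  p_hat <- mean(g) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 50000))
  expect_lt(abs(p_hat - 0.5), 3 * se)
  props <- as.vector(table(factor(g, 0:2))) / 50000
  expect_equal(props, c(0.25, 0.5, 0.25), tolerance = 0.02)
  expect_gt(hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0)), 0.001)
  pop2 <- simulate_population(cfg, 50000, seed = 4)
  expect_identical(pop$dosage, pop2$dosage)
})

test_that("adding a SNP to the panel does not perturb earlier draws", {
  s1 <- data.frame(rsid = "rsA", risk_allele_freq = 0.3, allelic_or = 1.2)
  s2 <- rbind(s1, data.frame(rsid = "rsB", risk_allele_freq = 0.4,
                             allelic_or = 1.5))
  p1 <- simulate_population(sim_config(s1), 500, seed = 8)
  p2 <- simulate_population(sim_config(s2), 500, seed = 8)
  expect_identical(p1$dosage[, "rsA"], p2$dosage[, "rsA"])
})

test_that("LD pairs are drawn at the configured r2", {
  snps <- data.frame(rsid = c("rsX", "rsY"),
                     risk_allele_freq = c(0.25, 0.30),
                     allelic_or = c(1, 1))
  cfg <- sim_config(snps, ld_pairs = data.frame(rsid_a = "rsX",
                                                rsid_b = "rsY", r2 = 0.58))
  pop <- simulate_population(cfg, 20000, seed = 14)
  expect_equal(as.numeric(ld_r2(pop$dosage[, 1], pop$dosage[, 2])), 0.58,
               tolerance = 0.03)
  # infeasible pair is rejected at config time
  expect_error(sim_config(data.frame(rsid = c("a", "b"),
                                     risk_allele_freq = c(0.05, 0.95),
                                     allelic_or = c(1, 1)),
                          ld_pairs = data.frame(rsid_a = "a", rsid_b = "b",
                                                r2 = 0.9)), "max r2")
})

test_that("null disease model gives equal case/control frequencies", {
  fx <- make_fixture("null", n_case = 150, n_control = 450, seed = 16)
  res <- assoc_screen(fx$genotypes)
  expect_false(any(res$significant))
  expect_equal(res$f_a, res$f_u, tolerance = 0.06)
})

test_that("effect simulation shifts case scores upward and recovers the OR
           direction", {
  fx <- make_fixture("score1", n_case = 120, n_control = 400, seed = 18)
  sc <- predict(fx$model, fx$genotypes)
  expect_gt(mean(sc$score[sc$status == 1]), mean(sc$score[sc$status == 0]))
  # single-SNP OR points the right way at study-like size
  cfg <- sim_config(data.frame(rsid = "rs7023329", risk_allele_freq = 0.51,
                               allelic_or = 1.67))
  gt <- simulate_case_control(cfg, seed = 18)
  tab <- allele_counts(gt$dosage[, 1], gt$status)
  expect_gt(allelic_or_ci(tab)$or, 1.2)
})

test_that("case-control sampling is deterministic, sized, and budgeted", {
  cfg <- sim_config(data.frame(rsid = "rs1", risk_allele_freq = 0.4,
                               allelic_or = 1.5), n_case = 50,
                    n_control = 150)
  g1 <- simulate_case_control(cfg, seed = 22)
  g2 <- simulate_case_control(cfg, seed = 22)
  expect_identical(g1$dosage, g2$dosage)
  expect_equal(sum(g1$status == 1), 50)
  expect_equal(sum(g1$status == 0), 150)
  expect_equal(mean(g1$age[g1$status == 1]), 55.9, tolerance = 6)
  cfg$baseline_log_odds <- -30
  cfg$draw_budget <- 20000
  expect_error(simulate_case_control(cfg, seed = 22), "budget")
})

test_that("fixture presets carry the published risk panels", {
  fx1 <- make_fixture("score1", n_case = 5, n_control = 15, seed = 1)
  expect_equal(unname(coef(fx1$model)), c(1.41, 1.67, 1.79))
  fx2 <- make_fixture("score2", n_case = 5, n_control = 15, seed = 1)
  expect_equal(unname(coef(fx2$model)), c(1.41, 1.67, 1.58))
  expect_true("rs1049380" %in% fx2$model$entries$rsid)
  fx0 <- make_fixture("null", n_case = 5, n_control = 15, seed = 1)
  sc <- predict(fx0$model, fx0$genotypes)
  expect_true(all(sc$score == 1))
  expect_error(make_fixture("bogus"), "arg")
})

test_that("simulate() on a fitted model reproduces its per-allele effects
           in expectation", {
  m <- score_model("rsZ", "A", 1.6, 0.4, other_allele = "G")
  gt <- simulate(m, seed = 30, n_case = 250, n_control = 750)
  fit <- logistic_assoc(gt$dosage[, 1], gt$status)
  expect_equal(fit$or, 1.6, tolerance = 0.35)
})

test_that("simulated-cohort AUC matches the exact AUC of the known score
           distributions", {
  fx <- make_fixture("score1", n_case = 5, n_control = 15, seed = 1)
  e <- fx$model$entries
  cfg <- fx$config
  # exact genotype-class distribution in cases and controls: 27 combinations
  grid <- expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2)
  hwe_w <- function(p, g) dbinom(g, 2, p)
  f_pop <- hwe_w(e$risk_allele_freq[1], grid$g1) *
    hwe_w(e$risk_allele_freq[2], grid$g2) *
    hwe_w(e$risk_allele_freq[3], grid$g3)
  pr_case <- plogis(cfg$baseline_log_odds +
                      as.matrix(grid) %*% log(e$allelic_or))
  w_case <- f_pop * pr_case / sum(f_pop * pr_case)
  w_ctrl <- f_pop * (1 - pr_case) / sum(f_pop * (1 - pr_case))
  gm <- as.matrix(grid)
  colnames(gm) <- e$rsid
  score <- genetic_score(gm, fx$model)$score
  # exact AUC: P(score_case > score_control) + 0.5 P(tie)
  comp <- outer(score, score, function(a, b) (a > b) + 0.5 * (a == b))
  auc_exact <- as.numeric(t(w_case) %*% comp %*% w_ctrl)
  big <- sim_config(fx$config$snps, n_case = 10000, n_control = 10000)
  aucs <- vapply(1:3, function(i) {
    gt <- simulate_case_control(big, seed = 400 + i)
    auc_mann_whitney(predict(fx$model, gt)$score, gt$status)
  }, numeric(1))
  expect_equal(mean(aucs), auc_exact, tolerance = 0.005)
})

test_that("null-cohort association p-values are uniform", {
  set.seed(44)
  n <- 600
  dosage <- matrix(rbinom(n * 1000, 2, 0.3), n, 1000,
                   dimnames = list(NULL, paste0("s", 1:1000)))
  gt <- genotype_table(dosage, status = rep(c(1L, 0L), c(200, 400)),
                       counted_allele = rep("A", 1000),
                       other_allele = rep("G", 1000))
  res <- assoc_screen(gt)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
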