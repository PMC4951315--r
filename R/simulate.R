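#' Simulation configuration for a case-control genotype study
#'
#' Describes the generative model the simulator draws from: SNPs with
#' population risk-allele frequencies sampled under Hardy-Weinberg
#' equilibrium (optionally in two-locus LD pairs at a target r-squared), a
#' logistic disease model whose per-allele log-odds are the log allelic ORs
#' (so the simulated per-allele effect matches the multiplicative-model
#' assumption), case-control ascertainment by rejection sampling, and a
#' normally distributed age covariate shifted in cases.  The defaults are
#' the structure of a 346-case / 1,130-control renal-cell-carcinoma study:
#' ages 55.9 +/- 12.5 in cases versus 51.2 +/- 9.7 in controls, and per-allele
#' ORs in the 1.4-1.8 range.
#'
#' @param snps data.frame with columns `rsid`, `risk_allele_freq`,
#'   `allelic_or`, and optionally `risk_allele`, `other_allele`.
#' @param n_case,n_control target cohort sizes.
#' @param ld_pairs optional data.frame (`rsid_a`, `rsid_b`, `r2`) of SNP
#'   pairs to draw from two-locus haplotypes at the target r-squared; each
#'   pair is checked for feasibility at construction.
#' @param baseline_log_odds intercept of the disease model.  The default -4
#'   (prevalence around 2-4% given the default SNPs) is arbitrary: under
#'   case-control ascertainment the intercept shifts the sampling effort,
#'   not the odds ratios.
#' @param age_case_mean,age_case_sd,age_control_mean,age_control_sd age
#'   distribution per group, in years.
#' @param d_sign +1/-1 sign of the haplotype covariance D for LD pairs.
#' @param draw_budget maximum population draws before
#'   [simulate_case_control()] gives up (guards against an intercept so
#'   extreme that cases essentially never occur).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(snps, n_case = 346, n_control = 1130,
                       ld_pairs = NULL, baseline_log_odds = -4,
                       age_case_mean = 55.9, age_case_sd = 12.5,
                       age_control_mean = 51.2, age_control_sd = 9.7,
                       d_sign = 1, draw_budget = 2e6) {
  snps <- as.data.frame(snps)
  stopifnot(all(c("rsid", "risk_allele_freq", "allelic_or") %in% names(snps)))
  if (any(snps$risk_allele_freq <= 0 | snps$risk_allele_freq >= 1))
    stop("risk_allele_freq must be in (0, 1)")
  if (any(snps$allelic_or <= 0)) stop("allelic_or must be positive")
  if (is.null(snps$risk_allele)) snps$risk_allele <- "A"
  if (is.null(snps$other_allele)) snps$other_allele <- "G"
  if (!is.null(ld_pairs)) {
    ld_pairs <- as.data.frame(ld_pairs)
    for (i in seq_len(nrow(ld_pairs))) {
      ia <- match(ld_pairs$rsid_a[i], snps$rsid)
      ib <- match(ld_pairs$rsid_b[i], snps$rsid)
      if (anyNA(c(ia, ib))) stop("ld_pairs reference unknown rsid")
      # feasibility check: errors here rather than mid-simulation
      haplotype_freqs_for_r2(snps$risk_allele_freq[ia],
                             snps$risk_allele_freq[ib],
                             ld_pairs$r2[i], d_sign = d_sign)
    }
  }
  structure(list(snps = snps, n_case = n_case, n_control = n_control,
                 ld_pairs = ld_pairs, baseline_log_odds = baseline_log_odds,
                 age_case_mean = age_case_mean, age_case_sd = age_case_sd,
                 age_control_mean = age_control_mean,
                 age_control_sd = age_control_sd, d_sign = d_sign,
                 draw_budget = draw_budget),
            class = "sim_config")
}

# derived per-stage RNG stream: one master seed, one sub-seed per key, so
# adding SNPs or stages never perturbs earlier draws
stage_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1987654291
  as.integer((seed + h) %% 2147483647L)
}

#' Simulate an unascertained population sample of genotypes
#'
#' Independent SNPs are drawn as two Bernoulli(p) alleles per subject
#' (Hardy-Weinberg sampling); SNPs named in `config$ld_pairs` are drawn as
#' two haplotypes from [haplotype_freqs_for_r2()].  Reproducible: the same
#' seed gives the same table, and each SNP has its own derived RNG stream.
#'
#' @param config a [sim_config()].
#' @param n number of subjects.
#' @param seed master RNG seed.
#' @return A [genotype_table()] without status (dosages count risk alleles).
#' @export
simulate_population <- function(config, n, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  snps <- config$snps
  m <- nrow(snps)
  dosage <- matrix(NA_real_, n, m, dimnames = list(NULL, snps$rsid))
  in_pair <- character(0)
  if (!is.null(config$ld_pairs)) {
    for (i in seq_len(nrow(config$ld_pairs))) {
      a <- config$ld_pairs$rsid_a[i]; b <- config$ld_pairs$rsid_b[i]
      ia <- match(a, snps$rsid); ib <- match(b, snps$rsid)
      h <- haplotype_freqs_for_r2(snps$risk_allele_freq[ia],
                                  snps$risk_allele_freq[ib],
                                  config$ld_pairs$r2[i],
                                  d_sign = config$d_sign)
      set.seed(stage_seed(seed, paste0("pair:", a, ":", b)))
      # two haplotypes per subject; haplotype 1=AB, 2=Ab, 3=aB, 4=ab
      hap <- matrix(sample.int(4, 2 * n, replace = TRUE, prob = h), ncol = 2)
      dosage[, ia] <- rowSums(hap <= 2)            # carries A
      dosage[, ib] <- rowSums(hap == 1 | hap == 3) # carries B
      in_pair <- c(in_pair, a, b)
    }
  }
  for (k in seq_len(m)) {
    if (snps$rsid[k] %in% in_pair) next
    set.seed(stage_seed(seed, paste0("snp:", snps$rsid[k])))
    dosage[, k] <- stats::rbinom(n, 2, snps$risk_allele_freq[k])
  }
  genotype_table(dosage, status = NULL,
                 counted_allele = snps$risk_allele,
                 other_allele = snps$other_allele,
                 subject_id = paste0("S", seq_len(n)), snp_id = snps$rsid)
}

#' Simulate an ascertained case-control cohort
#'
#' Draws subjects from [simulate_population()], assigns disease status from
#' the logistic model `logit P(case) = baseline_log_odds + sum_k g_k log(OR_k)`,
#' and accumulates subjects by rejection sampling until the configured
#' numbers of cases and controls are reached (mirroring case-control
#' ascertainment).  Ages are then drawn per group from the configured
#' normal distributions.
#'
#' @param config a [sim_config()].
#' @param seed master RNG seed.
#' @return A [genotype_table()] with `status` (cases first) and `age`.
#' @export
simulate_case_control <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  need_case <- config$n_case; need_ctrl <- config$n_control
  logor <- log(config$snps$allelic_or)
  chunk <- max(1000L, 4L * (need_case + need_ctrl))
  got_case <- got_ctrl <- NULL
  drawn <- 0L; round_ <- 0L
  while ((is.null(got_case) || nrow(got_case) < need_case) ||
         (is.null(got_ctrl) || nrow(got_ctrl) < need_ctrl)) {
    if (drawn >= config$draw_budget)
      stop(sprintf(
        "draw budget %d exhausted with %d/%d cases and %d/%d controls; ",
        config$draw_budget, NROW(got_case), need_case, NROW(got_ctrl),
        need_ctrl), "baseline_log_odds is likely too extreme")
    round_ <- round_ + 1L
    pop <- simulate_population(config, chunk,
                               seed = stage_seed(seed, paste0("cc:", round_)))
    eta <- config$baseline_log_odds + as.vector(pop$dosage %*% logor)
    set.seed(stage_seed(seed, paste0("disease:", round_)))
    y <- stats::rbinom(chunk, 1, stats::plogis(eta))
    drawn <- drawn + chunk
    got_case <- rbind(got_case, pop$dosage[y == 1, , drop = FALSE])
    got_ctrl <- rbind(got_ctrl, pop$dosage[y == 0, , drop = FALSE])
  }
  dosage <- rbind(got_case[seq_len(need_case), , drop = FALSE],
                  got_ctrl[seq_len(need_ctrl), , drop = FALSE])
  status <- rep(c(1L, 0L), c(need_case, need_ctrl))
  set.seed(stage_seed(seed, "age"))
  age <- c(stats::rnorm(need_case, config$age_case_mean, config$age_case_sd),
           stats::rnorm(need_ctrl, config$age_control_mean,
                        config$age_control_sd))
  genotype_table(dosage, status = status,
                 counted_allele = config$snps$risk_allele,
                 other_allele = config$snps$other_allele,
                 subject_id = paste0("S", seq_len(nrow(dosage))),
                 snp_id = config$snps$rsid, age = round(age, 1))
}

# risk-SNP panels used by the fixture presets; ORs and risk alleles follow
# the published renal-cell-carcinoma risk SNPs, frequencies are plausible
# Han-Chinese reference values (the models are insensitive to the exact
# choice; see the methods vignette)
preset_snps <- function(preset) {
  base <- data.frame(
    rsid = c("rs10054504", "rs7023329", "rs718314", "rs1049380"),
    risk_allele = c("T", "A", "G", "A"),
    other_allele = c("C", "G", "A", "G"),
    allelic_or = c(1.41, 1.67, 1.79, 1.58),
    risk_allele_freq = c(0.35, 0.51, 0.25, 0.30))
  switch(preset,
         score1 = base[1:3, ],
         score2 = base[c(1, 2, 4), ],
         null = transform(base[1:3, ], allelic_or = 1),
         stop("unknown preset: ", preset))
}

#' Deterministic test fixtures: cohort plus matching score model
#'
#' Presets bundle a simulated case-control [genotype_table()] with the
#' matching [score_model()]:
#' `"score1"` — the three-SNP risk panel rs10054504 / rs7023329 / rs718314
#' (ORs 1.41, 1.67, 1.79); `"score2"` — rs10054504 / rs7023329 / rs1049380
#' (ORs 1.41, 1.67, 1.58); `"null"` — the same SNPs with all ORs forced to
#' 1, so scores are exactly 1 for every subject.
#'
#' @param preset `"score1"`, `"score2"` or `"null"`.
#' @param n_case,n_control cohort sizes (small by default: fixtures are for
#'   tests and examples).
#' @param seed master RNG seed.
#' @return A list with elements `genotypes` (a [genotype_table()]), `model`
#'   (a [score_model()]) and `config` (the [sim_config()] used).
#' @examples
#' fx <- make_fixture("score1", n_case = 30, n_control = 100)
#' head(predict(fx$model, fx$genotypes))
#' @export
make_fixture <- function(preset = c("score1", "score2", "null"),
                         n_case = 60, n_control = 200, seed = 1) {
  preset <- match.arg(preset)
  snps <- preset_snps(preset)
  cfg <- sim_config(snps, n_case = n_case, n_control = n_control)
  gt <- simulate_case_control(cfg, seed = seed)
  model <- score_model(rsid = snps$rsid, risk_allele = snps$risk_allele,
                       allelic_or = snps$allelic_or,
                       risk_allele_freq = snps$risk_allele_freq,
                       other_allele = snps$other_allele,
                       freq_source = "external")
  list(genotypes = gt, model = model, config = cfg)
}

#' Simulate case-control cohorts from a fitted score model
#'
#' Treats the model's per-allele ORs and risk-allele frequencies as the
#' generative truth and draws ascertained cohorts via
#' [simulate_case_control()].
#'
#' @param object a [score_model()].
#' @param nsim number of cohorts.
#' @param seed master RNG seed.
#' @param n_case,n_control cohort sizes.
#' @param ... further arguments passed to [sim_config()].
#' @return A [genotype_table()] for `nsim = 1`, else a list of them.
#' @export
simulate.snp_score_model <- function(object, nsim = 1, seed = 1,
                                     n_case = 346, n_control = 1130, ...) {
  e <- object$entries
  fallback <- ifelse(e$risk_allele == "G", "A", "G")
  snps <- data.frame(rsid = e$rsid, risk_allele = e$risk_allele,
                     other_allele = ifelse(is.na(e$other_allele), fallback,
                                           e$other_allele),
                     allelic_or = e$allelic_or,
                     risk_allele_freq = e$risk_allele_freq)
  cfg <- sim_config(snps, n_case = n_case, n_control = n_control, ...)
  sims <- lapply(seq_len(nsim), function(i)
    simulate_case_control(cfg, seed = stage_seed(seed, paste0("sim:", i))))
  if (nsim == 1) sims[[1]] else sims
}
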