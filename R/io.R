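#' Read subject-level genotypes
#'
#' Reads a cohort's genotypes into a [genotype_table()] from one of three
#' formats:
#'
#' * `"tsv"` — the package's native dialect: one row per subject with columns
#'   `subject_id`, `status`, `age`, then one column per SNP holding
#'   two-character genotype strings (e.g. `"AG"`); missing is `"NN"`.
#' * `"ped_map"` — a PLINK text pedigree pair; `path` names the `.ped` file
#'   and the matching `.map` is found beside it (or pass `map`).  The `"0 0"`
#'   genotype is missing; phenotype 2/1 maps to case/control.
#' * `"vcf"` — a minimal biallelic VCF v4.x (GT field only, phasing ignored);
#'   requires the vcfR package.  The ALT allele is counted.  VCF carries no
#'   phenotype, so `status` is `NULL`.
#'
#' For `"tsv"` and `"ped_map"` the counted allele defaults to the minor
#' allele observed in the file (alphabetical on ties); map/VCF coordinates
#' are 1-based and carried as opaque metadata in `attr(x, "map")`.
#'
#' @param path input file path.
#' @param format one of `"tsv"`, `"ped_map"`, `"vcf"`.
#' @param counted_allele optional named character vector (names = rsIDs)
#'   forcing the counted allele for some or all SNPs.
#' @param map optional path to the `.map` file for `format = "ped_map"`.
#' @return A [genotype_table()].
#' @seealso [write_genotypes()], [read_score_model()]
#' @export
read_genotypes <- function(path, format = c("tsv", "ped_map", "vcf"),
                           counted_allele = NULL, map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tsv = read_genotypes_tsv(path, counted_allele),
         ped_map = read_genotypes_ped(path, map, counted_allele),
         vcf = read_genotypes_vcf(path))
}

split_genotype_strings <- function(gstr, snp, line_offset = 1L) {
  gstr <- toupper(trimws(gstr))
  bad <- !is.na(gstr) & nchar(gstr) != 2L
  if (any(bad))
    stop(sprintf("malformed genotype for %s at line %d: '%s'", snp,
                 which(bad)[1] + line_offset, gstr[which(bad)[1]]))
  a1 <- substr(gstr, 1, 1); a2 <- substr(gstr, 2, 2)
  miss <- is.na(gstr) | a1 %in% c("N", "0", ".") | a2 %in% c("N", "0", ".")
  a1[miss] <- NA; a2[miss] <- NA
  list(a1 = a1, a2 = a2)
}

# dosage of the counted allele from two allele-character vectors
alleles_to_dosage <- function(a1, a2, snp, forced = NULL) {
  obs <- table(c(a1, a2))
  if (length(obs) > 2)
    stop(sprintf("SNP %s has >2 alleles: %s", snp,
                 paste(names(obs), collapse = "/")))
  if (length(obs) == 0)
    stop(sprintf("SNP %s has no called genotypes", snp))
  als <- names(obs)
  if (!is.null(forced)) {
    if (!forced %in% als && length(obs) == 2)
      stop(sprintf("counted allele %s not observed at %s", forced, snp))
    counted <- forced
    other <- setdiff(als, forced)
    if (length(other) == 0) other <- "?"
  } else if (length(obs) == 1) {
    counted <- als; other <- "?"
  } else {
    # minor allele counted; alphabetical on ties
    ord <- order(obs, names(obs))
    counted <- als[ord[1]]; other <- als[ord[2]]
  }
  g <- (a1 == counted) + (a2 == counted)
  list(dosage = g, counted = counted, other = other)
}

read_genotypes_tsv <- function(path, counted_allele = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#")
  need <- c("subject_id", "status")
  if (!all(need %in% names(df)))
    stop("native TSV needs columns subject_id and status")
  snp_cols <- setdiff(names(df), c("subject_id", "status", "age"))
  if (length(snp_cols) == 0) stop("no SNP columns found")
  n <- nrow(df)
  if (n == 0) stop("no subjects in ", path)
  dosage <- matrix(NA_real_, n, length(snp_cols),
                   dimnames = list(df$subject_id, snp_cols))
  counted <- other <- character(length(snp_cols))
  for (k in seq_along(snp_cols)) {
    snp <- snp_cols[k]
    al <- split_genotype_strings(df[[snp]], snp)
    enc <- alleles_to_dosage(al$a1, al$a2, snp, counted_allele[snp])
    dosage[, k] <- enc$dosage
    counted[k] <- enc$counted; other[k] <- enc$other
  }
  status <- suppressWarnings(as.integer(df$status))
  if (anyNA(status)) stop("non-integer status value in ", path)
  age <- if ("age" %in% names(df)) suppressWarnings(as.numeric(df$age))
  genotype_table(dosage, status = status, counted_allele = counted,
                 other_allele = other, subject_id = df$subject_id,
                 snp_id = snp_cols, age = age)
}

read_genotypes_ped <- function(ped_path, map_path = NULL,
                               counted_allele = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4) stop("map file needs 4 columns (chr, rsid, cM, pos)")
  names(map)[1:4] <- c("chr", "rsid", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(sprintf("ped row has %d fields; expected %d for %d SNPs",
                 ncol(ped), 6 + 2 * m, m))
  pheno <- ped[[6]]
  status <- ifelse(pheno == "2", 1L, ifelse(pheno == "1", 0L, NA_integer_))
  n <- nrow(ped)
  dosage <- matrix(NA_real_, n, m, dimnames = list(ped[[2]], map$rsid))
  counted <- other <- character(m)
  for (k in seq_len(m)) {
    a1 <- toupper(ped[[6 + 2 * k - 1]]); a2 <- toupper(ped[[6 + 2 * k]])
    miss <- a1 == "0" | a2 == "0"
    a1[miss] <- NA; a2[miss] <- NA
    enc <- alleles_to_dosage(a1, a2, map$rsid[k], counted_allele[map$rsid[k]])
    dosage[, k] <- enc$dosage
    counted[k] <- enc$counted; other[k] <- enc$other
  }
  gt <- genotype_table(dosage, status = status, counted_allele = counted,
                       other_allele = other, subject_id = ped[[2]],
                       snp_id = map$rsid)
  attr(gt, "map") <- map
  gt
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) fix else matrix(fix, nrow = 1,
                                             dimnames = list(NULL, names(fix)))
  if (any(nchar(fix[, "ALT"]) != 1 | grepl(",", fix[, "ALT"])))
    stop("only biallelic SNP records are supported")
  gtm <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles; "." or "./." is missing; phasing separators ignored
  alt_count <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dosage <- t(apply(gtm, c(1, 2), alt_count))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  colnames(dosage) <- ids
  gt <- genotype_table(dosage, status = NULL,
                       counted_allele = fix[, "ALT"],
                       other_allele = fix[, "REF"],
                       subject_id = colnames(gtm), snp_id = ids)
  attr(gt, "map") <- data.frame(chr = fix[, "CHROM"], rsid = ids,
                                cm = "0", pos = fix[, "POS"])
  gt
}

#' Write genotypes to the native TSV dialect or a ped/map pair
#'
#' The native dialect is the round-trip format: genotype strings are written
#' from the counted/other alleles so that reading the file back reproduces
#' dosages exactly.  For `"ped_map"`, `path` is the stem; `.ped` and `.map`
#' files are written (chromosome/position come from `attr(x, "map")` when
#' present, else placeholders).
#'
#' @param x a [genotype_table()].
#' @param path output file path (or stem for `"ped_map"`).
#' @param format `"tsv"` or `"ped_map"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("tsv", "ped_map")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "genotype_table"))
  geno_str <- function(k, sep = "") {
    g <- x$dosage[, k]
    a <- x$counted_allele[k]; b <- x$other_allele[k]
    out <- c(paste(b, b, sep = sep), paste(a, b, sep = sep),
             paste(a, a, sep = sep))[g + 1]
    out[is.na(g)] <- if (sep == "") "NN" else "0 0"
    out
  }
  if (format == "tsv") {
    df <- data.frame(subject_id = x$subject_id,
                     status = if (is.null(x$status)) NA else x$status)
    if (!is.null(x$age)) df$age <- x$age
    for (k in seq_along(x$snp_id)) df[[x$snp_id[k]]] <- geno_str(k)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    map <- attr(x, "map")
    if (is.null(map))
      map <- data.frame(chr = "0", rsid = x$snp_id, cm = "0",
                        pos = seq_along(x$snp_id))
    utils::write.table(map[, 1:4], paste0(path, ".map"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    alleles <- vapply(seq_along(x$snp_id), geno_str, character(nrow(x$dosage)),
                      sep = " ")
    alleles <- matrix(alleles, nrow = nrow(x$dosage))
    ped <- cbind(x$subject_id, x$subject_id, "0", "0", "0",
                 if (is.null(x$status)) "0" else as.character(x$status + 1L),
                 alleles)
    utils::write.table(ped, paste0(path, ".ped"), sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a SNP score-model file
#'
#' Expects a tab-separated file with header columns `rsid`, `risk_allele`,
#' `allelic_or`, `risk_allele_freq` and optionally `other_allele` and
#' `freq_source`.  Odds ratios below 1 are rejected: score models are stated
#' on the risk allele (OR >= 1); re-orient protective entries first with
#' [build_score_model()], which flips the allele and inverts the OR.
#'
#' @param path input file path.
#' @param ld_prune_r2 the r-squared threshold recorded on the model.
#' @return A `snp_score_model` (see [score_model()]).
#' @export
read_score_model <- function(path, ld_prune_r2 = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("rsid", "risk_allele", "allelic_or", "risk_allele_freq")
  if (nrow(df) == 0) stop("empty score-model file: ", path)
  if (!all(need %in% names(df)))
    stop("score-model file must have columns: ", paste(need, collapse = ", "))
  score_model(rsid = df$rsid, risk_allele = df$risk_allele,
              allelic_or = df$allelic_or,
              risk_allele_freq = df$risk_allele_freq,
              other_allele = df$other_allele,
              freq_source = if (!is.null(df$freq_source)) df$freq_source
                            else "external",
              ld_prune_r2 = ld_prune_r2)
}

#' Write a score model to TSV
#'
#' @param model a `snp_score_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "snp_score_model"))
  utils::write.table(model$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
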