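#' Construct a genotype table
#'
#' A `genotype_table` holds a cohort of subjects typed at a set of biallelic
#' SNPs: a subjects-by-SNPs dosage matrix counting copies of each SNP's
#' *counted* allele (0, 1, 2, or `NA` for missing), together with the
#' case/control status (1 = case, 0 = control) and an optional age covariate.
#' Which allele is counted is a property of the table, not of the score
#' model: re-orientation towards a model's risk alleles happens in memory at
#' scoring time (see [predict.snp_score_model()]), so files stay
#' allele-agnostic.
#'
#' @param dosage numeric matrix, subjects in rows and SNPs in columns; values
#'   must be 0, 1, 2 or `NA`.
#' @param status integer vector of 0/1 per subject, or `NULL` for a
#'   population sample without phenotypes.
#' @param counted_allele,other_allele character vectors, one base symbol per
#'   SNP; the two must differ at every SNP.
#' @param subject_id character vector of subject identifiers; defaults to the
#'   dosage rownames or `S1..Sn`.
#' @param snp_id character vector of rsIDs; defaults to the dosage colnames.
#' @param age optional numeric vector of ages in years.
#' @return An object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(matrix(c(2, 1, 0, 1), 2, 2,
#'                             dimnames = list(c("a", "b"), c("rs1", "rs2"))),
#'                      status = c(1, 0),
#'                      counted_allele = c("A", "T"),
#'                      other_allele = c("G", "C"))
#' gt
#' @export
genotype_table <- function(dosage, status = NULL,
                           counted_allele, other_allele,
                           subject_id = NULL, snp_id = NULL, age = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(subject_id)) subject_id <- rownames(dosage)
  if (is.null(subject_id)) subject_id <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(snp_id)) snp_id <- colnames(dosage)
  if (is.null(snp_id)) stop("snp_id required (or dosage colnames)")
  rownames(dosage) <- subject_id
  colnames(dosage) <- snp_id
  obj <- structure(list(
    subject_id = as.character(subject_id),
    status = if (!is.null(status)) as.integer(status),
    age = if (!is.null(age)) as.numeric(age),
    snp_id = as.character(snp_id),
    dosage = dosage,
    counted_allele = toupper(as.character(counted_allele)),
    other_allele = toupper(as.character(other_allele))
  ), class = "genotype_table")
  validate_genotype_table(obj)
}

validate_genotype_table <- function(x) {
  n <- nrow(x$dosage); m <- ncol(x$dosage)
  if (length(x$subject_id) != n) stop("subject_id length != number of rows")
  if (length(x$snp_id) != m) stop("snp_id length != number of columns")
  if (anyDuplicated(x$snp_id)) stop("duplicate snp_id")
  bad <- !is.na(x$dosage) & !(x$dosage %in% c(0, 1, 2))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (!is.null(x$status)) {
    if (length(x$status) != n) stop("status length != number of subjects")
    if (!all(x$status %in% c(0L, 1L))) stop("status must be 0 (control) or 1 (case)")
  }
  if (!is.null(x$age) && length(x$age) != n) stop("age length != number of subjects")
  if (length(x$counted_allele) != m || length(x$other_allele) != m)
    stop("counted_allele/other_allele must have one entry per SNP")
  if (any(x$counted_allele == x$other_allele))
    stop("counted_allele must differ from other_allele for every SNP")
  x
}

#' @export
print.genotype_table <- function(x, ...) {
  n <- nrow(x$dosage)
  cat("genotype_table:", n, "subjects x", ncol(x$dosage), "SNPs\n")
  if (!is.null(x$status))
    cat("  cases:", sum(x$status == 1L), " controls:", sum(x$status == 0L), "\n")
  if (!is.null(x$age))
    cat(sprintf("  age: mean %.1f (sd %.1f)\n", mean(x$age, na.rm = TRUE),
                stats::sd(x$age, na.rm = TRUE)))
  miss <- sum(is.na(x$dosage))
  cat("  SNPs:", paste(utils::head(x$snp_id, 5), collapse = ", "),
      if (ncol(x$dosage) > 5) "...", "\n")
  cat("  missing genotypes:", miss, "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

#' Subset a genotype table
#'
#' @param x a [genotype_table()].
#' @param i subject index (logical, integer or character).
#' @param j SNP index (logical, integer or rsID).
#' @param ... ignored.
#' @return A `genotype_table` with the selected subjects and SNPs.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$snp_id)
  if (anyNA(j)) stop("unknown snp_id in subset")
  if (is.character(i)) i <- match(i, x$subject_id)
  genotype_table(x$dosage[i, j, drop = FALSE],
                 status = if (!is.null(x$status)) x$status[i],
                 counted_allele = x$counted_allele[j],
                 other_allele = x$other_allele[j],
                 subject_id = x$subject_id[i],
                 snp_id = x$snp_id[j],
                 age = if (!is.null(x$age)) x$age[i])
}

# dosage of `allele` at snp k: identity if allele is counted, 2 - g if it is
# the other allele, error otherwise
oriented_dosage <- function(gt, snp, allele) {
  k <- match(snp, gt$snp_id)
  if (is.na(k)) stop("SNP not in table: ", snp)
  g <- gt$dosage[, k]
  if (allele == gt$counted_allele[k]) g
  else if (allele == gt$other_allele[k]) 2 - g
  else stop(sprintf("allele %s not observed at %s (alleles %s/%s)", allele,
                    snp, gt$counted_allele[k], gt$other_allele[k]))
}
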