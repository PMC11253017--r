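#' Genotype panel container
#'
#' A `genotype_panel` holds a biallelic dosage matrix (lines x SNPs) together
#' with its marker map and allele labels. Dosages count copies of `allele1`
#' (the counted allele) and lie in \{0, 1, 2\}, with `NA` for missing calls.
#' Inbred lines concentrate at 0 and 2.
#'
#' @param dosage Integer matrix, `n_lines x n_snps`, entries in 0..2 or `NA`.
#' @param sample_ids Character vector of unique line identifiers (rows).
#' @param snp_ids Character vector of unique SNP identifiers (columns).
#' @param chromosome Chromosome label per SNP.
#' @param position Base-pair position per SNP (non-negative).
#' @param allele1 Counted allele label per SNP (dosage counts its copies).
#' @param allele2 Other allele label per SNP; must differ from `allele1`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage`, `sample_ids`, `snp_ids`, `map` (data.frame with `snp_id`,
#'   `chromosome`, `position`, `allele1`, `allele2`).
#' @export
genotype_panel <- function(dosage, sample_ids, snp_ids, chromosome, position,
                           allele1, allele2) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != length(snp_ids)) {
    stop("dosage dimensions must be (|sample_ids|, |snp_ids|)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids", call. = FALSE)
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids", call. = FALSE)
  m <- length(snp_ids)
  stopifnot(length(chromosome) == m, length(position) == m,
            length(allele1) == m, length(allele2) == m)
  if (any(position < 0, na.rm = TRUE)) {
    stop("positions must be non-negative", call. = FALSE)
  }
  if (any(as.character(allele1) == as.character(allele2))) {
    stop("allele1 and allele2 must differ for every SNP", call. = FALSE)
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(dosage) <- list(sample_ids, snp_ids)
  structure(
    list(
      dosage = dosage,
      sample_ids = sample_ids,
      snp_ids = snp_ids,
      map = data.frame(
        snp_id = snp_ids,
        chromosome = as.character(chromosome),
        position = as.integer(position),
        allele1 = as.character(allele1),
        allele2 = as.character(allele2),
        stringsAsFactors = FALSE
      )
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$dosage))
  cat(sprintf(
    "<genotype_panel> %d lines x %d SNPs (%d chromosomes), %.2f%% missing\n",
    length(x$sample_ids), length(x$snp_ids),
    length(unique(x$map$chromosome)),
    100 * n_miss / length(x$dosage)
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel by lines and/or SNPs
#'
#' @param panel A `genotype_panel`.
#' @param samples Character vector of sample ids (or logical/integer index).
#' @param snps Character vector of SNP ids (or logical/integer index).
#' @return A `genotype_panel` restricted to the requested lines/SNPs, in the
#'   requested order.
#' @export
subset_panel <- function(panel, samples = NULL, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ri <- if (is.null(samples)) seq_along(panel$sample_ids) else {
    if (is.character(samples)) {
      idx <- match(samples, panel$sample_ids)
      if (anyNA(idx)) {
        stop("unknown sample ids: ",
             paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      idx
    } else samples
  }
  ci <- if (is.null(snps)) seq_along(panel$snp_ids) else {
    if (is.character(snps)) {
      idx <- match(snps, panel$snp_ids)
      if (anyNA(idx)) {
        stop("unknown SNP ids: ",
             paste(snps[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      idx
    } else snps
  }
  genotype_panel(
    dosage = panel$dosage[ri, ci, drop = FALSE],
    sample_ids = panel$sample_ids[ri],
    snp_ids = panel$snp_ids[ci],
    chromosome = panel$map$chromosome[ci],
    position = panel$map$position[ci],
    allele1 = panel$map$allele1[ci],
    allele2 = panel$map$allele2[ci]
  )
}
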