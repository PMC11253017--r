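#' Counted-allele frequencies
#'
#' `p[i]` is the frequency of each SNP's counted allele (allele1) among the
#' non-missing calls: sum of dosages over twice the number of called lines.
#'
#' @param panel A [genotype_panel()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$snp_ids) == 0 || length(panel$sample_ids) == 0) {
    stop("empty panel", call. = FALSE)
  }
  called <- colSums(!is.na(panel$dosage))
  if (any(called == 0)) {
    stop("SNP(s) with all calls missing: ",
         paste(utils::head(panel$snp_ids[called == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(colSums(panel$dosage, na.rm = TRUE) / (2 * called),
                  panel$snp_ids)
}

#' Genomic relationship matrix
#'
#' Realized-relatedness estimator on standardized dosages. Off-diagonal
#' entries are
#' \deqn{A_{jk} = \frac{1}{m_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' averaged over the \eqn{m_{jk}} SNPs called in both lines
#' (pairwise-complete handling, which keeps `A` exactly symmetric without
#' imputation). The diagonal follows either the same formula (`standard`,
#' i.e. \eqn{A = WW^\top/m} with column-standardized `W` when there is no
#' missingness) or the Yang et al. estimator
#' \eqn{A_{jj} = 1 + \frac{1}{m}\sum_i
#'   \frac{x_{ij}^2 - (1 + 2p_i) x_{ij} + 2p_i^2}{2p_i(1-p_i)}}
#' (`yang`, the default, matching the common GREML tooling). SNPs with
#' missing fraction above `grm_missing_max` (default 2%, i.e. genotyping
#' quality at least 98%) are excluded first; SNPs monomorphic among the
#' used lines are skipped with a warning.
#'
#' @param panel QC-passed [genotype_panel()].
#' @param diagonal `"yang"` or `"standard"`.
#' @param grm_missing_max Maximum per-SNP missing fraction for GRM SNPs.
#' @return Object of class `grm`: list with `A` (n x n), `sample_ids`,
#'   `n_snps_used` (n x n pairwise counts), `diagonal`, `snp_ids` used.
#' @export
compute_grm <- function(panel, diagonal = c("yang", "standard"),
                        grm_missing_max = 0.02) {
  stopifnot(inherits(panel, "genotype_panel"))
  diagonal <- match.arg(diagonal)
  n <- length(panel$sample_ids)
  if (n < 2) stop("need at least 2 lines for a GRM", call. = FALSE)

  d <- panel$dosage
  miss_frac <- colMeans(is.na(d))
  keep <- miss_frac <= grm_missing_max
  d <- d[, keep, drop = FALSE]
  snp_ids <- panel$snp_ids[keep]
  if (ncol(d) == 0) stop("zero usable SNPs for the GRM", call. = FALSE)

  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * called)
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) skipped in GRM")
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
    snp_ids <- snp_ids[poly]
  }
  if (ncol(d) == 0) stop("zero usable SNPs for the GRM", call. = FALSE)
  m <- ncol(d)

  denom <- sqrt(2 * p * (1 - p))
  Z <- sweep(sweep(d, 2, 2 * p), 2, denom, "/")
  obs <- !is.na(Z)
  Z[!obs] <- 0
  storage.mode(obs) <- "double"
  M <- tcrossprod(obs)              # pairwise non-missing counts
  A <- tcrossprod(Z)
  if (any(M == 0)) {
    stop("line pair(s) share zero called SNPs; relax grm_missing_max",
         call. = FALSE)
  }
  A <- A / M

  if (diagonal == "yang") {
    x <- d
    num <- x^2 - sweep(x, 2, 1 + 2 * p, "*") + matrix(2 * p^2, nrow(x), m,
                                                      byrow = TRUE)
    num <- sweep(num, 2, 2 * p * (1 - p), "/")
    mj <- rowSums(!is.na(num))
    diag(A) <- 1 + rowSums(num, na.rm = TRUE) / mj
  }

  dimnames(A) <- list(panel$sample_ids, panel$sample_ids)
  structure(
    list(A = A, sample_ids = panel$sample_ids, n_snps_used = M,
         diagonal = diagonal, snp_ids = snp_ids),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d lines, %d SNPs, diagonal = %s, mean diag = %.3f\n",
              length(x$sample_ids), length(x$snp_ids), x$diagonal,
              mean(diag(x$A))))
  invisible(x)
}

#' Write/read a GRM as tab-separated text
#'
#' Plain n x n matrix with row and column sample ids.
#'
#' @param grm A `grm` object (or, for reading, the file written by
#'   `write_grm_tsv`).
#' @param path File path.
#' @return `read_grm_tsv` returns a `grm` (with `n_snps_used` absent);
#'   `write_grm_tsv` returns `path` invisibly.
#' @export
write_grm_tsv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  df <- data.frame(sample_id = grm$sample_ids, grm$A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  A <- as.matrix(df[, -1, drop = FALSE])
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, sample_ids = ids, n_snps_used = NULL,
                 diagonal = "unknown", snp_ids = NULL),
            class = "grm")
}

#' Write/read a GRM in the GCTA binary triple
#'
#' `prefix.grm.bin` holds the lower triangle (diagonal included, row by
#' row) as little-endian float32, `prefix.grm.N.bin` the matching pairwise
#' SNP counts, and `prefix.grm.id` family/within-family ids. Float32
#' storage means values round-trip to ~1e-7 relative precision.
#'
#' @param grm A `grm`.
#' @param prefix Path prefix (files get `.grm.bin`, `.grm.N.bin`,
#'   `.grm.id` appended).
#' @return `read_grm_bin` returns a `grm`; `write_grm_bin` returns
#'   `prefix` invisibly.
#' @export
write_grm_bin <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$sample_ids)
  lt <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  ord <- order(lt[, 1], lt[, 2])  # row by row
  vals <- grm$A[lt[ord, , drop = FALSE]]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  close(con)
  nmat <- grm$n_snps_used
  if (is.null(nmat)) nmat <- matrix(length(grm$snp_ids %||% 0), n, n)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(nmat[lt[ord, , drop = FALSE]]), con, size = 4,
           endian = "little")
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_bin
#' @export
read_grm_bin <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  nv <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nv, size = 4,
                  endian = "little")
  nvals <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = nv, size = 4,
                   endian = "little")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  Nm <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n)) {
    A[i, 1:i] <- vals[k:(k + i - 1L)]
    Nm[i, 1:i] <- nvals[k:(k + i - 1L)]
    k <- k + i
  }
  A <- A + t(A) - diag(diag(A))
  Nm <- Nm + t(Nm) - diag(diag(Nm))
  structure(list(A = A, sample_ids = as.character(ids), n_snps_used = Nm,
                 diagonal = "unknown", snp_ids = NULL),
            class = "grm")
}
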