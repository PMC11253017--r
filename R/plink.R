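#' Read genotypes in PLINK format
#'
#' Reads either the text dialect (`.ped`/`.map`) or the binary dialect
#' (`.bed`/`.bim`/`.fam`, SNP-major). Dosages count copies of each SNP's
#' allele1 (the A1 allele of the bim/ped as loaded); missing calls become
#' `NA`. The pair `write_plink()` / `read_plink()` round-trips a panel
#' bit-exactly in both dialects.
#'
#' @param path_prefix Path without extension; the dialect's three files must
#'   share it.
#' @param dialect `"text"` (ped/map) or `"binary"` (bed/bim/fam).
#' @return A [genotype_panel()].
#' @export
read_plink <- function(path_prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") read_plink_text(path_prefix) else
    read_plink_binary(path_prefix)
}

plink_file <- function(prefix, ext) {
  path <- paste0(prefix, ".", ext)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  path
}

read_map_like <- function(path, n_cols) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != n_cols) {
    stop(sprintf("%s: expected %d columns, found %d", path, n_cols, ncol(df)),
         call. = FALSE)
  }
  df
}

read_plink_text <- function(prefix) {
  map_path <- plink_file(prefix, "map")
  ped_path <- plink_file(prefix, "ped")
  map <- read_map_like(map_path, 4L)  # chr, id, cM, bp
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (n == 0) stop(ped_path, ": empty ped file", call. = FALSE)
  dosage <- matrix(NA_integer_, n, m)
  a1 <- rep(NA_character_, m)
  a2 <- rep(NA_character_, m)
  ids <- character(n)

  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m) {
      stop(sprintf("%s line %d: expected %d fields (6 + 2 x %d SNPs), found %d",
                   ped_path, i, 6L + 2L * m, m, length(f)), call. = FALSE)
    }
    ids[i] <- f[2]
    g1 <- f[seq(7L, by = 2L, length.out = m)]
    g2 <- f[seq(8L, by = 2L, length.out = m)]
    called <- g1 != "0" & g2 != "0"
    # establish allele labels per SNP from first observed calls
    new1 <- is.na(a1) & called
    a1[new1] <- g1[new1]
    other <- is.na(a2) & called & g1 != a1
    a2[other] <- g1[other]
    other <- is.na(a2) & called & g2 != a1
    a2[other] <- g2[other]
    dosage[i, called] <- (g1[called] == a1[called]) +
      (g2[called] == a1[called])
  }
  if (anyDuplicated(ids)) stop(ped_path, ": duplicated IIDs", call. = FALSE)
  # SNPs never called or monomorphic in file: fill placeholder second allele
  a1[is.na(a1)] <- "A"
  a2[is.na(a2)] <- ifelse(a1[is.na(a2)] == "B", "A", "B")

  genotype_panel(dosage, ids, map[[2]], map[[1]],
                 as.integer(map[[4]]), a1, a2)
}

read_plink_binary <- function(prefix) {
  bim_path <- plink_file(prefix, "bim")
  fam_path <- plink_file(prefix, "fam")
  bed_path <- plink_file(prefix, "bed")
  bim <- read_map_like(bim_path, 6L)  # chr, id, cM, bp, a1, a2
  fam <- read_map_like(fam_path, 6L)
  m <- nrow(bim)
  n <- nrow(fam)
  bpv <- ceiling(n / 4)  # bytes per variant

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop(bed_path, ": not a bed file (bad magic bytes)", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop(bed_path, ": only SNP-major bed files are supported", call. = FALSE)
  }
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    stop(sprintf("%s: %d data bytes but fam/bim imply %d (n=%d, m=%d)",
                 bed_path, length(body), bpv * m, n, m), call. = FALSE)
  }
  # 2-bit codes, sample 1 in the lowest bits: 00 hom A1, 01 missing,
  # 10 het, 11 hom A2. Dosage counts A1.
  code_dosage <- c(2L, NA_integer_, 1L, 0L)
  byte <- as.integer(body)
  codes <- rbind(byte %% 4L, (byte %/% 4L) %% 4L,
                 (byte %/% 16L) %% 4L, byte %/% 64L)
  dosage <- matrix(code_dosage[codes + 1L], nrow = 4L * bpv, ncol = m)
  dosage <- dosage[seq_len(n), , drop = FALSE]

  genotype_panel(dosage, fam[[2]], bim[[2]], bim[[1]],
                 as.integer(bim[[4]]), bim[[5]], bim[[6]])
}

#' Write genotypes in PLINK format
#'
#' @param panel A [genotype_panel()].
#' @param path_prefix Output path without extension.
#' @param dialect `"binary"` (bed/bim/fam) or `"text"` (ped/map).
#' @return `path_prefix`, invisibly.
#' @export
write_plink <- function(panel, path_prefix, dialect = c("binary", "text")) {
  stopifnot(inherits(panel, "genotype_panel"))
  dialect <- match.arg(dialect)
  if (dialect == "text") write_plink_text(panel, path_prefix) else
    write_plink_binary(panel, path_prefix)
  invisible(path_prefix)
}

chrom_numeric <- function(chr) sub("^chr", "", chr)

write_plink_text <- function(panel, prefix) {
  map <- data.frame(chrom_numeric(panel$map$chromosome), panel$map$snp_id,
                    0L, panel$map$position)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  n <- length(panel$sample_ids)
  m <- length(panel$snp_ids)
  a1 <- matrix(panel$map$allele1, n, m, byrow = TRUE)
  a2 <- matrix(panel$map$allele2, n, m, byrow = TRUE)
  d <- panel$dosage
  g1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, a1, a2))
  g2 <- ifelse(is.na(d), "0", ifelse(d == 2L, a1, a2))
  geno <- matrix("", n, 2L * m)
  geno[, seq(1L, by = 2L, length.out = m)] <- g1
  geno[, seq(2L, by = 2L, length.out = m)] <- g2
  lines <- paste(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9,
                 apply(geno, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
}

write_plink_binary <- function(panel, prefix) {
  bim <- data.frame(chrom_numeric(panel$map$chromosome), panel$map$snp_id,
                    0L, panel$map$position, panel$map$allele1,
                    panel$map$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$sample_ids, panel$sample_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)

  n <- length(panel$sample_ids)
  m <- length(panel$snp_ids)
  bpv <- ceiling(n / 4)
  # dosage (A1 copies) -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  dosage_code <- function(d) {
    code <- integer(length(d))
    code[is.na(d)] <- 1L
    code[!is.na(d) & d == 1L] <- 2L
    code[!is.na(d) & d == 0L] <- 3L
    code
  }
  pad <- 4L * bpv - n
  codes <- matrix(0L, 4L * bpv, m)
  codes[seq_len(n), ] <- apply(panel$dosage, 2, dosage_code)
  mult <- c(1L, 4L, 16L, 64L)
  bytes <- codes[seq(1, 4L * bpv, by = 4L), , drop = FALSE] * mult[1] +
    codes[seq(2, 4L * bpv, by = 4L), , drop = FALSE] * mult[2] +
    codes[seq(3, 4L * bpv, by = 4L), , drop = FALSE] * mult[3] +
    codes[seq(4, 4L * bpv, by = 4L), , drop = FALSE] * mult[4]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
}
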