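test_that("binary PLINK round trip is bit-exact, including missing calls", {
  sim <- tiny_sim(n = 23, m = 41, seed = 2, missing_rate = 0.05,
                  inbreeding = 0.7)
  prefix <- withr::local_tempfile()
  write_plink(sim$panel, prefix, dialect = "binary")
  back <- read_plink(prefix, dialect = "binary")
  expect_identical(back$dosage, sim$panel$dosage)
  expect_identical(back$sample_ids, sim$panel$sample_ids)
  expect_equal(back$map$allele1, sim$panel$map$allele1)
  expect_equal(back$map$allele2, sim$panel$map$allele2)
  expect_equal(back$map$position, sim$panel$map$position)
})

test_that("text PLINK decodes hand-written genotypes and canonicalizes", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "toy")
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"),
             paste0(prefix, ".map"))
  writeLines(c(
    "f1 s1 0 0 0 -9 A A C C",
    "f2 s2 0 0 0 -9 A G C T",
    "f3 s3 0 0 0 -9 G G T T"
  ), paste0(prefix, ".ped"))
  panel <- read_plink(prefix, dialect = "text")
  # allele1 = first-listed allele: A at snp1, C at snp2
  expect_equal(panel$map$allele1, c("A", "C"))
  expect_equal(unname(panel$dosage[, "snp1"]), c(2L, 1L, 0L))
  expect_equal(unname(panel$dosage[, "snp2"]), c(2L, 1L, 0L))

  # write -> read is the identity once a panel is in reader-canonical
  # orientation (the ped stores no counted-allele convention of its own)
  prefix2 <- file.path(dir, "toy2")
  write_plink(panel, prefix2, dialect = "text")
  back <- read_plink(prefix2, dialect = "text")
  expect_identical(back$dosage, panel$dosage)
  expect_equal(back$map$allele1, panel$map$allele1)
  back2 <- read_plink(prefix2, dialect = "text")
  expect_identical(back, back2)
})

test_that("malformed PLINK input fails loudly with context", {
  dir <- withr::local_tempdir()
  sim <- tiny_sim(n = 6, m = 10, seed = 3)
  prefix <- file.path(dir, "p")
  write_plink(sim$panel, prefix, dialect = "binary")

  # corrupt the magic bytes
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = file.size(paste0(prefix, ".bed")))
  raw[1] <- as.raw(0x00)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix, "binary"), "magic")

  # bed/bim dimension mismatch
  write_plink(sim$panel, prefix, dialect = "binary")
  bim <- readLines(paste0(prefix, ".bim"))
  writeLines(bim[-1], paste0(prefix, ".bim"))
  expect_error(read_plink(prefix, "binary"), "bytes")

  # ped with wrong field count
  write_plink(sim$panel, prefix, dialect = "text")
  ped <- readLines(paste0(prefix, ".ped"))
  ped[2] <- paste(ped[2], "A")
  writeLines(ped, paste0(prefix, ".ped"))
  expect_error(read_plink(prefix, "text"), "line 2")
})

test_that("qc_filter applies SNP missingness, MAF, then sample missingness", {
  # clean panel: exact no-op
  sim <- tiny_sim(n = 20, m = 30, seed = 4, maf_low = 0.2)
  res <- qc_filter(sim$panel)
  expect_identical(res$panel$dosage, sim$panel$dosage)
  expect_equal(res$report$n_snps_removed_missingness, 0)
  expect_equal(res$report$n_snps_removed_maf, 0)
  expect_equal(res$report$n_samples_removed_missingness, 0)

  # hand-counted MAF: snp1 has 1 of 20 allele copies (MAF 0.05, kept),
  # snp2 has 0 copies (MAF 0 < 0.01, removed)
  d <- cbind(c(1L, rep(0L, 9)), rep(0L, 10), rep(c(0L, 2L), 5))
  pan <- manual_panel(d)
  res2 <- qc_filter(pan)
  expect_equal(res2$report$n_snps_removed_maf, 1)
  expect_equal(res2$panel$snp_ids, c("snp001", "snp003"))
})

test_that("qc_filter removes exactly the SNPs a brute-force scan flags", {
  sim <- tiny_sim(n = 60, m = 100, seed = 5, missing_rate = 0.03,
                  maf_low = 0.2)
  # inject ~10% missingness into 40 SNPs
  d <- sim$panel$dosage
  set.seed(6)
  hit <- sample(100, 40)
  for (j in hit) d[sample(60, 6), j] <- NA_integer_
  pan <- manual_panel(d)

  res <- qc_filter(pan, max_snp_missing = 0.05, min_maf = 0,
                   max_sample_missing = 1)
  expected_removed <- colnames(pan$dosage)[colMeans(is.na(d)) > 0.05]
  expect_setequal(setdiff(pan$snp_ids, res$panel$snp_ids), expected_removed)
  expect_equal(res$report$n_snps_removed_missingness,
               length(expected_removed))

  # idempotence
  res_again <- qc_filter(res$panel, max_snp_missing = 0.05, min_maf = 0,
                         max_sample_missing = 1)
  expect_identical(res_again$panel$dosage, res$panel$dosage)

  # counts reconcile: removed + retained = input
  rep1 <- qc_filter(pan)$report
  expect_equal(rep1$n_snps_in - rep1$n_snps_removed_missingness -
                 rep1$n_snps_removed_maf, rep1$n_snps_out)
  expect_equal(rep1$n_samples_in - rep1$n_samples_removed_missingness,
               rep1$n_samples_out)
})

test_that("fully filtered panels raise explicit errors", {
  pan <- manual_panel(matrix(0L, 5, 4))  # all monomorphic
  expect_error(qc_filter(pan), "no SNPs left")
})

test_that("line_means averages records and respects the sample-ID order", {
  ph <- data.frame(
    line_id = rep(c("a", "b"), each = 4),
    trait = "Zn",
    year = rep(c(2018L, 2018L, 2019L, 2019L), 2),
    replicate = rep(1:2, 4),
    value = c(10, 12, 14, 16, 1, 1, 1, 1)
  )
  m <- line_means(ph, "Zn", sample_ids = c("b", "a"))
  expect_equal(m, c(b = 1, a = 13))
  expect_error(line_means(ph, "Cu"), "trait not found")
  expect_message(line_means(ph, "Zn", sample_ids = c("a", "b", "ghost")),
                 "dropped")

  # 4 records per line for 149 lines -> 149 means
  sim <- tiny_sim(n = 149, m = 20, seed = 7)
  means <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
  expect_length(means, 149)
  one <- sim$phenotypes[sim$phenotypes$line_id == "line_001" &
                          sim$phenotypes$trait == "trait1", "value"]
  expect_equal(unname(means["line_001"]), mean(one))
})

test_that("phenotype tables round-trip through TSV", {
  sim <- tiny_sim(n = 15, m = 10, n_traits = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(sim$phenotypes, path)
  back <- read_phenotypes(path)
  expect_equal(back$value, sim$phenotypes$value)
  expect_equal(back$line_id, sim$phenotypes$line_id)
  expect_error(write_phenotypes(data.frame(x = 1), path), "missing column")
})
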