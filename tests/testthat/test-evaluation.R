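test_that("k-fold partitions are balanced, exhaustive and deterministic", {
  ids <- sprintf("line_%03d", 1:149)
  f <- kfold_split(ids, k = 5, seed = 42)
  expect_equal(sort(as.integer(table(f))), c(29L, 30L, 30L, 30L, 30L))
  expect_setequal(names(f), ids)
  expect_identical(f, kfold_split(ids, k = 5, seed = 42))
  expect_false(identical(unname(f), unname(kfold_split(ids, 5, seed = 43))))

  f10 <- kfold_split(sprintf("s%02d", 1:10), k = 5, seed = 1)
  expect_true(all(table(f10) == 2L))
  expect_error(kfold_split(letters[1:3], k = 5), "k must be")
})

test_that("pearson_r, fisher_ci and corr_pvalue match their formulas", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.3, 2.9)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  y <- x - mean(x)
  z <- rnorm(7)
  z_orth <- z - mean(z) - sum((z - mean(z)) * y) / sum(y^2) * y
  expect_equal(pearson_r(y, z_orth), 0, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 7)), "zero variance")

  # 30-point sum-formula oracle
  set.seed(2)
  a <- rnorm(30); b <- 0.6 * a + rnorm(30)
  r_hand <- (sum(a * b) - 30 * mean(a) * mean(b)) /
    sqrt((sum(a^2) - 30 * mean(a)^2) * (sum(b^2) - 30 * mean(b)^2))
  expect_equal(pearson_r(a, b), r_hand, tolerance = 1e-12)

  ci <- fisher_ci(0, 30)
  expect_equal(unname(ci), c(-1, 1) * tanh(qnorm(0.975) / sqrt(27)))
  for (r in c(-0.9, -0.3, 0, 0.5, 0.99)) {
    ci_r <- fisher_ci(r, 25)
    expect_true(ci_r[1] <= r && r <= ci_r[2])
  }
  expect_equal(fisher_ci(1, 20), c(1, 1))

  expect_equal(corr_pvalue(0, 30), 1)
  ps <- vapply(seq(0.05, 0.95, by = 0.1), corr_pvalue, numeric(1), n = 30)
  expect_true(all(diff(ps) < 0))
  expect_warning(p1 <- corr_pvalue(1, 10), "exactly 0")
  expect_equal(p1, 0)
  tt <- 0.75 * sqrt(28) / sqrt(1 - 0.75^2)
  expect_equal(corr_pvalue(0.75, 30), 2 * pt(-tt, df = 28))
})

test_that("scores are coefficient-weighted allele counts with flips and imputation", {
  # 2-SNP toy: b = (0.5, -1), dosages (2, 1) -> score 0
  pan <- manual_panel(rbind(c(2L, 1L), c(0L, 2L)))
  model <- structure(
    list(snp_ids = pan$snp_ids, effect_allele = pan$map$allele1,
         other_allele = pan$map$allele2, coefficient = c(0.5, -1),
         frequency = c(0.5, 0.75), mu = 0, n_train = 2L, m = 2L,
         sigma_g2 = 1, sigma_e2 = 1),
    class = "snp_effect_model")
  s <- score_lines(model, pan)
  expect_equal(as.numeric(s), c(0, -2))

  # zero coefficients -> zero scores
  model0 <- model; model0$coefficient <- c(0, 0)
  expect_equal(as.numeric(score_lines(model0, pan)), c(0, 0))

  # allele flip: panel counting the other allele gives identical scores
  pan_flip <- genotype_panel(2L - pan$dosage, pan$sample_ids, pan$snp_ids,
                             pan$map$chromosome, pan$map$position,
                             allele1 = pan$map$allele2,
                             allele2 = pan$map$allele1)
  expect_equal(as.numeric(score_lines(model, pan_flip)), as.numeric(s))

  # missing call imputed at 2p from the model's stored frequency
  d_na <- pan$dosage; d_na[1, 1] <- NA_integer_
  pan_na <- manual_panel(d_na)
  s_na <- score_lines(model, pan_na)
  expect_equal(as.numeric(s_na[1]), 0.5 * (2 * 0.5) + (-1) * 1)

  # irreconcilable alleles are excluded; > 50% unusable is an error
  pan_bad1 <- manual_panel(pan$dosage, a1 = c("A", "T"), a2 = c("G", "C"))
  expect_warning(s_bad <- score_lines(model, pan_bad1), "irreconcilable")
  expect_equal(attr(s_bad, "n_excluded"), 1L)
  pan_bad2 <- manual_panel(pan$dosage, a1 = c("T", "T"), a2 = c("C", "C"))
  expect_error(score_lines(model, pan_bad2), "unusable")
})

test_that("exported coefficients reproduce in-memory scores bit-exactly", {
  sim <- tiny_sim(n = 20, m = 40, seed = 16, missing_rate = 0.04)
  g <- compute_grm(sim$panel, grm_missing_max = 1)
  y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
  vc <- reml_fit(y, g)
  bv <- blup_breeding_values(vc, y, g)
  model <- backsolve_snp_effects(bv, vc, sim$panel)

  path <- withr::local_tempfile(fileext = ".tsv")
  export_coefficients(model, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header, c("snp_id", "allele", "coefficient", "frequency"))
  expect_equal(length(readLines(path)) - 1L, length(sim$panel$snp_ids))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  export_coefficients(model, path3, include_freq = FALSE)
  expect_length(strsplit(readLines(path3, n = 1), "\t")[[1]], 3L)

  oa <- setNames(model$other_allele, model$snp_ids)
  model_back <- read_snp_effects(path, other_alleles = oa)
  expect_identical(score_lines(model_back, sim$panel),
                   score_lines(model, sim$panel))
})

test_that("two-tier significance verdict matches exhaustive evaluation", {
  expect_true(significance_decision(
    c(0.0005, 0.01, 0.02, 0.04, 0.03))$significant)
  expect_false(significance_decision(
    c(0.0005, 0.06, 0.01, 0.01, 0.01))$significant)
  # all five below nominal but none below the adjusted threshold
  expect_false(significance_decision(rep(0.002, 5))$significant)

  # truth table over enumerated p-vectors
  levels <- c(0.0005, 0.002, 0.03, 0.07)
  grid <- expand.grid(p1 = levels, p2 = levels, p3 = levels)
  for (i in seq_len(nrow(grid))) {
    p <- as.numeric(grid[i, ])
    truth <- (min(p) < 0.001) && all(p < 0.05)
    res <- significance_decision(p)
    expect_identical(res$significant, truth)
    expect_equal(res$n_below_nominal, sum(p < 0.05))
    expect_equal(res$n_below_adjusted, sum(p < 0.001))
  }
})

test_that("cross-validation isolates training from test data", {
  sim <- tiny_sim(n = 60, m = 80, seed = 17, h2 = 0.6)
  cv1 <- cross_validate(sim$panel, sim$phenotypes, "trait1", k = 3,
                        seed = 5, keep_models = TRUE)

  # perturb the phenotypes of fold 1's *test* lines only
  fold1_ids <- names(cv1$assignment)[cv1$assignment == 1]
  ph2 <- sim$phenotypes
  sel <- ph2$line_id %in% fold1_ids
  ph2$value[sel] <- ph2$value[sel] + rnorm(sum(sel), 50, 10)
  cv2 <- cross_validate(sim$panel, ph2, "trait1", k = 3, seed = 5,
                        keep_models = TRUE)

  # the model trained without fold 1 must be identical
  expect_identical(cv1$models[[1]]$coefficient, cv2$models[[1]]$coefficient)
  expect_identical(cv1$models[[1]]$frequency, cv2$models[[1]]$frequency)
  # while folds trained *with* those lines must differ
  expect_false(identical(cv1$models[[2]]$coefficient,
                         cv2$models[[2]]$coefficient))
})

test_that("cross-validation reports are deterministic and well-formed", {
  sim <- tiny_sim(n = 45, m = 60, seed = 18, h2 = 0.6)
  cv1 <- cross_validate(sim$panel, sim$phenotypes, "trait1", k = 5, seed = 2)
  cv2 <- cross_validate(sim$panel, sim$phenotypes, "trait1", k = 5, seed = 2)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(nrow(cv1$folds), 5L)
  expect_true(all(cv1$folds$n_train + cv1$folds$n_test == 45L))
  with(cv1$folds, {
    expect_true(all(ci_low <= r & r <= ci_high))
    expect_true(all(p_value > 0 & p_value <= 1))
  })
  expect_equal(cv1$mean_r, mean(cv1$folds$r))
})

test_that("prediction accuracy increases with heritability", {
  mean_r_at <- function(h2) {
    mean(vapply(1:3, function(s) {
      sim <- tiny_sim(n = 250, m = 500, n_chromosomes = 5, h2 = h2,
                      n_causal = 100, seed = 100 + s)
      cross_validate(sim$panel, sim$phenotypes, "trait1", k = 5,
                     seed = s)$mean_r
    }, numeric(1)))
  }
  expect_gt(mean_r_at(0.8), mean_r_at(0.2))
})

test_that("trait correlation matrix is symmetric with unit diagonal", {
  sim <- tiny_sim(n = 149, m = 60, n_traits = 3, seed = 19,
                  pleiotropy_frac = 0)
  R <- trait_correlation_matrix(sim$phenotypes)
  expect_identical(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  # independent architectures + independent environments: near-zero r
  expect_lt(max(abs(R[upper.tri(R)])), 0.3)

  ph_const <- sim$phenotypes
  ph_const$value[ph_const$trait == "trait2"] <- 5
  expect_error(trait_correlation_matrix(ph_const), "constant")
})
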