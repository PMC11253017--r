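test_that("REML optimum beats a dense restricted-likelihood grid", {
  for (seed in 1:5) {
    sim <- tiny_sim(n = 30, m = 80, seed = seed, h2 = 0.5)
    g <- compute_grm(sim$panel, diagonal = "standard")
    y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
    y <- (y - mean(y)) / sd(y)  # unit scale so the [0.01, 5]^2 grid bites
    vc <- reml_fit(y, g)

    grid <- seq(0.01, 5, length.out = 50)
    ll_fit <- ll_reml_dense(vc$sigma_g2, vc$sigma_e2, unname(y), unname(g$A))
    ll_grid <- outer(grid, grid, Vectorize(function(a, b) {
      ll_reml_dense(a, b, unname(y), unname(g$A))
    }))
    expect_gte(ll_fit, max(ll_grid) - 1e-9)
    # and the eigendecomposition likelihood agrees with the dense formula
    expect_equal(vc$loglik, ll_fit, tolerance = 1e-8)
  }
})

test_that("accepted EM iterations never decrease the likelihood", {
  sim <- tiny_sim(n = 40, m = 100, seed = 9, h2 = 0.4)
  g <- compute_grm(sim$panel)
  y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
  vc <- reml_fit(y, g)
  dll <- diff(vc$loglik_trace)
  em <- vc$update_type == "EM"
  expect_true(all(dll[em] >= -1e-8))
  expect_true(vc$converged)
  expect_true(vc$sigma_g2 >= 0 && vc$sigma_e2 >= 0)
  expect_true(vc$h2 >= 0 && vc$h2 <= 1)
})

test_that("identity relationship matrix is flagged as unidentifiable", {
  y <- setNames(rnorm(30, 5, 1), paste0("id", 1:30))
  A <- diag(30)
  dimnames(A) <- list(names(y), names(y))
  expect_warning(vc <- reml_fit(y, A), "identi")
  expect_false(vc$identifiable)
  # only the sum is identified; it should match the sample variance scale
  expect_equal(vc$sigma_g2 + vc$sigma_e2, var(as.numeric(y)),
               tolerance = 0.15)
})

test_that("guards reject degenerate inputs", {
  y <- setNames(rnorm(20), paste0("id", 1:20))
  A <- diag(20); dimnames(A) <- list(names(y), names(y))
  expect_error(reml_fit(y[1:5], A[1:5, 1:5]), "at least 10")
  expect_error(reml_fit(setNames(rep(1, 20), names(y)), A), "zero variance")
  A_bad <- A; A_bad[1, 2] <- 0.5
  expect_error(suppressWarnings(reml_fit(y, A_bad)), "symmetric")
  y_bad <- y; y_bad[3] <- NA
  expect_error(reml_fit(y_bad, A), "non-finite")
})

test_that("BLUP matches dense Henderson mixed-model equations", {
  for (seed in 1:4) {
    # frequency-centered GRMs are exactly singular (the 1-vector is in
    # their null space), so the MME route needs a proper-rank relationship
    # matrix: add a small diagonal ridge to both sides of the comparison
    sim <- tiny_sim(n = 12, m = 120, seed = seed, h2 = 0.6)
    g <- compute_grm(sim$panel, diagonal = "standard")
    A <- g$A + diag(0.05, 12)
    y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
    y <- (y - mean(y)) / sd(y)  # unit scale: 1e-10 is an absolute bound
    vc <- suppressWarnings(reml_fit(y, A, max_iter = 200))
    bv <- blup_breeding_values(vc, y, A)
    mme <- henderson_mme(unname(y), unname(A), vc$sigma_g2, vc$sigma_e2)
    expect_lt(max(abs(unname(bv$bv) - mme$g)), 1e-10)
    expect_lt(abs(bv$mu - mme$mu), 1e-10)
  }
})

test_that("BLUPs shrink to zero as genetic variance vanishes", {
  sim <- tiny_sim(n = 20, m = 50, seed = 11)
  g <- compute_grm(sim$panel, diagonal = "standard")
  y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
  vc0 <- fixed_vc(1e-9, 1, g$sample_ids)
  bv0 <- blup_breeding_values(vc0, y, g)
  expect_lt(max(abs(bv0$bv)), 1e-6)
  expect_equal(bv0$mu, mean(y), tolerance = 1e-4)
})

test_that("GBLUP equals ridge SNP-BLUP genomic values (shared components)", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(15:50, 1)
    m <- sample(30:200, 1)
    sim <- tiny_sim(n = n, m = m, seed = seed, h2 = 0.5,
                    inbreeding = sample(c(1, 0.5), 1))
    g <- compute_grm(sim$panel, diagonal = "standard")
    y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
    vc <- fixed_vc(1.3, 0.9, g$sample_ids)
    bv <- blup_breeding_values(vc, y, g)
    rr <- ridge_snp_blup(y, sim$panel, lambda = vc$sigma_e2 / vc$sigma_g2)
    expect_lt(max(abs(bv$bv - rr$fitted[names(bv$bv)])), 1e-8)
  }
})

test_that("ridge effects vanish as lambda grows and match scalar algebra", {
  sim <- tiny_sim(n = 20, m = 30, seed = 13)
  y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
  rr <- ridge_snp_blup(y, sim$panel, lambda = 1e10)
  expect_lt(max(abs(rr$effects)), 1e-6)

  # single SNP, n = 4: closed-form (w'w + lambda)^(-1) w'(y - ybar)
  pan <- manual_panel(matrix(c(0L, 0L, 2L, 2L), 4, 1))
  y4 <- setNames(c(1, 2, 3, 6), pan$sample_ids)
  lambda <- 0.7
  w <- (c(0, 0, 2, 2) - 1) / sqrt(2 * 0.5 * 0.5)
  expected <- sum(w * (y4 - mean(y4))) / (sum(w^2) + lambda * 1)
  rr4 <- ridge_snp_blup(y4, pan, lambda = lambda)
  expect_equal(unname(rr4$effects), expected, tolerance = 1e-12)
})

test_that("back-solved SNP effects match the dense formula and re-score ghat", {
  sim <- tiny_sim(n = 25, m = 60, seed = 14, h2 = 0.5)
  g <- compute_grm(sim$panel, diagonal = "standard")
  y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
  vc <- reml_fit(y, g)
  bv <- blup_breeding_values(vc, y, g)
  model <- backsolve_snp_effects(bv, vc, sim$panel)

  # dense oracle: u = (sg2/m) W' V^-1 (y - mu), over polymorphic SNPs
  p <- allele_frequencies(sim$panel)
  poly <- p > 0 & p < 1
  W <- standardize_dosage(sim$panel$dosage)
  m <- ncol(W)
  V <- vc$sigma_g2 * unname(g$A) + diag(vc$sigma_e2, 25)
  u <- (vc$sigma_g2 / m) * drop(t(W) %*% solve(V, unname(y) - bv$mu))
  b_expected <- u / sqrt(2 * p[poly] * (1 - p[poly]))
  expect_lt(max(abs(model$coefficient[poly] - unname(b_expected))), 1e-10)
  expect_true(all(model$coefficient[!poly] == 0))

  # scoring the training lines reproduces ghat up to an additive constant
  scores <- score_lines(model, sim$panel)
  dev <- (scores - mean(scores)) - (bv$bv - mean(bv$bv))
  expect_lt(max(abs(dev)), 1e-8)

  # zero genetic variance -> all coefficients zero
  vc0 <- fixed_vc(0, 1, g$sample_ids)
  bv0 <- blup_breeding_values(vc0, y, g)
  model0 <- backsolve_snp_effects(bv0, vc0, sim$panel)
  expect_true(all(model0$coefficient == 0))
})

test_that("REML estimates are invariant to sample reordering", {
  sim <- tiny_sim(n = 30, m = 80, seed = 15, h2 = 0.5)
  g <- compute_grm(sim$panel)
  y <- line_means(sim$phenotypes, "trait1", sim$panel$sample_ids)
  vc <- reml_fit(y, g)

  perm <- sample(30)
  panel_p <- subset_panel(sim$panel, samples = perm)
  g_p <- compute_grm(panel_p)
  y_p <- y[panel_p$sample_ids]
  vc_p <- reml_fit(y_p, g_p)
  expect_equal(vc_p$sigma_g2, vc$sigma_g2, tolerance = 1e-6)
  expect_equal(vc_p$sigma_e2, vc$sigma_e2, tolerance = 1e-6)
  expect_equal(vc_p$loglik, vc$loglik, tolerance = 1e-8)

  bv <- blup_breeding_values(vc, y, g)
  bv_p <- blup_breeding_values(vc_p, y_p, g_p)
  expect_equal(bv_p$bv[names(bv$bv)], bv$bv, tolerance = 1e-6)
})
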