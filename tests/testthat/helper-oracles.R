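# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (dense algebra, double loops,
# brute-force enumeration) so it cannot share a code path with the
# package implementation it checks.

# Small simulated panel with phenotypes for one or more traits.
tiny_sim <- function(n = 40, m = 120, n_traits = 1, h2 = 0.5, seed = 1,
                     n_chromosomes = 2, n_causal = 30, ld_rho = 0.3,
                     missing_rate = 0, inbreeding = 1, ...) {
  cfg <- panel_config(
    n_lines = n, n_snps = m, n_chromosomes = n_chromosomes,
    n_traits = n_traits, h2 = h2, n_causal = max(1, min(n_causal, m)),
    ld_rho = ld_rho,
    missing_rate = missing_rate, inbreeding = inbreeding,
    trait_means = 100, seed = seed, ...
  )
  c(simulate_panel(cfg), list(config = cfg))
}

# Hand-built panel from an explicit dosage matrix.
manual_panel <- function(dosage, a1 = NULL, a2 = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  genotype_panel(
    dosage,
    sample_ids = sprintf("s%02d", seq_len(n)),
    snp_ids = sprintf("snp%03d", seq_len(m)),
    chromosome = rep("1", m),
    position = seq_len(m) * 100L,
    allele1 = a1 %||% rep("A", m),
    allele2 = a2 %||% rep("G", m)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2 m) per-entry GRM oracle with pairwise-complete missing handling.
naive_grm <- function(dosage, diagonal = "standard") {
  n <- nrow(dosage)
  called <- colSums(!is.na(dosage))
  p <- colSums(dosage, na.rm = TRUE) / (2 * called)
  use <- which(p > 0 & p < 1)
  A <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      num <- 0
      cnt <- 0
      for (i in use) {
        xj <- dosage[j, i]
        xk <- dosage[k, i]
        if (!is.na(xj) && !is.na(xk)) {
          num <- num + (xj - 2 * p[i]) * (xk - 2 * p[i]) /
            (2 * p[i] * (1 - p[i]))
          cnt <- cnt + 1
        }
      }
      A[j, k] <- num / cnt
    }
  }
  if (diagonal == "yang") {
    for (j in seq_len(n)) {
      num <- 0
      cnt <- 0
      for (i in use) {
        x <- dosage[j, i]
        if (!is.na(x)) {
          num <- num + (x^2 - (1 + 2 * p[i]) * x + 2 * p[i]^2) /
            (2 * p[i] * (1 - p[i]))
          cnt <- cnt + 1
        }
      }
      A[j, j] <- 1 + num / cnt
    }
  }
  A
}

# Dense restricted log-likelihood, straight from the determinant formula.
ll_reml_dense <- function(sg2, se2, y, A) {
  n <- length(y)
  V <- sg2 * A + diag(se2, n)
  Vinv <- solve(V)
  one <- rep(1, n)
  xvx <- drop(t(one) %*% Vinv %*% one)
  beta <- drop(t(one) %*% Vinv %*% y) / xvx
  r <- y - beta
  -0.5 * (determinant(V, logarithm = TRUE)$modulus[1] + log(xvx) +
            drop(t(r) %*% Vinv %*% r))
}

# Henderson mixed-model-equation solve (dense, requires invertible A).
henderson_mme <- function(y, A, sg2, se2) {
  n <- length(y)
  lambda <- se2 / sg2
  one <- matrix(1, n, 1)
  lhs <- rbind(
    cbind(t(one) %*% one, t(one)),
    cbind(one, diag(n) + lambda * solve(A))
  )
  rhs <- c(sum(y), y)
  sol <- solve(lhs, rhs)
  list(mu = sol[1], g = sol[-1])
}

# Column-standardized dosage matrix (sample allele frequencies).
standardize_dosage <- function(dosage) {
  p <- colMeans(dosage) / 2
  keep <- p > 0 & p < 1
  sweep(sweep(dosage[, keep, drop = FALSE], 2, 2 * p[keep]), 2,
        sqrt(2 * p[keep] * (1 - p[keep])), "/")
}

# variance_components stub for tests that fix the components by hand.
fixed_vc <- function(sg2, se2, ids, mean_diag = 1) {
  structure(
    list(sigma_g2 = sg2, sigma_e2 = se2,
         h2 = mean_diag * sg2 / (mean_diag * sg2 + se2),
         se_sigma_g2 = NA_real_, se_sigma_e2 = NA_real_, se_h2 = NA_real_,
         mean_diag = mean_diag, loglik = NA_real_, n_iterations = 0L,
         converged = TRUE, boundary = FALSE, identifiable = TRUE,
         loglik_trace = numeric(0), update_type = character(0),
         sample_ids = ids, n = length(ids)),
    class = "variance_components"
  )
}
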