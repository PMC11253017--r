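#' BLUP breeding values from a fitted GBLUP model
#'
#' Given REML variance components, computes the generalized-least-squares
#' intercept \eqn{\hat\mu = (1^\top V^{-1} 1)^{-1} 1^\top V^{-1} y} and the
#' best linear unbiased predictions
#' \eqn{\hat g = \hat\sigma^2_g A V^{-1} (y - 1\hat\mu)} with
#' \eqn{V = A\hat\sigma^2_g + I\hat\sigma^2_e}. Breeding values are
#' deviations from the population mean, in trait units.
#'
#' @param vc `variance_components` from [reml_fit()] on the same `(y, A)`.
#' @param y Named per-line trait means (same lines as the fit).
#' @param A `grm` or matrix used in the fit.
#' @param pev Also compute per-line prediction error variances
#'   (`diag(sigma_g2 A - sigma_g2^2 A P A)`); costs a dense solve.
#' @return Object of class `breeding_values`: `sample_ids`, `bv`, `mu`,
#'   optional `pev`, and internals reused by [backsolve_snp_effects()].
#' @export
blup_breeding_values <- function(vc, y, A, pev = FALSE) {
  stopifnot(inherits(vc, "variance_components"))
  Am <- grm_matrix(A, y)
  y <- as.numeric(stats::setNames(y, names(y))[rownames(Am)])
  n <- length(y)
  if (!vc$converged) {
    warning("variance components did not converge; BLUPs may be unreliable")
  }
  # invert V = sg2 A + se2 I in the eigenbasis of A: stays well-defined for
  # near-boundary fits and the slightly indefinite Yang-diagonal GRMs as
  # long as every lam_i sg2 + se2 > 0
  eg <- eigen((Am + t(Am)) / 2, symmetric = TRUE)
  v <- eg$values * vc$sigma_g2 + vc$sigma_e2
  if (any(v <= 0)) {
    stop("V is numerically singular (eigenvalue ", format(min(v)),
         "); consider adding a small jitter to the GRM diagonal",
         call. = FALSE)
  }
  Vinv <- eg$vectors %*% (t(eg$vectors) / v)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vinv %*% y)) / drop(crossprod(one, Vinv %*% one))
  r <- y - mu
  vinv_r <- drop(Vinv %*% r)
  g <- vc$sigma_g2 * drop(Am %*% vinv_r)

  pev_vec <- NULL
  if (pev) {
    xvx <- drop(crossprod(one, Vinv %*% one))
    P <- Vinv - (Vinv %*% one %*% t(one) %*% Vinv) / xvx
    pev_vec <- pmax(diag(vc$sigma_g2 * Am -
                           vc$sigma_g2^2 * Am %*% P %*% Am), 0)
    names(pev_vec) <- rownames(Am)
  }

  structure(
    list(sample_ids = rownames(Am),
         bv = stats::setNames(g, rownames(Am)),
         mu = mu, pev = pev_vec,
         sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
         vinv_r = stats::setNames(vinv_r, rownames(Am))),
    class = "breeding_values"
  )
}

#' @export
print.breeding_values <- function(x, ...) {
  cat(sprintf("<breeding_values> %d lines, mu = %.4g, bv range [%.4g, %.4g]\n",
              length(x$bv), x$mu, min(x$bv), max(x$bv)))
  invisible(x)
}

#' Write breeding values as TSV (FID/IID/BV layout)
#'
#' @param bv A `breeding_values`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breeding_values <- function(bv, path) {
  stopifnot(inherits(bv, "breeding_values"))
  utils::write.table(
    data.frame(FID = bv$sample_ids, IID = bv$sample_ids, BV = unname(bv$bv)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Back-solve per-SNP coefficients from GBLUP breeding values
#'
#' Converts the line-level GBLUP solution into marker effects via the
#' ridge/GBLUP equivalence: on the column-standardized genotype scale
#' \eqn{\hat u = (\hat\sigma^2_g / m) W^\top V^{-1}(y - 1\hat\mu)}, then the
#' per-allele (dosage-scale) coefficient is
#' \eqn{b_i = \hat u_i / \sqrt{2 p_i (1 - p_i)}}. Together with the stored
#' allele frequencies and the counted-allele labels, the coefficients form
#' a portable score file: any genotyped line can be scored without the
#' training data. Missing calls are mean-imputed at dosage \eqn{2 p_i}
#' before standardizing; monomorphic SNPs get coefficient 0 with a warning.
#'
#' @param bv `breeding_values` from [blup_breeding_values()].
#' @param vc The matching `variance_components`.
#' @param panel The training [genotype_panel()] (the one the GRM came from).
#' @param p Optional allele frequencies; default [allele_frequencies()] of
#'   `panel`.
#' @return Object of class `snp_effect_model`: `snp_ids`, `effect_allele`,
#'   `other_allele`, `coefficient` (trait units per allele copy),
#'   `frequency`, `mu`, and training metadata.
#' @export
backsolve_snp_effects <- function(bv, vc, panel, p = NULL) {
  stopifnot(inherits(bv, "breeding_values"),
            inherits(vc, "variance_components"),
            inherits(panel, "genotype_panel"))
  idx <- match(bv$sample_ids, panel$sample_ids)
  if (anyNA(idx)) {
    stop("breeding values and panel have mismatched sample ids",
         call. = FALSE)
  }
  d <- panel$dosage[idx, , drop = FALSE]
  if (is.null(p)) p <- allele_frequencies(panel)
  p <- p[panel$snp_ids]

  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) assigned coefficient 0")
  }
  m <- sum(!mono)
  if (m == 0) stop("no polymorphic SNPs to back-solve", call. = FALSE)

  sd2p <- sqrt(2 * p * (1 - p))
  x <- d
  if (anyNA(x)) {
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- 2 * p[na_idx[, 2]]
  }
  W <- sweep(sweep(x, 2, 2 * p), 2, ifelse(mono, 1, sd2p), "/")
  W[, mono] <- 0
  u <- (vc$sigma_g2 / m) * drop(crossprod(W, bv$vinv_r))
  b <- ifelse(mono, 0, u / ifelse(mono, 1, sd2p))

  structure(
    list(snp_ids = panel$snp_ids,
         effect_allele = panel$map$allele1,
         other_allele = panel$map$allele2,
         coefficient = unname(b),
         frequency = unname(p),
         mu = bv$mu,
         n_train = length(bv$sample_ids), m = m,
         sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2),
    class = "snp_effect_model"
  )
}

#' @export
print.snp_effect_model <- function(x, ...) {
  cat(sprintf(
    "<snp_effect_model> %d SNPs (%d polymorphic), trained on %d lines\n",
    length(x$snp_ids), x$m, x$n_train))
  invisible(x)
}

#' Ridge-regression SNP-BLUP (direct marker-effect solve)
#'
#' Solves \eqn{\hat u = (W^\top W + \lambda m I)^{-1} W^\top (y - \bar y)}
#' on column-standardized genotypes with \eqn{\lambda =
#' \sigma^2_e/\sigma^2_g}, the marker-space formulation that is
#' algebraically identical to GBLUP with the standard-diagonal GRM
#' \eqn{A = WW^\top/m}. Used as an independent route to the same genomic
#' values; requires a panel without missing calls.
#'
#' @param y Named per-line trait means.
#' @param panel [genotype_panel()] with no missing calls.
#' @param lambda Ridge ratio `sigma_e2 / sigma_g2`.
#' @return List with `effects` (standardized scale), `fitted` (genomic
#'   values `W effects`, named), `lambda`, `m`.
#' @export
ridge_snp_blup <- function(y, panel, lambda) {
  stopifnot(inherits(panel, "genotype_panel"), lambda >= 0)
  if (anyNA(panel$dosage)) {
    stop("ridge_snp_blup requires a panel without missing calls",
         call. = FALSE)
  }
  idx <- match(names(y), panel$sample_ids)
  if (anyNA(idx)) stop("names(y) must match panel sample ids", call. = FALSE)
  d <- panel$dosage[idx, , drop = FALSE]
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  W <- sweep(sweep(d[, poly, drop = FALSE], 2, 2 * p[poly]), 2,
             sqrt(2 * p[poly] * (1 - p[poly])), "/")
  m <- ncol(W)
  yc <- as.numeric(y) - mean(y)
  G <- crossprod(W) + diag(lambda * m, m)
  u <- tryCatch(solve(G, crossprod(W, yc)), error = function(e) {
    warning("singular ridge system; using pseudo-inverse")
    MASS::ginv(G) %*% crossprod(W, yc)
  })
  u <- drop(u)
  effects <- stats::setNames(rep(0, length(panel$snp_ids)), panel$snp_ids)
  effects[poly] <- u
  fitted <- stats::setNames(drop(W %*% u), names(y))
  list(effects = effects, fitted = fitted, lambda = lambda, m = m)
}
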