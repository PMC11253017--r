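#' Configuration for the synthetic panel generator
#'
#' Builds the parameter set for [simulate_genotypes()] and
#' [simulate_phenotypes()]. The defaults describe the study design the
#' package targets: a diversity panel of 149 fully inbred spring wheat lines
#' genotyped at 11,405 array SNPs on 21 chromosomes, phenotyped for the grain
#' content of seven elements (K, Ca, Mg, Mn, Fe, Zn, Cu) with four
#' measurements per line (two field years x two replicates), i.e. 596
#' phenotypic records per trait.
#'
#' Per-trait arguments (`h2`, `n_causal`, `trait_means`, `trait_sds`,
#' `year_sd`) are recycled to `n_traits` if scalar.
#'
#' @param n_lines Number of inbred lines.
#' @param n_snps Number of biallelic SNPs.
#' @param n_chromosomes Number of chromosomes; SNPs are split evenly and
#'   linkage disequilibrium does not cross chromosome boundaries.
#' @param maf_low,maf_high Bounds of the uniform distribution the per-SNP
#'   counted-allele frequency is drawn from, in (0, 0.5].
#' @param ld_rho Adjacent-SNP correlation of the latent Gaussian process in
#'   `[0, 1)`; 0 gives independent SNPs.
#' @param n_traits Number of (possibly genetically correlated) traits.
#' @param h2 Target narrow-sense heritability per trait, on the scale of
#'   per-line mean phenotypes, in `[0, 1]`.
#' @param n_causal Causal SNPs per trait; default `min(300, n_snps)`.
#' @param pleiotropy_frac Fraction of each trait's causal SNPs drawn from a
#'   pool shared (with shared effect sizes) by all traits; induces positive
#'   genetic correlation between traits.
#' @param n_years Number of measurement years.
#' @param reps_per_year Replicates per year.
#' @param trait_means Population mean per trait (mg/kg).
#' @param trait_sds Phenotypic standard deviation of per-line means per trait
#'   (mg/kg). Default 10% of `trait_means`.
#' @param year_sd Standard deviation of the per-(line, year) environmental
#'   effect (trait units). Default 5% of `trait_means`.
#' @param inbreeding Probability a line is fully autozygous; 1 (default)
#'   makes all dosages 0 or 2, as for selfing wheat varieties.
#' @param missing_rate Probability a genotype call is set missing.
#' @param seed RNG seed; the generator is deterministic given the config.
#' @param trait_names Optional trait labels; default the seven grain
#'   elements when `n_traits == 7`, otherwise `trait1..`.
#'
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_lines = 149, n_snps = 11405, n_chromosomes = 21,
                         maf_low = 0.05, maf_high = 0.5, ld_rho = 0.9,
                         n_traits = 7,
                         h2 = c(0.70, 0.65, 0.50, 0.60, 0.45, 0.50, 0.55),
                         n_causal = NULL, pleiotropy_frac = 0.3,
                         n_years = 2, reps_per_year = 2,
                         trait_means = c(4300, 420, 1150, 46, 38, 29, 5.1),
                         trait_sds = NULL, year_sd = NULL,
                         inbreeding = 1, missing_rate = 0, seed = 1,
                         trait_names = NULL) {
  n_lines <- check_count(n_lines, "n_lines")
  n_snps <- check_count(n_snps, "n_snps")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  n_traits <- check_count(n_traits, "n_traits")
  n_years <- check_count(n_years, "n_years")
  reps_per_year <- check_count(reps_per_year, "reps_per_year")
  check_prob(maf_low, "maf_low", lo = 1e-12, hi = 0.5)
  check_prob(maf_high, "maf_high", lo = 1e-12, hi = 0.5)
  if (maf_low > maf_high) stop("maf_low must be <= maf_high", call. = FALSE)
  check_prob(ld_rho, "ld_rho", hi = 1 - 1e-12)
  check_prob(pleiotropy_frac, "pleiotropy_frac")
  check_prob(inbreeding, "inbreeding")
  check_prob(missing_rate, "missing_rate")
  if (n_snps < n_chromosomes) {
    stop("n_snps must be >= n_chromosomes", call. = FALSE)
  }

  recycle <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, n_traits)
    if (length(x) == n_traits) return(x)
    # defaults sized for 7 traits: truncate/recycle explicitly otherwise
    if (length(x) > n_traits) return(x[seq_len(n_traits)])
    stop(sprintf("`%s` must have length 1 or n_traits", name), call. = FALSE)
  }
  h2 <- check_prob(recycle(h2, "h2"), "h2")
  trait_means <- recycle(trait_means, "trait_means")
  trait_sds <- if (is.null(trait_sds)) 0.1 * abs(trait_means) else
    recycle(trait_sds, "trait_sds")
  year_sd <- if (is.null(year_sd)) 0.05 * abs(trait_means) else
    recycle(year_sd, "year_sd")
  if (any(trait_sds <= 0)) stop("trait_sds must be positive", call. = FALSE)
  if (any(year_sd < 0)) stop("year_sd must be non-negative", call. = FALSE)
  if (is.null(n_causal)) n_causal <- min(300L, n_snps)
  n_causal <- vapply(recycle(n_causal, "n_causal"), check_count,
                     integer(1), name = "n_causal")
  if (any(n_causal > n_snps)) {
    stop("n_causal must be <= n_snps", call. = FALSE)
  }
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 7L) {
      c("K", "Ca", "Mg", "Mn", "Fe", "Zn", "Cu")
    } else {
      paste0("trait", seq_len(n_traits))
    }
  }
  stopifnot(length(trait_names) == n_traits, !anyDuplicated(trait_names))

  structure(
    list(
      n_lines = n_lines, n_snps = n_snps, n_chromosomes = n_chromosomes,
      maf_low = maf_low, maf_high = maf_high, ld_rho = ld_rho,
      n_traits = n_traits, h2 = h2, n_causal = n_causal,
      pleiotropy_frac = pleiotropy_frac, n_years = n_years,
      reps_per_year = reps_per_year, trait_means = trait_means,
      trait_sds = trait_sds, year_sd = year_sd, inbreeding = inbreeding,
      missing_rate = missing_rate, seed = as.integer(seed),
      trait_names = trait_names
    ),
    class = "panel_config"
  )
}

#' Read/write a panel configuration as YAML
#'
#' @param path File path.
#' @param config A `panel_config`.
#' @return `read_panel_config` returns a `panel_config`;
#'   `write_panel_config` returns `path` invisibly.
#' @export
read_panel_config <- function(path) {
  do.call(panel_config, yaml::read_yaml(path))
}

#' @rdname read_panel_config
#' @export
write_panel_config <- function(config, path) {
  stopifnot(inherits(config, "panel_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Split n_snps as evenly as possible across chromosomes.
chromosome_blocks <- function(n_snps, n_chromosomes) {
  sizes <- rep(n_snps %/% n_chromosomes, n_chromosomes)
  extra <- n_snps %% n_chromosomes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Latent AR(1) Gaussian field: one row per line, one column per SNP,
# correlation ld_rho between adjacent SNPs, reset at chromosome boundaries.
latent_ar1 <- function(n_lines, block_sizes, rho) {
  m <- sum(block_sizes)
  z <- matrix(stats::rnorm(n_lines * m), n_lines, m)
  if (rho > 0) {
    s <- sqrt(1 - rho^2)
    start <- cumsum(c(1L, block_sizes[-length(block_sizes)]))
    is_start <- rep(FALSE, m)
    is_start[start] <- TRUE
    for (j in 2:m) {
      if (!is_start[j]) z[, j] <- rho * z[, j - 1L] + s * z[, j]
    }
  }
  z
}

#' Simulate genotypes for a panel of inbred lines
#'
#' Draws a biallelic dosage matrix with local linkage disequilibrium via a
#' first-order autoregressive latent Gaussian copula: each line carries one
#' (fully inbred) or two latent AR(1) chains per chromosome, thresholded at
#' the per-SNP counted-allele frequency. Per-SNP frequencies are uniform on
#' `[maf_low, maf_high]`. Deterministic given `config$seed`.
#'
#' @param config A [panel_config()].
#' @return A [genotype_panel()] with dosages in \{0, 2\} for fully inbred
#'   lines (plus 1 under partial inbreeding) and `NA` where missingness was
#'   injected.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_lines
  m <- config$n_snps
  blocks <- chromosome_blocks(m, config$n_chromosomes)

  with_seed(stage_seed(config$seed, "genotypes"), {
    p <- stats::runif(m, config$maf_low, config$maf_high)
    thr <- stats::qnorm(p)
    thr_mat <- matrix(thr, n, m, byrow = TRUE)

    z1 <- latent_ar1(n, blocks, config$ld_rho)
    a1 <- (z1 < thr_mat)
    if (config$inbreeding >= 1) {
      dosage <- 2L * a1
    } else {
      z2 <- latent_ar1(n, blocks, config$ld_rho)
      a2 <- (z2 < thr_mat)
      autozygous <- stats::runif(n) < config$inbreeding
      dosage <- a1 + a2
      dosage[autozygous, ] <- 2L * a1[autozygous, ]
    }
    storage.mode(dosage) <- "integer"

    alleles <- matrix(NA_character_, m, 2)
    bases <- c("A", "C", "G", "T")
    a1_idx <- sample.int(4L, m, replace = TRUE)
    a2_off <- sample.int(3L, m, replace = TRUE)
    alleles[, 1] <- bases[a1_idx]
    alleles[, 2] <- bases[(a1_idx - 1L + a2_off) %% 4L + 1L]

    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      dosage[miss] <- NA_integer_
    }

    chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), blocks)
    within <- sequence(blocks)
    genotype_panel(
      dosage = dosage,
      sample_ids = sprintf("line_%03d", seq_len(n)),
      snp_ids = sprintf("SNP_%05d", seq_len(m)),
      chromosome = chrom,
      position = within * 1000L,
      allele1 = alleles[, 1],
      allele2 = alleles[, 2]
    )
  })
}

#' Simulate replicated phenotypes with known genetic architecture
#'
#' For each trait, `n_causal` SNPs receive i.i.d. normal effects on the
#' standardized genotype scale (an infinitesimal-like architecture matching
#' the GBLUP working model). A fraction `pleiotropy_frac` of causal SNPs is
#' shared across traits with shared effect sizes, inducing positive genetic
#' correlation. True breeding values are rescaled so that
#' `Var(BV) / Var(per-line mean phenotype)` equals the target `h2` in
#' expectation. Each line gets `n_years * reps_per_year` observations:
#' `trait_mean + BV + year effect (per line-year cell) + residual`, with the
#' residual variance solved from `h2`, `trait_sds` and `year_sd` (and set to
#' zero when `h2 = 1` leaves none).
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param config The same [panel_config()] used for the panel.
#' @return A list with `phenotypes` (long data.frame: `line_id`, `trait`,
#'   `year`, `replicate`, `value`) and `architecture` (list of class
#'   `true_architecture`: `causal_indices`, `causal_effects`, `true_bv`
#'   matrix, `realized_h2`).
#' @export
simulate_phenotypes <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "panel_config"))
  n <- length(panel$sample_ids)
  m <- length(panel$snp_ids)
  if (n != config$n_lines || m != config$n_snps) {
    stop("panel dimensions do not match config", call. = FALSE)
  }
  ny <- config$n_years
  nr <- config$reps_per_year
  years <- 2018L + seq_len(ny) - 1L

  # line-mean environmental variance that the design must supply per trait
  P <- config$trait_sds^2
  env_mean_var <- (1 - config$h2) * P
  res_var <- (env_mean_var - config$year_sd^2 / ny) * ny * nr
  if (any(res_var < -1e-8 * P)) {
    bad <- config$trait_names[res_var < -1e-8 * P]
    stop("year_sd too large for target h2 (no residual variance left) for ",
         "trait(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  res_var[res_var < 0] <- 0

  with_seed(stage_seed(config$seed, "phenotypes"), {
    # sample-standardized genotypes; monomorphic-in-sample columns are zero
    x <- panel$dosage
    if (anyNA(x)) {
      # mean-impute for BV construction only
      mu_col <- colMeans(x, na.rm = TRUE)
      idx <- which(is.na(x), arr.ind = TRUE)
      x[idx] <- mu_col[idx[, 2]]
    }
    cm <- colMeans(x)
    csd <- sqrt(colMeans(x^2) - cm^2)

    n_shared <- round(config$pleiotropy_frac * config$n_causal)
    poly <- which(csd > 0)
    shared_idx <- if (max(n_shared) > 0) {
      sample(poly, max(n_shared))
    } else integer(0)
    shared_eff <- stats::rnorm(length(shared_idx))

    causal_indices <- vector("list", config$n_traits)
    causal_effects <- vector("list", config$n_traits)
    true_bv <- matrix(0, n, config$n_traits,
                      dimnames = list(panel$sample_ids, config$trait_names))
    realized_h2 <- stats::setNames(numeric(config$n_traits),
                                   config$trait_names)
    pheno <- vector("list", config$n_traits)

    for (t in seq_len(config$n_traits)) {
      nc <- config$n_causal[t]
      ns <- min(n_shared[t], length(shared_idx))
      own_pool <- setdiff(poly, shared_idx[seq_len(ns)])
      n_own <- min(nc - ns, length(own_pool))  # capped by polymorphic SNPs
      own <- if (n_own > 0) sample(own_pool, n_own) else integer(0)
      idx <- c(shared_idx[seq_len(ns)], own)
      eff <- c(shared_eff[seq_len(ns)], stats::rnorm(length(own))) /
        sqrt(length(idx))
      W <- sweep(sweep(x[, idx, drop = FALSE], 2, cm[idx]), 2, csd[idx], "/")
      bv <- drop(W %*% eff)
      sd_bv <- stats::sd(bv)
      target_sd <- sqrt(config$h2[t]) * config$trait_sds[t]
      if (sd_bv > 0 && target_sd > 0) {
        scl <- target_sd / sd_bv
        bv <- bv * scl
        eff <- eff * scl
      } else {
        bv <- rep(0, n)
        eff <- rep(0, length(eff))
      }
      true_bv[, t] <- bv
      causal_indices[[t]] <- idx
      causal_effects[[t]] <- eff

      year_eff <- matrix(stats::rnorm(n * ny, 0, config$year_sd[t]), n, ny)
      obs <- array(0, c(n, ny, nr))
      for (yy in seq_len(ny)) {
        for (rr in seq_len(nr)) {
          obs[, yy, rr] <- config$trait_means[t] + bv + year_eff[, yy] +
            stats::rnorm(n, 0, sqrt(res_var[t]))
        }
      }
      pheno[[t]] <- data.frame(
        line_id = rep(panel$sample_ids, times = ny * nr),
        trait = config$trait_names[t],
        year = rep(rep(years, each = n), times = nr),
        replicate = rep(seq_len(nr), each = n * ny),
        value = as.vector(obs),
        stringsAsFactors = FALSE
      )
      lm_t <- rowMeans(matrix(as.vector(obs), n, ny * nr))
      v <- stats::var(lm_t)
      realized_h2[t] <- if (v > 0) stats::var(bv) / v else 0
    }

    phenotypes <- do.call(rbind, pheno)
    rownames(phenotypes) <- NULL
    architecture <- structure(
      list(causal_indices = causal_indices, causal_effects = causal_effects,
           true_bv = true_bv, realized_h2 = realized_h2),
      class = "true_architecture"
    )
    list(phenotypes = phenotypes, architecture = architecture)
  })
}

#' Simulate a full panel (genotypes + phenotypes) in one call
#'
#' @param config A [panel_config()].
#' @return List with `panel`, `phenotypes`, `architecture`.
#' @export
simulate_panel <- function(config = panel_config()) {
  panel <- simulate_genotypes(config)
  ph <- simulate_phenotypes(panel, config)
  list(panel = panel, phenotypes = ph$phenotypes,
       architecture = ph$architecture)
}
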