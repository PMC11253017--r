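#' Random k-fold partition of lines
#'
#' Uniformly random assignment of lines to `k` folds with sizes differing
#' by at most one (`floor(n/k)` or `ceiling(n/k)`); deterministic given
#' `seed`. For 149 lines and `k = 5` the fold sizes are 30, 30, 30, 30, 29.
#'
#' @param sample_ids Line identifiers.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Object of class `fold_assignment`: named integer vector of fold
#'   labels in `1..k`, with attributes `k` and `seed`.
#' @export
kfold_split <- function(sample_ids, k = 5, seed = 1) {
  n <- length(sample_ids)
  k <- check_count(k, "k", min = 2L)
  if (k > n) stop("k must be <= number of lines", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids", call. = FALSE)
  labels <- with_seed(stage_seed(seed, "folds"), {
    sample(rep(seq_len(k), length.out = n))
  })
  structure(stats::setNames(labels, sample_ids), k = k, seed = seed,
            class = "fold_assignment")
}

#' Pearson correlation with guards
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`, each with
#'   nonzero variance.
#' @return Sample Pearson correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  if (stats::sd(y) == 0) stop("y has zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Fisher-z confidence interval for a correlation
#'
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{(1+level)/2} / \sqrt{n-3})}.
#'
#' @param r Sample correlation.
#' @param n Sample size (`>= 4`).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(ci_low, ci_high)`; degenerate `c(r, r)` at `|r| = 1`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (abs(r) == 1) return(c(r, r))
  z <- stats::qnorm((1 + level) / 2)
  half <- z / sqrt(n - 3)
  ci <- tanh(atanh(r) + c(-half, half))
  stats::setNames(ci, c("ci_low", "ci_high"))
}

#' Two-sided p-value for a correlation
#'
#' t-test on \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} against Student t with
#' `n - 2` degrees of freedom.
#'
#' @param r Sample correlation.
#' @param n Sample size (`>= 4`).
#' @return Two-sided p-value in `(0, 1]`; exactly 0 (with a warning) at
#'   `|r| = 1`.
#' @export
corr_pvalue <- function(r, n) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (abs(r) == 1) {
    warning("|r| = 1: p-value is exactly 0")
    return(0)
  }
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Score genotyped lines with a SNP-effect model
#'
#' For each line, `score = sum_i b_i d_i` where `d_i` is the line's dosage
#' of the model's effect allele. Model SNPs are matched to the panel by id;
#' when the panel counts the other allele the dosage is flipped
#' (`d <- 2 - d`); SNPs whose panel alleles cannot be reconciled with the
#' model's allele pair are excluded and reported. Missing calls are imputed
#' at `2 p_i` using the model's stored (training-set) frequency. Scores are
#' sums over SNPs, so they estimate breeding values up to an additive
#' constant; correlation-based evaluation is invariant to that constant.
#'
#' @param model `snp_effect_model` from [backsolve_snp_effects()] or
#'   [read_snp_effects()].
#' @param panel [genotype_panel()] of lines to score.
#' @return Named numeric score vector with attribute `n_excluded`
#'   (model SNPs absent or allele-mismatched). More than 50% excluded is
#'   an error.
#' @export
score_lines <- function(model, panel) {
  stopifnot(inherits(model, "snp_effect_model"),
            inherits(panel, "genotype_panel"))
  mi <- match(model$snp_ids, panel$snp_ids)
  present <- !is.na(mi)

  pa1 <- panel$map$allele1[mi[present]]
  pa2 <- panel$map$allele2[mi[present]]
  ea <- model$effect_allele[present]
  oa <- model$other_allele[present]
  direct <- pa1 == ea & pa2 == oa
  flipped <- pa2 == ea & pa1 == oa
  ok <- direct | flipped

  n_absent <- sum(!present)
  n_mismatch <- sum(!ok)
  n_excluded <- n_absent + n_mismatch
  if (n_excluded > 0.5 * length(model$snp_ids)) {
    stop(sprintf("%d of %d model SNPs unusable in the panel (%d absent, %d allele-mismatched)",
                 n_excluded, length(model$snp_ids), n_absent, n_mismatch),
         call. = FALSE)
  }
  if (n_mismatch > 0) {
    warning(n_mismatch, " SNP(s) with irreconcilable alleles excluded")
  }

  use_model <- which(present)[ok]
  use_panel <- mi[present][ok]
  d <- panel$dosage[, use_panel, drop = FALSE]
  flip <- flipped[ok]
  if (any(flip)) d[, flip] <- 2L - d[, flip]
  if (anyNA(d)) {
    pimp <- model$frequency[use_model]
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- 2 * pimp[na_idx[, 2]]
  }
  scores <- drop(d %*% model$coefficient[use_model])
  structure(stats::setNames(scores, panel$sample_ids),
            n_excluded = n_excluded)
}

#' Two-tier significance verdict over a trait's per-fold p-values
#'
#' A trait's breeding-value prediction is declared significant when at
#' least one fold's p-value clears the multiple-testing-adjusted threshold
#' (default 0.001) AND every fold clears the nominal level (default 0.05).
#'
#' @param pvalues Numeric vector of per-model p-values (one per fold).
#' @param nominal Nominal significance level.
#' @param adjusted Multiple-testing-adjusted level.
#' @return List: `significant` (logical), `n_below_nominal`,
#'   `n_below_adjusted`, thresholds.
#' @export
significance_decision <- function(pvalues, nominal = 0.05,
                                  adjusted = 0.001) {
  if (length(pvalues) < 1 || any(!is.finite(pvalues))) {
    stop("need >= 1 finite p-value", call. = FALSE)
  }
  list(
    significant = min(pvalues) < adjusted && all(pvalues < nominal),
    n_below_nominal = sum(pvalues < nominal),
    n_below_adjusted = sum(pvalues < adjusted),
    nominal = nominal, adjusted = adjusted
  )
}

# Fit the full training-only model for one fold: allele frequencies, GRM,
# REML, BLUP and back-solved SNP effects all from training lines only.
fit_training_model <- function(panel, y_all, train_ids,
                               diagonal = "yang", grm_missing_max = 0.02) {
  train_panel <- subset_panel(panel, samples = train_ids)
  y <- y_all[train_ids]
  grm <- compute_grm(train_panel, diagonal = diagonal,
                     grm_missing_max = grm_missing_max)
  vc <- reml_fit(y, grm)
  bv <- blup_breeding_values(vc, y, grm)
  model <- backsolve_snp_effects(bv, vc, train_panel)
  list(vc = vc, bv = bv, model = model)
}

#' k-fold cross-validated prediction accuracy for one trait
#'
#' Implements the evaluation loop: lines are partitioned into `k` folds;
#' for each fold the full pipeline (training-set allele frequencies, GRM,
#' REML variance components, BLUP, back-solved SNP coefficients) is fitted
#' on the training lines only, the held-out lines are scored from their
#' genotypes, and the Pearson correlation between scores and observed
#' line means is recorded with its Fisher-z 95% CI and two-sided p-value.
#' Folds whose REML fit does not converge are flagged and excluded from
#' the mean accuracy with a warning.
#'
#' @param panel QC-passed [genotype_panel()].
#' @param phenos Long phenotype data.frame.
#' @param trait Trait name.
#' @param k Number of folds.
#' @param seed Seed for the partition.
#' @param nominal,adjusted Significance thresholds for the verdict.
#' @param diagonal GRM diagonal convention passed to [compute_grm()].
#' @param grm_missing_max GRM SNP missingness ceiling.
#' @param level CI level.
#' @param keep_models Keep each fold's `snp_effect_model` in the result.
#' @return Object of class `cv_report`: `folds` data.frame (trait, fold,
#'   n_train, n_test, r, ci_low, ci_high, p_value, converged), `mean_r`
#'   over converged folds, `verdict` from [significance_decision()],
#'   `assignment`, and optionally `models`.
#' @export
cross_validate <- function(panel, phenos, trait, k = 5, seed = 1,
                           nominal = 0.05, adjusted = 0.001,
                           diagonal = "yang", grm_missing_max = 0.02,
                           level = 0.95, keep_models = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  y_all <- line_means(phenos, trait, sample_ids = panel$sample_ids)
  ids <- names(y_all)
  folds <- kfold_split(ids, k = k, seed = seed)

  rows <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    test_ids <- ids[folds == f]
    train_ids <- ids[folds != f]
    row <- data.frame(
      trait = trait, fold = f, n_train = length(train_ids),
      n_test = length(test_ids), r = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = NA_real_, converged = FALSE,
      row.names = NULL
    )
    fit <- tryCatch(
      fit_training_model(panel, y_all, train_ids, diagonal = diagonal,
                         grm_missing_max = grm_missing_max),
      error = function(e) {
        warning("fold ", f, " failed and is flagged: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      test_panel <- subset_panel(panel, samples = test_ids)
      scores <- score_lines(fit$model, test_panel)
      r <- pearson_r(scores, y_all[test_ids])
      ci <- fisher_ci(r, length(test_ids), level = level)
      row$r <- r
      row$ci_low <- ci[1]
      row$ci_high <- ci[2]
      row$p_value <- corr_pvalue(r, length(test_ids))
      row$converged <- fit$vc$converged
      if (keep_models) models[[f]] <- fit$model
    }
    rows[[f]] <- row
  }
  folds_df <- do.call(rbind, rows)
  ok <- folds_df$converged & !is.na(folds_df$r)
  if (!all(ok)) {
    warning(sum(!ok), " fold(s) with failed or non-converged REML ",
            "excluded from the mean accuracy")
  }
  p_use <- folds_df$p_value[!is.na(folds_df$p_value)]
  structure(
    list(
      trait = trait,
      folds = folds_df,
      mean_r = if (any(ok)) mean(folds_df$r[ok]) else NA_real_,
      verdict = if (length(p_use)) {
        significance_decision(p_use, nominal, adjusted)
      } else {
        list(significant = FALSE, n_below_nominal = 0L,
             n_below_adjusted = 0L, nominal = nominal, adjusted = adjusted)
      },
      assignment = folds,
      models = models,
      k = k, seed = seed
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> trait %s: mean r = %.3f over %d folds, %s\n",
    x$trait, x$mean_r, x$k,
    if (x$verdict$significant) "significant" else "not significant"))
  print(x$folds[, c("fold", "n_train", "n_test", "r", "ci_low", "ci_high",
                    "p_value")], digits = 3)
  invisible(x)
}
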