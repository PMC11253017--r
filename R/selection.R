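#' Top-k lines by estimated breeding value
#'
#' Returns the ids of the `k` lines with the largest BLUP breeding values.
#' Ties at the cutoff are broken by the stable order of `sample_ids` (the
#' earlier-listed line wins), so the selection is deterministic.
#'
#' @param bv `breeding_values` (or a named numeric vector).
#' @param k Number of lines to select (default 30).
#' @return Character vector of `k` line ids, highest BV first.
#' @export
rank_by_bv <- function(bv, k = 30) {
  v <- if (inherits(bv, "breeding_values")) bv$bv else bv
  if (is.null(names(v))) stop("breeding values must be named", call. = FALSE)
  k <- check_count(k, "k")
  if (k > length(v)) stop("k must be <= number of lines", call. = FALSE)
  ord <- order(-v, seq_along(v))
  names(v)[ord[seq_len(k)]]
}

#' Expected response to selection
#'
#' Computes both selection-gain summaries for a trait:
#' * `bv_response`: mean estimated BV of the selected top-`k` lines minus
#'   the population mean BV (already on the genetic scale, so no extra
#'   heritability weighting);
#' * `pheno_response`: the breeder's-equation gain
#'   \eqn{(P_{top} - P_{mean}) h^2}, where \eqn{P_{top}} is the mean
#'   phenotype of the selected lines and \eqn{P_{mean}} the population
#'   mean phenotype.
#'
#' `mode` chooses the selected set: the `k` lines with the highest
#' estimated BV (`"by_bv"`) or with the highest phenotypic line means
#' (`"by_phenotype"`).
#'
#' @param bv `breeding_values` for the population.
#' @param phenos Long phenotype data.frame.
#' @param trait Trait name.
#' @param vc `variance_components` supplying `h2`.
#' @param k Selected-set size (default 30).
#' @param mode `"by_bv"` or `"by_phenotype"`.
#' @return Object of class `selection_report`: `trait`, `mode`, `top_ids`,
#'   `bv_response`, `pheno_response`, `p_top`, `p_mean`, `h2`, `k`.
#' @export
response_to_selection <- function(bv, phenos, trait, vc, k = 30,
                                  mode = c("by_bv", "by_phenotype")) {
  stopifnot(inherits(bv, "breeding_values"),
            inherits(vc, "variance_components"))
  mode <- match.arg(mode)
  k <- check_count(k, "k")
  means <- line_means(phenos, trait, sample_ids = bv$sample_ids)
  missing_ph <- setdiff(bv$sample_ids, names(means))
  if (length(missing_ph)) {
    stop("lines without ", trait, " phenotypes: ",
         paste(utils::head(missing_ph, 5), collapse = ", "), call. = FALSE)
  }
  if (k > length(bv$sample_ids)) {
    stop("k must be <= number of lines", call. = FALSE)
  }

  top_ids <- if (mode == "by_bv") {
    rank_by_bv(bv, k)
  } else {
    rank_by_bv(means, k)
  }

  p_top <- mean(means[top_ids])
  p_mean <- mean(means)
  structure(
    list(
      trait = trait, mode = mode, top_ids = top_ids, k = k,
      bv_response = mean(bv$bv[top_ids]) - mean(bv$bv),
      pheno_response = (p_top - p_mean) * vc$h2,
      p_top = p_top, p_mean = p_mean, h2 = vc$h2
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    paste0("<selection_report> %s, top %d %s: BV response = %.4g, ",
           "phenotypic response x h2 = %.4g (h2 = %.3f)\n"),
    x$trait, x$k, x$mode, x$bv_response, x$pheno_response, x$h2))
  invisible(x)
}
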