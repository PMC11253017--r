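#' Read and write replicated phenotype tables
#'
#' Phenotypes are stored long: one row per measurement, tab-separated with
#' header `line_id`, `trait`, `year`, `replicate`, `value` (trait units,
#' mg/kg for element content). Values must be finite.
#'
#' @param path File path.
#' @param phenos Phenotype data.frame in the long layout above.
#' @return `read_phenotypes` returns the validated data.frame;
#'   `write_phenotypes` returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(df, context = path)
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenos, path) {
  validate_phenotypes(phenos)
  utils::write.table(phenos, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_phenotypes <- function(df, context = "phenotype table") {
  need <- c("line_id", "trait", "year", "replicate", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(context, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$value) || any(!is.finite(df$value))) {
    stop(context, ": `value` must be finite numeric", call. = FALSE)
  }
  df
}

#' Per-line trait means
#'
#' Arithmetic mean of every record a line has for `trait` — the averaging
#' over the study's four measurement points (2 years x 2 replicates) that
#' produces the response variable of the mixed model. Lines with zero
#' records for the trait are dropped with a message rather than propagated
#' as `NaN`.
#'
#' @param phenos Long phenotype data.frame (see [read_phenotypes()]).
#' @param trait Trait name.
#' @param sample_ids Optional ordering: the returned vector is matched to
#'   this id list (ids absent from the table are dropped and reported).
#' @return Named numeric vector of per-line means.
#' @export
line_means <- function(phenos, trait, sample_ids = NULL) {
  validate_phenotypes(phenos)
  sub <- phenos[phenos$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0) stop("trait not found: ", trait, call. = FALSE)
  means <- tapply(sub$value, sub$line_id, mean)
  means <- stats::setNames(as.numeric(means), names(means))
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, names(means))
    if (length(absent)) {
      message(length(absent), " line(s) with no ", trait,
              " records dropped: ", paste(utils::head(absent, 5),
                                          collapse = ", "))
    }
    keep <- intersect(sample_ids, names(means))
    means <- means[keep]
  }
  means
}

#' Pairwise Pearson correlations between trait line-means
#'
#' @param phenos Long phenotype data.frame.
#' @return Symmetric correlation matrix (unit diagonal) across traits,
#'   computed on per-line means over lines present for every trait.
#' @export
trait_correlation_matrix <- function(phenos) {
  validate_phenotypes(phenos)
  traits <- unique(phenos$trait)
  if (length(traits) < 2) stop("need >= 2 traits", call. = FALSE)
  mats <- lapply(traits, function(tr) line_means(phenos, tr))
  common <- Reduce(intersect, lapply(mats, names))
  wide <- vapply(mats, function(v) v[common], numeric(length(common)))
  colnames(wide) <- traits
  sds <- apply(wide, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ", paste(traits[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(wide)
  r[seq(1, length(traits)^2, by = length(traits) + 1)] <- 1
  r
}
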