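#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so package functions are deterministic given their
#' `seed` argument without clobbering the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a per-stage seed from a base seed. Offsets are fixed per stage so a
# single run seed expands reproducibly; result kept inside 32-bit range.
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 0L, phenotypes = 1L, folds = 2L, missing = 3L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
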