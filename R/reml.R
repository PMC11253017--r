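#' Restricted maximum likelihood for the GBLUP model
#'
#' Fits \eqn{y = 1\mu + g + e} with \eqn{g \sim N(0, A\sigma^2_g)} and
#' \eqn{e \sim N(0, I\sigma^2_e)} by REML, maximizing
#' \deqn{\ell_R = -\tfrac{1}{2}\left[\log|V| + \log|X^\top V^{-1} X|
#'   + y^\top P y\right]}
#' with \eqn{V = A\sigma^2_g + I\sigma^2_e}, \eqn{X = 1} and
#' \eqn{P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}}.
#' A one-time eigendecomposition of `A` makes every likelihood evaluation
#' O(n). Optimization is average-information REML after three EM warm-up
#' iterations, falling back to an EM step whenever the AI step leaves the
#' feasible region or would decrease the likelihood. Variance components
#' are floored at `1e-6 * var(y)` so `V` stays invertible; hitting the
#' floor is flagged. Standard errors come from the inverse
#' average-information matrix; `se_h2` by the delta method.
#'
#' Heritability is reported as \eqn{h^2 = V(G)/V(P)} with
#' \eqn{V(G) = \bar{A}_{jj}\,\sigma^2_g} and
#' \eqn{V(P) = V(G) + \sigma^2_e}, where \eqn{\bar{A}_{jj}} is the mean
#' diagonal of `A`. For outbred samples \eqn{\bar{A}_{jj} \approx 1} and
#' this is the familiar \eqn{\sigma^2_g/(\sigma^2_g+\sigma^2_e)}; for a
#' fully inbred panel the relationship diagonal averages \eqn{1 + f
#' \approx 2}, and the mean-diagonal factor keeps \eqn{V(G)} equal to the
#' average modeled genetic variance per line, so \eqn{h^2} matches
#' `Var(breeding values) / Var(line means)`.
#'
#' When `A` is (numerically) a multiple of the identity only the total
#' variance is identified; the fit then settles wherever the flat ridge
#' leaves it (typically near an equal split of the initialization) and a
#' warning is issued.
#'
#' @param y Named numeric vector of per-line trait means.
#' @param A A `grm` object or a symmetric matrix with dimnames matching
#'   `names(y)`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol_loglik,tol_param Convergence: `|delta loglik| < tol_loglik`
#'   and max relative parameter change `< tol_param`.
#' @param verbose Print the iteration trace.
#' @return Object of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `h2`, `se_sigma_g2`, `se_sigma_e2`, `se_h2`, `loglik`, `n_iterations`,
#'   `converged`, `boundary`, `loglik_trace`, `update_type`, plus the
#'   internals needed by [blup_breeding_values()].
#' @export
reml_fit <- function(y, A, max_iter = 200L, tol_loglik = 1e-8,
                     tol_param = 1e-6, verbose = FALSE) {
  Am <- grm_matrix(A, y)
  y <- as.numeric(y[rownames(Am)])
  n <- length(y)
  if (n < 10) stop("need at least 10 lines for REML", call. = FALSE)
  if (any(!is.finite(y))) stop("y contains non-finite values", call. = FALSE)
  vy <- stats::var(y)
  if (vy <= 0) stop("y has zero variance", call. = FALSE)
  if (max(abs(Am - t(Am))) > 1e-8) {
    stop("A is not symmetric", call. = FALSE)
  }

  eg <- eigen((Am + t(Am)) / 2, symmetric = TRUE)
  lam <- eg$values
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  flat <- max(lam) - min(lam) < 1e-10 * max(abs(lam), 1)
  if (flat) {
    warning("A is numerically a multiple of the identity: only the total ",
            "variance sigma_g2 + sigma_e2 is identified")
  }

  floor_v <- 1e-6 * vy
  theta <- c(vy / 2, vy / 2)
  # A may be indefinite (e.g. Yang-diagonal GRMs): the feasible region is
  # {theta : lam_i * sg2 + se2 > 0 for all i}; start inside it
  if (min(lam) < 0) {
    while (min(lam) * theta[1] + theta[2] <= floor_v &&
           theta[1] > floor_v) {
      theta[1] <- theta[1] / 2
    }
  }

  # All quantities in the eigenbasis of A; O(n) per evaluation.
  eval_at <- function(theta) {
    v <- lam * theta[1] + theta[2]
    if (any(v <= 0)) return(NULL)
    xvx <- sum(xt^2 / v)
    xvy <- sum(xt * yt / v)
    beta <- xvy / xvx
    r <- yt - xt * beta
    py <- r / v                       # P y in the eigenbasis
    ypy <- sum(yt * py)
    ll <- -0.5 * (sum(log(v)) + log(xvx) + ypy)
    list(v = v, xvx = xvx, beta = beta, py = py, ll = ll)
  }
  # P z for z given in the eigenbasis
  apply_P <- function(z, st) {
    zv <- z / st$v
    zv - (xt / st$v) * (sum(xt * zv) / st$xvx)
  }
  st <- eval_at(theta)
  if (is.null(st)) {
    stop("could not find a feasible starting point: A has eigenvalues ",
         "that make V non-positive-definite for all trial values",
         call. = FALSE)
  }
  ll_trace <- st$ll
  upd_trace <- character(0)
  converged <- FALSE
  boundary <- FALSE
  n_flat <- 0L
  AI <- NULL

  for (it in seq_len(max_iter)) {
    # gradient and AI pieces at current theta
    py <- st$py
    gpy <- lam * py                  # A_g P y
    epy <- py                        # A_e P y
    pgpy <- apply_P(gpy, st)
    pepy <- apply_P(epy, st)
    yPAgPy <- sum(gpy * py)          # y'P A_g P y  (since P y = py)
    yPAePy <- sum(epy * py)
    trPAg <- sum(lam / st$v) - sum(xt^2 * lam / st$v^2) / st$xvx
    trPAe <- sum(1 / st$v) - sum(xt^2 / st$v^2) / st$xvx
    grad <- -0.5 * c(trPAg - yPAgPy, trPAe - yPAePy)
    # AI_jk = 0.5 * y'P A_j P A_k P y
    AI <- 0.5 * matrix(c(
      sum((lam * pgpy) * py),
      sum((1 * pgpy) * py),
      sum((lam * pepy) * py),
      sum((1 * pepy) * py)
    ), 2, 2)

    # damped step toward `target`: halve until V is positive definite
    # (and, when monotone = TRUE, the likelihood does not decrease)
    damped <- function(target, monotone) {
      s <- 1
      for (h in 1:30) {
        cand <- pmax(theta + s * (target - theta), floor_v)
        st_cand <- eval_at(cand)
        if (!is.null(st_cand) &&
            (!monotone || st_cand$ll >= st$ll - 1e-12)) {
          return(list(theta = cand, st = st_cand, damped = s < 1))
        }
        s <- s / 2
      }
      NULL
    }
    em_target <- pmax(c(
      theta[1] + 2 * theta[1]^2 * grad[1] / n,
      theta[2] + 2 * theta[2]^2 * grad[2] / n
    ), floor_v)

    res <- NULL
    type <- "EM"
    if (it > 3L) {
      step <- tryCatch(solve(AI, grad), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        res <- damped(theta + step, monotone = TRUE)
        if (!is.null(res)) type <- "AI"
      }
    }
    if (is.null(res)) {
      res <- damped(em_target, monotone = TRUE)
      type <- "EM"
    }
    if (is.null(res)) {
      # no ascent step available: accept a feasible damped EM move so the
      # iteration can terminate on the parameter-change criterion
      res <- damped(em_target, monotone = FALSE)
      type <- "EM-damped"
    }
    if (is.null(res)) {
      converged <- FALSE
      break
    }
    theta_new <- res$theta
    st_new <- res$st
    dll <- st_new$ll - st$ll
    dpar <- max(abs(theta_new - theta) / pmax(abs(theta), floor_v))
    if (verbose) {
      message(sprintf("iter %3d [%s] ll=%.8f sg2=%.6g se2=%.6g", it, type,
                      st_new$ll, theta_new[1], theta_new[2]))
    }
    theta <- theta_new
    st <- st_new
    ll_trace <- c(ll_trace, st$ll)
    upd_trace <- c(upd_trace, type)
    n_flat <- if (abs(dll) < tol_loglik) n_flat + 1L else 0L
    # converged when both criteria hold, or when the likelihood has been
    # flat for several iterations (parameters drifting along a ridge or
    # pinned at the boundary carry no further information)
    if ((abs(dll) < tol_loglik && dpar < tol_param) || n_flat >= 5L) {
      converged <- TRUE
      break
    }
  }
  boundary <- any(theta <= floor_v * (1 + 1e-9))
  if (!converged) {
    warning("REML did not converge in ", max_iter, " iterations")
  }

  # SEs from the AI matrix at the optimum
  se <- c(NA_real_, NA_real_)
  se_h2 <- NA_real_
  Vinv_ai <- tryCatch(solve(AI), error = function(e) NULL)
  cg <- mean(diag(Am))  # mean relationship diagonal (~1 outbred, ~2 inbred)
  h2 <- cg * theta[1] / (cg * theta[1] + theta[2])
  if (!is.null(Vinv_ai) && all(is.finite(Vinv_ai)) &&
      all(diag(Vinv_ai) >= 0)) {
    se <- sqrt(diag(Vinv_ai))
    s <- cg * theta[1] + theta[2]
    gr <- c(cg * theta[2], -cg * theta[1]) / s^2
    v_h2 <- drop(t(gr) %*% Vinv_ai %*% gr)
    if (is.finite(v_h2) && v_h2 >= 0) se_h2 <- sqrt(v_h2)
  }

  structure(
    list(
      sigma_g2 = theta[1], sigma_e2 = theta[2], h2 = h2,
      se_sigma_g2 = se[1], se_sigma_e2 = se[2], se_h2 = se_h2,
      mean_diag = cg,
      loglik = st$ll, n_iterations = length(upd_trace),
      converged = converged, boundary = boundary,
      identifiable = !flat,
      loglik_trace = ll_trace, update_type = upd_trace,
      sample_ids = rownames(Am), n = n
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    paste0("<variance_components> sigma_g2 = %.4g (SE %.3g), ",
           "sigma_e2 = %.4g (SE %.3g)\n  h2 = %.3f (SE %.3g), ",
           "logLik = %.4f, %d iterations, converged = %s\n"),
    x$sigma_g2, x$se_sigma_g2, x$sigma_e2, x$se_sigma_e2,
    x$h2, x$se_h2, x$loglik, x$n_iterations, x$converged
  ))
  invisible(x)
}

#' Write variance components as JSON
#'
#' @param vc A `variance_components`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variance_components <- function(vc, path) {
  stopifnot(inherits(vc, "variance_components"))
  keep <- c("sigma_g2", "sigma_e2", "h2", "se_sigma_g2", "se_sigma_e2",
            "se_h2", "loglik", "n_iterations", "converged", "boundary")
  jsonlite::write_json(unclass(vc)[keep], path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# Resolve a grm object or matrix against names(y); returns the matrix
# reordered to y's names (or y reordered to the matrix when y is unnamed).
grm_matrix <- function(A, y) {
  Am <- if (inherits(A, "grm")) A$A else as.matrix(A)
  if (is.null(rownames(Am))) {
    if (!is.null(names(y)) && length(y) == nrow(Am)) {
      dimnames(Am) <- list(names(y), names(y))
    } else if (length(y) == nrow(Am)) {
      ids <- paste0("id", seq_len(nrow(Am)))
      dimnames(Am) <- list(ids, ids)
      names(y) <- ids
    } else {
      stop("y and A have mismatched sizes", call. = FALSE)
    }
  }
  if (is.null(names(y))) {
    if (length(y) != nrow(Am)) stop("y and A have mismatched sizes",
                                    call. = FALSE)
    names(y) <- rownames(Am)
  }
  if (!setequal(names(y), rownames(Am)) || length(y) != nrow(Am)) {
    stop("names(y) do not match the GRM sample ids", call. = FALSE)
  }
  Am[names(y), names(y)]
}
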