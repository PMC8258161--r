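#' Chebyshev center of a polytope
#'
#' The point maximizing the radius of the inscribed ball, found by linear
#' programming (variables split into positive/negative parts so coordinates
#' may be negative).  Serves as the strictly interior start point of the
#' hit-and-run sampler and as the degeneracy probe of [build_polytope()].
#'
#' @param poly a [polytope()].
#' @param require_interior if `TRUE` (default) an error is raised when the
#'   maximal inscribed radius is not positive (empty or lower-dimensional
#'   polytope); if `FALSE` the result is returned with the radius for the
#'   caller to inspect.
#' @return list with `center` (named numeric) and `radius`.
#' @examples
#' sq <- polytope(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), c(1, 0, 1, 0))
#' chebyshev_center(sq)$center
#' @export
chebyshev_center <- function(poly, require_interior = TRUE) {
  A <- poly$A; b <- poly$b
  d <- ncol(A)
  nr <- sqrt(rowSums(A^2))
  # vars: x+ (d), x- (d), r ; maximize r s.t. A(x+ - x-) + ||a_i|| r <= b_i
  obj <- c(rep(0, 2 * d), 1)
  M <- cbind(A, -A, nr)
  neg <- b < 0
  sol <- boot::simplex(a = obj,
                       A1 = if (any(!neg)) M[!neg, , drop = FALSE] else NULL,
                       b1 = if (any(!neg)) b[!neg] else NULL,
                       A2 = if (any(neg)) -M[neg, , drop = FALSE] else NULL,
                       b2 = if (any(neg)) -b[neg] else NULL,
                       maxi = TRUE, n.iter = 200 * (nrow(A) + 2 * d + 1))
  if (sol$solved != 1) {
    if (require_interior)
      abort_fluxred("polytope is infeasible (no Chebyshev center found)",
                    "fluxred_infeasible")
    return(list(center = setNames(rep(NA_real_, d), poly$labels), radius = -Inf))
  }
  x <- unname(sol$soln[seq_len(d)] - sol$soln[d + seq_len(d)])
  r <- unname(sol$value)
  if (require_interior && r <= 0)
    abort_fluxred("polytope is degenerate (zero inscribed radius)",
                  "fluxred_infeasible")
  list(center = setNames(x, poly$labels), radius = r)
}

#' Uniform samples from a polytope by hit-and-run MCMC
#'
#' Classic hit-and-run: from the current point draw a random direction,
#' intersect the induced chord with the polytope, and jump to a uniform
#' point on the chord.  Directions are isotropic Gaussian after a
#' per-coordinate pre-scaling by the chord widths through the Chebyshev
#' center, which mitigates slow mixing on elongated flux polytopes.  The
#' chain starts at the Chebyshev center, discards `burn_in` steps, and keeps
#' every `thinning`-th state.
#'
#' @param poly a [polytope()].
#' @param n_samples number of retained samples (n_S).
#' @param seed integer seed; the sampler uses a private RNG stream and
#'   restores the caller's RNG state.
#' @param burn_in discarded initial steps.
#' @param thinning steps between retained samples; default `ceiling(d^2)`.
#' @param x0 optional start point (defaults to the Chebyshev center).
#' @return a `flux_sample_set`: matrix (n_samples x d, colnames = coordinate
#'   labels) with attributes `seed`, `burn_in`, `thinning`, and `polytope`.
#' @examples
#' sq <- polytope(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), c(1, 0, 1, 0))
#' s <- hit_and_run(sq, 500, seed = 1)
#' colMeans(s)
#' @export
hit_and_run <- function(poly, n_samples, seed = 1L, burn_in = 1000L,
                        thinning = NULL, x0 = NULL) {
  if (n_samples < 1) abort_fluxred("n_samples must be >= 1", "fluxred_config_error")
  A <- poly$A; b <- poly$b
  d <- ncol(A)
  thinning <- thinning %||% as.integer(ceiling(d^2))
  if (is.null(x0)) x0 <- chebyshev_center(poly)$center
  if (!in_polytope(poly, x0))
    abort_fluxred("start point is not feasible", "fluxred_infeasible")
  # coordinate pre-scaling: chord width along each axis through x0
  widths <- vapply(seq_len(d), function(j) {
    u <- rep(0, d); u[j] <- 1
    tt <- chord_limits(A, b, x0, u)
    w <- tt[2] - tt[1]
    if (!is.finite(w) || w <= 0) 1 else w
  }, numeric(1))
  X <- matrix(NA_real_, n_samples, d, dimnames = list(NULL, poly$labels))
  with_seed(seed, {
    x <- as.numeric(x0)
    Ax <- drop(A %*% x)
    total <- burn_in + n_samples * thinning
    kept <- 0L
    for (step in seq_len(total)) {
      u <- rnorm(d) * widths
      u <- u / sqrt(sum(u^2))
      Au <- drop(A %*% u)
      slack <- b - Ax
      pos <- Au > 1e-14; negd <- Au < -1e-14
      tmax <- if (any(pos)) min(slack[pos] / Au[pos]) else Inf
      tmin <- if (any(negd)) max(slack[negd] / Au[negd]) else -Inf
      if (!is.finite(tmin) || !is.finite(tmax) || tmax < tmin) next
      t <- runif(1, tmin, tmax)
      x <- x + t * u
      Ax <- Ax + t * Au
      if (step > burn_in && (step - burn_in) %% thinning == 0) {
        kept <- kept + 1L
        X[kept, ] <- x
      }
    }
    if (kept < n_samples) X <- X[seq_len(kept), , drop = FALSE]
  })
  structure(X, class = c("flux_sample_set", "matrix", "array"),
            seed = seed, burn_in = burn_in, thinning = thinning,
            polytope = poly)
}

# chord [tmin, tmax] of {x + t u} inside A x <= b
chord_limits <- function(A, b, x, u) {
  Au <- drop(A %*% u)
  slack <- b - drop(A %*% x)
  pos <- Au > 1e-14; negd <- Au < -1e-14
  c(if (any(negd)) max(slack[negd] / Au[negd]) else -Inf,
    if (any(pos)) min(slack[pos] / Au[pos]) else Inf)
}

#' Center of mass of a flux sample set
#'
#' Coordinate-wise mean of the samples — the sampling estimate of the most
#' likely flux map (center of mass of the feasible flux space).  If floating
#' point drift puts the mean marginally outside the polytope it is nudged
#' toward the Chebyshev center until feasible.
#'
#' @param samples a `flux_sample_set` from [hit_and_run()].
#' @return named numeric vector of free coordinates.
#' @export
center_of_mass <- function(samples) {
  if (nrow(samples) == 0) abort_fluxred("empty sample set", "fluxred_config_error")
  m <- colMeans(samples)
  poly <- attr(samples, "polytope")
  if (!is.null(poly) && !in_polytope(poly, m, tol = 0)) {
    ctr <- chebyshev_center(poly)$center
    for (eps in 10^(-12:0)) {
      cand <- (1 - eps) * m + eps * ctr
      if (in_polytope(poly, cand, tol = 0)) return(setNames(cand, colnames(samples)))
    }
  }
  m
}

#' Sample the feasible flux space of a model
#'
#' Convenience wrapper for Phase I of the robust design workflow: build the
#' free-flux basis and polytope, then draw `n_samples` uniform flux maps.
#'
#' @inheritParams hit_and_run
#' @param model a [network_model()].
#' @return a `flux_sample_set` with attribute `basis`.
#' @export
sample_flux_space <- function(model, n_samples = 1000L, seed = 1L,
                              burn_in = 1000L, thinning = NULL) {
  basis <- free_flux_basis(model)
  poly <- build_polytope(basis, model)
  s <- hit_and_run(poly, n_samples, seed = seed, burn_in = burn_in,
                   thinning = thinning, x0 = poly$center)
  attr(s, "basis") <- basis
  s
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("<flux_sample_set> %d samples x %d coordinates (seed %s, thinning %d)\n",
              nrow(x), ncol(x), format(attr(x, "seed")), attr(x, "thinning")))
  invisible(x)
}

#' Tidy a flux sample set into a tibble
#'
#' @param x a `flux_sample_set`.
#' @param ... unused.
#' @return tibble with a `sample` index column and one column per free
#'   coordinate.
#' @method tidy flux_sample_set
#' @export
tidy.flux_sample_set <- function(x, ...) {
  out <- as_tibble(unclass(x)[seq_len(nrow(x)), , drop = FALSE])
  out$sample <- seq_len(nrow(x))
  dplyr::relocate(out, "sample")
}
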