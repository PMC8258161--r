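#' Jacobian of the measurements with respect to the free fluxes
#'
#' Differentiates the steady-state labeling cascade implicitly: per EMU
#' level, with `A(v) X = B(v, lower levels)`, the sensitivity of the level
#' solution to a free coordinate `z_k` solves
#' `A dX = dB/dz_k - (dA/dz_k) X`, cascading the lower-level derivative MIDs
#' through the convolution terms.  Differentiation is with respect to the
#' free coordinates (free net fluxes, then exchange fluxes), composing the
#' constant Jacobian of the affine free-to-full map with the forward/backward
#' split `fwd = max(net,0) + xch`; at `net = 0` the split is non-smooth and
#' the right derivative is used (such samples are flagged via the
#' `kink_fluxes` attribute).  Rate-measurement rows are the constant linear
#' map from free coordinates to the measured net fluxes.
#'
#' @param sys an [emu_decompose()] result.
#' @param basis the [free_flux_basis()] defining the free coordinates.
#' @param v a [flux_state()].
#' @param mix a [mixture()].
#' @param catalog tracer catalogue.
#' @param background natural 13C background (atom%), as in
#'   [simulate_labeling()].
#' @return matrix (rows = measurements in [simulate_labeling()] order,
#'   columns = free coordinates) with attributes `y` (the simulated
#'   measurement tibble) and `kink_fluxes`.
#' @export
jacobian <- function(sys, basis, v, mix, catalog, background = 0) {
  casc <- emu_cascade(sys, v, mix, catalog, basis = basis,
                      background = background)
  groups <- sys$groups
  d <- n_free(basis)
  rows <- list(); rnames <- character(0)
  for (i in seq_len(nrow(groups))) {
    key <- emu_key(groups$metabolite[i], sort(groups$positions[[i]]))
    dm <- casc$dmids[[key]]
    sh <- groups$shifts[[i]]
    rows[[length(rows) + 1L]] <- dm[sh + 1L, , drop = FALSE]
    rnames <- c(rnames, paste0(groups$id[i], ".m", sh))
  }
  rates <- sys$model$measurements$rates
  if (nrow(rates) > 0) {
    nn <- length(basis$free_net)
    dnet <- cbind(basis$N, matrix(0, length(basis$rids), d - nn))
    rownames(dnet) <- basis$rids
    rows[[length(rows) + 1L]] <- dnet[rates$flux, , drop = FALSE]
    rnames <- c(rnames, paste0("rate.", rates$flux))
  }
  J <- do.call(rbind, rows)
  dimnames(J) <- list(rnames, free_labels(basis))
  attr(J, "y") <- assemble_measurements(sys, casc$mids, v)
  attr(J, "kink_fluxes") <- casc$fl$kink
  J
}

#' Finite-difference Jacobian (oracle)
#'
#' Central differences over the free coordinates, with the step shrunk
#' (up to `max_shrink` halvings) whenever a perturbed point leaves the
#' feasible polytope.  Used to validate the analytic [jacobian()].
#'
#' @inheritParams jacobian
#' @param poly the feasibility [polytope()] in free coordinates; if `NULL`,
#'   perturbed points are not feasibility-checked.
#' @param h base step size, scaled per coordinate by `max(1, |z_k|)`.
#' @param max_shrink maximal number of step halvings near the boundary.
#' @return matrix like [jacobian()] (labeling and rate rows).
#' @export
jacobian_fd <- function(sys, basis, v, mix, catalog, poly = NULL, h = 1e-6,
                        max_shrink = 30L, background = 0) {
  z <- as.numeric(v$z)
  d <- length(z)
  sim_z <- function(zz) {
    st <- flux_state(basis, zz)
    y <- simulate_labeling(sys, st, mix, catalog, background = background)
    y$value
  }
  y0 <- sim_z(z)
  J <- matrix(NA_real_, length(y0), d)
  for (k in seq_len(d)) {
    hk <- h * max(1, abs(z[k]))
    ok <- FALSE
    for (try in 0:max_shrink) {
      zp <- z; zp[k] <- z[k] + hk
      zm <- z; zm[k] <- z[k] - hk
      if (is.null(poly) || (in_polytope(poly, zp, tol = 0) &&
                            in_polytope(poly, zm, tol = 0))) { ok <- TRUE; break }
      hk <- hk / 2
    }
    if (!ok)
      abort_fluxred(sprintf("cannot place a feasible central-difference stencil for coordinate %d",
                            k), "fluxred_infeasible")
    J[, k] <- (sim_z(zp) - sim_z(zm)) / (2 * hk)
  }
  colnames(J) <- free_labels(basis)
  J
}
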