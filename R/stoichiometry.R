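#' Stoichiometric matrix over balanced metabolites
#'
#' One row per balanced (intracellular) metabolite pool, one column per
#' reaction net flux; entries are signed stoichiometric coefficients
#' (products positive, educts negative), counting repeated instances.
#'
#' @param model a [network_model()].
#' @return numeric matrix `S` with dimnames (metabolite ids, reaction ids);
#'   the steady-state condition is `S %*% v_net = 0`.
#' @export
build_stoichiometry <- function(model) {
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  rids <- reaction_ids(model)
  S <- matrix(0, length(bal), length(rids), dimnames = list(bal, rids))
  for (r in model$reactions) {
    for (e in r$educts)
      if (e$met %in% bal) S[e$met, r$id] <- S[e$met, r$id] - 1
    for (p in r$products)
      if (p$met %in% bal) S[p$met, r$id] <- S[p$met, r$id] + 1
  }
  S
}

#' Free-flux basis of the stoichiometric system
#'
#' Splits the flux vector into dependent and free coordinates.  The number of
#' free net fluxes is `n - rank(M)` where `M` stacks the stoichiometric
#' matrix with the fixed-rate equality constraints (e.g. the normalized
#' uptake); every bidirectional reaction additionally contributes one free
#' exchange coordinate.  The free set is chosen deterministically by
#' column-pivoted QR of `M`: pivot columns become dependent, the rest are
#' free, ties broken by reaction declaration order.  Any admissible full flux
#' vector is reproduced from its free coordinates through the affine map
#' `v_net = N z_net + p`.
#'
#' @param model a [network_model()].
#' @param S optional pre-computed stoichiometric matrix.
#' @return object of class `free_flux_basis`: list with `free_net`,
#'   `free_xch` (reaction ids), `N` (n x n_free_net map), `p` (particular
#'   solution honoring fixed rates), `rids`, and `xch_rids`.
#' @export
free_flux_basis <- function(model, S = build_stoichiometry(model)) {
  rids <- colnames(S)
  n <- length(rids)
  fixed <- model$constraints$fixed
  E <- matrix(0, nrow(fixed), n, dimnames = list(NULL, rids))
  for (i in seq_len(nrow(fixed))) E[i, fixed$flux[i]] <- 1
  M <- rbind(S, E)
  d <- c(rep(0, nrow(S)), fixed$value)
  if (nrow(M) == 0) {
    N <- diag(n); dimnames(N) <- list(rids, rids)
    basis <- list(free_net = rids, N = N, p = setNames(rep(0, n), rids))
  } else {
    qrM <- qr(M, LAPACK = TRUE)
    r <- qr_rank(qrM, M)
    piv <- qrM$pivot
    basic <- sort(piv[seq_len(r)])
    free <- setdiff(seq_len(n), basic)
    MB <- M[, basic, drop = FALSE]
    qrB <- qr(MB)
    # least-squares particular solution; residual check catches inconsistent
    # fixed rates (no v with S v = 0 honoring them)
    p_basic <- qr.coef(qrB, d)
    if (max(abs(MB %*% p_basic - d)) > 1e-8 * max(1, max(abs(d))))
      abort_fluxred("fixed-rate constraints are inconsistent with the stoichiometry",
                    "fluxred_infeasible")
    p <- setNames(rep(0, n), rids)
    p[basic] <- p_basic
    N <- matrix(0, n, length(free), dimnames = list(rids, rids[free]))
    if (length(free) > 0) {
      NB <- -qr.solve(qrB, M[, free, drop = FALSE])
      N[basic, ] <- NB
      N[cbind(free, seq_along(free))] <- 1
    }
    basis <- list(free_net = rids[free], N = N, p = p)
  }
  bidir <- vapply(model$reactions, `[[`, NA, "bidirectional")
  basis$xch_rids <- rids[bidir]
  basis$free_xch <- basis$xch_rids
  basis$rids <- rids
  structure(basis, class = "free_flux_basis")
}

qr_rank <- function(qrM, M) {
  dR <- abs(diag(qr.R(qrM)))
  if (length(dR) == 0) return(0L)
  sum(dR > max(dim(M)) * .Machine$double.eps * max(dR))
}

#' @export
print.free_flux_basis <- function(x, ...) {
  cat(sprintf("<free_flux_basis> %d free net (%s), %d free exchange\n",
              length(x$free_net), paste(x$free_net, collapse = ", "),
              length(x$free_xch)))
  invisible(x)
}

n_free <- function(basis) length(basis$free_net) + length(basis$free_xch)

free_labels <- function(basis) {
  c(paste0("net.", basis$free_net),
    if (length(basis$free_xch)) paste0("xch.", basis$free_xch))
}

#' Full flux state from free coordinates
#'
#' Maps a free-coordinate vector `z` (free net fluxes first, then exchange
#' fluxes of bidirectional reactions) to the complete flux state.  Forward
#' and backward fluxes follow the net/exchange parametrization
#' `fwd = max(net, 0) + xch`, `bwd = max(-net, 0) + xch`.
#'
#' @param basis a [free_flux_basis()].
#' @param z numeric vector of length `length(free_net) + length(free_xch)`.
#' @return object of class `flux_state`: list with `net` (named over all
#'   reactions), `xch` (named over bidirectional reactions), `fwd`, `bwd`,
#'   and the generating coordinates `z`.
#' @export
flux_state <- function(basis, z) {
  nn <- length(basis$free_net)
  zn <- z[seq_len(nn)]
  zx <- z[nn + seq_along(basis$free_xch)]
  net <- drop(basis$N %*% zn) + basis$p
  xch <- setNames(rep(0, length(basis$rids)), basis$rids)
  xch[basis$free_xch] <- zx
  fwd <- pmax(net, 0) + xch
  bwd <- pmax(-net, 0) + xch
  structure(list(net = net, xch = xch[basis$xch_rids], fwd = fwd, bwd = bwd,
                 z = setNames(z, free_labels(basis))),
            class = "flux_state")
}

#' Feasible flux polytope in free coordinates
#'
#' Expresses all constraints — net-flux bounds, exchange bounds, and general
#' linear inequalities `C v <= c` — as an inequality system `A z <= b` over
#' the free coordinates.  Rows rendered constant by the null-space projection
#' are checked for consistency and dropped.  The polytope must have a
#' strictly interior point (Chebyshev radius above `tol`); degenerate
#' (lower-dimensional) polytopes are rejected with guidance to convert the
#' blocking near-equality constraints into equalities.
#'
#' @param basis a [free_flux_basis()].
#' @param model the [network_model()] the basis came from.
#' @param tol minimal Chebyshev radius regarded as full-dimensional.
#' @return a [polytope()] over the free coordinates.
#' @export
build_polytope <- function(basis, model, tol = 1e-9) {
  labels <- free_labels(basis)
  nn <- length(basis$free_net)
  d <- n_free(basis)
  rows <- list(); rhs <- numeric(0); rnames <- character(0)
  add_row <- function(a, b, nm) {
    if (max(abs(a)) < 1e-12) {
      if (b < -1e-9)
        abort_fluxred(sprintf("constraint '%s' is infeasible (constant %.3g > bound)", nm, -b),
                      "fluxred_infeasible")
      return(invisible())
    }
    rows[[length(rows) + 1L]] <<- a; rhs[length(rhs) + 1L] <<- b
    rnames[length(rnames) + 1L] <<- nm
  }
  fixed_fluxes <- model$constraints$fixed$flux
  nb <- model$constraints$net_bounds
  for (i in seq_len(nrow(nb))) {
    fl <- nb$flux[i]
    if (fl %in% fixed_fluxes) next
    a <- c(basis$N[fl, ], rep(0, d - nn))
    if (is.finite(nb$hi[i])) add_row(a, nb$hi[i] - basis$p[fl], paste0(fl, ".hi"))
    if (is.finite(nb$lo[i])) add_row(-a, basis$p[fl] - nb$lo[i], paste0(fl, ".lo"))
  }
  lin <- model$constraints$linear
  if (!is.null(lin)) {
    for (i in seq_along(lin$rhs)) {
      a <- c(drop(lin$coef[i, , drop = FALSE] %*% basis$N), rep(0, d - nn))
      b <- lin$rhs[i] - drop(lin$coef[i, , drop = FALSE] %*% basis$p)
      if (lin$op[i] == "eq")
        abort_fluxred("linear equality constraints must be folded as fixed fluxes",
                      "fluxred_model_error")
      add_row(a, b, paste0("lin", i))
    }
  }
  xb <- model$constraints$xch_bounds
  for (i in seq_len(nrow(xb))) {
    j <- nn + match(xb$flux[i], basis$free_xch)
    a <- rep(0, d); a[j] <- 1
    add_row(a, xb$hi[i], paste0(xb$flux[i], ".xhi"))
    a <- rep(0, d); a[j] <- -1
    add_row(a, -xb$lo[i], paste0(xb$flux[i], ".xlo"))
  }
  A <- do.call(rbind, rows)
  dimnames(A) <- list(rnames, labels)
  poly <- polytope(A, rhs, labels = labels)
  ctr <- chebyshev_center(poly, require_interior = FALSE)
  if (ctr$radius <= tol)
    abort_fluxred(paste0(
      "flux polytope is empty or degenerate (Chebyshev radius ",
      format(ctr$radius, digits = 3),
      "); convert near-equality constraints into fixed fluxes"),
      "fluxred_infeasible")
  poly$center <- ctr$center
  poly$radius <- ctr$radius
  poly
}

#' Convex polytope `A x <= b`
#'
#' Lightweight container used for the feasible flux space; also accepts any
#' hand-built system (boxes, simplices) so the sampler can be validated
#' against analytic distributions.
#'
#' @param A inequality matrix (one row per constraint).
#' @param b right-hand side vector.
#' @param labels coordinate names.
#' @return object of class `polytope`.
#' @export
polytope <- function(A, b, labels = colnames(A) %||% paste0("z", seq_len(ncol(A)))) {
  stopifnot(nrow(A) == length(b))
  colnames(A) <- labels
  structure(list(A = A, b = as.numeric(b), labels = labels), class = "polytope")
}

#' @export
print.polytope <- function(x, ...) {
  cat(sprintf("<polytope> %d constraints in %d dimensions (%s)\n",
              nrow(x$A), ncol(x$A), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Membership test
#'
#' @param poly a [polytope()].
#' @param x coordinate vector or matrix (rows = points).
#' @param tol constraint violation tolerance.
#' @return logical vector.
#' @export
in_polytope <- function(poly, x, tol = 1e-9) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  apply(poly$A %*% t(x) - poly$b <= tol, 2, all)
}

#' Export a polytope as CSV for external samplers
#'
#' Writes the system `A x <= b` as a table with one row per constraint:
#' coordinate columns plus a final `rhs` column.
#'
#' @param poly a [polytope()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_polytope_csv <- function(poly, path) {
  df <- as.data.frame(poly$A)
  df$rhs <- poly$b
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
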