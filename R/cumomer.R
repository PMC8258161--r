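#' Brute-force cumomer cascade simulation
#'
#' Independent reference implementation of the steady-state labeling model:
#' instead of the demand-driven EMU decomposition it balances *all* cumomers
#' (cumulative isotopomer fractions — the probability that a given carbon
#' subset of a pool is fully 13C-labeled) of every non-substrate pool, level
#' by level.  At level k the balance of a product cumomer is linear in
#' level-k cumomers, with condensation cross-terms being products of
#' strictly lower-level (already solved) cumomers.  Fragment mass isotopomer
#' distributions are then recovered by inclusion–exclusion over the fragment
#' carbon subsets.  Complexity is exponential in the per-metabolite carbon
#' count, so this is an oracle for small networks (<= ~12 carbons per pool),
#' used in the test suite to pin the EMU simulator to 1e-8.
#'
#' @inheritParams simulate_labeling
#' @param model a [network_model()].
#' @param groups measurement groups to report (default: the model's).
#' @return measurement tibble with the same layout as [simulate_labeling()].
#' @export
cumomer_simulate <- function(model, v, mix, catalog,
                             groups = model$measurements$groups,
                             background = 0) {
  role <- setNames(model$metabolites$role, model$metabolites$id)
  ncarb <- setNames(model$metabolites$n_carbons, model$metabolites$id)
  if (any(ncarb[role != "input"] > 14))
    abort_fluxred("cumomer oracle limited to <= 14 carbons per pool",
                  "fluxred_config_error")

  # boundary cumomers of input pools: P(all positions in S labeled)
  cums <- new.env(parent = emptyenv())
  for (m in names(role)[role == "input"]) {
    dist <- substrate_isotopomer_distribution(catalog, m, mix[[m]] %||%
      abort_fluxred(sprintf("mixture does not cover substrate '%s'", m),
                    "fluxred_mixture_error"), background = background)
    n <- ncarb[[m]]
    for (sz in seq_len(n)) {
      for (S in subsets_of_size(n, sz)) {
        val <- 0
        for (s in 0:(2^n - 1))
          if (all(bitwAnd(bitwShiftR(s, S - 1L), 1L) == 1L))
            val <- val + dist[s + 1L]
        assign(emu_key(m, S), val, envir = cums)
      }
    }
  }

  # enumerate production events: (flux value, product instance, educt side)
  events <- list()
  nbl <- setNames(model$constraints$net_bounds$lo, model$constraints$net_bounds$flux)
  for (r in model$reactions) {
    sides <- list(list(f = v$fwd[[r$id]], prods = r$products, educts = r$educts))
    if (r$bidirectional || isTRUE(nbl[r$id] < 0))
      sides <- c(sides, list(list(f = v$bwd[[r$id]], prods = r$educts,
                                  educts = r$products)))
    for (sd_ in sides)
      for (inst in sd_$prods)
        if (role[inst$met] != "input")
          events[[length(events) + 1L]] <- list(
            met = inst$met, atoms = inst$atoms, f = sd_$f, educts = sd_$educts)
  }
  influx <- tapply(vapply(events, `[[`, 0, "f"),
                   vapply(events, `[[`, "", "met"), sum)

  unknown_mets <- names(role)[role != "input" & ncarb[names(role)] > 0]
  orphans <- setdiff(unknown_mets, names(influx))
  if (any(groups$metabolite %in% orphans))
    abort_fluxred(sprintf("measured metabolite '%s' is never produced",
                          intersect(groups$metabolite, orphans)[1]),
                  "fluxred_unreachable")
  unknown_mets <- setdiff(unknown_mets, orphans)
  maxlev <- max(ncarb[unknown_mets])
  for (lev in seq_len(maxlev)) {
    keys <- character(0); kmet <- character(0); kpos <- list()
    for (m in unknown_mets) {
      if (ncarb[[m]] < lev) next
      for (S in subsets_of_size(ncarb[[m]], lev)) {
        keys <- c(keys, emu_key(m, S)); kmet <- c(kmet, m)
        kpos[[length(kpos) + 1L]] <- S
      }
    }
    if (length(keys) == 0) next
    idx <- setNames(seq_along(keys), keys)
    A <- matrix(0, length(keys), length(keys))
    b <- numeric(length(keys))
    diag(A) <- influx[kmet]
    for (ev in events) {
      if (ev$f == 0) next
      np <- length(ev$atoms)
      if (np < lev) next
      for (S in subsets_of_size(np, lev)) {
        i <- idx[[emu_key(ev$met, S)]]
        letters_needed <- ev$atoms[S]
        # factor per educt carrying some of the needed carbons
        fac_keys <- character(0); fac_mets <- character(0); fac_sz <- integer(0)
        for (e in ev$educts) {
          hit <- which(e$atoms %in% letters_needed)
          if (length(hit) > 0) {
            fac_keys <- c(fac_keys, emu_key(e$met, sort(hit)))
            fac_mets <- c(fac_mets, e$met)
            fac_sz <- c(fac_sz, length(hit))
          }
        }
        if (length(fac_keys) == 1 && fac_sz[1] == lev &&
            role[fac_mets[1]] != "input") {
          A[i, idx[[fac_keys[1]]]] <- A[i, idx[[fac_keys[1]]]] - ev$f
        } else {
          b[i] <- b[i] + ev$f * prod(vapply(fac_keys, get, 0, envir = cums))
        }
      }
    }
    if (any(diag(A) <= 1e-12)) {
      dead <- unique(kmet[diag(A) <= 1e-12])
      abort_fluxred(sprintf("singular cumomer system at level %d: pool(s) without throughput: %s",
                            lev, paste(dead, collapse = ", ")), "fluxred_singular")
    }
    x <- solve(A, b)
    for (i in seq_along(keys)) assign(keys[i], x[i], envir = cums)
  }

  # fragment MIDs by inclusion-exclusion over fragment subsets
  rows <- vector("list", nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    met <- groups$metabolite[gi]
    pos <- sort(groups$positions[[gi]])
    p <- length(pos)
    mid <- numeric(p + 1L)
    for (mu_bits in 0:(2^p - 1)) {
      mu <- pos[bitwAnd(bitwShiftR(mu_bits, 0:(p - 1)), 1L) == 1L]
      rest <- setdiff(pos, mu)
      q <- 0
      for (t_bits in 0:(2^length(rest) - 1)) {
        Tset <- rest[bitwAnd(bitwShiftR(t_bits, seq_along(rest) - 1L), 1L) == 1L]
        u <- sort(c(mu, Tset))
        cu <- if (length(u) == 0) 1 else get(emu_key(met, u), envir = cums)
        q <- q + (-1)^length(Tset) * cu
      }
      mid[length(mu) + 1L] <- mid[length(mu) + 1L] + q
    }
    sh <- groups$shifts[[gi]]
    rows[[gi]] <- tibble(type = "ms", group = groups$id[gi], shift = sh,
                         value = mid[sh + 1L])
  }
  rates <- model$measurements$rates
  if (nrow(rates) > 0)
    rows[[length(rows) + 1L]] <- tibble(type = "rate", group = rates$flux,
                                        shift = NA_integer_,
                                        value = unname(v$net[rates$flux]))
  dplyr::bind_rows(rows)
}

subsets_of_size <- function(n, k) {
  if (k > n) return(list())
  if (k == 0) return(list(integer(0)))
  cb <- combn(n, k)
  lapply(seq_len(ncol(cb)), function(j) cb[, j])
}
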