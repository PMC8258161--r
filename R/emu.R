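#' Elementary metabolite unit (EMU) decomposition
#'
#' Traces every measured fragment back through the carbon atom transitions to
#' the minimal set of EMUs (metabolite carbon-position subsets) whose
#' flux-weighted balances determine the fragment mass isotopomer
#' distributions.  At cleavage-free transitions an EMU maps to a single
#' same-size precursor EMU; where a fragment's carbons originate from several
#' educt molecules (condensations), the precursor mass distribution is the
#' convolution of strictly smaller EMUs, which is what makes the level-wise
#' cascade linear.  The backward direction of bidirectional reactions (and of
#' reactions whose net flux may turn negative) contributes transitions too.
#'
#' @param model a [network_model()].
#' @param groups measurement groups (tibble as in
#'   `model$measurements$groups`); defaults to the model's own groups.
#' @return an `emu_system`: node table, production terms, and level
#'   structure, reusable across flux states and mixtures.
#' @export
emu_decompose <- function(model, groups = model$measurements$groups) {
  if (nrow(groups) == 0)
    abort_fluxred("no measurement groups to decompose", "fluxred_model_error")
  role <- setNames(model$metabolites$role, model$metabolites$id)
  producers <- producer_index(model)

  nodes <- list()   # key -> list(met, pos, size, input)
  terms <- list()   # per non-input node key: list of production terms
  queue <- character(0)
  add_node <- function(met, pos) {
    key <- emu_key(met, pos)
    if (is.null(nodes[[key]])) {
      nodes[[key]] <<- list(met = met, pos = pos, size = length(pos),
                            input = unname(role[met]) == "input")
      if (!nodes[[key]]$input) queue <<- c(queue, key)
    }
    key
  }
  for (i in seq_len(nrow(groups)))
    add_node(groups$metabolite[i], sort(groups$positions[[i]]))

  while (length(queue) > 0) {
    key <- queue[1]; queue <- queue[-1]
    node <- nodes[[key]]
    prods <- producers[[node$met]]
    if (is.null(prods) || length(prods) == 0)
      abort_fluxred(sprintf(
        "metabolite '%s' carries a measured fragment but is never produced (unreachable from any substrate)",
        node$met), "fluxred_unreachable")
    node_terms <- lapply(prods, function(pr) {
      # pr: list(rxn = index, dir, inst_atoms = atoms of this product instance,
      #          sources = educt side instances)
      letters_needed <- pr$inst_atoms[node$pos]
      srcs <- list()
      for (e in pr$sources) {
        hit <- which(e$atoms %in% letters_needed)
        if (length(hit) > 0)
          srcs[[length(srcs) + 1L]] <- list(met = e$met, pos = sort(hit))
      }
      src_keys <- vapply(srcs, function(s) add_node(s$met, s$pos), "")
      list(rxn = pr$rxn, dir = pr$dir, sources = src_keys)
    })
    terms[[key]] <- node_terms
  }

  finalize_emu_system(model, nodes, terms, groups)
}

# all (reaction, direction, product instance) triples producing each metabolite
producer_index <- function(model) {
  nb <- model$constraints$net_bounds
  lo <- setNames(nb$lo, nb$flux)
  out <- list()
  for (ri in seq_along(model$reactions)) {
    r <- model$reactions[[ri]]
    dirs <- list(list(dir = "f", prods = r$products, educts = r$educts))
    if (r$bidirectional || isTRUE(lo[r$id] < 0))
      dirs <- c(dirs, list(list(dir = "b", prods = r$educts, educts = r$products)))
    for (dd in dirs) {
      for (inst in dd$prods) {
        out[[inst$met]] <- c(out[[inst$met]], list(
          list(rxn = ri, dir = dd$dir, inst_atoms = inst$atoms,
               sources = dd$educts)))
      }
    }
  }
  out
}

finalize_emu_system <- function(model, nodes, terms, groups) {
  keys <- names(nodes)
  sizes <- vapply(nodes, `[[`, 0L, "size")
  input <- vapply(nodes, `[[`, NA, "input")
  keys <- keys[order(sizes, keys)]  # deterministic ordering
  levels <- sort(unique(sizes[!input]))
  structure(list(
    model = model,
    nodes = nodes[keys],
    terms = terms,
    levels = levels,
    groups = groups
  ), class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  ninp <- sum(vapply(x$nodes, `[[`, NA, "input"))
  cat(sprintf("<emu_system> %d EMUs (%d substrate-side), levels: %s\n",
              length(x$nodes), ninp, paste(x$levels, collapse = ", ")))
  invisible(x)
}

# marginal MID of a position subset of an input pool with isotopomer dist
input_emu_mid <- function(dist, pos) {
  n <- as.integer(round(log2(length(dist))))
  mid <- numeric(length(pos) + 1L)
  for (s in 0:(length(dist) - 1L)) {
    bits <- bitwAnd(bitwShiftR(s, pos - 1L), 1L)
    k <- sum(bits)
    mid[k + 1L] <- mid[k + 1L] + dist[s + 1L]
  }
  mid
}

# per-(reaction, dir) flux values and (optionally) their z-derivatives
direction_fluxes <- function(model, basis, v, grad = FALSE) {
  f <- list(f = v$fwd, b = v$bwd)
  if (!grad) return(f)
  d <- n_free(basis)
  nn <- length(basis$free_net)
  rids <- basis$rids
  dnet <- cbind(basis$N, matrix(0, length(rids), d - nn,
                                dimnames = list(rids, NULL)))
  dxch <- matrix(0, length(rids), d, dimnames = list(rids, NULL))
  for (j in seq_along(basis$free_xch)) dxch[basis$free_xch[j], nn + j] <- 1
  pos <- v$net >= 0  # right derivative at the fwd/bwd kink
  f$df <- dnet * pos + dxch
  f$db <- -dnet * (!pos) + dxch
  f$kink <- rids[abs(v$net) < 1e-9 & rids %in% basis$xch_rids]
  f
}

# core level-by-level EMU cascade; returns mids (and dmids when basis given)
emu_cascade <- function(sys, v, mix, catalog, basis = NULL, background = 0) {
  model <- sys$model
  grad <- !is.null(basis)
  fl <- direction_fluxes(model, basis, v, grad = grad)
  d <- if (grad) n_free(basis) else 0L

  # input pool isotopomer distributions under this mixture
  input_mets <- unique(vapply(sys$nodes[vapply(sys$nodes, `[[`, NA, "input")],
                              `[[`, "", "met"))
  dists <- lapply(input_mets, function(m)
    substrate_isotopomer_distribution(catalog, m, mix[[m]] %||%
      abort_fluxred(sprintf("mixture does not cover substrate '%s'", m),
                    "fluxred_mixture_error"),
      background = background))
  names(dists) <- input_mets

  mids <- list(); dmids <- list()
  for (key in names(sys$nodes)) {
    node <- sys$nodes[[key]]
    if (node$input) {
      mids[[key]] <- input_emu_mid(dists[[node$met]], node$pos)
      if (grad) dmids[[key]] <- matrix(0, node$size + 1L, d)
    }
  }

  rids <- reaction_ids(model)
  for (lev in sys$levels) {
    unk <- names(sys$nodes)[vapply(sys$nodes, function(n)
      !n$input && n$size == lev, NA)]
    if (length(unk) == 0) next
    nk <- length(unk)
    idx <- setNames(seq_len(nk), unk)
    A <- matrix(0, nk, nk, dimnames = list(unk, unk))
    B <- matrix(0, nk, lev + 1L)
    dA <- if (grad) replicate(d, matrix(0, nk, nk), simplify = FALSE)
    dB <- if (grad) replicate(d, matrix(0, nk, lev + 1L), simplify = FALSE)
    for (key in unk) {
      i <- idx[[key]]
      for (term in sys$terms[[key]]) {
        rid <- rids[term$rxn]
        fv <- fl[[term$dir]][[rid]]
        dfv <- if (grad) (if (term$dir == "f") fl$df else fl$db)[rid, ] else NULL
        A[i, i] <- A[i, i] + fv
        if (grad) for (t in seq_len(d)) dA[[t]][i, i] <- dA[[t]][i, i] + dfv[t]
        src <- term$sources
        if (length(src) == 1 && !is.na(idx[src])) {
          j <- idx[[src]]
          A[i, j] <- A[i, j] - fv
          if (grad) for (t in seq_len(d)) dA[[t]][i, j] <- dA[[t]][i, j] - dfv[t]
        } else {
          cmid <- conv_mid_list(mids[src])
          B[i, ] <- B[i, ] + fv * cmid
          if (grad) {
            for (t in seq_len(d)) {
              dc <- numeric(lev + 1L)
              for (s in seq_along(src)) {
                parts <- mids[src]
                parts[[s]] <- dmids[[src[s]]][, t]
                dc <- dc + conv_mid_list(parts)
              }
              dB[[t]][i, ] <- dB[[t]][i, ] + dfv[t] * cmid + fv * dc
            }
          }
        }
      }
    }
    diag_influx <- diag(A)
    if (any(diag_influx <= 1e-12)) {
      dead <- unique(vapply(unk[diag_influx <= 1e-12],
                            function(k) sys$nodes[[k]]$met, ""))
      abort_fluxred(sprintf(
        "singular labeling system at EMU level %d: pool(s) without throughput: %s",
        lev, paste(dead, collapse = ", ")), "fluxred_singular")
    }
    Ainv <- tryCatch(solve(A), error = function(e) abort_fluxred(
      sprintf("singular labeling system at EMU level %d", lev), "fluxred_singular"))
    X <- Ainv %*% B
    dX <- if (grad) lapply(seq_len(d), function(t)
      Ainv %*% (dB[[t]] - dA[[t]] %*% X))
    for (key in unk) {
      mids[[key]] <- X[idx[[key]], ]
      if (grad)
        dmids[[key]] <- do.call(cbind, lapply(dX, function(m) m[idx[[key]], ]))
    }
  }
  list(mids = mids, dmids = if (grad) dmids, fl = fl)
}

#' Simulate steady-state labeling measurements
#'
#' Evaluates the noise-free measurement model y = f(v, x_inp): mass
#' isotopomer distributions of every measured fragment at isotopic steady
#' state, plus the simulated extracellular rate measurements.
#'
#' @param sys an [emu_decompose()] result.
#' @param v a [flux_state()] (strictly feasible).
#' @param mix a [mixture()] covering all substrate pools.
#' @param catalog a [parse_tracer_spec()] catalogue.
#' @param background natural 13C background (atom%) at nominally unlabeled
#'   tracer positions; 0 by default.
#' @return a tibble with columns `type` (`"ms"`/`"rate"`), `group`, `shift`,
#'   `value`.  MID rows of one fragment sum to 1.
#' @export
simulate_labeling <- function(sys, v, mix, catalog, background = 0) {
  casc <- emu_cascade(sys, v, mix, catalog, basis = NULL, background = background)
  assemble_measurements(sys, casc$mids, v)
}

assemble_measurements <- function(sys, mids, v) {
  groups <- sys$groups
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    key <- emu_key(groups$metabolite[i], sort(groups$positions[[i]]))
    mid <- mids[[key]]
    sh <- groups$shifts[[i]]
    rows[[i]] <- tibble(type = "ms", group = groups$id[i], shift = sh,
                        value = mid[sh + 1L])
  }
  rates <- sys$model$measurements$rates
  if (nrow(rates) > 0)
    rows[[length(rows) + 1L]] <- tibble(type = "rate", group = rates$flux,
                                        shift = NA_integer_,
                                        value = unname(v$net[rates$flux]))
  dplyr::bind_rows(rows)
}

#' Standard deviation of a labeling measurement
#'
#' Affine GC-MS error model `sigma(y) = slope * y + intercept`; the default
#' coefficients are the literature-survey values slope = 4.120e-2 and
#' intercept = 6.655e-3 used throughout.
#'
#' @param y measured or simulated mass-isotopomer fraction, in `[0, 1]`.
#' @param slope,intercept error-model coefficients.
#' @return standard deviation(s).
#' @examples
#' error_sigma(0)    # intercept
#' error_sigma(0.5)
#' @export
error_sigma <- function(y, slope = 4.120e-2, intercept = 6.655e-3) {
  slope * y + intercept
}

#' Diagonal measurement covariance
#'
#' Applies the model's affine error model to the simulated labeling values
#' and appends the configured rate-measurement standard deviations; the
#' measurement errors are assumed independent, so the covariance is
#' diagonal.
#'
#' @param y measurement tibble from [simulate_labeling()].
#' @param model the [network_model()].
#' @return numeric vector of variances (the diagonal of Sigma), aligned with
#'   the rows of `y`.
#' @export
measurement_variances <- function(y, model) {
  em <- model$measurements$error_model
  sig <- numeric(nrow(y))
  ms <- y$type == "ms"
  sig[ms] <- error_sigma(y$value[ms], em[["slope"]], em[["intercept"]])
  if (any(!ms)) {
    rates <- model$measurements$rates
    sig[!ms] <- rates$sd[match(y$group[!ms], rates$flux)]
  }
  if (any(sig <= 0))
    abort_fluxred("non-positive measurement standard deviation", "fluxred_model_error")
  sig^2
}
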