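#' Construct a 13C-MFA network model
#'
#' A `network_model` bundles everything a tracer-design study needs to know
#' about the biological system: the metabolite pools with their carbon counts,
#' the reactions with per-reaction carbon atom transitions, linear flux
#' constraints, and the measurement configuration (GC-MS fragment groups with
#' an affine error model, plus extracellular rate measurements).  Models are
#' usually read from a FluxML-subset XML file with [parse_model()]; this
#' constructor is the programmatic route used by the fixture generators.
#'
#' @param metabolites tibble with columns `id`, `n_carbons`, `role`
#'   (`"input"`, `"balanced"`, or `"output"`).  Input pools are substrate
#'   sources with fixed isotopomer composition; balanced pools obey
#'   steady-state mass balances; output pools are drains whose labeling is
#'   still simulated but which carry no balance row.
#' @param reactions list of reactions as returned by [reaction()].
#' @param constraints list with elements `net_bounds` (tibble `flux`,`lo`,`hi`),
#'   `xch_bounds` (tibble, bidirectional reactions only), `fixed`
#'   (tibble `flux`,`value`; equality constraints such as a normalized uptake),
#'   and optionally `linear` (list with `coef` matrix over net fluxes, `rhs`,
#'   `op` in `"le"`/`"eq"`).
#' @param measurements list with elements `groups` (tibble `id`, `metabolite`,
#'   `positions` list-column, `shifts` list-column), `error_model` (numeric
#'   `c(slope, intercept)` giving sigma = slope*y + intercept), `rates`
#'   (tibble `flux`, `value`, `sd`), and `normalization` (`NULL` or
#'   `list(flux=, value=)`).
#' @param name optional model name.
#'
#' @return an object of class `network_model`.
#' @seealso [parse_model()], [write_model()], [build_stoichiometry()]
#' @export
network_model <- function(metabolites, reactions, constraints, measurements,
                          name = "model") {
  metabolites <- as_tibble(metabolites)
  constraints <- normalize_constraints(constraints, reactions)
  measurements <- normalize_measurements(measurements)
  # the normalization flux is an equality constraint
  norm <- measurements$normalization
  if (!is.null(norm) && !norm$flux %in% constraints$fixed$flux)
    constraints$fixed <- dplyr::bind_rows(constraints$fixed,
                                          tibble(flux = norm$flux, value = norm$value))
  m <- structure(list(
    name = name,
    metabolites = metabolites,
    reactions = reactions,
    constraints = constraints,
    measurements = measurements
  ), class = "network_model")
  validate_network_model(m)
  m
}

#' Define a reaction with carbon atom transitions
#'
#' Atom transitions use the FluxML letter convention: every educt carbon gets
#' a distinct single-character label, and each product carbon carries the
#' label of the educt carbon it originates from.  The atom map must therefore
#' be a bijection between educt and product carbons (carbon conservation).
#' A metabolite consumed or produced with stoichiometric coefficient k simply
#' appears k times in `educts`/`products`.
#'
#' @param id reaction identifier.
#' @param educts,products lists of `list(met = <metabolite id>,
#'   atoms = <character vector of per-carbon labels>)`.  Pools without carbon
#'   (e.g. CO2 sinks modeled as 0-carbon) use `atoms = character(0)`.
#' @param bidirectional logical; bidirectional reactions get an exchange-flux
#'   coordinate and contribute atom transitions in both directions.
#' @return a list of class `fluxred_reaction`.
#' @export
reaction <- function(id, educts, products, bidirectional = FALSE) {
  structure(list(id = id, educts = educts, products = products,
                 bidirectional = isTRUE(bidirectional)),
            class = "fluxred_reaction")
}

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

normalize_constraints <- function(con, reactions) {
  rids <- vapply(reactions, `[[`, "", "id")
  bidir <- vapply(reactions, `[[`, NA, "bidirectional")
  con$net_bounds <- if (is.null(con$net_bounds)) {
    tibble(flux = rids, lo = -100, hi = 100)
  } else {
    nb <- as_tibble(con$net_bounds)
    missing <- setdiff(rids, nb$flux)
    dplyr::bind_rows(nb, tibble(flux = missing, lo = -100, hi = 100))
  }
  con$xch_bounds <- if (is.null(con$xch_bounds)) {
    tibble(flux = rids[bidir], lo = 0, hi = 200)
  } else {
    xb <- as_tibble(con$xch_bounds)
    missing <- setdiff(rids[bidir], xb$flux)
    dplyr::bind_rows(xb, tibble(flux = missing, lo = 0, hi = 200))
  }
  con$fixed <- as_tibble(con$fixed %||% tibble(flux = character(), value = numeric()))
  con$linear <- con$linear
  con
}

normalize_measurements <- function(ms) {
  em <- ms$error_model %||% c(slope = 4.120e-2, intercept = 6.655e-3)
  names(em) <- c("slope", "intercept")
  list(
    groups = as_tibble(ms$groups %||%
      tibble(id = character(), metabolite = character(),
             positions = list(), shifts = list())),
    error_model = em,
    rates = as_tibble(ms$rates %||% tibble(flux = character(), value = numeric(),
                                           sd = numeric())),
    normalization = ms$normalization)
}

validate_network_model <- function(m) {
  mets <- m$metabolites
  if (anyDuplicated(mets$id))
    abort_fluxred("duplicated metabolite ids", "fluxred_model_error")
  if (any(mets$n_carbons < 0))
    abort_fluxred("negative carbon count", "fluxred_model_error")
  if (!all(mets$role %in% c("input", "balanced", "output")))
    abort_fluxred("metabolite role must be input/balanced/output",
                  "fluxred_model_error")
  ncarb <- setNames(mets$n_carbons, mets$id)
  rids <- reaction_ids(m)
  if (anyDuplicated(rids))
    abort_fluxred("duplicated reaction ids", "fluxred_model_error")
  for (r in m$reactions) {
    for (side in c("educts", "products")) {
      for (term in r[[side]]) {
        if (!term$met %in% mets$id)
          abort_fluxred(
            sprintf("reaction '%s' references unknown metabolite '%s'",
                    r$id, term$met),
            "fluxred_dangling_ref")
        if (length(term$atoms) != ncarb[[term$met]])
          abort_fluxred(
            sprintf("reaction '%s': atom labels for '%s' have length %d, expected %d",
                    r$id, term$met, length(term$atoms), ncarb[[term$met]]),
            "fluxred_carbon_imbalance")
      }
    }
    ea <- unlist(lapply(r$educts, `[[`, "atoms"))
    pa <- unlist(lapply(r$products, `[[`, "atoms"))
    if (anyDuplicated(ea) || anyDuplicated(pa))
      abort_fluxred(
        sprintf("reaction '%s': atom labels must be distinct within each side", r$id),
        "fluxred_carbon_imbalance")
    if (length(ea) != length(pa) || !setequal(ea, pa))
      abort_fluxred(
        sprintf("reaction '%s': educt carbons (%d) do not map onto product carbons (%d)",
                r$id, length(ea), length(pa)),
        "fluxred_carbon_imbalance")
  }
  # constraints reference known fluxes
  for (fl in c(m$constraints$net_bounds$flux, m$constraints$xch_bounds$flux,
               m$constraints$fixed$flux))
    if (!fl %in% rids)
      abort_fluxred(sprintf("constraint references unknown flux '%s'", fl),
                    "fluxred_dangling_ref")
  bidir <- setNames(vapply(m$reactions, `[[`, NA, "bidirectional"), rids)
  if (any(!bidir[m$constraints$xch_bounds$flux]))
    abort_fluxred("exchange bounds given for a unidirectional reaction",
                  "fluxred_model_error")
  # measurement groups
  for (i in seq_len(nrow(m$measurements$groups))) {
    g <- m$measurements$groups[i, ]
    if (!g$metabolite %in% mets$id)
      abort_fluxred(sprintf("measurement group '%s' references unknown metabolite '%s'",
                            g$id, g$metabolite), "fluxred_dangling_ref")
    pos <- g$positions[[1]]
    if (anyDuplicated(pos) || any(pos < 1 | pos > ncarb[[g$metabolite]]))
      abort_fluxred(sprintf("measurement group '%s': invalid carbon positions", g$id),
                    "fluxred_model_error")
    sh <- g$shifts[[1]]
    if (any(sh < 0 | sh > length(pos)) || anyDuplicated(sh) ||
        any(diff(sort(sh)) != 1))
      abort_fluxred(sprintf("measurement group '%s': mass shifts must be a contiguous subset of 0..%d",
                            g$id, length(pos)), "fluxred_model_error")
  }
  for (fl in m$measurements$rates$flux)
    if (!fl %in% rids)
      abort_fluxred(sprintf("rate measurement references unknown flux '%s'", fl),
                    "fluxred_dangling_ref")
  norm <- m$measurements$normalization
  if (!is.null(norm) && !norm$flux %in% rids)
    abort_fluxred("normalization references unknown flux", "fluxred_dangling_ref")
  invisible(m)
}

#' @export
print.network_model <- function(x, ...) {
  nb <- sum(x$metabolites$role == "balanced")
  bid <- sum(vapply(x$reactions, `[[`, NA, "bidirectional"))
  cat(sprintf("<network_model '%s'>\n", x$name))
  cat(sprintf("  %d metabolites (%d balanced), %d reactions (%d bidirectional)\n",
              nrow(x$metabolites), nb, length(x$reactions), bid))
  cat(sprintf("  %d measurement groups, %d rate measurements\n",
              nrow(x$measurements$groups), nrow(x$measurements$rates)))
  invisible(x)
}
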