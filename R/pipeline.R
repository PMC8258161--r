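#' Run the robustified tracer design scan
#'
#' The core of the robust-design workflow: for every sampled flux map and
#' every candidate tracer mixture, simulate the labeling measurements,
#' compute the analytic Jacobian, assemble the Fisher information matrix,
#' select active (identifiable) flux sets for every achievable size, and
#' evaluate the reference-normalized D-criterion.  Per-record failures
#' (singular labeling systems, degenerate FIMs) are recorded as flags, never
#' abort the scan, and results are independent of the evaluation order.
#'
#' @param model a [network_model()].
#' @param catalog a tracer catalogue ([parse_tracer_spec()]).
#' @param grid a [enumerate_mixtures()] grid (or a list of [mixture()]s).
#' @param samples a `flux_sample_set` from [sample_flux_space()] /
#'   [hit_and_run()]; its `basis` attribute (or `basis` argument) defines
#'   the free coordinates.
#' @param reference the reference mixture the D-criterion is normalized to.
#' @param control an [identifiability_control()].
#' @param basis optional [free_flux_basis()] (defaults to the sample set's).
#' @param background natural 13C background (atom%).
#' @param method active-set selection method passed to
#'   [select_active_fluxes()]; the default greedy removal matches the
#'   iterative procedure used at scan scale.
#' @return a `red_pool`: list with `records` (tibble: `sample`, `mixture`,
#'   `n_act`, `phi_d`, `ref_degenerate`, `active`, `sds` list-column),
#'   `pairs` (tibble: per (sample, mixture) the maximal `n_act`, degeneracy
#'   flag, singular-value floor and FIM diagonal for one-flux designs), the
#'   grid, reference index, control settings and provenance.
#' @export
run_red <- function(model, catalog, grid, samples, reference,
                    control = identifiability_control(), basis = NULL,
                    background = 0, method = "greedy") {
  basis <- basis %||% attr(samples, "basis") %||% free_flux_basis(model)
  sys <- emu_decompose(model)
  mixtures <- if (inherits(grid, "mixture_grid"))
    lapply(seq_len(grid$n_total), grid_mixture, grid = grid)
  else lapply(grid, mixture)
  reference <- mixture(reference)
  n_s <- nrow(samples)
  labels <- free_labels(basis)

  rec_rows <- list(); pair_rows <- list()
  for (si in seq_len(n_s)) {
    v <- flux_state(basis, samples[si, ])
    ref_fim <- tryCatch({
      J <- jacobian(sys, basis, v, reference, catalog, background = background)
      fisher_information(J, measurement_variances(attr(J, "y"), model))
    }, fluxred_singular = function(e) NULL)
    for (mi in seq_along(mixtures)) {
      res <- evaluate_pair(sys, basis, v, mixtures[[mi]], catalog, model,
                           ref_fim, control, background, method)
      res$pair$sample <- si; res$pair$mixture <- mi
      pair_rows[[length(pair_rows) + 1L]] <- res$pair
      if (!is.null(res$records) && nrow(res$records) > 0) {
        res$records$sample <- si; res$records$mixture <- mi
        rec_rows[[length(rec_rows) + 1L]] <- res$records
      }
    }
  }
  records <- dplyr::bind_rows(rec_rows)
  if (nrow(records) > 0) {
    records <- dplyr::relocate(records, "sample", "mixture")
  } else {
    records <- tibble(sample = integer(), mixture = integer(), n_act = integer(),
                      phi_d = numeric(), ref_degenerate = logical(),
                      active = character(), sds = list())
  }
  pairs <- dplyr::relocate(dplyr::bind_rows(pair_rows), "sample", "mixture")
  structure(list(records = records, pairs = pairs, grid = grid,
                 mixtures = mixtures, reference = reference,
                 control = control, labels = labels, n_samples = n_s,
                 catalog = catalog, model_name = model$name,
                 seed = attr(samples, "seed")),
            class = "red_pool")
}

# one (flux sample, mixture) evaluation -> records over n_act + pair summary
evaluate_pair <- function(sys, basis, v, mix, catalog, model, ref_fim,
                          control, background, method) {
  d <- n_free(basis)
  fail_pair <- tibble(max_nact = 0L, degenerate = TRUE, sim_failed = TRUE,
                      sv_floor = NA_real_, fim_diag = list(NULL))
  FIM <- tryCatch({
    J <- jacobian(sys, basis, v, mix, catalog, background = background)
    fisher_information(J, measurement_variances(attr(J, "y"), model))
  }, fluxred_singular = function(e) NULL)
  if (is.null(FIM)) return(list(pair = fail_pair, records = NULL))

  afs_max <- select_active_fluxes(FIM, "max", control, method = method)
  pair <- tibble(max_nact = afs_max$n_act, degenerate = afs_max$degenerate,
                 sim_failed = FALSE, sv_floor = afs_max$sv_floor,
                 fim_diag = list(setNames(diag(FIM), free_labels(basis))))
  if (afs_max$degenerate) return(list(pair = pair, records = NULL))

  recs <- vector("list", afs_max$n_act)
  for (k in seq_len(afs_max$n_act)) {
    afs <- if (k == afs_max$n_act) afs_max
           else select_active_fluxes(FIM, k, control, method = method)
    if (!afs$achievable) next
    phi <- NA_real_; ref_deg <- TRUE
    if (!is.null(ref_fim)) {
      ref_floor <- control$sv_rel * svd(ref_fim, nu = 0, nv = 0)$d[1]
      if (admissible_subset(ref_fim, afs$active, ref_floor, control$cond_max)) {
        cov_ref <- covariance(ref_fim[afs$active, afs$active, drop = FALSE])
        phi <- d_criterion(afs$cov, cov_ref, k)
        ref_deg <- FALSE
      }
    }
    recs[[k]] <- tibble(
      n_act = k, phi_d = phi, ref_degenerate = ref_deg,
      active = paste(free_labels(basis)[afs$active], collapse = ","),
      sds = list(setNames(sqrt(diag(afs$cov)), free_labels(basis)[afs$active])))
  }
  list(pair = pair, records = dplyr::bind_rows(recs))
}

#' @export
print.red_pool <- function(x, ...) {
  cat(sprintf("<red_pool> %d flux samples x %d mixtures, %d records\n",
              x$n_samples, length(x$mixtures), nrow(x$records)))
  invisible(x)
}

#' Aggregate a design-record pool into the decision metrics
#'
#' Phase III of the workflow: per (mixture, n_act) the median D-criterion
#' over the flux samples that achieve `n_act` identifiable fluxes, the
#' coverage (share of samples achieving `n_act`, in percent; simulation
#' failures count as non-covering), and per mixture the tracer cost;
#' per (mixture, flux) the identifiability frequency (share of samples
#' whose maximal active set contains the flux) and the quartiles of the
#' flux standard deviation when identified.
#'
#' @param pool a `red_pool` from [run_red()].
#' @param amounts named grams per substrate for the cost criterion;
#'   defaults to [required_amounts()] of the pool's catalogue when the
#'   chemostat settings are present, otherwise costs are `NA`.
#' @return a `red_aggregated`: list of tibbles `metrics` (`mixture`,
#'   `n_act`, `phi_d_med`, `coverage`, `cost`), `flux_stats` (`mixture`,
#'   `flux`, `ident_freq`, `sd_q1`, `sd_med`, `sd_q3`), and `provenance`.
#' @export
aggregate_pool <- function(pool, amounts = NULL) {
  n_s <- pool$n_samples
  amounts <- amounts %||% tryCatch(required_amounts(pool$catalog),
                                   fluxred_config_error = function(e) NULL)
  costs <- vapply(seq_along(pool$mixtures), function(mi) {
    if (is.null(amounts)) return(NA_real_)
    tracer_cost(pool$catalog, pool$mixtures[[mi]], amounts)
  }, numeric(1))

  max_k <- if (nrow(pool$pairs) > 0) max(pool$pairs$max_nact) else 0L
  metrics <- list()
  for (mi in seq_along(pool$mixtures)) {
    pr <- pool$pairs[pool$pairs$mixture == mi, ]
    for (k in seq_len(max_k)) {
      ach <- sum(pr$max_nact >= k)
      rk <- pool$records[pool$records$mixture == mi & pool$records$n_act == k, ]
      metrics[[length(metrics) + 1L]] <- tibble(
        mixture = mi, n_act = k,
        phi_d_med = if (nrow(rk) > 0) median(rk$phi_d, na.rm = TRUE) else NA_real_,
        coverage = 100 * ach / n_s,
        cost = costs[mi])
    }
  }
  metrics <- dplyr::bind_rows(metrics)

  flux_stats <- list()
  for (mi in seq_along(pool$mixtures)) {
    pr <- pool$pairs[pool$pairs$mixture == mi, ]
    top <- dplyr::inner_join(
      pool$records[pool$records$mixture == mi, ],
      tibble(sample = pr$sample, n_act = pr$max_nact), by = c("sample", "n_act"))
    for (fl in pool$labels) {
      sds <- vapply(seq_len(nrow(top)), function(i) {
        s <- top$sds[[i]]
        if (fl %in% names(s)) s[[fl]] else NA_real_
      }, numeric(1))
      hit <- !is.na(sds)
      qs <- if (any(hit)) quantile(sds[hit], c(0.25, 0.5, 0.75), names = FALSE)
            else rep(NA_real_, 3)
      flux_stats[[length(flux_stats) + 1L]] <- tibble(
        mixture = mi, flux = fl, ident_freq = sum(hit) / n_s,
        sd_q1 = qs[1], sd_med = qs[2], sd_q3 = qs[3])
    }
  }
  structure(list(metrics = metrics,
                 flux_stats = dplyr::bind_rows(flux_stats),
                 provenance = list(n_samples = n_s, seed = pool$seed,
                                   model = pool$model_name,
                                   sv_rel = pool$control$sv_rel,
                                   cond_max = pool$control$cond_max)),
            class = "red_aggregated")
}

#' @export
print.red_aggregated <- function(x, ...) {
  cat(sprintf("<red_aggregated> %d mixtures x n_act 1..%d\n",
              length(unique(x$metrics$mixture)), max(x$metrics$n_act)))
  print(head(x$metrics, 10))
  invisible(x)
}

#' Tidy the aggregated metrics
#'
#' @param x a `red_aggregated`.
#' @param ... unused.
#' @return the `metrics` tibble.
#' @method tidy red_aggregated
#' @export
tidy.red_aggregated <- function(x, ...) x$metrics

#' One-row summary of an aggregated pool
#'
#' @param x a `red_aggregated`.
#' @param ... unused.
#' @return tibble with sample count, mixture count, the maximal `n_act`
#'   reached and the best coverage at that size.
#' @method glance red_aggregated
#' @export
glance.red_aggregated <- function(x, ...) {
  mk <- max(x$metrics$n_act)
  tibble(n_samples = x$provenance$n_samples,
         n_mixtures = length(unique(x$metrics$mixture)),
         max_nact = mk,
         best_coverage_at_max = max(x$metrics$coverage[x$metrics$n_act == mk]))
}

#' Dimension-reduced one-flux designs
#'
#' For a single flux of interest: per mixture the frequency with which the
#' flux is identifiable *alone* (all other free fluxes fixed to the sampled
#' reference values, so the information is the corresponding FIM diagonal
#' entry) and the distribution of its expected standard deviation
#' `1/sqrt(FIM_jj)`.
#'
#' @param pool a `red_pool`.
#' @param flux a free-coordinate label (see `pool$labels`).
#' @return tibble `mixture`, `ident_freq`, `sd_q1`, `sd_med`, `sd_q3`.
#' @export
partial_design <- function(pool, flux) {
  if (!flux %in% pool$labels)
    abort_fluxred(sprintf("unknown free flux '%s' (available: %s)", flux,
                          paste(pool$labels, collapse = ", ")),
                  "fluxred_config_error")
  out <- list()
  for (mi in seq_along(pool$mixtures)) {
    pr <- pool$pairs[pool$pairs$mixture == mi & !pool$pairs$sim_failed, ]
    fim_jj <- vapply(pr$fim_diag, function(dg) dg[[flux]], numeric(1))
    ok <- fim_jj >= pr$sv_floor & fim_jj > 0
    sds <- 1 / sqrt(fim_jj[ok])
    qs <- if (any(ok)) quantile(sds, c(0.25, 0.5, 0.75), names = FALSE)
          else rep(NA_real_, 3)
    out[[mi]] <- tibble(mixture = mi, ident_freq = sum(ok) / pool$n_samples,
                        sd_q1 = qs[1], sd_med = qs[2], sd_q3 = qs[3])
  }
  dplyr::bind_rows(out)
}

#' Ternary slice of the aggregated metrics
#'
#' Holds every substrate except `substrate` at a fixed composition and
#' tabulates the three species fractions of `substrate` against the metrics
#' — the data behind a mixture-triangle plot.
#'
#' @param agg a `red_aggregated`.
#' @param pool the `red_pool` it came from (for the grid).
#' @param substrate substrate with exactly 3 species.
#' @param n_act design size to slice at.
#' @param fixed named list of the other substrates' [mixture()] fractions;
#'   defaults to the reference mixture's.
#' @return tibble with the three species fractions, `phi_d_med`, `coverage`,
#'   `cost`.
#' @export
ternary_slice <- function(agg, pool, substrate, n_act,
                          fixed = pool$reference[setdiff(names(pool$reference), substrate)]) {
  grid <- pool$grid
  if (!inherits(grid, "mixture_grid"))
    abort_fluxred("ternary_slice needs a lattice mixture grid", "fluxred_config_error")
  sp <- colnames(grid$per_substrate[[substrate]])
  if (length(sp) != 3)
    abort_fluxred(sprintf("substrate '%s' has %d species; a ternary slice needs 3",
                          substrate, length(sp)), "fluxred_config_error")
  rows <- list()
  for (mi in seq_along(pool$mixtures)) {
    mx <- pool$mixtures[[mi]]
    match_fixed <- all(vapply(names(fixed), function(s)
      max(abs(mx[[s]][names(fixed[[s]])] - fixed[[s]])) < 1e-9, NA))
    if (!match_fixed) next
    met <- agg$metrics[agg$metrics$mixture == mi & agg$metrics$n_act == n_act, ]
    fr <- mx[[substrate]][sp]
    rows[[length(rows) + 1L]] <- tibble(
      mixture = mi, !!sp[1] := fr[[1]], !!sp[2] := fr[[2]], !!sp[3] := fr[[3]],
      phi_d_med = met$phi_d_med, coverage = met$coverage, cost = met$cost)
  }
  dplyr::bind_rows(rows)
}

#' Export / re-import a pool directory
#'
#' Writes the records, pair summaries, aggregated metrics and provenance as
#' CSV + JSON into a directory; `read_pool()` restores the aggregated pool
#' identically (list-columns are serialized as JSON strings).
#'
#' @param pool a `red_pool`.
#' @param agg its `red_aggregated` (computed if missing).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_pool <- function(pool, dir, agg = aggregate_pool(pool)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    df <- as.data.frame(df)
    for (cl in names(df))
      if (is.list(df[[cl]]))
        df[[cl]] <- vapply(df[[cl]], function(x)
          as.character(jsonlite::toJSON(as.list(x), auto_unbox = TRUE, digits = NA)),
          "")
    tryCatch(utils::write.csv(df, file.path(dir, name), row.names = FALSE),
             error = function(e) abort_fluxred(
               sprintf("failed writing '%s': %s", file.path(dir, name),
                       conditionMessage(e)), "fluxred_io_error"))
  }
  wr(pool$records, "records.csv")
  wr(pool$pairs, "pairs.csv")
  wr(agg$metrics, "metrics.csv")
  wr(agg$flux_stats, "flux_stats.csv")
  jsonlite::write_json(agg$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname export_pool
#' @export
read_pool <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path))
      abort_fluxred(sprintf("missing pool file '%s'", path), "fluxred_io_error")
    df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    # all-NA numeric columns come back logical; restore their type
    for (cl in names(df))
      if (is.logical(df[[cl]]) && all(is.na(df[[cl]])))
        df[[cl]] <- as.numeric(df[[cl]])
    df
  }
  structure(list(metrics = rd("metrics.csv"),
                 flux_stats = rd("flux_stats.csv"),
                 provenance = jsonlite::read_json(file.path(dir, "provenance.json"),
                                                  simplifyVector = TRUE)),
            class = "red_aggregated")
}
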