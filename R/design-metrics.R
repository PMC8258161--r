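#' Fisher information matrix of a tracer design
#'
#' `FIM = J' Sigma^-1 J` for a diagonal measurement covariance; the result
#' is symmetrized to remove floating-point asymmetry and is positive
#' semidefinite by construction.
#'
#' @param J measurement Jacobian (rows = measurements, columns = free
#'   fluxes), e.g. from [jacobian()].
#' @param variances diagonal of Sigma (vector of measurement variances),
#'   e.g. from [measurement_variances()].
#' @return symmetric matrix (free fluxes x free fluxes).
#' @export
fisher_information <- function(J, variances) {
  if (length(variances) != nrow(J))
    abort_fluxred(sprintf("variance vector length %d does not match %d measurement rows",
                          length(variances), nrow(J)), "fluxred_config_error")
  if (any(variances <= 0))
    abort_fluxred("variances must be strictly positive", "fluxred_config_error")
  FIM <- crossprod(J / sqrt(variances))
  (FIM + t(FIM)) / 2
}

#' Identifiability thresholds
#'
#' A candidate active-flux set is admissible when the FIM restricted to it
#' has minimal singular value at least `sv_rel * ||FIM||_2` (spectral norm of
#' the *full* FIM, so admissibility is monotone under taking subsets) and
#' condition number at most `cond_max`.
#'
#' @param sv_rel relative lower threshold on singular values.
#' @param cond_max upper threshold on the condition number.
#' @param exhaustive_limit up to this many free fluxes subset selection is
#'   exact (enumeration); above it the greedy removal heuristic is used.
#' @param objective `"det"` (default: minimal covariance determinant among
#'   admissible equal-size sets) or `"trace"`.
#' @return list of class `identifiability_control`.
#' @export
identifiability_control <- function(sv_rel = 1e-9, cond_max = 1e10,
                                    exhaustive_limit = 12L,
                                    objective = c("det", "trace")) {
  list(sv_rel = sv_rel, cond_max = cond_max,
       exhaustive_limit = as.integer(exhaustive_limit),
       objective = match.arg(objective))
}

admissible_subset <- function(FIM, subset, sv_floor, cond_max) {
  sub <- FIM[subset, subset, drop = FALSE]
  sv <- svd(sub, nu = 0, nv = 0)$d
  min(sv) > 0 && min(sv) >= sv_floor && max(sv) / min(sv) <= cond_max
}

subset_objective <- function(FIM, subset, objective) {
  sub <- FIM[subset, subset, drop = FALSE]
  cv <- tryCatch(chol2inv(chol(sub)), error = function(e) NULL)
  if (is.null(cv)) return(Inf)
  if (objective == "det") det(cv) else sum(diag(cv))
}

#' Select statistically identifiable (active) fluxes
#'
#' Removes statistically non-identifiable free fluxes — conceptually fixing
#' them to their value in the reference flux map — until the restricted FIM
#' is invertible under the configured thresholds.  The removal chain is
#' greedy: while the thresholds are violated (and further down to size 1, to
#' expose every achievable `n_act`), the flux with the largest absolute
#' component in the singular vector of the smallest singular value is
#' dropped, ties broken by declaration order.  For problems with at most
#' `control$exhaustive_limit` free fluxes the set reported for a requested
#' size is the exact optimum over all subsets of that size (minimal
#' `det(Cov)` among admissible sets); the greedy chain serves as the
#' fallback and, with `verify = TRUE`, self-reports suboptimality.
#'
#' @param FIM Fisher information matrix over the free fluxes.
#' @param n_act `"max"` (largest admissible set) or an integer target size.
#' @param control an [identifiability_control()].
#' @param method `"auto"` (exhaustive up to `exhaustive_limit`, else greedy),
#'   `"greedy"`, or `"exhaustive"`.
#' @param verify when `TRUE` and the problem is small enough, a greedy
#'   result is compared against enumeration and flagged if suboptimal.
#' @return list of class `active_flux_set` with elements `active` (indices),
#'   `fixed` (removed indices), `n_act`, `cov`, `det_cov`, `degenerate`
#'   (no non-empty admissible set), `achievable` (logical: requested size
#'   admissible), and `suboptimal` flag.
#' @export
select_active_fluxes <- function(FIM, n_act = "max",
                                 control = identifiability_control(),
                                 method = c("auto", "greedy", "exhaustive"),
                                 verify = FALSE) {
  method <- match.arg(method)
  p <- ncol(FIM)
  norm2 <- if (p > 0) svd(FIM, nu = 0, nv = 0)$d[1] else 0
  sv_floor <- control$sv_rel * norm2
  if (norm2 <= 0) {
    return(structure(list(active = integer(0), fixed = seq_len(p), n_act = 0L,
                          cov = NULL, det_cov = NA_real_, degenerate = TRUE,
                          achievable = identical(n_act, 0L), suboptimal = FALSE,
                          sv_floor = sv_floor),
                     class = "active_flux_set"))
  }
  use_exhaustive <- method == "exhaustive" ||
    (method == "auto" && p <= control$exhaustive_limit)
  chain <- greedy_chain(FIM, sv_floor, control$cond_max)
  max_greedy <- if (length(chain$admissible_sizes)) max(chain$admissible_sizes) else 0L

  if (identical(n_act, "max")) {
    if (use_exhaustive) {
      for (k in p:1) {
        best <- best_subset(FIM, k, sv_floor, control)
        if (!is.null(best)) return(finish_set(FIM, best, p, k, sv_floor, FALSE))
      }
      return(finish_set(FIM, integer(0), p, 0L, sv_floor, FALSE, degenerate = TRUE))
    }
    if (max_greedy == 0L)
      return(finish_set(FIM, integer(0), p, 0L, sv_floor, FALSE, degenerate = TRUE))
    set <- chain$sets[[as.character(max_greedy)]]
    sub_flag <- FALSE
    if (verify && p <= control$exhaustive_limit) {
      best <- best_subset(FIM, max_greedy, sv_floor, control)
      sub_flag <- is.null(best) ||
        subset_objective(FIM, set, control$objective) >
          subset_objective(FIM, best, control$objective) * (1 + 1e-6)
    }
    return(finish_set(FIM, set, p, max_greedy, sv_floor, sub_flag))
  }

  k <- as.integer(n_act)
  if (k < 1 || k > p)
    abort_fluxred(sprintf("n_act = %d outside 1..%d", k, p), "fluxred_config_error")
  if (use_exhaustive) {
    best <- best_subset(FIM, k, sv_floor, control)
    if (is.null(best))
      return(finish_set(FIM, integer(0), p, 0L, sv_floor, FALSE, degenerate = TRUE,
                        achievable = FALSE))
    return(finish_set(FIM, best, p, k, sv_floor, FALSE))
  }
  if (!k %in% chain$admissible_sizes)
    return(finish_set(FIM, integer(0), p, 0L, sv_floor, FALSE, degenerate = TRUE,
                      achievable = FALSE))
  set <- chain$sets[[as.character(k)]]
  sub_flag <- FALSE
  if (verify && p <= control$exhaustive_limit) {
    best <- best_subset(FIM, k, sv_floor, control)
    sub_flag <- is.null(best) ||
      subset_objective(FIM, set, control$objective) >
        subset_objective(FIM, best, control$objective) * (1 + 1e-6)
  }
  finish_set(FIM, set, p, k, sv_floor, sub_flag)
}

finish_set <- function(FIM, set, p, k, sv_floor, suboptimal,
                       degenerate = FALSE, achievable = TRUE) {
  cov <- if (length(set) > 0) covariance(FIM[set, set, drop = FALSE]) else NULL
  structure(list(active = set, fixed = setdiff(seq_len(p), set),
                 n_act = as.integer(k), cov = cov,
                 det_cov = if (!is.null(cov)) det(cov) else NA_real_,
                 degenerate = degenerate, achievable = achievable && !degenerate,
                 suboptimal = suboptimal, sv_floor = sv_floor),
            class = "active_flux_set")
}

#' @export
print.active_flux_set <- function(x, ...) {
  if (x$degenerate) cat("<active_flux_set> degenerate (no admissible subset)\n")
  else cat(sprintf("<active_flux_set> n_act = %d, active: %s\n", x$n_act,
                   paste(x$active, collapse = ", ")))
  invisible(x)
}

# nested removal chain: sets[["k"]] is the retained set of size k
greedy_chain <- function(FIM, sv_floor, cond_max) {
  p <- ncol(FIM)
  current <- seq_len(p)
  sets <- list(); admissible <- integer(0)
  while (length(current) >= 1) {
    sets[[as.character(length(current))]] <- current
    if (admissible_subset(FIM, current, sv_floor, cond_max))
      admissible <- c(admissible, length(current))
    if (length(current) == 1) break
    sub <- FIM[current, current, drop = FALSE]
    sv <- svd(sub)
    u <- sv$u[, which.min(sv$d)]
    drop_local <- which.max(abs(u))  # ties: first (declaration order)
    current <- current[-drop_local]
  }
  list(sets = sets, admissible_sizes = admissible)
}

best_subset <- function(FIM, k, sv_floor, control) {
  p <- ncol(FIM)
  best <- NULL; best_obj <- Inf
  cb <- combn(p, k)
  for (j in seq_len(ncol(cb))) {
    s <- cb[, j]
    if (!admissible_subset(FIM, s, sv_floor, control$cond_max)) next
    obj <- subset_objective(FIM, s, control$objective)
    if (obj < best_obj) { best_obj <- obj; best <- s }
  }
  best
}

#' Covariance from a restricted FIM
#'
#' Inverse of the FIM restricted to an active flux set (linearized flux
#' covariance); errors if the restriction is not positive definite,
#' which the admissibility thresholds are meant to preclude.
#'
#' @param FIM_act FIM submatrix over the active fluxes.
#' @return symmetric positive-definite covariance matrix.
#' @export
covariance <- function(FIM_act) {
  cv <- tryCatch(chol2inv(chol(FIM_act)), error = function(e)
    abort_fluxred("restricted FIM is not positive definite", "fluxred_singular"))
  dimnames(cv) <- dimnames(FIM_act)
  (cv + t(cv)) / 2
}

#' Reference-normalized D-criterion
#'
#' `Phi_D = (det(Cov_ref) / det(Cov_candidate))^(1 / (2 n_act))`, both
#' covariances taken over the *same* active flux set.  Values above 1 mean
#' the candidate mixture is expected to determine the active fluxes more
#' precisely than the reference mixture; the `1/(2 n_act)` root makes the
#' value read as an average standard-deviation ratio (set `exponent =
#' 1/n_act` for the variance-ratio convention).
#'
#' @param cov_candidate,cov_reference covariance matrices over the same
#'   active set.
#' @param n_act size of the active set.
#' @param exponent root applied to the determinant ratio.
#' @return scalar criterion value.
#' @examples
#' d_criterion(diag(2), diag(4, 2), n_act = 2)  # 2.0
#' @export
d_criterion <- function(cov_candidate, cov_reference, n_act,
                        exponent = 1 / (2 * n_act)) {
  dc <- det(cov_candidate); dr <- det(cov_reference)
  if (dc <= 0 || dr <= 0)
    abort_fluxred("covariance determinants must be positive", "fluxred_singular")
  (dr / dc)^exponent
}

#' Required substrate amounts for a chemostat labeling experiment
#'
#' Grams of each substrate consumed until sampling: medium concentration
#' (g/L) x dilution rate (1/h) x working volume (L) x duration (h), with the
#' duration given by the number of reactor residence times divided by the
#' dilution rate (isotopic stationarity of protein-bound amino acids is
#' conventionally assumed after ~5 residence times).
#'
#' @param catalog a `tracer_catalog` carrying concentrations and chemostat
#'   settings, or `NULL` when the parameters are passed explicitly.
#' @param concentrations named g/L vector (overrides the catalogue).
#' @param dilution_rate 1/h.
#' @param working_volume L.
#' @param residence_times dimensionless.
#' @return named vector of grams per substrate.
#' @export
required_amounts <- function(catalog = NULL, concentrations = NULL,
                             dilution_rate = NULL, working_volume = NULL,
                             residence_times = NULL) {
  conc <- concentrations %||% catalog$concentrations
  ch <- catalog$chemostat
  D <- dilution_rate %||% ch$dilution_rate
  V <- working_volume %||% ch$working_volume
  n_res <- residence_times %||% ch$residence_times
  if (is.null(conc) || is.null(D) || is.null(V) || is.null(n_res) ||
      any(is.na(conc)))
    abort_fluxred("chemostat settings incomplete (concentration, dilution rate, volume, residence times)",
                  "fluxred_config_error")
  duration <- n_res / D
  conc * D * V * duration
}

#' Tracer cost of a mixture
#'
#' Cost criterion: the price of the labeled medium, summing over substrates
#' and species `fraction x grams(substrate) x price ($/g)`.
#'
#' @param catalog a `tracer_catalog` with prices.
#' @param mix a [mixture()].
#' @param amounts named grams per substrate, e.g. from [required_amounts()].
#' @return cost in $.
#' @export
tracer_cost <- function(catalog, mix, amounts = required_amounts(catalog)) {
  total <- 0
  for (sub in names(mix)) {
    sp <- catalog$species[catalog$species$substrate == sub, ]
    fr <- mix[[sub]]
    pr <- sp$price[match(names(fr), sp$label)]
    if (anyNA(pr))
      abort_fluxred(sprintf("missing price for species '%s' of '%s'",
                            names(fr)[which(is.na(pr))[1]], sub),
                    "fluxred_tracer_error")
    if (is.na(amounts[sub] %||% NA))
      abort_fluxred(sprintf("missing required amount for substrate '%s'", sub),
                    "fluxred_config_error")
    total <- total + sum(fr * pr) * amounts[[sub]]
  }
  total
}
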