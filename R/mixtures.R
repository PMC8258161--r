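#' Enumerate tracer mixtures on a simplex lattice
#'
#' For a substrate with `s` available species and grid step `d` (with `1/d`
#' integral), all fraction vectors with entries that are multiples of `d`
#' and sum to 1 are enumerated; the count equals the closed form
#' `choose(1/d + s - 1, s - 1)`, i.e. `1/(s-1)! * prod_{i=0}^{s-2}(1/d+1+i)`.
#' Multi-substrate grids are the Cartesian product over substrates.
#' Fractions are stored as exact integer multiples of `d`, so mixture
#' identities never suffer float drift.
#'
#' @param species either a named integer vector (substrate -> species count)
#'   or a `tracer_catalog`, whose species labels are then attached.
#' @param step grid step `d` (e.g. 0.1 for 10% steps).
#' @return a `mixture_grid`: list with `per_substrate` (named list of
#'   integer count matrices, one row per lattice point), `labels`,
#'   `step`, `n_per_substrate`, and `n_total`.
#' @examples
#' g <- enumerate_mixtures(c(GLYC = 3), step = 0.1)
#' g$n_total  # 66
#' @export
enumerate_mixtures <- function(species, step = 0.1) {
  m_inv <- 1 / step
  if (abs(m_inv - round(m_inv)) > 1e-9)
    abort_fluxred("1/step must be an integer", "fluxred_config_error")
  m_inv <- as.integer(round(m_inv))
  if (inherits(species, "tracer_catalog")) {
    labels <- split(species$species$label, species$species$substrate)
    labels <- labels[unique(species$species$substrate)]  # keep declaration order
    counts <- vapply(labels, length, 0L)
  } else {
    counts <- species
    labels <- lapply(counts, function(k) paste0("species", seq_len(k)))
  }
  if (any(counts < 1))
    abort_fluxred("each substrate needs at least one species", "fluxred_config_error")
  per <- lapply(seq_along(counts), function(i) {
    M <- compositions_matrix(m_inv, counts[[i]])
    colnames(M) <- labels[[i]]
    M
  })
  names(per) <- names(counts)
  n_per <- vapply(per, nrow, 0L)
  # cross-check against the closed-form lattice count
  expected <- vapply(counts, function(s) choose(m_inv + s - 1, s - 1), 0)
  stopifnot(all(n_per == expected))
  structure(list(per_substrate = per, labels = labels, step = step,
                 n_per_substrate = n_per, n_total = as.integer(prod(n_per))),
            class = "mixture_grid")
}

# all non-negative integer vectors of length k summing to total (lexicographic)
compositions_matrix <- function(total, k) {
  if (k == 1) return(matrix(total, 1, 1))
  out <- list()
  for (first in 0:total) {
    rest <- compositions_matrix(total - first, k - 1)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  M <- do.call(rbind, out)
  dimnames(M) <- NULL
  M
}

#' Closed-form simplex-lattice size
#'
#' @param s number of species.
#' @param step grid step `d` with `1/d` integral.
#' @return number of lattice mixtures, `1/(s-1)! * prod_{i=0}^{s-2}(1/d+1+i)`.
#' @export
mixture_count <- function(s, step) {
  m_inv <- round(1 / step)
  if (s == 1) return(1)
  prod(m_inv + 1 + 0:(s - 2)) / factorial(s - 1)
}

#' @export
print.mixture_grid <- function(x, ...) {
  cat(sprintf("<mixture_grid> step %g: %s => %d mixtures\n", x$step,
              paste(sprintf("%s(%d)", names(x$n_per_substrate), x$n_per_substrate),
                    collapse = " x "), x$n_total))
  invisible(x)
}

# cartesian index (one row per substrate-local lattice row) for mixture i
grid_index <- function(grid, i) {
  n_per <- grid$n_per_substrate
  i0 <- i - 1L
  idx <- integer(length(n_per))
  for (j in rev(seq_along(n_per))) {
    idx[j] <- i0 %% n_per[j] + 1L
    i0 <- i0 %/% n_per[j]
  }
  setNames(idx, names(n_per))
}

#' Extract one mixture from a grid
#'
#' @param grid a [enumerate_mixtures()] result.
#' @param i mixture index in `1..n_total`.
#' @return a [mixture()].
#' @export
grid_mixture <- function(grid, i) {
  if (i < 1 || i > grid$n_total)
    abort_fluxred("mixture index out of range", "fluxred_config_error")
  idx <- grid_index(grid, i)
  mx <- lapply(names(idx), function(s) {
    counts <- grid$per_substrate[[s]][idx[[s]], ]
    setNames(counts * grid$step, colnames(grid$per_substrate[[s]]))
  })
  names(mx) <- names(idx)
  mixture(mx)
}

#' Tidy a mixture grid into a long tibble
#'
#' @param x a `mixture_grid`.
#' @param ... unused.
#' @return tibble with columns `mixture`, `substrate`, `species`, `fraction`.
#' @method tidy mixture_grid
#' @export
tidy.mixture_grid <- function(x, ...) {
  rows <- lapply(seq_len(x$n_total), function(i) {
    mx <- grid_mixture(x, i)
    dplyr::bind_rows(lapply(names(mx), function(s)
      tibble(mixture = i, substrate = s, species = names(mx[[s]]),
             fraction = unname(mx[[s]]))))
  })
  dplyr::bind_rows(rows)
}

#' Locate a mixture's index in a grid
#'
#' @param grid a `mixture_grid`.
#' @param mix a [mixture()] whose fractions lie on the grid.
#' @return integer index.
#' @export
grid_locate <- function(grid, mix) {
  idx <- integer(length(grid$per_substrate))
  for (j in seq_along(grid$per_substrate)) {
    s <- names(grid$per_substrate)[j]
    counts <- round(mix[[s]][colnames(grid$per_substrate[[s]])] / grid$step)
    counts[is.na(counts)] <- 0
    hit <- which(apply(grid$per_substrate[[s]], 1, function(r) all(r == counts)))
    if (length(hit) != 1)
      abort_fluxred(sprintf("mixture is not on the grid for substrate '%s'", s),
                    "fluxred_config_error")
    idx[j] <- hit
  }
  i <- 0L
  for (j in seq_along(idx)) i <- i * grid$n_per_substrate[j] + (idx[j] - 1L)
  as.integer(i + 1L)
}
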