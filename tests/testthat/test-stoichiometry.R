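make_simple <- function(reactions, mets, net_bounds = NULL, fixed = NULL,
                        groups = NULL) {
  network_model(mets, reactions,
                constraints = list(net_bounds = net_bounds, fixed = fixed),
                measurements = list(groups = groups), name = "adhoc")
}

one_c <- function(met, atoms = "a") list(met = met, atoms = atoms)

test_that("stoichiometric matrix covers balanced pools only", {
  mets <- tibble::tibble(id = c("A", "B", "C"), n_carbons = 1,
                         role = c("input", "balanced", "output"))
  rxns <- list(reaction("v1", list(one_c("A")), list(one_c("B"))),
               reaction("v2", list(one_c("B")), list(one_c("C"))))
  S <- build_stoichiometry(make_simple(rxns, mets))
  expect_equal(dim(S), c(1L, 2L))
  expect_equal(unname(S["B", ]), c(1, -1))
})

diamond <- function(fixed_uptake = FALSE) {
  mets <- tibble::tibble(id = c("X", "A", "B", "C", "D", "Out"), n_carbons = 1,
                         role = c("input", "balanced", "balanced", "balanced",
                                  "balanced", "output"))
  rxns <- list(
    reaction("upt", list(one_c("X")), list(one_c("A"))),
    reaction("v1", list(one_c("A")), list(one_c("B"))),
    reaction("v2", list(one_c("A")), list(one_c("C"))),
    reaction("v3", list(one_c("B")), list(one_c("D"))),
    reaction("v4", list(one_c("C")), list(one_c("D"))),
    reaction("out", list(one_c("D")), list(one_c("Out"))))
  make_simple(rxns, mets,
              net_bounds = tibble::tibble(flux = vapply(rxns, `[[`, "", "id"),
                                          lo = 0, hi = 100),
              fixed = if (fixed_uptake) tibble::tibble(flux = "upt", value = 100))
}

test_that("free-flux count is n - rank(S) plus one exchange per bidirectional step", {
  m <- diamond()
  S <- build_stoichiometry(m)
  expect_equal(qr(S)$rank, 4)
  basis <- free_flux_basis(m)
  expect_length(basis$free_net, 6 - 4)
  expect_length(basis$free_xch, 0)

  # linear chain: 1 free net flux
  ch <- get_fixture("chain")
  expect_length(free_flux_basis(ch$model)$free_net, 1)

  # one bidirectional step adds one exchange coordinate
  br <- fixture_setup("branch")
  expect_length(br$basis$free_net, 2)
  expect_equal(br$basis$free_xch, "cleave2")
})

test_that("a model without balanced pools leaves every flux free", {
  mets <- tibble::tibble(id = c("A", "B"), n_carbons = 1,
                         role = c("input", "output"))
  rxns <- list(reaction("v1", list(one_c("A")), list(one_c("B"))),
               reaction("v2", list(one_c("A")), list(one_c("B"))))
  m <- make_simple(rxns, mets,
                   net_bounds = tibble::tibble(flux = c("v1", "v2"), lo = 0, hi = 10))
  S <- build_stoichiometry(m)
  expect_equal(dim(S), c(0L, 2L))
  expect_length(free_flux_basis(m)$free_net, 2)
})

test_that("the affine map reproduces admissible flux vectors (S v = 0)", {
  for (name in c("branch", "clavam")) {
    st <- fixture_setup(name)
    S <- build_stoichiometry(st$model)
    samples <- hit_and_run(st$poly, 1000, seed = 11, burn_in = 200, thinning = 3)
    for (i in seq_len(nrow(samples))) {
      v <- flux_state(st$basis, samples[i, ])
      expect_lt(max(abs(S %*% v$net)), 1e-9)
      expect_true(all(v$xch >= 0))
      expect_true(all(v$fwd >= -1e-12) && all(v$bwd >= -1e-12))
    }
  }
})

test_that("fixed rates inconsistent with the stoichiometry are rejected", {
  mets <- tibble::tibble(id = c("A", "B", "C"), n_carbons = 1,
                         role = c("input", "balanced", "output"))
  rxns <- list(reaction("v1", list(one_c("A")), list(one_c("B"))),
               reaction("v2", list(one_c("B")), list(one_c("C"))))
  m <- make_simple(rxns, mets,
                   fixed = tibble::tibble(flux = c("v1", "v2"), value = c(100, 50)))
  expect_error(free_flux_basis(m), class = "fluxred_infeasible")
})

test_that("the diamond with fixed uptake reduces to the unit split interval", {
  m <- diamond(fixed_uptake = TRUE)
  basis <- free_flux_basis(m)
  expect_length(basis$free_net, 1)
  poly <- build_polytope(basis, m)
  expect_equal(ncol(poly$A), 1)
  ctr <- chebyshev_center(poly)
  expect_equal(unname(ctr$center), 50, tolerance = 1e-9)
  expect_equal(ctr$radius, 50, tolerance = 1e-9)
  # endpoints via brute-force over the 1-D chord
  lim <- fluxred:::chord_limits(poly$A, poly$b, ctr$center, 1)
  expect_equal(unname(ctr$center + lim), c(0, 100), tolerance = 1e-9)
})

test_that("contradictory bounds yield an infeasibility error", {
  mets <- tibble::tibble(id = c("A", "B", "C"), n_carbons = 1,
                         role = c("input", "balanced", "output"))
  rxns <- list(reaction("v1", list(one_c("A")), list(one_c("B"))),
               reaction("v2", list(one_c("B")), list(one_c("C"))))
  m <- make_simple(rxns, mets,
                   net_bounds = tibble::tibble(flux = c("v1", "v2"),
                                               lo = c(10, 0), hi = c(100, 5)))
  basis <- free_flux_basis(m)
  expect_error(build_polytope(basis, m), class = "fluxred_infeasible")
})

test_that("polytope membership agrees with direct evaluation of all constraints", {
  st <- fixture_setup("branch")
  samples <- hit_and_run(st$poly, 200, seed = 5, burn_in = 100, thinning = 2)
  direct <- apply(samples, 1, function(z)
    all(st$poly$A %*% z - st$poly$b <= 1e-9))
  expect_true(all(in_polytope(st$poly, samples) == direct))
  # points outside
  outside <- samples + 1e3
  expect_false(any(in_polytope(st$poly, outside)))
})

test_that("polytope CSV export writes the inequality system", {
  st <- fixture_setup("branch")
  path <- withr::local_tempfile(fileext = ".csv")
  write_polytope_csv(st$poly, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), nrow(st$poly$A))
  expect_equal(df$rhs, st$poly$b)
})
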