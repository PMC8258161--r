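test_that("pass-through chains report the substrate MID unchanged", {
  st <- fixture_setup("chain")
  v <- flux_state(st$basis, 50)
  y0 <- simulate_labeling(st$sys, v, mixture(S0 = c("12C" = 1)), st$catalog)
  expect_equal(y0$value, c(1, 0, 0))
  yU <- simulate_labeling(st$sys, v, mixture(S0 = c(U = 1)), st$catalog)
  expect_equal(yU$value, c(0, 0, 1))
  y5 <- simulate_labeling(st$sys, v, mixture(S0 = c(U = 0.5, "12C" = 0.5)), st$catalog)
  expect_equal(y5$value, c(0.5, 0, 0.5))
})

test_that("condensation EMUs convolve the two precursor units", {
  m <- condensation_model()
  cat <- condensation_catalog()
  sys <- emu_decompose(m)
  # the size-2 EMU of C must be fed by a convolution of two size-1 EMUs
  expect_equal(sys$levels, c(1L, 2L))
  basis <- free_flux_basis(m)
  v <- flux_state(basis, rep(10, length(basis$free_net)))
  y <- simulate_labeling(sys, v,
                         mixture(Ax = c(L = 0.5, U0 = 0.5), Bx = c(L = 1)), cat)
  expect_equal(y$value, c(0, 0.5, 0.5))  # conv of (0.5, 0.5) and (0, 1)
})

test_that("fragments on never-produced metabolites are flagged at decomposition", {
  mets <- tibble::tibble(id = c("A", "B", "Z"), n_carbons = 1,
                         role = c("input", "balanced", "balanced"))
  rxns <- list(reaction("v1", list(list(met = "A", atoms = "a")),
                        list(list(met = "B", atoms = "a"))),
               reaction("v2", list(list(met = "B", atoms = "a")),
                        list(list(met = "A", atoms = "a"))))
  m <- network_model(mets, rxns, constraints = list(),
                     measurements = list(groups = tibble::tibble(
                       id = "gz", metabolite = "Z", positions = list(1L),
                       shifts = list(0:1))))
  expect_error(emu_decompose(m), class = "fluxred_unreachable")
})

test_that("the affine GC-MS error model evaluates exactly", {
  expect_equal(error_sigma(0), 6.655e-3)
  expect_equal(error_sigma(1), 4.7855e-2)
  expect_equal(error_sigma(0.5), 2.7255e-2)
})

test_that("measurement variances combine labeling and rate errors", {
  st <- fixture_setup("branch")
  v <- flux_state(st$basis, st$poly$center)
  y <- simulate_labeling(st$sys, v, mixture(st$fx$facts$informative_mixture),
                         st$catalog)
  vars <- measurement_variances(y, st$model)
  expect_length(vars, nrow(y))
  expect_true(all(vars > 0))
  ms <- y$type == "ms"
  expect_equal(vars[ms], error_sigma(y$value[ms])^2)
  expect_equal(unname(vars[!ms]), 2^2)  # upt_b rate sd
})

test_that("simulated fragment MIDs are normalized for random fluxes and mixtures", {
  withr::local_seed(31)
  for (name in c("branch", "clavam")) {
    st <- fixture_setup(name)
    samples <- hit_and_run(st$poly, 3, seed = 17, burn_in = 200)
    for (i in seq_len(nrow(samples))) {
      v <- flux_state(st$basis, samples[i, ])
      y <- simulate_labeling(st$sys, v, random_mixture(st$catalog), st$catalog)
      ms <- y[y$type == "ms", ]
      sums <- tapply(ms$value, ms$group, sum)
      expect_true(all(abs(sums - 1) < 1e-9), info = name)
      expect_true(all(ms$value > -1e-12 & ms$value < 1 + 1e-12), info = name)
    }
  }
})

test_that("EMU and cumomer simulations agree on a condensation toy", {
  m <- condensation_model(); cat <- condensation_catalog()
  sys <- emu_decompose(m)
  basis <- free_flux_basis(m)
  withr::local_seed(8)
  for (i in 1:3) {
    v <- flux_state(basis, runif(length(basis$free_net), 5, 50))
    mx <- random_mixture(cat)
    y1 <- simulate_labeling(sys, v, mx, cat)
    y2 <- cumomer_simulate(m, v, mx, cat)
    expect_lt(max(abs(y1$value - y2$value)), 1e-10)
  }
})

test_that("labeling is invariant under global flux scaling", {
  st <- fixture_setup("branch")
  mx <- mixture(st$fx$facts$informative_mixture)
  z <- st$poly$center
  # scaling every net and exchange flux leaves steady-state labeling unchanged;
  # the normalized uptake is fixed, so compare two hand-built flux states
  v1 <- flux_state(st$basis, z)
  v2 <- v1
  for (f in c("net", "fwd", "bwd")) v2[[f]] <- 3 * v2[[f]]
  v2$xch <- 3 * v2$xch
  y1 <- simulate_labeling(st$sys, v1, mx, st$catalog)
  y2 <- simulate_labeling(st$sys, v2, mx, st$catalog)
  ms <- y1$type == "ms"
  expect_equal(y1$value[ms], y2$value[ms], tolerance = 1e-12)
})

test_that("labeling is affine in one substrate's fractions (no self-condensation)", {
  m <- condensation_model(); cat <- condensation_catalog()
  sys <- emu_decompose(m)
  basis <- free_flux_basis(m)
  v <- flux_state(basis, rep(20, length(basis$free_net)))
  mxB <- c(L = 0.3, U0 = 0.7)
  mx1 <- mixture(Ax = c(L = 1, U0 = 0), Bx = mxB)
  mx2 <- mixture(Ax = c(L = 0, U0 = 1), Bx = mxB)
  a <- 0.37
  mxm <- mixture(Ax = c(L = a, U0 = 1 - a), Bx = mxB)
  y1 <- simulate_labeling(sys, v, mx1, cat)$value
  y2 <- simulate_labeling(sys, v, mx2, cat)$value
  ym <- simulate_labeling(sys, v, mxm, cat)$value
  expect_equal(ym, a * y1 + (1 - a) * y2, tolerance = 1e-12)
})

test_that("singular labeling systems name the dead pool", {
  st <- fixture_setup("branch")
  z <- st$poly$center
  z[] <- c(0, 100, 0)  # cleave2 = 0: F has no throughput
  err <- tryCatch(simulate_labeling(st$sys, flux_state(st$basis, z),
                                    mixture(st$fx$facts$informative_mixture),
                                    st$catalog),
                  fluxred_singular = function(e) conditionMessage(e))
  expect_match(err, "F")
})
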