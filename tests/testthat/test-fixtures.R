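test_that("chain manifest facts hold", {
  st <- fixture_setup("chain")
  expect_length(st$basis$free_net, st$fx$facts$free_net)
  expect_length(st$basis$free_xch, st$fx$facts$free_xch)
  withr::local_seed(6)
  for (i in 1:3) {
    w <- runif(2); w <- w / sum(w)
    mx <- mixture(S0 = setNames(w, c("U", "12C")))
    v <- flux_state(st$basis, runif(1, 10, 90))
    y <- simulate_labeling(st$sys, v, mx, st$catalog)
    # terminal MID equals the substrate MID (pure pass-through)
    dist <- fluxred:::substrate_isotopomer_distribution(st$catalog, "S0", mx$S0)
    expect_equal(y$value, fluxred:::input_emu_mid(dist, 1:2), tolerance = 1e-12)
  }
})

test_that("branch-cycle manifest mixtures behave as advertised", {
  st <- fixture_setup("branch")
  v <- flux_state(st$basis, st$poly$center)
  for (case in list(list(mx = st$fx$facts$informative_mixture,
                         n = st$fx$facts$max_nact_informative),
                    list(mx = st$fx$facts$degenerate_mixture,
                         n = st$fx$facts$max_nact_degenerate))) {
    J <- jacobian(st$sys, st$basis, v, mixture(case$mx), st$catalog)
    FIM <- fisher_information(J, measurement_variances(attr(J, "y"), st$model))
    expect_equal(select_active_fluxes(FIM, "max")$n_act, case$n)
  }
  # unlabeled feed: labeling rows of the Jacobian vanish entirely
  J0 <- jacobian(st$sys, st$basis, v, mixture(st$fx$facts$degenerate_mixture),
                 st$catalog)
  lab <- grep("^rate", rownames(J0), invert = TRUE)
  expect_lt(max(abs(J0[lab, ])), 1e-12)
})

test_that("the clavam analog matches the study's combinatorial setting", {
  st <- fixture_setup("clavam")
  g <- enumerate_mixtures(st$catalog, step = 0.1)
  expect_equal(unname(g$n_per_substrate), c(286L, 66L))
  expect_equal(g$n_total, st$fx$facts$grid_total_10pct)
  expect_equal(g$n_total, 286L * 66L)
  # printed price anchors
  sp <- st$catalog$species
  expect_equal(sp$price[sp$label == "12C" & sp$substrate == "GLYCx"], 0.36)
  expect_equal(sp$price[sp$label == "U-13C5"], 3449)
  # chemostat-derived substrate amounts
  am <- required_amounts(st$catalog)
  expect_equal(unname(am[c("GLYCx", "ARGx")]), c(25, 0.2125))
})

test_that("a small scan on the clavam analog completes and aggregates", {
  st <- fixture_setup("clavam")
  s <- hit_and_run(st$poly, 3, seed = 19, burn_in = 300)
  attr(s, "basis") <- st$basis
  ref <- mixture(st$fx$facts$reference_mixture)
  mixtures <- list(
    ref,
    mixture(GLYCx = c("2-13C1" = 1), ARGx = c("U-13C5" = 1)),
    mixture(GLYCx = c("12C" = 1), ARGx = c("12C" = 1)))
  pool <- run_red(st$model, st$catalog, mixtures, s, reference = ref)
  agg <- aggregate_pool(pool)
  expect_gt(nrow(agg$metrics), 0)
  expect_true(all(agg$metrics$coverage >= 0 & agg$metrics$coverage <= 100))
  # coverage monotone in n_act here too
  for (mi in unique(agg$metrics$mixture)) {
    cov <- agg$metrics$coverage[agg$metrics$mixture == mi]
    expect_true(all(diff(cov) <= 1e-12))
  }
  # costs: fully unlabeled is the cheapest option
  costs <- agg$metrics$cost[!duplicated(agg$metrics$mixture)]
  expect_lt(costs[3], costs[1])
  expect_lt(costs[3], costs[2])
  # the all-unlabeled mixture never reaches the labeled designs' n_act
  mx3 <- agg$metrics[agg$metrics$mixture == 3, ]
  mx2 <- agg$metrics[agg$metrics$mixture == 2, ]
  top <- max(agg$metrics$n_act[agg$metrics$coverage > 0 & agg$metrics$mixture == 2])
  expect_equal(mx3$coverage[mx3$n_act == top], 0)
})

test_that("fixture generators are deterministic", {
  expect_equal(make_chain(3, 2), make_chain(3, 2))
  expect_equal(make_branch_cycle(), make_branch_cycle())
  expect_equal(make_clavam_analog(), make_clavam_analog())
})
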