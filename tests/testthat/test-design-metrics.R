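random_spd <- function(p, cond = 10) {
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  d <- exp(seq(0, log(cond), length.out = p))
  Q %*% diag(d, p) %*% t(Q)
}

test_that("the Fisher information is J' Sigma^-1 J", {
  expect_equal(fisher_information(diag(2), rep(1, 2)), diag(2))
  expect_equal(fisher_information(matrix(2), 4), matrix(1))
  J <- cbind(c(1, 2), 0)  # second flux structurally non-identifiable
  FIM <- fisher_information(J, c(1, 1))
  expect_equal(FIM[, 2], c(0, 0))
  expect_equal(FIM[2, ], c(0, 0))
  expect_error(fisher_information(diag(2), rep(1, 3)), class = "fluxred_config_error")
})

test_that("FIMs are symmetric positive semidefinite on fixture evaluations", {
  st <- fixture_setup("branch")
  withr::local_seed(3)
  samples <- hit_and_run(st$poly, 3, seed = 29, burn_in = 200)
  for (i in seq_len(nrow(samples))) {
    v <- flux_state(st$basis, samples[i, ])
    J <- jacobian(st$sys, st$basis, v, random_mixture(st$catalog), st$catalog)
    FIM <- fisher_information(J, measurement_variances(attr(J, "y"), st$model))
    expect_lt(max(abs(FIM - t(FIM))), 1e-10)
    expect_gt(min(eigen(FIM, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("active-flux selection handles the canonical cases", {
  afs <- select_active_fluxes(diag(c(1e6, 1e-16)))
  expect_equal(afs$n_act, 1L)
  expect_equal(afs$active, 1L)

  afs <- select_active_fluxes(diag(4))
  expect_equal(afs$n_act, 4L)
  expect_length(afs$fixed, 0)

  afs <- select_active_fluxes(matrix(0, 3, 3))
  expect_true(afs$degenerate)
  expect_equal(afs$n_act, 0L)
})

test_that("covariance is the inverse of the restricted FIM", {
  cv <- covariance(diag(c(4, 25)))
  expect_equal(cv, diag(c(0.25, 0.04)))
  expect_equal(sqrt(diag(cv)), c(0.5, 0.2))
  withr::local_seed(77)
  FIM <- random_spd(6, cond = 1e4)
  expect_lt(max(abs(covariance(FIM) %*% FIM - diag(6))), 1e-8)
  expect_error(covariance(matrix(c(1, 2, 2, 1), 2)), class = "fluxred_singular")
})

test_that("the reference-normalized D-criterion follows the determinant algebra", {
  expect_equal(d_criterion(diag(2), diag(2), 2), 1)
  expect_equal(d_criterion(diag(2), diag(4, 2), 2), 2)
  withr::local_seed(5)
  for (p in c(2, 4)) {
    cr <- random_spd(p)
    expect_equal(d_criterion(4 * cr, cr, p), 0.5)
    expect_equal(d_criterion(cr, cr, p), 1)
  }
  # alternative exponent convention
  expect_equal(d_criterion(diag(2), diag(4, 2), 2, exponent = 1 / 2), 4)
  expect_error(d_criterion(matrix(c(1, 2, 2, 1), 2), diag(2), 2),
               class = "fluxred_singular")
})

test_that("shrinking all sigmas by alpha scales the criterion by 1/alpha", {
  withr::local_seed(21)
  J <- matrix(rnorm(30), 10, 3)
  vars <- runif(10, 0.5, 2)^2
  cov_ref <- covariance(fisher_information(J, vars))
  alpha <- 0.2
  cov_scaled <- covariance(fisher_information(J, alpha^2 * vars))
  expect_equal(d_criterion(cov_scaled, cov_ref, 3),
               d_criterion(cov_ref, cov_ref, 3) / alpha)
})

test_that("returned maximal active sets cannot be enlarged", {
  withr::local_seed(55)
  ctl <- identifiability_control(sv_rel = 1e-6, cond_max = 1e4)
  for (trial in 1:20) {
    p <- sample(3:6, 1)
    # mix well- and ill-conditioned blocks
    FIM <- random_spd(p, cond = 10^sample(2:8, 1))
    afs <- select_active_fluxes(FIM, "max", ctl, method = "exhaustive")
    if (afs$degenerate || afs$n_act == p) next
    norm2 <- svd(FIM, nu = 0, nv = 0)$d[1]
    for (extra in afs$fixed) {
      grown <- sort(c(afs$active, extra))
      expect_false(fluxred:::admissible_subset(FIM, grown,
                                               ctl$sv_rel * norm2, ctl$cond_max))
    }
  }
})

test_that("greedy removal matches exhaustive enumeration or flags itself", {
  withr::local_seed(99)
  ctl <- identifiability_control(sv_rel = 1e-4, cond_max = 1e6)
  n_checked <- 0
  for (trial in 1:40) {
    p <- sample(3:7, 1)
    FIM <- random_spd(p, cond = 10^sample(1:8, 1))
    greedy <- select_active_fluxes(FIM, "max", ctl, method = "greedy",
                                   verify = TRUE)
    exact <- select_active_fluxes(FIM, "max", ctl, method = "exhaustive")
    expect_equal(greedy$degenerate, exact$degenerate)
    if (exact$degenerate) next
    expect_equal(greedy$n_act, exact$n_act)
    matched <- isTRUE(all.equal(greedy$det_cov, exact$det_cov, tolerance = 1e-6)) ||
      greedy$det_cov <= exact$det_cov * (1 + 1e-9)
    expect_true(matched || greedy$suboptimal)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 10)
})

test_that("chemostat amounts and tracer costs reproduce hand arithmetic", {
  am <- required_amounts(concentrations = c(GLYC = 20, ARG = 0.17),
                         dilution_rate = 0.03, working_volume = 0.25,
                         residence_times = 5)
  expect_equal(unname(am["GLYC"]), 25)       # 20 g/L * 0.03/h * 0.25 L * (5/0.03) h
  expect_equal(unname(am["ARG"]), 0.2125)

  cat1 <- tracer_catalog(list(substrates = list(list(id = "S", species = list(
    list(label = "U", pattern = c(1, 1), purity = 99, price = 3449),
    list(label = "12C", pattern = c(0, 0), purity = 100, price = 0.36))))))
  expect_equal(tracer_cost(cat1, mixture(S = c(U = 1)), amounts = c(S = 1)), 3449)
  expect_equal(tracer_cost(cat1, mixture(S = c("12C" = 1)), amounts = c(S = 25)), 9)
  expect_equal(tracer_cost(cat1, mixture(S = c(U = 1)), amounts = c(S = 0)), 0)
  expect_error(tracer_cost(cat1, mixture(S = c(nope = 1)), amounts = c(S = 1)),
               class = "fluxred_tracer_error")
})
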