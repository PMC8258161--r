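unit_square <- function() {
  polytope(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), c(1, 0, 1, 0),
           labels = c("x", "y"))
}

test_that("Chebyshev centers match closed forms", {
  interval <- polytope(rbind(1, -1), c(100, 0), labels = "z")
  expect_equal(unname(chebyshev_center(interval)$center), 50)

  sq <- chebyshev_center(unit_square())
  expect_equal(unname(sq$center), c(0.5, 0.5))
  expect_equal(sq$radius, 0.5)

  # right triangle x,y >= 0, x + y <= 1: center is the incenter (r, r),
  # r = (a + b - c)/2 = (2 - sqrt(2))/2
  tri <- polytope(rbind(c(-1, 0), c(0, -1), c(1, 1)), c(0, 0, 1))
  r <- (2 - sqrt(2)) / 2
  ct <- chebyshev_center(tri)
  expect_equal(unname(ct$center), c(r, r), tolerance = 1e-9)
  expect_equal(ct$radius, r, tolerance = 1e-9)
})

test_that("infeasible systems are reported", {
  bad <- polytope(rbind(1, -1), c(5, -10))  # x <= 5 and x >= 10
  expect_error(chebyshev_center(bad), class = "fluxred_infeasible")
})

test_that("hit-and-run is seed-deterministic and feasible", {
  sq <- unit_square()
  s1 <- hit_and_run(sq, 500, seed = 7)
  s2 <- hit_and_run(sq, 500, seed = 7)
  s3 <- hit_and_run(sq, 500, seed = 8)
  expect_identical(unclass(s1)[, ], unclass(s2)[, ])
  expect_false(isTRUE(all.equal(unclass(s1)[, ], unclass(s3)[, ])))
  expect_true(all(in_polytope(sq, s1)))
  expect_equal(nrow(s1), 500)
})

test_that("the sampler does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(hit_and_run(unit_square(), 10, seed = 1))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("samples on boxes and intervals match the uniform law", {
  sq <- unit_square()
  s <- hit_and_run(sq, 5000, seed = 2)
  expect_true(all(abs(colMeans(s) - 0.5) < 0.03))
  expect_true(all(abs(apply(s, 2, var) - 1 / 12) < 0.015))

  interval <- polytope(rbind(1, -1), c(1, 0))
  si <- hit_and_run(interval, 10000, seed = 3, thinning = 2)
  ks <- suppressWarnings(stats::ks.test(as.numeric(si[, 1]), "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(10000))  # 1% critical value
})

test_that("a single draw is a feasible point", {
  s <- hit_and_run(unit_square(), 1, seed = 4)
  expect_equal(nrow(s), 1)
  expect_true(in_polytope(unit_square(), s[1, ]))
})

test_that("n_samples must be positive", {
  expect_error(hit_and_run(unit_square(), 0, seed = 1),
               class = "fluxred_config_error")
})

test_that("center of mass is the coordinate-wise mean, kept feasible", {
  interval <- polytope(rbind(1, -1), c(1, 0))
  s <- structure(matrix(c(0.2, 0.8), 2, 1), class = c("flux_sample_set", "matrix", "array"),
                 polytope = interval)
  expect_equal(unname(center_of_mass(s)), 0.5)
  one <- structure(matrix(0.3, 1, 1), class = c("flux_sample_set", "matrix", "array"),
                   polytope = interval)
  expect_equal(unname(center_of_mass(one)), 0.3)

  sq <- hit_and_run(unit_square(), 5000, seed = 5)
  expect_true(all(abs(center_of_mass(sq) - 0.5) < 0.03))
})

test_that("model-level sampling returns feasible flux maps with metadata", {
  st <- fixture_setup("branch")
  s <- sample_flux_space(st$model, n_samples = 50, seed = 9, burn_in = 200)
  expect_equal(nrow(s), 50)
  expect_true(all(in_polytope(attr(s, "polytope"), s)))
  expect_s3_class(attr(s, "basis"), "free_flux_basis")
  td <- tidy(s)
  expect_equal(names(td)[1], "sample")
  expect_equal(nrow(td), 50)
})
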