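# Smooth random functions: construction law, exact calculus, statistics.

test_that("truncation index and coefficient layout follow the construction", {
  z <- sample_srf(L = 8, lambda_w = 2, seed = 1)
  expect_identical(z$r, 4)
  expect_length(z$a, 5L)        # a_0 .. a_4
  expect_length(z$b, 4L)        # b_1 .. b_4  -> 9 coefficients in total

  expect_identical(sample_srf(8, 0.1, seed = 1)$r, 80)

  z0 <- sample_srf(L = 1, lambda_w = 2, alpha = 3, seed = 7)
  expect_identical(z0$r, 0)
  tt <- c(-2, 0, 0.4, 11)
  expect_equal(srf_eval(z0, tt), rep(3 * z0$a[1L], 4L))  # constant alpha*a0
})

test_that("seeding is reproducible and leaves the caller's RNG alone", {
  set.seed(999)
  before <- rnorm(1)
  set.seed(999)
  z1 <- sample_srf(8, 2, seed = 5)
  z2 <- sample_srf(8, 2, seed = 5)
  z3 <- sample_srf(8, 2, seed = 6)
  after <- rnorm(1)
  expect_identical(z1$a, z2$a)
  expect_identical(z1$b, z2$b)
  expect_false(isTRUE(all.equal(z1$a, z3$a)))
  expect_identical(before, after)   # sampler restored the RNG state
})

test_that("invalid construction inputs are rejected with explanation", {
  expect_error(sample_srf(-1, 2), "positive")
  expect_error(sample_srf(8, 0), "positive")
  expect_error(tube_exceedance_bound(0, 1, 1, 1), "positive")
})

test_that("evaluation is L-periodic and derivatives follow cosine calculus", {
  for (seed in 1:100) {
    z <- sample_srf(8, 2, seed = seed)
    t <- with_seed(seed + 1000L, runif(10, -5, 5))
    expect_near(srf_eval(z, t + 8), srf_eval(z, t), 1e-9)
  }

  # hand-set coefficients: zeta(t) = cos(2 pi t / 8)
  z <- sample_srf(8, 2, seed = 1)
  z$a <- c(0, 1, 0, 0, 0)
  z$b <- rep(0, 4)
  z$alpha <- 1
  expect_equal(srf_eval(z, 0, 0L), 1)
  expect_equal(srf_eval(z, 0, 1L), 0)
  expect_equal(srf_eval(z, 0, 2L), -(2 * pi / 8)^2)
})

test_that("derivative transform maps (a, b) to (omega b, -omega a)", {
  z <- sample_srf(8, 2, seed = 11)
  d <- srf_derivative(z)
  expect_equal(d$a, c(0, z$omega * z$b))
  expect_equal(d$b, -z$omega * z$a[-1L])

  # applying the transform twice == one order-2 evaluation, coefficient-wise
  dd <- srf_derivative(srf_derivative(z))
  d2 <- srf_derivative(z, order = 2L)
  expect_near(dd$a, d2$a, 1e-12)
  expect_near(dd$b, d2$b, 1e-12)

  zz <- z; zz$a[] <- 0; zz$b[] <- 0
  dz <- srf_derivative(zz)
  expect_true(all(dz$a == 0) && all(dz$b == 0))

  # r = 0: any derivative of the constant is zero
  z0 <- sample_srf(1, 2, seed = 2)
  expect_equal(srf_eval(z0, 0.3, 3L), 0)
})

test_that("finite differences converge to the exact derivative at O(h^2)", {
  z <- sample_srf(8, 2, seed = 3)
  t <- 1.234
  err <- vapply(c(1e-2, 5e-3, 2.5e-3), function(h) {
    abs((srf_eval(z, t + h) - srf_eval(z, t - h)) / (2 * h) -
          srf_eval(z, t, 1L))
  }, numeric(1L))
  expect_true(all(diff(log(err)) < log(0.3)))  # roughly quarters per halving
})

test_that("closed-form antiderivative matches adaptive quadrature", {
  z <- sample_srf(8, 2, seed = 17, alpha = 1.3)
  grid <- c(0.5, 1.7, 3.1, 7.9)
  exact <- srf_integral(z, grid)
  quad <- vapply(grid, function(tt) {
    stats::integrate(function(s) srf_eval(z, s), 0, tt,
                     rel.tol = 1e-12)$value
  }, numeric(1L))
  expect_near(exact, quad, 1e-8)

  zz <- z; zz$a[] <- 0; zz$b[] <- 0
  expect_equal(srf_integral(zz, grid), rep(0, 4L))
  expect_error(srf_integral(z, c(1, 0.5)), "increasing")
})

test_that("pointwise second moments match the coefficient law", {
  n <- 5000L
  mom <- srf_moments(8, 2)
  expect_equal(mom$sigma2, 5 / 9)     # (r+1)/(2r+1) with r = 4
  t0 <- 1.3
  vals <- vapply(seq_len(n), function(i) {
    srf_eval(sample_srf(8, 2, seed = i), t0)
  }, numeric(1L))
  dvals <- vapply(seq_len(n), function(i) {
    srf_eval(sample_srf(8, 2, seed = i), t0, 1L)
  }, numeric(1L))
  # E[zeta^2] within 3 SE of (r+1)/(2r+1)
  se <- stats::sd(vals^2) / sqrt(n)
  expect_lt(abs(mean(vals^2) - mom$sigma2), 3 * se)
  # E[zetadot^2] within 3 SE of alpha^2 sum omega_j^2 / (2r+1)
  se_d <- stats::sd(dvals^2) / sqrt(n)
  expect_lt(abs(mean(dvals^2) - mom$lambda2sq), 3 * se_d)
})

test_that("big-mode integral paths have Brownian variance", {
  n <- 2000L
  v <- vapply(seq_len(n), function(i) {
    z <- sample_srf(8, 0.01, mode = "big", seed = i)
    srf_integral(z, c(0.5, 1))
  }, numeric(2L))
  expect_lt(abs(stats::var(v[1L, ]) - 0.5), 0.05)  # Var[int_0^0.5] ~ 0.5
  expect_lt(abs(stats::var(v[2L, ]) - 1.0), 0.10)  # Var[int_0^1]   ~ 1
})

test_that("tube bound behaves like a Gaussian tail bound", {
  mom <- srf_moments(8, 2)
  u <- seq(mom$sigma, 5 * mom$sigma, length.out = 25)
  bnd <- tube_exceedance_bound(mom$sigma, mom$lambda2, u, T = 8,
                               clip = FALSE)
  expect_true(all(diff(bnd) < 0))                        # decreasing in u
  expect_equal(tube_exceedance_bound(mom$sigma, mom$lambda2, Inf, 8), 0)
  expect_true(all(tube_exceedance_bound(mom$sigma, mom$lambda2, u, 8) <= 1))
})
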