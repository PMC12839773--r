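# Tracking synthesis, closed-loop simulation, discrepancy metrics.

test_that("pole-placement gains expand (s + p)^kappa", {
  expect_equal(unname(hurwitz_gains(2, 2)), c(4, 4))
  expect_equal(unname(hurwitz_gains(1, 3.5)), 3.5)
  expect_equal(unname(hurwitz_gains(3, 1)), c(1, 3, 3))
  expect_error(hurwitz_gains(2, -1), "positive")
  expect_error(assert_hurwitz(c(-1, 2)), "Hurwitz")
})

test_that("the elementary tracking law reduces correctly", {
  # on-reference jets: v equals the reference top derivative
  expect_equal(tracking_v(c(1, 2), c(1, 2, 7), c(4, 4)), 7)
  # kappa = 2, e = 1, edot = 0, lambda = (4, 4), ref'' = 0  ->  v = -4
  expect_equal(tracking_v(c(1, 0), c(0, 0, 0), c(4, 4)), -4)
  expect_error(tracking_v(c(1, 0), c(0, 0), c(4, 4)), "mismatch")
})

test_that("noise-free closed-loop error follows the target linear ODE", {
  se <- fix_simple(stochastic = FALSE)
  cert <- fix_simple_cert(se)
  ref <- reference_constant(c(y = 0.5))
  p <- 2
  ctrl <- tracking_controller(se, cert, ref, gains = p, mode = "mean")
  x0 <- c(x1 = 1.5, x2 = 0.3)   # offset start
  dt <- 1e-3
  tr <- simulate_closed_loop(se, ctrl, list(), x0, c(0, 4), dt,
                             reference = ref)
  # companion-form solution of e'' + 4 e' + 4 e = 0 via the matrix exponential
  lam <- hurwitz_gains(2, p)
  A <- rbind(c(0, 1), -lam)
  e0 <- c(x0[["x1"]] - 0.5, x0[["x2"]])
  exact <- vapply(tr$t, function(tt) {
    (as.matrix(Matrix::expm(A * tt)) %*% e0)[1L]
  }, numeric(1L))
  expect_near(tr$eact_y, exact, 1e-6)

  # fitted decay rate recovers the designed pole within 10%; the rate is
  # measured on the repeated-pole eigenmode (edot0 = -p e0), where the
  # error norm is exactly exponential
  for (p in c(1, 2, 5)) {
    ctrl_p <- tracking_controller(se, cert, ref, gains = p, mode = "mean")
    x0_p <- c(x1 = 1.5, x2 = -p * 1.0)
    tr_p <- simulate_closed_loop(se, ctrl_p, list(), x0_p, c(0, 6 / p), dt,
                                 reference = ref)
    expect_lt(abs(fit_decay_rate(tr_p) - p) / p, 0.1)
  }
})

test_that("halving the step shrinks the terminal error like dt^4", {
  se <- fix_simple(stochastic = FALSE)
  cert <- fix_simple_cert(se)
  ref <- fix_step_ref()
  ctrl <- tracking_controller(se, cert, ref, gains = 2, mode = "mean")
  x0 <- c(x1 = 0.4, x2 = 0)
  term <- function(dt) {
    tr <- simulate_closed_loop(se, ctrl, list(), x0, c(0, 2), dt,
                               reference = ref)
    unlist(tr[nrow(tr), c("x1", "x2")])
  }
  ref_state <- term(5e-4)
  e1 <- max(abs(term(8e-3) - ref_state))
  e2 <- max(abs(term(4e-3) - ref_state))
  ratio <- e1 / e2
  expect_gt(ratio, 8)    # classical RK4: ratio ~ 16
  expect_lt(ratio, 40)
})

test_that("mean-mode residual error scales linearly in the noise amplitude", {
  # linear-response property, exercised where the fluctuation-to-action
  # coupling is O(1): the simple generic example (three noise channels)
  se <- fix_simple()
  cert <- fix_simple_cert(se)
  ref <- reference_constant(c(y = 0.5))
  ctrl <- tracking_controller(se, cert, ref, gains = 2, mode = "mean")
  steady_rms <- function(alpha) {
    signals <- lapply(stats::setNames(1:3, c("zx1", "zx2", "zy")),
                      function(i) {
                        sample_srf(8, 2, alpha = alpha, seed = 100L + i)
                      })
    tr <- simulate_closed_loop(se, ctrl, signals,
                               c(x1 = 0.5, x2 = 0), c(0, 12), 2e-3,
                               reference = ref)
    sw <- tr$t >= 4
    sqrt(mean(tr$eact_y[sw]^2))
  }
  rms <- vapply(c(1e-6, 1e-5, 1e-4), steady_rms, numeric(1L))
  r1 <- rms[2L] / rms[1L]
  r2 <- rms[3L] / rms[2L]
  expect_gt(r1, 5); expect_lt(r1, 20)
  expect_gt(r2, 5); expect_lt(r2, 20)
})

test_that("discrepancy metrics recover closed forms", {
  # hand-built trace: constant offset c over [0, T] with identity precision
  T <- 3; cc <- 0.4
  t <- seq(0, T, 0.01)
  tr <- tibble::tibble(t = t, eact_y = rep(cc, length(t)),
                       eobs_y = rep(0, length(t)))
  class(tr) <- c("flat_trace", class(tr))
  m <- discrepancy_metrics(tr)
  expect_equal(m$risk, T * cc^2 / 2, tolerance = 1e-12)
  expect_equal(m$ise_act, T * cc^2, tolerance = 1e-12)

  tr0 <- tibble::tibble(t = t, eact_y = rep(0, length(t)),
                        eobs_y = rep(0, length(t)))
  class(tr0) <- c("flat_trace", class(tr0))
  m0 <- discrepancy_metrics(tr0)
  expect_equal(m0$risk, 0)
  expect_equal(m0$max_eact, 0)

  expect_error(discrepancy_metrics(tr, Pi = matrix(-1)), "positive definite")
})

test_that("tracking risk < open-loop risk < zero-action risk when offset", {
  params <- oculomotor_params(alpha = 1e-5)
  model <- build_oculomotor(params)
  cert <- oculomotor_certificate(model)
  par <- functional_parametrisation(model, cert)
  ref <- oculomotor_reference("quatrefoil")
  signals <- oculomotor_signals(params, seed = 4)
  x_on <- oculomotor_state_on_reference(par, ref, 0, signals)
  x0 <- x_on + c(0.3, -0.2, 0, 0)
  # short horizon: with zero action the eye model is only locally stable
  # (the position equation is quadratic in X), so the comparison window
  # must precede its escape time
  span <- c(0, 0.3); dt <- 1e-3

  risk_of <- function(ctrl) {
    tr <- simulate_closed_loop(model, ctrl, signals, x0, span, dt,
                               reference = ref)
    discrepancy_metrics(tr)$risk
  }
  r_track <- risk_of(tracking_controller(model, cert, ref, gains = 2,
                                         mode = "oracle"))
  r_open <- risk_of(openloop_controller(par, ref, mode = "oracle"))
  r_zero <- risk_of(zero_controller(model$inputs))
  expect_lt(r_track, r_open)
  expect_lt(r_open, r_zero)
})
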