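# Input delay: delta-flatness, delayed observer, integral predictor,
# predictive tracking.

test_that("delta-flat parametrisation shifts only the action", {
  dm <- delayed_model(fix_simple(), tau = 0.3)
  dp <- delta_flat_parametrisation(dm)
  expect_equal(unname(dp$shifts[c("x1", "x2")]), c(0, 0))
  expect_equal(unname(dp$shifts["u"]), 0.3)          # u(t) lives at t + tau
  # shift algebra: residuals of the shifted substitution reduce to the
  # undelayed residuals, which vanish symbolically
  expect_true(verify_delta_flat(dm, dp)$all_zero)

  # tau = 0 reduces exactly to the undelayed parametrisation
  dp0 <- delta_flat_parametrisation(delayed_model(fix_simple(), 0))
  base <- functional_parametrisation(fix_simple(), fix_simple_cert())
  expect_identical(lapply(dp0$base$states, deparse1),
                   lapply(base$states, deparse1))
  expect_true(all(dp0$shifts == 0))
})

test_that("the delayed observer predicts the advanced state", {
  lin <- fix_linear(a = -0.7)
  dm <- delayed_model(lin, tau = 0.5)

  # exactly consistent history: the error stays on the invariant manifold
  obs0 <- delayed_observer_simulate(
    dm, K_obs = 0.8, u_fun = function(t) 0, x0 = c(x = 1),
    xhat_init = function(t) c(x = exp(-0.7 * (t + 0.5))),
    t_span = c(0, 2), dt = 2e-4)
  expect_lt(max(abs(obs0$perr_x)), 1e-9)

  # K = 0 with identical initialisation: open-loop copy, error identically 0
  obsK0 <- delayed_observer_simulate(
    dm, K_obs = 0, u_fun = function(t) 0, x0 = c(x = 1),
    xhat_init = function(t) c(x = exp(-0.7 * (t + 0.5))),
    t_span = c(0, 2), dt = 1e-3)
  expect_lt(max(abs(obsK0$perr_x)), 1e-12)

  # stabilising gain: the prediction error shrinks by >= 1e3
  obs <- delayed_observer_simulate(
    dm, K_obs = 1.5, u_fun = function(t) 0.3 * sin(t), x0 = c(x = 1),
    xhat_init = function(t) c(x = 0), t_span = c(0, 40), dt = 2e-3)
  expect_lt(abs(obs$perr_x[nrow(obs)]), 1e-3 * abs(obs$perr_x[1L]))
})

test_that("the integral predictor solves the implicit relation", {
  lin <- fix_linear(a = -0.7)
  tau <- 0.5

  # tau = 0: empty integral, the predictor returns x(t)
  p0 <- integral_predictor(delayed_model(lin, 0), c(x = 2),
                           function(t) 0)
  expect_identical(unname(p0$xpred), 2)

  # linear flow oracle: prediction = e^(a tau) x(t) at step tau/200
  p <- integral_predictor(delayed_model(lin, tau), c(x = 2),
                          function(t) 0, n_grid = 200L)
  expect_lt(abs(p$xpred - 2 * exp(-0.7 * tau)), 1e-6)
  expect_lte(p$residual, 1e-10)

  # quadrature refinement: error drops at order >= 2
  errs <- vapply(c(25L, 50L, 100L), function(ng) {
    abs(integral_predictor(delayed_model(lin, tau), c(x = 2),
                           function(t) 0, n_grid = ng)$xpred -
          2 * exp(-0.7 * tau))
  }, numeric(1L))
  expect_true(all(errs[-1L] / errs[-3L] < 0.3))  # ~ quarters per doubling

  # non-convergence is reported, not silently truncated
  expect_error(
    integral_predictor(delayed_model(fix_linear(a = 40), tau = 1),
                       c(x = 1), function(t) 0, cap = 3L),
    "did not converge")
})

test_that("predictive tracking cancels the delay", {
  se <- fix_simple(stochastic = FALSE)
  dse <- delayed_model(se, tau = 0.2)
  ref <- fix_step_ref()
  for (pk in c("integral", "observer")) {
    tr <- simulate_delayed_tracking(dse, ref, gains = 2, predictor = pk,
                                    x0 = c(x1 = 0, x2 = 0),
                                    t_span = c(0, 10), dt = 2e-3)
    expect_lt(abs(tr$eact_y[nrow(tr)]), 1e-4,
              label = paste("terminal error,", pk, "predictor"))
  }
})

test_that("the predictive loop recovers the undelayed decay rate", {
  se <- fix_simple(stochastic = FALSE)
  ref <- reference_constant(c(y = 0))
  p <- 2
  x0 <- c(x1 = 1, x2 = 0)
  # undelayed benchmark
  cert <- fix_simple_cert(se)
  ctrl <- tracking_controller(se, cert, ref, gains = p, mode = "mean")
  tr0 <- simulate_closed_loop(se, ctrl, list(), x0, c(0, 3), 1e-3,
                              reference = ref)
  rate0 <- fit_decay_rate(tr0)
  # delayed loop with the integral predictor, tau small next to 1/p
  tr1 <- simulate_delayed_tracking(delayed_model(se, 0.1), ref, gains = p,
                                   predictor = "integral", x0 = x0,
                                   t_span = c(0, 3), dt = 1e-3)
  rate1 <- fit_decay_rate(tr1)
  expect_lt(abs(rate1 - rate0) / rate0, 0.2)
})
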