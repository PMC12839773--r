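# Oculomotor demonstration: model structure, references, open loop,
# end-to-end experiments.

test_that("the mean reduction recovers the deterministic eye model", {
  params <- oculomotor_params()
  m <- mean_model(build_oculomotor(params))
  # torque channels: vpsi' = upsi / (2 Ie), vphi' = uphi / Ie
  v <- list(xX = 0, xY = 0, vpsi = 0, vphi = 0, upsi = 2 * params$Ie,
            uphi = params$Ie)
  expect_equal(eval_expr(m$rhs$vpsi, v), 1)
  expect_equal(eval_expr(m$rhs$vphi, v), 1)
  # at X = X0 the position equation reduces to Xdot = d * vpsi
  v2 <- list(xX = params$X0, xY = 0, vpsi = 0.3, vphi = 0, upsi = 0, uphi = 0)
  expect_equal(eval_expr(m$rhs$xX, v2), params$d * 0.3)
})

test_that("angle-form and screen-form models agree through Listing's law", {
  params <- oculomotor_params()
  cart <- mean_model(build_oculomotor(params))
  ang <- build_oculomotor_angles(params)
  psi0 <- 0.04; phi0 <- -0.03; vpsi0 <- 0.01; vphi0 <- 0.02
  u_fun <- function(t) c(upsi = 3e-7 * sin(2 * t), uphi = 2e-7 * cos(t))
  x0_ang <- c(psi = psi0, phi = phi0, vpsi = vpsi0, vphi = vphi0)
  x0_cart <- c(xX = params$X0 + params$d * tan(psi0),
               xY = params$Y0 + params$d * tan(phi0),
               vpsi = vpsi0, vphi = vphi0)
  tr_a <- simulate_open_loop(ang, u_fun, list(), x0_ang, c(0, 1), 1e-3)
  tr_c <- simulate_open_loop(cart, u_fun, list(), x0_cart, c(0, 1), 1e-3)
  expect_near(tr_c$xX, tr_a$y_X, 1e-6)
  expect_near(tr_c$xY, tr_a$y_Y, 1e-6)
})

test_that("sigmoid reference matches its closed-form landmarks", {
  r <- reference_sigmoid(xl = 1, xh = 4, gamma = 4, t_raise = 20,
                         component = "X")
  expect_near(ref_eval(r, 20 - 1e3, 0L, "X"), 1, 1e-12)     # lower plateau
  expect_equal(ref_eval(r, 20, 0L, "X"), 2.5)                # half rise
  expect_equal(ref_eval(r, 20, 1L, "X"), 6)                  # gamma(xh-xl)/2
  # supplied derivatives agree with central differences at O(h^2)
  h <- 1e-4
  fd <- (ref_eval(r, 20.5 + h, 0L, "X") - ref_eval(r, 20.5 - h, 0L, "X")) /
    (2 * h)
  expect_near(fd, ref_eval(r, 20.5, 1L, "X"), 1e-6)
})

test_that("quatrefoil reference is the stated curve", {
  r <- reference_quatrefoil(a = 2)
  expect_near(ref_eval(r, 0, 0L), c(0, 0), 1e-14)
  expect_near(ref_eval(r, pi / 4, 0L, "X"), sqrt(2), 1e-12)
  expect_near(ref_eval(r, pi / 4, 0L, "Y"), sqrt(2), 1e-12)
  # closed form vs direct parametrisation on a grid
  tt <- seq(0, 2 * pi, length.out = 33)
  expect_near(ref_eval(r, tt, 0L, "X"), 4 * sin(tt)^2 * cos(tt), 1e-12)
  expect_near(ref_eval(r, tt, 0L, "Y"), 4 * cos(tt)^2 * sin(tt), 1e-12)
  expect_near(ref_eval(r, tt + 2 * pi, 0L, "X"), ref_eval(r, tt, 0L, "X"),
              1e-12)
})

test_that("hypocycloid reference closes after its least common period", {
  r <- reference_hypocycloid(a = 2, b = 6 / 5)
  expect_near(ref_eval(r, 0, 0L), c(2, 0), 1e-14)
  expect_equal(r$domain[2L], 6 * pi)   # arguments t and 2t/3 close at 6 pi
  expect_near(ref_eval(r, 6 * pi, 0L), ref_eval(r, 0, 0L), 1e-9)
  tt <- seq(0, 6 * pi, length.out = 101)
  for (k in 0:2) expect_true(all(is.finite(ref_eval(r, tt, k))))
  expect_error(reference_hypocycloid(a = 1, b = 2))
})

test_that("open-loop torques vanish on a constant reference", {
  ol <- oculomotor_openloop(reference = reference_constant(c(X = 1, Y = -2)))
  u <- ol$u_fun(0.7)
  expect_near(unname(u), c(0, 0), 1e-15)
})

test_that("noise-free open loop reproduces the reference", {
  params <- oculomotor_params(alpha = 0)
  ref <- oculomotor_reference("quatrefoil")
  ol <- oculomotor_openloop(params, ref, mode = "mean")
  x0 <- ol$x_fun(0)
  tr <- simulate_open_loop(mean_model(ol$model), ol$u_fun, list(), x0,
                           c(0, 2), dt = 1e-3, reference = ref)
  expect_lt(max(abs(tr$eact_X), abs(tr$eact_Y)), 1e-6)
})

test_that("small fluctuations visibly perturb the open-loop torques", {
  params <- oculomotor_params(alpha = 2e-6)
  ref <- oculomotor_reference("sigmoid")
  signals <- oculomotor_signals(params, seed = 9)
  ol_mean <- oculomotor_openloop(params, ref, mode = "mean")
  ol_orac <- oculomotor_openloop(params, ref, mode = "oracle",
                                 signals = signals)
  tt <- seq(15, 25, 0.5)
  du <- vapply(tt, function(t) {
    max(abs(ol_orac$u_fun(t) - ol_mean$u_fun(t)))
  }, numeric(1L))
  expect_gt(max(du), 0)   # paired paths differ under fluctuations
})

test_that("the end-to-end tracking experiment meets its contracts", {
  # noise-free, on-reference start: the reference is invariant
  ex0 <- run_tracking_experiment(params = oculomotor_params(alpha = 0),
                                 reference = "quatrefoil", seed = 1,
                                 mode = "mean", dt = 2e-3)
  expect_lt(ex0$metrics$max_eact, 1e-6)

  # the study configuration: four channels, each with r = 4 harmonics
  ex <- run_tracking_experiment(reference = "quatrefoil", seed = 3,
                                mode = "oracle", dt = 2e-3)
  expect_identical(vapply(ex$signals, function(s) s$r, numeric(1L)),
                   c(zX = 4, zY = 4, zpsi = 4, zphi = 4))
  # oracle tracking stays below the frozen reference-run threshold
  # (validated run: max |eps_act| ~ 1e-12; threshold leaves margin)
  expect_lt(ex$metrics$rms_eact, 1e-8)

  # decoupling entries delta/(2 d Ie) never drop below d/(2 Ie): no
  # singularity on any simulated path
  params <- ex$params
  dmin <- min((params$d^2 + (ex$trace$xX - params$X0)^2) /
                (2 * params$d * params$Ie))
  expect_gte(dmin, params$d / (2 * params$Ie))
})

test_that("noise-free oculomotor errors decay at the designed pole", {
  params <- oculomotor_params(alpha = 0)
  model <- build_oculomotor(params)
  cert <- oculomotor_certificate(model)
  ref <- reference_constant(c(X = 1, Y = -1))
  p <- 2
  ctrl <- tracking_controller(model, cert, ref, gains = p, mode = "mean")
  # eigenmode start: choose the angular speeds so that each position error
  # decays as exp(-p t) exactly (edot = -p e at t = 0)
  xX0 <- 1.4; xY0 <- -0.7
  eX <- xX0 - 1; eY <- xY0 - (-1)
  vpsi0 <- -p * eX * params$d / (params$d^2 + (xX0 - params$X0)^2)
  vphi0 <- -p * eY * params$d / (params$d^2 + (xY0 - params$Y0)^2)
  x0 <- c(xX = xX0, xY = xY0, vpsi = vpsi0, vphi = vphi0)
  tr <- simulate_closed_loop(model, ctrl, zero_signals(model), x0, c(0, 3),
                             1e-3, reference = ref)
  expect_lt(abs(fit_decay_rate(tr) - p) / p, 0.1)
})
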