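# Flatness engine: Brunovsky analysis, parametrisation, feedback,
# realisation, point-to-point planning.

test_that("Brunovsky analysis certifies the worked examples", {
  di <- build_double_integrator()
  c_di <- brunovsky_analysis(di, list(quote(x1)))
  expect_identical(c_di$kappa, 2L)
  expect_true(c_di$flat)

  om <- build_oculomotor()
  c_om <- oculomotor_certificate(om)
  expect_identical(c_om$kappa, c(2L, 2L))
  expect_true(c_om$flat)
  expect_identical(sum(c_om$kappa), length(om$states))
  # decoupling matrix is diagonal: off-diagonal entries identically zero
  expect_true(is_zero_expr(c_om$A[[1L, 2L]]))
  expect_true(is_zero_expr(c_om$A[[2L, 1L]]))

  bm <- build_bergman()
  c_bm <- brunovsky_analysis(bm, list(quote(G)), omega_names = "G")
  expect_identical(c_bm$kappa, 3L)
  expect_true(c_bm$flat)

  # sum of indices never exceeds n, with equality exactly on flat verdicts
  for (cc in list(c_di, c_om, c_bm)) {
    expect_lte(sum(cc$kappa), length(cc$model$states))
    expect_identical(cc$flat, sum(cc$kappa) == length(cc$model$states))
  }
})

test_that("a deficient candidate is analysed but not certified", {
  se <- fix_simple(stochastic = FALSE)
  cert <- brunovsky_analysis(se, list(quote(x2)))
  expect_identical(cert$kappa, 1L)   # input appears immediately
  expect_false(cert$flat)            # 1 != n = 2
  expect_match(cert$reason, "!=")
  expect_error(functional_parametrisation(se, cert), "not flat")
})

test_that("degenerate candidates are rejected with diagnostics", {
  se <- fix_simple(stochastic = FALSE)
  expect_error(brunovsky_analysis(se, list(quote(x1 + u))), "endogenous")

  # autonomous first state never reaches the input within the cap
  m <- control_affine_model(states = c("x1", "x2"), inputs = "u",
                            rhs = list(x1 = quote(x1), x2 = quote(u)),
                            name = "disconnected")
  expect_error(brunovsky_analysis(m, list(quote(x1))), "no control input")
})

test_that("the parametrisations reproduce the closed forms", {
  # deterministic simple example: x1 = y, x2 = ydot, u = yddot - f(y, ydot)
  sed <- fix_simple(stochastic = FALSE)
  pd <- functional_parametrisation(sed, fix_simple_cert(sed))
  pts <- list(y_d0 = 0.7, y_d1 = -1.2, y_d2 = 0.4)
  expect_equal(eval_expr(pd$states$x1, pts), 0.7)
  expect_equal(eval_expr(pd$states$x2, pts), -1.2)
  expect_equal(eval_expr(pd$inputs$u, pts),
               0.4 - (-sin(0.7) - (-1.2)))

  # stochastic simple example: x1 = y - zy, x2 = ydot - zydot - zx1
  se <- fix_simple()
  ps <- functional_parametrisation(se, fix_simple_cert(se))
  pts <- list(y_d0 = 0.7, y_d1 = -1.2, y_d2 = 0.4,
              zy_d0 = 0.05, zy_d1 = -0.02, zy_d2 = 0.01,
              zx1_d0 = 0.03, zx1_d1 = 0.02, zx2_d0 = -0.04)
  x1v <- 0.7 - 0.05
  x2v <- -1.2 - (-0.02) - 0.03
  expect_equal(eval_expr(ps$states$x1, pts), x1v)
  expect_equal(eval_expr(ps$states$x2, pts), x2v)
  expect_equal(eval_expr(ps$inputs$u, pts),
               0.4 - (-sin(x1v) - x2v) - 0.01 - 0.02 - (-0.04))
})

test_that("substituted parametrisations leave zero residuals", {
  for (model in list(fix_simple(), fix_simple(stochastic = FALSE),
                     build_double_integrator(), build_oculomotor(),
                     build_bergman())) {
    cands <- if (length(model$inputs) == 2L) {
      list(quote(xX), quote(xY))
    } else {
      model$outputs[1L]
    }
    cert <- brunovsky_analysis(model, cands)
    par <- functional_parametrisation(model, cert)
    res <- verify_parametrisation(model, par)
    expect_true(res$all_zero, label = paste("residuals zero for", model$name))
  }
})

test_that("a corrupted parametrisation leaves exactly the dropped term", {
  se <- fix_simple()
  par <- functional_parametrisation(se, fix_simple_cert(se))
  # drop the zeta_x2 term of the action law
  par$inputs$u <- fold_expr(subst_expr(par$inputs$u, list(zx2_d0 = 0)))
  res <- verify_parametrisation(se, par)
  expect_false(res$all_zero)
  expect_true(res$zero["x1"])
  # the x2 residual equals -zeta_x2 (sign per lhs - rhs convention)
  leftover <- fold_expr(call("+", res$residuals$x2, quote(zx2_d0)))
  expect_true(is_zero_expr(leftover))
})

test_that("linearising feedback inverts the decoupling relation", {
  di <- build_double_integrator()
  fb <- linearising_feedback(di, brunovsky_analysis(di, list(quote(x1))))
  u <- fb(c(x1 = 0.3, x2 = -2), v = 1.7)
  expect_equal(unname(u), 1.7)   # double integrator: u = v

  om <- build_oculomotor()
  cert <- oculomotor_certificate(om)
  fb_om <- linearising_feedback(om, cert)
  x <- c(xX = 1, xY = -0.5, vpsi = 0.02, vphi = -0.01)
  v <- c(0.4, -0.3)
  u <- fb_om(x, v)
  # push u back through the flat-output dynamics: omega'' must equal v
  jets <- model_jet_names(om, cert$gamma)
  vals <- c(as.list(x), as.list(u),
            stats::setNames(as.list(rep(0, length(jets))), jets))
  expect_near(vapply(cert$gamma, eval_expr, numeric(1L), values = vals),
              v, 1e-9)
})

test_that("the chain realisation is trajectory-equivalent to the model", {
  om <- build_oculomotor()
  cert <- oculomotor_certificate(om)
  real <- brunovsky_realisation(cert)
  expect_identical(length(real$states), sum(cert$kappa))
  # two of the four chain equations are pure integrations
  expect_identical(real$rhs$X_d0, quote(X_d1))
  expect_identical(real$rhs$Y_d0, quote(Y_d1))

  u_fun <- function(t) c(upsi = 2e-7 * sin(t), uphi = -1e-7 * cos(t))
  x0 <- c(xX = 0.5, xY = -0.2, vpsi = 0.01, vphi = 0.005)
  z0 <- chain_coordinates(cert, x0)
  tr1 <- simulate_open_loop(om, u_fun, list(zX = 0, zY = 0, zpsi = 0,
                                            zphi = 0),
                            x0, c(0, 1), dt = 1e-3)
  tr2 <- simulate_open_loop(real, u_fun, list(zX = 0, zY = 0, zpsi = 0,
                                              zphi = 0),
                            z0, c(0, 1), dt = 1e-3)
  expect_near(tr2$X_d0, tr1$xX, 1e-6)
  expect_near(tr2$Y_d0, tr1$xY, 1e-6)
})

test_that("point-to-point plans interpolate the endpoint jets", {
  di <- build_double_integrator()
  cert <- brunovsky_analysis(di, list(quote(x1)))
  plan <- plan_point_to_point(di, cert, c(x1 = 0, x2 = 0),
                              c(x1 = 1, x2 = 0), 0, 1)
  # unique cubic: 3 t^2 - 2 t^3
  tt <- seq(0, 1, 0.1)
  expect_near(ref_eval(plan, tt, 0L, "w1"), 3 * tt^2 - 2 * tt^3, 1e-12)

  # coincident endpoints with zero velocity: constant polynomial
  plan0 <- plan_point_to_point(di, cert, c(x1 = 2, x2 = 0),
                               c(x1 = 2, x2 = 0), 0, 1)
  expect_near(ref_eval(plan0, tt, 0L, "w1"), rep(2, length(tt)), 1e-12)
  expect_near(ref_eval(plan0, tt, 1L, "w1"), rep(0, length(tt)), 1e-12)

  expect_error(plan_point_to_point(di, cert, c(x1 = 0, x2 = 0),
                                   c(x1 = 1, x2 = 0), 1, 1), "exceed")
})
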