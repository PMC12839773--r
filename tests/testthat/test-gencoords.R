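# Generalised coordinates: the linearised differentiation d1 and the
# Bergman / car demonstrations.

kinds_zv <- c(z = "var", zeta = "fluct")

test_that("d1 obeys the first-order truncation rule", {
  # d1(z) = z'
  expect_equal(deparse1(jet_poly_expr(d1(jet_poly(quote(z), kinds_zv)))),
               "z_d1")
  # the product rule at order zero is untouched: d1(z zeta) = z' zeta + z zeta'
  got <- d1(jet_poly(quote(z * zeta), kinds_zv))
  want <- jet_poly(quote(z_d1 * zeta_d0 + z_d0 * zeta_d1), kinds_zv)
  expect_true(jp_equal(got, want))
  expect_true(jp_equal(d1(jet_poly(quote(z * zeta), kinds_zv),
                          mode = "full"), want))
  # but every cross product of derivatives is truncated:
  # d1(z' zeta) = z'' zeta (the z' zeta' term vanishes: orders 1 + 1 > 1)
  got2 <- d1(jet_poly(quote(z_d1 * zeta), kinds_zv))
  want2 <- jet_poly(quote(z_d2 * zeta_d0), kinds_zv)
  expect_true(jp_equal(got2, want2))
  full2 <- d1(jet_poly(quote(z_d1 * zeta), kinds_zv), mode = "full")
  wantf2 <- jet_poly(quote(z_d2 * zeta_d0 + z_d1 * zeta_d1), kinds_zv)
  expect_true(jp_equal(full2, wantf2))
})

test_that("on linear expressions d1 coincides with full differentiation", {
  kinds <- c(z1 = "var", z2 = "var", zeta = "fluct")
  for (e in list(quote(2 * z1 + 3 * z2), quote(z1 - zeta),
                 quote(5 * z2 + 1))) {
    p <- jet_poly(e, kinds)
    expect_true(jp_equal(d1(p), d1(p, mode = "full")),
                label = paste("linear d1 ==", deparse1(e)))
  }
})

test_that("d1 is linear and its output satisfies the truncation invariant", {
  kinds <- c(z1 = "var", z2 = "var")
  e1 <- jet_poly(quote(z1^2 * z2 + z1), kinds)
  e2 <- jet_poly(quote(z2^3 - z1 * z2), kinds)
  a <- 2.5; b <- -1.25
  lhs <- d1(jp_wrap(jp_add(jp_scale(e1$terms, a), jp_scale(e2$terms, b)),
                    kinds))
  rhs <- jp_wrap(jp_add(jp_scale(d1(e1)$terms, a),
                        jp_scale(d1(e2)$terms, b)), kinds)
  expect_true(jp_equal(lhs, rhs))

  # structural soundness: at most one differentiated factor per monomial
  for (p in list(d1(e1), d1(d1(e1)), d1(e2))) {
    for (tm in p$terms) {
      orders <- jet_order(names(tm$p))
      expect_lte(sum(tm$p[orders > 0L]), 1L)
    }
  }
})

test_that("repeated d1 realises the local linear approximation", {
  # F(z) = z^2: d1^k F = 2 z z^(k), the gradient contracted with the k-jet
  kinds <- c(z = "var")
  p <- jet_poly(quote(z^2), kinds)
  for (k in 1:3) {
    p <- d1(p)
    want <- jp_wrap(jp_mul(jp_mul(jp_const(2), jp_sym("z", 0L)),
                           jp_sym("z", k)), kinds)
    expect_true(jp_equal(p, want), label = paste("order", k))
  }
})

test_that("the Bergman chains differ exactly by -2 X' G' at order 3", {
  bm <- build_bergman()
  ch <- lin_derivative_chain(bm, quote(G), k = 3L)
  expect_length(ch$diff[[1L]]$terms, 0L)   # orders 1, 2 agree
  expect_length(ch$diff[[2L]]$terms, 0L)
  want <- jet_poly(quote(-2 * G_d1 * X_d1), model_kinds(bm))
  expect_true(jp_equal(ch$diff[[3L]], want))
  # the action reaches the full chain at order 3, not earlier
  expect_false("u" %in% all.vars(ch$full_sub[[2L]]))
  expect_true("u" %in% all.vars(ch$full_sub[[3L]]))
})

test_that("kappa <= 2 components give identical chains (car, oculomotor)", {
  car <- build_car()
  cert <- brunovsky_analysis(car, list(quote(Vx)), omega_names = "Vx")
  expect_identical(cert$kappa, 1L)         # action already present
  cc <- lin_derivative_chain(car, quote(Vx), k = 1L)
  expect_true(jp_equal(cc$full[[1L]], cc$lin[[1L]]))

  om <- build_oculomotor()
  co <- lin_derivative_chain(om, quote(xX), k = 2L)
  expect_true(jp_equal(co$full[[2L]], co$lin[[2L]]))
})

test_that("meal-excited tracking separates the two laws", {
  demo <- bergman_demo(dt = 0.05)
  # flatness-based law: exact linearisation, errors at numerical floor
  expect_lt(demo$rms_flat, 1e-6)
  # generalised-coordinate law is steered by -2 X' G': strictly worse
  expect_gt(demo$rms_gc, demo$rms_flat)
  expect_gt(demo$rms_gc, 1e-4)             # visibly excited, not a tie
  # the jet-level discrepancy is the single cross term
  want <- jet_poly(quote(-2 * G_d1 * X_d1),
                   model_kinds(build_bergman()))
  expect_true(jp_equal(demo$jet_discrepancy, want))
  # the driving term is genuinely nonzero along the run
  expect_gt(max(abs(demo$drive$drive)), 1e-3)
})

test_that("at equilibrium with no meal both laws agree", {
  demo <- bergman_demo(reference = reference_constant(c(G = 110)),
                       meal = FALSE, t_span = c(0, 60), dt = 0.05)
  expect_lt(demo$rms_flat, 1e-6)
  expect_lt(demo$rms_gc, 1e-6)
})
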