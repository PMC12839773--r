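# Shared fixtures: all built in code at test time.

simple_f <- quote(-sin(x1) - x2)

fix_simple <- function(stochastic = TRUE) {
  build_simple_example(simple_f, stochastic = stochastic)
}

fix_simple_cert <- function(model = fix_simple()) {
  brunovsky_analysis(model, list(model$outputs$y), omega_names = "y")
}

# linear scalar plant xdot = a x + u, used across the delay tests
fix_linear <- function(a = -0.7) {
  control_affine_model(
    states = "x", inputs = "u",
    rhs = list(x = quote(a * x + u)),
    outputs = list(y = quote(x)),
    params = list(a = a), name = "linear scalar"
  )
}

# sigmoid step from 0 to 1, handy single-component reference
fix_step_ref <- function(component = "y") {
  reference_sigmoid(xl = 0, xh = 1, gamma = 1, t_raise = 3,
                    component = component)
}

# constant-signal binding for a fluctuation channel
const_signal <- function(v) exo_signal(function(t, order) {
  if (order == 0L) rep(v, length(t)) else rep(0, length(t))
})

expect_near <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("|%s - %s| <= %s",
                              deparse(substitute(object)),
                              deparse(substitute(expected)), tol))
}
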