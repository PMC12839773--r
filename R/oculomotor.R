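# Oculomotor demonstration: a fixed-head eye tracking a point on a screen at
# distance d.  Listing's law reduces the kinematics to yaw and pitch; in
# screen (Cartesian) coordinates the generative model is
#   dX/dt  = v_psi (d^2 + (X - X0 - zX)^2)/d + dzX/dt
#   dY/dt  = v_phi (d^2 + (Y - Y0 - zY)^2)/d + dzY/dt
#   2 Ie dv_psi/dt = u_psi + z_psi      (doubled yaw inertia)
#   Ie   dv_phi/dt = u_phi + z_phi
# which is differentially flat with the screen position (X, Y) as flat
# output.  The decoupling entries are delta_X/(2 d Ie) and delta_Y/(d Ie)
# with delta_* = d^2 + (pos - centre - fluct)^2 >= d^2 > 0, so the feedback
# is singularity-free on every trajectory.

#' Oculomotor parameter set
#'
#' @param Ie eye rotational inertia, kg m^2 (> 0).
#' @param d screen distance, m (> 0).
#' @param X0,Y0 orthogonal projection of the eye on the screen, m.
#' @param L,lambda_w period and wavelength of the four fluctuation channels.
#' @param alpha fluctuation amplitude scale.
#' @return a named list of class \code{"oculo_params"}.
#' @export
oculomotor_params <- function(Ie = 4.032e-7, d = 10, X0 = 0, Y0 = 0,
                              L = 8, lambda_w = 2, alpha = 1e-5) {
  stopifnot(Ie > 0, d > 0, L > 0, lambda_w > 0, alpha >= 0)
  structure(list(Ie = Ie, d = d, X0 = X0, Y0 = Y0,
                 L = L, lambda_w = lambda_w, alpha = alpha),
            class = "oculo_params")
}

#' Build the oculomotor generative model (screen coordinates)
#'
#' @param params an [oculomotor_params()] list.
#' @return a \code{"flat_model"} with states \code{xX, xY, vpsi, vphi},
#'   torques \code{upsi, uphi} and fluctuation channels
#'   \code{zX, zY, zpsi, zphi} (the position channels enter through their
#'   first derivatives, the torque channels additively).
#' @export
build_oculomotor <- function(params = oculomotor_params()) {
  control_affine_model(
    states = c("xX", "xY", "vpsi", "vphi"),
    inputs = c("upsi", "uphi"),
    flucts = c("zX", "zY", "zpsi", "zphi"),
    rhs = list(
      xX = quote(vpsi * (d^2 + (xX - X0 - zX_d0)^2) / d + zX_d1),
      xY = quote(vphi * (d^2 + (xY - Y0 - zY_d0)^2) / d + zY_d1),
      vpsi = quote((upsi + zpsi_d0) / (2 * Ie)),
      vphi = quote((uphi + zphi_d0) / Ie)
    ),
    outputs = list(X = quote(xX), Y = quote(xY)),
    params = params[c("Ie", "d", "X0", "Y0")],
    name = "oculomotor (screen coordinates)"
  )
}

#' Build the oculomotor model in angle coordinates
#'
#' Mean (noise-free) model in yaw/pitch angles: \eqn{\dot\psi = v_\psi},
#' \eqn{\dot\phi = v_\phi}, \eqn{2 I_e \dot v_\psi = u_\psi},
#' \eqn{I_e \dot v_\phi = u_\phi}; the screen position is recovered through
#' Listing-law kinematics \eqn{X = X_0 + d\tan\psi},
#' \eqn{Y = Y_0 + d\tan\phi}.  Used as the change-of-variables cross-check
#' for the Cartesian model.
#'
#' @param params an [oculomotor_params()] list.
#' @return a \code{"flat_model"}.
#' @export
build_oculomotor_angles <- function(params = oculomotor_params()) {
  control_affine_model(
    states = c("psi", "phi", "vpsi", "vphi"),
    inputs = c("upsi", "uphi"),
    rhs = list(
      psi = quote(vpsi),
      phi = quote(vphi),
      vpsi = quote(upsi / (2 * Ie)),
      vphi = quote(uphi / Ie)
    ),
    outputs = list(X = quote(X0 + d * tan(psi)),
                   Y = quote(Y0 + d * tan(phi))),
    params = params[c("Ie", "d", "X0", "Y0")],
    name = "oculomotor (angle coordinates)"
  )
}

#' Flatness certificate of the oculomotor model
#'
#' Convenience wrapper: candidates \eqn{(X, Y)}, Brunovsky indices
#' \eqn{(2, 2)}.
#'
#' @param model a model from [build_oculomotor()].
#' @return a \code{"flat_certificate"}.
#' @export
oculomotor_certificate <- function(model = build_oculomotor()) {
  brunovsky_analysis(model, list(quote(xX), quote(xY)),
                     omega_names = c("X", "Y"))
}

#' Bind the four oculomotor fluctuation channels
#'
#' Samples four independent smooth random functions (channels
#' \code{zX, zY, zpsi, zphi}) from the configured law, with sub-seeds derived
#' from \code{seed}.
#'
#' @param params an [oculomotor_params()] list.
#' @param seed integer master seed.
#' @return named list of \code{"srf"} objects.
#' @export
oculomotor_signals <- function(params = oculomotor_params(), seed = 1L) {
  nms <- c("zX", "zY", "zpsi", "zphi")
  sig <- lapply(seq_along(nms), function(i) {
    sample_srf(params$L, params$lambda_w, mode = "standard",
               alpha = params$alpha, seed = as.integer(seed) * 16L + i)
  })
  stats::setNames(sig, nms)
}

#' Built-in oculomotor reference trajectories
#'
#' \code{"sigmoid"}: smooth gaze steps in X and Y (the X channel uses the
#' plateau/stiffness configuration of the sigmoid demonstration, the Y
#' channel the same family with a later half-rise); \code{"quatrefoil"} and
#' \code{"hypocycloid"}: smooth pursuit along closed curves.
#'
#' @param name one of \code{"sigmoid"}, \code{"quatrefoil"},
#'   \code{"hypocycloid"}.
#' @param a,b curve parameters for the parametric families.
#' @return a \code{"flat_reference"} with components \code{X}, \code{Y}.
#' @export
oculomotor_reference <- function(name = c("quatrefoil", "sigmoid",
                                          "hypocycloid"),
                                 a = 2, b = 6 / 5) {
  name <- match.arg(name)
  switch(name,
    quatrefoil = reference_quatrefoil(a = a),
    hypocycloid = reference_hypocycloid(a = a, b = b),
    sigmoid = {
      rx <- reference_sigmoid(xl = 1, xh = 4, gamma = 4, t_raise = 20,
                              component = "X")
      ry <- reference_sigmoid(xl = 1, xh = 3, gamma = 4, t_raise = 40,
                              component = "Y")
      out <- reference_trajectory(c(rx$components, ry$components),
                                  max_order = 3L, domain = c(0, 80),
                                  name = "sigmoid")
      out
    }
  )
}

# Initial state matching the reference jets at time t (optionally with the
# true fluctuation jets substituted).
oculomotor_state_on_reference <- function(par, reference, t = 0,
                                          signals = NULL) {
  vars <- unique(unlist(lapply(par$states, all.vars)))
  wjets <- vars[is_jet_name(vars) & jet_base(vars) %in% par$omega_names]
  zjets <- setdiff(vars, wjets)
  vals <- stats::setNames(rep(0, length(vars)), vars)
  for (w in wjets) {
    vals[w] <- ref_eval(reference, t, jet_order(w), component = jet_base(w))
  }
  if (!is.null(signals) && length(zjets) > 0L) {
    jf <- make_jet_evaluator(zjets, signals)
    vals[zjets] <- jf(t)
  }
  vapply(par$states, function(e) eval_expr(e, as.list(vals)), numeric(1L))
}

#' Open-loop oculomotor torques from the functional parametrisation
#'
#' Substitutes the reference for the flat output in the input
#' parametrisation, giving the feedforward torque law; in oracle mode the
#' true fluctuation jets are substituted as well.
#'
#' @param params an [oculomotor_params()] list.
#' @param reference a \code{"flat_reference"} with components X, Y.
#' @param mode \code{"mean"} (noise-free feedforward) or \code{"oracle"}.
#' @param signals fluctuation bindings (required in oracle mode).
#' @return a list with \code{u_fun(t)} (named torque vector),
#'   \code{x_fun(t)} (named reference state vector), the model, certificate
#'   and parametrisation.
#' @export
oculomotor_openloop <- function(params = oculomotor_params(), reference,
                                mode = c("mean", "oracle"), signals = NULL) {
  mode <- match.arg(mode)
  model <- build_oculomotor(params)
  cert <- oculomotor_certificate(model)
  par <- functional_parametrisation(model, cert)
  ctrl <- openloop_controller(par, reference, mode = mode)
  jets_fun <- if (mode == "oracle") {
    make_jet_evaluator(attr(ctrl, "jet_names"), signals)
  } else {
    function(t) NULL
  }
  u_fun <- function(t) ctrl(t, NULL, jets_fun(t))
  x_fun <- function(t) {
    oculomotor_state_on_reference(par, reference, t,
                                  if (mode == "oracle") signals else NULL)
  }
  list(u_fun = u_fun, x_fun = x_fun, model = model, cert = cert, par = par)
}

#' Run an end-to-end oculomotor tracking experiment
#'
#' Builds the model, binds four smooth random fluctuation channels,
#' synthesises the flatness-based tracking controller, simulates the closed
#' loop pathwise and reports the discrepancy metrics.
#'
#' @param params an [oculomotor_params()] list (its \code{alpha} sets the
#'   fluctuation scale).
#' @param reference a reference name understood by [oculomotor_reference()]
#'   or a \code{"flat_reference"}.
#' @param gains designed pole (scalar) or per-component gain vectors.
#' @param seed master seed for the fluctuation channels.
#' @param mode controller knowledge mode, \code{"oracle"} or \code{"mean"}.
#' @param t_span simulation span; default: the reference's domain.
#' @param dt integration step.
#' @param x0 named initial state; default: exact reference jets at the start
#'   (oracle-consistent when \code{mode = "oracle"}).
#' @return a list of class \code{"oculo_experiment"}: \code{trace},
#'   \code{metrics}, \code{cert}, \code{signals}, \code{reference}.
#' @export
run_tracking_experiment <- function(params = oculomotor_params(),
                                    reference = "quatrefoil", gains = 2,
                                    seed = 1L,
                                    mode = c("oracle", "mean"),
                                    t_span = NULL, dt = 1e-3, x0 = NULL) {
  mode <- match.arg(mode)
  if (is.character(reference)) reference <- oculomotor_reference(reference)
  model <- build_oculomotor(params)
  cert <- oculomotor_certificate(model)
  par <- functional_parametrisation(model, cert)
  signals <- oculomotor_signals(params, seed = seed)
  ctrl <- tracking_controller(model, cert, reference, gains = gains,
                              mode = mode)
  if (is.null(t_span)) {
    t_span <- reference$domain
    if (!all(is.finite(t_span))) t_span <- c(0, 2 * pi)
  }
  if (is.null(x0)) {
    x0 <- oculomotor_state_on_reference(
      par, reference, t_span[1L],
      if (mode == "oracle") signals else NULL)
  }
  trace <- simulate_closed_loop(model, ctrl, signals, x0, t_span, dt,
                                reference = reference)
  # the decoupling entries stay >= d^2/(2 d Ie) along any path; assert it
  dmin <- min((params$d^2 +
                 (trace$xX - params$X0)^2) / (2 * params$d * params$Ie))
  stopifnot(dmin > 0)
  structure(
    list(trace = trace, metrics = discrepancy_metrics(trace),
         cert = cert, signals = signals, reference = reference,
         params = params, mode = mode, seed = seed),
    class = "oculo_experiment"
  )
}

#' @export
print.oculo_experiment <- function(x, ...) {
  cat("<oculomotor tracking experiment>\n")
  cat("  reference: ", x$reference$name, " | mode: ", x$mode,
      " | alpha = ", x$params$alpha, " | seed = ", x$seed, "\n", sep = "")
  cat(sprintf("  max |eps_act| = %.3g, RMS = %.3g, risk = %.3g\n",
              x$metrics$max_eact, x$metrics$rms_eact, x$metrics$risk))
  invisible(x)
}
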