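# Input-delayed systems: delta-flatness on the delayed simple example and
# the two predictor schemes (delayed observer, integral predictor) that make
# predictive tracking possible under an action delay tau.
#
# Histories are uniform ring buffers at the simulation step with linear
# interpolation between nodes.

#' Attach an input delay to a model
#'
#' The plant equations keep their form but every input symbol is driven by
#' the action committed \code{tau} time units earlier:
#' \eqn{\dot x(t) = f(x(t)) + G(x(t))\,u(t - \tau) + N(\zeta)}.
#'
#' @param model a \code{"flat_model"}.
#' @param tau input delay (>= 0).
#' @return a \code{"delayed_model"}.
#' @export
delayed_model <- function(model, tau) {
  stopifnot(inherits(model, "flat_model"), is.numeric(tau), tau >= 0)
  structure(list(base = model, tau = tau), class = "delayed_model")
}

#' @export
print.delayed_model <- function(x, ...) {
  cat("<input-delayed model: tau = ", x$tau, ">\n", sep = "")
  print(x$base)
  invisible(x)
}

# --- uniform history buffer ----------------------------------------------

sample_path <- function(times, fun, width) {
  v <- vapply(times, fun, numeric(width))
  if (width == 1L) matrix(v, ncol = 1L) else t(v)
}

history_buffer <- function(t0, dt, tau, init_fun, width) {
  n_hist <- max(1L, ceiling(tau / dt)) + 2L
  times <- t0 - dt * (n_hist:0)
  vals <- sample_path(times, init_fun, width)
  dimnames(vals) <- NULL
  env <- new.env(parent = emptyenv())
  env$times <- times
  env$vals <- vals
  env
}

history_append <- function(buf, t, v) {
  buf$times <- c(buf$times, t)
  buf$vals <- rbind(buf$vals, matrix(unname(v), nrow = 1L))
  invisible(buf)
}

history_interp <- function(buf, t) {
  ts <- buf$times
  n <- length(ts)
  out <- if (t <= ts[1L]) {
    buf$vals[1L, ]
  } else if (t >= ts[n]) {
    buf$vals[n, ]
  } else {
    i <- findInterval(t, ts)
    w <- (t - ts[i]) / (ts[i + 1L] - ts[i])
    (1 - w) * buf$vals[i, ] + w * buf$vals[i + 1L, ]
  }
  unname(out)
}

# --- delta-flatness on the delayed simple example -------------------------

#' Delta-flat parametrisation of the delayed simple example
#'
#' For the simple generic example with an action delay,
#' \eqn{\dot x_2(t) = f(x_1, x_2) + u(t-\tau) + \zeta_{x2}}, the system stays
#' flat once time shifts are allowed: the state parametrisation is the
#' undelayed one, while the action is the undelayed action law evaluated one
#' delay ahead — every term of \eqn{u(t)} carries the argument \eqn{t+\tau}.
#'
#' @param model the delayed simple example, a \code{"delayed_model"} whose
#'   base comes from [build_simple_example()].
#' @return a \code{"delta_flat_parametrisation"}: the base expressions plus a
#'   named vector of time shifts (0 for the states, \eqn{+\tau} for the
#'   action).
#' @export
delta_flat_parametrisation <- function(model) {
  stopifnot(inherits(model, "delayed_model"))
  base <- model$base
  cert <- brunovsky_analysis(base, list(base$outputs[[1L]]),
                             omega_names = names(base$outputs)[1L])
  par <- functional_parametrisation(base, cert)
  shifts <- c(stats::setNames(rep(0, length(par$states)), names(par$states)),
              stats::setNames(rep(model$tau, length(par$inputs)),
                              names(par$inputs)))
  structure(list(base = par, tau = model$tau, shifts = shifts,
                 cert = cert),
            class = "delta_flat_parametrisation")
}

#' @export
print.delta_flat_parametrisation <- function(x, ...) {
  cat("<delta-flat parametrisation (tau = ", x$tau, ")>\n", sep = "")
  for (nm in names(x$base$states)) {
    cat("  ", nm, "(t) = ", deparse1(x$base$states[[nm]]), "\n", sep = "")
  }
  for (nm in names(x$base$inputs)) {
    cat("  ", nm, "(t) = [", deparse1(x$base$inputs[[nm]]),
        "] evaluated at t + ", x$tau, "\n", sep = "")
  }
  invisible(x)
}

#' Verify a delta-flat parametrisation
#'
#' The time shift commutes with differentiation and with every static map,
#' so substituting the shifted parametrisation into the delayed equations
#' leaves exactly the residuals of the unshifted parametrisation in the
#' undelayed model; those are simplified and zero-tested symbolically.
#'
#' @param model a \code{"delayed_model"}.
#' @param dpar a \code{"delta_flat_parametrisation"}.
#' @return a \code{"flat_residuals"} object.
#' @export
verify_delta_flat <- function(model, dpar) {
  verify_parametrisation(model$base, dpar$base)
}

# --- delayed observer -----------------------------------------------------

#' Co-simulate a plant with input delay and its delayed observer
#'
#' Plant: \eqn{\dot x(t) = f(x(t), u(t-\tau))}.  Observer:
#' \eqn{\dot{\hat x}(t) = f(\hat x(t), u(t)) +
#' K_{obs}\,(x(t) - \hat x(t-\tau))}; its simulation yields an estimate
#' \eqn{\hat x(t)} of \eqn{x(t+\tau)}, and the prediction error
#' \eqn{x(t) - \hat x(t-\tau)} tends to zero for stabilising gains (verified
#' empirically per run; no gain certificate is computed).
#'
#' @param model a \code{"delayed_model"} (mean model; fluctuation-free).
#' @param K_obs observer gain matrix (n x n) or scalar for n = 1.
#' @param u_fun input path, a function of t defined on
#'   \code{[t_span[1] - tau, t_span[2]]}.
#' @param x0 named plant initial state.
#' @param xhat_init function of t giving the observer history on
#'   \code{[t_span[1] - tau, t_span[1]]} (named or plain numeric vector).
#' @param t_span,dt simulation span and fixed step.
#' @return a tibble: time, plant states, observer states \code{xhat_*}, and
#'   prediction-error columns \code{perr_*} = \eqn{x(t) - \hat x(t-\tau)}.
#' @export
delayed_observer_simulate <- function(model, K_obs, u_fun, x0, xhat_init,
                                      t_span, dt = 1e-3) {
  stopifnot(inherits(model, "delayed_model"))
  base <- model$base
  tau <- model$tau
  n <- length(base$states)
  K <- matrix(as.numeric(K_obs), n, n)
  vars <- c(base$states, base$inputs)
  if (length(model_jet_names(base)) > 0L) {
    stop("delayed_observer_simulate expects a fluctuation-free (mean) model.")
  }
  f_fun <- make_evaluator(base$rhs[base$states], vars)
  x0 <- x0[base$states]

  n_steps <- max(1L, round(diff(t_span) / dt))
  times <- t_span[1L] + dt * (0:n_steps)
  buf <- history_buffer(t_span[1L], dt, tau,
                        function(t) unname(xhat_init(t)), n)
  X <- matrix(NA_real_, n_steps + 1L, n,
              dimnames = list(NULL, base$states))
  Xh <- matrix(NA_real_, n_steps + 1L, n)
  Perr <- matrix(NA_real_, n_steps + 1L, n)

  x <- unname(x0)
  xh <- unname(xhat_init(t_span[1L]))
  for (s in 0:n_steps) {
    t <- times[s + 1L]
    X[s + 1L, ] <- x
    Xh[s + 1L, ] <- xh
    Perr[s + 1L, ] <- x - history_interp(buf, t - tau)
    if (any(!is.finite(c(x, xh)))) {
      stop("non-finite state at t = ", signif(t, 8), ".")
    }
    if (s == n_steps) break
    dstate <- function(tt, xx, xxh) {
      innov <- history_interp(buf, tt - tau)
      list(dx = f_fun(c(xx, u_fun(tt - tau))),
           dxh = f_fun(c(xxh, u_fun(tt))) + as.numeric(K %*% (xx - innov)))
    }
    k1 <- dstate(t, x, xh)
    k2 <- dstate(t + dt / 2, x + dt / 2 * k1$dx, xh + dt / 2 * k1$dxh)
    k3 <- dstate(t + dt / 2, x + dt / 2 * k2$dx, xh + dt / 2 * k2$dxh)
    k4 <- dstate(t + dt, x + dt * k3$dx, xh + dt * k3$dxh)
    x <- x + dt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
    xh <- xh + dt / 6 * (k1$dxh + 2 * k2$dxh + 2 * k3$dxh + k4$dxh)
    history_append(buf, t + dt, xh)
  }
  out <- tibble::as_tibble(as.data.frame(X))
  out <- tibble::add_column(out, t = times, .before = 1L)
  for (j in seq_len(n)) {
    out[[paste0("xhat_", base$states[j])]] <- Xh[, j]
    out[[paste0("perr_", base$states[j])]] <- Perr[, j]
  }
  out
}

# --- integral predictor ---------------------------------------------------

#' Integral (Picard) state predictor for an input-delayed plant
#'
#' Solves the implicit integral relation for the advanced state
#' \eqn{\bar x(t) = x(t+\tau)}: the predicted path \eqn{z} on
#' \eqn{[t, t+\tau]} satisfies
#' \eqn{z(s) = x(t) + \int_t^s f(z(\xi), u(\xi - \tau))\, d\xi}, where the
#' integrand's input values are the actions already committed on
#' \eqn{[t-\tau, t]}.  The fixed point is computed by Picard iteration with
#' trapezoidal quadrature, warm-started when a previous predicted path is
#' supplied.
#'
#' @param model a \code{"delayed_model"} (mean model).
#' @param x_t named current state \eqn{x(t)}.
#' @param u_hist function of time returning the committed input vector
#'   (needed on \code{[t - tau, t]}).
#' @param t current time.
#' @param n_grid number of quadrature sub-intervals on \eqn{[t, t+\tau]}.
#' @param tol fixed-point tolerance on the sup norm of the path update.
#' @param cap maximum Picard iterations; non-convergence is an error
#'   reporting the last residual.
#' @param warm_start optional matrix (n_grid+1 x n) initial path guess.
#' @return a list: \code{xpred} (named prediction of \eqn{x(t+\tau)}),
#'   \code{path} (the converged grid path), \code{iterations},
#'   \code{residual}.
#' @export
integral_predictor <- function(model, x_t, u_hist, t = 0, n_grid = 200L,
                               tol = 1e-10, cap = 100L, warm_start = NULL) {
  stopifnot(inherits(model, "delayed_model"), tol > 0, cap >= 1L)
  base <- model$base
  tau <- model$tau
  x_t <- unname(x_t[base$states])
  n <- length(base$states)
  if (tau == 0) {
    return(list(xpred = stats::setNames(x_t, base$states),
                path = matrix(x_t, 1L, n), iterations = 0L, residual = 0))
  }
  if (length(model_jet_names(base)) > 0L) {
    stop("integral_predictor expects a fluctuation-free (mean) model.")
  }
  vars <- c(base$states, base$inputs)
  f_vec <- make_vec_evaluator(base$rhs[base$states], vars)
  h <- tau / n_grid
  s_grid <- t + h * (0:n_grid)
  u_vals <- sample_path(s_grid - tau, u_hist, length(base$inputs))
  u_cols <- lapply(seq_len(ncol(u_vals)), function(j) u_vals[, j])
  names(u_cols) <- base$inputs
  z <- warm_start
  if (is.null(z) || !all(dim(z) == c(n_grid + 1L, n))) {
    z <- matrix(x_t, n_grid + 1L, n, byrow = TRUE)
  }
  res <- Inf
  for (it in seq_len(cap)) {
    cols <- c(lapply(seq_len(n), function(j) z[, j]), u_cols)
    names(cols)[seq_len(n)] <- base$states
    g <- f_vec(cols, n_grid + 1L)
    z_new <- matrix(x_t, n_grid + 1L, n, byrow = TRUE)
    for (j in seq_len(n)) {
      z_new[, j] <- x_t[j] + trapz_cum(s_grid, g[, j])
    }
    res <- max(abs(z_new - z))
    z <- z_new
    if (res <= tol) {
      return(list(xpred = stats::setNames(z[n_grid + 1L, ], base$states),
                  path = z, iterations = it, residual = res))
    }
  }
  stop("integral predictor did not converge within ", cap,
       " iterations (last residual ", signif(res, 3), ").")
}

# --- predictive tracking --------------------------------------------------

#' Predictive flatness-based tracking under input delay
#'
#' Closes the loop on an input-delayed plant with the undelayed tracking law
#' applied to a prediction of the advanced state: at each step the predictor
#' estimates \eqn{x(t+\tau)} (integral predictor from the committed input
#' history, delayed observer, or the exact advance for diagnostics), and the
#' action \eqn{u(t) = \kappa(\bar x(t), \omega_r(t+\tau))} is committed.
#' In \code{"none"} mode the law ignores the delay (for comparison).
#'
#' @param model a \code{"delayed_model"} built on a flat base model.
#' @param reference a \code{"flat_reference"} for the flat output.
#' @param gains pole or gain list for [tracking_controller()].
#' @param predictor \code{"integral"}, \code{"observer"} or \code{"none"}.
#' @param signals fluctuation bindings for the plant; the controller sees
#'   their advanced jets only in oracle mode.
#' @param mode controller knowledge mode.
#' @param x0 named initial state.
#' @param u_init input history on \code{[t0 - tau, t0]} (function of t).
#' @param pred_grid quadrature sub-intervals of the integral predictor.
#' @param K_obs observer gain (observer predictor only).
#' @param t_span,dt span and step.
#' @return a \code{"flat_trace"} tibble (with prediction available in the
#'   attribute \code{"predictor"}).
#' @export
simulate_delayed_tracking <- function(model, reference, gains = 2,
                                      predictor = c("integral", "observer",
                                                    "none"),
                                      signals = list(),
                                      mode = c("mean", "oracle"),
                                      x0, u_init = NULL, pred_grid = 25L,
                                      K_obs = NULL,
                                      t_span = c(0, 10), dt = 1e-3) {
  predictor <- match.arg(predictor)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "delayed_model"))
  base <- model$base
  tau <- model$tau
  if (tau < dt && tau > 0) stop("need tau >= dt (or tau = 0).")
  cert <- brunovsky_analysis(base, base$outputs[1L],
                             omega_names = names(base$outputs)[1L])
  ctrl <- tracking_controller(base, cert, reference, gains = gains,
                              mode = mode)
  ctrl_jets <- attr(ctrl, "jet_names")
  model_jets <- model_jet_names(base)
  jets_fun <- make_jet_evaluator(unique(c(model_jets, ctrl_jets)), signals)
  nu <- length(base$inputs)
  if (is.null(u_init)) u_init <- function(t) rep(0, nu)
  vars <- c(base$states, base$inputs, model_jets)
  rhs_fun <- make_evaluator(base$rhs[base$states], vars)
  out_name <- names(base$outputs)[1L]
  y_fun <- make_evaluator(base$outputs[1L], vars)

  n_steps <- max(1L, round(diff(t_span) / dt))
  times <- t_span[1L] + dt * (0:n_steps)
  x <- x0[base$states]
  n <- length(x)
  ubuf <- history_buffer(t_span[1L], dt, max(tau, dt),
                         function(t) unname(u_init(t)), nu)
  # mean model of the base for the predictor
  pred_model <- delayed_model(mean_model(base), tau)
  obs <- NULL
  if (predictor == "observer") {
    if (is.null(K_obs)) K_obs <- diag(2, n)
    obs_buf <- history_buffer(t_span[1L], dt, tau, function(t) x, n)
    obs_f <- make_evaluator(mean_model(base)$rhs[base$states],
                            c(base$states, base$inputs))
    obs_state <- unname(x)
  }
  warm <- NULL
  X <- matrix(NA_real_, n_steps + 1L, n, dimnames = list(NULL, base$states))
  U <- matrix(NA_real_, n_steps + 1L, nu)
  Yv <- numeric(n_steps + 1L)
  u_delayed <- function(tt) {
    stats::setNames(history_interp(ubuf, tt - tau), base$inputs)
  }
  for (s in 0:n_steps) {
    t <- times[s + 1L]
    xn <- x
    xbar <- switch(predictor,
      none = xn,
      integral = {
        p <- integral_predictor(pred_model, xn,
                                function(tt) history_interp(ubuf, tt),
                                t = t, n_grid = pred_grid,
                                warm_start = warm)
        warm <- p$path
        p$xpred
      },
      observer = stats::setNames(obs_state, base$states)
    )
    t_eval <- if (predictor == "none") t else t + tau
    jets_now <- jets_fun(t)
    jets_ctrl <- if (mode == "oracle") jets_fun(t_eval) else jets_now
    u_now <- ctrl(t_eval, xbar, jets_ctrl)
    history_append(ubuf, t, unname(u_now))
    X[s + 1L, ] <- x
    U[s + 1L, ] <- u_now
    Yv[s + 1L] <- y_fun(c(x, u_now, jets_now))
    if (any(!is.finite(x))) stop("non-finite state at t = ", signif(t, 8), ".")
    if (s == n_steps) break
    plant_d <- function(tt, xx) {
      rhs_fun(c(xx, u_delayed(tt), jets_fun(tt)))
    }
    k1 <- plant_d(t, x)
    k2 <- plant_d(t + dt / 2, x + dt / 2 * k1)
    k3 <- plant_d(t + dt / 2, x + dt / 2 * k2)
    k4 <- plant_d(t + dt, x + dt * k3)
    if (predictor == "observer") {
      od <- function(tt, xo) {
        obs_f(c(xo, history_interp(ubuf, tt))) +
          as.numeric(K_obs %*% (history_interp_state(X, times, s, tt, x) -
                                  history_interp(obs_buf, tt - tau)))
      }
      o1 <- od(t, obs_state)
      o2 <- od(t + dt / 2, obs_state + dt / 2 * o1)
      o3 <- od(t + dt / 2, obs_state + dt / 2 * o2)
      o4 <- od(t + dt, obs_state + dt * o3)
      obs_state <- obs_state + dt / 6 * (o1 + 2 * o2 + 2 * o3 + o4)
      history_append(obs_buf, t + dt, obs_state)
    }
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  tr <- tibble::as_tibble(as.data.frame(X))
  tr <- tibble::add_column(tr, t = times, .before = 1L)
  for (j in seq_len(nu)) tr[[paste0("u_", base$inputs[j])]] <- U[, j]
  tr[[paste0("y_", out_name)]] <- Yv
  rv <- ref_eval(reference, times, 0L,
                 component = names(reference$components)[1L])
  tr[[paste0("ref_", out_name)]] <- rv
  tr[[paste0("eact_", out_name)]] <- Yv - rv
  structure(tr, class = c("flat_trace", class(tr)),
            dt = dt, model = paste0(base$name, " + delay"),
            controller = paste0("predictive tracking (", predictor, ")"),
            mode = mode, gains = attr(ctrl, "gains"),
            predictor = predictor, tau = tau)
}

# linear interpolation of the plant state inside the current step (the
# observer's innovation uses x at stage times not yet committed to X)
history_interp_state <- function(X, times, s, tt, x_now) {
  if (tt <= times[1L]) return(X[1L, ])
  if (tt >= times[s + 1L]) return(x_now)
  i <- findInterval(tt, times[seq_len(s + 1L)])
  w <- (tt - times[i]) / (times[i + 1L] - times[i])
  xi1 <- if (i + 1L == s + 1L) x_now else X[i + 1L, ]
  (1 - w) * X[i, ] + w * xi1
}
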