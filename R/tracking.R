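# Flatness-based tracking synthesis and pathwise closed-loop simulation
# under smooth random fluctuations, plus the active-inference discrepancy
# and risk metrics evaluated along simulated paths.

#' Pole-placement tracking gains
#'
#' For a chain of length \eqn{\kappa}, places all closed-loop error poles at
#' \eqn{-p}: the gain vector \eqn{(\lambda_0, \ldots, \lambda_{\kappa-1})}
#' collects the coefficients of \eqn{(s+p)^\kappa} below the leading one, so
#' the error obeys \eqn{e^{(\kappa)} + \sum_j \lambda_j e^{(j)} = 0}.
#'
#' @param kappa chain length (positive integer); vectorised — a vector of
#'   indices yields a list of gain vectors.
#' @param p designed pole (> 0), units 1/time.
#' @return numeric gain vector \eqn{(\lambda_0, \ldots)} or a list of them.
#' @examples
#' hurwitz_gains(2, 2)  # (4, 4): (s+2)^2 = s^2 + 4 s + 4
#' @export
hurwitz_gains <- function(kappa, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    stop("designed pole `p` must be a single positive number.")
  }
  one <- function(k) {
    k <- as.integer(k)
    stopifnot(k >= 1L)
    j <- 0:(k - 1L)
    stats::setNames(choose(k, j) * p^(k - j), paste0("lambda", j))
  }
  if (length(kappa) == 1L) one(kappa) else lapply(kappa, one)
}

# Validate that s^kappa + sum lambda_j s^j is Hurwitz.
assert_hurwitz <- function(lambda) {
  roots <- polyroot(c(lambda, 1))
  if (any(Re(roots) >= -1e-12)) {
    stop("gain vector (", paste(signif(lambda, 4), collapse = ", "),
         ") is not Hurwitz: closed-loop error would not decay.")
  }
  invisible(lambda)
}

#' Elementary tracking new-input law
#'
#' \eqn{v = \omega_r^{(\kappa)} - \sum_{j<\kappa} \lambda_j
#' (\omega^{(j)} - \omega_r^{(j)})} for one flat-output component.
#'
#' @param omega_jet numeric vector \eqn{(\omega, \dot\omega, \ldots,
#'   \omega^{(\kappa-1)})} of measured jets.
#' @param ref_jet numeric vector \eqn{(\omega_r, \ldots,
#'   \omega_r^{(\kappa)})} — one entry longer than \code{omega_jet}.
#' @param lambda gain vector of length \eqn{\kappa}.
#' @return the scalar new input \eqn{v}.
#' @export
tracking_v <- function(omega_jet, ref_jet, lambda) {
  k <- length(lambda)
  if (length(omega_jet) != k || length(ref_jet) != k + 1L) {
    stop("jet order mismatch: need ", k, " measured jets and ", k + 1L,
         " reference jets.")
  }
  ref_jet[k + 1L] - sum(lambda * (omega_jet - ref_jet[seq_len(k)]))
}

#' Flatness-based tracking controller
#'
#' Composes the elementary tracking law on each flat-output component with
#' the linearising feedback \eqn{u = A^{-1}(v - b)}.  In \code{"oracle"} mode
#' the law uses the true fluctuation jets (the full-knowledge assumption of
#' the pathwise laws); in \code{"mean"} mode every fluctuation term is set to
#' zero, leaving the law the agent can compute from the mean model.
#'
#' @param model a \code{"flat_model"}.
#' @param cert a flat \code{"flat_certificate"}.
#' @param reference a \code{"flat_reference"} whose component names match
#'   \code{cert$omega_names} (or are matched by position).
#' @param gains list of gain vectors (one per component) or a single pole
#'   passed to [hurwitz_gains()].
#' @param mode \code{"oracle"} or \code{"mean"}.
#' @return a \code{"flat_controller"}: a function \code{(t, x, jets)}
#'   returning the named input vector, carrying its metadata as fields.
#' @export
tracking_controller <- function(model, cert, reference, gains = 2,
                                mode = c("oracle", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cert, "flat_certificate"),
            inherits(reference, "flat_reference"))
  if (!cert$flat) stop("certificate verdict is not flat (", cert$reason, ").")
  m <- length(cert$omega)
  if (is.numeric(gains) && length(gains) == 1L) {
    gains <- hurwitz_gains(cert$kappa, gains)
    if (m == 1L) gains <- list(gains)
  }
  stopifnot(length(gains) == m)
  for (g in gains) assert_hurwitz(g)
  if (max(cert$kappa) > reference$max_order) {
    stop("reference must be differentiable to order ", max(cert$kappa), ".")
  }
  ref_comp <- names(reference$components)
  if (!all(cert$omega_names %in% ref_comp)) ref_comp <- cert$omega_names

  chains <- cert$chains
  A <- cert$A
  b <- cert$b
  if (mode == "mean") {
    jets_all <- model_jet_names(model, extra_exprs = c(
      unlist(chains, recursive = FALSE), as.list(A), b))
    zero <- stats::setNames(as.list(rep(0, length(jets_all))), jets_all)
    chains <- lapply(chains, function(ch) {
      lapply(ch, function(e) fold_expr(subst_expr(e, zero)))
    })
    A <- matrix(lapply(as.list(A), function(e) {
      fold_expr(subst_expr(e, zero))
    }), nrow = m, ncol = m)
    b <- lapply(b, function(e) fold_expr(subst_expr(e, zero)))
  }
  jet_names <- model_jet_names(model, extra_exprs = c(
    unlist(chains, recursive = FALSE), as.list(A), b))
  vars <- c(model$states, jet_names)
  chain_funs <- lapply(chains, function(ch) make_evaluator(ch, vars))
  A_fun <- make_evaluator(as.list(t(A)), vars)
  b_fun <- make_evaluator(b, vars)
  kappa <- cert$kappa
  inputs <- model$inputs

  law <- function(t, x, jets = NULL) {
    vals <- c(x, stats::setNames(rep(0, length(jet_names)), jet_names))
    if (!is.null(jets)) vals[names(jets)] <- jets
    v <- numeric(m)
    for (i in seq_len(m)) {
      omega_jet <- chain_funs[[i]](vals)
      ref_jet <- vapply(0:kappa[i], function(k) {
        ref_eval(reference, t, k, component = ref_comp[i])
      }, numeric(1L))
      v[i] <- tracking_v(omega_jet, ref_jet, gains[[i]])
    }
    A_num <- matrix(A_fun(vals), m, m, byrow = TRUE)
    b_num <- b_fun(vals)
    if (!all(is.finite(A_num)) || abs(det(A_num)) < 1e-12) {
      stop("decoupling matrix singular at t = ", signif(t, 6), ".")
    }
    stats::setNames(as.numeric(solve(A_num, v - b_num)), inputs)
  }
  new_controller(law, jet_names = jet_names, mode = mode,
                 kind = "tracking", gains = gains, reference = reference)
}

#' Open-loop controller from the functional parametrisation
#'
#' Substitutes the reference jets for the flat-output jets in the input
#' parametrisation \eqn{u = B(\omega\text{-jet}, \zeta\text{-jet})}; oracle
#' mode additionally substitutes the true fluctuation jets.
#'
#' @param par a \code{"flat_parametrisation"}.
#' @param reference a \code{"flat_reference"}.
#' @param mode \code{"oracle"} or \code{"mean"}.
#' @return a \code{"flat_controller"} ignoring the measured state.
#' @export
openloop_controller <- function(par, reference, mode = c("oracle", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(par, "flat_parametrisation"))
  exprs <- par$inputs
  vars0 <- unique(unlist(lapply(exprs, all.vars)))
  wjets <- vars0[is_jet_name(vars0) & jet_base(vars0) %in% par$omega_names]
  zjets <- setdiff(vars0, wjets)
  if (mode == "mean") {
    zero <- stats::setNames(as.list(rep(0, length(zjets))), zjets)
    exprs <- lapply(exprs, function(e) fold_expr(subst_expr(e, zero)))
    zjets <- character(0)
  }
  vars <- c(wjets, zjets)
  u_fun <- make_evaluator(exprs, vars)
  ref_comp <- names(reference$components)
  if (!all(par$omega_names %in% ref_comp)) ref_comp <- par$omega_names
  inputs <- names(par$inputs)
  law <- function(t, x, jets = NULL) {
    vals <- stats::setNames(rep(0, length(vars)), vars)
    for (w in wjets) {
      i <- match(jet_base(w), par$omega_names)
      vals[w] <- ref_eval(reference, t, jet_order(w),
                          component = ref_comp[i])
    }
    if (!is.null(jets)) {
      common <- intersect(names(jets), zjets)
      vals[common] <- jets[common]
    }
    stats::setNames(u_fun(vals), inputs)
  }
  new_controller(law, jet_names = zjets, mode = mode, kind = "open-loop",
                 gains = NULL, reference = reference)
}

#' Zero-action controller
#' @param inputs character vector of input names.
#' @return a \code{"flat_controller"} that always returns zero action.
#' @export
zero_controller <- function(inputs) {
  law <- function(t, x, jets = NULL) stats::setNames(rep(0, length(inputs)), inputs)
  new_controller(law, jet_names = character(0), mode = "mean",
                 kind = "zero-action", gains = NULL, reference = NULL)
}

new_controller <- function(law, jet_names, mode, kind, gains, reference) {
  structure(law, class = c("flat_controller", "function"),
            jet_names = jet_names, mode = mode, kind = kind,
            gains = gains, reference = reference)
}

# ---- closed-loop simulation ---------------------------------------------

#' Simulate a (closed-loop) random ODE pathwise
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of
#' \eqn{\dot x = \mathrm{rhs}(x, u(t,x), \zeta\text{-jet}(t))}, sample path
#' by sample path: the bound fluctuations are evaluated exactly (they are
#' trigonometric polynomials), so the integration is an ordinary, pathwise
#' one and is bit-reproducible given the bindings and the step.
#'
#' @param model a \code{"flat_model"}.
#' @param controller a \code{"flat_controller"} (or any function
#'   \code{(t, x, jets)} returning the named input vector).
#' @param signals named list binding each fluctuation base name to an
#'   \code{"srf"}, an [exo_signal()], or a constant.
#' @param x0 named initial state vector.
#' @param t_span length-2 time interval.
#' @param dt fixed step (> 0); the band-limited fluctuations have wavelength
#'   \eqn{\ge 0.1} in the study configurations, so the default resolves all
#'   spectral content.
#' @param reference optional \code{"flat_reference"}; adds reference and
#'   error columns for the model outputs whose names match its components.
#' @return a \code{"flat_trace"} tibble: time, states, inputs, outputs
#'   \code{y_*}, mean-predicted outputs \code{yhat_*}, observation
#'   discrepancies \code{eobs_*}, and (with a reference) \code{ref_*} and
#'   action discrepancies \code{eact_*}; metadata in attributes.
#' @export
simulate_closed_loop <- function(model, controller, signals = list(),
                                 x0, t_span, dt = 1e-3, reference = NULL) {
  stopifnot(inherits(model, "flat_model"), dt > 0)
  x0 <- x0[model$states]
  if (any(is.na(x0))) stop("`x0` must supply every state by name.")
  ctrl_jets <- attr(controller, "jet_names") %||% character(0)
  model_jets <- model_jet_names(model)
  out_jets <- unique(unlist(lapply(model$outputs, all.vars)))
  out_jets <- out_jets[is_jet_name(out_jets) & jet_base(out_jets) %in% model$flucts]
  all_jets <- unique(c(model_jets, ctrl_jets, out_jets))
  jets_fun <- make_jet_evaluator(all_jets, signals)

  vars <- c(model$states, model$inputs, all_jets)
  rhs_fun <- make_evaluator(model$rhs[model$states], vars)
  out_names <- names(model$outputs)
  y_fun <- make_evaluator(model$outputs, vars)
  zero_jets <- stats::setNames(rep(0, length(all_jets)), all_jets)

  n_steps <- max(1L, round(diff(t_span) / dt))
  times <- t_span[1L] + dt * (0:n_steps)
  nx <- length(x0)
  nu <- length(model$inputs)
  X <- matrix(NA_real_, n_steps + 1L, nx, dimnames = list(NULL, model$states))
  U <- matrix(NA_real_, n_steps + 1L, nu,
              dimnames = list(NULL, model$inputs))
  Y <- matrix(NA_real_, n_steps + 1L, length(out_names))
  Yhat <- Y

  deriv <- function(t, x) {
    jets <- jets_fun(t)
    u <- controller(t, x, jets)
    list(dx = rhs_fun(c(x, u, jets)), u = u, jets = jets)
  }
  x <- x0
  for (s in 0:n_steps) {
    t <- times[s + 1L]
    st <- deriv(t, x)
    X[s + 1L, ] <- x
    U[s + 1L, ] <- st$u
    if (length(out_names) > 0L) {
      Y[s + 1L, ] <- y_fun(c(x, st$u, st$jets))
      Yhat[s + 1L, ] <- y_fun(c(x, st$u, zero_jets))
    }
    if (any(!is.finite(x))) {
      stop("non-finite state at t = ", signif(t, 8),
           "; simulation aborted.")
    }
    if (s == n_steps) break
    k1 <- st$dx
    k2 <- deriv(t + dt / 2, x + dt / 2 * k1)$dx
    k3 <- deriv(t + dt / 2, x + dt / 2 * k2)$dx
    k4 <- deriv(t + dt, x + dt * k3)$dx
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  tr <- tibble::as_tibble(as.data.frame(X))
  tr <- tibble::add_column(tr, t = times, .before = 1L)
  for (j in seq_len(nu)) tr[[paste0("u_", model$inputs[j])]] <- U[, j]
  if (length(out_names) > 0L) {
    for (j in seq_along(out_names)) {
      tr[[paste0("y_", out_names[j])]] <- Y[, j]
      tr[[paste0("yhat_", out_names[j])]] <- Yhat[, j]
      tr[[paste0("eobs_", out_names[j])]] <- Y[, j] - Yhat[, j]
    }
  }
  if (!is.null(reference)) {
    for (nm in intersect(out_names, names(reference$components))) {
      rv <- ref_eval(reference, times, 0L, component = nm)
      tr[[paste0("ref_", nm)]] <- rv
      tr[[paste0("eact_", nm)]] <- Y[, match(nm, out_names)] - rv
    }
  }
  structure(tr,
            class = c("flat_trace", class(tr)),
            dt = dt, model = model$name,
            controller = attr(controller, "kind") %||% "custom",
            mode = attr(controller, "mode") %||% NA_character_,
            gains = attr(controller, "gains"),
            signals = names(signals))
}

#' Simulate a model under a prescribed input path
#'
#' @param model a \code{"flat_model"}.
#' @param u_fun function of time returning the named input vector.
#' @inheritParams simulate_closed_loop
#' @return a \code{"flat_trace"}.
#' @export
simulate_open_loop <- function(model, u_fun, signals = list(), x0, t_span,
                               dt = 1e-3, reference = NULL) {
  ctrl <- new_controller(function(t, x, jets = NULL) u_fun(t),
                         jet_names = character(0), mode = "mean",
                         kind = "prescribed-input", gains = NULL,
                         reference = reference)
  simulate_closed_loop(model, ctrl, signals, x0, t_span, dt, reference)
}

#' @export
print.flat_trace <- function(x, ...) {
  cat("<simulation trace: ", attr(x, "model"), ", ",
      attr(x, "controller"), ">\n", sep = "")
  NextMethod()
}

# ---- discrepancy and risk metrics ---------------------------------------

#' Active-inference discrepancy metrics along a trace
#'
#' Reports the observation discrepancy \eqn{\varepsilon_{obs} = y - \hat y}
#' (sensed minus mean-predicted output) and the action discrepancy
#' \eqn{\varepsilon_{act} = y - y_r} path, their integrated squared norms,
#' and the Gaussian risk proxy
#' \deqn{\mathrm{Risk} \approx \int \tfrac12\,\varepsilon_{act}^\top \Pi\,
#'   \varepsilon_{act}\, dt,}
#' the pointwise Kullback-Leibler divergence between Gaussian anticipated and
#' goal-conditioned outcome densities with equal covariances and precision
#' \eqn{\Pi}, integrated along the path by the trapezoid rule.
#'
#' @param trace a \code{"flat_trace"} containing \code{eact_*} columns.
#' @param Pi output precision matrix (symmetric positive definite); default
#'   identity.
#' @return a \code{"flat_metrics"} list: \code{paths} (tibble of t and the
#'   discrepancy columns) and scalar summaries \code{ise_act},
#'   \code{ise_obs}, \code{risk}, \code{max_eact}, \code{rms_eact}.
#' @export
discrepancy_metrics <- function(trace, Pi = NULL) {
  eact_cols <- grep("^eact_", names(trace), value = TRUE)
  eobs_cols <- grep("^eobs_", names(trace), value = TRUE)
  if (length(eact_cols) == 0L) {
    stop("trace has no action-discrepancy columns; simulate with a reference.")
  }
  p <- length(eact_cols)
  if (is.null(Pi)) Pi <- diag(p)
  Pi <- as.matrix(Pi)
  if (!isSymmetric(unname(Pi)) || any(eigen(Pi, TRUE, TRUE)$values <= 0)) {
    stop("`Pi` must be symmetric positive definite.")
  }
  t <- trace$t
  E <- as.matrix(trace[eact_cols])
  quad <- rowSums((E %*% Pi) * E)
  risk <- pracma::trapz(t, quad / 2)
  ise_act <- pracma::trapz(t, rowSums(E^2))
  ise_obs <- if (length(eobs_cols) > 0L) {
    pracma::trapz(t, rowSums(as.matrix(trace[eobs_cols])^2))
  } else {
    NA_real_
  }
  enorm <- sqrt(rowSums(E^2))
  structure(
    list(paths = tibble::as_tibble(trace[c("t", eobs_cols, eact_cols)]),
         ise_act = ise_act, ise_obs = ise_obs, risk = risk,
         max_eact = max(enorm), rms_eact = sqrt(mean(enorm^2))),
    class = "flat_metrics"
  )
}

#' @export
print.flat_metrics <- function(x, ...) {
  cat("<discrepancy metrics>\n")
  cat(sprintf("  risk proxy      : %.6g\n", x$risk))
  cat(sprintf("  ISE (action)    : %.6g\n", x$ise_act))
  if (is.finite(x$ise_obs)) {
    cat(sprintf("  ISE (observation): %.6g\n", x$ise_obs))
  }
  cat(sprintf("  max |eps_act|   : %.6g\n", x$max_eact))
  cat(sprintf("  RMS |eps_act|   : %.6g\n", x$rms_eact))
  invisible(x)
}

#' One-row summary of a metrics object
#' @param x a \code{"flat_metrics"}.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance flat_metrics
#' @export
glance.flat_metrics <- function(x, ...) {
  tibble::tibble(risk = x$risk, ise_act = x$ise_act, ise_obs = x$ise_obs,
                 max_eact = x$max_eact, rms_eact = x$rms_eact)
}

#' Fit the exponential decay rate of the tracking-error norm
#'
#' Log-linear fit of \eqn{\|\varepsilon_{act}\|} over the central window
#' \eqn{[0.2 T, 0.8 T]} of the trace, truncated at a noise floor, used to
#' recover the designed closed-loop pole from simulations.
#'
#' @param trace a \code{"flat_trace"} with \code{eact_*} columns.
#' @param floor values below this are excluded from the fit.
#' @param window fraction window of the time span used for the fit.
#' @return the fitted decay rate (positive for decaying errors).
#' @export
fit_decay_rate <- function(trace, floor = 1e-11, window = c(0.2, 0.8)) {
  eact_cols <- grep("^eact_", names(trace), value = TRUE)
  e <- sqrt(rowSums(as.matrix(trace[eact_cols])^2))
  t <- trace$t
  T <- diff(range(t))
  keep <- t >= t[1L] + window[1L] * T & t <= t[1L] + window[2L] * T &
    e > floor
  if (sum(keep) < 5L) stop("not enough points above the floor for the fit.")
  fit <- stats::lm(log(e[keep]) ~ t[keep])
  -unname(stats::coef(fit)[2L])
}
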