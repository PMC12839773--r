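# Generalised coordinates of motion: a linearised (first-order)
# differentiation d1 acting on polynomials in jet symbols, and the Bergman
# glucose-insulin demonstration of when the linearised chain suffices for
# tracking (Brunovsky index <= 2) and when it fails (index 3: the full third
# derivative carries a -2 X' G' cross term that d1 truncates).
#
# Expressions are held as polynomials over jet symbols "name_d<k>"; each
# base name has a kind: "var" (internal state), "fluct" (exogenous signal),
# "input" (action), with parameters substituted numerically.  The truncation
# rule implemented for d1: a monomial is deleted iff it contains two or more
# differentiated factors, counting multiplicity — all cross products of
# derivatives vanish.  On expressions linear in the variables d1 coincides
# with full time differentiation, and repeated application realises the
# local linear approximation d^k/dt^k F(xi) = grad F(xi) . xi^(k); chains of
# Brunovsky index <= 2 are untouched by the truncation.

# ---- jet polynomials -----------------------------------------------------

jp_zero <- function() list()

jp_const <- function(c) if (c == 0) list() else list(list(c = c, p = integer(0)))

jp_sym <- function(name, order = 0L) {
  p <- stats::setNames(1L, jet_name(name, order))
  list(list(c = 1, p = p))
}

jp_norm <- function(poly) {
  if (length(poly) == 0L) return(poly)
  canon <- function(p) {
    p <- p[p != 0L]
    if (length(p) > 0L) p <- p[order(names(p))]
    p
  }
  keys <- vapply(poly, function(tm) {
    p <- canon(tm$p)
    paste(names(p), p, sep = "^", collapse = "*")
  }, character(1L))
  out <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    ctot <- sum(vapply(poly[idx], function(tm) tm$c, numeric(1L)))
    if (abs(ctot) > 1e-14) {
      out[[length(out) + 1L]] <- list(c = ctot, p = canon(poly[[idx[1L]]]$p))
    }
  }
  out
}

jp_add <- function(a, b) jp_norm(c(a, b))

jp_scale <- function(a, s) {
  lapply(a, function(tm) list(c = tm$c * s, p = tm$p))
}

jp_mul <- function(a, b) {
  out <- list()
  for (ta in a) for (tb in b) {
    p <- ta$p
    for (nm in names(tb$p)) p[nm] <- (p[nm] %||NA% 0L) + tb$p[[nm]]
    out[[length(out) + 1L]] <- list(c = ta$c * tb$c, p = p)
  }
  jp_norm(out)
}

`%||NA%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

jp_pow <- function(a, k) {
  out <- jp_const(1)
  for (i in seq_len(k)) out <- jp_mul(out, a)
  out
}

#' Parse an expression into a jet polynomial
#'
#' @param expr quoted expression or string: polynomial in jet symbols (plain
#'   symbols are order-0), with numeric coefficients, \code{+ - * ^} and
#'   division by numbers.
#' @param kinds named character vector mapping base names to
#'   \code{"var"}, \code{"fluct"} or \code{"input"}.
#' @return a \code{"jet_poly"} object.
#' @export
jet_poly <- function(expr, kinds) {
  expr <- parse_model_expr(expr)
  rec <- function(e) {
    if (is.numeric(e)) return(jp_const(as.numeric(e)))
    if (is.name(e)) {
      nm <- as.character(e)
      base <- if (is_jet_name(nm)) jet_base(nm) else nm
      ordr <- if (is_jet_name(nm)) jet_order(nm) else 0L
      if (!base %in% names(kinds)) {
        stop("symbol `", base, "` has no declared kind.")
      }
      return(jp_sym(base, ordr))
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (op == "(") return(rec(e[[2L]]))
      if (op == "+" && length(e) == 2L) return(rec(e[[2L]]))
      if (op == "-" && length(e) == 2L) return(jp_scale(rec(e[[2L]]), -1))
      if (op == "+") return(jp_add(rec(e[[2L]]), rec(e[[3L]])))
      if (op == "-") return(jp_add(rec(e[[2L]]), jp_scale(rec(e[[3L]]), -1)))
      if (op == "*") return(jp_mul(rec(e[[2L]]), rec(e[[3L]])))
      if (op == "/") {
        den <- e[[3L]]
        if (!is.numeric(den)) stop("only division by numbers is supported.")
        return(jp_scale(rec(e[[2L]]), 1 / as.numeric(den)))
      }
      if (op == "^") {
        k <- e[[3L]]
        if (!is.numeric(k) || k != round(k) || k < 0) {
          stop("only non-negative integer powers are supported.")
        }
        return(jp_pow(rec(e[[2L]]), as.integer(k)))
      }
      stop("`", op, "` is outside the polynomial jet grammar.")
    }
    stop("unsupported construct: ", deparse(e))
  }
  structure(list(terms = jp_norm(rec(expr)), kinds = kinds),
            class = "jet_poly")
}

jp_wrap <- function(terms, kinds) {
  structure(list(terms = jp_norm(terms), kinds = kinds), class = "jet_poly")
}

#' Convert a jet polynomial back to an R expression
#' @param p a \code{"jet_poly"}.
#' @return a language object.
#' @export
jet_poly_expr <- function(p) {
  stopifnot(inherits(p, "jet_poly"))
  if (length(p$terms) == 0L) return(0)
  kinds <- p$kinds
  render <- function(nm) {
    # order-0 states and inputs print as bare symbols (the model convention);
    # exogenous signals keep their explicit jet form at every order
    base <- jet_base(nm)
    if (jet_order(nm) == 0L && kinds[[base]] %in% c("var", "input")) {
      as.name(base)
    } else {
      as.name(nm)
    }
  }
  term_expr <- function(tm) {
    e <- NULL
    for (nm in names(tm$p)) {
      f <- if (tm$p[[nm]] == 1L) render(nm) else {
        call("^", render(nm), as.integer(tm$p[[nm]]))
      }
      e <- if (is.null(e)) f else call("*", e, f)
    }
    if (is.null(e)) return(tm$c)
    if (tm$c == 1) e else call("*", tm$c, e)
  }
  # order terms deterministically for readable output
  keys <- vapply(p$terms, function(tm) paste(names(tm$p), collapse = ","),
                 character(1L))
  terms <- p$terms[order(keys)]
  out <- term_expr(terms[[1L]])
  for (tm in terms[-1L]) {
    if (tm$c < 0) {
      tm$c <- -tm$c
      out <- call("-", out, term_expr(tm))
    } else {
      out <- call("+", out, term_expr(tm))
    }
  }
  out
}

#' @export
print.jet_poly <- function(x, ...) {
  cat(deparse1(jet_poly_expr(x)), "\n")
  invisible(x)
}

# First-order truncation: a monomial vanishes iff it carries two or more
# differentiated factors (counting multiplicity) — every cross product of
# derivatives, e.g. z' zeta', z' z', is set to zero, while a single
# differentiated factor of any order survives with arbitrary undifferentiated
# cofactors (which is what makes repeated application produce the local
# linear approximation grad F . xi^(k)).
term_drop_first_order <- function(tm, kinds) {
  if (length(tm$p) == 0L) return(FALSE)
  orders <- jet_order(names(tm$p))
  pw <- as.integer(tm$p)
  sum(pw[orders > 0L]) >= 2L
}

#' Differentiate a jet polynomial in time
#'
#' \code{mode = "full"} is the ordinary total derivative in jet coordinates
#' (each symbol advances one order by the product rule).  \code{mode =
#' "first_order"} is the linearised differentiation d1: the product rule is
#' applied and every monomial violating the first-order truncation rule is
#' deleted.
#'
#' @param p a \code{"jet_poly"}.
#' @param mode \code{"full"} or \code{"first_order"}.
#' @return a \code{"jet_poly"}.
#' @export
d1 <- function(p, mode = c("first_order", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "jet_poly"))
  kinds <- p$kinds
  out <- list()
  for (tm in p$terms) {
    for (nm in names(tm$p)) {
      base <- jet_base(nm)
      if (kinds[[base]] == "input") {
        stop("differentiating the action symbol `", base,
             "` is not supported (the action is not a time-differentiated ",
             "quantity in these chains).")
      }
      e <- tm$p[[nm]]
      nxt <- jet_name(base, jet_order(nm) + 1L)
      np <- tm$p
      np[nm] <- np[nm] - 1L
      np[nxt] <- (np[nxt] %||NA% 0L) + 1L
      out[[length(out) + 1L]] <- list(c = tm$c * e, p = np[np != 0L])
    }
  }
  out <- jp_norm(out)
  if (mode == "first_order") {
    out <- out[!vapply(out, term_drop_first_order, logical(1L),
                       kinds = kinds)]
  }
  jp_wrap(out, kinds)
}

jp_subst_sym <- function(p, nm, rep_poly) {
  out <- list()
  for (tm in p$terms) {
    if (!nm %in% names(tm$p)) {
      out[[length(out) + 1L]] <- tm
      next
    }
    k <- tm$p[[nm]]
    rest <- tm$p[names(tm$p) != nm]
    base <- list(list(c = tm$c, p = rest))
    repk <- jp_pow(rep_poly$terms, k)
    out <- c(out, jp_mul(base, repk))
  }
  jp_wrap(out, p$kinds)
}

jp_equal <- function(a, b) {
  d <- jp_add(a$terms, jp_scale(b$terms, -1))
  length(jp_norm(d)) == 0L
}

# ---- model-level chains --------------------------------------------------

model_kinds <- function(model) {
  stats::setNames(
    c(rep("var", length(model$states)),
      rep("fluct", length(model$flucts)),
      rep("input", length(model$inputs))),
    c(model$states, model$flucts, model$inputs)
  )
}

# Replace every first-order *state* symbol by the model dynamics (so the
# result lives at order zero plus exogenous jets and inputs).
jp_subst_dynamics_first <- function(p, dyn) {
  repeat {
    syms <- unique(unlist(lapply(p$terms, function(tm) names(tm$p))))
    todo <- syms[jet_base(syms) %in% names(dyn) & jet_order(syms) == 1L]
    if (length(todo) == 0L) return(p)
    p <- jp_subst_sym(p, todo[1L], dyn[[jet_base(todo[1L])]])
  }
}

# Lazy, memoised substituted derivatives of the states: the k-th derivative
# of state s as an order-0 expression (states, exogenous jets, inputs).
# Only the (state, order) pairs actually requested are differentiated, so
# chains that merely *use* an input-carrying equation never attempt to
# differentiate the action.
make_state_deriv_fn <- function(model, kinds) {
  dyn <- lapply(model$states, function(s) jet_poly(model$rhs[[s]], kinds))
  names(dyn) <- model$states
  cache <- new.env(parent = emptyenv())
  get_deriv <- function(s, k) {
    key <- paste0(s, "|", k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- if (k == 1L) {
      dyn[[s]]
    } else {
      jp_subst_dynamics_first(d1(get_deriv(s, k - 1L), mode = "full"), dyn)
    }
    cache[[key]] <- val
    val
  }
  get_deriv
}

# Replace every state derivative symbol (order >= 1), leaving an expression
# in order-0 states, exogenous jets and inputs.
jp_subst_all_state_derivs <- function(p, model, get_deriv) {
  repeat {
    syms <- unique(unlist(lapply(p$terms, function(tm) names(tm$p))))
    todo <- syms[jet_base(syms) %in% model$states & jet_order(syms) >= 1L]
    if (length(todo) == 0L) return(p)
    ords <- jet_order(todo)
    nm <- todo[which.max(ords)]
    p <- jp_subst_sym(p, nm, get_deriv(jet_base(nm), jet_order(nm)))
  }
}

#' Full and linearised derivative chains of a model output
#'
#' Computes the first \code{k} time derivatives of an output expression in
#' jet coordinates twice: with the full total derivative and with the
#' linearised differentiation d1.  The first derivative substitutes the
#' model dynamics (so both chains start from the same expression); higher
#' derivatives keep state-derivative symbols, which is where the two
#' operators part ways.  The per-order difference (full minus linearised) is
#' returned, together with fully substituted chains (every state-derivative
#' symbol resolved through the dynamics) ready for numeric use in control
#' laws.
#'
#' @param model a \code{"flat_model"}.
#' @param output output expression (default: the model's first output).
#' @param k chain length (>= 1).
#' @return a list with \code{full}, \code{lin}, \code{diff} (jet
#'   polynomials, one per order) and \code{full_sub}, \code{lin_sub}
#'   (substituted expressions in states, exogenous jets and inputs).
#' @export
lin_derivative_chain <- function(model, output = NULL, k = 3L) {
  stopifnot(inherits(model, "flat_model"), k >= 1L)
  if (is.null(output)) output <- model$outputs[[1L]]
  kinds <- model_kinds(model)
  dyn <- lapply(model$states, function(s) jet_poly(model$rhs[[s]], kinds))
  names(dyn) <- model$states
  h <- jet_poly(output, kinds)
  first <- jp_subst_dynamics_first(d1(h, mode = "full"), dyn)
  full <- lin <- vector("list", k)
  full[[1L]] <- lin[[1L]] <- first
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      full[[j + 1L]] <- d1(full[[j]], mode = "full")
      lin[[j + 1L]] <- d1(lin[[j]], mode = "first_order")
    }
  }
  diffs <- lapply(seq_len(k), function(j) {
    jp_wrap(jp_add(full[[j]]$terms, jp_scale(lin[[j]]$terms, -1)), kinds)
  })
  get_deriv <- make_state_deriv_fn(model, kinds)
  full_sub <- lapply(full, function(p) {
    jet_poly_expr(jp_subst_all_state_derivs(p, model, get_deriv))
  })
  lin_sub <- lapply(lin, function(p) {
    jet_poly_expr(jp_subst_all_state_derivs(p, model, get_deriv))
  })
  list(full = full, lin = lin, diff = diffs,
       full_sub = full_sub, lin_sub = lin_sub)
}

# ---- Bergman minimal model ----------------------------------------------

#' Bergman minimal model parameters (synthetic defaults)
#'
#' Three-state glucose-insulin minimal model with a meal disturbance.  The
#' rate constants and basal levels are documented synthetic values of
#' literature-plausible magnitude (rates of order 1e-2 to 1e-1 per minute,
#' basal glucose of order 100 mg/dL, basal insulin of order 10 mU/L), chosen
#' so a meal visibly excites the insulin-action/glucose cross term; all are
#' overridable.
#'
#' @param k1,k2,k3,k4 rate constants, 1/min (> 0).
#' @param Gb,Ib basal glucose (mg/dL) and insulin (mU/L).
#' @param B meal amplitude (mg/dL/min), \code{gamma_meal} onset stiffness
#'   (1/min), \code{t_bol} bolus/meal time (min), \code{d_meal} decay rate
#'   (1/min).
#' @return a named list of class \code{"bergman_params"}.
#' @export
bergman_params <- function(k1 = 0.03, k2 = 0.02, k3 = 0.01, k4 = 0.05,
                           Gb = 110, Ib = 10,
                           B = 5, gamma_meal = 0.8, t_bol = 30,
                           d_meal = 0.06) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0, k4 > 0, B >= 0, gamma_meal > 0,
            d_meal > 0)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, Gb = Gb, Ib = Ib,
                 B = B, gamma_meal = gamma_meal, t_bol = t_bol,
                 d_meal = d_meal),
            class = "bergman_params")
}

#' Build the Bergman minimal model
#'
#' \deqn{\dot G = -k_1 (G - G_b) - X G + D(t)}
#' \deqn{\dot X = -k_2 X + k_3 (I - I_b)}
#' \deqn{\dot I = -k_4 (I - I_b) + u}
#' with blood glucose \eqn{G}, tissue insulin action \eqn{X}, plasma insulin
#' \eqn{I}, insulin infusion \eqn{u} and meal input \eqn{D} (an exogenous
#' known signal, channel name \code{Dm}).  Flat with \eqn{\omega = G},
#' Brunovsky index 3: the glucose equation must be differentiated exactly
#' twice more before the action appears.
#'
#' @param params a [bergman_params()] list.
#' @return a \code{"flat_model"}.
#' @export
build_bergman <- function(params = bergman_params()) {
  control_affine_model(
    states = c("G", "X", "I"),
    inputs = "u",
    flucts = "Dm",
    rhs = list(
      G = quote(-k1 * (G - Gb) - X * G + Dm_d0),
      X = quote(-k2 * X + k3 * (I - Ib)),
      I = quote(-k4 * (I - Ib) + u)
    ),
    outputs = list(G = quote(G)),
    params = params[c("k1", "k2", "k3", "k4", "Gb", "Ib")],
    name = "Bergman minimal model"
  )
}

#' Meal disturbance signal
#'
#' \eqn{D(t) = \tfrac B2 (1 + \tanh(\gamma (t - t_{bol})))\,
#' e^{-d_{meal} (t - t_{bol})}}: a smooth bolus onset with exponential
#' washout.  Closed-form derivatives to order 3.
#'
#' @param params a [bergman_params()] list.
#' @return an [exo_signal()].
#' @export
bergman_meal <- function(params = bergman_params()) {
  B <- params$B; g <- params$gamma_meal
  tb <- params$t_bol; dm <- params$d_meal
  exo_signal(function(t, order) {
    s <- tanh(g * (t - tb))
    sech2 <- 1 - s^2
    E <- exp(-dm * (t - tb))
    S0 <- (B / 2) * (1 + s)
    S1 <- (B / 2) * g * sech2
    S2 <- -(B) * g^2 * s * sech2
    S3 <- -(B) * g^3 * sech2 * (1 - 3 * s^2)
    E1 <- -dm * E
    E2 <- dm^2 * E
    E3 <- -dm^3 * E
    switch(as.character(order),
      "0" = S0 * E,
      "1" = S1 * E + S0 * E1,
      "2" = S2 * E + 2 * S1 * E1 + S0 * E2,
      "3" = S3 * E + 3 * S2 * E1 + 3 * S1 * E2 + S0 * E3,
      stop("meal signal supplies derivatives to order 3.")
    )
  }, max_order = 3L)
}

#' Compare flatness-based and generalised-coordinate glucose tracking
#'
#' Paired noise-free simulations of the Bergman model under a glucose
#' reference: the flatness-based tracking law (exact third-derivative chain)
#' versus the law built from the linearised (generalised-coordinate) third
#' derivative at matched gains.  Both laws share the measured derivative
#' chains up to order two (where full and linearised differentiation agree);
#' they differ exactly by the truncated cross term \eqn{-2 \dot X \dot G},
#' which steers the generalised-coordinate error dynamics whenever the run
#' excites \eqn{\dot X \dot G \ne 0}.
#'
#' @param params a [bergman_params()] list.
#' @param reference a \code{"flat_reference"} for G (default: a sigmoid
#'   descent from 140 to 100 mg/dL crossing the meal window).
#' @param gains pole (1/min) or a length-3 gain vector.
#' @param meal include the meal disturbance?
#' @param t_span,dt span (min) and step.
#' @param steady_window fraction of the span treated as the steady window
#'   for the RMS comparison.
#' @return a list of class \code{"bergman_demo"}: traces for both laws, the
#'   driving-term path, steady-window RMS errors, and the symbolic
#'   jet-level discrepancy.
#' @export
bergman_demo <- function(params = bergman_params(), reference = NULL,
                         gains = 0.5, meal = TRUE,
                         t_span = c(0, 120), dt = 0.02,
                         steady_window = 0.5) {
  model <- build_bergman(params)
  if (is.null(reference)) {
    reference <- reference_sigmoid(xl = 100, xh = 140, gamma = 0.1,
                                   t_raise = mean(t_span), component = "G")
    # descending: mirror in time by flipping around t_raise
    f <- reference$components$G
    reference$components$G <- function(t, order) {
      v <- f(2 * mean(t_span) - t, order)
      if (order %% 2L == 1L) -v else v
    }
  }
  mealsig <- if (meal) bergman_meal(params) else exo_zero()
  signals <- list(Dm = mealsig)
  cert <- brunovsky_analysis(model, list(quote(G)), omega_names = "G")
  stopifnot(cert$flat, cert$kappa == 3L)
  if (length(gains) == 1L) gains <- hurwitz_gains(3L, gains)
  assert_hurwitz(gains)

  ctrl_flat <- tracking_controller(model, cert, reference,
                                   gains = list(gains), mode = "oracle")
  chains <- lin_derivative_chain(model, quote(G), k = 3L)
  ctrl_gc <- gc_tracking_controller(model, chains, reference, gains)

  par <- functional_parametrisation(model, cert)
  x0 <- oculomotor_state_on_reference(par, reference, t_span[1L], signals)
  tr_flat <- simulate_closed_loop(model, ctrl_flat, signals, x0, t_span, dt,
                                  reference = reference)
  tr_gc <- simulate_closed_loop(model, ctrl_gc, signals, x0, t_span, dt,
                                reference = reference)

  # driving term -2 Xdot Gdot along the generalised-coordinate run
  kinds <- model_kinds(model)
  fX <- make_evaluator(list(model$rhs$X), c(model$states))
  fG <- make_evaluator(list(model$rhs$G),
                       c(model$states, "Dm_d0"))
  Dm0 <- exo_eval(mealsig, tr_gc$t, 0L)
  if (length(Dm0) == 1L) Dm0 <- rep(Dm0, nrow(tr_gc))
  drive <- -2 *
    vapply(seq_len(nrow(tr_gc)), function(i) {
      fX(c(G = tr_gc$G[i], X = tr_gc$X[i], I = tr_gc$I[i]))
    }, numeric(1L)) *
    vapply(seq_len(nrow(tr_gc)), function(i) {
      fG(c(G = tr_gc$G[i], X = tr_gc$X[i], I = tr_gc$I[i], Dm_d0 = Dm0[i]))
    }, numeric(1L))

  sw <- tr_flat$t >= t_span[1L] + steady_window * diff(t_span)
  rms <- function(e) sqrt(mean(e^2))
  structure(
    list(trace_flat = tr_flat, trace_gc = tr_gc,
         drive = tibble::tibble(t = tr_gc$t, drive = drive),
         rms_flat = rms(tr_flat$eact_G[sw]),
         rms_gc = rms(tr_gc$eact_G[sw]),
         jet_discrepancy = chains$diff[[3L]],
         gains = gains, params = params, meal = meal),
    class = "bergman_demo"
  )
}

# Tracking law built on the linearised third derivative: v as in the flat
# law (shared measured chains to order 2), but u solves lin_sub[[3]] = v.
gc_tracking_controller <- function(model, chains, reference, lambda) {
  e3 <- chains$lin_sub[[3L]]
  meas <- chains$full_sub[1:2]
  jetn <- unique(unlist(lapply(c(list(e3), meas), function(e) {
    v <- all.vars(e)
    v[is_jet_name(v) & jet_base(v) %in% model$flucts]
  })))
  vars <- c(model$states, model$inputs, jetn)
  c1_expr <- d_partial(e3, model$inputs[1L])
  c0_expr <- fold_expr(subst_expr(
    e3, stats::setNames(list(0), model$inputs[1L])))
  meas_fun <- make_evaluator(c(model$outputs[1L], meas), vars)
  c_fun <- make_evaluator(list(c0_expr, c1_expr), vars)
  comp <- names(reference$components)[1L]
  law <- function(t, x, jets = NULL) {
    vals <- c(x, stats::setNames(rep(0, length(model$inputs) + length(jetn)),
                                 c(model$inputs, jetn)))
    if (!is.null(jets)) vals[names(jets)] <- jets
    oj <- meas_fun(vals)
    rj <- vapply(0:3, function(k) ref_eval(reference, t, k, component = comp),
                 numeric(1L))
    v <- tracking_v(oj, rj, lambda)
    cc <- c_fun(vals)
    stats::setNames((v - cc[1L]) / cc[2L], model$inputs[1L])
  }
  new_controller(law, jet_names = jetn, mode = "oracle",
                 kind = "generalised-coordinate tracking",
                 gains = list(lambda), reference = reference)
}

#' @export
print.bergman_demo <- function(x, ...) {
  cat("<Bergman tracking comparison>\n")
  cat("  jet-level discrepancy (full - linearised, order 3): ",
      deparse1(jet_poly_expr(x$jet_discrepancy)), "\n", sep = "")
  cat(sprintf("  steady RMS error: flatness-based %.3g | generalised-coordinate %.3g\n",
              x$rms_flat, x$rms_gc))
  cat("  meal: ", x$meal, "\n", sep = "")
  invisible(x)
}

#' Longitudinal car model (cruise control)
#'
#' \eqn{M \dot V_x = -F(V_x) + u/r}: the action is already present in the
#' dynamics, \eqn{\kappa = 1}, so full and linearised differentiation give
#' the same tracking law.
#'
#' @param M mass (kg), \code{r} wheel radius (m), \code{c1,c2} linear and
#'   quadratic friction coefficients.
#' @return a \code{"flat_model"}.
#' @export
build_car <- function(M = 1200, r = 0.3, c1 = 30, c2 = 1.5) {
  control_affine_model(
    states = "Vx",
    inputs = "u",
    rhs = list(Vx = quote((-(c1 * Vx + c2 * Vx^2) + u / r) / M)),
    outputs = list(Vx = quote(Vx)),
    params = list(M = M, r = r, c1 = c1, c2 = c2),
    name = "car longitudinal model"
  )
}
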