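# Control-affine stochastic generative models.
#
# A model holds symbolic state equations
#     dx/dt = f(x, theta) + G(x, theta) u + N(zeta-jet)
# stored as one right-hand-side expression per state (affinity in u is
# validated, not assumed), plus output expressions y = h(x, zeta, theta).
# Exogenous smooth signals (fluctuations, known disturbances) enter through
# jet symbols "<name>_d<k>" carrying formal derivatives of any order; setting
# every jet symbol to zero yields the mean (deterministic) model.

MODEL_FUN_WHITELIST <- c(
  "+", "-", "*", "/", "^", "(",
  "sin", "cos", "tan", "exp", "log", "sqrt",
  "asin", "acos", "atan", "sinh", "cosh"
)

parse_model_expr <- function(x) {
  if (is.language(x) || is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    e <- tryCatch(str2lang(x), error = function(cnd) {
      stop("cannot parse expression: ", x, call. = FALSE)
    })
    return(e)
  }
  stop("expressions must be quoted calls or single strings.")
}

check_expr_grammar <- function(e, where = "expression") {
  walk <- function(x) {
    if (is.numeric(x) || is.name(x)) return(invisible(NULL))
    if (is.call(x)) {
      fn <- as.character(x[[1L]])
      if (!fn %in% MODEL_FUN_WHITELIST) {
        stop("function `", fn, "` is not in the model grammar (", where, ").",
             call. = FALSE)
      }
      for (a in as.list(x)[-1L]) walk(a)
      return(invisible(NULL))
    }
    stop("unsupported construct in ", where, ": ", deparse(x), call. = FALSE)
  }
  walk(e)
  invisible(NULL)
}

#' Define a control-affine stochastic generative model
#'
#' @param states character vector of state symbol names.
#' @param inputs character vector of input (action) symbol names.
#' @param flucts character vector of exogenous-signal base names; the signal
#'   \code{"z"} appears in expressions through jet symbols \code{z_d0}
#'   (the signal), \code{z_d1} (its derivative), and so on.
#' @param rhs named list (one entry per state, in state order) of right-hand
#'   sides, as quoted R expressions or strings in the documented infix grammar
#'   (arithmetic plus elementary functions).
#' @param outputs named list of output expressions in states, fluctuation
#'   jets and parameters.
#' @param params named numeric vector/list of parameter values, substituted
#'   into every expression at build time.
#' @param name optional model name.
#' @return an object of class \code{"flat_model"}.
#' @examples
#' build_double_integrator()
#' @export
control_affine_model <- function(states, inputs, flucts = character(),
                                 rhs, outputs = list(), params = list(),
                                 name = "model") {
  states <- as.character(states)
  inputs <- as.character(inputs)
  flucts <- as.character(flucts)
  params <- as.list(params)
  if (length(rhs) != length(states)) {
    stop("`rhs` must have one entry per state (", length(states), ").")
  }
  if (is.null(names(rhs)) || !identical(sort(names(rhs)), sort(states))) {
    names(rhs) <- states
  }
  rhs <- lapply(rhs[states], parse_model_expr)
  outputs <- lapply(outputs, parse_model_expr)
  psubs <- lapply(params, as.numeric)
  rhs <- lapply(rhs, function(e) fold_expr(subst_expr(e, psubs)))
  outputs <- lapply(outputs, function(e) fold_expr(subst_expr(e, psubs)))
  for (nm in names(rhs)) check_expr_grammar(rhs[[nm]], paste0("rhs of ", nm))
  for (nm in names(outputs)) check_expr_grammar(outputs[[nm]], paste0("output ", nm))

  model <- structure(
    list(states = states, inputs = inputs, flucts = flucts,
         rhs = rhs, outputs = outputs, params = params, name = name),
    class = "flat_model"
  )
  validate_model_symbols(model)
  validate_control_affine(model)
  model
}

validate_model_symbols <- function(model) {
  ok_plain <- c(model$states, model$inputs)
  for (nm in names(c(model$rhs, model$outputs))) NULL
  check_one <- function(e, where) {
    for (v in all.vars(e)) {
      if (v %in% ok_plain) next
      if (is_jet_name(v) && jet_base(v) %in% model$flucts) next
      stop("undeclared symbol `", v, "` in ", where,
           " (declare states/inputs/flucts or supply a parameter value).",
           call. = FALSE)
    }
  }
  for (nm in model$states) check_one(model$rhs[[nm]], paste0("rhs of ", nm))
  for (nm in names(model$outputs)) {
    check_one(model$outputs[[nm]], paste0("output ", nm))
  }
  invisible(model)
}

validate_control_affine <- function(model) {
  for (nm in model$states) {
    e <- model$rhs[[nm]]
    for (u1 in intersect(model$inputs, all.vars(e))) {
      g <- d_partial(e, u1)
      for (u2 in intersect(model$inputs, all.vars(g))) {
        stop("model is not control-affine: rhs of ", nm,
             " is nonlinear in inputs (", u1, ", ", u2, ").", call. = FALSE)
      }
    }
  }
  invisible(model)
}

#' Mean (deterministic) reduction of a model
#'
#' Sets every fluctuation jet symbol to zero, yielding the deterministic
#' generative model that underlies mean-mode control synthesis.
#'
#' @param model a \code{"flat_model"}.
#' @return a \code{"flat_model"} without fluctuation terms.
#' @export
mean_model <- function(model) {
  jets <- model_jet_names(model)
  subs <- stats::setNames(as.list(rep(0, length(jets))), jets)
  model$rhs <- lapply(model$rhs, function(e) fold_expr(subst_expr(e, subs)))
  model$outputs <- lapply(model$outputs, function(e) {
    fold_expr(subst_expr(e, subs))
  })
  model$flucts <- character()
  model$name <- paste0(model$name, " (mean)")
  model
}

# All fluctuation jet symbols appearing in the model expressions.
model_jet_names <- function(model, extra_exprs = list()) {
  vars <- unique(unlist(lapply(c(model$rhs, model$outputs, extra_exprs),
                               all.vars)))
  vars[is_jet_name(vars) & jet_base(vars) %in% model$flucts]
}

# Total time derivative of `expr` along the model flow: state partials are
# contracted with the right-hand sides and each exogenous jet symbol advances
# one order.  `expr` must not contain input symbols (their time derivatives
# are not part of the static-feedback setting).
model_total_derivative <- function(expr, model) {
  vars <- all.vars(expr)
  bad <- intersect(vars, model$inputs)
  if (length(bad) > 0L) {
    stop("cannot differentiate an expression containing input symbols (",
         paste(bad, collapse = ", "),
         "); dynamic extension is out of scope.", call. = FALSE)
  }
  terms <- list()
  for (v in vars) {
    if (v %in% model$states) {
      dv <- model$rhs[[v]]
    } else if (is_jet_name(v) && jet_base(v) %in% model$flucts) {
      dv <- jet_sym(jet_base(v), jet_order(v) + 1L)
    } else {
      next
    }
    pd <- d_partial(expr, v)
    if (is.numeric(pd) && pd == 0) next
    terms <- c(terms, list(fold_expr(call("*", pd, dv))))
  }
  if (length(terms) == 0L) return(0)
  out <- terms[[1L]]
  for (k in seq_along(terms)[-1L]) out <- call("+", out, terms[[k]])
  fold_expr(out)
}

#' @export
print.flat_model <- function(x, ...) {
  cat("<control-affine generative model: ", x$name, ">\n", sep = "")
  cat("  states: ", paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  if (length(x$flucts)) {
    cat("  fluctuations: ", paste(x$flucts, collapse = ", "), "\n", sep = "")
  }
  for (nm in x$states) {
    cat("  d", nm, "/dt = ", deparse1(x$rhs[[nm]]), "\n", sep = "")
  }
  for (nm in names(x$outputs)) {
    cat("  ", nm, " = ", deparse1(x$outputs[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' Double integrator model
#'
#' The minimal flat system \eqn{\dot x_1 = x_2,\ \dot x_2 = u}: freely choose
#' \eqn{x_1(t)}, differentiate once for \eqn{x_2} and once more for \eqn{u}.
#'
#' @return a \code{"flat_model"}.
#' @export
build_double_integrator <- function() {
  control_affine_model(
    states = c("x1", "x2"),
    inputs = "u",
    rhs = list(x1 = quote(x2), x2 = quote(u)),
    outputs = list(y = quote(x1)),
    name = "double integrator"
  )
}

#' Simple generic example model
#'
#' The two-state, single-input system
#' \deqn{\dot x_1 = x_2 + \zeta_{x1},\quad
#'       \dot x_2 = f(x_1, x_2) + u + \zeta_{x2},\quad
#'       y = x_1 + \zeta_y,}
#' flat with flat output \eqn{y}.  With \code{stochastic = FALSE} the
#' fluctuation channels are omitted, giving the deterministic counterpart
#' whose parametrisation is \eqn{x_1 = y}, \eqn{x_2 = \dot y},
#' \eqn{u = \ddot y - f(y, \dot y)}.
#'
#' @param f quoted expression (or string) for the smooth internal dynamics
#'   \eqn{f(x_1, x_2)}.
#' @param stochastic include the three fluctuation channels?
#' @return a \code{"flat_model"}.
#' @export
build_simple_example <- function(f = quote(-x1 - x2), stochastic = TRUE) {
  f <- parse_model_expr(f)
  if (stochastic) {
    control_affine_model(
      states = c("x1", "x2"),
      inputs = "u",
      flucts = c("zx1", "zx2", "zy"),
      rhs = list(
        x1 = quote(x2 + zx1_d0),
        x2 = fold_expr(call("+", call("+", f, quote(u)), quote(zx2_d0)))
      ),
      outputs = list(y = quote(x1 + zy_d0)),
      name = "simple generic example"
    )
  } else {
    control_affine_model(
      states = c("x1", "x2"),
      inputs = "u",
      rhs = list(
        x1 = quote(x2),
        x2 = fold_expr(call("+", f, quote(u)))
      ),
      outputs = list(y = quote(x1)),
      name = "simple generic example (deterministic)"
    )
  }
}

# ---- exogenous signal bindings ------------------------------------------

#' Wrap a closed-form signal for use as an exogenous binding
#'
#' @param fun function of \code{(t, order)} returning the order-th derivative
#'   of the signal at \code{t}.
#' @param max_order highest derivative order \code{fun} supports.
#' @return an \code{"exo_signal"} object.
#' @export
exo_signal <- function(fun, max_order = Inf) {
  structure(list(fun = fun, max_order = max_order), class = "exo_signal")
}

#' Zero exogenous signal
#' @return an \code{"exo_signal"} that is identically zero at all orders.
#' @export
exo_zero <- function() exo_signal(function(t, order) rep(0, length(t)))

#' Zero bindings for every fluctuation channel of a model
#'
#' Convenience for noise-free runs of a stochastic model without reducing it
#' to its mean form.
#'
#' @param model a \code{"flat_model"}.
#' @return named list of zero signals, one per declared fluctuation.
#' @export
zero_signals <- function(model) {
  stats::setNames(lapply(model$flucts, function(nm) exo_zero()),
                  model$flucts)
}

exo_eval <- function(sig, t, order = 0L) {
  if (inherits(sig, "srf")) return(srf_eval(sig, t, order))
  if (inherits(sig, "exo_signal")) {
    if (order > sig$max_order) {
      stop("signal does not supply derivatives of order ", order, ".")
    }
    return(sig$fun(t, order))
  }
  if (is.numeric(sig)) return(if (order == 0L) rep(sig, length(t)) else rep(0, length(t)))
  stop("unsupported exogenous signal binding of class ",
       paste(class(sig), collapse = "/"), ".")
}

# Build a function t -> named numeric vector for a set of jet symbol names,
# given bindings name -> signal.  Missing bindings error.
make_jet_evaluator <- function(jet_names, signals) {
  if (length(jet_names) == 0L) {
    return(function(t) stats::setNames(numeric(0), character(0)))
  }
  bases <- jet_base(jet_names)
  orders <- jet_order(jet_names)
  missing <- setdiff(unique(bases), names(signals))
  if (length(missing) > 0L) {
    stop("no binding supplied for fluctuation(s): ",
         paste(missing, collapse = ", "), ".")
  }
  function(t) {
    out <- numeric(length(jet_names))
    for (i in seq_along(jet_names)) {
      out[i] <- exo_eval(signals[[bases[i]]], t, orders[i])
    }
    stats::setNames(out, jet_names)
  }
}
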