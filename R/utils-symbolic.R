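# Lightweight symbolic layer on base R expression objects.
#
# Conventions used throughout the package:
#   * states, inputs and parameters are plain symbols ("x1", "upsi", "k1");
#   * exogenous signals (fluctuations, known disturbances) and flat-output
#     components appear through *jet symbols* "<name>_d<k>" denoting the k-th
#     time derivative of the signal <name> ("zX_d0", "zX_d1", "w1_d2", ...);
#   * partial derivatives come from stats::D, substitution from substitute();
#   * "identically zero" is decided by constant folding plus evaluation at
#     random generic points, to 12 significant digits relative to the term
#     magnitude of the expression.

jet_sym <- function(name, order) as.name(paste0(name, "_d", order))

jet_name <- function(name, order) paste0(name, "_d", order)

is_jet_name <- function(x) grepl("^.+_d[0-9]+$", x)

jet_base <- function(x) sub("_d[0-9]+$", "", x)

jet_order <- function(x) as.integer(sub("^.+_d([0-9]+)$", "\\1", x))

#' Substitute symbols in an expression
#'
#' @param expr a language object (call, symbol or numeric).
#' @param subs named list mapping symbol names to language objects or numbers.
#' @return the substituted language object.
#' @keywords internal
subst_expr <- function(expr, subs) {
  if (length(subs) == 0L) return(expr)
  do.call(substitute, list(expr, subs))
}

# Constant-folding simplifier.  Keeps expressions produced by repeated
# differentiation/substitution from ballooning; makes no claim of canonical
# form (zero-testing is numeric).
fold_expr <- function(e) {
  if (is.numeric(e) || is.name(e)) return(e)
  if (!is.call(e)) return(e)
  op <- as.character(e[[1L]])
  if (op == "(") return(fold_expr(e[[2L]]))
  args <- lapply(as.list(e)[-1L], fold_expr)
  num <- vapply(args, is.numeric, logical(1L))
  if (all(num) && op %in% c("+", "-", "*", "/", "^", "sqrt", "exp", "log",
                            "sin", "cos", "tan", "atan", "asin", "acos",
                            "sinh", "cosh", "tanh", "abs")) {
    val <- tryCatch(do.call(op, args), error = function(cnd) NULL)
    if (!is.null(val) && is.finite(val)) return(val)
  }
  zero <- function(x) is.numeric(x) && identical(as.numeric(x), 0)
  one  <- function(x) is.numeric(x) && identical(as.numeric(x), 1)
  if (op == "+") {
    if (length(args) == 1L) return(args[[1L]])
    if (zero(args[[1L]])) return(args[[2L]])
    if (zero(args[[2L]])) return(args[[1L]])
  } else if (op == "-") {
    if (length(args) == 1L) {
      if (is.numeric(args[[1L]])) return(-args[[1L]])
    } else {
      if (zero(args[[2L]])) return(args[[1L]])
      if (zero(args[[1L]])) return(as.call(list(as.name("-"), args[[2L]])))
    }
  } else if (op == "*") {
    if (zero(args[[1L]]) || zero(args[[2L]])) return(0)
    if (one(args[[1L]])) return(args[[2L]])
    if (one(args[[2L]])) return(args[[1L]])
  } else if (op == "/") {
    if (zero(args[[1L]])) return(0)
    if (one(args[[2L]])) return(args[[1L]])
  } else if (op == "^") {
    if (one(args[[2L]])) return(args[[1L]])
    if (zero(args[[2L]])) return(1)
    if (one(args[[1L]])) return(1)
  }
  as.call(c(e[[1L]], args))
}

# Partial derivative with constant folding.  `stats::D` covers every function
# the package's model grammar admits.
d_partial <- function(expr, name) {
  fold_expr(stats::D(expr, name))
}

# Magnitude proxy: the expression with every binary minus turned into plus
# and unary minus dropped, evaluated at the same point.  Bounds (up to
# cancellations inside sub-products) the size of the terms whose cancellation
# the zero test must resolve.
abs_scale_expr <- function(e) {
  if (is.numeric(e)) return(abs(e))
  if (is.name(e)) return(e)
  if (!is.call(e)) return(e)
  op <- as.character(e[[1L]])
  args <- lapply(as.list(e)[-1L], abs_scale_expr)
  if (op == "-") {
    if (length(args) == 1L) return(args[[1L]])
    return(as.call(c(as.name("+"), args)))
  }
  as.call(c(e[[1L]], args))
}

# Draw generic evaluation points for the free variables of a set of
# expressions.  Values are O(1) and bounded away from 0 to dodge poles.
generic_points <- function(vars, n = 10L, seed = 20260925L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- stats::runif(length(vars), min = 0.15, max = 1.35) *
      sample(c(-1, 1), length(vars), replace = TRUE)
    stats::setNames(as.list(v), vars)
  })
}

eval_expr <- function(expr, values) {
  eval(expr, envir = values, enclos = baseenv())
}

#' Test whether an expression is (generically) identically zero
#'
#' Constant folding first; then evaluation at random generic points with a
#' tolerance relative to the magnitude of the expression's terms (12
#' significant digits).
#'
#' @param expr language object.
#' @param extra_values named list of fixed numeric values (e.g. parameters).
#' @param n number of random points.
#' @param tol relative tolerance.
#' @return logical.
#' @keywords internal
is_zero_expr <- function(expr, extra_values = list(), n = 10L, tol = 1e-12) {
  expr <- fold_expr(expr)
  if (is.numeric(expr)) return(abs(expr) < tol)
  vars <- setdiff(all.vars(expr), names(extra_values))
  scale_e <- abs_scale_expr(expr)
  pts <- generic_points(vars, n = n)
  ok <- 0L
  for (p in pts) {
    vals <- c(p, extra_values)
    v <- tryCatch(eval_expr(expr, vals), error = function(cnd) NA_real_)
    s <- tryCatch(eval_expr(scale_e, vals), error = function(cnd) NA_real_)
    if (!is.finite(v) || !is.finite(s)) next
    if (abs(v) <= tol * (1 + abs(s))) ok <- ok + 1L else return(FALSE)
  }
  ok > 0L
}

# Evaluate a list of expressions at random generic points, returning a matrix
# (points x expressions).  Used for generic rank / nonsingularity tests.
eval_at_generic <- function(exprs, extra_values = list(), n = 6L) {
  vars <- setdiff(unique(unlist(lapply(exprs, all.vars))), names(extra_values))
  pts <- generic_points(vars, n = n, seed = 20260114L)
  out <- matrix(NA_real_, nrow = n, ncol = length(exprs))
  for (i in seq_len(n)) {
    vals <- c(pts[[i]], extra_values)
    out[i, ] <- vapply(exprs, function(e) {
      tryCatch(as.numeric(eval_expr(e, vals)), error = function(cnd) NA_real_)
    }, numeric(1L))
  }
  out
}

# Compile expressions into one function returning c(e1, e2, ...) so that hot
# simulation loops benefit from the byte-code compiler.
make_evaluator <- function(exprs, vars) {
  exprs <- unname(lapply(exprs, fold_expr))
  if (length(vars) == 0L) {
    vals <- vapply(exprs, function(e) as.numeric(eval(e, baseenv())), numeric(1L))
    return(function(values = NULL) vals)
  }
  body <- if (length(exprs) == 1L) exprs[[1L]] else as.call(c(quote(c), exprs))
  formals_list <- stats::setNames(rep(alist(x = ), length(vars)), vars)
  f <- eval(call("function", as.pairlist(formals_list), body), baseenv())
  nv <- length(vars)
  function(values) {
    if (is.null(names(values))) {
      stopifnot(length(values) == nv)
      do.call(f, as.list(values))      # positional: caller follows `vars`
    } else {
      do.call(f, as.list(values[vars]))
    }
  }
}

# Vectorised evaluator: arguments are equal-length vectors (supplied as a
# named list of columns); returns a matrix with one column per expression,
# recycling scalar results of constant sub-expressions.
make_vec_evaluator <- function(exprs, vars) {
  exprs <- unname(lapply(exprs, fold_expr))
  formals_list <- stats::setNames(rep(alist(x = ), length(vars)), vars)
  funs <- lapply(exprs, function(e) {
    eval(call("function", as.pairlist(formals_list), e), baseenv())
  })
  function(cols, nrow_out) {
    out <- matrix(NA_real_, nrow_out, length(funs))
    for (j in seq_along(funs)) {
      v <- do.call(funs[[j]], cols)
      out[, j] <- if (length(v) == 1L) rep(v, nrow_out) else v
    }
    out
  }
}

# RNG bookkeeping: every sampler takes an explicit integer seed and restores
# the caller's RNG state afterwards (no global state contract).
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal cumulative integral on a uniform or non-uniform grid.
trapz_cum <- function(t, y) {
  if (length(t) < 2L) return(rep(0, length(t)))
  c(0, cumsum(diff(t) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2))
}
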