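# Symbolic flatness engine: dynamical-extension analysis of candidate flat
# outputs, functional parametrisation, linearising feedback, chain-form
# realisation and polynomial point-to-point planning.
#
# The engine works on the package's expression layer (utils-symbolic.R).
# "Identically zero" and "generically nonsingular" are decided by constant
# folding plus evaluation at random generic points; the constructive Phase
# I-III conditions are what is verified (non-existence of differential
# relations among flat-output components is not algorithmically checkable
# here, and certificates say so in their print method).

#' Brunovsky analysis of candidate flat outputs
#'
#' Runs the dynamical extension algorithm on an m-tuple of candidate outputs:
#' each candidate is differentiated along the model flow until a combination
#' of control inputs carrying a new independent input direction appears
#' (Phase I); the candidate tuple is a flat output iff the Brunovsky indices
#' sum to the state dimension (Phase II), in which case the decoupling matrix
#' and drift terms assembled here define the linearising feedback (Phase III).
#'
#' @param model a \code{"flat_model"}.
#' @param candidates list of candidate flat-output expressions (quoted or
#'   strings), functions of the states and possibly fluctuation jets, never
#'   of the inputs.
#' @param omega_names names for the flat-output components (default
#'   \code{w1, w2, ...}).
#' @param max_order derivative cap before a candidate is rejected (default
#'   \code{2 n}).
#' @return a \code{"flat_certificate"}: Brunovsky indices \code{kappa},
#'   derivative chains, decoupling matrix \code{A}, drift terms \code{b},
#'   and the flat verdict.
#' @examples
#' cert <- brunovsky_analysis(build_double_integrator(), list(quote(x1)))
#' cert$kappa  # 2
#' @export
brunovsky_analysis <- function(model, candidates, omega_names = NULL,
                               max_order = NULL) {
  stopifnot(inherits(model, "flat_model"))
  candidates <- lapply(candidates, parse_model_expr)
  m <- length(candidates)
  n <- length(model$states)
  if (m != length(model$inputs)) {
    stop("need as many candidate components as inputs (",
         length(model$inputs), ").")
  }
  if (is.null(omega_names)) omega_names <- paste0("w", seq_len(m))
  if (is.null(max_order)) max_order <- 2L * n
  for (i in seq_len(m)) {
    bad <- intersect(all.vars(candidates[[i]]), model$inputs)
    if (length(bad) > 0L) {
      stop("candidate ", i, " contains input symbol(s) ",
           paste(bad, collapse = ", "),
           ": flat-output candidates must be endogenous (input-free).")
    }
  }

  kappa <- integer(m)
  chains <- vector("list", m)
  gamma <- vector("list", m)
  rows <- vector("list", m)  # input-coefficient rows (lists of expressions)
  acc_rows <- list()
  for (i in seq_len(m)) {
    E <- fold_expr(candidates[[i]])
    chain_i <- list(E)
    found <- FALSE
    for (k in seq_len(max_order)) {
      Enext <- model_total_derivative(E, model)
      row <- lapply(model$inputs, function(u) d_partial(Enext, u))
      has_input <- !all(vapply(row, function(e) is_zero_expr(e), logical(1L)))
      if (has_input) {
        if (!row_is_independent(acc_rows, row)) {
          stop("candidate ", i, " (", deparse1(candidates[[i]]), "): inputs ",
               "appear at order ", k, " but only along directions already ",
               "used by earlier components; true dynamic extension would be ",
               "required, which is outside this engine's scope.")
        }
        kappa[i] <- k
        gamma[[i]] <- fold_expr(Enext)
        rows[[i]] <- row
        acc_rows <- c(acc_rows, list(row))
        found <- TRUE
        break
      }
      E <- fold_expr(Enext)
      chain_i <- c(chain_i, list(E))
    }
    if (!found) {
      stop("candidate ", i, " (", deparse1(candidates[[i]]), "): no control ",
           "input appeared within ", max_order, " differentiations; ",
           "candidate rejected.")
    }
    chains[[i]] <- chain_i
  }

  A <- matrix(list(), nrow = m, ncol = m)
  for (i in seq_len(m)) for (j in seq_len(m)) A[[i, j]] <- rows[[i]][[j]]
  u_zero <- stats::setNames(as.list(rep(0, m)), model$inputs)
  b <- lapply(gamma, function(g) fold_expr(subst_expr(g, u_zero)))

  det_ok <- decoupling_generically_nonsingular(A)
  flat <- (sum(kappa) == n) && det_ok
  reason <- if (sum(kappa) != n) {
    sprintf("sum of Brunovsky indices %d != state dimension %d",
            sum(kappa), n)
  } else if (!det_ok) {
    "decoupling matrix is identically singular"
  } else {
    "indices sum to the state dimension and the decoupling matrix is generically nonsingular"
  }

  structure(
    list(model = model, omega = candidates, omega_names = omega_names,
         kappa = kappa, chains = chains, gamma = gamma,
         A = A, b = b, flat = flat, reason = reason),
    class = "flat_certificate"
  )
}

# Generic row-rank growth test by evaluation at random points.
row_is_independent <- function(acc_rows, row) {
  if (length(acc_rows) == 0L) return(TRUE)
  exprs <- c(unlist(acc_rows, recursive = FALSE), row)
  vals <- eval_at_generic(exprs, n = 8L)
  m <- length(row)
  for (p in seq_len(nrow(vals))) {
    v <- vals[p, ]
    if (any(!is.finite(v))) next
    prev <- matrix(v[seq_len(length(acc_rows) * m)], ncol = m, byrow = TRUE)
    full <- rbind(prev, v[length(acc_rows) * m + seq_len(m)])
    if (qr(full)$rank > qr(prev)$rank) return(TRUE)
  }
  FALSE
}

decoupling_generically_nonsingular <- function(A) {
  m <- nrow(A)
  vals <- eval_at_generic(as.list(t(A)), n = 8L)
  for (p in seq_len(nrow(vals))) {
    v <- vals[p, ]
    if (any(!is.finite(v))) next
    if (abs(det(matrix(v, m, m, byrow = TRUE))) > 1e-10) return(TRUE)
  }
  FALSE
}

#' @export
print.flat_certificate <- function(x, ...) {
  cat("<flatness certificate>\n")
  cat("  model: ", x$model$name, " (n = ", length(x$model$states),
      ", m = ", length(x$model$inputs), ")\n", sep = "")
  for (i in seq_along(x$omega)) {
    cat(sprintf("  %s = %s   kappa = %d\n", x$omega_names[i],
                deparse1(x$omega[[i]]), x$kappa[i]))
  }
  cat("  verdict: ", if (x$flat) "FLAT" else "NOT FLAT",
      " (", x$reason, ")\n", sep = "")
  cat("  note: constructive Phase I-III conditions only; differential\n",
      "  independence of the components is not algorithmically checked.\n",
      sep = "")
  invisible(x)
}

#' Tidy summary of a flatness certificate
#'
#' @param x a \code{"flat_certificate"}.
#' @param ... unused.
#' @return a tibble with one row per flat-output component.
#' @method tidy flat_certificate
#' @export
tidy.flat_certificate <- function(x, ...) {
  tibble::tibble(
    component = x$omega_names,
    expression = vapply(x$omega, deparse1, character(1L)),
    kappa = x$kappa,
    flat = x$flat
  )
}

# ---- functional parametrisation -----------------------------------------

#' Functional parametrisation from a flatness certificate
#'
#' Inverts the stacked derivative-chain map to express every state — and,
#' through the decoupling relation, every input — as closed-form functions of
#' the flat-output jet and the fluctuation jet: the quasi-static form
#' \eqn{x = A(\omega, \dot\omega, \ldots, \zeta, \ldots)},
#' \eqn{u = B(\omega, \ldots, \zeta, \ldots)} that replaces the differential
#' equations.
#'
#' @param model a \code{"flat_model"}.
#' @param cert a flat \code{"flat_certificate"} for that model.
#' @return a \code{"flat_parametrisation"}: named state and input expressions
#'   in the jet symbols \code{w<i>_d<k>} and \code{<fluct>_d<k>}.
#' @export
functional_parametrisation <- function(model, cert) {
  stopifnot(inherits(cert, "flat_certificate"))
  if (!cert$flat) {
    stop("certificate verdict is not flat (", cert$reason,
         "); no parametrisation exists on this route.")
  }
  m <- length(cert$omega)
  eqs <- list()
  for (i in seq_len(m)) {
    for (k in seq_len(cert$kappa[i]) - 1L) {
      eqs[[length(eqs) + 1L]] <- list(
        lhs = jet_sym(cert$omega_names[i], k),
        rhs = cert$chains[[i]][[k + 1L]]
      )
    }
  }
  solved <- list()
  remaining <- eqs
  repeat {
    progress <- FALSE
    keep <- logical(length(remaining))
    for (q in seq_along(remaining)) {
      e <- fold_expr(subst_expr(remaining[[q]]$rhs, solved))
      unsolved <- setdiff(intersect(all.vars(e), model$states), names(solved))
      if (length(unsolved) == 0L) {
        keep[q] <- FALSE  # redundant equation; consistency is checked later
        next
      }
      if (length(unsolved) > 1L) {
        keep[q] <- TRUE
        next
      }
      s <- unsolved
      c1 <- d_partial(e, s)
      if (!is_zero_expr(d_partial(c1, s))) {
        keep[q] <- TRUE  # not affine in the remaining state yet
        next
      }
      c0 <- fold_expr(subst_expr(e, stats::setNames(list(0), s)))
      sol <- fold_expr(call("/",
                            fold_expr(call("-", remaining[[q]]$lhs, c0)),
                            c1))
      solved[[s]] <- sol
      solved <- lapply(solved, function(se) fold_expr(subst_expr(se, solved)))
      keep[q] <- FALSE
      progress <- TRUE
    }
    remaining <- remaining[keep]
    if (length(names(solved)) == length(model$states)) break
    if (!progress) {
      stop("symbolic solve of the derivative-chain map failed; unsolved ",
           "equations: ",
           paste(vapply(remaining, function(z) {
             paste0(deparse1(z$lhs), " = ", deparse1(z$rhs))
           }, character(1L)), collapse = "; "))
    }
  }
  solved <- solved[model$states]

  # inputs: A(x, zeta) u = (w_i^(kappa_i) - b_i), then substitute x = A(jets)
  top <- lapply(seq_len(m), function(i) {
    jet_sym(cert$omega_names[i], cert$kappa[i])
  })
  rhs_vec <- lapply(seq_len(m), function(i) {
    fold_expr(call("-", top[[i]], cert$b[[i]]))
  })
  u_exprs <- solve_symbolic_linear(cert$A, rhs_vec)
  u_exprs <- lapply(u_exprs, function(e) fold_expr(subst_expr(e, solved)))
  names(u_exprs) <- model$inputs

  structure(
    list(model = model, omega_names = cert$omega_names, kappa = cert$kappa,
         states = solved, inputs = u_exprs),
    class = "flat_parametrisation"
  )
}

# Solve A x = b symbolically for small m via the adjugate (m <= 3).
solve_symbolic_linear <- function(A, b) {
  m <- nrow(A)
  mul <- function(x, y) fold_expr(call("*", x, y))
  sub <- function(x, y) fold_expr(call("-", x, y))
  add <- function(x, y) fold_expr(call("+", x, y))
  dv  <- function(x, y) fold_expr(call("/", x, y))
  if (m == 1L) return(list(dv(b[[1L]], A[[1L, 1L]])))
  if (m == 2L) {
    det <- sub(mul(A[[1, 1]], A[[2, 2]]), mul(A[[1, 2]], A[[2, 1]]))
    x1 <- dv(sub(mul(A[[2, 2]], b[[1L]]), mul(A[[1, 2]], b[[2L]])), det)
    x2 <- dv(sub(mul(A[[1, 1]], b[[2L]]), mul(A[[2, 1]], b[[1L]])), det)
    return(list(x1, x2))
  }
  if (m == 3L) {
    det2 <- function(a, b2, c, d) sub(mul(a, d), mul(b2, c))
    det <- add(
      sub(mul(A[[1, 1]], det2(A[[2, 2]], A[[2, 3]], A[[3, 2]], A[[3, 3]])),
          mul(A[[1, 2]], det2(A[[2, 1]], A[[2, 3]], A[[3, 1]], A[[3, 3]]))),
      mul(A[[1, 3]], det2(A[[2, 1]], A[[2, 2]], A[[3, 1]], A[[3, 2]])))
    xs <- vector("list", 3L)
    for (j in 1:3) {
      M <- A
      for (i in 1:3) M[[i, j]] <- b[[i]]
      detj <- add(
        sub(mul(M[[1, 1]], det2(M[[2, 2]], M[[2, 3]], M[[3, 2]], M[[3, 3]])),
            mul(M[[1, 2]], det2(M[[2, 1]], M[[2, 3]], M[[3, 1]], M[[3, 3]]))),
        mul(M[[1, 3]], det2(M[[2, 1]], M[[2, 2]], M[[3, 1]], M[[3, 2]])))
      xs[[j]] <- dv(detj, det)
    }
    return(xs)
  }
  stop("symbolic linear solve implemented for m <= 3.")
}

#' @export
print.flat_parametrisation <- function(x, ...) {
  cat("<functional parametrisation (", x$model$name, ")>\n", sep = "")
  for (nm in names(x$states)) {
    cat("  ", nm, " = ", deparse1(x$states[[nm]]), "\n", sep = "")
  }
  for (nm in names(x$inputs)) {
    cat("  ", nm, " = ", deparse1(x$inputs[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

# Time derivative of an expression living in jet-symbol space: every jet
# symbol advances one order; anything else must be absent.
jet_time_derivative <- function(expr) {
  vars <- all.vars(expr)
  bad <- vars[!is_jet_name(vars)]
  if (length(bad) > 0L) {
    stop("expression is not purely in jet symbols: ",
         paste(bad, collapse = ", "))
  }
  terms <- list()
  for (v in vars) {
    pd <- d_partial(expr, v)
    if (is.numeric(pd) && pd == 0) next
    nxt <- jet_sym(jet_base(v), jet_order(v) + 1L)
    terms <- c(terms, list(fold_expr(call("*", pd, nxt))))
  }
  if (length(terms) == 0L) return(0)
  out <- terms[[1L]]
  for (k in seq_along(terms)[-1L]) out <- call("+", out, terms[[k]])
  fold_expr(out)
}

#' Verify a functional parametrisation against its model
#'
#' Substitutes the parametrisation into every model equation and simplifies;
#' the residuals should be identically zero ("identically verified").  The
#' zero test is constant folding plus evaluation at random generic points to
#' 12 significant digits; nonzero residuals are the informative return.
#'
#' @param model a \code{"flat_model"}.
#' @param par a \code{"flat_parametrisation"} (its expressions may also be
#'   modified by hand, e.g. to study a corrupted parametrisation).
#' @return a \code{"flat_residuals"} object: named residual expressions, a
#'   per-equation zero verdict and \code{all_zero}.
#' @export
verify_parametrisation <- function(model, par) {
  stopifnot(inherits(par, "flat_parametrisation"))
  subs <- c(par$states, par$inputs)
  res <- list()
  zero <- logical(length(model$states))
  names(zero) <- model$states
  for (nm in model$states) {
    lhs <- jet_time_derivative(par$states[[nm]])
    rhs <- fold_expr(subst_expr(model$rhs[[nm]], subs))
    r <- fold_expr(call("-", lhs, rhs))
    res[[nm]] <- r
    zero[nm] <- is_zero_expr(r)
  }
  structure(list(residuals = res, zero = zero, all_zero = all(zero)),
            class = "flat_residuals")
}

#' @export
print.flat_residuals <- function(x, ...) {
  cat("<parametrisation residuals>\n")
  for (nm in names(x$residuals)) {
    cat("  ", nm, ": ",
        if (x$zero[nm]) "0" else deparse1(x$residuals[[nm]]), "\n", sep = "")
  }
  cat("  all zero: ", x$all_zero, "\n", sep = "")
  invisible(x)
}

# ---- linearising feedback -----------------------------------------------

#' Linearising feedback from a flatness certificate
#'
#' Returns the static feedback \eqn{u = A(x,\zeta)^{-1} (v - b(x,\zeta))}
#' that renders the closed loop \eqn{\omega_i^{(\kappa_i)} = v_i}.
#'
#' @param model a \code{"flat_model"}.
#' @param cert a flat \code{"flat_certificate"}.
#' @return a function \code{(x, v, jets = NULL)} mapping the named state
#'   vector, new-input vector and (optionally) named fluctuation-jet values
#'   to the named input vector; it signals an error, reporting the point, if
#'   the decoupling matrix is singular there.
#' @export
linearising_feedback <- function(model, cert) {
  stopifnot(inherits(cert, "flat_certificate"))
  if (!cert$flat) stop("certificate verdict is not flat (", cert$reason, ").")
  m <- length(model$inputs)
  jetn <- model_jet_names(model, extra_exprs = c(as.list(cert$A), cert$b))
  vars <- c(model$states, jetn)
  A_fun <- make_evaluator(as.list(t(cert$A)), vars)
  b_fun <- make_evaluator(cert$b, vars)
  function(x, v, jets = NULL) {
    vals <- c(as.list(x),
              stats::setNames(as.list(rep(0, length(jetn))), jetn))
    if (!is.null(jets)) vals[names(jets)] <- jets
    vals <- unlist(vals)
    A_num <- matrix(A_fun(vals), m, m, byrow = TRUE)
    b_num <- b_fun(vals)
    if (!all(is.finite(A_num)) || abs(det(A_num)) < 1e-12) {
      stop("decoupling matrix singular (or non-finite) at x = (",
           paste(signif(x, 6), collapse = ", "), ").")
    }
    stats::setNames(as.numeric(solve(A_num, v - b_num)), model$inputs)
  }
}

# ---- chain-form realisation ---------------------------------------------

#' Brunovsky chain-form realisation
#'
#' Rewrites the model in the flat-output coordinates
#' \eqn{(\omega_1, \dot\omega_1, \ldots, \omega_m^{(\kappa_m - 1)})}: pure
#' integrator chains closed by the flat-output dynamics
#' \eqn{\omega_i^{(\kappa_i)} = \gamma_i}, with the original states replaced
#' through the functional parametrisation.  This is the smooth random
#' realisation of the model: driving it with the same input and fluctuation
#' paths reproduces the flat-output trajectories of the original system.
#'
#' @param cert a flat \code{"flat_certificate"}.
#' @param par optional precomputed \code{"flat_parametrisation"}.
#' @return a \code{"flat_model"} whose states are the jet symbols of the
#'   flat output.
#' @export
brunovsky_realisation <- function(cert, par = NULL) {
  stopifnot(inherits(cert, "flat_certificate"))
  if (!cert$flat) stop("certificate verdict is not flat (", cert$reason, ").")
  model <- cert$model
  if (is.null(par)) par <- functional_parametrisation(model, cert)
  st <- character(0)
  rhs <- list()
  for (i in seq_along(cert$kappa)) {
    k_i <- cert$kappa[i]
    nm <- cert$omega_names[i]
    for (k in seq_len(k_i) - 1L) {
      zname <- jet_name(nm, k)
      st <- c(st, zname)
      if (k < k_i - 1L) {
        rhs[[zname]] <- jet_sym(nm, k + 1L)
      } else {
        rhs[[zname]] <- fold_expr(subst_expr(cert$gamma[[i]], par$states))
      }
    }
  }
  outputs <- stats::setNames(
    lapply(cert$omega_names, function(nm) jet_sym(nm, 0L)),
    cert$omega_names
  )
  control_affine_model(
    states = st, inputs = model$inputs, flucts = model$flucts,
    rhs = rhs, outputs = outputs, params = list(),
    name = paste0(model$name, " (chain realisation)")
  )
}

# Map an original-model state vector to the chain coordinates (noise-free).
chain_coordinates <- function(cert, x, jets = NULL) {
  out <- numeric(0)
  jetn <- model_jet_names(cert$model,
                          extra_exprs = unlist(cert$chains, recursive = FALSE))
  vals <- c(as.list(x), stats::setNames(as.list(rep(0, length(jetn))), jetn))
  if (!is.null(jets)) vals[names(jets)] <- jets
  for (i in seq_along(cert$kappa)) {
    for (k in seq_len(cert$kappa[i]) - 1L) {
      v <- eval_expr(cert$chains[[i]][[k + 1L]], vals)
      out <- c(out, stats::setNames(v, jet_name(cert$omega_names[i], k)))
    }
  }
  out
}

# ---- point-to-point planning --------------------------------------------

#' Polynomial point-to-point steering plan
#'
#' Implements constructive global controllability on a flat system: the
#' endpoint states are pushed through the derivative chains (fluctuations set
#' to zero) to flat-output jet conditions, and each component gets the unique
#' polynomial of degree \eqn{2\kappa_i - 1} interpolating the \eqn{\kappa_i}
#' jet conditions at each endpoint.  The open-loop input from the functional
#' parametrisation then steers the noise-free model from \code{x0} to
#' \code{x1}.
#'
#' @param model a \code{"flat_model"}.
#' @param cert a flat \code{"flat_certificate"}.
#' @param x0,x1 named initial and final state vectors.
#' @param t0,t1 initial and final times (\code{t1 > t0}).
#' @return a \code{"flat_reference"} for the flat output (polynomial
#'   components, derivatives of every order).
#' @export
plan_point_to_point <- function(model, cert, x0, x1, t0 = 0, t1 = 1) {
  stopifnot(inherits(cert, "flat_certificate"))
  if (!cert$flat) stop("certificate verdict is not flat (", cert$reason, ").")
  if (t1 <= t0) stop("`t1` must exceed `t0`.")
  T <- t1 - t0
  jets0 <- chain_coordinates(cert, x0)
  jets1 <- chain_coordinates(cert, x1)
  coefs <- list()
  for (i in seq_along(cert$kappa)) {
    k_i <- cert$kappa[i]
    nm <- cert$omega_names[i]
    w0 <- jets0[jet_name(nm, seq_len(k_i) - 1L)]
    w1 <- jets1[jet_name(nm, seq_len(k_i) - 1L)]
    deg <- 2L * k_i - 1L
    M <- matrix(0, nrow = 2L * k_i, ncol = deg + 1L)
    rhs <- c(w0, w1)
    for (k in seq_len(k_i) - 1L) {
      M[k + 1L, k + 1L] <- factorial(k)                # order k at s = 0
      for (j in k:deg) {                               # order k at s = T
        M[k_i + k + 1L, j + 1L] <-
          factorial(j) / factorial(j - k) * T^(j - k)
      }
    }
    coefs[[nm]] <- as.numeric(solve(M, rhs))
  }
  ref <- reference_polynomial(coefs, t0 = t0)
  ref$name <- "point-to-point plan"
  ref$domain <- c(t0, t1)
  ref
}
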