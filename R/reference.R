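# Reference trajectories: goal paths with exact derivatives to a stated
# maximal order.  A reference is a named list of component functions
# (t, order) -> value; families used by the demonstrations (sigmoid step,
# quatrefoil, hypocycloid, polynomials) supply closed-form derivatives.

#' Construct a reference trajectory from derivative-supplying closures
#'
#' @param components named list of functions \code{(t, order)} returning the
#'   order-th derivative of the component at \code{t} (vectorised in t).
#' @param max_order highest derivative order supplied.
#' @param domain length-2 numeric, the intended time span.
#' @param name display name.
#' @return an object of class \code{"flat_reference"}.
#' @export
reference_trajectory <- function(components, max_order = 2L,
                                 domain = c(0, Inf), name = "reference") {
  stopifnot(is.list(components), length(components) >= 1L,
            !is.null(names(components)))
  structure(
    list(components = components, max_order = max_order,
         domain = domain, name = name, dim = length(components)),
    class = "flat_reference"
  )
}

#' Evaluate a reference trajectory
#'
#' @param ref a \code{"flat_reference"}.
#' @param t numeric vector of times.
#' @param order derivative order.
#' @param component component name or index (default: all, as a matrix).
#' @return numeric vector (one component) or matrix \code{|t| x dim}.
#' @export
ref_eval <- function(ref, t, order = 0L, component = NULL) {
  stopifnot(inherits(ref, "flat_reference"))
  if (order > ref$max_order) {
    stop("reference `", ref$name, "` supplies derivatives up to order ",
         ref$max_order, ", asked for ", order, ".")
  }
  if (!is.null(component)) {
    return(ref$components[[component]](t, order))
  }
  vapply(ref$components, function(f) f(t, order), numeric(length(t)))
}

#' @export
print.flat_reference <- function(x, ...) {
  cat("<reference trajectory: ", x$name, ">\n", sep = "")
  cat("  components: ", paste(names(x$components), collapse = ", "),
      " | derivatives to order ", x$max_order, "\n", sep = "")
  invisible(x)
}

#' Sigmoid (smooth step) reference
#'
#' \deqn{x_r(t) = \frac{x_h - x_l}{2}\big(1 + \tanh(\gamma (t - t_{raise}))\big) + x_l}
#' rising smoothly from \eqn{x_l} to \eqn{x_h}, with half-rise at
#' \eqn{t_{raise}} and stiffness \eqn{\gamma}.  Closed-form derivatives to
#' order 3.
#'
#' @param xl,xh low and high plateaus (\code{xh > xl}).
#' @param gamma stiffness (> 0), 1/time.
#' @param t_raise half-rise time.
#' @param component component name.
#' @return a \code{"flat_reference"} with one component.
#' @export
reference_sigmoid <- function(xl = 1, xh = 4, gamma = 4, t_raise = 20,
                              component = "w") {
  stopifnot(xh > xl, gamma > 0)
  amp <- (xh - xl) / 2
  f <- function(t, order) {
    s <- tanh(gamma * (t - t_raise))
    sech2 <- 1 - s^2
    switch(as.character(order),
      "0" = amp * (1 + s) + xl,
      "1" = amp * gamma * sech2,
      "2" = -2 * amp * gamma^2 * s * sech2,
      "3" = -2 * amp * gamma^3 * sech2 * (1 - 3 * s^2),
      stop("sigmoid reference supplies derivatives to order 3.")
    )
  }
  reference_trajectory(stats::setNames(list(f), component),
                       max_order = 3L, name = "sigmoid")
}

#' Constant reference
#'
#' @param values named numeric vector of component set-points.
#' @return a \code{"flat_reference"} (derivatives of any order are zero).
#' @export
reference_constant <- function(values) {
  comps <- lapply(values, function(v) {
    force(v)
    function(t, order) if (order == 0L) rep(v, length(t)) else rep(0, length(t))
  })
  reference_trajectory(comps, max_order = 10L, name = "constant")
}

# Reference whose components are finite sums  sum_k c_k trig(w_k t + p_k):
# derivatives of every order in closed form.
trig_component <- function(coef, omega, phase) {
  force(coef); force(omega); force(phase)
  function(t, order) {
    shift <- order * pi / 2
    out <- rep(0, length(t))
    for (k in seq_along(coef)) {
      out <- out + coef[k] * omega[k]^order * cos(omega[k] * t + phase[k] + shift)
    }
    out
  }
}

#' Quatrefoil reference curve
#'
#' The four-lobed rosette \eqn{X(t) = 2a\sin^2 t\cos t},
#' \eqn{Y(t) = 2a\cos^2 t\sin t}, period \eqn{2\pi}; internally expressed as
#' the trigonometric polynomials \eqn{X = \tfrac a2(\cos t - \cos 3t)},
#' \eqn{Y = \tfrac a2(\sin t + \sin 3t)}, so derivatives of every order are
#' closed-form.
#'
#' @param a size parameter (> 0).
#' @param components names of the two components.
#' @return a \code{"flat_reference"} with components X, Y.
#' @export
reference_quatrefoil <- function(a = 2, components = c("X", "Y")) {
  stopifnot(a > 0)
  X <- trig_component(c(a / 2, -a / 2), c(1, 3), c(0, 0))
  Y <- trig_component(c(a / 2, a / 2), c(1, 3), c(-pi / 2, -pi / 2))
  reference_trajectory(stats::setNames(list(X, Y), components),
                       max_order = 10L, domain = c(0, 2 * pi),
                       name = "quatrefoil")
}

#' Hypocycloid reference curve
#'
#' \eqn{X(t) = (a-b)\cos t + b\cos\frac{(a-b)t}{b}},
#' \eqn{Y(t) = (a-b)\sin t - b\sin\frac{(a-b)t}{b}}; for rational
#' \eqn{(a-b)/b} the curve closes after the least common period of the two
#' angular arguments.
#'
#' @param a outer radius (> b).
#' @param b rolling radius (> 0).
#' @param components names of the two components.
#' @return a \code{"flat_reference"} with components X, Y and the closing
#'   period stored in its domain.
#' @export
reference_hypocycloid <- function(a = 2, b = 6 / 5, components = c("X", "Y")) {
  stopifnot(a > b, b > 0)
  w2 <- (a - b) / b
  X <- trig_component(c(a - b, b), c(1, w2), c(0, 0))
  Y <- trig_component(c(a - b, -b), c(1, w2), c(-pi / 2, -pi / 2))
  reference_trajectory(stats::setNames(list(X, Y), components),
                       max_order = 10L,
                       domain = c(0, closing_period(w2)),
                       name = "hypocycloid")
}

# Smallest T = 2*pi*k (integer k) with w2 * k also an integer: the least
# common period of the angular arguments t and w2 * t, for rational w2.
closing_period <- function(w2, max_k = 1000L) {
  for (k in seq_len(max_k)) {
    if (abs(w2 * k - round(w2 * k)) < 1e-9) return(2 * pi * k)
  }
  stop("frequency ratio is not rational within denominator ", max_k, ".")
}

#' Polynomial reference from coefficient vectors
#'
#' @param coefs named list; each element is the coefficient vector
#'   \eqn{(c_0, c_1, \ldots)} of a polynomial in \eqn{(t - t0)}.
#' @param t0 expansion point.
#' @return a \code{"flat_reference"}.
#' @export
reference_polynomial <- function(coefs, t0 = 0) {
  comps <- lapply(coefs, function(cf) {
    force(cf)
    function(t, order) {
      s <- t - t0
      out <- rep(0, length(t))
      deg <- length(cf) - 1L
      if (order > deg) return(out)
      for (j in order:deg) {
        out <- out + cf[j + 1L] * factorial(j) / factorial(j - order) *
          s^(j - order)
      }
      out
    }
  })
  reference_trajectory(comps, max_order = 10L, name = "polynomial")
}
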