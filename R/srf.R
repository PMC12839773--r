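#' Sample a periodic smooth random function
#'
#' Draws an L-periodic, band-limited Gaussian trigonometric sum
#' \deqn{\zeta(t) = \alpha\Big(a_0 + \sum_{j=1}^{r} a_j \cos(2\pi j t/L)
#'   + b_j \sin(2\pi j t/L)\Big), \qquad r = \lfloor L/\lambda_w \rfloor,}
#' the fluctuation model used throughout the package.  The truncation index
#' \code{r} makes the function \eqn{2\pi/\lambda_w}-band-limited; being a
#' trigonometric polynomial it is entire, with closed-form derivatives and
#' antiderivatives of every order.
#'
#' Two normalisations are available:
#' \describe{
#'   \item{\code{"standard"}}{every coefficient is i.i.d.
#'     \eqn{N(0, 1/(2r+1))}; the pointwise variance is
#'     \eqn{\alpha^2 (r+1)/(2r+1)}.}
#'   \item{\code{"big"}}{the DC coefficient has variance
#'     \eqn{2/((2r+1)\lambda_w)} (approximately \eqn{1/L}) and each harmonic
#'     coefficient twice that, \eqn{4/((2r+1)\lambda_w)} — the two-sided
#'     spectral weight, since each \eqn{j>0} pair covers frequencies
#'     \eqn{\pm 2\pi j/L}.  With this flat unit spectral density the
#'     indefinite integral \eqn{\int_0^t \zeta} has variance
#'     \eqn{\approx t} and converges to a standard Brownian path as
#'     \eqn{\lambda_w \to 0}.}
#' }
#'
#' @param L period, in time units (> 0).
#' @param lambda_w wavelength parameter, in time units (> 0).
#' @param mode normalisation, \code{"standard"} or \code{"big"}.
#' @param alpha amplitude scale applied multiplicatively to the whole sum.
#' @param seed integer seed; identical seeds give identical coefficients.
#'   The caller's RNG state is left untouched.
#' @return an object of class \code{"srf"}: a list with the period, the
#'   wavelength, the truncation index \code{r}, coefficient vectors \code{a}
#'   (\eqn{a_0 \ldots a_r}) and \code{b} (\eqn{b_1 \ldots b_r}), the angular
#'   frequencies, the mode, the amplitude and the seed.
#' @examples
#' z <- sample_srf(L = 8, lambda_w = 2, seed = 1)
#' z$r                      # 4
#' srf_eval(z, 0.3)         # value
#' srf_eval(z, 0.3, order = 2)  # exact second derivative
#' @export
sample_srf <- function(L, lambda_w, mode = c("standard", "big"),
                       alpha = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("`L` must be a single positive number, got ", deparse(L), ".")
  }
  if (!is.numeric(lambda_w) || length(lambda_w) != 1L ||
      !is.finite(lambda_w) || lambda_w <= 0) {
    stop("`lambda_w` must be a single positive number, got ",
         deparse(lambda_w), ".")
  }
  if (!is.numeric(alpha) || alpha < 0) stop("`alpha` must be >= 0.")
  r <- floor(L / lambda_w)
  m <- 2 * r + 1
  sd0 <- switch(mode,
    standard = sqrt(1 / m),
    big      = sqrt(2 / (m * lambda_w))
  )
  sdh <- switch(mode,
    standard = sqrt(1 / m),
    big      = sqrt(4 / (m * lambda_w))
  )
  # fixed draw order: a_0, then (a_j, b_j) pairs for j = 1..r
  coefs <- with_seed(seed, {
    draws <- stats::rnorm(m)
    draws
  })
  a <- numeric(r + 1)
  b <- numeric(max(r, 0))
  a[1L] <- sd0 * coefs[1L]
  if (r > 0) {
    idx <- 1L + seq_len(2 * r)
    pair <- matrix(coefs[idx], nrow = 2L)
    a[-1L] <- sdh * pair[1L, ]
    b <- sdh * pair[2L, ]
  }
  structure(
    list(L = L, lambda_w = lambda_w, r = r,
         a = a, b = b,
         omega = if (r > 0) 2 * pi * seq_len(r) / L else numeric(0),
         mode = mode, alpha = alpha, seed = as.integer(seed),
         sd_dc = sd0, sd_harmonic = sdh),
    class = "srf"
  )
}

#' Evaluate a smooth random function or one of its derivatives
#'
#' Exact, closed-form evaluation by term-wise trigonometric differentiation;
#' no finite differencing is involved.
#'
#' @param f an \code{"srf"} object.
#' @param t numeric vector of times.
#' @param order derivative order (0 = the function itself).
#' @return numeric vector of the same length as \code{t}.
#' @export
srf_eval <- function(f, t, order = 0L) {
  stopifnot(inherits(f, "srf"))
  order <- as.integer(order)
  if (order < 0L) stop("`order` must be >= 0.")
  if (order > 0L) f <- srf_derivative(f, order)
  if (f$r == 0L) return(rep(f$alpha * f$a[1L], length(t)))
  arg <- outer(t, f$omega)                     # |t| x r
  vals <- f$a[1L] + cos(arg) %*% f$a[-1L] + sin(arg) %*% f$b
  as.numeric(f$alpha * vals)
}

#' Closed-form derivative of a smooth random function
#'
#' One application maps the coefficient pair \eqn{(a_j, b_j)} to
#' \eqn{(\omega_j b_j, -\omega_j a_j)} with \eqn{\omega_j = 2\pi j/L}, and the
#' DC term to zero; the result is again a trigonometric polynomial of the same
#' band limit and so is itself an \code{"srf"}-like object.
#'
#' @param f an \code{"srf"} object.
#' @param order number of differentiations (>= 1).
#' @return an \code{"srf"} object representing \eqn{\zeta^{(\mathrm{order})}}.
#' @export
srf_derivative <- function(f, order = 1L) {
  stopifnot(inherits(f, "srf"))
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1.")
  g <- f
  for (k in seq_len(order)) {
    if (g$r == 0L) {
      g$a[1L] <- 0
      next
    }
    a_new <- c(0, g$omega * g$b)
    b_new <- -g$omega * g$a[-1L]
    g$a <- a_new
    g$b <- b_new
  }
  g$derivative_order <- (f$derivative_order %||% 0L) + order
  g
}

#' Indefinite integral of a smooth random function on a grid
#'
#' Evaluates \eqn{\int_0^t \zeta(s)\,ds} by the exact term-wise
#' antiderivative.  In the big normalisation these integral paths converge to
#' standard Brownian paths as the wavelength shrinks.
#'
#' @param f an \code{"srf"} object.
#' @param t_grid increasing numeric vector of times.
#' @return numeric vector of \eqn{\int_0^t f} on the grid.
#' @export
srf_integral <- function(f, t_grid) {
  stopifnot(inherits(f, "srf"))
  if (is.unsorted(t_grid, strictly = FALSE)) {
    stop("`t_grid` must be increasing.")
  }
  out <- f$a[1L] * t_grid
  if (f$r > 0L) {
    arg <- outer(t_grid, f$omega)
    out <- out + sin(arg) %*% (f$a[-1L] / f$omega) -
      (cos(arg) - 1) %*% (f$b / f$omega)
  }
  as.numeric(f$alpha * out)
}

#' Analytic second moments of the smooth-random-function law
#'
#' Returns the exact ensemble moments implied by the coefficient law:
#' \eqn{\sigma^2 = E[\zeta(t)^2]} (pointwise, stationary in \eqn{t}) and
#' \eqn{\lambda_2^2 = E[\dot\zeta(t)^2]}.  These are the two inputs of the
#' tube-exceedance bound.
#'
#' @param L,lambda_w,mode,alpha as in [sample_srf()].
#' @return a list with \code{r}, \code{sigma2}, \code{sigma},
#'   \code{lambda2sq}, \code{lambda2}.
#' @export
srf_moments <- function(L, lambda_w, mode = c("standard", "big"), alpha = 1) {
  mode <- match.arg(mode)
  proto <- sample_srf(L, lambda_w, mode = mode, alpha = alpha, seed = 0L)
  r <- proto$r
  v0 <- proto$sd_dc^2
  vh <- proto$sd_harmonic^2
  sigma2 <- alpha^2 * (v0 + r * vh)
  lambda2sq <- alpha^2 * vh * sum(proto$omega^2)
  list(r = r, sigma2 = sigma2, sigma = sqrt(sigma2),
       lambda2sq = lambda2sq, lambda2 = sqrt(lambda2sq))
}

#' Tube-exceedance bound for a smooth random fluctuation
#'
#' Upper bound on the probability that the fluctuation leaves a tube of
#' half-width \code{u_thr} around the nominal path over a horizon \code{T}:
#' \deqn{P\Big(\sup_{[0,T]} \zeta \ge u\Big) \le
#'   e^{-u^2/(2\sigma^2)}\left(\frac{\sigma}{\sqrt{2\pi}\,u}
#'   + \frac{T\,\lambda_2}{2\pi\,\sigma}\right)}
#' with \eqn{\sigma^2 = E[\zeta^2]} and \eqn{\lambda_2^2 = E[\dot\zeta^2]}:
#' a Mill's-ratio tail term plus a Rice up-crossing term sharing the Gaussian
#' factor.  The raw bound can exceed 1; because it is reported as a
#' probability it is clipped to \eqn{[0, 1]} unless \code{clip = FALSE}.
#'
#' @param sigma RMS of the fluctuation (> 0).
#' @param lambda2 RMS of its first derivative (> 0).
#' @param u_thr threshold, same units as the fluctuation (> 0); vectorised.
#' @param T horizon, time units (> 0).
#' @param clip clip the reported bound to \eqn{[0,1]}?
#' @return numeric vector of bounds, one per threshold.
#' @export
tube_exceedance_bound <- function(sigma, lambda2, u_thr, T, clip = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number (zero RMS is rejected).")
  }
  if (!is.numeric(lambda2) || lambda2 <= 0) stop("`lambda2` must be > 0.")
  if (!is.numeric(T) || T <= 0) stop("`T` must be > 0.")
  if (any(!is.finite(u_thr) & !is.infinite(u_thr)) || any(u_thr <= 0)) {
    stop("`u_thr` must be positive.")
  }
  raw <- exp(-u_thr^2 / (2 * sigma^2)) *
    (sigma / (sqrt(2 * pi) * u_thr) + T * lambda2 / (2 * pi * sigma))
  raw[is.infinite(u_thr)] <- 0
  if (clip) pmin(pmax(raw, 0), 1) else raw
}

#' Tabulate a smooth random function and its first two derivatives
#'
#' @param f an \code{"srf"} object.
#' @param t_start,t_end,dt uniform grid specification.
#' @return a tibble with columns \code{t}, \code{zeta}, \code{dzeta},
#'   \code{d2zeta}.
#' @export
srf_grid <- function(f, t_start = 0, t_end = f$L, dt = f$lambda_w / 20) {
  t <- seq(t_start, t_end, by = dt)
  tibble::tibble(
    t = t,
    zeta = srf_eval(f, t, 0L),
    dzeta = srf_eval(f, t, 1L),
    d2zeta = srf_eval(f, t, 2L)
  )
}

#' @export
print.srf <- function(x, ...) {
  cat("<smooth random function>\n")
  cat(sprintf("  L = %g, lambda_w = %g, r = %d (%d coefficients)\n",
              x$L, x$lambda_w, x$r, 2 * x$r + 1))
  cat(sprintf("  mode = %s, alpha = %g, seed = %d\n",
              x$mode, x$alpha, x$seed))
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
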