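# ggplot2 views of the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a smooth random function with its first derivative
#'
#' @param object an \code{"srf"}.
#' @param t_start,t_end,dt evaluation grid.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot srf
#' @export
autoplot.srf <- function(object, t_start = 0, t_end = 2 * object$L,
                         dt = object$lambda_w / 20, ...) {
  g <- srf_grid(object, t_start, t_end, dt)
  df <- rbind(
    data.frame(t = g$t, value = g$zeta, curve = "zeta"),
    data.frame(t = g$t, value = g$dzeta, curve = "d zeta/dt")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = value, colour = curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("smooth random function (L = %g, lambda = %g, r = %d)",
                      object$L, object$lambda_w, object$r),
      x = "time", y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulation trace: outputs against their references
#'
#' @param object a \code{"flat_trace"}.
#' @param ... unused.
#' @return a ggplot (outputs and references over time, one facet per
#'   output, plus the action-discrepancy norm).
#' @method autoplot flat_trace
#' @export
autoplot.flat_trace <- function(object, ...) {
  ycols <- grep("^y_", names(object), value = TRUE)
  parts <- list()
  for (yc in ycols) {
    nm <- sub("^y_", "", yc)
    parts[[length(parts) + 1L]] <- data.frame(
      t = object$t, value = object[[yc]], series = "actual", component = nm)
    rc <- paste0("ref_", nm)
    if (rc %in% names(object)) {
      parts[[length(parts) + 1L]] <- data.frame(
        t = object$t, value = object[[rc]], series = "reference",
        component = nm)
    }
  }
  df <- do.call(rbind, parts)
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = value, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(actual = "blue",
                                            reference = "red")) +
    ggplot2::labs(x = "time", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the phase portrait of a planar tracking run
#'
#' For traces with exactly two referenced outputs (e.g. the eye position on
#' the screen): reference curve in red, actual movement in blue.
#'
#' @param trace a \code{"flat_trace"} with two \code{y_*}/\code{ref_*} pairs.
#' @return a ggplot.
#' @export
plot_tracking_plane <- function(trace) {
  ycols <- grep("^y_", names(trace), value = TRUE)
  rcols <- grep("^ref_", names(trace), value = TRUE)
  if (length(ycols) != 2L || length(rcols) != 2L) {
    stop("need a trace with exactly two referenced outputs.")
  }
  df <- rbind(
    data.frame(x = trace[[ycols[1L]]], y = trace[[ycols[2L]]],
               series = "actual"),
    data.frame(x = trace[[rcols[1L]]], y = trace[[rcols[2L]]],
               series = "reference")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = series)) +
    ggplot2::geom_path() +
    ggplot2::scale_colour_manual(values = c(actual = "blue",
                                            reference = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sub("^y_", "", ycols[1L]),
                  y = sub("^y_", "", ycols[2L]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Bergman tracking comparison
#'
#' @param object a \code{"bergman_demo"}.
#' @param ... unused.
#' @return a ggplot of the glucose tracking errors of the two laws.
#' @method autoplot bergman_demo
#' @export
autoplot.bergman_demo <- function(object, ...) {
  df <- rbind(
    data.frame(t = object$trace_flat$t, error = object$trace_flat$eact_G,
               law = "flatness-based"),
    data.frame(t = object$trace_gc$t, error = object$trace_gc$eact_G,
               law = "generalised-coordinate")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = error, colour = law)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "glucose tracking error (mg/dL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
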