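#' LC gradient profiles
#'
#' A gradient profile is an ordered set of `(time, %B)` breakpoints with
#' linear interpolation between them, where %B is the organic mobile-phase
#' fraction delivered by the pump. Times are minutes and strictly
#' increasing; %B lies in \[0, 100\].
#'
#' @param time_min breakpoint times, minutes, strictly increasing.
#' @param percent_b %B at each breakpoint, within \[0, 100\].
#' @return a `gradient_profile` object (a tibble of breakpoints).
#' @seealso [percent_b()], [lc_gradient_default()]
#' @export
gradient_profile <- function(time_min, percent_b) {
  time_min <- as.numeric(time_min)
  percent_b <- as.numeric(percent_b)
  if (length(time_min) != length(percent_b) || length(time_min) < 2) {
    stop_nanosampler("need at least two matching (time, %B) breakpoints", "gradient_error")
  }
  if (any(diff(time_min) <= 0)) {
    stop_nanosampler("breakpoint times must be strictly increasing", "gradient_error")
  }
  if (any(percent_b < 0) || any(percent_b > 100)) {
    stop_nanosampler("%B must lie within [0, 100]", "gradient_error")
  }
  out <- tibble::tibble(time_min = time_min, percent_b = percent_b)
  class(out) <- c("gradient_profile", class(tibble::tibble()))
  out
}

#' Default analytical gradient
#'
#' The bundled 50-minute pump program: %B starts at 1, ramps to 5 in the
#' first minute, runs the 5–25% elution gradient over 20 min, steps
#' through wash oscillations up to 75% and returns to 1% for the final
#' 15 min. Encoded as breakpoints
#' (0,1)(1,5)(21,25)(23,45)(24,75)(28,75)(29,25)(30,25)(31,75)(34,75)(35,1)(50,1).
#'
#' @return a [gradient_profile()].
#' @export
lc_gradient_default <- function() {
  gradient_profile(
    time_min = c(0, 1, 21, 23, 24, 28, 29, 30, 31, 34, 35, 50),
    percent_b = c(1, 5, 25, 45, 75, 75, 25, 25, 75, 75, 1, 1)
  )
}

#' Evaluate a gradient profile
#'
#' @param profile a [gradient_profile()].
#' @param t time(s) in minutes, within the profile's span.
#' @return %B at `t` (piecewise-linear interpolation), vectorized.
#' @examples
#' percent_b(lc_gradient_default(), c(0, 11, 21))
#' @export
percent_b <- function(profile, t) {
  t <- as.numeric(t)
  if (any(t < min(profile$time_min)) || any(t > max(profile$time_min))) {
    stop_nanosampler(
      sprintf("time outside the gradient span [%g, %g] min",
              min(profile$time_min), max(profile$time_min)),
      "range_error"
    )
  }
  stats::approx(profile$time_min, profile$percent_b, xout = t, ties = "ordered")$y
}

#' @rdname gradient_profile
#' @param x a `gradient_profile`.
#' @param ... unused.
#' @export
glance.gradient_profile <- function(x, ...) {
  tibble::tibble(
    duration_min = max(x$time_min) - min(x$time_min),
    start_percent_b = x$percent_b[1],
    end_percent_b = x$percent_b[nrow(x)],
    max_percent_b = max(x$percent_b),
    n_breakpoints = nrow(x)
  )
}

#' @rdname gradient_profile
#' @param object a `gradient_profile`.
#' @export
autoplot.gradient_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min, y = .data$percent_b)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Time (min)", y = "%B",
                  title = "Pump gradient profile") +
    ggplot2::theme_minimal()
}
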