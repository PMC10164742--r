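#' Fit the critical-speed hyperbola to speed--time-to-exhaustion data
#'
#' Sustainable speed falls hyperbolically with exhaustion time:
#' \deqn{Spd(T_{lim}) = CS + \frac{ADC}{B + T_{lim}}}
#' where CS (m/s) is the critical speed (the asymptote), ADC (m) the
#' anaerobic distance capacity, and B (s) a free time-offset constant.
#' Fitting treats duration as the independent variable and minimises speed
#' residuals by Levenberg-Marquardt nonlinear least squares, initialised at
#' CS0 = min speed, B0 = 10 s, and ADC0 from the two extreme points.
#'
#' Points are drawn from exhaustive runs at fixed speeds; when the speed at
#' maximal oxygen uptake (`vvo2max`) is given, only speeds inside `band`
#' (default 90--140% of it) are admitted, matching the protocol range over
#' which the hyperbola holds.
#'
#' @param points data frame with columns `speed_ms` and `duration_s` (time to
#'   exhaustion), at least 4 distinct points.
#' @param vvo2max optional speed at VO2max (m/s) used to apply `band`.
#' @param band admissible speed band as fractions of `vvo2max`.
#' @return an object of class `cs_model` with components `CS`, `ADC`, `B`,
#'   `fitted.values`, `residuals`, `data`, `flagged` (TRUE when CS <= 0).
#'   Methods: `print`, `coef`, `predict`, `residuals`, `fitted`, `plot`.
#' @examples
#' pts <- data.frame(duration_s = c(60, 120, 300, 600, 900))
#' pts$speed_ms <- 4.5 + 180 / (8 + pts$duration_s)
#' fit <- cs_model(pts)
#' coef(fit)   # CS 4.5, ADC 180, B 8
#' @export
cs_model <- function(points, vvo2max = NULL, band = c(0.9, 1.4)) {
  if (!is.data.frame(points) ||
      !all(c("speed_ms", "duration_s") %in% names(points))) {
    stop("points must be a data frame with speed_ms and duration_s columns")
  }
  if (!is.null(vvo2max)) {
    keep <- points$speed_ms >= band[1] * vvo2max &
      points$speed_ms <= band[2] * vvo2max
    points <- points[keep, , drop = FALSE]
  }
  points <- points[order(points$duration_s), , drop = FALSE]
  if (nrow(unique(points[c("speed_ms", "duration_s")])) < 4) {
    stop("at least 4 distinct (speed, duration) points are required")
  }
  v <- points$speed_ms; t <- points$duration_s
  B0 <- 10
  CS0 <- min(v)
  # ADC0 from the two extreme-duration points: v = CS + ADC/(B0 + t)
  i1 <- which.min(t); i2 <- which.max(t)
  ADC0 <- max((v[i1] - v[i2]) / (1 / (B0 + t[i1]) - 1 / (B0 + t[i2])), 1)
  fit <- minpack.lm::nlsLM(
    v ~ CS + ADC / (B + t),
    data = data.frame(v = v, t = t),
    start = list(CS = CS0, ADC = ADC0, B = B0),
    lower = c(CS = 0, ADC = 0, B = 0),
    control = minpack.lm::nls.lm.control(ptol = 1e-12, ftol = 1e-14,
                                         maxiter = 500)
  )
  est <- stats::coef(fit)
  fitted <- est[["CS"]] + est[["ADC"]] / (est[["B"]] + t)
  flagged <- est[["CS"]] <= 0
  if (flagged) warning("non-physical fit: CS <= 0; result flagged")
  structure(
    list(
      CS = est[["CS"]], ADC = est[["ADC"]], B = est[["B"]],
      data = points, fitted.values = fitted, residuals = v - fitted,
      fit = fit, flagged = flagged, call = match.call()
    ),
    class = "cs_model"
  )
}

#' @export
coef.cs_model <- function(object, ...) {
  c(CS = object$CS, ADC = object$ADC, B = object$B)
}

#' @export
residuals.cs_model <- function(object, ...) object$residuals

#' @export
fitted.cs_model <- function(object, ...) object$fitted.values

#' @export
print.cs_model <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Critical-speed hyperbola (n = %d):\n  CS = %s m/s, ADC = %s m, B = %s s\n",
    nrow(x$data), format(x$CS, digits = digits),
    format(x$ADC, digits = digits), format(x$B, digits = digits)
  ))
  if (x$flagged) cat("  [flagged: non-physical CS]\n")
  invisible(x)
}

#' @export
predict.cs_model <- function(object, duration, ...) {
  if (missing(duration)) return(object$fitted.values)
  if (any(duration < 0)) stop("duration must be non-negative")
  object$CS + object$ADC / (object$B + duration)
}

#' @export
plot.cs_model <- function(x, ...) {
  tt <- seq(min(x$data$duration_s) * 0.5, max(x$data$duration_s) * 1.5,
            length.out = 400)
  graphics::plot(tt, predict(x, tt), type = "l",
                 xlab = "time to exhaustion (s)", ylab = "speed (m/s)", ...)
  graphics::points(x$data$duration_s, x$data$speed_ms, pch = 19)
  graphics::abline(h = x$CS, lty = 3)
  invisible(x)
}

#' Time spent at VO2max during an exhaustive run
#'
#' The run to exhaustion at the speed at VO2max lasts `t_lim` seconds, of
#' which the first `ta_vo2max` seconds are spent attaining 95% of VO2max;
#' the remainder is the time actually held at maximal aerobic energy.
#'
#' @param t_lim time to exhaustion (s).
#' @param ta_vo2max time to attain >= 95% VO2max (s); must not exceed
#'   `t_lim`.
#' @return seconds at VO2max.
#' @export
tlim_at_vvo2max <- function(t_lim, ta_vo2max) {
  if (any(ta_vo2max > t_lim)) {
    stop("time to attain VO2max cannot exceed the time to exhaustion")
  }
  if (any(t_lim < 0) || any(ta_vo2max < 0)) stop("times must be non-negative")
  t_lim - ta_vo2max
}

#' Convert time at VO2max to the submaximal test speed
#'
#' Scales the time held at VO2max during the run at vVO2max to its
#' equivalent at the slower speed Vsub95 (the adjusted speed at which maximal
#' aerobic energy is still reached), in proportion to the speed ratio.
#'
#' @param time_at_max seconds held at VO2max during the vVO2max run.
#' @param vvo2max speed at VO2max (m/s).
#' @param vsub95 the adjusted submaximal speed (m/s), positive.
#' @return converted time (s).
#' @export
tlim_converted <- function(time_at_max, vvo2max, vsub95) {
  if (any(vsub95 <= 0)) stop("vsub95 must be positive")
  if (any(time_at_max < 0) || any(vvo2max <= 0)) {
    stop("time_at_max must be non-negative and vvo2max positive")
  }
  time_at_max * vvo2max / vsub95
}

#' Duration over which maximal aerobic speed is sustainable
#'
#' Combines the time to exhaustion at Vsub95 with the converted time at
#' VO2max from the vVO2max run. The published form carries a double negative
#' ("minus negative"), which resolves algebraically to a sum; `sign =
#' "subtract"` exposes the literal-subtraction reading for comparison.
#'
#' @param tlim_vsub95 time to exhaustion at Vsub95 (s), non-negative.
#' @param tlim_converted converted time at VO2max (s), non-negative.
#' @param sign `"add"` (default) or `"subtract"`.
#' @return MAS duration (s).
#' @export
mas_duration <- function(tlim_vsub95, tlim_converted,
                         sign = c("add", "subtract")) {
  sign <- match.arg(sign)
  if (any(tlim_vsub95 < 0) || any(tlim_converted < 0)) {
    stop("durations must be non-negative")
  }
  if (sign == "add") tlim_vsub95 + tlim_converted
  else tlim_vsub95 - tlim_converted
}

#' Maximal aerobic speed from the critical-speed hyperbola
#'
#' MAS is the minimum speed eliciting maximal aerobic energy, read off the
#' fitted speed--duration hyperbola at the MAS duration: `CS + ADC / (B +
#' MAS_dur)`. It always exceeds CS for a positive ADC and finite duration.
#'
#' @param cs a fitted [cs_model()] (or a list with `CS`, `ADC`, `B`).
#' @param mas_dur MAS duration (s), positive; see [mas_duration()].
#' @return MAS in m/s.
#' @examples
#' fit <- list(CS = 4.5, ADC = 180, B = 8)
#' mas(fit, 620)  # 4.7866...
#' @export
mas <- function(cs, mas_dur) {
  if (any(mas_dur <= 0)) stop("MAS duration must be positive")
  cs$CS + cs$ADC / (cs$B + mas_dur)
}
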