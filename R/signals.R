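#' Breath-by-breath oxygen-uptake trace
#'
#' A time series of oxygen uptake during a run, with optional respiratory
#' exchange ratio and heart rate channels. Time is seconds from run start and
#' must be strictly increasing; VO2 is in ml.kg-1.min-1 (the cart's native
#' unit -- the energy chain converts at the boundary).
#'
#' @param time sample times (s), strictly increasing.
#' @param vo2 oxygen uptake (ml.kg-1.min-1), non-negative.
#' @param rer,hr optional respiratory exchange ratio / heart rate channels.
#' @return a data frame of class `vo2_trace`.
#' @export
vo2_trace <- function(time, vo2, rer = NULL, hr = NULL) {
  if (length(time) != length(vo2)) stop("time and vo2 lengths differ")
  if (length(time) < 2) stop("a trace needs at least 2 samples")
  if (any(diff(time) <= 0)) stop("trace time must be strictly increasing")
  if (any(vo2 < 0)) stop("vo2 must be non-negative")
  out <- data.frame(time = time, vo2 = vo2)
  if (!is.null(rer)) out$rer <- rer
  if (!is.null(hr)) out$hr <- hr
  class(out) <- c("vo2_trace", class(out))
  out
}

#' Resample a VO2 trace to 1 s and smooth with a 5 s moving average
#'
#' Breath-by-breath data are irregularly sampled; the standard preprocessing
#' interpolates linearly onto a 1 s grid aligned to run start (t = 0) and
#' applies a centred moving average. Edge windows are truncated (shorter
#' averages), so constants and interior points of straight lines pass through
#' unchanged; the filter is idempotent on constant traces.
#'
#' @param trace a [vo2_trace()].
#' @param step grid spacing (s), default 1.
#' @param window moving-average width in samples, default 5 (i.e. 5 s on the
#'   default grid); must be odd.
#' @return a smoothed `vo2_trace` on the regular grid (rer/hr channels are
#'   interpolated but not smoothed).
#' @export
resample_and_smooth <- function(trace, step = 1, window = 5) {
  if (!inherits(trace, "vo2_trace")) trace <- vo2_trace(trace$time, trace$vo2)
  if (window %% 2 != 1) stop("window must be odd")
  grid <- seq(0, floor(max(trace$time) / step) * step, by = step)
  v <- stats::approx(trace$time, trace$vo2, xout = grid, rule = 2)$y
  sm <- moving_average(v, window)
  out <- vo2_trace(grid, sm)
  for (ch in intersect(c("rer", "hr"), names(trace))) {
    out[[ch]] <- stats::approx(trace$time, trace[[ch]], xout = grid, rule = 2)$y
  }
  out
}

# centred moving average with truncated edge windows
moving_average <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# multi-exponential on-kinetics model:
# baseline + sum_i A_i (1 - exp(-(t - d_i)/tau_i)) for t > d_i
vo2_kinetics_eval <- function(t, baseline, A, tau, delay) {
  y <- rep(baseline, length(t))
  for (i in seq_along(A)) {
    on <- t > delay[i]
    y[on] <- y[on] + A[i] * (1 - exp(-(t[on] - delay[i]) / tau[i]))
  }
  y
}

#' Fit multi-exponential VO2 on-kinetics
#'
#' Oxygen uptake at exercise onset rises as a sum of delayed exponentials
#' \deqn{VO_2(t) = b + \sum_i A_i (1 - e^{-(t-\delta_i)/\tau_i}) \cdot 1[t > \delta_i]}
#' with two (cardiodynamic + primary) or three (+ slow component) terms.
#' Fitting is weighted least squares (uniform weights by default, optionally
#' inverse-variance from the local residual spread) by Levenberg-Marquardt
#' with five deterministic multi-starts to guard against local minima;
#' `n_terms = "auto"` picks 2 vs 3 terms by AICc. Terms are returned sorted
#' by delay; amplitudes are constrained non-negative and delays to the run
#' duration.
#'
#' @param trace a smoothed [vo2_trace()] (see [resample_and_smooth()]) of at
#'   least 60 s.
#' @param n_terms 2, 3, or `"auto"`.
#' @param weighting `"uniform"` or `"inverse_variance"`.
#' @param seed integer seed for the multi-start perturbations (deterministic
#'   given the seed).
#' @return an object of class `vo2_kinetics`: `baseline`, `terms` (data
#'   frame with `amplitude`, `tau`, `delay`), `n_terms`, `weighted_sse`,
#'   `fitted.values`, `plateau` (baseline + sum of amplitudes). Methods:
#'   `print`, `coef`, `predict`, `residuals`, `fitted`.
#' @export
fit_vo2_kinetics <- function(trace, n_terms = c("auto", "2", "3"),
                             weighting = c("uniform", "inverse_variance"),
                             seed = 1) {
  n_terms <- as.character(n_terms)
  n_terms <- match.arg(n_terms)
  weighting <- match.arg(weighting)
  t <- trace$time; y <- trace$vo2
  if (max(t) - min(t) < 60) stop("kinetics fitting needs at least 60 s of data")

  w <- rep(1, length(y))
  if (weighting == "inverse_variance") {
    # local residual spread against a coarse running mean
    bw <- max(11, 2 * floor(length(y) / 40) + 1)
    resid_local <- y - moving_average(y, bw)
    s2 <- moving_average(resid_local^2, bw)
    w <- 1 / pmax(s2, stats::median(s2) * 0.1)
  }

  if (n_terms == "2") {
    pick <- fit_kinetics_k(t, y, w, 2, seed)
  } else {
    # the 3-term fit is warm-started from the 2-term solution (third
    # amplitude zero), so its SSE can never exceed the nested 2-term SSE
    f2 <- fit_kinetics_k(t, y, w, 2, seed)
    warm <- if (is.null(f2)) NULL else {
      c(f2$baseline, f2$A, 0, f2$tau, mean(f2$tau), f2$delay, max(f2$delay))
    }
    f3 <- fit_kinetics_k(t, y, w, 3, seed, extra_start = warm)
    pick <- if (n_terms == "3") f3 else {
      if (aicc_wls(f3, length(y)) < aicc_wls(f2, length(y))) f3 else f2
    }
  }
  if (is.null(pick)) {
    stop("VO2 kinetics fit failed to converge from any start; ",
         "check the trace for missing onset or non-physiological values")
  }
  ord <- order(pick$delay)
  terms <- data.frame(amplitude = pick$A[ord], tau = pick$tau[ord],
                      delay = pick$delay[ord])
  fitted <- vo2_kinetics_eval(t, pick$baseline, terms$amplitude, terms$tau,
                              terms$delay)
  structure(
    list(
      baseline = pick$baseline, terms = terms, n_terms = nrow(terms),
      weighted_sse = sum(w * (y - fitted)^2),
      fitted.values = fitted, residuals = y - fitted,
      plateau = pick$baseline + sum(terms$amplitude),
      trace = trace, weights = w
    ),
    class = "vo2_kinetics"
  )
}

# one k-term WLS fit, best of 5 deterministic starts (plus optional
# warm starts supplied by the caller)
fit_kinetics_k <- function(t, y, w, k, seed, extra_start = NULL) {
  baseline0 <- mean(y[seq_len(min(3, length(y)))])
  Atot <- max(max(y) - baseline0, 1)
  t_max <- max(t)
  base_start <- switch(
    k,
    NULL,
    list(A = Atot * c(0.7, 0.3), tau = c(20, 60), delay = c(0, 15)),
    list(A = Atot * c(0.6, 0.3, 0.1), tau = c(15, 45, 100), delay = c(0, 10, 40))
  )
  jit <- with_preserved_seed(seed, {
    matrix(stats::runif(5 * 3 * k, 0.5, 1.8), nrow = 5)
  })
  jit[1, ] <- 1  # first start unperturbed
  lower <- c(0, rep(0, k), rep(0.5, k), rep(0, k))
  upper <- c(max(y), rep(3 * Atot, k), rep(5 * t_max, k), rep(0.75 * t_max, k))
  starts <- lapply(seq_len(5), function(s) {
    c(baseline0,
      base_start$A * jit[s, 1:k],
      base_start$tau * jit[s, k + 1:k],
      base_start$delay * jit[s, 2 * k + 1:k])
  })
  if (!is.null(extra_start)) starts <- c(starts, list(extra_start))
  best <- NULL
  for (par0 in starts) {
    par0 <- pmin(pmax(par0, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        lower = lower, upper = upper,
        fn = function(p) {
          sqrt(w) * (y - vo2_kinetics_eval(t, p[1], p[1 + 1:k],
                                           p[1 + k + 1:k], p[1 + 2 * k + 1:k]))
        },
        control = minpack.lm::nls.lm.control(ptol = 1e-12, ftol = 1e-14,
                                             maxiter = 1000)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      p <- fit$par
      best <- list(baseline = p[1], A = p[1 + 1:k], tau = p[1 + k + 1:k],
                   delay = p[1 + 2 * k + 1:k], sse = sse, k = k)
    }
  }
  best
}

aicc_wls <- function(fit, n) {
  k <- 3 * fit$k + 2  # baseline + 3 per term + error variance
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(fit$sse, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
coef.vo2_kinetics <- function(object, ...) {
  tt <- object$terms
  out <- c(baseline = object$baseline)
  for (i in seq_len(nrow(tt))) {
    v <- c(tt$amplitude[i], tt$tau[i], tt$delay[i])
    names(v) <- paste0(c("A", "tau", "delay"), i)
    out <- c(out, v)
  }
  out
}

#' @export
residuals.vo2_kinetics <- function(object, ...) object$residuals

#' @export
fitted.vo2_kinetics <- function(object, ...) object$fitted.values

#' @export
predict.vo2_kinetics <- function(object, time, ...) {
  if (missing(time)) return(object$fitted.values)
  vo2_kinetics_eval(time, object$baseline, object$terms$amplitude,
                    object$terms$tau, object$terms$delay)
}

#' @export
print.vo2_kinetics <- function(x, digits = 4, ...) {
  cat(sprintf(
    "VO2 on-kinetics fit: %d exponential term(s), baseline %s, plateau %s ml/kg/min\n",
    x$n_terms, format(x$baseline, digits = digits),
    format(x$plateau, digits = digits)
  ))
  print(round(x$terms, digits))
  cat("weighted SSE:", format(x$weighted_sse, digits = digits), "\n")
  invisible(x)
}

#' Time to attain VO2max
#'
#' The primary criterion for attaining VO2max during an exhaustive run is
#' reaching at least 95% of the measured maximum. This returns the earliest
#' grid time at which the (smoothed) trace satisfies it; if the criterion is
#' never met the result is `NA` with attribute `secondary_criteria_required
#' = TRUE`, signalling that a fallback determination would be needed (not
#' implemented here).
#'
#' @param x a smoothed [vo2_trace()] or a [fit_vo2_kinetics()] object
#'   (evaluated on a 1 s grid over the trace duration).
#' @param vo2max measured maximal oxygen uptake (ml.kg-1.min-1), positive.
#' @param threshold criterion fraction of VO2max, default 0.95.
#' @return time in seconds, or `NA` with the flag attribute set.
#' @export
time_to_vo2max <- function(x, vo2max, threshold = 0.95) {
  if (!is.finite(vo2max) || vo2max <= 0) stop("vo2max must be positive")
  if (inherits(x, "vo2_kinetics")) {
    grid <- seq(0, floor(max(x$trace$time)), by = 1)
    v <- predict(x, grid)
  } else {
    grid <- x$time
    v <- x$vo2
  }
  hit <- which(v >= threshold * vo2max)
  if (!length(hit)) {
    return(structure(NA_real_, secondary_criteria_required = TRUE))
  }
  structure(grid[hit[1]], secondary_criteria_required = FALSE)
}

#' Evaluate the five VO2max attainment criteria
#'
#' A maximal test is accepted when at least three of five criteria hold:
#' a VO2 plateau (stage-to-stage change <= 2.1 ml.kg-1.min-1 despite
#' increasing load), respiratory exchange ratio at max >= 1.1, peak blood
#' lactate > 8 mmol/L, heart rate >= 90% of the age-predicted maximum
#' (taken as 220 - age), and volitional exhaustion. Missing measurements
#' count as unmet.
#'
#' @param age athlete age in years, positive.
#' @param plateau_delta stage-to-stage VO2 change at max (ml.kg-1.min-1).
#' @param rer respiratory exchange ratio at max.
#' @param peak_bla peak post-exercise blood lactate (mmol/L).
#' @param hr peak heart rate (beats/min).
#' @param exhaustion logical, volitional exhaustion reached.
#' @return list with `satisfied` (>= 3 criteria met), `count`, and `detail`
#'   (named logical vector).
#' @export
evaluate_vo2max_criteria <- function(age, plateau_delta = NA, rer = NA,
                                     peak_bla = NA, hr = NA,
                                     exhaustion = FALSE) {
  if (!is.finite(age) || age <= 0) stop("age must be positive")
  apmhr <- 220 - age
  detail <- c(
    plateau = isTRUE(plateau_delta <= 2.1),
    rer = isTRUE(rer >= 1.1),
    lactate = isTRUE(peak_bla > 8),
    heart_rate = isTRUE(hr >= 0.9 * apmhr),
    exhaustion = isTRUE(exhaustion)
  )
  list(satisfied = sum(detail) >= 3, count = sum(detail), detail = detail,
       apmhr = apmhr)
}

#' Lactate threshold by the log-log breakpoint method
#'
#' Blood lactate rises slowly with speed up to a threshold and steeply
#' beyond; on log(lactate) vs log(speed) axes the two regimes are close to
#' linear. The threshold speed is found by fitting two straight segments,
#' choosing the interior split (at least 3 points per segment) that
#' minimises the pooled SSE, and intersecting the segments. If the split
#' does not improve on a single line (SSE ratio < `min_f_ratio`) no
#' threshold is declared.
#'
#' @param points data frame with columns `speed_ms` (increasing) and `bla`
#'   (mmol/L, positive); at least 6 points.
#' @param min_f_ratio required single-line SSE / two-segment SSE
#'   improvement ratio.
#' @return a list of class `lactate_threshold`: `vLT` (m/s), `split` (index
#'   of the last point in the lower segment), `sse_single`, `sse_two`,
#'   `segments` (coefficients on the log-log scale).
#' @export
lactate_threshold_loglog <- function(points, min_f_ratio = 1.5) {
  if (!is.data.frame(points) || !all(c("speed_ms", "bla") %in% names(points))) {
    stop("points must be a data frame with speed_ms and bla columns")
  }
  n <- nrow(points)
  if (n < 6) stop("at least 6 lactate points are required")
  if (any(diff(points$speed_ms) <= 0)) stop("speeds must be strictly increasing")
  if (any(points$bla <= 0)) stop("lactate values must be positive")
  lx <- log(points$speed_ms); ly <- log(points$bla)

  sse_lm <- function(idx) {
    f <- stats::lm.fit(cbind(1, lx[idx]), ly[idx])
    list(sse = sum(f$residuals^2), coef = f$coefficients)
  }
  single <- sse_lm(seq_len(n))
  best <- NULL
  for (k in 3:(n - 3)) {
    lo <- sse_lm(1:k); hi <- sse_lm((k + 1):n)
    sse <- lo$sse + hi$sse
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, split = k, lo = lo$coef, hi = hi$coef)
    }
  }
  # a perfectly straight (or near-straight) profile has no breakpoint
  scale_ss <- sum((ly - mean(ly))^2)
  if (single$sse <= 1e-12 * max(scale_ss, 1) ||
      single$sse / max(best$sse, 1e-300) < min_f_ratio) {
    stop("no lactate threshold detected: the two-segment fit does not improve on a single line")
  }
  if (abs(best$lo[2] - best$hi[2]) < 1e-12) {
    stop("no lactate threshold detected: segment slopes coincide")
  }
  x_star <- unname((best$hi[1] - best$lo[1]) / (best$lo[2] - best$hi[2]))
  structure(
    list(
      vLT = exp(x_star), split = best$split,
      sse_single = single$sse, sse_two = best$sse,
      segments = list(lower = unname(best$lo), upper = unname(best$hi)),
      n = n
    ),
    class = "lactate_threshold"
  )
}

#' @export
print.lactate_threshold <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Log-log lactate threshold: vLT = %s m/s (split after point %d of %d)\n",
    format(x$vLT, digits = digits), x$split, x$n
  ))
  invisible(x)
}

#' Delta-50 velocity and the Vsub95 adjustment
#'
#' `v_delta50()` is the midpoint of the lactate-threshold speed and the
#' speed at VO2max -- the canonical heavy-domain test speed. Because most
#' athletes cannot reach VO2max there, the test speed is nudged by a
#' fraction of vVO2max (default +/-5%): `vsub95_adjust()` returns
#' `vdelta50 + fraction * vvo2max`.
#'
#' @param vlt lactate-threshold speed (m/s), must be below `vvo2max`.
#' @param vvo2max speed at VO2max (m/s).
#' @param vdelta50 the delta-50 speed (m/s).
#' @param fraction signed fraction of vVO2max to add (e.g. `0.05` or
#'   `-0.05`).
#' @return speed in m/s.
#' @examples
#' v_delta50(4, 5)            # 4.5
#' vsub95_adjust(4.5, 5, 0.05)  # 4.75
#' @export
v_delta50 <- function(vlt, vvo2max) {
  if (any(vlt <= 0) || any(vvo2max <= 0)) stop("speeds must be positive")
  if (any(vlt >= vvo2max)) stop("vLT must be below vVO2max")
  (vlt + vvo2max) / 2
}

#' @rdname v_delta50
#' @export
vsub95_adjust <- function(vdelta50, vvo2max, fraction = 0.05) {
  if (any(vdelta50 <= 0) || any(vvo2max <= 0)) stop("speeds must be positive")
  vdelta50 + fraction * vvo2max
}
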