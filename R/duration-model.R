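#' Parameters of the rational speed- or energy-duration model
#'
#' All-out running speed (or the corresponding energy demand) declines with
#' event duration following a rational function
#' \deqn{Spd(t) = \frac{MAnS + b\,t}{1 + c\,t}}
#' whose value at `t = 0` is the maximal anaerobic speed (MAnS, m/s) or
#' maximal anaerobic energy (E_MAnS, ml.kg-1.s-1), and whose long-duration
#' asymptote is `b / c` -- the speed (or energy) an athlete can sustain on
#' aerobic supply, i.e. the maximal aerobic speed MAS (energy E_MAS). The
#' curvature constant `c` (1/s) controls how fast the curve falls between the
#' two plateaus; it is fixed at 0.0185 /s by default throughout the package.
#'
#' The model is strictly decreasing only when `b < MAnS * c` (equivalently
#' `MAS < MAnS`, i.e. the anaerobic reserve is positive). A parameter set
#' violating that condition is accepted but flagged with a warning, since
#' fits to degenerate data can produce it.
#'
#' @param MAnS intercept at `t = 0`: maximal anaerobic speed (m/s) or energy
#'   (ml.kg-1.s-1).
#' @param b numerator slope (m/s^2 or ml.kg-1.s-2); `b / c` is the aerobic
#'   asymptote. Must be non-negative.
#' @param c curvature constant (1/s), positive; default 0.0185.
#' @param type `"speed"` or `"energy"`; affects labels only, the algebra is
#'   identical.
#' @return an object of class `reri_params`: a list with elements `MAnS`,
#'   `b`, `c`, `type`, plus derived `MAS` (= b/c) and `RERI` (= MAnS/MAS).
#' @seealso [speed_at()], [reri_model()], [two_trial_calibrate()]
#' @examples
#' p <- reri_params(MAnS = 9.0, b = 0.074, c = 0.0185)
#' p$MAS   # 4.0
#' p$RERI  # 2.25
#' @export
reri_params <- function(MAnS, b, c = 0.0185, type = c("speed", "energy")) {
  type <- match.arg(type)
  if (!is.finite(MAnS) || MAnS <= 0) stop("MAnS must be positive")
  if (!is.finite(c) || c <= 0) stop("curvature constant c must be positive")
  if (!is.finite(b) || b < 0) stop("b must be non-negative")
  degenerate <- b >= MAnS * c
  if (degenerate) {
    warning(sprintf(
      "degenerate profile: b/c = %.4g is not below MAnS = %.4g; the curve is not strictly decreasing",
      b / c, MAnS
    ))
  }
  structure(
    list(
      MAnS = MAnS, b = b, c = c, type = type,
      MAS = b / c, RERI = if (b > 0) MAnS / (b / c) else Inf,
      degenerate = degenerate
    ),
    class = "reri_params"
  )
}

#' @export
print.reri_params <- function(x, digits = 4, ...) {
  lab <- if (x$type == "speed") c("MAnS", "m/s", "MAS") else c("E_MAnS", "ml/kg/s", "E_MAS")
  cat(sprintf(
    "Rational %s-duration parameters:\n  %s = %s %s, b = %s, c = %s /s\n  %s = b/c = %s %s, RERI = %s\n",
    x$type, lab[1], format(x$MAnS, digits = digits), lab[2],
    format(x$b, digits = digits), format(x$c, digits = digits),
    lab[3], format(x$MAS, digits = digits), lab[2], format(x$RERI, digits = digits)
  ))
  if (isTRUE(x$degenerate)) cat("  [flagged: degenerate, not strictly decreasing]\n")
  invisible(x)
}

as_reri_params <- function(x, type = "speed") {
  if (inherits(x, "reri_model")) return(x$params)
  if (inherits(x, "reri_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    nm <- names(x)
    mans <- x[[intersect(c("MAnS", "E_MAnS"), nm)[1]]]
    b <- x[[intersect(c("b", "b_spd", "b_E"), nm)[1]]]
    cc <- x[[intersect(c("c", "c_spd", "c_E"), nm)[1]]]
    if (any(c("E_MAnS", "b_E") %in% nm)) type <- "energy"
    return(reri_params(mans, b, cc, type = type))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as rational-model parameters")
}

#' Evaluate the rational speed/energy-duration model
#'
#' `speed_at()` returns `(MAnS + b t) / (1 + c t)` -- the highest mean speed
#' sustainable for an all-out effort of duration `t`. `energy_at()` is the
#' same algebra for the energy variant and insists the parameters are of type
#' `"energy"`.
#'
#' @param params a [reri_params()] object (or a fitted [reri_model()]).
#' @param t duration(s) in seconds, non-negative; vectorised.
#' @return speed in m/s (or energy in ml.kg-1.s-1).
#' @examples
#' p <- reri_params(10, b = 0.111, c = 0.0185)
#' speed_at(p, c(0, 100))   # 10, 7.4035...
#' @export
speed_at <- function(params, t) {
  params <- as_reri_params(params)
  if (any(!is.finite(t)) || any(t < 0)) stop("duration t must be non-negative")
  (params$MAnS + params$b * t) / (1 + params$c * t)
}

#' @rdname speed_at
#' @export
energy_at <- function(params, t) {
  params <- as_reri_params(params, type = "energy")
  if (params$type != "energy") {
    stop("energy_at() expects energy-type parameters; use speed_at() for the speed model")
  }
  speed_at_unchecked(params, t)
}

speed_at_unchecked <- function(params, t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("duration t must be non-negative")
  (params$MAnS + params$b * t) / (1 + params$c * t)
}

#' Invert the speed-duration model for a target distance
#'
#' Finds the duration `t*` such that the mean model speed times `t*` covers a
#' given distance `d`, i.e. the predicted race time. Substituting Spd(t) t = d
#' gives the quadratic `b t^2 + (MAnS - c d) t - d = 0`; for `d > 0` and
#' `b > 0` its two roots have opposite signs (the product of roots is
#' `-d/b < 0`), so the larger root is the unique positive solution and no
#' tie-breaking arises. With `b = 0` the equation is linear,
#' `t = d / (MAnS - c d)`, which has no positive solution when
#' `MAnS <= c d`.
#'
#' @param params a [reri_params()] object (speed type) or fitted model.
#' @param distance target distance(s) in metres, positive; vectorised.
#' @return predicted duration(s) in seconds.
#' @examples
#' p <- reri_params(10, b = 0.111, c = 0.0185)
#' t800 <- invert_for_duration(p, 800)      # ~109.2 s
#' speed_at(p, t800) * t800                 # 800, round trip
#' @export
invert_for_duration <- function(params, distance) {
  params <- as_reri_params(params)
  if (any(!is.finite(distance)) || any(distance <= 0)) {
    stop("distance must be positive")
  }
  MAnS <- params$MAnS; b <- params$b; cc <- params$c
  if (b == 0) {
    denom <- MAnS - cc * distance
    if (any(denom <= 0)) {
      stop(sprintf(
        "no finite race time: with b = 0 the model cannot cover %.6g m (requires MAnS > c*d = %.6g)",
        max(distance), cc * max(distance)
      ))
    }
    return(distance / denom)
  }
  # larger quadratic root; the branch avoids catastrophic cancellation on
  # whichever side -B + disc (or B + disc) would subtract nearly equal numbers
  B <- MAnS - cc * distance
  disc <- sqrt(B^2 + 4 * b * distance)
  ifelse(B > 0, 2 * distance / (B + disc), (-B + disc) / (2 * b))
}

#' Calibrate the speed-duration model from two all-out trials
#'
#' The two-trial procedure: with the curvature constant `c` fixed (default
#' 0.0185 /s), the rational model is linear in `(MAnS, b)`, so two trials at
#' distinct durations determine it exactly. Writing `v_i (1 + c t_i) =
#' MAnS + b t_i` for each trial gives a 2x2 linear system; the calibrated
#' curve passes through both trial mean speeds with zero residual. The
#' derived maximal aerobic speed `MAS = b/c` and reserve index
#' `RERI = MAnS/MAS` are attached.
#'
#' @param trial_short,trial_long [run_trial()] objects (or anything
#'   `validate_trials()` accepts as one row); the short trial must have the
#'   smaller duration.
#' @param c fixed curvature constant (1/s).
#' @return a fitted [reri_model()] object with `method = "two_trial"`.
#' @examples
#' # Sebastian Coe, from championship 400 m and mile times:
#' m <- two_trial_calibrate(run_trial(47.05, 400), run_trial(227.33, 1609))
#' coef(m)                                   # MAnS ~10.44, b ~0.116
#' predict(m, distance = 800)                # ~104 s predicted 800 m
#' @export
two_trial_calibrate <- function(trial_short, trial_long, c = 0.0185) {
  if (!is.finite(c) || c <= 0) stop("curvature constant c must be positive")
  ts <- as_trial_row(trial_short)
  tl <- as_trial_row(trial_long)
  if (ts$duration_s == tl$duration_s) {
    stop("the two trials must have distinct durations (singular system)")
  }
  if (ts$duration_s > tl$duration_s) { tmp <- ts; ts <- tl; tl <- tmp }
  t1 <- ts$duration_s; v1 <- ts$speed_ms
  t2 <- tl$duration_s; v2 <- tl$speed_ms
  A <- rbind(c(1, t1), c(1, t2))
  y <- c(v1 * (1 + c * t1), v2 * (1 + c * t2))
  sol <- solve(A, y)
  params <- reri_params(MAnS = sol[1], b = max(sol[2], 0), c = c, type = "speed")
  if (sol[2] < 0) {
    warning("two-trial solve produced b < 0 (long trial faster than model allows); clamped to 0")
  }
  data <- rbind(as.data.frame(ts), as.data.frame(tl))
  new_reri_model(params, data, value_col = "speed_ms", method = "two_trial",
                 call = match.call())
}

as_trial_row <- function(x) {
  if (inherits(x, "run_trial")) return(x)
  if (is.data.frame(x) && nrow(x) == 1) return(validate_trials(x))
  if (is.numeric(x) && length(x) == 2) {
    # (distance, duration) pair
    return(run_trial(duration = x[2], distance = x[1]))
  }
  stop("expected a run_trial, a one-row trial data frame, or a (distance, duration) pair")
}

new_reri_model <- function(params, data, value_col, method, call,
                           fit = NULL) {
  t <- data$duration_s
  obs <- data[[value_col]]
  fitted <- speed_at_unchecked(params, t)
  structure(
    list(
      params = params, type = params$type,
      data = data, value_col = value_col,
      fitted.values = fitted, residuals = obs - fitted,
      method = method, fit = fit, call = call,
      flagged = isTRUE(params$degenerate)
    ),
    class = "reri_model"
  )
}

#' Fit the rational speed/energy-duration model to all-out trials
#'
#' Least-squares estimation of the rational model parameters from a set of
#' all-out trials. With the curvature constant fixed (`fix_c`, the default
#' and the standard use) the model is linear in `(MAnS, b)` after multiplying
#' through by `1 + c t`; the fit minimises speed residuals exactly via linear
#' least squares on the transformed design, and with exactly two trials it
#' reproduces [two_trial_calibrate()] to machine precision. With
#' `free_c = TRUE` all three parameters are estimated by Levenberg-Marquardt
#' nonlinear least squares on the speed residuals (initialised at MAnS0 = max
#' observed speed, c0 = `fix_c`, b0 = c0 * min observed speed; parameter
#' tolerance 1e-10), requiring at least three trials.
#'
#' @param trials a data frame of trials (see [validate_trials()]) or a list
#'   of [run_trial()] objects. For an energy fit, a data frame with columns
#'   `duration_s` and `energy` (ml.kg-1.s-1).
#' @param fix_c the fixed curvature constant (1/s); ignored as a constraint
#'   when `free_c = TRUE` but still used as the starting value.
#' @param free_c estimate `c` as well (opt-in).
#' @param type `"speed"` or `"energy"`.
#' @return an object of class `reri_model` with components `params`
#'   ([reri_params()]), `fitted.values`, `residuals`, `data`, `method`
#'   (`"linear_fixed_c"`, `"nls_free_c"` or `"two_trial"`), and `flagged`
#'   (TRUE when the fit violates the strictly-decreasing condition).
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `plot`, `simulate`.
#' @examples
#' p <- reri_params(9.03, b = 0.077, c = 0.0185)
#' d <- simulate_trials(p, durations = c(7, 25, 60, 150, 400))
#' fit <- reri_model(d)
#' coef(fit)
#' @export
reri_model <- function(trials, fix_c = 0.0185, free_c = FALSE,
                       type = c("speed", "energy")) {
  type <- match.arg(type)
  cl <- match.call()
  if (is.list(trials) && !is.data.frame(trials) &&
      all(vapply(trials, inherits, logical(1), "run_trial"))) {
    trials <- do.call(rbind, lapply(trials, as.data.frame))
  }
  if (type == "energy") {
    if (!all(c("duration_s", "energy") %in% names(trials))) {
      stop("an energy fit needs columns duration_s and energy")
    }
    data <- data.frame(duration_s = trials$duration_s, energy = trials$energy)
    value_col <- "energy"
  } else {
    data <- validate_trials(trials)
    value_col <- "speed_ms"
  }
  t <- data$duration_s
  v <- data[[value_col]]
  if (anyDuplicated(t)) stop("trial durations must be distinct")
  n <- length(t)

  if (!free_c) {
    if (!is.finite(fix_c) || fix_c <= 0) stop("fix_c must be positive")
    if (n < 2) stop("at least 2 trials are needed with a fixed c")
    # v (1 + c t) = MAnS + b t  =>  linear LS on speed residuals:
    # v = MAnS/(1+ct) + b t/(1+ct)
    w <- 1 + fix_c * t
    X <- cbind(MAnS = 1 / w, b = t / w)
    sol <- stats::lm.fit(X, v)$coefficients
    params <- suppressWarnings(
      reri_params(sol[["MAnS"]], max(sol[["b"]], 0), fix_c, type = type)
    )
    if (params$degenerate) {
      warning("fitted parameters violate the strictly-decreasing condition; result flagged")
    }
    return(new_reri_model(params, data, value_col,
                          method = if (n == 2) "two_trial" else "linear_fixed_c",
                          call = cl))
  }

  if (n < 3) stop("at least 3 trials are needed to estimate c freely")
  start <- list(MAnS = max(v), b = fix_c * min(v), c = fix_c)
  df <- data.frame(t = t, v = v)
  fit <- minpack.lm::nlsLM(
    v ~ (MAnS + b * t) / (1 + c * t),
    data = df, start = start,
    lower = c(MAnS = 1e-8, b = 0, c = 1e-8),
    control = minpack.lm::nls.lm.control(
      ptol = 1e-10, ftol = 1e-12, maxiter = 500
    )
  )
  est <- stats::coef(fit)
  params <- suppressWarnings(
    reri_params(est[["MAnS"]], est[["b"]], est[["c"]], type = type)
  )
  if (params$degenerate) {
    warning("fitted parameters violate the strictly-decreasing condition; result flagged")
  }
  new_reri_model(params, data, value_col, method = "nls_free_c",
                 call = cl, fit = fit)
}

#' @export
coef.reri_model <- function(object, ...) {
  p <- object$params
  c(MAnS = p$MAnS, b = p$b, c = p$c, MAS = p$MAS, RERI = p$RERI)
}

#' @export
residuals.reri_model <- function(object, ...) object$residuals

#' @export
fitted.reri_model <- function(object, ...) object$fitted.values

#' @export
print.reri_model <- function(x, digits = 4, ...) {
  cat(sprintf("Rational %s-duration model (%s, n = %d trials)\n",
              x$type, x$method, nrow(x$data)))
  print(x$params, digits = digits)
  cat(sprintf("  residual SD: %s\n",
              format(stats::sd(x$residuals), digits = digits)))
  invisible(x)
}

#' @export
summary.reri_model <- function(object, ...) {
  p <- object$params
  out <- list(
    coefficients = coef(object),
    method = object$method, type = object$type,
    n = nrow(object$data),
    residuals = object$residuals,
    rse = sqrt(sum(object$residuals^2) / max(nrow(object$data) - 2, 1)),
    flagged = object$flagged
  )
  class(out) <- "summary.reri_model"
  out
}

#' @export
print.summary.reri_model <- function(x, digits = 4, ...) {
  cat(sprintf("Rational %s-duration model, method %s, n = %d\n",
              x$type, x$method, x$n))
  print(round(x$coefficients, digits))
  cat("Residual standard error:", format(x$rse, digits = digits), "\n")
  if (x$flagged) cat("Flagged: parameters violate the strictly-decreasing condition\n")
  invisible(x)
}

#' Predict race performance from a fitted duration model
#'
#' For duration targets the model speed is evaluated directly; for distance
#' targets the race time is obtained by [invert_for_duration()] and the speed
#' as distance/time. Supplying the actual performance adds the
#' predicted/actual speed ratio and the percent error on speed (and on time;
#' the two differ only through the pred/act ratio).
#'
#' @param object a fitted [reri_model()] (or bare [reri_params()] for
#'   `predict_performance()`).
#' @param distance target distance(s), metres.
#' @param duration target duration(s), seconds. Give one of
#'   `distance`/`duration`.
#' @param actual_duration,actual_speed the observed performance(s), optional.
#' @param newdata alternatively, a data frame with a `distance_m` or
#'   `duration_s` column and optional `actual_duration_s`/`actual_speed_ms`.
#' @param ... unused.
#' @return a data frame of class `reri_prediction` with columns
#'   `target_distance_m`, `predicted_duration_s`, `predicted_speed_ms`,
#'   `actual_speed_ms`, `ratio` (pred/act) and `percent_error` (on speed),
#'   `percent_error_time`.
#' @examples
#' m <- two_trial_calibrate(run_trial(47.05, 400), run_trial(227.33, 1609))
#' predict(m, distance = 800, actual_duration = 101.7)
#' @export
predict.reri_model <- function(object, distance = NULL, duration = NULL,
                               actual_duration = NULL, actual_speed = NULL,
                               newdata = NULL, ...) {
  if (!is.null(newdata)) {
    distance <- newdata$distance_m
    duration <- newdata$duration_s
    actual_duration <- newdata$actual_duration_s
    actual_speed <- newdata$actual_speed_ms
    if (!is.null(distance) && all(is.na(distance))) distance <- NULL
    if (!is.null(duration) && !is.null(distance)) duration <- NULL
  }
  predict_performance(object$params, distance = distance, duration = duration,
                      actual_duration = actual_duration,
                      actual_speed = actual_speed)
}

#' @rdname predict.reri_model
#' @param params a [reri_params()] object or fitted model.
#' @export
predict_performance <- function(params, distance = NULL, duration = NULL,
                                actual_duration = NULL, actual_speed = NULL) {
  params <- as_reri_params(params)
  if (is.null(distance) == is.null(duration)) {
    stop("give exactly one of distance or duration as the target")
  }
  if (!is.null(distance)) {
    pred_t <- invert_for_duration(params, distance)
    pred_v <- distance / pred_t
    tgt_d <- distance
  } else {
    if (any(duration < 0)) stop("target duration must be non-negative")
    pred_v <- speed_at_unchecked(params, duration)
    pred_t <- duration
    tgt_d <- pred_v * duration
  }
  n <- length(pred_t)
  act_v <- rep(NA_real_, n)
  if (!is.null(actual_speed)) act_v <- rep_len(actual_speed, n)
  if (!is.null(actual_duration)) {
    ad <- rep_len(actual_duration, n)
    if (is.null(distance)) {
      stop("actual_duration needs a distance target; give actual_speed instead")
    }
    fill <- is.na(act_v) & !is.na(ad)
    act_v[fill] <- tgt_d[fill] / ad[fill]
  }
  ratio <- pred_v / act_v
  out <- data.frame(
    target_distance_m = tgt_d,
    predicted_duration_s = pred_t,
    predicted_speed_ms = pred_v,
    actual_speed_ms = act_v,
    ratio = ratio,
    percent_error = 100 * abs(pred_v - act_v) / act_v,
    percent_error_time = 100 * abs(1 / ratio - 1)
  )
  class(out) <- c("reri_prediction", class(out))
  out
}

#' Predict a batch of performances and summarise the agreement
#'
#' Applies [predict_performance()] to each target and reports the per-target
#' results together with the mean and SD of the percent errors and the
#' coefficient of determination (R^2) of predicted versus actual speeds,
#' the summary statistics used to judge model agreement across a cohort of
#' trials.
#'
#' @param params a [reri_params()] object or fitted [reri_model()].
#' @param targets a data frame with a `distance_m` (or `duration_s`) column
#'   and optional `actual_duration_s` / `actual_speed_ms`.
#' @return a list of class `reri_batch` with elements `predictions` (the
#'   [predict_performance()] data frame), `mean_percent_error`,
#'   `sd_percent_error` (NA for a single target), `r_squared`, `n`.
#' @export
batch_predict <- function(params, targets) {
  if (!is.data.frame(targets) || nrow(targets) == 0) {
    stop("targets must be a non-empty data frame")
  }
  params <- as_reri_params(params)
  preds <- predict_performance(
    params,
    distance = targets$distance_m,
    duration = if (is.null(targets$distance_m)) targets$duration_s,
    actual_duration = targets$actual_duration_s,
    actual_speed = targets$actual_speed_ms
  )
  pe <- preds$percent_error
  have <- is.finite(pe)
  r2 <- NA_real_
  if (sum(have) >= 2 && stats::var(preds$actual_speed_ms[have]) > 0) {
    r2 <- 1 - sum((preds$predicted_speed_ms[have] - preds$actual_speed_ms[have])^2) /
      sum((preds$actual_speed_ms[have] - mean(preds$actual_speed_ms[have]))^2)
  }
  out <- list(
    predictions = preds,
    mean_percent_error = if (any(have)) mean(pe[have]) else NA_real_,
    sd_percent_error = if (sum(have) >= 2) stats::sd(pe[have]) else NA_real_,
    r_squared = r2,
    n = nrow(preds)
  )
  class(out) <- "reri_batch"
  out
}

#' @export
print.reri_batch <- function(x, digits = 3, ...) {
  cat(sprintf("Batch prediction over %d targets\n", x$n))
  cat(sprintf("  mean percent error: %s%s\n",
              format(x$mean_percent_error, digits = digits),
              if (is.na(x$sd_percent_error)) "" else
                paste0(" +/- ", format(x$sd_percent_error, digits = digits))))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 (predicted vs actual speed): %s\n",
                format(x$r_squared, digits = digits)))
  }
  invisible(x)
}

#' @export
plot.reri_model <- function(x, t_max = NULL, ...) {
  t_obs <- x$data$duration_s
  if (is.null(t_max)) t_max <- 1.5 * max(t_obs)
  tt <- seq(0, t_max, length.out = 400)
  ylab <- if (x$type == "speed") "all-out speed (m/s)" else "energy demand (ml/kg/s)"
  graphics::plot(tt, speed_at_unchecked(x$params, tt), type = "l",
                 xlab = "duration (s)", ylab = ylab, ...)
  graphics::points(t_obs, x$data[[x$value_col]], pch = 19)
  graphics::abline(h = x$params$MAS, lty = 3)
  invisible(x)
}

#' @export
simulate.reri_model <- function(object, nsim = 1, seed = NULL,
                                durations = NULL, noise_sd = 0, ...) {
  if (is.null(durations)) durations <- object$data$duration_s
  out <- replicate(
    nsim,
    simulate_trials(object$params, durations = durations,
                    noise_sd = noise_sd, seed = seed),
    simplify = FALSE
  )
  if (nsim == 1) out[[1]] else out
}
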