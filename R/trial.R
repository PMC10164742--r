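#' Construct and validate an all-out run trial
#'
#' A trial is one all-out performance: a track race over a known distance, or
#' a treadmill run at a set belt speed. Track speed is the mean speed
#' distance/duration; treadmill trials carry the set belt speed and may have
#' no distance. If both distance and speed are supplied they must agree with
#' the duration to within `tol` (relative).
#'
#' @param duration duration in seconds (> 0).
#' @param distance distance in metres; may be `NA` for treadmill trials.
#' @param speed mean speed in m/s; filled from `distance / duration` when
#'   missing.
#' @param mode `"track"` or `"treadmill"`.
#' @param tol relative tolerance for the speed--distance consistency check.
#' @return a one-row data frame of class `run_trial` with columns
#'   `mode`, `distance_m`, `duration_s`, `speed_ms`.
#' @examples
#' run_trial(duration = 47.05, distance = 400)          # 400 m race
#' run_trial(duration = 60, speed = 5, mode = "treadmill")
#' @export
run_trial <- function(duration, distance = NA_real_, speed = NA_real_,
                      mode = c("track", "treadmill"), tol = 1e-9) {
  mode <- match.arg(mode)
  if (!is.finite(duration) || duration <= 0) {
    stop("trial duration must be a positive number, got ", duration)
  }
  if (is.na(distance) && is.na(speed)) {
    stop("a trial needs a distance or a speed")
  }
  if (is.na(speed)) speed <- distance / duration
  if (!is.finite(speed) || speed <= 0) {
    stop("trial mean speed must be positive, got ", speed)
  }
  if (!is.na(distance)) {
    if (distance <= 0) stop("trial distance must be positive, got ", distance)
    if (abs(speed * duration - distance) > tol * distance) {
      stop(sprintf(
        "inconsistent trial: speed %.6g m/s x duration %.6g s = %.6g m, but distance is %.6g m",
        speed, duration, speed * duration, distance
      ))
    }
  }
  out <- data.frame(
    mode = mode, distance_m = distance,
    duration_s = duration, speed_ms = speed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("run_trial", class(out))
  out
}

#' Validate a table of run trials
#'
#' Accepts a data frame with columns `duration_s` and at least one of
#' `distance_m` / `speed_ms` (plus optional `mode`, `athlete_id`), applies the
#' [run_trial()] checks row by row, and fills missing speeds. Errors name the
#' offending rows.
#'
#' @param trials data frame of trials.
#' @param tol relative tolerance for the consistency check.
#' @return the validated data frame with `speed_ms` filled in.
#' @export
validate_trials <- function(trials, tol = 1e-9) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("trials must be a non-empty data frame")
  }
  if (!"duration_s" %in% names(trials)) stop("trials must have a duration_s column")
  if (!"mode" %in% names(trials)) trials$mode <- "track"
  if (!"distance_m" %in% names(trials)) trials$distance_m <- NA_real_
  if (!"speed_ms" %in% names(trials)) trials$speed_ms <- NA_real_
  bad <- character(0)
  for (i in seq_len(nrow(trials))) {
    row <- tryCatch(
      run_trial(
        duration = as.numeric(trials$duration_s[i]),
        distance = as.numeric(trials$distance_m[i]),
        speed = as.numeric(trials$speed_ms[i]),
        mode = as.character(trials$mode[i]),
        tol = tol
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(row)) {
      bad <- c(bad, sprintf("row %d: %s", i, row))
    } else {
      trials$speed_ms[i] <- row$speed_ms
    }
  }
  if (length(bad)) {
    stop("invalid trials:\n  ", paste(bad, collapse = "\n  "))
  }
  trials
}

#' @export
print.run_trial <- function(x, ...) {
  cat(sprintf(
    "Run trial (%s): %s%.2f s at %.3f m/s\n",
    x$mode,
    if (is.na(x$distance_m)) "" else sprintf("%.0f m in ", x$distance_m),
    x$duration_s, x$speed_ms
  ))
  invisible(x)
}
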