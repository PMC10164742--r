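#' Fit the submaximal VO2--speed regression
#'
#' Steady-state oxygen uptake rises linearly with submaximal running speed.
#' The per-athlete ordinary least-squares line is the basis for all energy
#' extrapolations: evaluated at MAS and MAnS it yields the maximal aerobic
#' and anaerobic energies (E_MAS, E_MAnS), and inverted at the measured
#' VO2max it yields the speed at VO2max (vVO2max).
#'
#' @param points data frame with columns `speed_ms` (m/s) and `vo2`
#'   (ml.kg-1.s-1); at least 3 points at distinct speeds.
#' @return an object of class `submax_model` wrapping the [stats::lm()] fit,
#'   with `slope`, `intercept`, `r_squared`, `n`. Methods: `print`, `coef`,
#'   `predict`.
#' @examples
#' d <- data.frame(speed_ms = 2:7)
#' d$vo2 <- 0.18 * d$speed_ms + 0.05
#' fit <- fit_submax(d)
#' coef(fit)                    # intercept 0.05, slope 0.18
#' extrapolate_energy(fit, 4.16)
#' @export
fit_submax <- function(points) {
  if (!is.data.frame(points) || !all(c("speed_ms", "vo2") %in% names(points))) {
    stop("points must be a data frame with speed_ms and vo2 columns")
  }
  if (nrow(points) < 3) stop("at least 3 submaximal points are required")
  if (length(unique(points$speed_ms)) < 2) {
    stop("degenerate submaximal data: all speeds equal")
  }
  fit <- stats::lm(vo2 ~ speed_ms, data = points)
  sl <- unname(stats::coef(fit)[2])
  if (sl <= 0) warning("submaximal regression slope is not positive; check units")
  ss_tot <- sum((points$vo2 - mean(points$vo2))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(
    list(
      fit = fit, slope = sl, intercept = unname(stats::coef(fit)[1]),
      r_squared = r2, n = nrow(points), data = points
    ),
    class = "submax_model"
  )
}

#' @export
coef.submax_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.submax_model <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Submaximal VO2-speed regression (n = %d):\n  vo2 = %s + %s * speed  (r^2 = %s)\n",
    x$n, format(x$intercept, digits = digits),
    format(x$slope, digits = digits), format(x$r_squared, digits = digits)
  ))
  invisible(x)
}

#' @export
predict.submax_model <- function(object, speed, ...) {
  if (missing(speed)) return(stats::fitted(object$fit))
  extrapolate_energy(object, speed)
}

#' Extrapolate the submax regression to a (maximal) speed
#'
#' Evaluates `intercept + slope * speed`; used at MAS for E_MAS and at MAnS
#' for E_MAnS, treating the linear oxygen cost of running as extendable
#' beyond the submaximal range.
#'
#' @param reg a [fit_submax()] object (or list with `slope`, `intercept`).
#' @param speed speed(s) in m/s, positive.
#' @return energy in ml.kg-1.s-1.
#' @export
extrapolate_energy <- function(reg, speed) {
  if (any(speed < 0)) stop("speed must be non-negative")
  reg$intercept + reg$slope * speed
}

#' Speed at VO2max from the submax regression
#'
#' Inverts the submaximal line at the measured VO2max: the speed whose
#' extrapolated oxygen demand equals VO2max.
#'
#' @param reg a [fit_submax()] object.
#' @param vo2max measured maximal oxygen uptake, ml.kg-1.s-1.
#' @return vVO2max in m/s.
#' @export
vvo2max_from_submax <- function(reg, vo2max) {
  if (reg$slope <= 0) stop("cannot invert a non-positive regression slope")
  (vo2max - reg$intercept) / reg$slope
}

#' Running energy reserve indices
#'
#' The running energy reserve index is the ratio of the anaerobic to the
#' aerobic maximum, on speeds (`reri_spd` = MAnS/MAS) or on extrapolated
#' energies (`reri_e` = E_MAnS/E_MAS). Both are dimensionless and exceed 1
#' for any athlete with an anaerobic reserve; they coincide exactly when the
#' submax regression passes through the origin, since the slope then cancels
#' in the ratio.
#'
#' @param mans,mas maximal anaerobic and aerobic speeds (m/s), `mas > 0`.
#' @param e_mans,e_mas maximal anaerobic and aerobic energies
#'   (ml.kg-1.s-1), `e_mas > 0`.
#' @return the dimensionless index.
#' @examples
#' reri_spd(9.86, 3.64)   # 2.71, a sprint-trained profile
#' reri_spd(8.17, 4.70)   # 1.74, endurance-trained
#' @export
reri_spd <- function(mans, mas) {
  if (any(mas <= 0)) stop("MAS must be positive")
  mans / mas
}

#' @rdname reri_spd
#' @export
reri_e <- function(e_mans, e_mas) {
  if (any(e_mas <= 0)) stop("E_MAS must be positive")
  e_mans / e_mas
}

#' Assemble an athlete profile
#'
#' Bundles the four maxima and the derived reserve indices; checks the
#' ordering invariants (MAnS > MAS > 0, indices > 1).
#'
#' @param MAS,MAnS maximal aerobic and anaerobic speed (m/s).
#' @param E_MAS,E_MAnS maximal aerobic and anaerobic energy (ml.kg-1.s-1);
#'   optional.
#' @param group group label: `"ST"` (sprint-trained), `"MD"` (middle
#'   distance), `"ET"` (endurance-trained) or `"unknown"`.
#' @return an object of class `athlete_profile`.
#' @export
athlete_profile <- function(MAS, MAnS, E_MAS = NA_real_, E_MAnS = NA_real_,
                            group = c("unknown", "ST", "MD", "ET")) {
  group <- match.arg(group)
  if (!is.finite(MAS) || MAS <= 0) stop("MAS must be positive")
  if (!is.finite(MAnS) || MAnS <= MAS) stop("MAnS must exceed MAS")
  if (!is.na(E_MAS) && E_MAS <= 0) stop("E_MAS must be positive")
  structure(
    list(
      MAS = MAS, MAnS = MAnS, E_MAS = E_MAS, E_MAnS = E_MAnS,
      RERI_spd = reri_spd(MAnS, MAS),
      RERI_E = if (!is.na(E_MAS) && !is.na(E_MAnS)) reri_e(E_MAnS, E_MAS) else NA_real_,
      group = group
    ),
    class = "athlete_profile"
  )
}

#' @export
print.athlete_profile <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Athlete profile (%s):\n  MAS %s  MAnS %s m/s   RERI_spd %s\n",
    x$group, format(x$MAS, digits = digits), format(x$MAnS, digits = digits),
    format(x$RERI_spd, digits = digits)
  ))
  if (!is.na(x$RERI_E)) {
    cat(sprintf("  E_MAS %s  E_MAnS %s ml/kg/s   RERI_E %s\n",
                format(x$E_MAS, digits = digits),
                format(x$E_MAnS, digits = digits),
                format(x$RERI_E, digits = digits)))
  }
  invisible(x)
}

#' Group centroids of the speed reserve index
#'
#' Published group means of RERI_spd for sprint-trained (ST), middle-distance
#' (MD) and endurance-trained (ET) athletes, used as nearest-centroid
#' references by [classify_group()].
#'
#' @return named numeric vector of centroids.
#' @export
reri_group_centroids <- function() c(ST = 2.71, MD = 2.20, ET = 1.75)

#' Classify an athlete by the speed reserve index
#'
#' Nearest-centroid assignment on RERI_spd against the group means (ST 2.71,
#' MD 2.20, ET 1.75). An exact midpoint tie is broken toward the group with
#' the smaller centroid (the slower-group label), so e.g. the ST/MD midpoint
#' 2.455 classifies as MD.
#'
#' @param x an [athlete_profile()], or a numeric RERI_spd value (vectorised).
#' @param centroids named centroid vector, see [reri_group_centroids()].
#' @return character vector of group labels.
#' @examples
#' classify_group(c(2.70, 1.80, 2.455))  # "ST" "ET" "MD"
#' @export
classify_group <- function(x, centroids = reri_group_centroids()) {
  r <- if (inherits(x, "athlete_profile")) x$RERI_spd else as.numeric(x)
  if (any(is.na(r))) stop("RERI_spd is missing; cannot classify")
  vapply(r, function(ri) {
    d <- abs(centroids - ri)
    cand <- names(centroids)[d == min(d)]
    if (length(cand) > 1) cand <- cand[which.min(centroids[cand])]
    cand
  }, character(1))
}
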