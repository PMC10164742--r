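# evaluate expr with a temporary RNG state; restores .Random.seed on exit so
# generators are pure functions of (arguments, seed)
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# truncated normal by rejection (bounds at mean +/- 3 sd by default)
rtruncnorm1 <- function(mean, sd, lower = mean - 3 * sd, upper = mean + 3 * sd) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Reference group statistics for trained runners
#'
#' Published descriptive statistics (mean and SD per training group) for
#' maximal aerobic/anaerobic speeds and energies and the derived reserve
#' indices: sprint-trained (ST), middle-distance (MD) and endurance-trained
#' (ET) athletes. These parameterise the synthetic-athlete generators and
#' the nearest-centroid classifier.
#'
#' @return data frame with one row per group and columns
#'   `<var>_mean` / `<var>_sd` for MAS, MAnS, E_MAS, E_MAnS, RERI_spd,
#'   RERI_E.
#' @export
group_reference <- function() {
  data.frame(
    group = c("ST", "MD", "ET"),
    MAS_mean = c(3.64, 4.13, 4.70), MAS_sd = c(0.17, 0.22, 0.44),
    MAnS_mean = c(9.86, 9.07, 8.17), MAnS_sd = c(0.61, 0.19, 0.38),
    E_MAS_mean = c(0.78, 0.88, 0.93), E_MAS_sd = c(0.06, 0.06, 0.08),
    E_MAnS_mean = c(2.05, 1.99, 1.68), E_MAnS_sd = c(0.12, 0.09, 0.14),
    RERI_spd_mean = c(2.71, 2.20, 1.75), RERI_spd_sd = c(0.11, 0.11, 0.14),
    RERI_E_mean = c(2.63, 2.27, 1.82), RERI_E_sd = c(0.12, 0.13, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic athlete
#'
#' Draws an athlete from the group distributions in [group_reference()],
#' with all normals truncated at three SDs to keep profiles physiological.
#' The default `"ratio"` method draws MAS and the speed reserve index
#' RERI_spd and sets MAnS = RERI_spd * MAS, which reproduces the published
#' within-group dispersion of the reserve index directly (MAS and MAnS are
#' positively correlated within a training group); `"independent"` draws
#' MAS and MAnS independently (redrawing until MAnS > MAS), which inflates
#' the dispersion of their ratio. Energies come from a per-athlete
#' submaximal regression whose intercept is drawn near zero, so RERI_E
#' tracks RERI_spd closely, and the speed-duration parameters use the
#' canonical parameterisation b = c * MAS.
#'
#' @param group `"ST"`, `"MD"` or `"ET"`.
#' @param seed integer seed; the generator is deterministic per seed and
#'   does not disturb the global RNG state.
#' @param method `"ratio"` (default) or `"independent"`, see Details.
#' @param c curvature constant for the generated speed-duration parameters.
#' @return a list with `profile` ([athlete_profile()]), `params`
#'   ([reri_params()], speed type), `energy_params`, `submax` (list with
#'   `slope`, `intercept`), `group`, `seed`.
#' @examples
#' a <- make_athlete("MD", seed = 42)
#' a$profile
#' @export
make_athlete <- function(group = c("ST", "MD", "ET"), seed,
                         method = c("ratio", "independent"), c = 0.0185) {
  group <- match.arg(group)
  method <- match.arg(method)
  g <- group_reference()
  g <- g[g$group == group, ]
  with_preserved_seed(seed, {
    MAS <- rtruncnorm1(g$MAS_mean, g$MAS_sd)
    if (method == "ratio") {
      reri <- rtruncnorm1(g$RERI_spd_mean, g$RERI_spd_sd,
                          lower = max(g$RERI_spd_mean - 3 * g$RERI_spd_sd, 1.02))
      MAnS <- reri * MAS
    } else {
      repeat {
        MAnS <- rtruncnorm1(g$MAnS_mean, g$MAnS_sd)
        if (MAnS > MAS) break
      }
    }
    intercept <- rtruncnorm1(0, 0.01)
    E_MAS <- rtruncnorm1(g$E_MAS_mean, g$E_MAS_sd, lower = 0.2)
    slope <- (E_MAS - intercept) / MAS
    E_MAnS <- intercept + slope * MAnS
    params <- reri_params(MAnS, b = c * MAS, c = c, type = "speed")
    energy_params <- reri_params(E_MAnS, b = c * E_MAS, c = c, type = "energy")
    list(
      profile = athlete_profile(MAS, MAnS, E_MAS, E_MAnS, group = group),
      params = params, energy_params = energy_params,
      submax = list(slope = slope, intercept = intercept),
      group = group, seed = seed
    )
  })
}

#' Simulate a cohort of synthetic athletes
#'
#' @param n_per_group athletes per group.
#' @param seed master seed; per-athlete seeds are drawn from it.
#' @param groups which groups to include.
#' @inheritParams make_athlete
#' @return data frame with one row per athlete: `group`, `MAS`, `MAnS`,
#'   `E_MAS`, `E_MAnS`, `RERI_spd`, `RERI_E`, `seed`.
#' @export
simulate_cohort <- function(n_per_group = 100, seed = 2,
                            groups = c("ST", "MD", "ET"),
                            method = c("ratio", "independent")) {
  method <- match.arg(method)
  sub_seeds <- with_preserved_seed(seed, {
    sample.int(.Machine$integer.max %/% 2, n_per_group * length(groups))
  })
  rows <- list()
  i <- 0
  for (grp in groups) {
    for (j in seq_len(n_per_group)) {
      i <- i + 1
      a <- make_athlete(grp, seed = sub_seeds[i], method = method)
      p <- a$profile
      rows[[i]] <- data.frame(
        group = grp, MAS = p$MAS, MAnS = p$MAnS,
        E_MAS = p$E_MAS, E_MAnS = p$E_MAnS,
        RERI_spd = p$RERI_spd, RERI_E = p$RERI_E,
        seed = sub_seeds[i], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate all-out trials from a speed-duration model
#'
#' Speeds come from the rational model with additive Gaussian noise;
#' distances are derived as speed times duration, so generated trials are
#' internally consistent. Give either target durations or target distances
#' (converted to durations through the noise-free model first).
#'
#' @param params [reri_params()] (speed type) or fitted [reri_model()].
#' @param durations trial durations (s).
#' @param distances alternatively, target distances (m).
#' @param noise_sd SD of the Gaussian speed noise (m/s); 0 for noise-free.
#' @param seed optional seed (RNG state is preserved).
#' @param mode trial mode label.
#' @return a validated trials data frame (`mode`, `distance_m`,
#'   `duration_s`, `speed_ms`).
#' @export
simulate_trials <- function(params, durations = NULL, distances = NULL,
                            noise_sd = 0, seed = NULL, mode = "track") {
  params <- as_reri_params(params)
  if (is.null(durations) == is.null(distances)) {
    stop("give exactly one of durations or distances")
  }
  if (is.null(durations)) durations <- invert_for_duration(params, distances)
  v <- speed_at_unchecked(params, durations)
  if (noise_sd > 0) {
    v <- v + with_preserved_seed(seed, stats::rnorm(length(v), 0, noise_sd))
    v <- pmax(v, 0.1)
  }
  data.frame(
    mode = mode, distance_m = v * durations,
    duration_s = durations, speed_ms = v,
    stringsAsFactors = FALSE
  )
}

#' Simulate a breath-by-breath VO2 trace
#'
#' Multi-exponential on-kinetics (see [fit_vo2_kinetics()]) sampled on a
#' regular grid with additive Gaussian noise, emulating the smoothed
#' breath-by-breath signal of an exhaustive run.
#'
#' @param baseline resting/baseline VO2 (ml.kg-1.min-1).
#' @param amplitudes,taus,delays parallel vectors defining the exponential
#'   terms (ml.kg-1.min-1, s, s).
#' @param duration trace length (s).
#' @param noise_sd SD of the additive noise (ml.kg-1.min-1).
#' @param seed optional seed.
#' @param step sampling interval (s).
#' @return a [vo2_trace()].
#' @export
simulate_vo2_trace <- function(baseline, amplitudes, taus, delays,
                               duration, noise_sd = 0, seed = NULL,
                               step = 1) {
  stopifnot(length(amplitudes) == length(taus),
            length(taus) == length(delays))
  if (any(amplitudes < 0) || any(taus <= 0) || any(delays < 0)) {
    stop("amplitudes/delays must be non-negative and taus positive")
  }
  t <- seq(0, duration, by = step)
  v <- vo2_kinetics_eval(t, baseline, amplitudes, taus, delays)
  if (noise_sd > 0) {
    v <- v + with_preserved_seed(seed, stats::rnorm(length(v), 0, noise_sd))
    v <- pmax(v, 0)
  }
  vo2_trace(t, v)
}

#' Simulate a two-segment log-log lactate curve
#'
#' Blood lactate versus speed with a breakpoint at the threshold speed:
#' on log-log axes the curve is piecewise linear and continuous, with a
#' shallow slope below `vlt` and a steep slope above. Gaussian noise is
#' added on the log scale.
#'
#' @param vlt threshold speed (m/s).
#' @param speeds test speeds (m/s), increasing.
#' @param slopes length-2 vector of log-log slopes (below, above).
#' @param bla_at_vlt lactate at the threshold (mmol/L).
#' @param noise_sd SD of the log-scale noise.
#' @param seed optional seed.
#' @return data frame with `speed_ms` and `bla` columns.
#' @export
simulate_lactate_curve <- function(vlt, speeds, slopes = c(0.8, 6),
                                   bla_at_vlt = 2.5, noise_sd = 0,
                                   seed = NULL) {
  if (vlt <= 0 || any(speeds <= 0)) stop("speeds must be positive")
  lx <- log(speeds) - log(vlt)
  ly <- log(bla_at_vlt) + ifelse(lx <= 0, slopes[1] * lx, slopes[2] * lx)
  if (noise_sd > 0) {
    ly <- ly + with_preserved_seed(seed, stats::rnorm(length(ly), 0, noise_sd))
  }
  data.frame(speed_ms = speeds, bla = exp(ly))
}
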