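#' Read and write run-trial tables
#'
#' Trials are stored as comma-separated UTF-8 text with a mandatory header
#' and columns `athlete_id`, `mode`, `distance_m`, `duration_s`, `speed_ms`;
#' any one of `distance_m` / `speed_ms` may be blank per row (a missing
#' speed is filled from distance/duration). Reading validates every row and
#' errors with the offending line numbers. Writing keeps full precision, so
#' a write--read round trip preserves all numeric fields.
#'
#' @param path file path.
#' @param trials validated trials data frame.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty trials file: ", path)
  need <- c("duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trials file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  validate_trials(df)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(format(trials, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read submaximal VO2--speed points
#'
#' Columns `speed_ms` and `vo2_ml_kg_min`; oxygen uptake is converted to the
#' internal per-second unit on read.
#'
#' @param path file path.
#' @return data frame with `speed_ms` and `vo2` (ml.kg-1.s-1).
#' @export
read_submax <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("speed_ms", "vo2_ml_kg_min") %in% names(df))) {
    stop("submax file needs columns speed_ms and vo2_ml_kg_min")
  }
  data.frame(speed_ms = df$speed_ms, vo2 = vo2_min_to_sec(df$vo2_ml_kg_min))
}

#' Read a breath-by-breath trace
#'
#' Columns `t_s`, `vo2_ml_kg_min`, optional `rer`, `hr`.
#'
#' @param path file path.
#' @return a [vo2_trace()] (VO2 kept in ml.kg-1.min-1).
#' @export
read_breath <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t_s", "vo2_ml_kg_min") %in% names(df))) {
    stop("breath file needs columns t_s and vo2_ml_kg_min")
  }
  vo2_trace(df$t_s, df$vo2_ml_kg_min, rer = df$rer, hr = df$hr)
}

#' Read lactate--speed points
#'
#' Columns `speed_ms`, `bla_mmol_l`.
#'
#' @param path file path.
#' @return data frame with `speed_ms` and `bla`.
#' @export
read_lactate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("speed_ms", "bla_mmol_l") %in% names(df))) {
    stop("lactate file needs columns speed_ms and bla_mmol_l")
  }
  data.frame(speed_ms = df$speed_ms, bla = df$bla_mmol_l)
}

#' Read and write model parameters as JSON
#'
#' The speed triple is stored as `{"MAnS": ..., "b_spd": ..., "c_spd": ...}`
#' (energy variant: `E_MAnS`, `b_E`, `c_E`).
#'
#' @param path file path.
#' @param params a [reri_params()] or fitted [reri_model()].
#' @return `read_params()` returns a [reri_params()]; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  as_reri_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  p <- as_reri_params(params)
  obj <- if (p$type == "speed") {
    list(MAnS = p$MAnS, b_spd = p$b, c_spd = p$c)
  } else {
    list(E_MAnS = p$MAnS, b_E = p$b, c_E = p$c)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' Collects the tunable constants of the toolkit: the curvature constants of
#' the speed and energy duration models (1/s), the sign convention for the
#' MAS-duration combination, the admissible speed band for critical-speed
#' points (as fractions of vVO2max), and the display rounding profile
#' (speeds 1 dp, ratios 2 dp, percent errors 1 dp -- display only, internal
#' values are never rounded).
#'
#' @param c_spd,c_E curvature constants (1/s), positive.
#' @param mas_dur_sign `"add"` or `"subtract"`, see [mas_duration()].
#' @param speed_band length-2 fractions of vVO2max, low < high.
#' @param rounding named list of display digits.
#' @return a list of class `reri_config`.
#' @export
reri_config <- function(c_spd = 0.0185, c_E = 0.0185,
                        mas_dur_sign = c("add", "subtract"),
                        speed_band = c(0.9, 1.4),
                        rounding = list(speed = 1, ratio = 2, error = 1)) {
  mas_dur_sign <- match.arg(mas_dur_sign)
  if (c_spd <= 0 || c_E <= 0) stop("curvature constants must be positive")
  if (length(speed_band) != 2 || speed_band[1] >= speed_band[2]) {
    stop("speed_band must be (low, high) with low < high")
  }
  structure(
    list(c_spd = c_spd, c_E = c_E, mas_dur_sign = mas_dur_sign,
         speed_band = speed_band, rounding = rounding),
    class = "reri_config"
  )
}

#' Read a run configuration from JSON or YAML
#'
#' @param path file path ending in `.json`, `.yml` or `.yaml`.
#' @return a [reri_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML config requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext)
  }
  do.call(reri_config, raw[intersect(names(raw), names(formals(reri_config)))])
}

#' Write a prediction report
#'
#' Writes a CSV report of a [batch_predict()] result with both
#' full-precision and display-rounded columns (speeds 1 dp, ratios 2 dp,
#' errors 1 dp), followed by comment lines echoing the summary statistics
#' and the configuration, so downstream comparisons are never ambiguous
#' about rounding.
#'
#' @param batch a [batch_predict()] result (or a bare prediction data
#'   frame).
#' @param path output file path.
#' @param config optional [reri_config()] to echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(batch, path, config = reri_config()) {
  preds <- if (inherits(batch, "reri_batch")) batch$predictions else batch
  r <- config$rounding
  out <- cbind(
    preds,
    display_speed_pred = round(preds$predicted_speed_ms, r$speed),
    display_speed_act = round(preds$actual_speed_ms, r$speed),
    display_ratio = round(preds$ratio, r$ratio),
    display_percent_error = round(preds$percent_error, r$error)
  )
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  if (inherits(batch, "reri_batch")) {
    writeLines(sprintf(
      "# mean_percent_error,%.10g", batch$mean_percent_error
    ), con)
    if (!is.na(batch$sd_percent_error)) {
      writeLines(sprintf("# sd_percent_error,%.10g", batch$sd_percent_error), con)
    }
    if (!is.na(batch$r_squared)) {
      writeLines(sprintf("# r_squared,%.10g", batch$r_squared), con)
    }
  }
  writeLines(sprintf("# config,c_spd=%g,c_E=%g,mas_dur_sign=%s,band=%g-%g",
                     config$c_spd, config$c_E, config$mas_dur_sign,
                     config$speed_band[1], config$speed_band[2]), con)
  invisible(path)
}
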