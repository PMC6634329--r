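#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: the stimulus
#' schedule (1.7 Hz modulation between 0.5 and 1.0 of full luminance,
#' display gamma 2.26, 85 Hz refresh, 300 s blocks), preprocessing
#' (change-rate threshold 5 SD, 50 ms blink padding, cubic-spline
#' interpolation), analysis (1° rotation step, right eye as positive
#' class) and simulation parameters (see [simulation_params()]).
#'
#' @param ... overrides as `section$key = value` supplied via nested lists,
#'   e.g. `default_config(schedule = list(freq = 2))`.
#' @return An object of class `run_config` (a nested named list).
#' @seealso [load_config()], [save_config()]
#' @export
default_config <- function(...) {
  cfg <- list(
    schedule = list(
      freq = 1.7, phase_left_deg = -90, phase_diff_deg = 180,
      gamma = 2.26, lum_lo = 0.5, lum_hi = 1.0, refresh_hz = 85,
      block_duration_s = 300),
    preprocessing = list(
      k_sd = 5, pad_ms = 50, min_run_ms = 0, interp = "spline"),
    analysis = list(
      rotation_step_deg = 1, positive_class = "right"),
    simulation = simulation_params(),
    seed = 1L,
    paths = list(input = ".", output = ".")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(over)) {
    if (is.list(cfg[[sec]]) && is.list(over[[sec]])) {
      unknown <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
      if (length(unknown))
        stop(sprintf("unknown config key(s) under '%s': %s", sec,
                     paste(unknown, collapse = ", ")))
      cfg[[sec]][names(over[[sec]])] <- over[[sec]]
    } else {
      cfg[[sec]] <- over[[sec]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected with the offending key path; omitted keys take
#' the defaults of [default_config()]. The format is chosen by file
#' extension (`.json` = JSON, anything else parsed as YAML, of which JSON
#' is a subset).
#'
#' @param path file path to a YAML or JSON document. An empty document
#'   yields the full default configuration.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
  cfg
}

#' Save a run configuration
#'
#' Writes YAML (default) or JSON depending on the file extension; the
#' round trip `save_config()` then [load_config()] reproduces the
#' configuration exactly.
#'
#' @param cfg a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$simulation <- unclass(x$simulation)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config`.
#' @return `cfg`, invisibly; stops naming the offending key otherwise.
#' @export
validate_config <- function(cfg) {
  sc <- cfg$schedule
  chk <- function(cond, key)
    if (!isTRUE(cond)) stop("invalid config value at ", key)
  chk(sc$freq > 0, "schedule$freq")
  chk(sc$gamma > 0, "schedule$gamma")
  chk(sc$lum_lo >= 0 && sc$lum_lo < sc$lum_hi && sc$lum_hi <= 1,
      "schedule$lum_lo/lum_hi")
  chk(sc$refresh_hz > 0, "schedule$refresh_hz")
  chk(sc$block_duration_s > 0, "schedule$block_duration_s")
  pp <- cfg$preprocessing
  chk(pp$k_sd > 0, "preprocessing$k_sd")
  chk(pp$pad_ms >= 0, "preprocessing$pad_ms")
  chk(cfg$analysis$rotation_step_deg > 0, "analysis$rotation_step_deg")
  chk(cfg$analysis$positive_class %in% c("left", "right"),
      "analysis$positive_class")
  validate_simulation_params(do.call(simulation_params, cfg$simulation))
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  cat(sprintf("  schedule: %g Hz, phase diff %g deg, gamma %.2f, %g s\n",
              x$schedule$freq, x$schedule$phase_diff_deg,
              x$schedule$gamma, x$schedule$block_duration_s))
  cat(sprintf("  preprocessing: k_sd %g, pad %g ms\n",
              x$preprocessing$k_sd, x$preprocessing$pad_ms))
  cat(sprintf("  seed: %d\n", as.integer(x$seed)))
  invisible(x)
}
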