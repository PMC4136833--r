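#' Read a cumulative-release curve from CSV
#'
#' Expects a header with columns `time_h` and `release` (extra columns are
#' ignored). Percent data are divided by 100. Rows are sorted by time;
#' duplicate times and non-numeric cells are reported with their row
#' numbers. Interval-proportional weights are attached.
#'
#' @param path CSV file path.
#' @param units `"fraction"` (default) or `"percent"`.
#' @return A [release_curve()].
#' @export
read_release_csv <- function(path, units = c("fraction", "percent")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("time_h", "release"), names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("time_h", "release")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing '%s' in row(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  dup <- unique(df$time_h[duplicated(df$time_h)])
  if (length(dup) > 0) {
    stop(sprintf("duplicated time value(s): %s h",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  df <- df[order(df$time_h), , drop = FALSE]
  vals <- if (units == "percent") df$release / 100 else df$release
  release_curve(times = df$time_h, values = vals)
}

#' Write a cumulative-release curve to CSV
#'
#' Writes the `time_h,release` layout read back by [read_release_csv()].
#'
#' @param curve A [release_curve()].
#' @param path Output path.
#' @param units `"fraction"` (default) or `"percent"`.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curve, path, units = c("fraction", "percent")) {
  stopifnot(inherits(curve, "release_curve"))
  units <- match.arg(units)
  vals <- if (units == "percent") 100 * curve$values else curve$values
  utils::write.csv(data.frame(time_h = curve$times, release = vals),
                   path, row.names = FALSE)
  invisible(path)
}

#' Sampling-with-replacement correction for cumulative release assays
#'
#' During a dialysis release experiment, each withdrawn sample of volume `v`
#' removes payload already released into the bath of volume `V` and is
#' replaced with fresh medium, diluting later measurements. The standard
#' correction reconstructs what the concentration would have been without
#' withdrawal: \eqn{C^{corr}_k = C_k + (v/V) \sum_{j<k} C_j}, and the
#' cumulative released amount is \eqn{V \cdot C^{corr}_k}.
#'
#' @param raw_concentrations Measured concentrations at the sampling times
#'   (mass/volume), in time order.
#' @param sample_volume Withdrawn volume `v` per sample, mL (0 disables the
#'   correction).
#' @param bath_volume Bath volume `V`, mL; must exceed `v`.
#' @param output `"amount"` (default): corrected cumulative amounts
#'   \eqn{V C^{corr}}; `"concentration"`: the corrected concentrations.
#' @return Numeric vector, same length as the input.
#' @export
cumulative_sampling_correction <- function(raw_concentrations, sample_volume,
                                           bath_volume,
                                           output = c("amount", "concentration")) {
  output <- match.arg(output)
  if (sample_volume < 0) stop("'sample_volume' must be non-negative",
                              call. = FALSE)
  if (bath_volume <= 0 || sample_volume >= bath_volume) {
    stop("'bath_volume' must be positive and exceed 'sample_volume'",
         call. = FALSE)
  }
  C <- raw_concentrations
  corrected <- C + (sample_volume / bath_volume) *
    c(0, cumsum(C))[seq_along(C)]
  if (output == "amount") corrected * bath_volume else corrected
}

#' Default analysis configuration
#'
#' All tunables of a simulate-and-fit run with their defaults: geometry,
#' series truncation, threshold-candidate policy, weighting rule, input
#' units, noise level and seed.
#'
#' @return A named list (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    geometry = list(a_cm = 0.5, b_cm = 2.9, H_cm = 3.8),
    truncation_order = 62L,
    tc_candidates = "observation_times",
    weights = "interval_proportional",
    units = "fraction",
    time_unit = "hours",
    noise_sd = 0.01,
    seed = 1L,
    output_dir = "results"), class = "run_config")
}

#' Read / write an analysis configuration
#'
#' Configurations are stored as YAML; missing fields are filled from
#' [default_run_config()], and a written configuration reads back losslessly.
#'
#' @param path YAML file path.
#' @return `read_run_config`: a `run_config` list. `write_run_config`:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  cfg <- utils::modifyList(unclass(default_run_config()),
                           yaml::read_yaml(path))
  cfg$truncation_order <- as.integer(cfg$truncation_order)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Geometry from a configuration
#'
#' @param config A `run_config`.
#' @return A [cyl_geometry()].
#' @export
config_geometry <- function(config) {
  g <- config$geometry
  cyl_geometry(a = g$a_cm, b = g$b_cm, H = g$H_cm)
}

# Report formatter: scientific notation with 3 significant digits, the
# precision the fitted-diffusivity tables are conventionally printed at.
format_sci3 <- function(x) formatC(x, format = "e", digits = 2)

#' Write a fit report CSV with 3-significant-digit scientific notation
#'
#' @param report A data.frame (e.g. from [diffusion_fit_report()] or
#'   [fit_release_kinetics()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  out <- report
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- format_sci3(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
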