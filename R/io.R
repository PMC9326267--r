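# File round-tripping. CSV dialect: comma-separated, '.' decimal, UTF-8,
# mandatory header; units are encoded in the column names (s_m, x_m, y_m).

#' Read and write filament path CSV files
#'
#' Paths are stored as physical-unit coordinate tables with the mandatory
#' header `s_m,x_m,y_m` (arclength from the anchor, then planar
#' coordinates, all in metres). Round-trips are lossless to at least 12
#' significant digits.
#'
#' @param file File path.
#' @return `read_filament_csv()` returns a [filament_path()].
#' @export
read_filament_csv <- function(file) {
  df <- read.csv(file)
  need <- c("s_m", "x_m", "y_m")
  if (!all(need %in% names(df)))
    .halt("path CSV must have header columns ", paste(need, collapse = ","))
  filament_path(df$x_m, df$y_m, s = df$s_m)
}

#' @param path A [filament_path()].
#' @rdname read_filament_csv
#' @export
write_filament_csv <- function(path, file) {
  stopifnot(inherits(path, "filament_path"))
  df <- as.data.frame(path)
  df[] <- lapply(df, function(v) format(v, digits = 15, scientific = TRUE))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a JSON or YAML configuration file
#'
#' @param file Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_config <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "json") {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .halt("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(file)
  } else .halt("unsupported config format: ", ext)
}

#' Write a stiffness fit as a JSON record
#'
#' Writes the summary record `{beta, alpha_deg, beta_sd, n_points,
#' residual, flow_id}`; the per-point profile can be written alongside with
#' [write_fit_profile_csv()].
#'
#' @param fit A [fit_filament_stiffness()] result.
#' @param file Output path.
#' @export
write_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "stiffness_fit"))
  rec <- list(beta = fit$beta, alpha_deg = fit$alpha * 180 / pi,
              beta_sd = fit$beta_sd, n_points = fit$n_points,
              residual = fit$residual, flow_id = fit$experiment$id)
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' @param file Output path.
#' @rdname write_fit_json
#' @export
write_fit_profile_csv <- function(fit, file) {
  stopifnot(inherits(fit, "stiffness_fit"))
  df <- fit$profile
  names(df) <- c("s_m", "delta_obs_m", "delta_pred_m", "beta_local_Nm2")
  df[] <- lapply(df, function(v) format(v, digits = 15, scientific = TRUE))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
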