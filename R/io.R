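.incubation_cols <- c("station_id", "season", "treatment", "replicate",
                      "time_d", "variable", "value", "censored")
.known_vars <- c("chl", "din", "dip", "tdp", "dop", "apa", "salinity")

#' Write incubation data as long-format CSV
#'
#' Long (tidy) layout: one row per (bottle, time, variable) observation,
#' which accommodates the sparser APA sampling schedule without sentinel
#' columns. A provenance comment header (tool version, seed if known,
#' timestamp) precedes the data.
#'
#' @param data an `incubation_data` data frame (or any data frame with
#'   the standard columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_incubation_csv <- function(data, path) {
  stopifnot(all(.incubation_cols %in% names(data)))
  cfg <- attr(data, "config")
  con <- file(path, "w")
  on.exit(close(con))
  # header is deterministic (no timestamp) so identical runs produce
  # byte-identical files; run timestamps belong in the manifest
  writeLines(c(
    sprintf("# doputil %s incubation data",
            as.character(utils::packageVersion("doputil"))),
    if (!is.null(cfg)) sprintf("# seed: %d", cfg$seed),
    "# units: chl ug/L; din dip tdp dop uM; apa nM P/h; time_d days"),
    con)
  utils::write.table(data[, .incubation_cols], con, sep = ",",
                     row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read long-format incubation CSV
#'
#' Validates the schema: known variable names, non-negative
#' concentrations, logical censored flags, and no duplicated
#' (station, season, treatment, replicate, time, variable) keys. Errors
#' name the offending data row. Row order in the file is immaterial: the
#' result is sorted.
#'
#' @param path CSV file as written by [write_incubation_csv()] (comment
#'   lines starting with `#` are skipped).
#' @return an `incubation_data` data frame.
#' @export
read_incubation_csv <- function(path) {
  if (!file.exists(path)) stop("read_incubation_csv: no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(.incubation_cols, names(df))
  if (length(missing_cols))
    stop("read_incubation_csv: missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad_var <- which(!df$variable %in% .known_vars)
  if (length(bad_var))
    stop("read_incubation_csv: unknown variable '",
         df$variable[bad_var[1]], "' at data row ", bad_var[1])
  if (!is.numeric(df$value))
    stop("read_incubation_csv: non-numeric value column")
  bad_neg <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad_neg))
    stop("read_incubation_csv: negative or non-finite ",
         df$variable[bad_neg[1]], " value at data row ", bad_neg[1])
  df$censored <- as.logical(df$censored)
  if (anyNA(df$censored))
    stop("read_incubation_csv: censored column must be TRUE/FALSE")
  key <- do.call(paste, c(df[c("station_id", "season", "treatment",
                               "replicate", "time_d", "variable")],
                          sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("read_incubation_csv: duplicated observation key at data row ",
         dup[1])
  df$replicate <- as.integer(df$replicate)
  df <- df[order(df$station_id, df$season, df$treatment, df$replicate,
                 df$variable, df$time_d), .incubation_cols]
  rownames(df) <- NULL
  class(df) <- c("incubation_data", "data.frame")
  df
}

#' Write a grid field as CF-style netCDF
#'
#' Dimensions `lat`/`lon` with cell-center coordinates and degree units;
#' masked cells stored as the fill value. Coordinate convention (cell
#' centers) is recorded in the global attributes.
#'
#' @param field a [grid_field()].
#' @param path output `.nc` file.
#' @param fill fill value for invalid cells.
#' @return `path`, invisibly.
#' @export
write_grid_netcdf <- function(field, path, fill = -9999) {
  stopifnot(inherits(field, "grid_field"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  var <- ncdf4::ncvar_def(field$name, field$units,
                          list(dim_lon, dim_lat), fill,
                          prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc))
  vals <- field$values
  vals[!field$mask] <- NA_real_
  ncdf4::ncvar_put(nc, var, t(vals))  # ncdf4 stores lon-major
  ncdf4::ncatt_put(nc, 0, "coordinate_convention",
                   "cell centers, regular lat/lon")
  ncdf4::ncatt_put(nc, 0, "source",
                   paste("doputil",
                         as.character(utils::packageVersion("doputil"))))
  invisible(path)
}

#' Read a grid field from netCDF
#'
#' Accepts any netCDF with `lat`/`lon` (or `latitude`/`longitude`)
#' dimensions. Latitude is normalized to ascending order and longitude to
#' [-180, 180) (0-360 files are re-indexed, values preserved); fill
#' values become masked cells. An all-fill variable yields a fully masked
#' field, not an error.
#'
#' @param path netCDF file.
#' @param variable variable name to read.
#' @return a [grid_field()].
#' @export
read_grid_netcdf <- function(path, variable) {
  if (!file.exists(path)) stop("read_grid_netcdf: no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop("read_grid_netcdf: variable '", variable, "' not in file (has: ",
         paste(names(nc$var), collapse = ", "), ")")
  dims <- names(nc$dim)
  lat_name <- intersect(c("lat", "latitude"), dims)[1]
  lon_name <- intersect(c("lon", "longitude"), dims)[1]
  if (is.na(lat_name) || is.na(lon_name))
    stop("read_grid_netcdf: file lacks lat/lon dimensions")
  lat <- as.numeric(ncdf4::ncvar_get(nc, lat_name))
  lon <- as.numeric(ncdf4::ncvar_get(nc, lon_name))
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = TRUE)
  v <- nc$var[[variable]]
  vdims <- sapply(v$dim, function(d) d$name)
  if (identical(vdims[1:2], c(lon_name, lat_name))) {
    vals <- t(vals)
  } else if (!identical(vdims[1:2], c(lat_name, lon_name))) {
    stop("read_grid_netcdf: variable '", variable,
         "' is not on (lat, lon) dimensions")
  }
  if (length(lat) > 1 && lat[1] > lat[2]) {
    lat <- rev(lat)
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  }
  lon_wrapped <- ((lon + 180) %% 360) - 180
  ord <- order(lon_wrapped)
  lon <- lon_wrapped[ord]
  vals <- vals[, ord, drop = FALSE]
  grid_field(lat, lon, vals, units = v$units, name = variable)
}

#' Analysis run configuration
#'
#' The knobs shared across the pipeline stages, with the canonical
#' defaults: Redfield N:P 16 (robustness variants 48 and 80), two-sided
#' alpha 0.05, index threshold 1.20, and below-detection values used at
#' the detection limit.
#'
#' @param redfield_np N:P requirement ratio for the potential-DOP
#'   calculation.
#' @param dop_ratio_variants ratio variants reported alongside the
#'   default.
#' @param alpha significance level, in (0, 1).
#' @param index_threshold Log10(Chl a / DIP) classification threshold.
#' @param censoring_policy how below-detection values enter summaries:
#'   `"at_limit"` (use the detection-limit value), `"half_limit"`, or
#'   `"drop"`.
#' @param include_t0 include the t = 0 sample in time averages.
#' @return list of class `run_config`.
#' @export
run_config <- function(redfield_np = 16,
                       dop_ratio_variants = c(16, 48, 80),
                       alpha = 0.05,
                       index_threshold = 1.20,
                       censoring_policy = c("at_limit", "half_limit",
                                            "drop"),
                       include_t0 = TRUE) {
  censoring_policy <- match.arg(censoring_policy)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("run_config: alpha must be in (0, 1)")
  if (any(dop_ratio_variants <= 0))
    stop("run_config: ratio variants must be positive")
  structure(list(redfield_np = redfield_np,
                 dop_ratio_variants = dop_ratio_variants,
                 alpha = alpha,
                 index_threshold = index_threshold,
                 censoring_policy = censoring_policy,
                 include_t0 = include_t0),
            class = "run_config")
}
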