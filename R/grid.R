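#' Regular latitude-longitude gridded scalar field
#'
#' A minimal container for a single-variable field on a regular lat/lon
#' grid with a validity mask. Cells are labelled by their centers
#' (e.g. 1-degree cells at -179.5, -178.5, ...); latitudes ascending,
#' longitudes in [-180, 180).
#'
#' @param lat,lon cell-center coordinates, strictly increasing, regular
#'   spacing.
#' @param values numeric matrix, `length(lat)` rows x `length(lon)`
#'   columns; `NA` where invalid.
#' @param mask logical matrix of the same shape, `TRUE` = valid. Defaults
#'   to `!is.na(values)`.
#' @param units unit string carried with the field.
#' @param name variable name.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(lat, lon, values, mask = NULL,
                       units = "", name = "field") {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("grid_field: values must be length(lat) x length(lon)")
  .check_regular <- function(x, what) {
    if (length(x) > 1L) {
      d <- diff(x)
      if (any(d <= 0) || max(abs(d - d[1])) > 1e-6 * abs(d[1]))
        stop("grid_field: ", what,
             " centers must be strictly increasing and regular")
    }
  }
  .check_regular(lat, "latitude")
  .check_regular(lon, "longitude")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- mask & !is.na(values)
  if (any(!is.finite(values[mask])))
    stop("grid_field: non-finite values inside the valid mask")
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 values = values, mask = mask,
                 units = units, name = name),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s]: %d x %d cells, %d valid\n",
              x$name, x$units, length(x$lat), length(x$lon),
              sum(x$mask)))
  rng <- range(x$values[x$mask])
  cat(sprintf("  lat %.2f..%.2f  lon %.2f..%.2f  values %.4g..%.4g\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              rng[1], rng[2]))
  invisible(x)
}

#' Grid specification for synthetic global fields
#'
#' @param res cell size in degrees (1 for the standard analysis grid).
#' @param lon_range,lat_range extents; must lie within [-180, 180] and
#'   [-90, 90].
#' @return list with cell-center vectors `lat`, `lon` and the `res`.
#' @export
grid_spec <- function(res = 1, lon_range = c(-180, 180),
                      lat_range = c(-90, 90)) {
  if (!is.numeric(res) || res <= 0 ||
      lon_range[1] < -180 || lon_range[2] > 180 ||
      lat_range[1] < -90 || lat_range[2] > 90 ||
      lon_range[1] >= lon_range[2] || lat_range[1] >= lat_range[2])
    stop("grid_spec: invalid grid specification")
  list(res = res,
       lon = seq(lon_range[1] + res / 2, lon_range[2] - res / 2, by = res),
       lat = seq(lat_range[1] + res / 2, lat_range[2] - res / 2, by = res))
}

#' Simulate synthetic global chlorophyll and DIP fields
#'
#' Builds a fine-resolution lognormal chlorophyll-a field with a
#' coastal-enrichment gradient around a synthetic continent, and a
#' coarse (analysis-grid) DIP field constructed with an inverse gradient
#' such that an exact, configurable fraction of ocean cells exceeds the
#' biomass-relative P-scarcity threshold Log10(Chl a / DIP) >=
#' `threshold`. A stand-in for satellite ocean-color and nutrient
#' climatologies: it has their resolution structure and masking, not
#' their geography.
#'
#' @param seed RNG seed; fields are bit-identical across runs for a fixed
#'   seed.
#' @param grid a [grid_spec()] for the coarse (analysis) grid.
#' @param subcells fine subcells per coarse cell side (>= 4 gives the
#'   fine field at least a 4x4 refinement).
#' @param exceed_fraction target fraction of ocean cells with index >=
#'   `threshold` (matched exactly after rounding to a whole number of
#'   cells).
#' @param threshold index threshold used in the construction
#'   (default 1.20).
#' @param land_fraction approximate fraction of coarse cells masked as
#'   land.
#' @param chl_cv lognormal spatial variability of the fine chlorophyll
#'   subcells within a coarse cell.
#' @return list with `chl_fine` (fine grid, ug L-1) and `dip_coarse`
#'   (coarse grid, uM), both `grid_field`s.
#' @export
simulate_global_fields <- function(seed = 1L, grid = grid_spec(),
                                   subcells = 4,
                                   exceed_fraction = 0.25,
                                   threshold = 1.20,
                                   land_fraction = 0.3,
                                   chl_cv = 0.3) {
  stopifnot(subcells >= 4, exceed_fraction >= 0, exceed_fraction <= 1)
  set.seed(seed)
  nlat <- length(grid$lat); nlon <- length(grid$lon)

  # deterministic synthetic continent: smooth bump field thresholded at
  # the requested land fraction
  latm <- matrix(grid$lat, nlat, nlon)
  lonm <- matrix(grid$lon, nlat, nlon, byrow = TRUE)
  bump <- cos(latm * pi / 60) * sin((lonm + 40) * pi / 120) +
    0.5 * cos((latm - 20) * pi / 45) * cos(lonm * pi / 90)
  land <- bump >= stats::quantile(bump, 1 - land_fraction)
  ocean <- !land
  n_ocean <- sum(ocean)
  if (n_ocean == 0) stop("simulate_global_fields: all-land grid")

  # coastal enrichment: chlorophyll decays with (grid) distance from land
  dist <- matrix(Inf, nlat, nlon)
  dist[land] <- 0
  # iterative chamfer sweep; grids are small so a few passes suffice
  for (sweep in 1:4) {
    for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
      nb <- c(if (i > 1) dist[i - 1, j] + 1,
              if (i < nlat) dist[i + 1, j] + 1,
              if (j > 1) dist[i, j - 1] + 1,
              if (j < nlon) dist[i, j + 1] + 1)
      if (length(nb)) dist[i, j] <- min(dist[i, j], nb)
    }
  }
  chl_coarse_mean <- exp(0.5 - 0.15 * pmin(dist, 15))  # ug L-1, ~1.6 coast

  # fine chlorophyll field: lognormal subcells around the coarse mean
  fres <- grid$res / subcells
  flat <- seq(min(grid$lat) - grid$res / 2 + fres / 2,
              max(grid$lat) + grid$res / 2 - fres / 2, by = fres)
  flon <- seq(min(grid$lon) - grid$res / 2 + fres / 2,
              max(grid$lon) + grid$res / 2 - fres / 2, by = fres)
  sdlog <- sqrt(log(1 + chl_cv^2))
  coarse_of_fine_lat <- ceiling(seq_along(flat) / subcells)
  coarse_of_fine_lon <- ceiling(seq_along(flon) / subcells)
  chl_fine <- matrix(NA_real_, length(flat), length(flon))
  base <- chl_coarse_mean[cbind(rep(coarse_of_fine_lat, length(flon)),
                                rep(coarse_of_fine_lon,
                                    each = length(flat)))]
  oc_fine <- ocean[cbind(rep(coarse_of_fine_lat, length(flon)),
                         rep(coarse_of_fine_lon, each = length(flat)))]
  vals <- base * exp(stats::rnorm(length(base), -sdlog^2 / 2, sdlog))
  vals[!oc_fine] <- NA_real_
  chl_fine[] <- vals
  chl_fine_field <- grid_field(flat, flon, chl_fine,
                               units = "ug L-1", name = "chl")

  # DIP constructed from the realized coarse chlorophyll so that exactly
  # round(exceed_fraction * n_ocean) ocean cells have index >= threshold
  chl_coarse <- regrid_mean(chl_fine_field, grid)
  n_exceed <- round(exceed_fraction * n_ocean)
  ocean_idx <- which(ocean)
  exceed_idx <- sample(ocean_idx, n_exceed)
  target_index <- matrix(NA_real_, nlat, nlon)
  target_index[ocean_idx] <-
    threshold - 0.1 - abs(stats::rnorm(n_ocean, 0, 0.4))
  target_index[exceed_idx] <-
    threshold + abs(stats::rnorm(n_exceed, 0, 0.3))
  dip <- chl_coarse$values / 10^target_index
  dip[!ocean] <- NA_real_
  dip_field <- grid_field(grid$lat, grid$lon, dip,
                          units = "uM", name = "dip")
  list(chl_fine = chl_fine_field, dip_coarse = dip_field)
}

#' Aggregate a fine grid to a coarse analysis grid by cell means
#'
#' Each coarse cell takes the arithmetic mean of its valid fine subcells;
#' cells whose valid-subcell fraction falls below `min_valid_fraction`
#' are masked. The fine grid must nest exactly within the coarse cells.
#'
#' @param fine a `grid_field` on the fine grid.
#' @param target a [grid_spec()] for the coarse grid.
#' @param min_valid_fraction minimum fraction of valid subcells (default
#'   0.1).
#' @param geometric use the geometric mean instead (appropriate for
#'   lognormal quantities such as chlorophyll); default arithmetic.
#' @return a `grid_field` on the coarse grid.
#' @export
regrid_mean <- function(fine, target, min_valid_fraction = 0.1,
                        geometric = FALSE) {
  stopifnot(inherits(fine, "grid_field"))
  fres_lat <- if (length(fine$lat) > 1) diff(fine$lat)[1] else target$res
  ratio <- target$res / fres_lat
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("regrid_mean: fine grid does not nest within the target cells")
  ratio <- round(ratio)
  # alignment: each fine center must fall inside exactly one coarse cell
  c_lat <- findInterval(fine$lat, c(target$lat - target$res / 2,
                                    max(target$lat) + target$res / 2),
                        rightmost.closed = TRUE)
  c_lon <- findInterval(fine$lon, c(target$lon - target$res / 2,
                                    max(target$lon) + target$res / 2),
                        rightmost.closed = TRUE)
  if (any(c_lat < 1 | c_lat > length(target$lat)) ||
      any(c_lon < 1 | c_lon > length(target$lon)))
    stop("regrid_mean: fine grid extends beyond the target grid")
  nlat <- length(target$lat); nlon <- length(target$lon)
  vals <- matrix(NA_real_, nlat, nlon)
  x <- fine$values
  x[!fine$mask] <- NA_real_
  if (geometric) x <- log(x)
  grp <- (rep(c_lon, each = length(fine$lat)) - 1L) * nlat +
    rep(c_lat, length(fine$lon))
  sums <- tapply(ifelse(is.na(x), 0, x), grp, sum)
  cnts <- tapply(!is.na(x), grp, sum)
  tots <- tapply(rep(1, length(x)), grp, sum)
  idx <- as.integer(names(sums))
  m <- sums / cnts
  m[cnts / tots < min_valid_fraction | cnts == 0] <- NA_real_
  vals[idx] <- m
  if (geometric) vals <- exp(vals)
  grid_field(target$lat, target$lon, vals,
             units = fine$units, name = fine$name)
}

#' Biomass-relative phosphorus scarcity index on a grid
#'
#' Cellwise Log10(chl / dip) on aligned coarse grids; cells where either
#' input is masked, or DIP is not strictly positive, are masked (never an
#' error).
#'
#' @param chl_1deg,dip_1deg aligned `grid_field`s (ug L-1 and uM).
#' @return dimensionless index `grid_field`.
#' @export
compute_index <- function(chl_1deg, dip_1deg) {
  stopifnot(inherits(chl_1deg, "grid_field"),
            inherits(dip_1deg, "grid_field"))
  if (!isTRUE(all.equal(chl_1deg$lat, dip_1deg$lat)) ||
      !isTRUE(all.equal(chl_1deg$lon, dip_1deg$lon)))
    stop("compute_index: grids are not aligned")
  ok <- chl_1deg$mask & dip_1deg$mask &
    !is.na(dip_1deg$values) & dip_1deg$values > 0 &
    !is.na(chl_1deg$values) & chl_1deg$values > 0
  vals <- matrix(NA_real_, nrow(chl_1deg$values), ncol(chl_1deg$values))
  vals[ok] <- log10(chl_1deg$values[ok] / dip_1deg$values[ok])
  grid_field(chl_1deg$lat, chl_1deg$lon, vals, mask = ok,
             units = "", name = "log10_chl_dip")
}

#' Flag grid cells above the DOP-utilization index threshold
#'
#' @param index a `grid_field` of Log10(Chl a / DIP) values.
#' @param threshold index threshold (default 1.20).
#' @param strict use strictly greater than instead of >=.
#' @return list with `flags` (logical-valued `grid_field`), `n_flagged`,
#'   `n_valid`, `fraction`, and `cells` (data frame of flagged cell
#'   centers and index values).
#' @export
classify_cells <- function(index, threshold = 1.20, strict = FALSE) {
  stopifnot(inherits(index, "grid_field"))
  flag <- matrix(NA, nrow(index$values), ncol(index$values))
  cmp <- if (strict) `>` else `>=`
  flag[index$mask] <- cmp(index$values[index$mask], threshold)
  n_valid <- sum(index$mask)
  n_flagged <- sum(flag[index$mask])
  ij <- which(index$mask & flag, arr.ind = TRUE)
  cells <- data.frame(lat = index$lat[ij[, 1]],
                      lon = index$lon[ij[, 2]],
                      index = index$values[ij])
  list(flags = grid_field(index$lat, index$lon, flag * 1,
                          mask = index$mask, name = "flag"),
       n_flagged = n_flagged, n_valid = n_valid,
       fraction = if (n_valid > 0) n_flagged / n_valid else NA_real_,
       cells = cells[order(cells$lat, cells$lon), ])
}
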