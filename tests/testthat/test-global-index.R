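small_spec <- function() grid_spec(res = 1, lon_range = c(-5, 5),
                                   lat_range = c(-3, 3))

fine_field <- function(vals, spec = small_spec(), sub = 2) {
  res <- spec$res / sub
  flat <- seq(min(spec$lat) - spec$res / 2 + res / 2,
              max(spec$lat) + spec$res / 2 - res / 2, by = res)
  flon <- seq(min(spec$lon) - spec$res / 2 + res / 2,
              max(spec$lon) + spec$res / 2 - res / 2, by = res)
  grid_field(flat, flon, vals(flat, flon), units = "ug L-1",
             name = "chl")
}

test_that("regridding preserves constants and computes subcell means", {
  sp <- small_spec()
  f <- fine_field(function(la, lo) matrix(3.7, length(la), length(lo)),
                  sp)
  coarse <- regrid_mean(f, sp)
  expect_true(all(coarse$values == 3.7))
  # one coarse cell from 2x2 subcells (1, 2, 3, 4) -> 2.5
  f2 <- fine_field(function(la, lo) {
    m <- matrix(0, length(la), length(lo)); m[1:2, 1:2] <- c(1, 2, 3, 4)
    m
  }, sp)
  coarse2 <- regrid_mean(f2, sp)
  expect_equal(coarse2$values[1, 1], 2.5)
})

test_that("regridding masks data-poor cells and keeps the global mean", {
  sp <- small_spec()
  f <- fine_field(function(la, lo)
    matrix(rnorm(length(la) * length(lo), 5), length(la), length(lo)),
    sp)
  # fully masked first coarse cell
  f$mask[1:2, 1:2] <- FALSE
  coarse <- regrid_mean(f, sp)
  expect_true(is.na(coarse$values[1, 1]))
  expect_false(coarse$mask[1, 1])
  # with no masking the area-unweighted mean is conserved
  f2 <- fine_field(function(la, lo)
    matrix(runif(length(la) * length(lo)), length(la), length(lo)), sp)
  coarse2 <- regrid_mean(f2, sp)
  expect_equal(mean(coarse2$values), mean(f2$values), tolerance = 1e-12)
  # non-nesting resolution is refused
  f3 <- grid_field(seq(-3.3, 3.3, by = 0.66), seq(-4.7, 4.7, by = 0.66),
                   matrix(1, 11, 15))
  expect_error(regrid_mean(f3, sp), "nest")
})

test_that("the index is the cellwise decimal log ratio", {
  sp <- small_spec()
  lat <- sp$lat; lon <- sp$lon
  chl <- grid_field(lat, lon, matrix(1, length(lat), length(lon)),
                    name = "chl")
  dip <- grid_field(lat, lon, matrix(0.1, length(lat), length(lon)),
                    name = "dip")
  idx <- compute_index(chl, dip)
  expect_true(all(idx$values == 1.0))
  chl10 <- grid_field(lat, lon, matrix(10, length(lat), length(lon)))
  expect_true(all(compute_index(chl10, dip)$values == 2.0))
  # zero-DIP cells become masked, no exception
  dip0 <- dip; dip0$values[2, 3] <- 0
  idx0 <- compute_index(chl, dip0)
  expect_false(idx0$mask[2, 3])
  expect_true(is.na(idx0$values[2, 3]))
  # misaligned grids are an error
  other <- grid_field(lat + 1, lon, matrix(1, length(lat), length(lon)))
  expect_error(compute_index(other, dip), "aligned")
})

test_that("the index is invariant under joint rescaling", {
  sp <- small_spec()
  set.seed(2)
  chl_v <- matrix(runif(length(sp$lat) * length(sp$lon), 0.1, 5),
                  length(sp$lat))
  dip_v <- matrix(runif(length(sp$lat) * length(sp$lon), 0.01, 0.5),
                  length(sp$lat))
  chl <- grid_field(sp$lat, sp$lon, chl_v)
  dip <- grid_field(sp$lat, sp$lon, dip_v)
  base <- compute_index(chl, dip)
  for (k in c(0.2, 7)) {
    scaled <- compute_index(grid_field(sp$lat, sp$lon, k * chl_v),
                            grid_field(sp$lat, sp$lon, k * dip_v))
    expect_equal(scaled$values, base$values, tolerance = 1e-12)
  }
})

test_that("cell flagging is exact and monotone in the threshold", {
  sp <- small_spec()
  n_cells <- length(sp$lat) * length(sp$lon)
  vals <- matrix(seq(0, 2, length.out = n_cells), length(sp$lat))
  idx <- grid_field(sp$lat, sp$lon, vals)
  all_f <- classify_cells(idx, threshold = -100)
  expect_equal(all_f$fraction, 1)
  none <- classify_cells(idx, threshold = 100)
  expect_equal(none$n_flagged, 0)
  th <- seq(0, 2, by = 0.25)
  counts <- vapply(th, function(t)
    classify_cells(idx, t)$n_flagged, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # strict vs inclusive comparison differs exactly at the threshold
  at <- classify_cells(idx, threshold = vals[2, 1])
  at_strict <- classify_cells(idx, threshold = vals[2, 1], strict = TRUE)
  expect_equal(at$n_flagged - at_strict$n_flagged, 1)
})

test_that("synthetic fields are deterministic and hit the set exceedance", {
  gs <- grid_spec(res = 1, lon_range = c(-30, 30),
                  lat_range = c(-25, 25))  # 3000 cells
  f1 <- simulate_global_fields(seed = 7, grid = gs,
                               exceed_fraction = 0.25)
  f2 <- simulate_global_fields(seed = 7, grid = gs,
                               exceed_fraction = 0.25)
  expect_identical(f1$chl_fine$values, f2$chl_fine$values)
  expect_identical(f1$dip_coarse$values, f2$dip_coarse$values)

  chl_coarse <- regrid_mean(f1$chl_fine, gs)
  idx <- compute_index(chl_coarse, f1$dip_coarse)
  cls <- classify_cells(idx, threshold = 1.20)
  expect_gte(cls$n_valid, 2000)
  expect_equal(cls$n_flagged, round(0.25 * cls$n_valid))
  # flagged-cell table is consistent with the count
  expect_equal(nrow(cls$cells), cls$n_flagged)
  expect_true(all(cls$cells$index >= 1.20))
  expect_error(simulate_global_fields(seed = 1, subcells = 2), "subcells")
  expect_error(grid_spec(res = 0), "invalid")
})
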