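tilted_world <- function(nr = 6, nc = 8) {
  spec <- grid_spec(0, 0, 1, 1, nc, nr)
  # elevation rises to the east; west column drains off-grid
  dem <- pn_raster(spec, outer(rep(1, nr), seq_len(nc)) * 100, "m")
  list(spec = spec, dem = dem, land = region_mask(spec, TRUE, "land"))
}

test_that("a uniformly tilted plane routes west with column-wise accumulation", {
  w <- tilted_world()
  fl <- fill_and_route(w$dem, w$land)
  # all cells except the westmost column point west (direction index 5)
  expect_true(all(fl$dir[, -1] == 5L))
  expect_true(all(fl$dir[, 1] == 0L))  # west column drains off-grid: outlets
  # accumulation grows by one per step along each row
  for (i in seq_len(6)) expect_equal(fl$accumulation[i, ], rev(seq_len(8)))
})

test_that("a closed bowl fills and drains through its single rim low", {
  spec <- grid_spec(0, 0, 1, 1, 5, 5)
  z <- matrix(100, 5, 5)
  z[2:4, 2:4] <- 10          # inner depression
  z[3, 1] <- 5               # low rim cell on the west edge
  dem <- pn_raster(spec, z, "m")
  land <- region_mask(spec, TRUE, "land")
  fl <- fill_and_route(dem, land)
  basins <- delineate_basins(fl, dem)
  # depression cells all reach an outlet; accumulation is conserved
  outlet_cells <- cbind(basins$table$outlet_row, basins$table$outlet_col)
  expect_equal(sum(fl$accumulation[outlet_cells]), 25)
  # the depression drains into the basin of the rim-low outlet
  rim_basin <- basins$id[3, 1]
  expect_true(all(basins$id[2:4, 2:4] == rim_basin))
})

test_that("a medial ridge splits the world into exactly two basins", {
  spec <- grid_spec(0, 0, 1, 1, 7, 4)
  # ridge down column 4; valleys to the west and east
  z <- outer(rep(1, 4), c(10, 20, 30, 100, 30, 20, 10))
  dem <- pn_raster(spec, z, "m")
  land <- region_mask(spec, TRUE, "land")
  fl <- fill_and_route(dem, land)
  basins <- delineate_basins(fl, dem)
  west <- unique(as.vector(basins$id[, 1:3]))
  east <- unique(as.vector(basins$id[, 5:7]))
  expect_length(intersect(west, east), 0)
  # per-basin accumulation at the outlet equals the basin cell count
  for (b in seq_len(nrow(basins$table))) {
    r <- basins$table$outlet_row[b]; c <- basins$table$outlet_col[b]
    expect_equal(fl$accumulation[r, c], basins$table$n_cells[b])
  }
  expect_equal(sum(basins$table$A_km2),
               sum(cell_areas_km2(spec)$values), tolerance = 1e-9)
})

test_that("basin climate integrates runoff with the documented unit chain", {
  spec <- grid_spec(0, 0, 1, 1, 4, 4)
  z <- outer(rep(1, 4), 4:1) * 50
  dem <- pn_raster(spec, z, "m")
  land <- region_mask(spec, TRUE, "land")
  basins <- delineate_basins(fill_and_route(dem, land), dem)
  # constant runoff: Q = runoff * area * 3.1536e7 * 1e-6
  runoff <- pn_raster(spec, 1e-5, "mm/s")
  temp <- pn_raster(spec, 15, "degC")
  basins <- basin_climate(basins, temp, runoff)
  total_area <- sum(basins$table$A_km2)
  expect_equal(sum(basins$table$Q_km3yr), 1e-5 * total_area * 3.1536e7 * 1e-6,
               tolerance = 1e-9)
  expect_true(all(abs(basins$table$T_C - 15) < 1e-12))
  # zero runoff
  b0 <- basin_climate(basins, temp, pn_raster(spec, 0, "mm/s"))
  expect_true(all(b0$table$Q_km3yr == 0))
})

test_that("BQART evaluates its warm and cold branches exactly", {
  fake <- structure(list(table = tibble::tibble(
    basin_id = 1:3, outlet_row = 1, outlet_col = 1, n_cells = 1,
    A_km2 = c(1, 1, 1), R_km = c(1, 0, 1), T_C = c(10, 10, 1),
    Q_km3yr = c(1, 1, 1))), class = "pn_basins")
  out <- bqart_flux(fake, bqart_params())
  expect_equal(out$table$Qs_MTyr, c(0.2, 0, 0.04))
  neg <- fake; neg$table$Q_km3yr[1] <- -1
  expect_error(bqart_flux(neg), "negative")
})

test_that("BQART flux is monotone in each warm-branch driver", {
  set.seed(71)
  base <- tibble::tibble(basin_id = 1, outlet_row = 1, outlet_col = 1,
                         n_cells = 1, A_km2 = runif(1, 10, 100),
                         R_km = runif(1, 0.1, 2), T_C = runif(1, 3, 25),
                         Q_km3yr = runif(1, 0.1, 5))
  qs <- function(tab) bqart_flux(structure(list(table = tab),
                                           class = "pn_basins"))$table$Qs_MTyr
  for (v in c("A_km2", "R_km", "T_C", "Q_km3yr")) {
    up <- base; up[[v]] <- up[[v]] * 1.5
    expect_gte(qs(up), qs(base))
  }
})

test_that("deposition rates follow the unit conversion and integrate back to the load", {
  spec <- grid_spec(0, 0, 1, 0.5, 5, 8)
  z <- matrix(rep(seq(10, 80, by = 10), 5), 8, 5) + runif(40)
  dem <- pn_raster(spec, z, "m")
  land <- region_mask(spec, TRUE, "land")
  basins <- delineate_basins(fill_and_route(dem, land), dem)
  basins <- basin_climate(basins, pn_raster(spec, 12, "degC"),
                          pn_raster(spec, 2e-5, "mm/s"))
  basins <- bqart_flux(basins)
  dep <- flux_to_deposition_rate(basins, dem)
  areas <- cell_areas_km2(spec)$values
  # rate * rho * dep_area integrates back to Qs per basin (within 1e-6)
  for (b in seq_len(nrow(basins$table))) {
    cells <- which(basins$id == basins$table$basin_id[b] &
                     dep$raster$values > 0)
    if (!length(cells)) next
    back <- sum(dep$raster$values[cells] * 2 * areas[cells] * 1e10 / 1e3) / 1e12
    expect_equal(back, basins$table$Qs_MTyr[b], tolerance = 1e-6)
  }
  # doubling density halves the rates
  dep2 <- flux_to_deposition_rate(basins, dem, bqart_params(bulk_density = 4))
  nz <- dep$raster$values > 0 & !is.na(dep$raster$values)
  expect_equal(dep2$raster$values[nz], dep$raster$values[nz] / 2)
  # worked spot value: Qs = 1 MT/yr over 100 km^2 at rho 2 -> 500 cm/ky
  expect_equal(1 * 1e12 / (2 * 100 * 1e10) * 1e3, 500)
})

test_that("two-class Jenks equals the exhaustive split search and 2-means", {
  expect_equal(jenks_two_class(c(1, 2, 3, 100, 101, 102)), 51.5)
  expect_equal(jenks_two_class(c(0, 10)), 5)
  expect_error(jenks_two_class(c(4, 4, 4)), "natural break")

  set.seed(72)
  x <- c(rnorm(120, 0, 1), rnorm(80, 6, 2))
  brk <- jenks_two_class(x)
  xs <- sort(x)
  ss <- vapply(seq_len(199), function(i) {
    lo <- xs[1:i]; hi <- xs[-(1:i)]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, 0)
  i_best <- which.min(ss)
  expect_equal(brk, (xs[i_best] + xs[i_best + 1]) / 2)
  # same partition as 1-D 2-means
  km <- stats::kmeans(x, centers = c(min(x), max(x)))
  km_split <- max(x[km$cluster == which.min(km$centers)])
  expect_equal(sum(x <= brk), sum(x <= km_split))
})

test_that("taphofacies classification respects the break and published overrides", {
  spec <- grid_spec(0, 0, 1, 1, 10, 10)
  set.seed(73)
  v <- matrix(runif(100, 0, 700), 10, 10)
  v[1, 1] <- NA
  r <- pn_raster(spec, v, "cm/ky")
  low <- classify_taphofacies(pn_raster(spec, 5, "cm/ky"), 10)
  expect_true(all(low$class == 1L))
  tf <- classify_taphofacies(r, 280.32, "sediment_flux")
  expect_equal(sum(tf$class == 2L, na.rm = TRUE), sum(v > 280.32, na.rm = TRUE))
  expect_equal(sum(tf$class == 1L, na.rm = TRUE), sum(v <= 280.32, na.rm = TRUE))
  expect_true(is.na(tf$class[1, 1]))
  expect_error(classify_taphofacies(pn_raster(spec, -1), 10), "negative")
})
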