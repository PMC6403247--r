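# Seeded synthetic palaeo-worlds with known ground truth: a continent with a
# western mountain belt and a meridional epicontinental seaway, latitude- and
# elevation-driven monthly climate, outcrop bands along the seaway's western
# shore, virtual species with Gaussian climatic niches, and occurrence
# sampling biased by outcrop and taphofacies class.

#' World generator configuration
#'
#' The default grid is 72 x 40 cells at 1.25 degrees (continental scale).
#' The DEM is a low plain that tapers into ocean at the grid margins, plus a
#' Gaussian-cross-section mountain ridge near the western margin, minus a
#' meridional seaway trough, plus seeded Gaussian noise; land is where the
#' DEM exceeds sea level. With the seaway on, the land splits into at least
#' two connected components (western and eastern subcontinents).
#'
#' @param spec A `pn_grid` (default 72 x 40 at 1.25 deg starting at 135W, 25N).
#' @param seed Integer seed.
#' @param sea_level Elevation of the coastline, m (default 0).
#' @param base_elev Plain elevation, m.
#' @param mountain_amp,mountain_lon,mountain_width Ridge amplitude (m),
#'   centre longitude and Gaussian width (deg).
#' @param seaway Logical: include the epicontinental seaway.
#' @param seaway_amp,seaway_lon,seaway_width Trough amplitude (m), centre
#'   longitude and Gaussian width (deg).
#' @param noise_sd DEM noise SD, m.
#' @return A `pn_world_config` list.
#' @export
world_config <- function(spec = grid_spec(-135, 25, 1.25, 1.25, 72, 40),
                         seed = 42, sea_level = 0, base_elev = 700,
                         mountain_amp = 2500, mountain_lon = -122,
                         mountain_width = 5,
                         seaway = TRUE, seaway_amp = 1500, seaway_lon = -97.5,
                         seaway_width = 3.5, noise_sd = 40) {
  stopifnot(mountain_amp >= 0, seaway_amp >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "pn_world_config")
}

#' Generate a synthetic palaeo-world
#'
#' @param cfg A `pn_world_config`.
#' @return List with `dem` (`pn_raster`, m) and `land` (`pn_mask`).
#' @export
make_world <- function(cfg = world_config()) {
  spec <- cfg$spec
  lon <- rep(lon_centers(spec), each = spec$n_rows)
  lat <- rep(lat_centers(spec), times = spec$n_cols)
  # normalised distance to the nearest grid edge, 0 at edges -> ocean ring
  ex <- pmin(lon - spec$lon_origin,
             spec$lon_origin + spec$n_cols * spec$dlon - lon) /
    (spec$n_cols * spec$dlon / 2)
  ey <- pmin(lat - spec$lat_origin,
             spec$lat_origin + spec$n_rows * spec$dlat - lat) /
    (spec$n_rows * spec$dlat / 2)
  shelf <- pmin(ex, ey)
  z <- -400 + (cfg$base_elev + 400) * pmin(shelf / 0.25, 1) +
    cfg$mountain_amp * exp(-(lon - cfg$mountain_lon)^2 / (2 * cfg$mountain_width^2))
  if (cfg$seaway)
    z <- z - cfg$seaway_amp * exp(-(lon - cfg$seaway_lon)^2 / (2 * cfg$seaway_width^2))
  set.seed(cfg$seed)
  z <- z + stats::rnorm(length(z), 0, cfg$noise_sd)
  zm <- matrix(z, spec$n_rows, spec$n_cols)
  land <- zm > cfg$sea_level
  if (!any(land)) stop("configuration yields no land cells")
  list(dem = pn_raster(spec, zm, units = "m"),
       land = region_mask(spec, land, "land"))
}

#' Count connected components of a mask (8-connectivity)
#'
#' @param mask A `pn_mask`.
#' @return Number of connected components of the member cells.
#' @export
n_components <- function(mask) {
  m <- mask$member
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      r0 <- ((i - 1) %% nr) + 1; c0 <- ((i - 1) %/% nr) + 1
      for (k in 1:8) {
        r1 <- r0 + D8_DROW[k]; c1 <- c0 + D8_DCOL[k]
        if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
        if (m[r1, c1] && lab[r1, c1] == 0L) {
          lab[(c1 - 1) * nr + r1] <- comp
          queue <- c(queue, (c1 - 1) * nr + r1)
        }
      }
    }
  }
  comp
}

#' Climate generator configuration
#'
#' Monthly temperature is
#' T_m = a - b |lat| - lapse max(elev - sea level, 0)/1000 +
#'       seasonal cos(2 pi (m - peak month)/12) (sign by hemisphere) + noise,
#' and monthly precipitation is
#' P_m = clip(base exp(-coast distance/decay) + orographic relief + noise, 0).
#'
#' @param equator_temp a, degC at the equator.
#' @param lat_gradient b, degC per degree latitude.
#' @param lapse_rate degC per km of elevation.
#' @param seasonal_amp Seasonal half-amplitude, degC.
#' @param peak_month Warmest month in the northern hemisphere (default 7).
#' @param precip_base Coastal precipitation, mm/s.
#' @param coast_decay_km Precipitation e-folding distance from the coast, km.
#' @param orographic mm/s of extra precipitation per km of elevation.
#' @param t_noise_sd,p_noise_sd Monthly noise SDs (degC, mm/s).
#' @param runoff_coef Fraction of annual precipitation that becomes surface
#'   runoff.
#' @param seed Integer seed.
#' @return A `pn_climate_config` list.
#' @export
climate_config <- function(equator_temp = 35, lat_gradient = 0.45,
                           lapse_rate = 6.5, seasonal_amp = 10,
                           peak_month = 7, precip_base = 2.2e-5,
                           coast_decay_km = 900, orographic = 6e-6,
                           t_noise_sd = 0.8, p_noise_sd = 1.5e-6,
                           runoff_coef = 0.4, seed = 42) {
  stopifnot(lapse_rate >= 0)
  structure(as.list(environment()), class = "pn_climate_config")
}

#' Generate a synthetic monthly climate
#'
#' @param dem A `pn_raster` of elevations, m.
#' @param land A `pn_mask` of land cells (sea cells drive coastal distance).
#' @param cfg A `pn_climate_config`.
#' @param sea_level Sea level used for the lapse term, m.
#' @return A `pn_monthly_climate`.
#' @export
make_climate <- function(dem, land, cfg = climate_config(), sea_level = 0) {
  spec <- dem$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  lat <- matrix(rep(lat_centers(spec), times = nc), nr, nc)
  lon <- matrix(rep(lon_centers(spec), each = nr), nr, nc)
  elev_km <- pmax(dem$values - sea_level, 0) / 1000
  sea_cells <- which(!land$member, arr.ind = TRUE)
  dist_coast <- if (nrow(sea_cells)) {
    sea_pts <- cbind(lon_centers(spec)[sea_cells[, "col"]],
                     lat_centers(spec)[sea_cells[, "row"]])
    d <- geosphere::distm(cbind(as.vector(lon), as.vector(lat)), sea_pts,
                          fun = haversine_km)
    matrix(apply(d, 1, min), nr, nc)
  } else matrix(0, nr, nc)
  hemi <- ifelse(lat >= 0, 1, -1)
  set.seed(cfg$seed)
  temp <- vector("list", 12); prec <- vector("list", 12)
  for (m in 1:12) {
    tm <- cfg$equator_temp - cfg$lat_gradient * abs(lat) -
      cfg$lapse_rate * elev_km +
      cfg$seasonal_amp * cos(2 * pi * (m - cfg$peak_month) / 12) * hemi +
      stats::rnorm(nr * nc, 0, cfg$t_noise_sd)
    pm <- cfg$precip_base * exp(-dist_coast / cfg$coast_decay_km) +
      cfg$orographic * elev_km +
      stats::rnorm(nr * nc, 0, cfg$p_noise_sd)
    temp[[m]] <- pn_raster(spec, tm, "degC")
    prec[[m]] <- pn_raster(spec, pmax(pm, 0), "mm/s")
  }
  monthly_climate(temp, prec)
}

#' Surface runoff from a synthetic climate
#'
#' A fixed runoff coefficient applied to annual-mean precipitation.
#'
#' @param mc A `pn_monthly_climate`.
#' @param cfg A `pn_climate_config` (supplies `runoff_coef`).
#' @return A `pn_raster` in mm/s.
#' @export
make_runoff <- function(mc, cfg = climate_config()) {
  p_ann <- Reduce(`+`, lapply(mc$precipitation, function(r) r$values)) / 12
  pn_raster(mc$spec, cfg$runoff_coef * p_ann, units = "mm/s")
}

#' Outcrop band along the seaway's western shore
#'
#' Member cells are land cells within `width_deg` west of the seaway centre
#' longitude; a narrower width emulates a more restricted preserved outcrop.
#'
#' @param land A `pn_mask`.
#' @param seaway_lon Seaway centre longitude, degrees.
#' @param width_deg Band width, degrees (> 0).
#' @return A `pn_mask` named `"outcrop"` (a strict subset of land).
#' @export
make_outcrop <- function(land, seaway_lon = -97.5, width_deg = 15) {
  if (width_deg <= 0) stop("outcrop width must be positive")
  spec <- land$spec
  lon <- matrix(rep(lon_centers(spec), each = spec$n_rows),
                spec$n_rows, spec$n_cols)
  member <- land$member & lon <= seaway_lon & lon >= seaway_lon - width_deg
  region_mask(spec, member, "outcrop")
}

#' Virtual species with a Gaussian climatic niche
#'
#' True suitability is the product of Gaussian responses on the chosen
#' predictors, exp(-sum (x_v - mu_v)^2 / (2 sigma_v^2)), normalised to a
#' maximum of 1 over land and 0 on sea.
#'
#' @param predictors A `pn_predictors`.
#' @param land A `pn_mask`.
#' @param optima Named numeric vector of niche optima mu_v (names select
#'   the predictors used).
#' @param breadths Named numeric vector of niche breadths sigma_v (> 0).
#' @param name Species label.
#' @return A `pn_virtual_species`: list with `true_suitability`
#'   (`pn_raster`), `optima`, `breadths`, `name`.
#' @export
virtual_species <- function(predictors, land, optima, breadths,
                            name = "virtual species") {
  stopifnot(length(optima) == length(breadths),
            all(names(optima) == names(breadths)), all(breadths > 0))
  spec <- land$spec
  logs <- matrix(0, spec$n_rows, spec$n_cols)
  for (v in names(optima)) {
    x <- predictors[[v]]$values
    logs <- logs - (x - optima[[v]])^2 / (2 * breadths[[v]]^2)
  }
  s <- exp(logs)
  s[!land$member] <- 0
  mx <- max(s[land$member], na.rm = TRUE)
  if (mx > 0) s[land$member] <- s[land$member] / mx
  structure(list(true_suitability = pn_raster(spec, s, "suitability"),
                 optima = optima, breadths = breadths, name = name),
            class = "pn_virtual_species")
}

#' Niche parameters scaled to the training region
#'
#' Convenience constructor: optima are the medians of each chosen predictor
#' over the region; the niche breadth -- the +/- 2 sigma tolerance envelope
#' of the Gaussian response -- is a fixed fraction of the regional value
#' range, so sigma = breadth_fraction x range / 4.
#'
#' @param predictors A `pn_predictors`.
#' @param region A `pn_mask` (typically the outcrop training region).
#' @param vars Predictor names the niche responds to.
#' @param breadth_fraction Niche breadth as a fraction of the regional range
#'   (default 0.25).
#' @return List with `optima` and `breadths` (sigmas) for
#'   [virtual_species()].
#' @export
niche_from_region <- function(predictors, region,
                              vars = c("T_coldest_q", "P_driest_q"),
                              breadth_fraction = 0.25) {
  cells <- which(region$member, arr.ind = TRUE)
  vals <- predictor_values(predictors[vars], cells)
  optima <- vapply(vals, stats::median, 0, na.rm = TRUE)
  breadths <- vapply(vals, function(x) diff(range(x, na.rm = TRUE)), 0) *
    breadth_fraction / 4
  list(optima = optima, breadths = breadths)
}

#' Occurrence sampling configuration
#'
#' Default per-bin target counts follow the magnitudes of the published
#' unique-occurrence table (2 to 58 per clade and bin). Preservation weights
#' default to 10:1 in favour of the high-flux taphofacies, which makes the
#' occurrence-taphofacies association detectable at these sample sizes.
#'
#' @param n_target Number of occurrences to draw.
#' @param weight_high,weight_low Preservation weights for high/low
#'   taphofacies classes (>= 0, not both 0).
#' @param outcrop_only Restrict sampling to the outcrop mask.
#' @param jitter_sd Coordinate jitter SD, degrees.
#' @param seed Integer seed.
#' @param replace Draw cells with replacement and keep duplicates (used for
#'   sampling-distribution checks; default FALSE).
#' @return A `pn_sampling_config` list.
#' @export
sampling_config <- function(n_target = 50, weight_high = 10, weight_low = 1,
                            outcrop_only = TRUE, jitter_sd = 0.2, seed = 42,
                            replace = FALSE) {
  stopifnot(n_target >= 0, weight_high >= 0, weight_low >= 0,
            weight_high + weight_low > 0)
  structure(as.list(environment()), class = "pn_sampling_config")
}

#' Published per-bin, per-clade unique-occurrence counts
#'
#' The five-substage training-sample sizes for the three clades, used as
#' default synthetic sampling targets.
#'
#' @return Tibble with `time_bin`, `clade`, `n`.
#' @export
default_bin_counts <- function() {
  bins <- default_time_bins(FALSE)$name
  tibble::tibble(
    time_bin = rep(bins, each = 3),
    clade = rep(c("Ceratopsidae", "Hadrosauridae", "Tyrannosauridae"), 5),
    n = c(6, 2, 19, 20, 39, 18, 40, 58, 33, 7, 17, 22, 43, 46, 29))
}

#' Sample preservation-biased occurrences of a virtual species
#'
#' Cell sampling weight is true suitability x preservation weight of the
#' cell's taphofacies class x outcrop membership (when `outcrop_only`).
#' Cells are drawn without replacement (with replacement then deduplicated
#' when fewer weighted cells than `n_target` exist); coordinates are cell
#' centres plus seeded Gaussian jitter.
#'
#' @param vs A `pn_virtual_species`.
#' @param facies A `pn_taphofacies` or NULL (no preservation bias).
#' @param outcrop A `pn_mask`.
#' @param cfg A `pn_sampling_config`.
#' @param clade,time_bin Labels for the generated occurrences.
#' @return Occurrence tibble with attribute `"cells"` (the drawn cell
#'   indices, the generator's own bookkeeping).
#' @export
sample_occurrences <- function(vs, facies, outcrop,
                               cfg = sampling_config(),
                               clade = "VirtualSpecies",
                               time_bin = "late Campanian") {
  spec <- vs$true_suitability$spec
  w <- vs$true_suitability$values
  w[is.na(w)] <- 0
  if (!is.null(facies)) {
    stopifnot(same_spec(spec, facies$spec))
    fw <- matrix(0, spec$n_rows, spec$n_cols)
    fw[facies$class == 1L] <- cfg$weight_low
    fw[facies$class == 2L] <- cfg$weight_high
    w <- w * fw
  }
  if (cfg$outcrop_only) w[!outcrop$member] <- 0
  if (all(w == 0)) stop("all sampling weights are zero")
  set.seed(cfg$seed)
  pos <- which(w > 0)
  draw <- function(n, replace)  # sample() would misread a length-1 pos
    pos[sample.int(length(pos), n, replace = replace, prob = w[pos])]
  cells <- if (isTRUE(cfg$replace)) {
    draw(cfg$n_target, TRUE)
  } else if (length(pos) >= cfg$n_target) {
    draw(cfg$n_target, FALSE)
  } else unique(draw(cfg$n_target, TRUE))
  rows <- ((cells - 1) %% spec$n_rows) + 1
  cols <- ((cells - 1) %/% spec$n_rows) + 1
  lon <- lon_centers(spec)[cols] + stats::rnorm(length(cells), 0, cfg$jitter_sd)
  lat <- lat_centers(spec)[rows] + stats::rnorm(length(cells), 0, cfg$jitter_sd)
  out <- occurrences(tibble::tibble(
    clade = clade, palaeo_lon = lon, palaeo_lat = lat, time_bin = time_bin,
    source_id = paste0("synth-", seq_along(cells))))
  attr(out, "cells") <- cells
  out
}

#' Packaged demonstration presets
#'
#' Builds a complete synthetic stage: world, climate, predictors, runoff,
#' outcrop mask and a virtual species. The `"campanian"` preset uses a wide
#' outcrop band (15 deg) and the `"maastrichtian"` preset a narrow one
#' (7 deg) on the same world, emulating the contraction of the preserved
#' sampling window between the two stages.
#'
#' @param preset `"campanian"` or `"maastrichtian"`.
#' @param seed Master seed; all generator seeds derive from it.
#' @param breadth_fraction Niche breadth of the preset species as a fraction
#'   of the reference-region climate range (default 0.25; see
#'   [niche_from_region()]).
#' @return List with `world`, `climate`, `predictors`, `runoff`, `outcrop`,
#'   `land`, `continent`, `retained`, `species`, `preset`, `seed`.
#' @export
synth_preset <- function(preset = c("campanian", "maastrichtian"), seed = 42,
                         breadth_fraction = 0.25) {
  preset <- match.arg(preset)
  world <- make_world(world_config(seed = seed))
  ccfg <- climate_config(seed = seed + 1)
  climate <- make_climate(world$dem, world$land, ccfg)
  predictors <- derive_predictors(climate, time_bin = preset)
  runoff <- make_runoff(climate, ccfg)
  width <- if (preset == "campanian") 15 else 7
  outcrop <- make_outcrop(world$land, width_deg = width)
  continent <- region_mask(world$land$spec, world$land$member,
                           "continent-projection")
  # the species is preset-invariant (a stable fundamental niche): its
  # parameters are set from the reference wide outcrop, and it responds to
  # variables that survive the collinearity screen there
  reference <- make_outcrop(world$land, width_deg = 15)
  retained <- suppressWarnings(pearson_filter(predictors, reference))
  niche_vars <- c(grep("^T_", retained, value = TRUE)[1],
                  grep("^P_", retained, value = TRUE)[1])
  niche_vars <- niche_vars[!is.na(niche_vars)]
  if (!length(niche_vars)) niche_vars <- retained[1]
  niche <- niche_from_region(predictors, reference, vars = niche_vars,
                             breadth_fraction = breadth_fraction)
  species <- virtual_species(predictors, world$land, niche$optima,
                             niche$breadths)
  list(world = world, climate = climate, predictors = predictors,
       runoff = runoff, outcrop = outcrop, land = world$land,
       continent = continent, retained = retained, species = species,
       preset = preset, seed = seed)
}
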