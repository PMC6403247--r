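# Shared fixtures, built in code. The demo stage is cached per test run
# because several files exercise the same synthetic world.

.demo_cache <- new.env(parent = emptyenv())

demo_stage <- function(preset = "campanian", seed = 42,
                       breadth_fraction = 0.25) {
  key <- paste(preset, seed, breadth_fraction)
  if (is.null(.demo_cache[[key]]))
    .demo_cache[[key]] <- synth_preset(preset, seed = seed,
                                       breadth_fraction = breadth_fraction)
  .demo_cache[[key]]
}

# small planar raster v = a*lon + b*lat (+ c)
planar_raster <- function(spec, a = 2, b = 3, c = 0, units = "") {
  v <- outer(lat_centers(spec), lon_centers(spec),
             function(la, lo) a * lo + b * la + c)
  pn_raster(spec, v, units)
}

# monthly climate with given temperature / precipitation vectors (length 12),
# constant in space on a tiny grid
cycle_climate <- function(tvec, pvec, spec = grid_spec(0, 0, 1, 1, 3, 2)) {
  monthly_climate(
    lapply(tvec, function(x) pn_raster(spec, x, "degC")),
    lapply(pvec, function(x) pn_raster(spec, x, "mm/s")))
}

random_occurrences <- function(n, spec, seed = 1, clade = "A",
                               time_bin = "late Campanian") {
  set.seed(seed)
  occurrences(tibble::tibble(
    clade = clade,
    palaeo_lon = stats::runif(n, spec$lon_origin,
                              spec$lon_origin + spec$n_cols * spec$dlon),
    palaeo_lat = stats::runif(n, spec$lat_origin,
                              spec$lat_origin + spec$n_rows * spec$dlat),
    time_bin = time_bin))
}
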