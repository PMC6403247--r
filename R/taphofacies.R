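# Virtual taphofacies: D8 flow routing on a priority-flood-filled palaeo-DEM,
# drainage-basin delineation, BQART sediment flux, conversion to deposition
# rates, and two-class Jenks classification of flux and runoff fields.

# neighbor offsets in the fixed tie-break order E, NE, N, NW, W, SW, S, SE
D8_DROW <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DCOL <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DIST <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

#' Fill depressions and route D8 flow
#'
#' Depressions are filled by priority-flood to their minimal spill elevation
#' (with a tiny epsilon gradient so flats drain toward the spill path); flow
#' directions are the steepest downslope D8 neighbour on the filled surface
#' (diagonal distance sqrt(2) x cell size), ties broken in the fixed order
#' E, NE, N, NW, W, SW, S, SE. Land cells whose steepest descent leaves the
#' land mask (to sea or off-grid) are outlets. The result is acyclic by
#' construction.
#'
#' @param dem A `pn_raster` of elevations (non-missing on land).
#' @param land A `pn_mask` of land cells.
#' @return A `pn_flow`: list with `dir` (integer matrix: 1..8 = neighbour
#'   index, 0 = outlet, NA = sea), `accumulation` (upstream cell count,
#'   self-inclusive), `filled` (filled DEM matrix), `spec`, `land`.
#' @export
fill_and_route <- function(dem, land) {
  stopifnot(inherits(dem, "pn_raster"), inherits(land, "pn_mask"))
  if (!same_spec(dem$spec, land$spec)) stop("grid mismatch")
  spec <- dem$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  L <- land$member
  if (any(is.na(dem$values[L]))) stop("DEM must be non-missing on land")
  z <- dem$values
  n_land <- sum(L)
  dir <- matrix(NA_integer_, nr, nc)
  acc <- matrix(NA_real_, nr, nc)
  flow <- structure(list(dir = dir, accumulation = acc, filled = z,
                         spec = spec, land = land), class = "pn_flow")
  if (n_land == 0) return(flow)
  eps <- 1e-6

  # priority-flood fill: seed with land cells adjacent to sea or the grid edge
  filled <- matrix(Inf, nr, nc)
  in_heap <- matrix(FALSE, nr, nc)
  heap_idx <- integer(0); heap_key <- numeric(0)  # simple vector-scan "heap"
  push <- function(i, key) {
    heap_idx <<- c(heap_idx, i); heap_key <<- c(heap_key, key)
  }
  boundary <- matrix(FALSE, nr, nc)
  for (k in 1:8) {
    rr <- row(z) + D8_DROW[k]; cc <- col(z) + D8_DCOL[k]
    off <- rr < 1 | rr > nr | cc < 1 | cc > nc
    nb_sea <- matrix(TRUE, nr, nc)
    nb_sea[!off] <- !L[cbind(rr[!off], cc[!off])]
    boundary <- boundary | nb_sea
  }
  seeds <- which(L & boundary)
  for (i in seeds) { push(i, z[i]); in_heap[i] <- TRUE }
  visited <- matrix(FALSE, nr, nc)
  while (length(heap_idx)) {
    j <- which.min(heap_key)
    i <- heap_idx[j]; key <- heap_key[j]
    heap_idx <- heap_idx[-j]; heap_key <- heap_key[-j]
    if (visited[i]) next
    visited[i] <- TRUE
    filled[i] <- key
    r0 <- ((i - 1) %% nr) + 1; c0 <- ((i - 1) %/% nr) + 1
    for (k in 1:8) {
      r1 <- r0 + D8_DROW[k]; c1 <- c0 + D8_DCOL[k]
      if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
      if (!L[r1, c1] || visited[r1, c1]) next
      push((c1 - 1) * nr + r1, max(z[r1, c1], key + eps))
    }
  }

  # steepest-descent D8 on the filled surface; a cell whose best descent
  # enters the sea, or that has no positive on-grid descent (edge drainage),
  # is an outlet
  for (i in which(L)) {
    r0 <- ((i - 1) %% nr) + 1; c0 <- ((i - 1) %/% nr) + 1
    best_k <- 0L; best_slope <- 0
    to_sea <- FALSE
    for (k in 1:8) {
      r1 <- r0 + D8_DROW[k]; c1 <- c0 + D8_DCOL[k]
      if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
      if (!L[r1, c1]) {
        zt <- if (is.na(z[r1, c1])) -Inf else z[r1, c1]
        slope <- (filled[r0, c0] - zt) / D8_DIST[k]
      } else {
        slope <- (filled[r0, c0] - filled[r1, c1]) / D8_DIST[k]
      }
      if (slope > best_slope) {
        best_slope <- slope
        best_k <- k
        to_sea <- !L[r1, c1]
      }
    }
    dir[r0, c0] <- if (best_k == 0L || to_sea) 0L else best_k
  }

  # accumulation: process in decreasing filled elevation (downstream is lower)
  ord <- order(filled[L], decreasing = TRUE)
  land_idx <- which(L)[ord]
  acc[L] <- 1
  for (i in land_idx) {
    k <- dir[i]
    if (is.na(k) || k == 0L) next
    r0 <- ((i - 1) %% nr) + 1; c0 <- ((i - 1) %/% nr) + 1
    r1 <- r0 + D8_DROW[k]; c1 <- c0 + D8_DCOL[k]
    acc[r1, c1] <- acc[r1, c1] + acc[r0, c0]
  }
  flow$dir <- dir; flow$accumulation <- acc; flow$filled <- filled
  flow
}

#' Delineate drainage basins
#'
#' Each land cell is assigned to the basin of the outlet its flow path
#' reaches. Basin area A is the sum of spherical cell areas; relief R is
#' (max basin elevation - outlet elevation) in km, measured on the raw DEM.
#'
#' @param flow A `pn_flow` from [fill_and_route()].
#' @param dem The raw DEM `pn_raster`.
#' @return A `pn_basins`: list with `id` (integer matrix of basin ids, NA on
#'   sea) and `table` (tibble: `basin_id`, `outlet_row`, `outlet_col`,
#'   `n_cells`, `A_km2`, `R_km`).
#' @export
delineate_basins <- function(flow, dem) {
  stopifnot(inherits(flow, "pn_flow"))
  spec <- flow$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  L <- flow$land$member
  id <- matrix(NA_integer_, nr, nc)
  # follow pointers with memoisation
  resolve <- function(i) {
    path <- integer(0)
    while (is.na(id[i])) {
      k <- flow$dir[i]
      if (k == 0L) { id[i] <<- i; break }
      path <- c(path, i)
      r0 <- ((i - 1) %% nr) + 1; c0 <- ((i - 1) %/% nr) + 1
      i <- (c0 + D8_DCOL[k] - 1) * nr + (r0 + D8_DROW[k])
    }
    if (length(path)) id[path] <<- id[i]
    id[i]
  }
  for (i in which(L)) resolve(i)
  areas <- cell_areas_km2(spec)$values
  land_cells <- which(L)
  df <- tibble::tibble(cell = land_cells, basin_id = id[land_cells],
                       area = areas[land_cells], elev = dem$values[land_cells])
  tab <- df |>
    dplyr::group_by(.data$basin_id) |>
    dplyr::summarise(n_cells = dplyr::n(), A_km2 = sum(.data$area),
                     max_elev = max(.data$elev), .groups = "drop") |>
    dplyr::mutate(outlet_row = ((.data$basin_id - 1) %% nr) + 1,
                  outlet_col = ((.data$basin_id - 1) %/% nr) + 1,
                  outlet_elev = dem$values[cbind(.data$outlet_row, .data$outlet_col)],
                  R_km = pmax(.data$max_elev - .data$outlet_elev, 0) / 1000) |>
    dplyr::select("basin_id", "outlet_row", "outlet_col", "n_cells",
                  "A_km2", "R_km")
  structure(list(id = id, table = tab, spec = spec, land = flow$land),
            class = "pn_basins")
}

#' Add basin climate statistics
#'
#' T is the area-weighted mean annual temperature over basin cells; Q is
#' runoff integrated over the basin,
#' Q \[km^3/yr\] = sum(runoff \[mm/s\] x area \[km^2\]) x 3.1536e7 s/yr x 1e-6 km/mm.
#' Cells with missing climate are skipped and weights renormalised.
#'
#' @param basins A `pn_basins`.
#' @param t_annual_mean `pn_raster`, degrees C.
#' @param runoff `pn_raster`, mm/s.
#' @return The `pn_basins` with `T_C` and `Q_km3yr` columns added.
#' @export
basin_climate <- function(basins, t_annual_mean, runoff) {
  stopifnot(inherits(basins, "pn_basins"))
  if (!same_spec(basins$spec, t_annual_mean$spec) ||
      !same_spec(basins$spec, runoff$spec)) stop("grid mismatch")
  L <- basins$land$member
  areas <- cell_areas_km2(basins$spec)$values
  cells <- which(L)
  df <- tibble::tibble(basin_id = basins$id[cells], area = areas[cells],
                       temp = t_annual_mean$values[cells],
                       run = runoff$values[cells])
  stats_tab <- df |>
    dplyr::group_by(.data$basin_id) |>
    dplyr::summarise(
      T_C = stats::weighted.mean(.data$temp, .data$area, na.rm = TRUE),
      Q_km3yr = sum(.data$run * .data$area, na.rm = TRUE) * 3.1536e7 * 1e-6,
      .groups = "drop")
  basins$table <- dplyr::left_join(
    dplyr::select(basins$table, -dplyr::any_of(c("T_C", "Q_km3yr"))),
    stats_tab, by = "basin_id")
  basins
}

#' BQART parameter set
#'
#' Constants of the BQART sediment-load model
#' Qs = omega B Q^0.31 A^0.5 R T (T >= 2 degC) and
#' Qs = 2 omega B Q^0.31 A^0.5 R (T < 2 degC), in MT/yr with Q in km^3/yr,
#' A in km^2, R in km, T in degC. B defaults to 1 (no glacial, lithologic or
#' anthropogenic terms resolvable in deep time). The bulk density and the
#' depositional-area rule govern the conversion of basin loads to a mapped
#' deposition rate.
#'
#' @param omega Scaling, MT/yr (default 0.02).
#' @param B Composite factor (default 1).
#' @param exponent_Q,exponent_A Discharge and area exponents (0.31, 0.5).
#' @param T_cold_cutoff Cold-branch cutoff, degC (default 2).
#' @param bulk_density Sediment bulk density, g/cm^3 (default 2).
#' @param deposition_quantile Basin cells at or below this elevation
#'   quantile form the depositional area (default 0.25).
#' @return A `pn_bqart_params` list.
#' @export
bqart_params <- function(omega = 0.02, B = 1, exponent_Q = 0.31,
                         exponent_A = 0.5, T_cold_cutoff = 2,
                         bulk_density = 2, deposition_quantile = 0.25) {
  stopifnot(omega > 0, B > 0, bulk_density > 0)
  structure(list(omega = omega, B = B, exponent_Q = exponent_Q,
                 exponent_A = exponent_A, T_cold_cutoff = T_cold_cutoff,
                 bulk_density = bulk_density,
                 deposition_quantile = deposition_quantile),
            class = "pn_bqart_params")
}

#' BQART sediment load per basin
#'
#' @param basins A `pn_basins` with climate statistics.
#' @param params A `pn_bqart_params`.
#' @return The `pn_basins` with a `Qs_MTyr` column added.
#' @export
bqart_flux <- function(basins, params = bqart_params()) {
  tab <- basins$table
  if (!all(c("T_C", "Q_km3yr") %in% names(tab)))
    stop("run basin_climate() first")
  if (any(tab$Q_km3yr < 0 | tab$A_km2 < 0 | tab$R_km < 0, na.rm = TRUE))
    stop("negative BQART inputs")
  base <- params$omega * params$B * tab$Q_km3yr^params$exponent_Q *
    tab$A_km2^params$exponent_A * tab$R_km
  basins$table$Qs_MTyr <- ifelse(tab$T_C >= params$T_cold_cutoff,
                                 base * tab$T_C, 2 * base)
  basins
}

#' Distribute basin sediment loads as a deposition-rate raster
#'
#' Each basin's load is spread uniformly over its depositional area (cells
#' at or below the basin's `deposition_quantile` elevation quantile):
#' rate \[cm/ky\] = Qs \[MT/yr\] x 1e12 / (rho \[g/cm^3\] x area \[km^2\] x 1e10) x 1e3.
#' Other land cells are 0; sea cells are missing. Basins with an empty
#' depositional area are flagged.
#'
#' @param basins A `pn_basins` with `Qs_MTyr`.
#' @param dem The raw DEM `pn_raster`.
#' @param params A `pn_bqart_params`.
#' @return List with `raster` (deposition rate, cm/ky) and `flagged`
#'   (basin ids with undefined rates).
#' @export
flux_to_deposition_rate <- function(basins, dem, params = bqart_params()) {
  stopifnot("Qs_MTyr" %in% names(basins$table))
  L <- basins$land$member
  areas <- cell_areas_km2(basins$spec)$values
  v <- matrix(NA_real_, basins$spec$n_rows, basins$spec$n_cols)
  v[L] <- 0
  flagged <- integer(0)
  for (b in seq_len(nrow(basins$table))) {
    bid <- basins$table$basin_id[b]
    cells <- which(basins$id == bid)
    cutoff <- stats::quantile(dem$values[cells], params$deposition_quantile,
                              names = FALSE)
    dep <- cells[dem$values[cells] <= cutoff]
    dep_area <- sum(areas[dep])
    if (dep_area <= 0) { flagged <- c(flagged, bid); next }
    rate <- basins$table$Qs_MTyr[b] * 1e12 /
      (params$bulk_density * dep_area * 1e10) * 1e3
    v[dep] <- rate
  }
  list(raster = pn_raster(basins$spec, v, units = "cm/ky"), flagged = flagged)
}

#' Two-class Jenks natural break
#'
#' Exhaustive scan over sorted split positions minimising the total
#' within-class sum of squared deviations for k = 2; the break is the
#' midpoint between the two boundary observations (ties take the smaller
#' break).
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return The break value.
#' @export
jenks_two_class <- function(values) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  if (n < 2 || x[1] == x[n])
    stop("no natural break: need at least 2 distinct finite values")
  css <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  best_ss <- Inf; best_break <- NA_real_
  for (i in seq_len(n - 1)) {
    ss <- css(x[1:i]) + css(x[(i + 1):n])
    brk <- (x[i] + x[i + 1]) / 2
    if (ss < best_ss - 1e-12 ||
        (abs(ss - best_ss) <= 1e-12 && brk < best_break)) {
      best_ss <- ss; best_break <- brk
    }
  }
  best_break
}

#' Classify a parameter raster into high/low taphofacies
#'
#' Class is `"high"` where value > break and `"low"` where
#' 0 <= value <= break; missing cells are `"n/a"`. The break may come from
#' [jenks_two_class()] or be supplied directly (e.g. published class bounds
#' such as 280.32 cm/ky for sediment flux or 1.97e-7 mm/s for runoff).
#'
#' @param r A `pn_raster` of non-negative values.
#' @param break_value The class boundary.
#' @param parameter `"sediment_flux"` or `"surface_runoff"`.
#' @return A `pn_taphofacies`: list with `class` (integer matrix: 1 = low,
#'   2 = high, NA = n/a), `break_value`, `parameter`, `units`, `spec`.
#' @export
classify_taphofacies <- function(r, break_value,
                                 parameter = c("sediment_flux",
                                               "surface_runoff")) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(r, "pn_raster"))
  if (any(r$values < 0, na.rm = TRUE)) stop("negative values are not classifiable")
  cls <- matrix(NA_integer_, r$spec$n_rows, r$spec$n_cols)
  cls[!is.na(r$values) & r$values <= break_value] <- 1L
  cls[!is.na(r$values) & r$values > break_value] <- 2L
  structure(list(class = cls, break_value = break_value,
                 parameter = parameter, units = r$units, spec = r$spec),
            class = "pn_taphofacies")
}

#' @export
print.pn_taphofacies <- function(x, ...) {
  cat(sprintf("<pn_taphofacies '%s'> break = %g %s; %d high / %d low cells\n",
              x$parameter, x$break_value, x$units,
              sum(x$class == 2L, na.rm = TRUE), sum(x$class == 1L, na.rm = TRUE)))
  invisible(x)
}
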