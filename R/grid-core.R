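# Gridded lat-lon data model shared by every stage: grid specs, rasters with
# NA-coded missing cells, region masks, bilinear resampling, spherical cell
# areas, and plain-text raster I/O (ESRI ASCII grid + JSON sidecar).

EARTH_RADIUS_KM <- 6371

#' Define a regular lat-lon grid
#'
#' Cell-centre registered, row 1 = southernmost row, longitudes normalised to
#' \[-180, 180). Extents are half-open \[edge, edge).
#'
#' @param lon_origin Western edge of the grid, degrees.
#' @param lat_origin Southern edge of the grid, degrees.
#' @param dlon,dlat Cell sizes in degrees (> 0).
#' @param n_cols,n_rows Grid dimensions (>= 1).
#' @return A `pn_grid` object.
#' @export
grid_spec <- function(lon_origin, lat_origin, dlon, dlat, n_cols, n_rows) {
  stopifnot(dlon > 0, dlat > 0, n_cols >= 1, n_rows >= 1)
  if (lat_origin < -90 || lat_origin + n_rows * dlat > 90 + 1e-9)
    stop("latitude extent must lie within [-90, 90]")
  if (n_cols * dlon > 360 + 1e-9) stop("longitude extent exceeds 360 degrees")
  lon_origin <- ((lon_origin + 180) %% 360) - 180
  structure(
    list(lon_origin = lon_origin, lat_origin = lat_origin,
         dlon = dlon, dlat = dlat, n_cols = as.integer(n_cols),
         n_rows = as.integer(n_rows)),
    class = "pn_grid")
}

#' @export
format.pn_grid <- function(x, ...) {
  sprintf("<pn_grid %d x %d cells, %.4g x %.4g deg, origin (%.4g, %.4g)>",
          x$n_rows, x$n_cols, x$dlon, x$dlat, x$lon_origin, x$lat_origin)
}

#' @export
print.pn_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Cell-centre coordinates of a grid
#' @param spec A `pn_grid`.
#' @return Numeric vector of cell-centre longitudes / latitudes.
#' @export
lon_centers <- function(spec) spec$lon_origin + (seq_len(spec$n_cols) - 0.5) * spec$dlon

#' @rdname lon_centers
#' @export
lat_centers <- function(spec) spec$lat_origin + (seq_len(spec$n_rows) - 0.5) * spec$dlat

same_spec <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lon_origin - b$lon_origin, a$lat_origin - b$lat_origin,
            a$dlon - b$dlon, a$dlat - b$dlat)) < tol) &&
    a$n_cols == b$n_cols && a$n_rows == b$n_rows
}

#' Construct a raster on a grid
#'
#' Values are stored as an `n_rows x n_cols` matrix with row 1 the
#' southernmost row; `NA` marks missing cells. All statistics and resampling
#' in the package ignore missing cells.
#'
#' @param spec A `pn_grid`.
#' @param values Numeric matrix (`n_rows x n_cols`) or a single number
#'   recycled over the grid.
#' @param units Free-text units label carried through I/O.
#' @return A `pn_raster`.
#' @export
pn_raster <- function(spec, values, units = "") {
  stopifnot(inherits(spec, "pn_grid"))
  if (length(values) == 1) values <- matrix(values, spec$n_rows, spec$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
    stop("values must be an n_rows x n_cols matrix")
  structure(list(spec = spec, values = values, units = units),
            class = "pn_raster")
}

#' @export
print.pn_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<pn_raster> %s\n  units: '%s'; %d missing cells; range [%s, %s]\n",
              format(x$spec), x$units, sum(is.na(x$values)),
              if (length(v)) signif(min(v), 6) else NA,
              if (length(v)) signif(max(v), 6) else NA))
  invisible(x)
}

#' Convert a raster to a tibble of cell centres
#'
#' @param x A `pn_raster`.
#' @param ... Unused.
#' @param drop_na Drop missing cells (default TRUE).
#' @return Tibble with columns `lon`, `lat`, `value`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.pn_raster <- function(x, ..., drop_na = TRUE) {
  out <- tibble::tibble(
    lon = rep(lon_centers(x$spec), each = x$spec$n_rows),
    lat = rep(lat_centers(x$spec), times = x$spec$n_cols),
    value = as.vector(x$values))
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Construct a region mask
#'
#' @param spec A `pn_grid`.
#' @param member Logical matrix (`n_rows x n_cols`) of member cells.
#' @param name Mask role: `"land"`, `"outcrop"`, `"continent-projection"` or
#'   `"custom"`.
#' @return A `pn_mask`.
#' @export
region_mask <- function(spec, member, name = "custom") {
  stopifnot(inherits(spec, "pn_grid"))
  if (length(member) == 1) member <- matrix(member, spec$n_rows, spec$n_cols)
  member <- as.matrix(member)
  storage.mode(member) <- "logical"
  member[is.na(member)] <- FALSE
  if (!all(dim(member) == c(spec$n_rows, spec$n_cols)))
    stop("member must be an n_rows x n_cols matrix")
  structure(list(spec = spec, member = member, name = name), class = "pn_mask")
}

#' @export
print.pn_mask <- function(x, ...) {
  cat(sprintf("<pn_mask '%s'> %s; %d member cells\n",
              x$name, format(x$spec), sum(x$member)))
  invisible(x)
}

#' Mask a raster to a region
#'
#' Cells outside the mask become missing; values inside are unchanged.
#'
#' @param r A `pn_raster`.
#' @param m A `pn_mask` on the same grid.
#' @return A `pn_raster`.
#' @export
apply_mask <- function(r, m) {
  stopifnot(inherits(r, "pn_raster"), inherits(m, "pn_mask"))
  if (!same_spec(r$spec, m$spec)) stop("raster and mask grids differ")
  v <- r$values
  v[!m$member] <- NA_real_
  pn_raster(r$spec, v, r$units)
}

#' Spherical cell areas
#'
#' Per-cell area on the authalic sphere,
#' A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom)), R = 6371 km.
#'
#' @param spec A `pn_grid`.
#' @return A `pn_raster` of areas in km^2.
#' @export
cell_areas_km2 <- function(spec) {
  stopifnot(inherits(spec, "pn_grid"))
  lat_bot <- (spec$lat_origin + (seq_len(spec$n_rows) - 1) * spec$dlat) * pi / 180
  lat_top <- lat_bot + spec$dlat * pi / 180
  row_area <- EARTH_RADIUS_KM^2 * (spec$dlon * pi / 180) * (sin(lat_top) - sin(lat_bot))
  pn_raster(spec, matrix(row_area, spec$n_rows, spec$n_cols), units = "km^2")
}

#' Bilinear resampling between grids
#'
#' Each target cell-centre value is the bilinear interpolation of the four
#' surrounding source cell centres. Missing-value propagation is strict: a
#' target cell whose four source neighbours include a missing cell is
#' missing, as are target centres outside the source centre hull.
#'
#' @param src Source `pn_raster` (at least 2 x 2 cells).
#' @param target Target `pn_grid`.
#' @return A `pn_raster` on `target`.
#' @export
resample_bilinear <- function(src, target) {
  stopifnot(inherits(src, "pn_raster"), inherits(target, "pn_grid"))
  sspec <- src$spec
  if (sspec$n_rows < 2 || sspec$n_cols < 2)
    stop("degenerate source grid: bilinear resampling needs at least 2 rows and 2 columns")
  if (sspec$dlat <= 0 || target$dlat <= 0)
    stop("mismatched latitude orientation: grids must run south to north")
  if (same_spec(sspec, target)) return(pn_raster(target, src$values, src$units))
  slon <- lon_centers(sspec); slat <- lat_centers(sspec)
  tlon <- lon_centers(target); tlat <- lat_centers(target)
  # fractional source indices of each target centre
  fx <- (tlon - slon[1]) / sspec$dlon
  fy <- (tlat - slat[1]) / sspec$dlat
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  tol <- 1e-9
  for (j in seq_len(target$n_cols)) {
    x <- fx[j]
    if (x < -tol || x > sspec$n_cols - 1 + tol) next
    i0 <- min(max(floor(x + tol), 0), sspec$n_cols - 2)
    wx <- x - i0
    for (i in seq_len(target$n_rows)) {
      y <- fy[i]
      if (y < -tol || y > sspec$n_rows - 1 + tol) next
      j0 <- min(max(floor(y + tol), 0), sspec$n_rows - 2)
      wy <- y - j0
      v00 <- src$values[j0 + 1, i0 + 1]; v01 <- src$values[j0 + 1, i0 + 2]
      v10 <- src$values[j0 + 2, i0 + 1]; v11 <- src$values[j0 + 2, i0 + 2]
      out[i, j] <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
        wy * ((1 - wx) * v10 + wx * v11)
    }
  }
  pn_raster(target, out, src$units)
}

#' Locate points on a grid
#'
#' @param lon,lat Point coordinates in degrees.
#' @param spec A `pn_grid`.
#' @return Integer matrix with columns `row`, `col` (NA for points outside
#'   the grid extent).
#' @export
cell_index <- function(lon, lat, spec) {
  col <- floor((lon - spec$lon_origin) / spec$dlon) + 1
  row <- floor((lat - spec$lat_origin) / spec$dlat) + 1
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# ---- I/O: ESRI ASCII grid with DX/DY extension + JSON sidecar for units ----

#' Write a raster as an ESRI ASCII grid
#'
#' Uses the DX/DY header extension when cells are non-square; missing cells
#' are written as the nodata value. A small JSON sidecar (`<path>.aux.json`)
#' carries the units label so it round-trips.
#'
#' @param r A `pn_raster`.
#' @param path Output file path.
#' @param nodata Nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "pn_raster"))
  s <- r$spec
  hdr <- c(sprintf("ncols %d", s$n_cols), sprintf("nrows %d", s$n_rows),
           sprintf("xllcorner %.10g", s$lon_origin),
           sprintf("yllcorner %.10g", s$lat_origin))
  hdr <- if (abs(s$dlon - s$dlat) < 1e-12) {
    c(hdr, sprintf("cellsize %.10g", s$dlon))
  } else c(hdr, sprintf("dx %.10g", s$dlon), sprintf("dy %.10g", s$dlat))
  hdr <- c(hdr, sprintf("NODATA_value %.10g", nodata))
  v <- r$values[rev(seq_len(s$n_rows)), , drop = FALSE]  # file rows run north -> south
  v[is.na(v)] <- nodata
  lines <- apply(v, 1, function(x) paste(sprintf("%.10g", x), collapse = " "))
  writeLines(c(hdr, lines), path)
  jsonlite::write_json(list(units = r$units), paste0(path, ".aux.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param units Units label; defaults to the JSON sidecar written by
#'   [write_ascii_grid()] when present.
#' @return A `pn_raster`.
#' @export
read_ascii_grid <- function(path, units = NULL) {
  lines <- readLines(path)
  known <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
             "dx", "dy", "nodata_value")
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (length(parts) != 2 || !key %in% known) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1
  }
  dlon <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  dlat <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dy
  spec <- grid_spec(hdr$xllcorner, hdr$yllcorner, dlon, dlat, hdr$ncols, hdr$nrows)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  v <- matrix(body, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  v <- v[rev(seq_len(spec$n_rows)), , drop = FALSE]  # back to row 1 = south
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  if (is.null(units)) {
    aux <- paste0(path, ".aux.json")
    units <- if (file.exists(aux)) jsonlite::read_json(aux)$units else ""
  }
  pn_raster(spec, v, units)
}

#' Plot a raster
#'
#' @param object A `pn_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pn_raster <- function(object, ...) {
  df <- as_tibble.pn_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
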