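# Kernel density surfaces, Getis-Ord Gi* hot/cold-spot classification,
# occurrence-by-taphofacies contingency tables, and the chi-squared / Yates /
# Fisher association tests.

#' Quartic kernel density surface
#'
#' K(d) = 3 / (pi h^2) (1 - (d/h)^2)^2 for d < h (0 otherwise), summed over
#' points at each cell centre with great-circle distances; each point's
#' kernel integrates to 1, so the surface integrates to n up to edge loss.
#'
#' @param lon,lat Point coordinates, degrees.
#' @param spec A `pn_grid`.
#' @param bandwidth_km Kernel bandwidth h in km (> 0).
#' @return A `pn_raster` of densities (points per km^2) with attributes
#'   `bandwidth_km` and `n`.
#' @export
kernel_density <- function(lon, lat, spec, bandwidth_km) {
  stopifnot(bandwidth_km > 0)
  n <- length(lon)
  v <- matrix(0, spec$n_rows, spec$n_cols)
  if (n > 0) {
    centers <- cbind(rep(lon_centers(spec), each = spec$n_rows),
                     rep(lat_centers(spec), times = spec$n_cols))
    d <- geosphere::distm(centers, cbind(lon, lat), fun = haversine_km)
    k <- 3 / (pi * bandwidth_km^2) * pmax(1 - (d / bandwidth_km)^2, 0)^2
    k[d >= bandwidth_km] <- 0
    v[] <- rowSums(k)
  }
  out <- pn_raster(spec, v, units = "points/km^2")
  attr(out, "bandwidth_km") <- bandwidth_km
  attr(out, "n") <- n
  out
}

#' Grid occurrences to a per-cell count raster
#'
#' @param occs Occurrence tibble.
#' @param spec A `pn_grid`.
#' @return A `pn_raster` of counts (0 where no occurrence).
#' @export
occurrence_counts <- function(occs, spec) {
  occs <- occurrences(occs)
  v <- matrix(0, spec$n_rows, spec$n_cols)
  if (nrow(occs)) {
    idx <- cell_index(occs$palaeo_lon, occs$palaeo_lat, spec)
    idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
    for (i in seq_len(nrow(idx))) v[idx[i, 1], idx[i, 2]] <- v[idx[i, 1], idx[i, 2]] + 1
  }
  pn_raster(spec, v, units = "count")
}

#' Getis-Ord Gi* hot/cold-spot classification
#'
#' For each masked cell i, with binary weights w_ij = 1 for masked cells j
#' within `radius_km` (self included):
#' Z_i = (sum_j w_ij x_j - Xbar W_i) /
#'       (S sqrt((n sum_j w_ij^2 - W_i^2) / (n - 1))),
#' with Xbar and S the mask-wide mean and (population) SD and n the masked
#' cell count; p is the two-sided normal tail. Hot cells have Z > 1 and
#' p < 0.05; cold cells Z < -1 and p < 0.05. A constant field (S = 0) gives
#' Z = 0 everywhere (all "neither").
#'
#' @param counts A `pn_raster` of non-negative values.
#' @param mask A `pn_mask`: the analysis mask (>= 2 member cells).
#' @param radius_km Neighbourhood radius, km.
#' @return A `pn_spots`: list with `z`, `p` (`pn_raster`s), `class` (integer
#'   matrix: 1 = cold, 2 = neither, 3 = hot, NA outside mask), `radius_km`,
#'   `mask`.
#' @export
gi_star <- function(counts, mask, radius_km) {
  stopifnot(inherits(counts, "pn_raster"), inherits(mask, "pn_mask"))
  if (!same_spec(counts$spec, mask$spec)) stop("grid mismatch")
  spec <- counts$spec
  cells <- which(mask$member, arr.ind = TRUE)
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 masked cells")
  x <- counts$values[cells]
  if (any(is.na(x) | x < 0)) stop("counts must be non-negative on the mask")
  lonc <- lon_centers(spec)[cells[, "col"]]
  latc <- lat_centers(spec)[cells[, "row"]]
  d <- gc_dist_matrix_km(lonc, latc)
  w <- d <= radius_km
  xbar <- mean(x)
  s <- sqrt(mean(x^2) - xbar^2)
  Wi <- rowSums(w)
  num <- as.vector(w %*% x) - xbar * Wi
  den <- s * sqrt(pmax(n * Wi - Wi^2, 0) / (n - 1))  # binary weights: sum w^2 = W
  z <- ifelse(den > 0, num / den, 0)
  if (s == 0) z <- rep(0, n)
  p <- 2 * stats::pnorm(-abs(z))
  zr <- matrix(NA_real_, spec$n_rows, spec$n_cols); zr[cells] <- z
  pr <- matrix(NA_real_, spec$n_rows, spec$n_cols); pr[cells] <- p
  cls <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  cls[cells] <- 2L
  cls[cells][z > 1 & p < 0.05] <- 3L
  cls[cells][z < -1 & p < 0.05] <- 1L
  structure(list(z = pn_raster(spec, zr, "z"), p = pn_raster(spec, pr, "p"),
                 class = cls, radius_km = radius_km, mask = mask),
            class = "pn_spots")
}

#' @export
print.pn_spots <- function(x, ...) {
  cat(sprintf("<pn_spots> radius %g km; %d hot, %d cold, %d neither\n",
              x$radius_km, sum(x$class == 3L, na.rm = TRUE),
              sum(x$class == 1L, na.rm = TRUE),
              sum(x$class == 2L, na.rm = TRUE)))
  invisible(x)
}

#' Build a 2x2 occurrence-by-taphofacies contingency table
#'
#' Rows are high/low taphofacies class, columns hot/cold spot class.
#' Occurrences in cells classed "neither" are excluded; occurrences in cells
#' with no taphofacies class ("n/a") are excluded and counted in the
#' `n_excluded_na_facies` attribute.
#'
#' @param occs Occurrence tibble.
#' @param spots A `pn_spots`.
#' @param facies A `pn_taphofacies` on the same grid.
#' @return A `pn_table2x2`: named list with counts `a` (high/hot),
#'   `b` (high/cold), `c` (low/hot), `d` (low/cold).
#' @export
build_contingency <- function(occs, spots, facies) {
  occs <- occurrences(occs)
  spec <- facies$spec
  if (!same_spec(spec, spots$mask$spec)) stop("grid mismatch")
  idx <- cell_index(occs$palaeo_lon, occs$palaeo_lat, spec)
  keep <- !is.na(idx[, 1])
  idx <- idx[keep, , drop = FALSE]
  spot_cls <- spots$class[idx]
  fac_cls <- facies$class[idx]
  n_na_facies <- sum(!is.na(spot_cls) & spot_cls != 2L & is.na(fac_cls))
  if (n_na_facies)
    warning(n_na_facies, " occurrence(s) in unclassified facies cells excluded")
  ok <- !is.na(spot_cls) & spot_cls != 2L & !is.na(fac_cls)
  tab <- table2x2(
    a = sum(ok & fac_cls == 2L & spot_cls == 3L),
    b = sum(ok & fac_cls == 2L & spot_cls == 1L),
    c = sum(ok & fac_cls == 1L & spot_cls == 3L),
    d = sum(ok & fac_cls == 1L & spot_cls == 1L))
  attr(tab, "n_excluded_na_facies") <- n_na_facies
  tab
}

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer counts: `a` high-facies hotspot,
#'   `b` high-facies cold spot, `c` low-facies hotspot, `d` low-facies cold
#'   spot.
#' @return A `pn_table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "pn_table2x2")
}

as_matrix_2x2 <- function(t) {
  matrix(c(t$a, t$c, t$b, t$d), 2, 2,
         dimnames = list(facies = c("high", "low"), spot = c("hot", "cold")))
}

#' @export
print.pn_table2x2 <- function(x, ...) {
  print(as_matrix_2x2(x)); invisible(x)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' chi^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)); with Yates' continuity
#' correction the numerator uses max(|ad - bc| - n/2, 0)^2. p-values from
#' the chi-squared distribution with 1 degree of freedom. Tables with a
#' zero margin are rejected.
#'
#' @param t A `pn_table2x2`.
#' @param yates Apply Yates' continuity correction.
#' @return List with `statistic`, `p`, `df = 1`.
#' @export
chi_squared_2x2 <- function(t, yates = FALSE) {
  stopifnot(inherits(t, "pn_table2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (n < 1 || any(margins == 0)) stop("degenerate margin")
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(delta - n / 2, 0)
  stat <- n * delta^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Enumerates all tables with the observed margins; the two-sided p-value is
#' the sum of hypergeometric point probabilities not exceeding the observed
#' table's probability times (1 + 1e-7).
#'
#' @param t A `pn_table2x2`.
#' @return Two-sided p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(t) {
  stopifnot(inherits(t, "pn_table2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  stopifnot(n >= 1)
  row1 <- a + b; col1 <- a + c
  lo <- max(0, row1 + col1 - n); hi <- min(row1, col1)
  probs <- stats::dhyper(lo:hi, col1, n - col1, row1)
  p_obs <- stats::dhyper(a, col1, n - col1, row1)
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' All association tests for a 2x2 table
#'
#' @param t A `pn_table2x2`.
#' @param label Optional label column.
#' @return One-row tibble: counts, `chi2`, `chi2_p`, `chi2_yates`,
#'   `chi2_yates_p`, `fisher_p`, `df`. Degenerate tables give NA statistics.
#' @export
association_tests <- function(t, label = NA_character_) {
  chi <- tryCatch(chi_squared_2x2(t, yates = FALSE), error = function(e) NULL)
  chy <- tryCatch(chi_squared_2x2(t, yates = TRUE), error = function(e) NULL)
  fis <- tryCatch(fisher_exact_2x2(t), error = function(e) NA_real_)
  tibble::tibble(
    label = label, a = t$a, b = t$b, c = t$c, d = t$d,
    n = t$a + t$b + t$c + t$d,
    chi2 = if (is.null(chi)) NA_real_ else chi$statistic,
    chi2_p = if (is.null(chi)) NA_real_ else chi$p,
    chi2_yates = if (is.null(chy)) NA_real_ else chy$statistic,
    chi2_yates_p = if (is.null(chy)) NA_real_ else chy$p,
    fisher_p = fis, df = 1)
}

#' Published latest-Cretaceous contingency tables
#'
#' The six 2x2 occurrence-by-taphofacies tables (Campanian, Maastrichtian
#' and pooled latest Cretaceous, for the sediment-flux and surface-runoff
#' taphofacies) packaged as a plain-text fixture, for reproducing the
#' published association statistics without any external data.
#'
#' @return Tibble with columns `stage`, `parameter`, `a`, `b`, `c`, `d`
#'   (counts as in [table2x2()]).
#' @export
published_contingency_tables <- function() {
  path <- system.file("extdata", "contingency_tables.csv",
                      package = "paleoniche", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
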