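# Fossil occurrence handling: CSV I/O, per-cell deduplication, Clark-Evans
# nearest-neighbour statistics, iterative spatial thinning to randomness, and
# substage time-binning.

#' Validate an occurrence table
#'
#' @param df Data frame with columns `clade`, `palaeo_lon`, `palaeo_lat`,
#'   `time_bin` (and optionally `source_id`).
#' @return A tibble with the canonical columns.
#' @export
occurrences <- function(df) {
  need <- c("clade", "palaeo_lon", "palaeo_lat", "time_bin")
  if (!all(need %in% names(df)))
    stop("occurrence table needs columns: ", paste(need, collapse = ", "))
  if (!"source_id" %in% names(df)) df$source_id <- as.character(seq_len(nrow(df)))
  df$source_id <- as.character(df$source_id)
  df$palaeo_lon <- as.numeric(df$palaeo_lon)
  df$palaeo_lat <- as.numeric(df$palaeo_lat)
  out <- tibble::as_tibble(df)[, c(need, "source_id")]
  if (nrow(out) && (any(!nzchar(out$clade)) || any(!nzchar(out$time_bin))))
    stop("clade and time_bin must be non-empty")
  out
}

#' Read / write occurrence CSV
#'
#' Plain UTF-8 CSV with header `clade,palaeo_lon,palaeo_lat,time_bin,source_id`.
#'
#' @param path File path.
#' @return A tibble of occurrences.
#' @export
read_occurrences <- function(path) {
  occurrences(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_occurrences
#' @param occs Occurrence tibble.
#' @export
write_occurrences <- function(occs, path) {
  utils::write.csv(occurrences(occs), path, row.names = FALSE)
  invisible(path)
}

#' The five latest-Cretaceous substage bins (plus the Danian)
#'
#' Three Campanian and two Maastrichtian substages of roughly equal
#' (~3.5 Myr) duration, followed by the Danian used for post-boundary
#' projection.
#'
#' @param include_danian Append the Danian bin (default TRUE).
#' @return Tibble with columns `name`, `age_max`, `age_min` (Ma), ordered
#'   old to young.
#' @export
default_time_bins <- function(include_danian = TRUE) {
  bins <- tibble::tibble(
    name = c("early Campanian", "middle Campanian", "late Campanian",
             "early Maastrichtian", "late Maastrichtian"),
    age_max = c(83.6, 79.77, 75.93, 72.1, 69.05),
    age_min = c(79.77, 75.93, 72.1, 69.05, 66.0))
  if (include_danian)
    bins <- dplyr::bind_rows(bins, tibble::tibble(
      name = "Danian", age_max = 66.0, age_min = 61.6))
  bins
}

#' Deduplicate occurrences to one per grid cell
#'
#' Keeps at most one occurrence per (clade, time_bin, grid cell); the first
#' in input order is retained and order is stable. Out-of-extent points are
#' excluded with a warning.
#'
#' @param occs Occurrence tibble.
#' @param spec A `pn_grid`.
#' @return Deduplicated occurrence tibble.
#' @export
dedupe_per_cell <- function(occs, spec) {
  occs <- occurrences(occs)
  if (!nrow(occs)) return(occs)
  idx <- cell_index(occs$palaeo_lon, occs$palaeo_lat, spec)
  out_of_extent <- is.na(idx[, "row"])
  if (any(out_of_extent))
    warning(sum(out_of_extent), " occurrence(s) outside the grid extent excluded")
  occs <- occs[!out_of_extent, ]
  idx <- idx[!out_of_extent, , drop = FALSE]
  key <- paste(occs$clade, occs$time_bin, idx[, "row"], idx[, "col"], sep = "\r")
  occs[!duplicated(key), ]
}

haversine_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

gc_dist_matrix_km <- function(lon, lat) {
  geosphere::distm(cbind(lon, lat), fun = haversine_km)
}

nn_distances_km <- function(lon, lat) {
  d <- gc_dist_matrix_km(lon, lat)
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Clark-Evans nearest-neighbour statistic
#'
#' R = mean observed great-circle nearest-neighbour distance over the
#' expectation 1/(2 sqrt(rho)) under complete spatial randomness at density
#' rho = n / area; z = (Dobs - Dexp) / SE with SE = 0.26136 / sqrt(n rho).
#' R < 1 (z < 0) indicates clustering; a regular lattice approaches R = 2.
#'
#' @param lon,lat Point coordinates, degrees.
#' @param study_area_km2 Study-area size (conventionally the training-mask
#'   area), km^2.
#' @return List with `R`, `z`, `n`, `d_obs_km`, `d_exp_km`.
#' @export
clark_evans <- function(lon, lat, study_area_km2) {
  n <- length(lon)
  stopifnot(n >= 3, study_area_km2 > 0, length(lat) == n)
  rho <- n / study_area_km2
  d_obs <- mean(nn_distances_km(lon, lat))
  d_exp <- 1 / (2 * sqrt(rho))
  se <- 0.26136 / sqrt(n * rho)
  list(R = d_obs / d_exp, z = (d_obs - d_exp) / se, n = n,
       d_obs_km = d_obs, d_exp_km = d_exp)
}

#' Thin a point set until spatially random
#'
#' Iteratively removes one member of the current closest pair while the
#' Clark-Evans test indicates significant clustering (one-sided z below
#' -z_crit(alpha)). The removed member is the one whose removal yields the
#' larger new mean nearest-neighbour distance; remaining ties are broken by
#' a seeded draw. Stops when randomness is reached or n = 3.
#'
#' @param occs Occurrence tibble (thinned within the whole set).
#' @param study_area_km2 Study-area size for the density, km^2.
#' @param alpha One-sided significance level (default 0.05).
#' @param seed Integer seed (tie-breaking).
#' @return List with `occurrences` (thinned tibble) and `report` (tibble:
#'   `n_initial`, `n_final`, `iterations`, `R_final`, `z_final`, `seed`).
#' @export
thin_to_random <- function(occs, study_area_km2, alpha = 0.05, seed = 1) {
  occs <- occurrences(occs)
  n0 <- nrow(occs)
  stopifnot(n0 >= 3)
  z_crit <- stats::qnorm(1 - alpha)
  rng <- local({ set.seed(seed); function(k) sample.int(k, 1) })
  keep <- seq_len(n0)
  iters <- 0L
  repeat {
    ce <- clark_evans(occs$palaeo_lon[keep], occs$palaeo_lat[keep],
                      study_area_km2)
    if (ce$z >= -z_crit || length(keep) <= 3) break
    d <- gc_dist_matrix_km(occs$palaeo_lon[keep], occs$palaeo_lat[keep])
    diag(d) <- Inf
    pair <- which(d == min(d), arr.ind = TRUE)[1, ]
    mean_nn_without <- vapply(pair, function(i) {
      rest <- keep[-i]
      mean(nn_distances_km(occs$palaeo_lon[rest], occs$palaeo_lat[rest]))
    }, 0)
    victim <- if (abs(diff(mean_nn_without)) > 1e-12) {
      pair[which.max(mean_nn_without)]
    } else pair[rng(2)]
    keep <- keep[-victim]
    iters <- iters + 1L
  }
  ce <- clark_evans(occs$palaeo_lon[keep], occs$palaeo_lat[keep], study_area_km2)
  list(occurrences = occs[keep, ],
       report = tibble::tibble(n_initial = n0, n_final = length(keep),
                               iterations = iters, R_final = ce$R,
                               z_final = ce$z, seed = seed))
}

#' Partition occurrences by substage time bin
#'
#' @param occs Occurrence tibble.
#' @param bins Time-bin tibble (see [default_time_bins()]).
#' @return List with `by_bin` (named list of occurrence tibbles) and
#'   `counts` (tibble bin x clade, long format with `n`).
#' @export
bin_by_substage <- function(occs, bins = default_time_bins(FALSE)) {
  occs <- occurrences(occs)
  unknown <- setdiff(unique(occs$time_bin), bins$name)
  if (length(unknown)) {
    warning("excluding occurrences with unknown time bin(s): ",
            paste(unknown, collapse = ", "))
    occs <- occs[occs$time_bin %in% bins$name, ]
  }
  by_bin <- lapply(stats::setNames(bins$name, bins$name),
                   function(b) occs[occs$time_bin == b, ])
  counts <- tidyr::expand_grid(time_bin = bins$name,
                               clade = sort(unique(occs$clade))) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = sum(occs$time_bin == .data$time_bin &
                            occs$clade == .data$clade)) |>
    dplyr::ungroup()
  list(by_bin = by_bin, counts = counts)
}
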