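# Bioclim-style candidate predictors from monthly climate, and the Pearson
# collinearity screen applied before niche modelling.

#' Canonical names of the 12 candidate climatic predictors
#' @export
predictor_names <- function() {
  c("T_annual_mean", "P_annual_mean",
    "T_coldest_q", "T_warmest_q", "T_driest_q", "T_wettest_q",
    "P_coldest_q", "P_warmest_q", "P_driest_q", "P_wettest_q",
    "T_annual_sd", "P_annual_sd")
}

#' Bundle a monthly climate annual cycle
#'
#' @param temperature List of 12 `pn_raster`s, degrees C (months 1..12).
#' @param precipitation List of 12 `pn_raster`s, mm/s.
#' @return A `pn_monthly_climate`.
#' @export
monthly_climate <- function(temperature, precipitation) {
  if (length(temperature) != 12 || length(precipitation) != 12)
    stop("need exactly 12 monthly rasters for temperature and precipitation")
  spec <- temperature[[1]]$spec
  for (r in c(temperature, precipitation)) {
    stopifnot(inherits(r, "pn_raster"))
    if (!same_spec(r$spec, spec)) stop("all monthly rasters must share one grid")
  }
  for (r in precipitation)
    if (any(r$values < 0, na.rm = TRUE)) stop("precipitation must be non-negative")
  structure(list(temperature = temperature, precipitation = precipitation,
                 spec = spec), class = "pn_monthly_climate")
}

# 3-consecutive-month windows with December-January wrap-around
quarter_windows <- function() lapply(1:12, function(m) ((m - 1 + 0:2) %% 12) + 1)

#' Derive the 12 candidate climatic predictors
#'
#' Quarters are 3-consecutive-month moving windows (with December-January
#' wrap-around): coldest/warmest minimise/maximise mean temperature,
#' driest/wettest minimise/maximise total precipitation, ties broken by the
#' earliest starting month. Annual SDs are population standard deviations of
#' the 12 monthly values. Cells missing in any month are missing in every
#' output layer.
#'
#' @param mc A `pn_monthly_climate`.
#' @param time_bin Provenance label stored on the result.
#' @return A named list of 12 `pn_raster`s (class `pn_predictors`).
#' @export
derive_predictors <- function(mc, time_bin = "") {
  stopifnot(inherits(mc, "pn_monthly_climate"))
  spec <- mc$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  tcube <- vapply(mc$temperature, function(r) r$values, matrix(0, nr, nc))
  pcube <- vapply(mc$precipitation, function(r) r$values, matrix(0, nr, nc))
  dim(tcube) <- c(nr * nc, 12); dim(pcube) <- c(nr * nc, 12)
  miss <- rowSums(is.na(tcube)) > 0 | rowSums(is.na(pcube)) > 0
  wins <- quarter_windows()
  tq <- vapply(wins, function(w) rowMeans(tcube[, w, drop = FALSE]), numeric(nr * nc))
  pq <- vapply(wins, function(w) rowMeans(pcube[, w, drop = FALSE]), numeric(nr * nc))
  psum <- vapply(wins, function(w) rowSums(pcube[, w, drop = FALSE]), numeric(nr * nc))
  # ties -> earliest starting month: max.col/which-style first index on ties
  first_min <- function(m) apply(m, 1, which.min)  # which.min takes the first tie
  first_max <- function(m) apply(m, 1, which.max)
  safe_idx <- function(m, f) { m[is.na(m)] <- 0; f(m) }
  i_cold <- safe_idx(tq, first_min); i_warm <- safe_idx(tq, first_max)
  i_dry  <- safe_idx(psum, first_min); i_wet <- safe_idx(psum, first_max)
  pick <- function(m, idx) m[cbind(seq_len(nrow(m)), idx)]
  pop_sd <- function(m) sqrt(rowMeans(m^2) - rowMeans(m)^2)
  lay <- list(
    T_annual_mean = rowMeans(tcube), P_annual_mean = rowMeans(pcube),
    T_coldest_q = pick(tq, i_cold), T_warmest_q = pick(tq, i_warm),
    T_driest_q = pick(tq, i_dry), T_wettest_q = pick(tq, i_wet),
    P_coldest_q = pick(pq, i_cold), P_warmest_q = pick(pq, i_warm),
    P_driest_q = pick(pq, i_dry), P_wettest_q = pick(pq, i_wet),
    T_annual_sd = pop_sd(tcube), P_annual_sd = pop_sd(pcube))
  units <- c(rep(c("degC", "mm/s"), 1), rep("degC", 4), rep("mm/s", 4),
             "degC", "mm/s")
  out <- purrr::imap(lay, function(v, nm) {
    v[miss] <- NA_real_
    pn_raster(spec, matrix(pmax(v, -Inf), nr, nc),
              units = units[match(nm, predictor_names())])
  })
  structure(out, class = "pn_predictors", time_bin = time_bin)
}

#' Predictor values at cells as a tibble
#'
#' @param ps A `pn_predictors` (or any named list of `pn_raster`s).
#' @param cells Integer matrix with columns `row`, `col`; default all cells.
#' @return Tibble, one column per predictor.
#' @export
predictor_values <- function(ps, cells = NULL) {
  spec <- ps[[1]]$spec
  if (is.null(cells)) {
    cells <- cbind(row = rep(seq_len(spec$n_rows), spec$n_cols),
                   col = rep(seq_len(spec$n_cols), each = spec$n_rows))
  }
  tibble::as_tibble(lapply(ps, function(r) r$values[cells]))
}

#' Pearson collinearity screen
#'
#' Pairwise Pearson correlations are computed over the cells of `region`
#' (the model training region). While any pair has |r| >= `r_max`, the
#' member of the worst pair with the larger mean absolute correlation to all
#' remaining variables is dropped (ties drop the later name in canonical
#' order). Zero-variance predictors are dropped first with a warning.
#'
#' @param ps A `pn_predictors`.
#' @param region A `pn_mask` (>= 3 member cells).
#' @param r_max Absolute-correlation cutoff (default 0.7).
#' @return Character vector of retained predictor names, with the final
#'   correlation matrix as attribute `"cor"`.
#' @export
pearson_filter <- function(ps, region, r_max = 0.7) {
  stopifnot(inherits(region, "pn_mask"), length(ps) >= 2)
  cells <- which(region$member, arr.ind = TRUE)
  if (nrow(cells) < 3) stop("need at least 3 region cells")
  vals <- predictor_values(ps, cells)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  keep <- names(ps)
  sds <- vapply(vals, stats::sd, 0)
  if (any(sds == 0)) {
    warning("dropping zero-variance predictor(s): ",
            paste(keep[sds == 0], collapse = ", "))
    keep <- keep[sds > 0]
  }
  canon <- keep  # canonical order = input order
  while (length(keep) > 1) {
    cm <- stats::cor(vals[keep])
    acm <- abs(cm); diag(acm) <- 0
    if (max(acm) < r_max) break
    worst <- which(acm == max(acm), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- vapply(pair, function(v) mean(acm[v, keep != v]), 0)
    drop <- if (abs(diff(mean_abs)) > 1e-12) pair[which.max(mean_abs)] else
      pair[which.max(match(pair, canon))]
    keep <- setdiff(keep, drop)
  }
  cm <- if (length(keep) > 1) stats::cor(vals[keep]) else
    matrix(1, 1, 1, dimnames = list(keep, keep))
  structure(keep, cor = cm)
}
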