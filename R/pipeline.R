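# Config-driven orchestration of the three analysis stages on synthetic
# presets: niche modelling with multi-threshold area quantification and
# forward/backward consensus, the taphofacies stage, and the
# occurrence-by-taphofacies association stage.

#' Pipeline configuration
#'
#' @param presets Synthetic stage presets to run, in temporal order.
#' @param clades Clade labels to simulate.
#' @param thresholds Binary-conversion thresholds, strictly increasing in
#'   (0, 1) (default 0.2 / 0.45 / 0.7).
#' @param k Evaluation replicates per model (default 50).
#' @param train_fraction Training share of presences (default 0.75).
#' @param reg_multiplier MaxEnt regularisation multiplier.
#' @param mode `"extrapolate"` or `"clamp"`.
#' @param scale `"logistic"` or `"raw"`.
#' @param n_presence Presences sampled per clade and preset.
#' @param max_deviation Forward/backward consensus rule (default 0.15).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pn_run_config` list.
#' @export
run_config <- function(presets = c("campanian", "maastrichtian"),
                       clades = "VirtualSpecies",
                       thresholds = c(0.2, 0.45, 0.7), k = 50,
                       train_fraction = 0.75, reg_multiplier = 1,
                       mode = "extrapolate", scale = "logistic",
                       n_presence = 50, max_deviation = 0.15,
                       seed = 42) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0 & thresholds < 1))
  structure(as.list(environment()), class = "pn_run_config")
}

stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Run the niche-modelling stage on synthetic presets
#'
#' For each clade and preset: sample presences of the preset's virtual
#' species on the outcrop mask, thin to spatial randomness, fit the
#' maximum-entropy model on the outcrop background, evaluate it by the
#' subsample procedure, project it to the outcrop and continental regions,
#' binarise at every threshold and quantify habitat areas; then run
#' adjacent-preset forward/backward consensus checks.
#'
#' @param cfg A `pn_run_config`.
#' @return List with `areas` (tibble: clade, train_bin, project_bin, region,
#'   threshold, area_km2), `evaluations`, `models`, `consensus` (tibble),
#'   `presets` (the generated stage data), `config`.
#' @export
run_enm_stage <- function(cfg = run_config()) {
  stages <- lapply(cfg$presets, synth_preset, seed = stage_seed(cfg, 0))
  names(stages) <- cfg$presets
  areas <- list(); evals <- list(); models <- list(); binmaps <- list()
  for (ci in seq_along(cfg$clades)) {
    clade <- cfg$clades[ci]
    for (si in seq_along(stages)) {
      st <- stages[[si]]
      scfg <- sampling_config(n_target = cfg$n_presence,
                              seed = stage_seed(cfg, 100 * ci + si))
      occs <- sample_occurrences(st$species, NULL, st$outcrop, scfg,
                                 clade = clade, time_bin = st$preset)
      occs <- dedupe_per_cell(occs, st$land$spec)
      if (nrow(occs) < 5) {
        warning("preset '", st$preset, "', clade '", clade,
                "': fewer than 5 presences, stage skipped")
        next
      }
      outcrop_area <- sum(cell_areas_km2(st$land$spec)$values[st$outcrop$member])
      thin <- thin_to_random(occs, outcrop_area,
                             seed = stage_seed(cfg, 200 * ci + si))
      occs <- thin$occurrences
      preds <- st$predictors[st$retained]
      pres_cells <- unique(cell_index(occs$palaeo_lon, occs$palaeo_lat,
                                      st$land$spec))
      X_pres <- predictor_values(preds, pres_cells)
      X_bg <- predictor_values(preds, which(st$outcrop$member, arr.ind = TRUE))
      X_bg <- X_bg[stats::complete.cases(X_bg), , drop = FALSE]
      model <- suppressWarnings(fit_maxent(
        X_pres, X_bg, reg_multiplier = cfg$reg_multiplier,
        seed = stage_seed(cfg, 300 * ci + si)))
      ev <- if (nrow(X_pres) >= 8) suppressWarnings(evaluate_maxent(
        X_pres, X_bg, k = cfg$k, train_fraction = cfg$train_fraction,
        reg_multiplier = cfg$reg_multiplier,
        seed = stage_seed(cfg, 400 * ci + si))) else NULL
      key <- paste(clade, st$preset, sep = "|")
      models[[key]] <- model
      evals[[key]] <- ev
      for (region in list(st$outcrop, st$continent)) {
        smap <- suitability_map(model, preds, region, mode = cfg$mode,
                                scale = cfg$scale,
                                provenance = list(clade = clade,
                                                  train_bin = st$preset))
        for (th in cfg$thresholds) {
          bh <- binarize_and_area(smap, th, region)
          binmaps[[paste(key, region$name, th, sep = "|")]] <- bh
          areas[[length(areas) + 1]] <- tibble::tibble(
            clade = clade, train_bin = st$preset, project_bin = st$preset,
            region = region$name, threshold = th, area_km2 = bh$area_km2)
        }
      }
    }
  }
  consensus <- list()
  if (length(cfg$presets) >= 2) {
    for (ci in seq_along(cfg$clades)) {
      clade <- cfg$clades[ci]
      for (si in seq_len(length(cfg$presets) - 1)) {
        a <- cfg$presets[si]; b <- cfg$presets[si + 1]
        ka <- paste(clade, a, sep = "|"); kb <- paste(clade, b, sep = "|")
        if (is.null(models[[ka]]) || is.null(models[[kb]])) next
        for (th in cfg$thresholds) {
          # forward: model trained in a projected onto b's continent, vs b's own
          sta <- stages[[a]]; stb <- stages[[b]]
          fwd <- suitability_map(models[[ka]],
                                 stb$predictors[models[[ka]]$expansion$vars],
                                 stb$continent, mode = cfg$mode,
                                 scale = cfg$scale)
          bwd <- suitability_map(models[[kb]],
                                 sta$predictors[models[[kb]]$expansion$vars],
                                 sta$continent, mode = cfg$mode,
                                 scale = cfg$scale)
          own_b <- binmaps[[paste(kb, "continent-projection", th, sep = "|")]]
          own_a <- binmaps[[paste(ka, "continent-projection", th, sep = "|")]]
          chk_f <- consensus_check(binarize_and_area(fwd, th, stb$continent),
                                   own_b, stb$continent, cfg$max_deviation)
          chk_b <- consensus_check(binarize_and_area(bwd, th, sta$continent),
                                   own_a, sta$continent, cfg$max_deviation)
          consensus[[length(consensus) + 1]] <- tibble::tibble(
            clade = clade, from = c(a, b), to = c(b, a),
            direction = c("forward", "backward"), threshold = th,
            deviation = c(chk_f$deviation, chk_b$deviation),
            pass = c(chk_f$pass, chk_b$pass))
        }
      }
    }
  }
  list(areas = dplyr::bind_rows(areas),
       evaluations = evals, models = models,
       consensus = dplyr::bind_rows(consensus),
       presets = stages, config = cfg)
}

#' Run the taphofacies stage on a synthetic preset
#'
#' Routes flow on the preset DEM, delineates basins, computes BQART fluxes
#' and the deposition-rate field, and classifies sediment flux and surface
#' runoff into high/low taphofacies by two-class Jenks breaks (or supplied
#' overrides).
#'
#' @param stage A [synth_preset()] result.
#' @param params A `pn_bqart_params`.
#' @param flux_break,runoff_break Optional class-bound overrides (e.g. the
#'   published 280.32 cm/ky and 1.97e-7 mm/s bounds).
#' @return List with `flow`, `basins` (with climate + flux columns),
#'   `deposition` (`pn_raster`), `flux_facies`, `runoff_facies`, `breaks`.
#' @export
run_taphonomy_stage <- function(stage, params = bqart_params(),
                                flux_break = NULL, runoff_break = NULL) {
  flow <- fill_and_route(stage$world$dem, stage$land)
  basins <- delineate_basins(flow, stage$world$dem)
  preds <- stage$predictors
  basins <- basin_climate(basins, preds$T_annual_mean, stage$runoff)
  basins <- bqart_flux(basins, params)
  dep <- flux_to_deposition_rate(basins, stage$world$dem, params)
  land_flux <- dep$raster$values[stage$land$member]
  land_run <- stage$runoff$values[stage$land$member]
  fb <- if (is.null(flux_break)) jenks_two_class(land_flux) else flux_break
  rb <- if (is.null(runoff_break)) jenks_two_class(land_run) else runoff_break
  list(flow = flow, basins = basins, deposition = dep$raster,
       flux_facies = classify_taphofacies(dep$raster, fb, "sediment_flux"),
       runoff_facies = classify_taphofacies(stage$runoff, rb, "surface_runoff"),
       breaks = c(sediment_flux = fb, surface_runoff = rb))
}

#' Run the association stage
#'
#' Kernel density of the occurrences defines the analysis mask (density
#' > 0); Gi* on per-cell occurrence counts classifies hot and cold spots;
#' occurrences falling in hot/cold cells are cross-tabulated against the
#' taphofacies classes and tested (chi-squared with and without Yates'
#' correction, Fisher's exact).
#'
#' @param occs Occurrence tibble (deduplicated, not thinned).
#' @param facies A `pn_taphofacies`.
#' @param spec The analysis grid.
#' @param gi_radius_km Gi* neighbourhood radius, km (default 1.5 cell
#'   sizes).
#' @param kd_bandwidth_km Kernel bandwidth, km (default 2 cell diagonals).
#' @param label Label for the result row.
#' @return List with `density`, `spots`, `table` (`pn_table2x2`), `tests`
#'   (one-row tibble from [association_tests()]).
#' @export
run_association_stage <- function(occs, facies, spec,
                                  gi_radius_km = NULL, kd_bandwidth_km = NULL,
                                  label = NA_character_) {
  cell_km <- mean(c(spec$dlon, spec$dlat)) * 111.2
  if (is.null(kd_bandwidth_km)) kd_bandwidth_km <- 2 * sqrt(2) * cell_km
  if (is.null(gi_radius_km)) gi_radius_km <- 1.5 * cell_km
  occs <- occurrences(occs)
  dens <- kernel_density(occs$palaeo_lon, occs$palaeo_lat, spec,
                         kd_bandwidth_km)
  mask <- region_mask(spec, dens$values > 0, "custom")
  counts <- occurrence_counts(occs, spec)
  spots <- gi_star(counts, mask, gi_radius_km)
  tab <- suppressWarnings(build_contingency(occs, spots, facies))
  list(density = dens, spots = spots, table = tab,
       tests = association_tests(tab, label = label))
}

#' Reproduce the published association statistics from packaged counts
#'
#' Runs the chi-squared (with and without Yates' correction) and Fisher
#' tests directly on the packaged printed contingency tables, bypassing the
#' raster stages.
#'
#' @return Tibble, one row per stage x parameter, with the counts and all
#'   test statistics.
#' @export
published_association_results <- function() {
  tabs <- published_contingency_tables()
  purrr::pmap_dfr(tabs, function(stage, parameter, a, b, c, d) {
    dplyr::mutate(association_tests(table2x2(a, b, c, d),
                                    label = paste(stage, parameter)),
                  stage = stage, parameter = parameter, .before = 1)
  })
}

#' Null calibration of the association stage
#'
#' Runs the association stage on seeded replicates in which the
#' preservation weights are equalised, so occurrence placement is
#' independent of the taphofacies class. Each replicate samples a
#' Campanian-style occurrence set of a broad-niche species, classifies hot
#' and cold spots, builds the occurrence-by-taphofacies table and records
#' the chi-squared p-value. Replicates whose table is degenerate (a zero
#' margin: no evidence either way) are recorded with `NA` and counted as
#' non-significant.
#'
#' @param n_replicates Number of seeded replicates (default 50).
#' @param seed Master seed.
#' @param n_occurrences Occurrence draws per replicate (default 400).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `replicate`, `chi2_p`, `degenerate`, `significant`;
#'   the fraction of non-significant replicates is attribute
#'   `"prop_nonsignificant"`.
#' @export
run_null_calibration <- function(n_replicates = 50, seed = 42,
                                 n_occurrences = 400, alpha = 0.05) {
  st <- synth_preset("campanian", seed = seed, breadth_fraction = 1)
  tp <- run_taphonomy_stage(st)
  cell_km <- mean(c(st$land$spec$dlon, st$land$spec$dlat)) * 111.2
  rows <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    occs <- suppressWarnings(dedupe_per_cell(sample_occurrences(
      st$species, tp$flux_facies, st$outcrop,
      sampling_config(n_target = n_occurrences, weight_high = 1,
                      weight_low = 1, seed = seed + 1000 + i,
                      replace = TRUE, jitter_sd = 0.5)), st$land$spec))
    a <- run_association_stage(occs, tp$flux_facies, st$land$spec,
                               gi_radius_km = 3 * cell_km)
    p <- a$tests$chi2_p
    tibble::tibble(replicate = i, chi2_p = p, degenerate = is.na(p),
                   significant = !is.na(p) & p < alpha)
  })
  attr(rows, "prop_nonsignificant") <- mean(!rows$significant)
  rows
}

#' Per-bin, per-clade raw occurrence counts
#'
#' The raw-diversity counting utility: counts occurrences per time bin and
#' clade with no correction.
#'
#' @param occs Occurrence tibble.
#' @return Tibble `time_bin` x `clade` with `n`.
#' @export
raw_diversity_counts <- function(occs) {
  occs <- occurrences(occs)
  dplyr::count(occs, .data$time_bin, .data$clade, name = "n")
}
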