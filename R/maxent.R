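# Presence-background maximum-entropy niche model: an L1-penalised Gibbs
# (log-linear) model over linear/quadratic/product features, fit by a
# monotone proximal-gradient method. Includes prediction with clamping or
# extrapolation, non-analogue flagging, AUC / TSS evaluation, subsample
# cross-evaluation with jackknife and permutation importance, binary habitat
# maps with spherical areas, and forward-backward consensus checks.

# ---- feature expansion --------------------------------------------------

build_expansion <- function(vars, classes) {
  feats <- list()
  if ("linear" %in% classes)
    for (v in vars) feats[[length(feats) + 1]] <- list(type = "linear", vars = v)
  if ("quadratic" %in% classes)
    for (v in vars) feats[[length(feats) + 1]] <- list(type = "quadratic", vars = v)
  if ("product" %in% classes && length(vars) > 1) {
    cmb <- utils::combn(vars, 2)
    for (k in seq_len(ncol(cmb)))
      feats[[length(feats) + 1]] <- list(type = "product", vars = cmb[, k])
  }
  feats
}

# variables are standardised to background mean 0 / SD 1 before feature
# construction, so quadratic and product surfaces are centred on the
# background climate rather than on an arbitrary unit origin
raw_features <- function(X, feats, var_mu, var_sd) {
  Z <- lapply(stats::setNames(names(var_mu), names(var_mu)), function(v)
    (X[[v]] - var_mu[[v]]) / var_sd[[v]])
  out <- vapply(feats, function(f) {
    switch(f$type,
           linear = Z[[f$vars]],
           quadratic = Z[[f$vars]]^2,
           product = Z[[f$vars[1]]] * Z[[f$vars[2]]])
  }, numeric(nrow(X)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- vapply(feats, function(f)
    paste(c(f$type, f$vars), collapse = ":"), "")
  out
}

feature_matrix <- function(X, expansion) {
  Fr <- raw_features(X, expansion$features, expansion$var_mu, expansion$var_sd)
  scale(Fr, center = expansion$mu, scale = expansion$sd)
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# ---- fitting ------------------------------------------------------------

#' Fit a maximum-entropy presence-background model
#'
#' Maximises the L1-penalised presence log-likelihood
#' L(lambda) = mean_presence(eta) - log sum_background exp(eta) - sum_j beta_j |lambda_j|
#' with eta = sum_j lambda_j f_j(x) over features standardised to background
#' mean 0 / SD 1, and beta_j = reg_multiplier / sqrt(m) (m = number of
#' presence cells). The objective is concave; optimisation is a monotone
#' proximal-gradient ascent with backtracking, stopped at KKT residual
#' 1e-7 or 5000 iterations. Deterministic given its inputs.
#'
#' @param presence Data frame of predictor values at presence cells (>= 5 rows).
#' @param background Data frame of predictor values at background cells
#'   (the training region; should contain the presence cells' region).
#' @param classes Feature classes, subset of
#'   `c("linear", "quadratic", "product")`.
#' @param reg_multiplier L1 regularisation multiplier (default 1).
#' @param seed Recorded on the model (fitting itself is deterministic).
#' @return A `pn_maxent` model object.
#' @export
fit_maxent <- function(presence, background,
                       classes = c("linear", "quadratic", "product"),
                       reg_multiplier = 1, seed = NA_integer_) {
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  m <- nrow(presence)
  if (m < 5) stop("need at least 5 presence cells")
  vars <- names(background)
  stopifnot(length(vars) >= 1, all(names(presence) == vars))
  if (!all(vapply(c(presence, background), function(x) all(is.finite(x)), TRUE)))
    stop("non-finite predictor values")
  const <- vapply(background, function(x) stats::sd(x) == 0, TRUE)
  if (any(const)) {
    warning("excluding constant predictor(s): ",
            paste(vars[const], collapse = ", "))
    vars <- vars[!const]
    if (!length(vars)) stop("no non-constant predictors left")
    presence <- presence[vars]; background <- background[vars]
  }
  feats <- build_expansion(vars, classes)
  var_mu <- vapply(background, mean, 0)
  var_sd <- vapply(background, stats::sd, 0)
  Fb_raw <- raw_features(background, feats, var_mu, var_sd)
  mu <- colMeans(Fb_raw); sd <- apply(Fb_raw, 2, stats::sd) * sqrt((nrow(Fb_raw) - 1) / nrow(Fb_raw))
  ok <- sd > 0
  feats <- feats[ok]; mu <- mu[ok]; sd <- sd[ok]
  expansion <- list(features = feats, mu = mu, sd = sd,
                    var_mu = var_mu, var_sd = var_sd, vars = vars,
                    classes = classes)
  Fb <- feature_matrix(background, expansion)
  Fp <- feature_matrix(presence, expansion)
  p <- ncol(Fb)
  fbar <- colMeans(Fp)
  beta <- rep(reg_multiplier / sqrt(m), p)

  smooth_obj <- function(lam) sum(fbar * lam) - logsumexp(Fb %*% lam)
  grad <- function(lam) {
    eta <- as.vector(Fb %*% lam)
    q <- exp(eta - logsumexp(eta))
    fbar - as.vector(crossprod(Fb, q))
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  lam <- rep(0, p)
  f_cur <- smooth_obj(lam)
  step <- 1
  obj_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(5000)) {
    g <- grad(lam)
    # KKT residual for -L + penalty
    res <- ifelse(lam != 0, abs(g - beta * sign(lam)),
                  pmax(abs(g) - beta, 0))
    if (max(res) < 1e-7) { converged <- TRUE; break }
    repeat {
      cand <- soft(lam + step * g, step * beta)
      f_new <- smooth_obj(cand)
      dlt <- cand - lam
      # sufficient-increase condition for the proximal step
      if (f_new >= f_cur + sum(g * dlt) - sum(dlt^2) / (2 * step) - 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    lam <- cand
    f_cur <- f_new
    obj_trace <- c(obj_trace, f_cur - sum(beta * abs(lam)))
    step <- min(step * 1.25, 1e3)
  }
  eta_b <- as.vector(Fb %*% lam)
  logZ <- logsumexp(eta_b)
  q <- exp(eta_b - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  train_range <- lapply(stats::setNames(vars, vars), function(v)
    range(c(background[[v]], presence[[v]])))
  structure(list(
    expansion = expansion, lambda = stats::setNames(as.vector(lam), colnames(Fb)),
    beta = beta, reg_multiplier = reg_multiplier, logZ = logZ, entropy = H,
    train_range = train_range, m = m, n_background = nrow(background),
    seed = seed, converged = converged,
    objective = f_cur - sum(beta * abs(lam)), objective_trace = obj_trace),
    class = "pn_maxent")
}

#' @export
print.pn_maxent <- function(x, ...) {
  cat(sprintf(paste0("<pn_maxent> %d presence / %d background cells, ",
                     "%d features (%d active), reg = %g\n",
                     "  converged: %s; penalised log-likelihood: %.6g; entropy: %.4g\n"),
              x$m, x$n_background, length(x$lambda), sum(x$lambda != 0),
              x$reg_multiplier, x$converged, x$objective, x$entropy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maximum-entropy model
#'
#' @param x A `pn_maxent`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `class`, `estimate`
#'   (coefficient on the standardised feature), `penalty`.
#' @export
tidy.pn_maxent <- function(x, ...) {
  tibble::tibble(
    feature = names(x$lambda),
    class = vapply(x$expansion$features, `[[`, "", "type"),
    estimate = unname(x$lambda),
    penalty = x$beta)
}

#' @rdname tidy.pn_maxent
#' @return For `glance()`: a one-row tibble with fit summaries.
#' @export
glance.pn_maxent <- function(x, ...) {
  tibble::tibble(m_presence = x$m, n_background = x$n_background,
                 n_features = length(x$lambda),
                 n_active = sum(x$lambda != 0),
                 reg_multiplier = x$reg_multiplier,
                 objective = x$objective, entropy = x$entropy,
                 converged = x$converged)
}

# ---- prediction ---------------------------------------------------------

clamp_to_range <- function(X, train_range) {
  for (v in names(train_range))
    X[[v]] <- pmin(pmax(X[[v]], train_range[[v]][1]), train_range[[v]][2])
  X
}

#' Predict suitability at cells
#'
#' @param object A `pn_maxent`.
#' @param newdata Data frame of predictor values.
#' @param mode `"extrapolate"` (features evaluated as-is) or `"clamp"`
#'   (variables truncated to their training range first).
#' @param scale `"logistic"` (default): s = c q / (1 + c q) with
#'   q = exp(eta - logZ) and c = exp(H); or `"raw"`: q renormalised to sum
#'   to 1 over the prediction rows.
#' @param ... Unused.
#' @return Numeric vector of suitabilities (NA where predictors are missing).
#' @export
predict.pn_maxent <- function(object, newdata,
                              mode = c("extrapolate", "clamp"),
                              scale = c("logistic", "raw"), ...) {
  mode <- match.arg(mode); scale <- match.arg(scale)
  newdata <- as.data.frame(newdata)
  missing_vars <- setdiff(object$expansion$vars, names(newdata))
  if (length(missing_vars))
    stop("newdata lacks model variable(s): ", paste(missing_vars, collapse = ", "))
  newdata <- newdata[object$expansion$vars]
  ok <- stats::complete.cases(newdata)
  out <- rep(NA_real_, nrow(newdata))
  if (!any(ok)) return(out)
  X <- newdata[ok, , drop = FALSE]
  if (mode == "clamp") X <- clamp_to_range(X, object$train_range)
  eta <- as.vector(feature_matrix(X, object$expansion) %*% object$lambda)
  q <- exp(eta - object$logZ)
  out[ok] <- if (scale == "raw") q / sum(q) else {
    cq <- exp(object$entropy) * q
    cq / (1 + cq)
  }
  out
}

#' Non-analogue (MESS-style) flags
#'
#' TRUE where any model variable lies strictly outside its training range.
#' Flagged cells keep their suitability values and are interpreted with
#' caution.
#'
#' @param model A `pn_maxent`.
#' @param newdata Data frame of predictor values.
#' @return Logical vector (NA rows give FALSE).
#' @export
mess_flags <- function(model, newdata) {
  newdata <- as.data.frame(newdata)[model$expansion$vars]
  flag <- rep(FALSE, nrow(newdata))
  for (v in model$expansion$vars) {
    rng <- model$train_range[[v]]
    x <- newdata[[v]]
    flag <- flag | (!is.na(x) & (x < rng[1] | x > rng[2]))
  }
  flag
}

#' Project a model onto raster predictors
#'
#' @param model A `pn_maxent`.
#' @param predictors Named list of `pn_raster`s covering the model variables.
#' @param region A `pn_mask`: the prediction region.
#' @param mode,scale Passed to [predict.pn_maxent()].
#' @param provenance Optional named list echoed on the result.
#' @return A `pn_suitability`: list with `raster` (suitability `pn_raster`),
#'   `non_analogue` (logical matrix), `mode`, `scale`, `provenance`.
#' @export
suitability_map <- function(model, predictors, region,
                            mode = c("extrapolate", "clamp"),
                            scale = c("logistic", "raw"),
                            provenance = list()) {
  mode <- match.arg(mode); scale <- match.arg(scale)
  spec <- region$spec
  cells <- which(region$member, arr.ind = TRUE)
  X <- predictor_values(predictors, cells)
  s <- predict(model, X, mode = mode, scale = scale)
  na_flags <- mess_flags(model, X)
  v <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  v[cells] <- s
  fl <- matrix(FALSE, spec$n_rows, spec$n_cols)
  fl[cells] <- na_flags
  structure(list(raster = pn_raster(spec, v, units = "suitability"),
                 non_analogue = fl, mode = mode, scale = scale,
                 provenance = provenance),
            class = "pn_suitability")
}

# ---- evaluation ---------------------------------------------------------

#' Rank-based AUC
#'
#' The probability that a presence score exceeds a background score, with
#' ties counted half (equivalent to the Mann-Whitney statistic).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  r <- rank(c(presence_scores, background_scores))
  np <- length(presence_scores); nb <- length(background_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximum-TSS threshold
#'
#' Scans a threshold grid; at each t, sensitivity = fraction of presence
#' scores >= t, specificity = fraction of background scores < t,
#' TSS = sens + spec - 1. Ties return the smallest threshold.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @param grid Candidate thresholds (default 0, 0.01, ..., 1).
#' @return List with `threshold` and `tss`.
#' @export
tss_max <- function(presence_scores, background_scores,
                    grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  tss <- vapply(grid, function(t)
    mean(presence_scores >= t) + mean(background_scores < t) - 1, 0)
  i <- which.max(tss)  # which.max takes the first (smallest t) on ties
  list(threshold = grid[i], tss = tss[i])
}

model_gain <- function(model, presence, background) {
  eta_p <- as.vector(feature_matrix(
    as.data.frame(presence)[model$expansion$vars], model$expansion) %*% model$lambda)
  eta_b <- as.vector(feature_matrix(
    as.data.frame(background)[model$expansion$vars], model$expansion) %*% model$lambda)
  mean(eta_p) - logsumexp(eta_b) + log(length(eta_b))
}

#' Subsample evaluation with jackknife and permutation importance
#'
#' Runs `k` seeded random 75/25 presence splits: the model is fit on the
#' training share and test AUC computed against the full background.
#' Jackknife gains (with-only and without each variable) are computed on
#' the full presence set; percent contribution is the normalised drop in
#' training gain when each variable's values are permuted, averaged over
#' the k replicate fits and rescaled to 100.
#'
#' @param presence,background Predictor data frames (>= 8 presence rows).
#' @param k Number of replicates (default 50).
#' @param train_fraction Training share (default 0.75).
#' @param classes,reg_multiplier Passed to [fit_maxent()].
#' @param seed Integer seed; the report is bitwise reproducible.
#' @return A `pn_evaluation`: list with `auc` (per-replicate tibble),
#'   `auc_mean`, `auc_sd`, `jackknife` (tibble), `percent_contribution`
#'   (tibble), `k`, `train_fraction`, `seed`.
#' @export
evaluate_maxent <- function(presence, background, k = 50, train_fraction = 0.75,
                            classes = c("linear", "quadratic", "product"),
                            reg_multiplier = 1, seed = 1) {
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  m <- nrow(presence)
  stopifnot(m >= 8)
  vars <- names(background)
  set.seed(seed)
  n_train <- max(1, min(m - 1, round(train_fraction * m)))
  aucs <- numeric(k)
  contrib <- matrix(0, k, length(vars), dimnames = list(NULL, vars))
  for (r in seq_len(k)) {
    tr <- sample.int(m, n_train)
    fit <- suppressWarnings(fit_maxent(presence[tr, , drop = FALSE], background,
                                       classes = classes,
                                       reg_multiplier = reg_multiplier))
    sp <- predict(fit, presence[-tr, , drop = FALSE])
    sb <- predict(fit, background)
    aucs[r] <- auc(sp, sb)
    g0 <- model_gain(fit, presence[tr, , drop = FALSE], background)
    for (v in vars) {
      perm_p <- presence[tr, , drop = FALSE]
      perm_b <- background
      pool <- c(perm_p[[v]], perm_b[[v]])
      pool <- sample(pool)
      perm_p[[v]] <- pool[seq_len(nrow(perm_p))]
      perm_b[[v]] <- pool[-seq_len(nrow(perm_p))]
      gperm <- model_gain(fit, perm_p, perm_b)
      contrib[r, v] <- max(g0 - gperm, 0)
    }
  }
  cm <- colMeans(contrib)
  pct <- if (sum(cm) > 0) 100 * cm / sum(cm) else
    rep(100 / length(vars), length(vars))
  jack <- purrr::map_dfr(vars, function(v) {
    with_only <- suppressWarnings(fit_maxent(
      presence[, v, drop = FALSE], background[, v, drop = FALSE],
      classes = setdiff(classes, "product"), reg_multiplier = reg_multiplier))
    gain_with_only <- model_gain(with_only, presence[, v, drop = FALSE],
                                 background[, v, drop = FALSE])
    gain_without <- if (length(vars) > 1) {
      rest <- setdiff(vars, v)
      fit_wo <- suppressWarnings(fit_maxent(
        presence[, rest, drop = FALSE], background[, rest, drop = FALSE],
        classes = classes, reg_multiplier = reg_multiplier))
      model_gain(fit_wo, presence[, rest, drop = FALSE],
                 background[, rest, drop = FALSE])
    } else NA_real_
    tibble::tibble(variable = v, gain_with_only = gain_with_only,
                   gain_without = gain_without)
  })
  structure(list(
    auc = tibble::tibble(replicate = seq_len(k), auc = aucs),
    auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
    jackknife = jack,
    percent_contribution = tibble::tibble(variable = vars,
                                          percent = unname(pct)),
    k = k, train_fraction = train_fraction, seed = seed),
    class = "pn_evaluation")
}

#' @export
print.pn_evaluation <- function(x, ...) {
  cat(sprintf("<pn_evaluation> %d-fold subsample (train %.0f%%), seed %d\n  mean AUC %.4f (SD %.4f)\n",
              x$k, 100 * x$train_fraction, x$seed, x$auc_mean, x$auc_sd))
  invisible(x)
}

#' @rdname tidy.pn_maxent
#' @export
tidy.pn_evaluation <- function(x, ...) {
  dplyr::left_join(x$percent_contribution, x$jackknife, by = "variable")
}

#' @rdname tidy.pn_maxent
#' @export
glance.pn_evaluation <- function(x, ...) {
  tibble::tibble(k = x$k, train_fraction = x$train_fraction,
                 auc_mean = x$auc_mean, auc_sd = x$auc_sd, seed = x$seed)
}

# ---- binary habitat maps ------------------------------------------------

#' Binarise a suitability map and quantify habitat area
#'
#' Member cells are region cells with suitability >= `threshold`; the area
#' is the sum of spherical cell areas over members.
#'
#' @param smap A `pn_suitability`.
#' @param threshold Suitability threshold in (0, 1); the conventional set is
#'   0.2 / 0.45 / 0.7.
#' @param region A `pn_mask` on the same grid.
#' @return A `pn_binary_habitat`: list with `member` (logical matrix),
#'   `threshold`, `area_km2`, `region_name`, `spec`.
#' @export
binarize_and_area <- function(smap, threshold, region) {
  stopifnot(inherits(smap, "pn_suitability"), threshold > 0, threshold < 1)
  if (!same_spec(smap$raster$spec, region$spec)) stop("grid mismatch")
  member <- !is.na(smap$raster$values) & smap$raster$values >= threshold &
    region$member
  areas <- cell_areas_km2(region$spec)$values
  structure(list(member = member, threshold = threshold,
                 area_km2 = sum(areas[member]), region_name = region$name,
                 spec = region$spec),
            class = "pn_binary_habitat")
}

#' Consensus check between two binary habitat maps
#'
#' Deviation = fraction of region cells where the two binary maps differ;
#' the pair passes when deviation <= `max_deviation` (the conventional 15%
#' rule used to discard incoherent forward/backward projection pairs).
#'
#' @param map_a,map_b `pn_binary_habitat` maps on the same grid/threshold.
#' @param region A `pn_mask` (the comparison region).
#' @param max_deviation Maximum tolerated deviation fraction (default 0.15).
#' @return List with `deviation` and `pass`.
#' @export
consensus_check <- function(map_a, map_b, region, max_deviation = 0.15) {
  if (!same_spec(map_a$spec, map_b$spec) || !same_spec(map_a$spec, region$spec))
    stop("region mismatch")
  if (map_a$threshold != map_b$threshold) stop("threshold mismatch")
  idx <- region$member
  dev <- sum(map_a$member[idx] != map_b$member[idx]) / sum(idx)
  list(deviation = dev, pass = dev <= max_deviation)
}
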