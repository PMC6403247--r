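test_that("no presence-background contrast shrinks all coefficients to zero", {
  set.seed(51)
  bg <- data.frame(x = rnorm(200), y = rnorm(200))
  # presence == background makes every feature mean match exactly
  m <- fit_maxent(bg, bg)
  expect_true(all(m$lambda == 0))
  s <- predict(m, bg)
  expect_equal(stats::sd(s), 0)
})

test_that("one-variable fit matches a brute-force grid search of the objective", {
  bg <- data.frame(x = seq(0, 1, length.out = 10))
  pr <- data.frame(x = c(0.8, 0.82, 0.85, 0.9, 1.0))
  m <- fit_maxent(pr, bg, classes = "linear")
  expect_gt(m$lambda[1], 0)
  # independent objective evaluation over a 1-D grid
  zb <- (bg$x - m$expansion$var_mu) / m$expansion$var_sd
  zp <- (pr$x - m$expansion$var_mu) / m$expansion$var_sd
  fb <- (zb - m$expansion$mu) / m$expansion$sd
  fp <- (zp - m$expansion$mu) / m$expansion$sd
  beta <- 1 / sqrt(5)
  obj <- function(l) mean(fp * l) - log(sum(exp(fb * l))) - beta * abs(l)
  grid <- seq(-10, 10, by = 1e-3)
  best <- max(vapply(grid, obj, 0))
  expect_equal(m$objective, best, tolerance = 1e-3)
  expect_true(m$converged)
})

test_that("uniform duplication of the background leaves the fit unchanged", {
  set.seed(52)
  bg <- data.frame(x = rnorm(60), y = rnorm(60))
  pr <- bg[bg$x > 0.5, ][1:6, ]
  m1 <- fit_maxent(pr, bg)
  m2 <- fit_maxent(pr, rbind(bg, bg))
  expect_equal(m1$lambda, m2$lambda, tolerance = 1e-5)
})

test_that("the optimiser's objective trace is non-decreasing (convexity check)", {
  set.seed(53)
  bg <- data.frame(a = rnorm(150), b = runif(150), c = rnorm(150, 5, 2))
  pr <- bg[order(bg$a, decreasing = TRUE)[1:15], ]
  m <- fit_maxent(pr, bg)
  expect_true(all(diff(m$objective_trace) >= -1e-10))
})

test_that("prediction scales behave: raw sums to one, clamping is identity in range", {
  set.seed(54)
  bg <- data.frame(x = rnorm(100), y = rnorm(100))
  pr <- bg[bg$x + bg$y > 1, ][1:8, ]
  m <- fit_maxent(pr, bg)
  expect_equal(sum(predict(m, bg, scale = "raw")), 1, tolerance = 1e-9)
  # all background values are inside the training range by construction
  expect_equal(predict(m, bg, mode = "clamp"), predict(m, bg))
  # out-of-range cells differ between modes when coefficients are non-zero
  far <- data.frame(x = c(10, -10), y = c(10, -10))
  if (any(m$lambda != 0))
    expect_false(isTRUE(all.equal(predict(m, far, mode = "clamp"),
                                  predict(m, far))))
  expect_error(predict(m, data.frame(x = 1)), "lacks")
})

test_that("logistic suitability is invariant to affine rescaling of inputs", {
  set.seed(55)
  bg <- data.frame(x = rnorm(120), y = runif(120))
  pr <- bg[order(bg$y)[1:10], ]
  m1 <- fit_maxent(pr, bg)
  resc <- function(df) data.frame(x = 100 * df$x - 7, y = df$y / 50 + 3)
  m2 <- fit_maxent(resc(pr), resc(bg))
  expect_equal(predict(m1, bg), predict(m2, resc(bg)), tolerance = 1e-6)
})

test_that("single-variable suitability is monotone with the coefficient sign", {
  bg <- data.frame(x = seq(-2, 2, length.out = 50))
  pr <- data.frame(x = c(1.2, 1.4, 1.5, 1.8, 2.0))
  m <- fit_maxent(pr, bg, classes = "linear")
  s <- predict(m, bg)
  expect_gt(m$lambda[1], 0)
  expect_true(all(diff(s) > 0))
})

test_that("non-analogue flags equal the brute-force range check", {
  set.seed(56)
  bg <- data.frame(x = rnorm(80), y = rnorm(80))
  pr <- bg[1:10, ]
  m <- fit_maxent(pr, bg)
  expect_false(any(mess_flags(m, bg)))
  proj <- data.frame(x = rnorm(300, 0, 3), y = rnorm(300, 0, 3))
  flags <- mess_flags(m, proj)
  brute <- (proj$x < min(bg$x) | proj$x > max(bg$x) |
              proj$y < min(bg$y) | proj$y > max(bg$y))
  expect_identical(flags, brute)
  one_out <- bg; one_out$x[17] <- max(bg$x) + 1
  expect_identical(which(mess_flags(m, one_out)), 17L)
})

test_that("AUC is the exact pairwise rank probability", {
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc(c(5, 6), c(1, 2)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # random scores against brute-force pair counting
  set.seed(57)
  p <- runif(23); b <- runif(31)
  brute <- mean(outer(p, b, function(x, y) (x > y) + 0.5 * (x == y)))
  expect_equal(auc(p, b), brute, tolerance = 1e-12)
})

test_that("max-TSS threshold selection enumerates the grid with ties to the smallest", {
  sep <- tss_max(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$tss, 1)
  expect_equal(sep$threshold, 0.21)
  same <- tss_max(runif(50, 0, 1), runif(50, 0, 1))
  expect_lt(abs(same$tss), 0.35)
  ex <- tss_max(c(0.8, 0.6), c(0.5, 0.4, 0.1))
  expect_equal(ex$threshold, 0.51)
  expect_equal(ex$tss, 1)
})

test_that("subsample evaluation separates a deterministic niche and is reproducible", {
  # deterministic 1-variable niche, no noise: presences are the top-ranked
  # background cells, so AUC approaches its ceiling (1 - mean presence rank
  # deficit; ~0.978 for the top 10 of 200)
  bg <- data.frame(x = seq(0, 1, length.out = 200))
  pr <- data.frame(x = bg$x[191:200])
  ev <- evaluate_maxent(pr, bg, k = 10, seed = 3)
  expect_gte(ev$auc_mean, 0.97)
  ev2 <- evaluate_maxent(pr, bg, k = 10, seed = 3)
  expect_identical(ev$auc, ev2$auc)
  expect_identical(ev$percent_contribution, ev2$percent_contribution)
  expect_equal(sum(ev$percent_contribution$percent), 100, tolerance = 1e-6)
  expect_true(all(ev$percent_contribution$percent >= 0))
  expect_equal(nrow(ev$auc), 10)
})

test_that("evaluation under the null hovers at chance", {
  set.seed(58)
  bg <- data.frame(x = rnorm(150), y = rnorm(150))
  pr <- bg[sample(150, 50), ]
  ev <- evaluate_maxent(pr, bg, k = 50, seed = 4)
  expect_equal(ev$auc_mean, 0.5, tolerance = 0.1)
})

test_that("binary habitat areas are exact sums and monotone in threshold", {
  st <- demo_stage()
  preds <- st$predictors[st$retained]
  occs <- dedupe_per_cell(sample_occurrences(
    st$species, NULL, st$outcrop, sampling_config(n_target = 40, seed = 61)),
    st$land$spec)
  cells <- unique(cell_index(occs$palaeo_lon, occs$palaeo_lat, st$land$spec))
  m <- fit_maxent(predictor_values(preds, cells),
                  predictor_values(preds, which(st$outcrop$member,
                                                arr.ind = TRUE)))
  smap <- suitability_map(m, preds, st$continent)
  areas <- vapply(c(0.2, 0.45, 0.7), function(th)
    binarize_and_area(smap, th, st$continent)$area_km2, 0)
  expect_true(all(diff(areas) <= 0))
  # brute-force area oracle
  bh <- binarize_and_area(smap, 0.45, st$continent)
  brute <- 0
  areas_r <- cell_areas_km2(st$land$spec)$values
  for (i in seq_len(st$land$spec$n_rows)) for (j in seq_len(st$land$spec$n_cols))
    if (st$continent$member[i, j] && !is.na(smap$raster$values[i, j]) &&
        smap$raster$values[i, j] >= 0.45) brute <- brute + areas_r[i, j]
  expect_equal(bh$area_km2, brute, tolerance = 1e-12)
  # outcrop region area never exceeds the continental one
  smap_o <- suitability_map(m, preds, st$outcrop)
  expect_lte(binarize_and_area(smap_o, 0.45, st$outcrop)$area_km2,
             bh$area_km2)
})

test_that("consensus deviation counts differing cells over the region", {
  s <- grid_spec(0, 0, 1, 1, 10, 10)
  region <- region_mask(s, TRUE)
  mk <- function(member) structure(
    list(member = member, threshold = 0.45, area_km2 = 0,
         region_name = "custom", spec = s), class = "pn_binary_habitat")
  a <- mk(matrix(TRUE, 10, 10))
  expect_equal(consensus_check(a, a, region)$deviation, 0)
  expect_true(consensus_check(a, a, region)$pass)
  b <- mk(matrix(FALSE, 10, 10))
  expect_equal(consensus_check(a, b, region)$deviation, 1)
  d <- mk({ m <- matrix(TRUE, 10, 10); m[1:12] <- FALSE; m })
  chk <- consensus_check(a, d, region)
  expect_equal(chk$deviation, 0.12)
  expect_true(chk$pass)
})

test_that("tidy and glance methods expose the fit as tibbles", {
  set.seed(59)
  bg <- data.frame(x = rnorm(60), y = rnorm(60))
  pr <- bg[order(bg$x)[1:8], ]
  m <- fit_maxent(pr, bg)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("feature", "class", "estimate", "penalty"))
  expect_equal(nrow(td), length(m$lambda))
  gl <- glance(m)
  expect_equal(gl$m_presence, 8)
  expect_true(gl$converged)
})
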