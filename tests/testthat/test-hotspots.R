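test_that("kernel density conserves mass and is linear in points", {
  spec <- grid_spec(0, 0, 0.1, 0.1, 60, 60)
  areas <- cell_areas_km2(spec)$values
  empty <- kernel_density(numeric(0), numeric(0), spec, 50)
  expect_true(all(empty$values == 0))

  one <- kernel_density(3, 3, spec, 60)
  idx <- which(one$values == max(one$values), arr.ind = TRUE)
  centre <- cell_index(3, 3, spec)
  expect_lte(max(abs(idx[1, ] - centre[1, ])), 1)
  expect_equal(sum(one$values * areas), 1, tolerance = 0.02)

  two <- kernel_density(c(3, 3), c(3, 3), spec, 60)
  expect_equal(two$values, 2 * one$values)

  set.seed(81)
  n <- 25
  lon <- runif(n, 1.5, 4.5); lat <- runif(n, 1.5, 4.5)
  surf <- kernel_density(lon, lat, spec, 45)
  expect_equal(sum(surf$values * areas), n, tolerance = 0.02)
})

test_that("Gi* matches a hand evaluation on a 5x5 grid and degrades gracefully", {
  spec <- grid_spec(0, 40, 0.1, 0.1, 5, 5)
  mask <- region_mask(spec, TRUE)
  # constant field: zero variance convention
  flat <- gi_star(pn_raster(spec, 4), mask, radius_km = 12)
  expect_true(all(flat$z$values == 0))
  expect_true(all(flat$class == 2L))

  # single spike at the centre, radius = one cell size
  v <- matrix(0, 5, 5); v[3, 3] <- 10
  counts <- pn_raster(spec, v)
  cell_km <- 0.1 * 111.19
  spots <- gi_star(counts, mask, radius_km = cell_km * 1.05)
  # independent direct evaluation of the formula
  cells <- which(mask$member, arr.ind = TRUE)
  lonc <- lon_centers(spec)[cells[, "col"]]
  latc <- lat_centers(spec)[cells[, "row"]]
  d <- geosphere::distm(cbind(lonc, latc),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000) / 1000)
  x <- v[cells]; n <- length(x)
  xbar <- mean(x); s <- sqrt(mean(x^2) - xbar^2)
  for (i in c(1, 7, 13, 25)) {
    w <- d[i, ] <= cell_km * 1.05
    Wi <- sum(w)
    zi <- (sum(x[w]) - xbar * Wi) / (s * sqrt((n * Wi - Wi^2) / (n - 1)))
    expect_equal(spots$z$values[cells[i, 1], cells[i, 2]], zi,
                 tolerance = 1e-9)
  }
  # the spike's neighbourhood is hot-signed, far corners negative
  expect_gt(spots$z$values[3, 3], 0)
  expect_lt(spots$z$values[1, 1], 0)
  expect_error(gi_star(counts, region_mask(spec, {
    m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m }), 10), "masked cells")
})

test_that("contingency tables count occurrences by spot and facies class", {
  spec <- grid_spec(0, 0, 1, 1, 6, 6)
  # facies: west half high (2), east half low (1)
  fac_cls <- matrix(1L, 6, 6); fac_cls[, 1:3] <- 2L
  facies <- structure(list(class = fac_cls, break_value = 1,
                           parameter = "sediment_flux", units = "", spec = spec),
                      class = "pn_taphofacies")
  # spots: north hot (3), south cold (1), middle rows neither (2)
  spot_cls <- matrix(2L, 6, 6); spot_cls[5:6, ] <- 3L; spot_cls[1:2, ] <- 1L
  spots <- structure(list(class = spot_cls,
                          mask = region_mask(spec, TRUE)), class = "pn_spots")
  set.seed(82)
  occs <- random_occurrences(300, spec, seed = 82)
  tab <- build_contingency(occs, spots, facies)
  idx <- cell_index(occs$palaeo_lon, occs$palaeo_lat, spec)
  sc <- spot_cls[idx]; fc <- fac_cls[idx]
  expect_equal(tab$a, sum(sc == 3 & fc == 2))
  expect_equal(tab$b, sum(sc == 1 & fc == 2))
  expect_equal(tab$c, sum(sc == 3 & fc == 1))
  expect_equal(tab$d, sum(sc == 1 & fc == 1))
  expect_equal(tab$a + tab$b + tab$c + tab$d, sum(sc != 2))

  all_hot <- occs[spot_cls[idx] == 3 & fac_cls[idx] == 2, ]
  t2 <- build_contingency(all_hot, spots, facies)
  expect_equal(unlist(t2[c("b", "c", "d")]), c(b = 0, c = 0, d = 0))
  t0 <- build_contingency(occs[0, ], spots, facies)
  expect_equal(t0$a + t0$b + t0$c + t0$d, 0)
})

test_that("chi-squared matches the observed-vs-expected oracle and base R", {
  set.seed(83)
  for (i in 1:25) {
    t <- table2x2(sample(1:80, 1), sample(1:80, 1), sample(1:80, 1),
                  sample(1:80, 1))
    m <- matrix(c(t$a, t$c, t$b, t$d), 2)
    # generic sum (O-E)^2/E oracle
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(chi_squared_2x2(t)$statistic, sum((m - E)^2 / E),
                 tolerance = 1e-9)
    expect_equal(chi_squared_2x2(t)$statistic,
                 unname(suppressWarnings(
                   chisq.test(m, correct = FALSE)$statistic)))
    expect_equal(chi_squared_2x2(t, TRUE)$statistic,
                 unname(suppressWarnings(chisq.test(m)$statistic)),
                 tolerance = 1e-12)
    # Yates never exceeds the uncorrected statistic
    expect_lte(chi_squared_2x2(t, TRUE)$statistic,
               chi_squared_2x2(t)$statistic)
  }
  flat <- table2x2(10, 10, 10, 10)
  expect_equal(chi_squared_2x2(flat)$statistic, 0)
  expect_equal(chi_squared_2x2(flat)$p, 1)
  expect_error(chi_squared_2x2(table2x2(0, 0, 5, 5)), "degenerate")
})

test_that("Fisher's exact test enumerates the hypergeometric and is symmetric", {
  expect_equal(fisher_exact_2x2(table2x2(1, 1, 1, 1)), 1)
  set.seed(84)
  for (i in 1:20) {
    t <- table2x2(sample(0:30, 1), sample(1:30, 1), sample(1:30, 1),
                  sample(0:30, 1))
    m <- matrix(c(t$a, t$c, t$b, t$d), 2)
    expect_equal(fisher_exact_2x2(t), fisher.test(m)$p.value,
                 tolerance = 1e-9)
    # invariance to transposition and to swapping both labels
    expect_equal(fisher_exact_2x2(t),
                 fisher_exact_2x2(table2x2(t$a, t$c, t$b, t$d)))
    expect_equal(fisher_exact_2x2(t),
                 fisher_exact_2x2(table2x2(t$d, t$c, t$b, t$a)))
  }
})

test_that("the packaged contingency fixtures load and pool additively", {
  tabs <- published_contingency_tables()
  expect_equal(nrow(tabs), 6)
  for (param in c("sediment_flux", "surface_runoff")) {
    sub <- tabs[tabs$parameter == param, ]
    tot <- sub[sub$stage == "total", c("a", "b", "c", "d")]
    parts <- colSums(sub[sub$stage != "total", c("a", "b", "c", "d")])
    expect_equal(unlist(tot), parts)
  }
})
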