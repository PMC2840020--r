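test_that("HSI is the weighted geometric mean with zero propagation", {
  expect_equal(hsi(1, 1, 1), 1)
  expect_equal(hsi(0, 1, 1), 0)
  expect_equal(hsi(1, 0, 1), 0)
  expect_equal(hsi(1, 1, 0), 0)
  expect_equal(hsi(0.5, 0.75, 1), (0.25 * 0.5625)^(1 / 5))
  expect_equal(round(hsi(0.5, 0.75, 1), 4), 0.6755)
  expect_error(hsi(1.2, 1, 1), "\\[0, 1\\]")

  # monotone non-decreasing in each argument over a lattice, bounded by 1
  grid <- seq(0, 1, by = 0.25)
  vals <- array(hsi(rep(grid, times = 25),
                    rep(rep(grid, each = 5), times = 5),
                    rep(grid, each = 25)), c(5, 5, 5))
  expect_true(all(vals <= 1))
  expect_true(all(apply(vals, c(2, 3), diff) >= 0))
  expect_true(all(apply(vals, c(1, 3), diff) >= 0))
  expect_true(all(apply(vals, c(1, 2), diff) >= 0))
})

test_that("the HSI map equals the scalar index applied cell-wise", {
  g <- grid_spec(8, 8)
  M <- grid_raster(matrix(0.8, 8, 8), g)
  lc4 <- grid_raster(matrix(4, 8, 8), g)
  pop4 <- grid_raster(matrix(4, 8, 8), g)
  expect_equal(hsi_map(M, lc4, pop4)$values,
               matrix(0.8^(2 / 5), 8, 8))
  expect_equal(round(0.8^(2 / 5), 4), 0.9146)

  pop0 <- grid_raster(matrix(0, 8, 8), g)
  expect_true(all(hsi_map(M, lc4, pop0)$values == 0))

  set.seed(41)
  Mv <- matrix(runif(64), 8, 8)
  lcv <- matrix(sample(0:4, 64, TRUE), 8, 8)
  popv <- matrix(sample(0:4, 64, TRUE), 8, 8)
  out <- hsi_map(grid_raster(Mv, g), grid_raster(lcv, g), grid_raster(popv, g))
  expect_equal(out$values, hsi(Mv, lcv / 4, popv / 4))
})

test_that("habitat loss is the class 0-2 share inside the mask", {
  g <- grid_spec(6, 6)
  mask <- grid_raster(matrix(1, 6, 6), g)
  expect_equal(habitat_loss(grid_raster(matrix(3, 6, 6), g), mask), 0)
  expect_equal(habitat_loss(grid_raster(matrix(0, 6, 6), g), mask), 1)

  set.seed(42)
  cls <- matrix(sample(0:4, 36, TRUE), 6, 6)
  mv <- matrix(sample(0:1, 36, TRUE), 6, 6)
  mv[1, 1] <- 1
  loss <- habitat_loss(grid_raster(cls, g), grid_raster(mv, g))
  expect_equal(loss, sum(cls[mv == 1] <= 2) / sum(mv == 1))
  # loss and the class 3-4 share partition the mask exactly
  expect_equal(loss + sum(cls[mv == 1] >= 3) / sum(mv == 1), 1)
  expect_error(habitat_loss(grid_raster(cls, g),
                            grid_raster(matrix(0, 6, 6), g)), "empty")
})

test_that("potential habitat is the three-way conjunction", {
  g <- grid_spec(6, 6)
  all1 <- grid_raster(matrix(1, 6, 6), g)
  lc34 <- grid_raster(matrix(4, 6, 6), g)
  pop34 <- grid_raster(matrix(3, 6, 6), g)
  expect_equal(potential_habitat_mask(all1, lc34, pop34)$values, all1$values)
  pop2 <- grid_raster(matrix(2, 6, 6), g)
  expect_true(all(potential_habitat_mask(all1, lc34, pop2)$values == 0))

  set.seed(43)
  mv <- matrix(sample(0:1, 36, TRUE), 6, 6)
  lcv <- matrix(sample(0:4, 36, TRUE), 6, 6)
  popv <- matrix(sample(0:4, 36, TRUE), 6, 6)
  out <- potential_habitat_mask(grid_raster(mv, g), grid_raster(lcv, g),
                                grid_raster(popv, g))
  expect_equal(out$values, (mv == 1 & lcv >= 3 & popv >= 3) * 1)
})

test_that("protection proportion counts the overlap", {
  g <- grid_spec(6, 6)
  hab <- grid_raster(matrix(c(rep(1, 10), rep(0, 26)), 6, 6), g)
  sup <- grid_raster(matrix(1, 6, 6), g)
  expect_equal(protection_proportion(hab, sup), 1)
  disj <- grid_raster(matrix(c(rep(0, 10), rep(1, 26)), 6, 6), g)
  expect_equal(protection_proportion(hab, disj), 0)

  set.seed(44)
  hv <- matrix(sample(0:1, 36, TRUE), 6, 6); hv[2, 2] <- 1
  pv <- matrix(sample(0:1, 36, TRUE), 6, 6)
  expect_equal(protection_proportion(grid_raster(hv, g), grid_raster(pv, g)),
               sum(hv == 1 & pv == 1) / sum(hv == 1))
  expect_error(protection_proportion(grid_raster(hv * 0, g),
                                     grid_raster(pv, g)), "empty")
})

test_that("key localities are 8-connected patches sorted by area", {
  g <- grid_spec(12, 12)
  v <- matrix(0, 12, 12)
  v[4:8, 4:8] <- 1
  one <- key_localities(grid_raster(v, g), hsi_threshold = 0.5, min_area = 10)
  expect_equal(nrow(one), 1)
  expect_equal(one$area_km2, 25)
  expect_equal(one$mean_hsi, 1)

  # diagonal touch joins under 8-connectivity
  v2 <- matrix(0, 12, 12)
  v2[2:3, 2:3] <- 1
  v2[4:5, 4:5] <- 1
  expect_equal(nrow(key_localities(grid_raster(v2, g), 0.5)), 1)

  set.seed(45)
  for (rep in 1:5) {
    hv <- matrix(runif(144), 12, 12)
    got <- key_localities(grid_raster(hv, g), hsi_threshold = 0.6)
    lab <- flood_patches(hv >= 0.6)
    expect_equal(nrow(got), max(lab))
    expect_equal(sort(got$n_pixels), sort(unname(table(lab[lab > 0]))),
                 ignore_attr = TRUE)
  }

  # raising the threshold never increases total patch area
  hv <- matrix(runif(144), 12, 12)
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t) {
    sum(key_localities(grid_raster(hv, g), t)$area_km2)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("protection concentrates in marginal habitat on degraded landscapes", {
  # directional contrast: potential habitat (lowland, near water) is less
  # protected than forest at large, because reserves sit in the uplands
  wins <- 0L
  n_seeds <- 5L
  for (seed in seq_len(n_seeds)) {
    study <- simulate_study(landscape_config(seed = seed))
    ls <- study$landscape
    ens <- fit_ensemble(ls$stack, study$records, k = 3, n_background = 4000,
                        seed = seed + 100)
    scores <- swampcat:::ensemble_scores(
      ens, extract_at(ls$stack, study$records$x, study$records$y))
    mask <- suitable_mask(ens$mean_surface, omission_threshold(scores, 0.1))
    pop <- classify_population(ls$population)
    hab <- potential_habitat_mask(mask, study$landcover, pop)
    forest <- grid_raster((study$landcover$values >= 3) * 1,
                          study$landcover$grid)
    wins <- wins + (protection_proportion(hab, ls$protected) <
                      protection_proportion(forest, ls$protected))
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("historical buffers end up more degraded than recent ones", {
  study <- simulate_study(landscape_config(seed = 77))
  tab <- epoch_contingency(summarize_buffers(study$landcover, study$records))
  share_poor <- rowSums(tab$counts[, 1:3]) / rowSums(tab$counts)
  expect_gt(share_poor[["historical"]], share_poor[["recent"]])
})
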