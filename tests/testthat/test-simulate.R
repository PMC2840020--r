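small_config <- function(seed = 1, ...) {
  landscape_config(n_rows = 100, n_cols = 100, n_predictors = 6,
                   seed = seed, ...)
}

test_that("the generator is bit-reproducible from its seed", {
  a <- simulate_study(small_config(seed = 5))
  b <- simulate_study(small_config(seed = 5))
  expect_identical(a$landscape$stack$altitude$values,
                   b$landscape$stack$altitude$values)
  expect_identical(a$landscape$population$values, b$landscape$population$values)
  expect_identical(a$landcover$values, b$landcover$values)
  expect_identical(a$records, b$records)
})

test_that("generated layers respect their value domains", {
  ls <- generate_landscape(small_config(seed = 6))
  expect_true(all(ls$landcover$values %in% 0:4))
  expect_true(all(ls$population$values >= 0))
  expect_true(all(ls$protected$values %in% c(0, 1)))
  expect_true(all(ls$stack$dist_water$values >= 0))
  suit <- true_suitability(truth_model(), ls$stack)
  expect_true(all(suit$values >= 0 & suit$values <= 1))
})

test_that("each requested river leaves a zero-distance component", {
  ls <- generate_landscape(landscape_config(n_rows = 200, n_cols = 200,
                                            n_predictors = 3, n_rivers = 3,
                                            seed = 7))
  zero <- (ls$stack$dist_water$values == 0) * 1
  patches <- key_localities(grid_raster(zero, ls$stack[[1]]$grid),
                            hsi_threshold = 1)
  expect_gte(nrow(patches), 3)
})

test_that("occurrence sampling hits the requested counts and separation", {
  study <- simulate_study(landscape_config(seed = 8))
  expect_equal(nrow(study$records), 88)
  expect_equal(sum(study$records$epoch == "historical"), 29)
  expect_equal(sum(study$records$epoch == "recent"), 59)
  expect_gte(min(dist(cbind(study$records$x, study$records$y))), 1)
})

test_that("records track suitability: uniform truth gives uniform density", {
  ls <- generate_landscape(small_config(seed = 9))
  flat <- truth_model(intercept = 0, b_dist_water = -1e-9, b_precip = 0,
                      b_altitude = 0, noise = 0)
  rec <- sample_occurrences(ls, flat, n_historical = 60, n_recent = 140,
                            min_distance = 0, seed = 10)
  dtw <- extract_at(ls$stack, rec$x, rec$y)[, "dist_water"]
  qs <- stats::quantile(ls$stack$dist_water$values, c(0.25, 0.5, 0.75))
  obs <- table(cut(dtw, c(-Inf, qs, Inf)))
  gof <- stats::chisq.test(obs, p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.01)
})

test_that("greedy thinning keeps first-come records at the set separation", {
  two <- tibble::tibble(record_id = c("a", "b"), x = c(0, 0.3), y = c(0, 0.4),
                        epoch = "recent")
  thinned <- thin_records(two, 1)
  expect_equal(thinned$record_id, "a")
  expect_equal(nrow(thin_records(two, 0)), 2)

  # 107 candidates with 19 planted near-duplicates of kept sites -> 88 kept
  set.seed(11)
  sites <- expand.grid(x = seq(0, 27, 3), y = seq(0, 24, 3))[1:88, ]
  base <- tibble::tibble(record_id = sprintf("k%02d", 1:88),
                         x = sites$x, y = sites$y, epoch = "recent")
  dups <- base[sample(88, 19), ]
  dups$record_id <- sprintf("d%02d", 1:19)
  dups$x <- dups$x + runif(19, -0.3, 0.3)
  dups$y <- dups$y + runif(19, -0.3, 0.3)
  candidates <- dplyr::bind_rows(base, dups)[sample(107), ]
  expect_equal(nrow(candidates), 107)
  expect_equal(nrow(thin_records(candidates, 1)), 88)
})

test_that("degradation converts good classes only inside record buffers", {
  study <- simulate_study(small_config(seed = 12, degradation_strength = 0))
  ls <- study$landscape
  expect_identical(study$landcover$values, ls$landcover$values)

  forced <- degrade_landcover(ls$landcover, study$records, strength = 1,
                              seed = 13)
  g <- ls$stack[[1]]$grid
  hist_rec <- study$records[study$records$epoch == "historical", ]
  for (i in seq_len(nrow(hist_rec))) {
    px <- buffer_pixels(g, hist_rec$x[i], hist_rec$y[i])
    expect_true(all(forced$values[px] <= 2))
  }
  # untouched outside all buffers
  all_px <- do.call(rbind, lapply(seq_len(nrow(study$records)), function(i) {
    buffer_pixels(g, study$records$x[i], study$records$y[i])
  }))
  inside <- matrix(FALSE, g$n_rows, g$n_cols)
  inside[all_px] <- TRUE
  expect_identical(forced$values[!inside], ls$landcover$values[!inside])
})

test_that("default degradation yields a detectable epoch contrast", {
  # reduced-seed version of the generator's power property
  hits <- 0L
  n_seeds <- 12L
  for (seed in seq_len(n_seeds)) {
    study <- simulate_study(landscape_config(seed = 100 + seed))
    tab <- epoch_contingency(summarize_buffers(study$landcover, study$records))
    p <- adjusted_g_tests(tab, kinds = "order")$p
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("an impossible sampling request fails loudly", {
  ls <- generate_landscape(landscape_config(n_rows = 12, n_cols = 12,
                                            n_predictors = 3, n_rivers = 1,
                                            seed = 14))
  expect_error(
    sample_occurrences(ls, truth_model(), n_historical = 200, n_recent = 400,
                       seed = 15, max_proposals_per_record = 20),
    "hostile")
})
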