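test_that("features are background min-max scaled and lie in [0, 1]", {
  set.seed(51)
  bg <- cbind(p1 = runif(200, 10, 30), p2 = rnorm(200), p3 = rep(7, 200))
  expect_warning(ft <- build_features(bg, types = c("linear", "quadratic")),
                 "constant")
  expect_equal(ft$predictors, c("p1", "p2"))
  Fm <- feature_matrix(ft, cbind(p1 = 20, p2 = 0, p3 = 7))
  # background range [10, 30]: value 20 scales to 0.5, quadratic to 0.25
  expect_equal(unname(Fm[1, "p1:lin"]),
               (20 - min(bg[, "p1"])) / diff(range(bg[, "p1"])))
  expect_equal(unname(Fm[1, "p1:sq"]), unname(Fm[1, "p1:lin"])^2)

  full <- build_features(bg[, 1:2], types = c("linear", "quadratic", "hinge"))
  Fb <- feature_matrix(full, bg[, 1:2])
  expect_true(all(Fb >= 0 & Fb <= 1))
  expect_equal(ncol(Fb), 2 * (2 + 8))
  expect_error(suppressWarnings(build_features(cbind(k = rep(1, 10)),
                                               types = "linear")),
               "constant")
})

test_that("auto feature types follow the training sample size", {
  set.seed(52)
  bg <- cbind(a = runif(50), b = runif(50))
  small <- build_features(bg, types = "auto", n_presences = 10)
  expect_setequal(small$types, c("linear", "quadratic"))
  big <- build_features(bg, types = "auto", n_presences = 20)
  expect_true("hinge" %in% big$types)
})

test_that("a no-signal fit shrinks weights and predicts about one half", {
  set.seed(53)
  bg <- cbind(a = runif(2000), b = rnorm(2000))
  # exactly identical distributions: the gradient vanishes at zero weights
  fit0 <- fit_maxent(bg, bg, types = c("linear", "quadratic"))
  expect_true(all(fit0$lambda == 0))
  expect_equal(unname(range(predict(fit0, bg))), c(0.5, 0.5))
  # a large presence subsample: weights shrink, predictions stay near 0.5
  pres <- bg[sample(2000, 500), ]
  fit <- fit_maxent(pres, bg, types = c("linear", "quadratic"))
  preds <- predict(fit, bg)
  expect_true(all(abs(preds - 0.5) < 0.05))
  expect_lt(mean(abs(fit$lambda)), 0.5)
})

test_that("a separating feature earns a positive weight and tops the ranking", {
  set.seed(54)
  n <- 25
  g <- grid_spec(n, n)
  block <- matrix(0, n, n); block[5:12, 5:12] <- 1
  stack <- predictor_stack(
    sig = grid_raster(block, g),
    noise = grid_raster(matrix(rnorm(n * n), n, n), g)
  )
  inside <- which(block == 1)
  cells <- sample(inside, 20)
  rec <- tibble::tibble(
    record_id = as.character(seq_along(cells)),
    x = ((cells - 1) %/% n) + 0.5,
    y = n - ((cells - 1) %% n) - 0.5,
    epoch = factor(rep("recent", 20), levels = c("historical", "recent")))
  ens <- fit_ensemble(stack, rec, k = 1, test_fraction = 0,
                      n_background = 400, types = "linear", seed = 55)
  expect_gt(ens$models[[1]]$lambda[["sig:lin"]], 0)
  vc <- variable_contribution(ens, seed = 56)
  expect_equal(vc$predictor[1], "sig")
  expect_gt(vc$contribution[1], 50)
  # single-predictor-driven model: contributions sum to 100
  expect_equal(sum(vc$contribution), 100)
})

test_that("the penalized objective trace is monotone non-decreasing", {
  set.seed(57)
  bg <- cbind(a = runif(1500), b = rnorm(1500), c = runif(1500, -2, 2))
  pres <- cbind(a = runif(40, 0.5, 1), b = rnorm(40, 1), c = runif(40, 0, 1))
  fit <- fit_maxent(pres, bg, types = c("linear", "quadratic", "hinge"))
  expect_true(all(diff(fit$objective) >= 0))
  # raw probabilities over the background sum to one
  Fb <- feature_matrix(fit$features, bg)
  q <- exp(as.vector(Fb %*% fit$lambda) - fit$logZ)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  # entropy is that of the fitted raw distribution
  expect_equal(fit$entropy, -sum(q * log(q)), tolerance = 1e-9)
})

test_that("stronger regularization never activates more features", {
  set.seed(58)
  bg <- cbind(a = runif(800), b = rnorm(800), c = runif(800))
  pres <- cbind(a = runif(30, 0.6, 1), b = rnorm(30, 0.8), c = runif(30))
  active <- vapply(c(0.5, 1, 2, 4, 8), function(m) {
    sum(fit_maxent(pres, bg, types = c("linear", "quadratic"),
                   multiplier = m)$lambda != 0)
  }, numeric(1))
  expect_true(all(diff(active) <= 0))
})

test_that("AUC is exact pair counting and monotone-transform invariant", {
  expect_equal(compute_auc(rep(0.9, 4), rep(0.1, 6)), 1)
  expect_equal(compute_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)

  set.seed(59)
  pos <- runif(20); neg <- runif(30)
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(compute_auc(pos, neg), mean(pairs))
  expect_equal(compute_auc(exp(5 * pos), exp(5 * neg)), compute_auc(pos, neg))
  expect_equal(compute_auc(rank(c(pos, neg))[1:20] * 2 + 3,
                           rank(c(pos, neg))[21:50] * 2 + 3),
               compute_auc(pos, neg))
})

test_that("omission thresholds bound the strictly-omitted fraction", {
  scores <- seq(0.1, 1, by = 0.1)
  expect_equal(omission_threshold(scores, 0), 0.1)
  expect_equal(omission_threshold(scores, 0.1), 0.2)
  expect_equal(omission_threshold(scores, 0.4), 0.5)

  set.seed(60)
  for (rep in 1:50) {
    s <- runif(sample(3:60, 1))
    for (om in c(0, 0.05, 0.1, 0.25, 0.4, 0.7, 0.99)) {
      t <- omission_threshold(s, om)
      expect_lte(mean(s < t), om)
    }
  }
})

test_that("environmental distance matches a brute-force nearest-presence scan", {
  stack <- toy_stack(5, seed = 61)
  rec <- tibble::tibble(record_id = c("a", "b"), x = c(1.5, 3.5),
                        y = c(1.5, 4.5),
                        epoch = factor(c("recent", "recent"),
                                       levels = c("historical", "recent")))
  ed <- env_distance(stack, rec)
  X <- swampcat:::stack_matrix(stack)
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  pres <- extract_at(stack, rec$x, rec$y)
  Pz <- sweep(sweep(pres, 2, mu), 2, sdv, "/")
  d <- apply(Z, 1, function(z) {
    sqrt(min(colSums((t(Pz) - z)^2)))
  })
  expect_equal(as.vector(ed$values), 1 - d / max(d))
  # a presence cell scores exactly one; the farthest cell exactly zero
  pcell <- xy_to_cell(stack[[1]]$grid, rec$x[1], rec$y[1])
  expect_equal(ed$values[pcell], 1)
  expect_equal(min(ed$values), 0)
})

test_that("surface correlation hits the exact limits", {
  set.seed(62)
  g <- grid_spec(10, 10)
  a <- grid_raster(matrix(runif(100), 10, 10), g)
  b <- grid_raster(1 - a$values, g)
  expect_equal(surface_correlation(a, a, seed = 1), 1)
  expect_equal(surface_correlation(a, b, seed = 1), -1)
  flat <- grid_raster(matrix(1, 10, 10), g)
  expect_error(surface_correlation(a, flat, seed = 1), "variance")
})
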