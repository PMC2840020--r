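#' Configuration for the synthetic landscape generator
#'
#' The generator emulates the input bundle of the real analysis — a stack of
#' smooth climate-like predictors plus altitude and distance to water, a
#' land-cover map in classes 0-4, a human-population-density surface,
#' a protected-area mask and a river network — with the statistical
#' structure the pipeline assumes: suitability dominated by distance to
#' water, land-cover quality rising with suitability, protection biased
#' toward high (marginal) altitude, and land-cover degradation concentrated
#' around historical records.
#'
#' @param n_rows,n_cols Grid size (default 200 x 200).
#' @param resolution Pixel size in km (default 1).
#' @param n_predictors Total predictors including `altitude`,
#'   `precip_driest` and `dist_water` (default 21; minimum 3).
#' @param n_rivers Rivers to carve (default 4).
#' @param seed Integer seed; every generator draw derives from it.
#' @param degradation_strength Probability in `[0, 1]` that a good-habitat
#'   cell inside a historical-record buffer is converted to classes 0-2
#'   (default 0.6); recent-record buffers degrade at a quarter of it.
#' @param population_hotspots Population centres (default 5).
#' @param protected_fraction Fraction of cells protected (default 0.23,
#'   matching the forest-wide protection level the analysis compares
#'   against).
#' @param smoothness Gaussian smoothing radius of the random fields, in
#'   pixels (default 8).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 200, n_cols = 200, resolution = 1,
                             n_predictors = 21, n_rivers = 4, seed = 1,
                             degradation_strength = 0.6,
                             population_hotspots = 5,
                             protected_fraction = 0.23, smoothness = 8) {
  stopifnot(n_predictors >= 3,
            degradation_strength >= 0, degradation_strength <= 1,
            protected_fraction > 0, protected_fraction < 1)
  structure(as.list(environment()), class = "landscape_config")
}

# mean-zero, unit-sd Gaussian random field via separable kernel smoothing
smooth_field <- function(n_rows, n_cols, sigma) {
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  z <- band(n_rows) %*% matrix(stats::rnorm(n_rows * n_cols), n_rows) %*%
    t(band(n_cols))
  (z - mean(z)) / stats::sd(z)
}

carve_rivers <- function(altitude, n_rivers, max_steps) {
  nr <- nrow(altitude); nc <- ncol(altitude)
  wet <- matrix(FALSE, nr, nc)
  starts <- which(altitude >= stats::quantile(altitude, 0.9))
  if (length(starts) < n_rivers) {
    stop("grid too small to place the requested rivers", call. = FALSE)
  }
  starts <- sample(starts, n_rivers)
  for (s in starts) {
    r <- ((s - 1L) %% nr) + 1L
    c <- ((s - 1L) %/% nr) + 1L
    for (step in seq_len(max_steps)) {
      wet[r, c] <- TRUE
      nb <- expand.grid(dr = -1:1, dc = -1:1)
      nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
      rr <- r + nb$dr; cc <- c + nb$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      if (!any(ok)) break
      rr <- rr[ok]; cc <- cc[ok]
      # descend with a little roughness so channels meander
      h <- altitude[cbind(rr, cc)] + stats::rnorm(length(rr), 0, 2)
      pick <- which.min(h)
      r2 <- rr[pick]; c2 <- cc[pick]
      at_edge <- r2 == 1 || r2 == nr || c2 == 1 || c2 == nc
      r <- r2; c <- c2
      wet[r, c] <- TRUE
      if (at_edge) break
    }
  }
  wet
}

#' Generate a synthetic landscape
#'
#' Altitude comes from a smoothed random field; the climate-like layers are
#' random fields partially correlated with altitude (the driest-month
#' precipitation layer mildly anti-correlated); rivers are descending noisy
#' walks from high-altitude cells; distance to water is the exact Euclidean
#' transform of the river mask; land-cover classes are drawn per cell with
#' the good classes (3, 4) increasingly likely at high true suitability;
#' population density is log-normal decay around hotspots; the protected
#' mask covers the configured fraction of cells, biased toward high
#' altitude. All draws derive from `config$seed`, so repeated calls are
#' bit-identical.
#'
#' @param config A [landscape_config()].
#' @param truth A [truth_model()] used to tilt the land-cover draw.
#' @return A list of class `sdm_landscape` with elements `stack`
#'   ([predictor_stack()]), `landcover`, `population`, `protected`
#'   ([grid_raster()]s), `water` ([water_mask()]) and `config`.
#' @export
generate_landscape <- function(config = landscape_config(),
                               truth = truth_model()) {
  set.seed(config$seed)
  g <- grid_spec(config$n_rows, config$n_cols, config$resolution)
  z_alt <- smooth_field(g$n_rows, g$n_cols, config$smoothness)
  altitude <- 250 * exp(0.9 * z_alt)  # metres; lognormal-shaped relief

  wet <- carve_rivers(altitude, config$n_rivers,
                      max_steps = 4L * max(g$n_rows, g$n_cols))
  water <- water_mask(g, wet)
  dist_water <- distance_to_water(water)

  z_precip <- -0.45 * z_alt + sqrt(1 - 0.45^2) *
    smooth_field(g$n_rows, g$n_cols, config$smoothness)
  precip <- matrix(pmax(0, 60 + 35 * z_precip), g$n_rows, g$n_cols)  # mm, driest month

  layers <- list(
    altitude = grid_raster(altitude, g),
    precip_driest = grid_raster(precip, g),
    dist_water = dist_water
  )
  for (i in seq_len(config$n_predictors - 3L)) {
    rho <- stats::runif(1, -0.7, 0.7)
    z <- rho * z_alt + sqrt(1 - rho^2) *
      smooth_field(g$n_rows, g$n_cols, config$smoothness)
    layers[[sprintf("clim_%02d", i)]] <- grid_raster(10 * z + 25, g)
  }
  stack <- predictor_stack(layers)

  suit <- true_suitability(truth, stack)$values
  w <- array(0, c(g$n_rows, g$n_cols, 5))
  w[, , 1] <- 0.80 * (1 - suit) + 0.05
  w[, , 2] <- 0.50 * (1 - suit) + 0.05
  w[, , 3] <- 0.40 * (1 - suit) + 0.10
  w[, , 4] <- 1.20 * suit + 0.10
  w[, , 5] <- 0.90 * suit + 0.05
  u <- stats::runif(g$n_rows * g$n_cols) * apply(w, c(1, 2), sum)
  cum <- w[, , 1]
  cls <- matrix(0, g$n_rows, g$n_cols)
  for (k in 2:5) {
    cls[u > cum] <- k - 1
    cum <- cum + w[, , k]
  }
  landcover <- grid_raster(cls, g)

  dens <- matrix(0, g$n_rows, g$n_cols)
  ctr <- cell_center(g, as.vector(row(dens)), as.vector(col(dens)))
  # settlements concentrate in the lowlands, as in the study region
  low <- which(altitude <= stats::quantile(altitude, 0.4))
  hot <- sample(low, config$population_hotspots)
  for (h in hot) {
    hr <- ((h - 1L) %% g$n_rows) + 1L
    hc <- ((h - 1L) %/% g$n_rows) + 1L
    hxy <- cell_center(g, hr, hc)
    amp <- exp(stats::rnorm(1, log(60), 0.5))
    sig <- stats::runif(1, 4, 10)
    d2 <- (ctr[, 1] - hxy[1])^2 + (ctr[, 2] - hxy[2])^2
    dens <- dens + amp * exp(-d2 / (2 * sig^2))
  }
  dens <- dens * exp(stats::rnorm(length(dens), 0, 0.4))
  population <- grid_raster(matrix(dens, g$n_rows, g$n_cols), g)

  # reserves sit squarely in the uplands, away from the well-watered lowlands
  score <- 1.5 * z_alt + 0.6 * smooth_field(g$n_rows, g$n_cols, config$smoothness)
  protected <- grid_raster(
    (score >= stats::quantile(score, 1 - config$protected_fraction)) * 1, g)

  structure(list(stack = stack, landcover = landcover,
                 population = population, protected = protected,
                 water = water, config = config),
            class = "sdm_landscape")
}

#' True-suitability model of the synthetic landscape
#'
#' A logistic function of distance to water (dominant, strictly decreasing),
#' driest-month precipitation (positive) and altitude (negative), mirroring
#' the ranking of predictor importance the analysis is designed to recover.
#' `noise` is the logit-scale jitter applied when sampling occurrences.
#'
#' @param intercept,b_dist_water,b_precip,b_altitude Logit-scale
#'   coefficients; distance to water enters in km, precipitation and
#'   altitude as z-scores over the landscape.
#' @param noise Logit-scale standard deviation of the sampling jitter.
#' @return A list of class `truth_model`.
#' @export
truth_model <- function(intercept = 1.2, b_dist_water = -0.8, b_precip = 0.6,
                        b_altitude = -1.0, noise = 0.5) {
  stopifnot(b_dist_water < 0, noise >= 0)
  structure(list(intercept = intercept, b_dist_water = b_dist_water,
                 b_precip = b_precip, b_altitude = b_altitude, noise = noise),
            class = "truth_model")
}

#' @rdname truth_model
#' @param truth A `truth_model`.
#' @param stack A [predictor_stack()] containing `dist_water`,
#'   `precip_driest` and `altitude`.
#' @return `true_suitability()` returns a [grid_raster()] in `[0, 1]`.
#' @export
true_suitability <- function(truth, stack) {
  zs <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  eta <- truth$intercept +
    truth$b_dist_water * stack$dist_water$values +
    truth$b_precip * zs(stack$precip_driest$values) +
    truth$b_altitude * zs(stack$altitude$values)
  grid_raster(stats::plogis(eta), stack_grid(stack))
}

#' Greedy record thinning at a minimum separation
#'
#' One pass in input order: a record is kept iff it lies at least
#' `min_distance` from every record already kept.
#'
#' @param records Tibble with `x`, `y`.
#' @param min_distance Minimum separation in km (>= 0).
#' @return The kept rows of `records`.
#' @export
thin_records <- function(records, min_distance) {
  stopifnot(min_distance >= 0)
  if (nrow(records) == 0 || min_distance == 0) return(records)
  keep <- logical(nrow(records))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(records))) {
    if (!length(kx) ||
        min((kx - records$x[i])^2 + (ky - records$y[i])^2) >= min_distance^2) {
      keep[i] <- TRUE
      kx <- c(kx, records$x[i]); ky <- c(ky, records$y[i])
    }
  }
  records[keep, ]
}

#' Sample occurrence records from the true suitability surface
#'
#' Proposal cells are drawn uniformly and accepted with probability equal to
#' the (logit-jittered) true suitability; accepted points are jittered
#' uniformly within their cell and thinned on the fly at `min_distance`.
#' Epoch labels are assigned at random among the kept records, since in the
#' synthetic world the historical/recent contrast is created later by
#' [degrade_landcover()], not by where records fall.
#'
#' @param landscape An [generate_landscape()] result.
#' @param truth The [truth_model()] that defines suitability.
#' @param n_historical,n_recent Record counts (defaults 29 and 59, the
#'   published totals).
#' @param min_distance Thinning distance in km (default 1).
#' @param seed Optional integer seed.
#' @param max_proposals_per_record Rejection-sampling budget (default
#'   10000 proposals per requested record).
#' @return A tibble (`record_id`, `x`, `y`, `epoch`).
#' @export
sample_occurrences <- function(landscape, truth = truth_model(),
                               n_historical = 29, n_recent = 59,
                               min_distance = 1, seed = NULL,
                               max_proposals_per_record = 10000) {
  n <- n_historical + n_recent
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  stack <- landscape$stack
  g <- stack_grid(stack)
  suit <- true_suitability(truth, stack)$values
  pool <- which(!is.na(suit))
  kx <- numeric(0); ky <- numeric(0)
  budget <- n * max_proposals_per_record
  used <- 0L
  while (length(kx) < n && used < budget) {
    take <- min(2000L, budget - used)
    used <- used + take
    cells <- sample(pool, take, replace = TRUE)
    s <- stats::plogis(stats::qlogis(pmin(pmax(suit[cells], 1e-12),
                                          1 - 1e-12)) +
                         stats::rnorm(take, 0, truth$noise))
    acc <- cells[stats::runif(take) < s]
    if (!length(acc)) next
    r <- ((acc - 1L) %% g$n_rows) + 1L
    c <- ((acc - 1L) %/% g$n_rows) + 1L
    px <- g$origin_x + (c - 1 + stats::runif(length(acc))) * g$resolution
    py <- g$origin_y - (r - 1 + stats::runif(length(acc))) * g$resolution
    for (i in seq_along(acc)) {
      if (length(kx) >= n) break
      if (!length(kx) ||
          min((kx - px[i])^2 + (ky - py[i])^2) >= min_distance^2) {
        kx <- c(kx, px[i]); ky <- c(ky, py[i])
      }
    }
  }
  if (length(kx) < n) {
    stop("could not place ", n, " records within the proposal budget; ",
         "the landscape is too hostile", call. = FALSE)
  }
  epoch <- rep("recent", n)
  epoch[sample(n, n_historical)] <- "historical"
  tibble::tibble(record_id = sprintf("r%03d", seq_len(n)), x = kx, y = ky,
                 epoch = factor(epoch, levels = c("historical", "recent")))
}

#' Degrade land cover around occurrence records
#'
#' Inside the buffer of each historical record, every class-3/4 cell is
#' converted to a random class in 0-2 with probability `strength`; recent
#' buffers are degraded at `strength / 4`. Cells outside all buffers are
#' untouched. This is the synthetic analogue of habitat conversion having
#' progressed furthest where the species was recorded longest ago.
#'
#' @param landcover Class [grid_raster()] (0-4).
#' @param records Occurrence tibble with `x`, `y`, `epoch`.
#' @param strength Conversion probability in `[0, 1]`.
#' @param area Buffer area km2 (default 12).
#' @param seed Optional integer seed.
#' @return The degraded land-cover [grid_raster()].
#' @export
degrade_landcover <- function(landcover, records, strength, area = 12,
                              seed = NULL) {
  stopifnot(strength >= 0, strength <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (strength == 0) return(landcover)
  v <- landcover$values
  g <- landcover$grid
  for (i in seq_len(nrow(records))) {
    p <- if (records$epoch[i] == "historical") strength else strength / 4
    px <- buffer_pixels(g, records$x[i], records$y[i], area = area)
    good <- px[!is.na(v[px]) & v[px] >= 3, , drop = FALSE]
    if (!nrow(good)) next
    hit <- stats::runif(nrow(good)) < p
    if (any(hit)) {
      v[good[hit, , drop = FALSE]] <-
        sample(0:2, sum(hit), replace = TRUE)
    }
  }
  grid_raster(v, g)
}

#' Simulate a complete study: landscape, records, degraded land cover
#'
#' Convenience wrapper running [generate_landscape()],
#' [sample_occurrences()] and [degrade_landcover()] with seeds derived from
#' `config$seed`, so one integer reproduces the whole input bundle.
#'
#' @param config A [landscape_config()].
#' @param truth A [truth_model()].
#' @param n_historical,n_recent Record counts (defaults 29 and 59).
#' @return A list of class `sdm_study`: `landscape`, `records`,
#'   `landcover` (degraded), `truth`.
#' @export
simulate_study <- function(config = landscape_config(),
                           truth = truth_model(),
                           n_historical = 29, n_recent = 59) {
  landscape <- generate_landscape(config, truth)
  records <- sample_occurrences(landscape, truth,
                                n_historical = n_historical,
                                n_recent = n_recent,
                                seed = config$seed + 1L)
  landcover <- degrade_landcover(landscape$landcover, records,
                                 strength = config$degradation_strength,
                                 seed = config$seed + 2L)
  structure(list(landscape = landscape, records = records,
                 landcover = landcover, truth = truth, config = config),
            class = "sdm_study")
}
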