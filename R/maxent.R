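#' Predictor stacks
#'
#' A predictor stack is a named list of [grid_raster()] layers on one shared
#' grid. Cells masked in any layer are treated as masked everywhere.
#'
#' @param ... Named `grid_raster` layers, or a single named list of them.
#' @return An object of class `predictor_stack` (a named list).
#' @export
predictor_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "grid_raster")) {
    layers <- layers[[1]]
  }
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            all(nzchar(names(layers))))
  for (l in layers) stopifnot(inherits(l, "grid_raster"))
  do.call(stop_if_misaligned, c(layers, list(what = "stack layers")))
  structure(layers, class = "predictor_stack")
}

stack_grid <- function(stack) stack[[1]]$grid

# cell index convention: column-major position in the value matrix
stack_matrix <- function(stack, cells = NULL) {
  X <- vapply(stack, function(l) as.vector(l$values),
              numeric(stack_grid(stack)$n_rows * stack_grid(stack)$n_cols))
  if (!is.null(cells)) X <- X[cells, , drop = FALSE]
  X
}

unmasked_cells <- function(stack) {
  which(stats::complete.cases(stack_matrix(stack)))
}

#' Extract predictor values at point coordinates
#'
#' @param stack A [predictor_stack()].
#' @param x,y Coordinates (km).
#' @return A matrix (points x predictors); rows are `NA` off-grid or on
#'   masked cells.
#' @export
extract_at <- function(stack, x, y) {
  g <- stack_grid(stack)
  ij <- xy_to_cell(g, x, y)
  out <- matrix(NA_real_, length(x), length(stack),
                dimnames = list(NULL, names(stack)))
  ok <- stats::complete.cases(ij)
  for (p in seq_along(stack)) {
    out[ok, p] <- stack[[p]]$values[ij[ok, , drop = FALSE]]
  }
  out
}

#' Sample background cells
#'
#' Draws cells uniformly without replacement from the unmasked cells of the
#' stack, the presence-free "background" sample the model is normalized
#' over.
#'
#' @param stack A [predictor_stack()].
#' @param n Number of background cells (default 10000); capped at the number
#'   of unmasked cells.
#' @param seed Optional integer seed.
#' @return Integer vector of cell indices (column-major).
#' @export
sample_background <- function(stack, n = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- unmasked_cells(stack)
  sample(pool, min(n, length(pool)))
}

# ---- features -------------------------------------------------------------

#' Build a feature set from background predictor values
#'
#' Features are derived per predictor from its background sample: values are
#' min-max scaled to `[0, 1]` (and clamped to that range at prediction
#' time), then expanded into linear, quadratic, optional forward-hinge (at
#' `n_knots` equally spaced knots) and optional pairwise product features.
#' Constant predictors are dropped with a warning. With `types = "auto"` the
#' expansion follows the training sample size: linear + quadratic below 15
#' presences, hinge features added from 15 presences on.
#'
#' @param background Matrix of raw predictor values on the background sample
#'   (rows = cells, named columns = predictors).
#' @param types Character vector from `linear`, `quadratic`, `hinge`,
#'   `product`, or `"auto"`.
#' @param n_presences Training presence count; needed only for
#'   `types = "auto"`.
#' @param n_knots Hinge knots per predictor (default 8).
#' @return An object of class `sdm_features`.
#' @export
build_features <- function(background, types = "auto", n_presences = NULL,
                           n_knots = 8) {
  stopifnot(is.matrix(background), !is.null(colnames(background)))
  if (identical(types, "auto")) {
    if (is.null(n_presences)) {
      stop("types = \"auto\" needs n_presences", call. = FALSE)
    }
    types <- if (n_presences < 15) c("linear", "quadratic") else
      c("linear", "quadratic", "hinge")
  }
  stopifnot(all(types %in% c("linear", "quadratic", "hinge", "product")))
  mn <- apply(background, 2, min)
  mx <- apply(background, 2, max)
  keep <- mx > mn
  if (!all(keep)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(background)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("all predictors are constant", call. = FALSE)
  knots <- if ("hinge" %in% types) seq_len(n_knots) / (n_knots + 1) else numeric(0)
  structure(list(predictors = colnames(background)[keep],
                 mn = mn[keep], mx = mx[keep],
                 types = types, knots = knots),
            class = "sdm_features")
}

scale_predictors <- function(features, X) {
  X <- X[, features$predictors, drop = FALSE]
  Z <- sweep(sweep(X, 2, features$mn), 2, features$mx - features$mn, "/")
  Z[Z < 0] <- 0
  Z[Z > 1] <- 1
  Z
}

#' Expand raw predictor values into the model's feature matrix
#'
#' @param features An [build_features()] object.
#' @param X Matrix of raw predictor values (rows = cells).
#' @return Numeric feature matrix with one named column per feature.
#' @export
feature_matrix <- function(features, X) {
  Z <- scale_predictors(features, X)
  p <- colnames(Z)
  cols <- list()
  if ("linear" %in% features$types) {
    L <- Z; colnames(L) <- paste0(p, ":lin"); cols <- c(cols, list(L))
  }
  if ("quadratic" %in% features$types) {
    Q <- Z^2; colnames(Q) <- paste0(p, ":sq"); cols <- c(cols, list(Q))
  }
  if ("hinge" %in% features$types) {
    for (a in features$knots) {
      H <- (Z - a) / (1 - a)
      H[H < 0] <- 0
      colnames(H) <- sprintf("%s:h%.3f", p, a)
      cols <- c(cols, list(H))
    }
  }
  if ("product" %in% features$types && length(p) > 1) {
    pr <- utils::combn(seq_along(p), 2)
    P <- Z[, pr[1, ], drop = FALSE] * Z[, pr[2, ], drop = FALSE]
    colnames(P) <- paste0(p[pr[1, ]], "*", p[pr[2, ]])
    cols <- c(cols, list(P))
  }
  do.call(cbind, cols)
}

feature_predictor <- function(feature_names) {
  sub("[:*].*$", "", feature_names)
}

# ---- fitting --------------------------------------------------------------

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a penalized maximum-entropy presence/background model
#'
#' Maximizes the L1-penalized presence log-likelihood of a Gibbs
#' distribution over the background sample,
#' `mean_presence(eta) - log(sum_background(exp(eta))) - sum_j(beta_j |lambda_j|)`
#' with `eta = sum_j lambda_j f_j(x)` and per-feature penalty
#' `beta_j = multiplier * sd(f_j over presences) / sqrt(m)`. The solver is a
#' monotone proximal-gradient ascent (soft-thresholding step, adaptive step
#' size with backtracking), stopped when the objective improves by less than
#' `tol` or after `max_iter` iterations; the objective trace is
#' non-decreasing by construction.
#'
#' @param presence_X,background_X Raw predictor matrices at presence and
#'   background cells (named columns).
#' @param features Optional [build_features()] object; built from the
#'   background when `NULL`.
#' @param types,n_knots Passed to [build_features()] when building.
#' @param multiplier Regularization multiplier (default 1).
#' @param max_iter Iteration cap (default 1000).
#' @param tol Convergence threshold on the objective (default 1e-4).
#' @return An object of class `maxent_fit` carrying feature weights,
#'   penalties, the background log-partition value, the entropy of the
#'   fitted raw distribution, and the objective trace.
#' @export
fit_maxent <- function(presence_X, background_X, features = NULL,
                       types = "auto", n_knots = 8, multiplier = 1,
                       max_iter = 1000, tol = 1e-4) {
  m <- nrow(presence_X)
  if (is.null(m) || m < 2) stop("need at least 2 presences", call. = FALSE)
  if (is.null(features)) {
    features <- build_features(background_X, types = types,
                               n_presences = m, n_knots = n_knots)
  }
  Fp <- feature_matrix(features, presence_X)
  Fb <- feature_matrix(features, background_X)
  if (all(apply(Fb, 2, function(c) length(unique(c))) == 1)) {
    stop("degenerate background: all feature rows identical", call. = FALSE)
  }
  beta <- multiplier * apply(Fp, 2, stats::sd) / sqrt(m)
  fbar <- colMeans(Fp)
  J <- ncol(Fb)
  lambda <- numeric(J)

  objective <- function(lambda, eta_b) {
    sum(fbar * lambda) - log_sum_exp(eta_b) - sum(beta * abs(lambda))
  }
  eta_b <- as.vector(Fb %*% lambda)
  obj <- objective(lambda, eta_b)
  trace <- obj
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- exp(eta_b - log_sum_exp(eta_b))
    grad <- fbar - as.vector(crossprod(Fb, w))
    accepted <- FALSE
    for (half in 1:40) {
      cand <- lambda + step * grad
      cand <- sign(cand) * pmax(0, abs(cand) - step * beta)
      eta_c <- as.vector(Fb %*% cand)
      obj_c <- objective(cand, eta_c)
      if (obj_c >= obj) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    improvement <- obj_c - obj
    lambda <- cand; eta_b <- eta_c; obj <- obj_c
    trace <- c(trace, obj)
    step <- step * 2  # cautious growth so the next backtrack starts higher
    if (improvement < tol) { converged <- TRUE; break }
  }
  logZ <- log_sum_exp(eta_b)
  lw <- eta_b - logZ
  H <- -sum(exp(lw) * lw)
  structure(list(features = features, lambda = stats::setNames(lambda, colnames(Fb)),
                 beta = stats::setNames(beta, colnames(Fb)),
                 multiplier = multiplier, logZ = logZ, entropy = H,
                 objective = trace, iterations = length(trace) - 1L,
                 converged = converged,
                 n_presence = m, n_background = nrow(Fb)),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf(
    "<maxent_fit> %d features (%d active), %d presences vs %d background\n",
    length(x$lambda), sum(x$lambda != 0), x$n_presence, x$n_background))
  cat(sprintf("  entropy %.4f, objective %.6f after %d iterations%s\n",
              x$entropy, utils::tail(x$objective, 1), x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

maxent_linear_predictor <- function(object, X) {
  as.vector(feature_matrix(object$features, X) %*% object$lambda)
}

#' Predict logistic suitability from a fitted model
#'
#' The raw Gibbs probability `q(x) = exp(eta(x)) / Z` (normalized over the
#' fitted background sample) is mapped to `exp(H) q / (1 + exp(H) q)` where
#' `H` is the entropy of the fitted raw distribution, so a typical
#' background cell scores near 0.5 under a signal-free model.
#'
#' @param object A [fit_maxent()] fit.
#' @param newdata A [predictor_stack()] (returns a [grid_raster()]) or a raw
#'   predictor matrix (returns a vector).
#' @param ... Unused.
#' @return Logistic suitability in `[0, 1]`.
#' @export
predict.maxent_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "predictor_stack")) {
    missing <- setdiff(object$features$predictors, names(newdata))
    if (length(missing)) {
      stop("predictor(s) missing from stack: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    g <- stack_grid(newdata)
    cells <- unmasked_cells(newdata)
    X <- stack_matrix(newdata, cells)
    out <- matrix(NA_real_, g$n_rows, g$n_cols)
    out[cells] <- stats::plogis(
      object$entropy + maxent_linear_predictor(object, X) - object$logZ)
    return(grid_raster(out, g))
  }
  stats::plogis(object$entropy + maxent_linear_predictor(object, newdata) -
                  object$logZ)
}

# ---- evaluation -----------------------------------------------------------

#' Rank-based AUC of presence versus background scores
#'
#' The probability that a random presence outscores a random background
#' cell, with ties counting one half: the Mann-Whitney statistic scaled to
#' `[0, 1]`, computed by rank sums.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m > 0, n > 0)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Omission threshold for binarizing a suitability surface
#'
#' Sorts the occurrence scores ascending and returns the score at 0-based
#' index `floor(omission * N)`, so that the fraction of occurrences scoring
#' strictly below the threshold never exceeds `omission`. Cells with
#' prediction greater than or equal to the threshold count as suitable
#' (ties retained).
#'
#' @param occurrence_scores Model scores at all occurrence records.
#' @param omission Allowed omission fraction in `[0, 1)`.
#' @return The threshold score.
#' @export
omission_threshold <- function(occurrence_scores, omission) {
  stopifnot(length(occurrence_scores) > 0, omission >= 0, omission < 1)
  s <- sort(occurrence_scores)
  s[floor(omission * length(s)) + 1L]
}

#' Binary suitable-range mask at a threshold
#'
#' @param surface A suitability [grid_raster()].
#' @param threshold Cutoff; cells `>= threshold` are suitable.
#' @return A 0/1 [grid_raster()] (nodata propagates).
#' @export
suitable_mask <- function(surface, threshold) {
  grid_raster((surface$values >= threshold) * 1, surface$grid)
}

# ---- ensemble -------------------------------------------------------------

#' Fit a replicate ensemble of maximum-entropy models
#'
#' Runs `k` replicates, each on a random `1 - test_fraction` training split
#' of the presences against one shared background sample, records train and
#' test AUC per replicate, and averages the logistic prediction surfaces.
#'
#' @param stack A [predictor_stack()].
#' @param records Occurrence tibble (`x`, `y`, ...); see [read_records()].
#' @param k Number of replicates (default 10).
#' @param test_fraction Presence fraction held out per replicate
#'   (default 0.25).
#' @param n_background Background cells shared by all replicates
#'   (default 10000).
#' @param seed Optional integer seed controlling the background draw and the
#'   splits.
#' @inheritParams fit_maxent
#' @return An object of class `sdm_ensemble`: fitted models, a per-replicate
#'   AUC tibble, the mean logistic surface, and the design pieces needed for
#'   later evaluation.
#' @export
fit_ensemble <- function(stack, records, k = 10, test_fraction = 0.25,
                         n_background = 10000, types = "auto", n_knots = 8,
                         multiplier = 1, max_iter = 1000, tol = 1e-4,
                         seed = NULL) {
  stopifnot(k >= 1, test_fraction >= 0, test_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  n_test <- floor(test_fraction * n)
  if (test_fraction > 0 && n_test < 1) {
    stop("too few presences for a non-empty test split", call. = FALSE)
  }
  pres_X <- extract_at(stack, records$x, records$y)
  if (anyNA(pres_X)) stop("some records fall on masked or off-grid cells",
                          call. = FALSE)
  bg_cells <- sample_background(stack, n_background)
  bg_X <- stack_matrix(stack, bg_cells)
  features <- build_features(bg_X, types = types,
                             n_presences = n - n_test, n_knots = n_knots)
  g <- stack_grid(stack)
  all_cells <- unmasked_cells(stack)
  F_all <- feature_matrix(features, stack_matrix(stack, all_cells))
  F_bg <- feature_matrix(features, bg_X)

  models <- vector("list", k)
  auc <- vector("list", k)
  mean_surf <- numeric(length(all_cells))
  for (r in seq_len(k)) {
    test_idx <- if (n_test > 0) sample(n, n_test) else integer(0)
    train_idx <- setdiff(seq_len(n), test_idx)
    fit <- fit_maxent(pres_X[train_idx, , drop = FALSE], bg_X,
                      features = features, multiplier = multiplier,
                      max_iter = max_iter, tol = tol)
    eta_bg <- as.vector(F_bg %*% fit$lambda)
    score_bg <- stats::plogis(fit$entropy + eta_bg - fit$logZ)
    score_train <- predict(fit, pres_X[train_idx, , drop = FALSE])
    auc_train <- compute_auc(score_train, score_bg)
    auc_test <- if (n_test > 0) {
      compute_auc(predict(fit, pres_X[test_idx, , drop = FALSE]), score_bg)
    } else NA_real_
    surf <- stats::plogis(fit$entropy + as.vector(F_all %*% fit$lambda) -
                            fit$logZ)
    mean_surf <- mean_surf + surf / k
    models[[r]] <- fit
    auc[[r]] <- tibble::tibble(replicate = r, auc_train = auc_train,
                               auc_test = auc_test)
  }
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  out[all_cells] <- mean_surf
  structure(list(models = models, auc = dplyr::bind_rows(auc),
                 mean_surface = grid_raster(out, g), features = features,
                 bg_cells = bg_cells, bg_X = bg_X, pres_X = pres_X,
                 records = records, k = k, test_fraction = test_fraction),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %d replicates, %d presences vs %d background\n",
              x$k, nrow(x$pres_X), nrow(x$bg_X)))
  cat(sprintf("  mean AUC: train %.3f, test %.3f\n",
              mean(x$auc$auc_train), mean(x$auc$auc_test)))
  invisible(x)
}

ensemble_scores <- function(ensemble, X) {
  Fm <- feature_matrix(ensemble$features, X)
  s <- numeric(nrow(X))
  for (fit in ensemble$models) {
    s <- s + stats::plogis(fit$entropy + as.vector(Fm %*% fit$lambda) -
                             fit$logZ) / length(ensemble$models)
  }
  s
}

#' Permutation variable contribution
#'
#' For each predictor, its values are permuted across the evaluation cells
#' (all presences plus the background sample), the ensemble-mean suitability
#' is recomputed, and the drop in presence-versus-background AUC is
#' recorded; drops are averaged over `n_perm` permutations, floored at zero
#' and normalized to sum to 100 percent.
#'
#' @param ensemble A fitted [fit_ensemble()] object.
#' @param n_perm Permutations per predictor (default 3).
#' @param seed Optional integer seed.
#' @return A tibble (`predictor`, `auc_drop`, `contribution`) sorted by
#'   contribution.
#' @export
variable_contribution <- function(ensemble, n_perm = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- rbind(ensemble$pres_X, ensemble$bg_X)
  is_pres <- c(rep(TRUE, nrow(ensemble$pres_X)), rep(FALSE, nrow(ensemble$bg_X)))
  base_scores <- ensemble_scores(ensemble, X)
  base_auc <- compute_auc(base_scores[is_pres], base_scores[!is_pres])
  preds <- ensemble$features$predictors
  drop <- stats::setNames(numeric(length(preds)), preds)
  for (p in preds) {
    d <- 0
    for (s in seq_len(n_perm)) {
      Xp <- X
      Xp[, p] <- sample(Xp[, p])
      sc <- ensemble_scores(ensemble, Xp)
      d <- d + (base_auc - compute_auc(sc[is_pres], sc[!is_pres])) / n_perm
    }
    drop[[p]] <- max(0, d)
  }
  total <- sum(drop)
  contribution <- if (total > 0) 100 * drop / total else drop * 0
  dplyr::arrange(
    tibble::tibble(predictor = preds, auc_drop = unname(drop),
                   contribution = unname(contribution)),
    dplyr::desc(.data$contribution))
}

# ---- baselines and comparisons -------------------------------------------

#' Environmental-distance baseline suitability surface
#'
#' Scores each cell by its minimum Euclidean distance, in predictor space
#' standardized over the unmasked cells, to any presence; distances are
#' rescaled to a `[0, 1]` similarity, 1 at a presence and 0 at the farthest
#' unmasked cell.
#'
#' @param stack A [predictor_stack()].
#' @param records Occurrence tibble with `x`, `y`.
#' @return A [grid_raster()] in `[0, 1]`.
#' @export
env_distance <- function(stack, records) {
  stopifnot(nrow(records) >= 1)
  g <- stack_grid(stack)
  cells <- unmasked_cells(stack)
  X <- stack_matrix(stack, cells)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  P <- extract_at(stack, records$x, records$y)
  if (anyNA(P)) stop("some records fall on masked or off-grid cells",
                     call. = FALSE)
  P <- sweep(sweep(P, 2, mu), 2, sdv, "/")
  d2 <- outer(rowSums(Z^2), rep(1, nrow(P))) +
    outer(rep(1, nrow(Z)), rowSums(P^2)) - 2 * Z %*% t(P)
  d <- sqrt(pmax(0, apply(d2, 1, min)))
  dmax <- max(d)
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  out[cells] <- if (dmax > 0) 1 - d / dmax else 1
  grid_raster(out, g)
}

#' Pearson correlation of two suitability surfaces at sampled cells
#'
#' @param a,b Aligned [grid_raster()] surfaces.
#' @param n Cells to sample uniformly without replacement (default 5000).
#' @param seed Optional integer seed.
#' @return Pearson's r.
#' @export
surface_correlation <- function(a, b, n = 5000, seed = NULL) {
  stop_if_misaligned(a, b)
  if (!is.null(seed)) set.seed(seed)
  ok <- which(!is.na(a$values) & !is.na(b$values))
  cells <- if (length(ok) > n) sample(ok, n) else ok
  va <- a$values[cells]; vb <- b$values[cells]
  if (length(cells) < 2 || stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("need at least 2 sampled cells with variance in both surfaces",
         call. = FALSE)
  }
  stats::cor(va, vb)
}
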