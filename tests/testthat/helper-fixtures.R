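# Small in-code fixtures shared across test files.

# a tiny raster with arbitrary values and an optional mask
tiny_raster <- function(n_rows = 3, n_cols = 3, values = NULL, res = 1) {
  g <- grid_spec(n_rows, n_cols, resolution = res)
  if (is.null(values)) {
    values <- matrix(seq_len(n_rows * n_cols), n_rows, n_cols)
  }
  grid_raster(matrix(values, n_rows, n_cols), g)
}

# a deterministic two-predictor stack on an n x n grid
toy_stack <- function(n = 20, seed = 42) {
  set.seed(seed)
  g <- grid_spec(n, n)
  predictor_stack(
    a = grid_raster(matrix(stats::runif(n * n), n, n), g),
    b = grid_raster(matrix(stats::rnorm(n * n), n, n), g)
  )
}

# brute-force distance to nearest water-cell centre
brute_distance <- function(is_water, res = 1) {
  nr <- nrow(is_water); nc <- ncol(is_water)
  w <- which(is_water, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- sqrt(min((w[, 1] - i)^2 + (w[, 2] - j)^2)) * res
  }
  out
}

# brute-force G for a count table, straight from the formula
brute_g <- function(O) {
  O <- O[, colSums(O) > 0, drop = FALSE]
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  2 * sum(ifelse(O > 0, O * log(O / E), 0))
}

# flood-fill connected components (8-connectivity) for patch oracle
flood_patches <- function(on) {
  nr <- nrow(on); nc <- ncol(on)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(on)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      r <- ((cur - 1L) %% nr) + 1L; c <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            on[rr, cc] && lab[rr, cc] == 0L) {
          idx <- (cc - 1L) * nr + rr
          lab[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}
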