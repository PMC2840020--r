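#' Grid specification
#'
#' A `grid_spec` describes a rectangular planar raster grid in kilometre
#' units with square pixels. Cell `(i, j)` (1-based row/column, row 1 at the
#' top) has its centre at
#' `(origin_x + (j - 0.5) * resolution, origin_y - (i - 0.5) * resolution)`,
#' i.e. the origin is the top-left grid corner and y decreases downwards,
#' the usual raster convention.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param resolution Pixel edge length in km (> 0). Default 1 km, the working
#'   resolution of the analysis.
#' @param origin_x,origin_y Coordinates (km) of the top-left grid corner.
#'   Defaults place the lower-left corner at (0, 0).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, resolution = 1, origin_x = 0,
                      origin_y = n_rows * resolution) {
  stopifnot(n_rows >= 1, n_cols >= 1, resolution > 0)
  structure(
    list(origin_x = origin_x, origin_y = origin_y, resolution = resolution,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols @ %g km, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$resolution, x$origin_x, x$origin_y))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

stop_if_misaligned <- function(..., what = "rasters") {
  grids <- lapply(list(...), function(r) if (inherits(r, "grid_raster")) r$grid else r)
  for (g in grids[-1]) {
    if (!grids_equal(grids[[1]], g)) {
      stop("mixing ", what, " with unequal grid specifications", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Grid raster
#'
#' A single-layer raster: a numeric value matrix on a [grid_spec()]. Masked
#' (nodata) cells are stored as `NA` and are ignored by every statistic in
#' the package.
#'
#' @param values Numeric matrix, `n_rows x n_cols`; `NA` marks nodata.
#' @param grid A [grid_spec()] whose dimensions match `values`.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("value matrix shape does not match the grid specification", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_raster> %d x %d @ %g km; %d nodata cells; range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$resolution,
              sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Tidy a raster into a tibble of cell centres
#'
#' @param x A [grid_raster()].
#' @param ... Unused.
#' @param drop_na Drop masked cells (default `TRUE`).
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.grid_raster <- function(x, ..., drop_na = TRUE) {
  g <- x$grid
  ij <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  out <- tibble::tibble(
    row = ij$row, col = ij$col,
    x = g$origin_x + (ij$col - 0.5) * g$resolution,
    y = g$origin_y - (ij$row - 0.5) * g$resolution,
    value = as.vector(x$values[cbind(ij$row, ij$col)])
  )
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Map planar coordinates to grid cells
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors (km).
#' @return A two-column integer matrix (`row`, `col`); rows are `NA` for
#'   points outside the grid extent.
#' @export
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$resolution) + 1L
  row <- floor((grid$origin_y - y) / grid$resolution) + 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

cell_center <- function(grid, row, col) {
  cbind(x = grid$origin_x + (col - 0.5) * grid$resolution,
        y = grid$origin_y - (row - 0.5) * grid$resolution)
}

# ---- file I/O -------------------------------------------------------------

#' Read and write rasters as ESRI ASCII grids
#'
#' Rasters are stored in the plain-text ESRI ASCII grid format (`.asc`):
#' a header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, top row first. Values are
#' written at full double precision, so a write-then-read round trip is
#' bit-exact. Files whose header carries distinct `dx`/`dy` entries
#' (non-square pixels) are rejected.
#'
#' @param path File path.
#' @param raster A [grid_raster()].
#' @return `read_raster()` returns a [grid_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[[i]])) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    hdr[[tolower(parts[[1]])]] <- as.numeric(parts[[2]])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr))) {
    stop("raster grid metadata missing from header of ", path, call. = FALSE)
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    if (is.null(hdr$dx) || is.null(hdr$dy) || hdr$dx != hdr$dy) {
      stop("non-square pixels (dx != dy) are not supported", call. = FALSE)
    }
    hdr$cellsize <- hdr$dx
  }
  if (is.null(hdr$cellsize)) {
    stop("raster grid metadata missing: cellsize", call. = FALSE)
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("raster body has ", length(vals), " values; expected ",
         hdr$nrows * hdr$ncols, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  g <- grid_spec(n_rows = hdr$nrows, n_cols = hdr$ncols,
                 resolution = hdr$cellsize, origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize)
  grid_raster(m, g)
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "grid_raster"))
  g <- raster$grid
  v <- raster$values
  finite <- v[!is.na(v)]
  nodata <- -9999
  if (length(finite) && any(finite == nodata)) nodata <- floor(min(finite)) - 1
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin_x),
    sprintf("yllcorner %.17g", g$origin_y - g$n_rows * g$resolution),
    sprintf("cellsize %.17g", g$resolution),
    sprintf("NODATA_value %.17g", nodata)
  )
  out <- v
  out[is.na(out)] <- nodata
  body <- apply(out, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read occurrence records from CSV
#'
#' Expects header columns `record_id`, `x`, `y`, `epoch`; `epoch` must be
#' `historical` or `recent` (matched case-insensitively). Invalid rows are
#' reported by row number.
#'
#' @param path CSV file path.
#' @return A tibble with columns `record_id` (character), `x`, `y` (km,
#'   double) and `epoch` (factor with levels `historical`, `recent`).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("record_id", "x", "y", "epoch")
  if (!all(need %in% names(df))) {
    stop("records CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad_xy <- which(!is.finite(x) | !is.finite(y))
  if (length(bad_xy)) {
    stop("non-numeric or non-finite coordinate in row(s) ",
         paste(bad_xy, collapse = ", "), call. = FALSE)
  }
  epoch <- tolower(trimws(df$epoch))
  bad_ep <- which(!epoch %in% c("historical", "recent"))
  if (length(bad_ep)) {
    stop("unknown epoch \"", df$epoch[bad_ep[1]], "\" in row ", bad_ep[1],
         " (expected historical or recent)", call. = FALSE)
  }
  tibble::tibble(record_id = df$record_id, x = x, y = y,
                 epoch = factor(epoch, levels = c("historical", "recent")))
}

# ---- water ----------------------------------------------------------------

#' Water mask
#'
#' @param grid A [grid_spec()].
#' @param is_water Logical matrix matching the grid.
#' @return An object of class `water_mask`.
#' @export
water_mask <- function(grid, is_water) {
  stopifnot(inherits(grid, "grid_spec"), is.logical(is_water))
  if (nrow(is_water) != grid$n_rows || ncol(is_water) != grid$n_cols) {
    stop("water matrix shape does not match the grid", call. = FALSE)
  }
  structure(list(grid = grid, is_water = is_water), class = "water_mask")
}

#' Euclidean distance to the nearest water cell
#'
#' Per-cell minimum centre-to-centre Euclidean distance (km) to any water
#' cell; water cells get 0. The transform is exact (it matches the
#' brute-force minimum over all water-cell centres).
#'
#' @param mask A [water_mask()] with at least one water cell.
#' @return A [grid_raster()] of distances in km.
#' @export
distance_to_water <- function(mask) {
  stopifnot(inherits(mask, "water_mask"))
  if (!any(mask$is_water)) {
    stop("water mask is empty: cannot compute distances", call. = FALSE)
  }
  src <- matrix(1, mask$grid$n_rows, mask$grid$n_cols)
  src[mask$is_water] <- 0
  d <- EBImage::distmap(src, metric = "euclidean")
  grid_raster(as.matrix(d) * mask$grid$resolution, mask$grid)
}

#' Rasterize GeoJSON line features onto a grid as a water mask
#'
#' Accepts a GeoJSON FeatureCollection of `LineString` /
#' `MultiLineString` features in the grid's planar km coordinates; every
#' pixel crossed by a line (sampled at quarter-pixel steps) becomes water.
#'
#' @param path GeoJSON file path.
#' @param grid A [grid_spec()].
#' @return A [water_mask()].
#' @export
read_water_geojson <- function(path, grid) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  wet <- matrix(FALSE, grid$n_rows, grid$n_cols)
  mark_line <- function(coords) {
    pts <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    if (nrow(pts) < 2) return()
    step <- grid$resolution / 4
    for (s in seq_len(nrow(pts) - 1L)) {
      a <- pts[s, ]; b <- pts[s + 1L, ]
      len <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      cells <- xy_to_cell(grid, a[1] + t * (b[1] - a[1]),
                          a[2] + t * (b[2] - a[2]))
      cells <- cells[stats::complete.cases(cells), , drop = FALSE]
      if (nrow(cells)) wet[cells] <<- TRUE
    }
  }
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "LineString")) {
      mark_line(geom$coordinates)
    } else if (identical(geom$type, "MultiLineString")) {
      for (part in geom$coordinates) mark_line(part)
    }
  }
  water_mask(grid, wet)
}

# ---- buffers --------------------------------------------------------------

#' Pixels inside a circular buffer around a point
#'
#' The buffer is a circle of radius `sqrt(area / pi)` centred at `(x, y)`;
#' a pixel belongs to the buffer iff its centre lies within that radius.
#' The pixel containing the point is always included, so very small areas
#' degenerate to that single pixel. Pixels outside the grid are clipped.
#'
#' @param grid A [grid_spec()].
#' @param x,y Buffer centre (km).
#' @param area Buffer area in km2 (default 12, three times the assumed
#'   4 km2 home range).
#' @return A two-column integer matrix of (`row`, `col`) pixel indices;
#'   empty (with a warning) if the point lies outside the grid.
#' @export
buffer_pixels <- function(grid, x, y, area = 12) {
  stopifnot(area > 0)
  home <- xy_to_cell(grid, x, y)
  if (anyNA(home)) {
    warning("buffer centre lies outside the grid; returning no pixels")
    return(cbind(row = integer(0), col = integer(0)))
  }
  r <- sqrt(area / pi)
  res <- grid$resolution
  span <- ceiling(r / res) + 1L
  rows <- max(1L, home[1] - span):min(grid$n_rows, home[1] + span)
  cols <- max(1L, home[2] - span):min(grid$n_cols, home[2] + span)
  ij <- as.matrix(expand.grid(row = rows, col = cols))
  ctr <- cell_center(grid, ij[, 1], ij[, 2])
  inside <- (ctr[, 1] - x)^2 + (ctr[, 2] - y)^2 <= r^2
  inside[ij[, 1] == home[1] & ij[, 2] == home[2]] <- TRUE
  ij[inside, , drop = FALSE]
}
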