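#' Land-cover reclassification schemes
#'
#' A reclassification scheme maps the integer codes of a land-cover product
#' onto the ordinal habitat-quality classes 0-4 used throughout the
#' analysis: 0 unsuitable, 1 very poor, 2 poor (corridor at best), 3 good
#' (lowland forest), 4 very good (flooded/peat-swamp forest, mangrove).
#'
#' @param mapping Named integer vector: names are original product codes,
#'   values are classes in 0..4.
#' @param name Scheme name.
#' @param unmapped_policy What to do with codes absent from the mapping:
#'   `"error"` (default) or `"assign_class_0"`.
#' @return An object of class `reclass_scheme`.
#' @export
reclass_scheme <- function(mapping, name = "custom",
                           unmapped_policy = c("error", "assign_class_0")) {
  unmapped_policy <- match.arg(unmapped_policy)
  codes <- as.integer(names(mapping))
  if (anyNA(codes) || anyDuplicated(codes)) {
    stop("scheme codes must be unique integers", call. = FALSE)
  }
  if (!all(mapping %in% 0:4)) {
    stop("scheme classes must lie in 0..4", call. = FALSE)
  }
  structure(list(name = name, codes = codes, classes = as.integer(mapping),
                 unmapped_policy = unmapped_policy),
            class = "reclass_scheme")
}

#' @export
print.reclass_scheme <- function(x, ...) {
  cat(sprintf("<reclass_scheme> %s: %d codes, unmapped -> %s\n",
              x$name, length(x$codes), x$unmapped_policy))
  invisible(x)
}

#' Built-in reclassification schemes for the three land-cover products
#'
#' Returns the published code-to-class mapping for one of the three global
#' land-cover products used in the analysis: GlobCover v2.1, GLC2000, or the
#' SarVision classification of Borneo.
#'
#' @param name One of `"globcover"`, `"glc2000"`, `"sarvision"`.
#' @inheritParams reclass_scheme
#' @return A [reclass_scheme()].
#' @export
builtin_scheme <- function(name = c("globcover", "glc2000", "sarvision"),
                           unmapped_policy = "error") {
  name <- match.arg(name)
  mapping <- switch(name,
    globcover = c(`11` = 0, `12` = 0, `14` = 0, `20` = 1, `30` = 2, `40` = 3,
                  `70` = 1, `110` = 2, `130` = 1, `140` = 0, `160` = 4,
                  `170` = 4, `190` = 0),
    glc2000   = c(`1` = 3, `7` = 4, `8` = 4, `9` = 2, `11` = 1, `14` = 0,
                  `16` = 0, `17` = 0, `18` = 0, `19` = 0, `20` = 0, `22` = 0),
    sarvision = c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = 4, `6` = 4,
                  `7` = 0, `8` = 0, `9` = 0, `10` = 0, `11` = 0, `12` = 0,
                  `13` = 0, `14` = 0)
  )
  reclass_scheme(mapping, name = name, unmapped_policy = unmapped_policy)
}

#' Reclassify a land-cover raster into habitat classes 0-4
#'
#' @param raster Integer-valued [grid_raster()] of product codes.
#' @param scheme A [reclass_scheme()].
#' @return A [grid_raster()] of classes 0-4; nodata propagates.
#' @export
reclassify <- function(raster, scheme) {
  stopifnot(inherits(raster, "grid_raster"), inherits(scheme, "reclass_scheme"))
  v <- raster$values
  ok <- !is.na(v)
  if (any(v[ok] != round(v[ok]))) {
    stop("reclassify expects an integer-valued raster", call. = FALSE)
  }
  idx <- match(v, scheme$codes)
  unmapped <- ok & is.na(idx)
  if (any(unmapped)) {
    if (scheme$unmapped_policy == "error") {
      bad <- sort(unique(v[unmapped]))
      stop("unmapped land-cover code(s) ", paste(bad, collapse = ", "),
           " (", sum(unmapped), " cells) under scheme ", scheme$name,
           call. = FALSE)
    }
  }
  out <- matrix(NA_real_, nrow(v), ncol(v))
  mapped <- ok & !is.na(idx)
  out[mapped] <- scheme$classes[idx[mapped]]
  out[unmapped] <- 0
  grid_raster(out, raster$grid)
}

#' Classify human population density into classes 0-4
#'
#' Density classes follow the suitability convention of the land-cover
#' classes (4 best): class 0 for more than 25 inhabitants/km2 (unsuitable),
#' class 1 for 10-25, class 2 for 5-10, class 3 for 1-5, and class 4 below
#' 1 inhabitant/km2 (effectively uninhabited). Shared interval endpoints are
#' assigned to the lower-suitability class (10 and 25 to class 1, 5 to
#' class 2, 1 to class 3).
#'
#' @param density A [grid_raster()] of inhabitants per km2 (>= 0).
#' @return A [grid_raster()] of classes 0-4.
#' @export
classify_population <- function(density) {
  stopifnot(inherits(density, "grid_raster"))
  d <- density$values
  if (any(d < 0, na.rm = TRUE)) {
    stop("population density must be non-negative", call. = FALSE)
  }
  cls <- matrix(NA_real_, nrow(d), ncol(d))
  ok <- !is.na(d)
  cls[ok & d > 25] <- 0
  cls[ok & d >= 10 & d <= 25] <- 1
  cls[ok & d >= 5 & d < 10] <- 2
  cls[ok & d >= 1 & d < 5] <- 3
  cls[ok & d < 1] <- 4
  grid_raster(cls, density$grid)
}

#' Rescale habitat classes 0-4 to HSI weights
#'
#' Class 4 maps to 1, class 3 to 0.75, class 2 to 0.5, class 1 to 0.25 and
#' class 0 keeps its value 0, so that an unsuitable component zeroes the
#' habitat suitability index.
#'
#' @param class Numeric vector or matrix of classes in \{0, 1, 2, 3, 4\};
#'   `NA` passes through.
#' @return Weights in \{0, 0.25, 0.5, 0.75, 1\} with the shape of the input.
#' @export
rescale_for_hsi <- function(class) {
  ok <- !is.na(class)
  if (any(!(class[ok] %in% 0:4))) {
    stop("habitat class outside 0..4", call. = FALSE)
  }
  out <- class / 4
  out
}
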