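#' Habitat suitability index
#'
#' Weighted geometric mean `HSI = (M^2 * L^2 * H)^(1/5)` of the mean model
#' probability `M`, the rescaled land-cover weight `L` and the rescaled
#' human-population weight `H`; model probability and land cover carry
#' double weight. Any zero component zeroes the index.
#'
#' @param M,L,H Numeric vectors/matrices in `[0, 1]`.
#' @return HSI values in `[0, 1]`.
#' @export
hsi <- function(M, L, H) {
  for (v in list(M, L, H)) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("HSI components must lie in [0, 1]", call. = FALSE)
    }
  }
  (M^2 * L^2 * H)^(1 / 5)
}

#' Per-pixel HSI map
#'
#' Rescales the two class rasters to HSI weights (see [rescale_for_hsi()])
#' and applies [hsi()] cell-wise; nodata propagates.
#'
#' @param M Mean model probability [grid_raster()] in `[0, 1]`.
#' @param landcover_classes,population_classes Class rasters (0-4) aligned
#'   with `M`.
#' @return An HSI [grid_raster()].
#' @export
hsi_map <- function(M, landcover_classes, population_classes) {
  stop_if_misaligned(M, landcover_classes, population_classes)
  out <- hsi(M$values, rescale_for_hsi(landcover_classes$values),
             rescale_for_hsi(population_classes$values))
  grid_raster(out, M$grid)
}

#' Proportion of suitable range already converted to poor land cover
#'
#' Within a binary suitable-range mask, the fraction of unmasked pixels
#' falling in land-cover classes 0-2 (unsuitable to poor), read as the loss
#' of formerly suitable habitat to anthropogenic conversion.
#'
#' @param class_raster Land-cover class [grid_raster()] (0-4).
#' @param mask Binary suitable-range [grid_raster()] (nonzero = suitable).
#' @return Proportion in `[0, 1]`.
#' @export
habitat_loss <- function(class_raster, mask) {
  stop_if_misaligned(class_raster, mask)
  sel <- !is.na(mask$values) & mask$values != 0 & !is.na(class_raster$values)
  if (!any(sel)) stop("suitable mask is empty", call. = FALSE)
  sum(class_raster$values[sel] <= 2) / sum(sel)
}

#' Potential-habitat mask
#'
#' A cell is potential habitat iff it lies in the predicted suitable range,
#' carries land-cover class 3 or 4, and human-population class 3 or 4.
#'
#' @param mask Binary suitable-range [grid_raster()].
#' @param landcover_classes,population_classes Aligned class rasters (0-4).
#' @return A 0/1 [grid_raster()].
#' @export
potential_habitat_mask <- function(mask, landcover_classes,
                                   population_classes) {
  stop_if_misaligned(mask, landcover_classes, population_classes)
  out <- (!is.na(mask$values) & mask$values != 0 &
            !is.na(landcover_classes$values) & landcover_classes$values >= 3 &
            !is.na(population_classes$values) & population_classes$values >= 3) * 1
  out[is.na(mask$values)] <- NA
  grid_raster(out, mask$grid)
}

#' Proportion of habitat under protection
#'
#' @param habitat Binary habitat [grid_raster()] (nonzero = habitat); must
#'   contain at least one habitat cell.
#' @param protected Binary protected-area [grid_raster()].
#' @return `|habitat AND protected| / |habitat|`.
#' @export
protection_proportion <- function(habitat, protected) {
  stop_if_misaligned(habitat, protected)
  h <- !is.na(habitat$values) & habitat$values != 0
  if (!any(h)) stop("habitat mask is empty", call. = FALSE)
  p <- !is.na(protected$values) & protected$values != 0
  sum(h & p) / sum(h)
}

#' Extract contiguous high-HSI patches (key localities)
#'
#' Thresholds the HSI surface, labels connected components under
#' 8-connectivity (diagonal neighbours join, so river-following corridors
#' are not split), discards patches below a minimum area, and returns them
#' sorted by area, largest first. Patch ids follow raster scan order
#' (column-major), so labelling is deterministic.
#'
#' @param hsi_raster An HSI [grid_raster()].
#' @param hsi_threshold Cells with `HSI >= hsi_threshold` are candidate
#'   habitat; must lie in `(0, 1]`.
#' @param min_area Minimum patch area in km2 (default 0: keep all).
#' @return A tibble (`patch_id`, `n_pixels`, `area_km2`, `mean_hsi`,
#'   `row_min`, `row_max`, `col_min`, `col_max`).
#' @export
key_localities <- function(hsi_raster, hsi_threshold, min_area = 0) {
  stopifnot(hsi_threshold > 0, hsi_threshold <= 1)
  g <- hsi_raster$grid
  on <- !is.na(hsi_raster$values) & hsi_raster$values >= hsi_threshold
  cells <- which(on)
  empty <- tibble::tibble(patch_id = integer(0), n_pixels = integer(0),
                          area_km2 = numeric(0), mean_hsi = numeric(0),
                          row_min = integer(0), row_max = integer(0),
                          col_min = integer(0), col_max = integer(0))
  if (!length(cells)) return(empty)
  nr <- g$n_rows
  pos <- match(seq_len(nr * g$n_cols), cells)  # cell -> vertex id or NA
  edges <- integer(0)
  # 8-neighbour shifts with positive column-major offset (down, right,
  # down-right, up-right) cover every adjacency once
  for (shift in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r <- ((cells - 1L) %% nr) + 1L
    c <- ((cells - 1L) %/% nr) + 1L
    r2 <- r + shift[1]; c2 <- c + shift[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= g$n_cols
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- !is.na(pos[nb])
    edges <- c(edges, rbind(pos[cells[ok][has]], pos[nb[has]]))
  }
  graph <- igraph::make_graph(edges, n = length(cells), directed = FALSE)
  comp <- igraph::components(graph)$membership
  first_seen <- !duplicated(comp)
  patch_id <- match(comp, comp[first_seen])  # relabel in scan order
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  out <- tibble::tibble(patch_id = patch_id, row = rows, col = cols,
                        hsi = hsi_raster$values[cells]) |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(n_pixels = dplyr::n(),
                     area_km2 = dplyr::n() * g$resolution^2,
                     mean_hsi = mean(.data$hsi),
                     row_min = min(.data$row), row_max = max(.data$row),
                     col_min = min(.data$col), col_max = max(.data$col),
                     .groups = "drop") |>
    dplyr::filter(.data$area_km2 >= min_area) |>
    dplyr::arrange(dplyr::desc(.data$area_km2), .data$patch_id)
  out
}

#' Habitat-loss and protection accounting across omission scenarios
#'
#' For each omission scenario mask and each land-cover classification,
#' computes the habitat-loss proportion, the potential-habitat protection
#' proportion, and (per scheme) the protection proportion of all class-3/4
#' cells as a baseline, mirroring the scenario sweep of the published
#' analysis.
#'
#' @param masks Named list of binary suitable-range rasters, one per
#'   omission fraction (names like `"0"`, `"0.1"`, ...).
#' @param landcover_list Named list of land-cover class rasters (one per
#'   classification scheme).
#' @param population_classes Population class raster (0-4).
#' @param protected Binary protected-area raster.
#' @return A tibble (`scheme`, `omission`, `loss`, `protection`,
#'   `forest_protection`).
#' @export
habitat_accounting <- function(masks, landcover_list, population_classes,
                               protected) {
  rows <- list()
  for (scheme in names(landcover_list)) {
    lc <- landcover_list[[scheme]]
    forest <- grid_raster((!is.na(lc$values) & lc$values >= 3) * 1, lc$grid)
    forest_prot <- protection_proportion(forest, protected)
    for (om in names(masks)) {
      mask <- masks[[om]]
      habitat <- potential_habitat_mask(mask, lc, population_classes)
      prot <- if (any(habitat$values != 0, na.rm = TRUE)) {
        protection_proportion(habitat, protected)
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scheme = scheme, omission = as.numeric(om),
        loss = habitat_loss(lc, mask), protection = prot,
        forest_protection = forest_prot)
    }
  }
  dplyr::bind_rows(rows)
}
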