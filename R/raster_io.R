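#' Dated categorical land-use grid
#'
#' A `lulc_grid` couples a 2-D integer lattice of land-use class codes with
#' its calendar year, the area of one cell (km^2) and a nodata sentinel.
#' Row 1 is the northern edge and column 1 the western edge; all grids of a
#' scenario must share the same lattice (no reprojection is performed).
#'
#' @param codes integer matrix of class codes.
#' @param year calendar year the map refers to.
#' @param cell_area area of one cell in km^2 (default 1, i.e. 1 km cells).
#' @param nodata integer sentinel for cells outside the study region;
#'   excluded from every downstream metric.
#' @param legend optional class legend, see [class_legend()]. Non-nodata
#'   codes must all appear in it when supplied.
#' @return an object of class `lulc_grid`.
#' @export
lulc_grid <- function(codes, year, cell_area = 1, nodata = 0L, legend = NULL) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  if (any(!is.finite(codes)) || any(codes != round(codes)))
    stop("`codes` must be integer-valued")
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0)
    stop("`cell_area` must be a single positive number")
  storage.mode(codes) <- "integer"
  if (!is.null(legend)) {
    present <- setdiff(unique(as.vector(codes)), as.integer(nodata))
    bad <- setdiff(present, legend$code)
    if (length(bad))
      stop("codes not in legend: ", paste(bad, collapse = ", "))
  }
  structure(
    list(codes = codes, year = as.integer(year), cell_area = cell_area,
         nodata = as.integer(nodata), legend = legend),
    class = "lulc_grid"
  )
}

#' @export
print.lulc_grid <- function(x, ...) {
  cat("lulc_grid:", x$year, "-", nrow(x$codes), "x", ncol(x$codes),
      "cells of", x$cell_area, "km^2\n")
  tab <- table(x$codes[x$codes != x$nodata])
  print(tab)
  invisible(x)
}

#' County zone grid
#'
#' Integer lattice of evaluation-unit (county) identifiers aligned with the
#' land-use grids. Counties are whole-cell rasterised; a cell belongs to
#' exactly one county.
#'
#' @param zone_ids integer matrix of zone (county) identifiers; 0 = outside.
#' @param legend optional named character vector mapping id to county name.
#' @return an object of class `zone_grid`.
#' @export
zone_grid <- function(zone_ids, legend = NULL) {
  if (!is.matrix(zone_ids) || any(zone_ids != round(zone_ids)))
    stop("`zone_ids` must be an integer matrix")
  storage.mode(zone_ids) <- "integer"
  ids <- setdiff(sort(unique(as.vector(zone_ids))), 0L)
  if (!is.null(legend)) {
    miss <- setdiff(ids, as.integer(names(legend)))
    if (length(miss))
      stop("zone ids missing from legend: ", paste(miss, collapse = ", "))
  }
  structure(list(zone_ids = zone_ids, ids = ids, legend = legend),
            class = "zone_grid")
}

#' Class legend
#'
#' Maps each land-use class code to a class name and an ecological-level key
#' resolvable in [ecological_levels()].
#'
#' @param code integer class codes (unique).
#' @param name class names.
#' @param level_key keys into the ecological-level table.
#' @return data.frame with columns `code`, `name`, `level_key`.
#' @seealso [default_legend()]
#' @export
class_legend <- function(code, name, level_key) {
  if (anyDuplicated(code)) stop("class codes must be unique")
  data.frame(code = as.integer(code), name = as.character(name),
             level_key = as.character(level_key), stringsAsFactors = FALSE)
}

#' Default six-class land-use legend
#'
#' Farmland, forestland, grassland, water land, built-up land and unused
#' land, coded 1-6. The aggregate grassland class is keyed to the
#' high-density grassland ecological level; built-up land (absent from the
#' ecological-level table) shares the lowest level with unused land.
#'
#' @return a [class_legend()] data.frame.
#' @export
default_legend <- function() {
  class_legend(
    code = 1:6,
    name = c("farmland", "forestland", "grassland", "water_land",
             "built_up", "unused"),
    level_key = c("farmland", "forestland", "grassland_high", "water_land",
                  "built_up", "unused_land")
  )
}

# internal: raw matrix extraction for any grid-like object
grid_codes <- function(g) {
  if (inherits(g, "lulc_grid")) g$codes
  else if (inherits(g, "zone_grid")) g$zone_ids
  else if (is.matrix(g)) g
  else stop("not a grid object")
}

grid_cell_area <- function(g) if (inherits(g, "lulc_grid")) g$cell_area else NA_real_

#' Write a categorical grid to a single-band TIFF file
#'
#' Codes are stored as 16-bit unsigned integers, so roundtrips through
#' [load_grid()] are bit-exact for codes in 0..65535. No georeferencing tags
#' are written: grids of a scenario are assumed to share one lattice.
#'
#' @param grid a [lulc_grid()] (or integer matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  codes <- grid_codes(grid)
  if (any(codes < 0L) || any(codes > 65535L))
    stop("codes must lie in 0..65535 for 16-bit storage")
  tiff::writeTIFF(codes / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Load a categorical grid from a single-band TIFF file
#'
#' The band must be integer-valued; float rasters (e.g. NDVI layers) are
#' rejected so class maps and continuous fields cannot be confused.
#'
#' @param path path to a single-band TIFF written by [write_grid()].
#' @param year calendar year to attach.
#' @inheritParams lulc_grid
#' @return a [lulc_grid()].
#' @export
load_grid <- function(path, year, cell_area = 1, nodata = 0L, legend = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- tryCatch(tiff::readTIFF(path, info = TRUE, payload = FALSE),
                   error = function(e) stop("unreadable raster: ", path))
  if (any(info$bits.per.sample > 16L))
    stop("non-integer band: expected a categorical (integer) raster in ",
         path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (is.array(img) && length(dim(img)) == 3L)
    stop("expected a single-band raster: ", path)
  if (any(!is.finite(img)) || any(img != round(img)))
    stop("non-integer band: expected a categorical raster in ", path)
  lulc_grid(matrix(as.integer(img), nrow(img), ncol(img)),
            year = year, cell_area = cell_area, nodata = nodata,
            legend = legend)
}

#' Check that grids share one lattice
#'
#' Passes iff all grids have identical dimensions and (where defined)
#' identical cell areas, and errors otherwise naming the offending pair.
#'
#' @param grids list of `lulc_grid` / `zone_grid` objects or matrices.
#' @return TRUE, invisibly, on success.
#' @export
align_check <- function(grids) {
  if (length(grids) < 2L) stop("need at least two grids to align-check")
  dims <- lapply(grids, function(g) dim(grid_codes(g)))
  areas <- vapply(grids, grid_cell_area, numeric(1))
  for (i in seq_along(grids)[-1L]) {
    if (!identical(dims[[1L]], dims[[i]]))
      stop(sprintf("shape mismatch between grid 1 (%dx%d) and grid %d (%dx%d)",
                   dims[[1L]][1], dims[[1L]][2], i, dims[[i]][1], dims[[i]][2]))
    if (!is.na(areas[1L]) && !is.na(areas[i]) &&
        !isTRUE(all.equal(areas[1L], areas[i])))
      stop(sprintf("cell-area mismatch between grid 1 (%g) and grid %d (%g)",
                   areas[1L], i, areas[i]))
  }
  invisible(TRUE)
}

#' Aggregate a continuous field by zone
#'
#' @param values numeric matrix, same shape as the zone grid. `NA` cells are
#'   treated as nodata and excluded.
#' @param zones a [zone_grid()].
#' @param reducer `"mean"` or `"sum"`.
#' @return data.frame with columns `zone` and `value`, one row per zone id
#'   of the zone grid. A zone whose cells are all nodata gets `NA` and a
#'   warning, never a silent zero.
#' @export
zonal_aggregate <- function(values, zones, reducer = c("mean", "sum")) {
  reducer <- match.arg(reducer)
  z <- grid_codes(zones)
  if (!identical(dim(values), dim(z))) stop("shape mismatch values vs zones")
  keep <- z != 0L & !is.na(values)
  fn <- if (reducer == "mean") mean else sum
  agg <- tapply(values[keep], z[keep], fn)
  ids <- zones$ids
  out <- data.frame(zone = ids,
                    value = as.numeric(agg[as.character(ids)]))
  if (anyNA(out$value))
    warning("zones with no data: ",
            paste(out$zone[is.na(out$value)], collapse = ", "))
  out
}
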