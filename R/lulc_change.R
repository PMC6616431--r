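#' Ecological levels of land-use classes
#'
#' Dimensionless ranking of the ecological function of each land-use type,
#' used by the land-cover change direction model ([lcdm()]). Water land
#' ranks highest, unused land lowest; grassland is split by density.
#' Built-up land is assigned the lowest level (it is absent from the
#' published table). All values are editable.
#'
#' @param ... named overrides or additions, e.g. `grassland_high = 0.13`.
#' @return named numeric vector of levels in (0, 1).
#' @export
ecological_levels <- function(...) {
  lv <- c(farmland = 0.11, forestland = 0.245, shrub_land = 0.147,
          grassland_high = 0.125, grassland_mid = 0.063,
          grassland_low = 0.018, water_land = 0.282, unused_land = 0.01,
          built_up = 0.01)
  over <- c(...)
  lv[names(over)] <- over
  if (any(lv <= 0) || any(lv >= 1)) stop("ecological levels must lie in (0,1)")
  lv
}

#' Land-use transfer matrix between two dates
#'
#' Cross-tabulates the two class maps cell by cell: entry (i, j) is the
#' area (km^2) that was class i at the first date and class j at the
#' second. Diagonal entries (unchanged area) are recorded but excluded from
#' the total transformed area `A`. Nodata cells at either date are dropped.
#'
#' @param g1,g2 aligned [lulc_grid()]s sharing one legend.
#' @param zones optional [zone_grid()]; when given, a named list of
#'   per-county transfer matrices is returned instead.
#' @return an object of class `transfer_matrix` (or a named list of them):
#'   list with `flow` (class x class area matrix, km^2), `from_year`,
#'   `to_year` and `legend`.
#' @export
transfer_matrix <- function(g1, g2, zones = NULL) {
  align_check(c(list(g1, g2), if (!is.null(zones)) list(zones)))
  legend <- g1$legend %||% g2$legend %||% default_legend()
  lev <- legend$code
  keep <- g1$codes != g1$nodata & g2$codes != g2$nodata
  make_tm <- function(sel) {
    f1 <- factor(g1$codes[sel], levels = lev, labels = legend$name)
    f2 <- factor(g2$codes[sel], levels = lev, labels = legend$name)
    flow <- unclass(table(from = f1, to = f2)) * g1$cell_area
    structure(list(flow = flow, from_year = g1$year, to_year = g2$year,
                   legend = legend),
              class = "transfer_matrix")
  }
  if (is.null(zones)) return(make_tm(keep))
  out <- lapply(zones$ids, function(id)
    make_tm(keep & zones$zone_ids == id))
  names(out) <- zones$ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total transformed area of a transfer matrix
#'
#' Sum of all off-diagonal flows (km^2) -- the `A` of the LCDM.
#'
#' @param tm a [transfer_matrix()].
#' @return total changed area in km^2.
#' @export
changed_area <- function(tm) {
  f <- tm$flow
  sum(f) - sum(diag(f))
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("transfer_matrix", x$from_year, "->", x$to_year,
      sprintf("(A = %g km^2 changed)\n", changed_area(x)))
  print(round(x$flow, 2))
  invisible(x)
}

#' Land-cover change direction model (LCDM)
#'
#' Area-weighted mean change in ecological level over all class
#' transitions, in percent:
#' \deqn{LCDM = \frac{\sum_{i \ne j} A_{ij} (D_j - D_i)}{A} \times 100\%}
#' where \eqn{A_{ij}} is the area moving from class i to class j,
#' \eqn{D} the ecological level of a class and \eqn{A} the total
#' transformed area. Positive values mean the land-cover change benefited
#' ecosystem function (e.g. farmland to forestland), negative values the
#' opposite. Unchanged (diagonal) area does not enter either sum.
#'
#' @param tm a [transfer_matrix()].
#' @param levels ecological-level table, see [ecological_levels()].
#' @return LCDM score in percent.
#' @export
lcdm <- function(tm, levels = ecological_levels()) {
  A <- changed_area(tm)
  if (A <= 0)
    stop("no transformed area: LCDM is undefined when A = 0")
  key <- tm$legend$level_key[match(rownames(tm$flow), tm$legend$name)]
  miss <- key[!key %in% names(levels)]
  if (length(miss))
    stop("no ecological level for: ", paste(unique(miss), collapse = ", "))
  D <- levels[key]
  f <- tm$flow
  diag(f) <- 0
  dd <- outer(D, D, function(di, dj) dj - di)  # D_j - D_i
  sum(f * dd) / A * 100
}

#' Restored area per county
#'
#' Area (km^2) that was farmland at the first date and forestland or
#' grassland at the second -- the programme's restored area, the response
#' variable of the EHI regression.
#'
#' @param g1,g2 aligned [lulc_grid()]s.
#' @param zones a [zone_grid()].
#' @param farmland_code class code of farmland (default 1).
#' @param restored_codes codes counted as restoration targets (default
#'   forestland 2 and grassland 3).
#' @return data.frame with columns `zone` and `restored_km2` (>= 0).
#' @export
restored_area <- function(g1, g2, zones, farmland_code = 1L,
                          restored_codes = c(2L, 3L)) {
  align_check(list(g1, g2, zones))
  conv <- g1$codes == farmland_code & matrix(g2$codes %in% restored_codes,
                                             nrow(g2$codes))
  tal <- tapply(as.vector(conv), as.vector(zones$zone_ids), sum)
  out <- data.frame(zone = zones$ids,
                    restored_km2 = as.numeric(tal[as.character(zones$ids)]) *
                      g1$cell_area)
  out$restored_km2[is.na(out$restored_km2)] <- 0
  out
}

#' Net area change per class
#'
#' Signed change (km^2) of each class between the two dates of a transfer
#' matrix: gains (column sum) minus losses (row sum). Changes sum to zero
#' over all classes.
#'
#' @param tm a [transfer_matrix()].
#' @return named numeric vector of signed changes in km^2.
#' @export
net_change <- function(tm) {
  colSums(tm$flow) - rowSums(tm$flow)
}
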