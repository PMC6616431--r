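#' Maximum-value composite of half-month NDVI layers
#'
#' Per pixel and month, the maximum of the two half-month values --
#' the standard cloud-suppression composite for AVHRR-type records.
#'
#' @param x either one year of a [generate_ndvi_stack()] stack
#'   (`nrow x ncol x 12 x 2` array) or a whole `ndvi_stack`.
#' @return monthly array `nrow x ncol x 12` (or list of them per year).
#' @export
mvc_composite <- function(x) {
  if (inherits(x, "ndvi_stack"))
    return(lapply(x$data, mvc_composite))
  if (length(dim(x)) != 4L || dim(x)[4] != 2L)
    stop("expected an nrow x ncol x months x 2 array")
  pmax(x[, , , 1, drop = FALSE], x[, , , 2, drop = FALSE])[, , , 1]
}

#' Growing-season mean NDVI
#'
#' Per pixel, the arithmetic mean of the April-August monthly composites --
#' the annual NDVI value, insulated from extreme winter months.
#'
#' @param monthly `nrow x ncol x 12` monthly composite array
#'   (see [mvc_composite()]).
#' @param months growing-season months (default April-August).
#' @return `nrow x ncol` annual NDVI matrix.
#' @export
growing_season_mean <- function(monthly, months = 4:8) {
  if (length(dim(monthly)) != 3L) stop("expected a monthly composite array")
  if (any(months > dim(monthly)[3])) stop("missing month in composite")
  d <- dim(monthly)
  sub <- monthly[, , months, drop = FALSE]
  matrix(rowMeans(matrix(sub, d[1] * d[2], length(months))), d[1], d[2])
}

#' County and regional mean NDVI
#'
#' Mean of the annual NDVI lattice over each county's cells, plus a
#' `"region"` row averaging all in-region cells. With equal-area cells the
#' mean is the area-weighted county value.
#'
#' @param annual `nrow x ncol` annual NDVI matrix.
#' @param zones a [zone_grid()].
#' @return data.frame with columns `zone` (county ids and `"region"`) and
#'   `ndvi`.
#' @export
regional_mean <- function(annual, zones) {
  za <- zonal_aggregate(annual, zones, "mean")
  rbind(
    data.frame(zone = as.character(za$zone), ndvi = za$value),
    data.frame(zone = "region",
               ndvi = mean(annual[zones$zone_ids != 0L], na.rm = TRUE))
  )
}

#' Annual NDVI series per county and for the region
#'
#' Full preprocessing chain over an NDVI stack: maximum-value composite,
#' growing-season mean, then county/regional averaging for every year.
#'
#' @param stack an `ndvi_stack` from [generate_ndvi_stack()].
#' @param zones a [zone_grid()].
#' @return data.frame with columns `zone`, `year`, `ndvi`.
#' @export
ndvi_series <- function(stack, zones) {
  out <- lapply(seq_along(stack$years), function(i) {
    annual <- growing_season_mean(mvc_composite(stack$data[[i]]))
    rm <- regional_mean(annual, zones)
    rm$year <- stack$years[i]
    rm
  })
  do.call(rbind, out)[, c("zone", "year", "ndvi")]
}
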