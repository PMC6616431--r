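#' Default landscape resilience values
#'
#' Editable per-class resilience scores used by [ecological_resilience()]:
#' forests and water bodies recover structure and function fastest after
#' disturbance, built-up land essentially not at all. These are package
#' defaults (the upstream source table is not reproduced here); analyses
#' should pass their own table where one is available.
#'
#' @param ... named overrides, e.g. `grassland = 0.7`.
#' @return named numeric vector, one value per default legend class.
#' @export
resilience_values <- function(...) {
  ei <- c(farmland = 0.4, forestland = 0.9, grassland = 0.6,
          water_land = 0.8, built_up = 0.05, unused = 0.2)
  over <- c(...)
  ei[names(over)] <- over
  if (any(ei < 0)) stop("resilience values must be >= 0")
  ei
}

#' Delineate landscape patches
#'
#' A patch is a maximal connected set of same-class cells under 4- or
#' 8-connectivity. When a zone grid is supplied, patches are delineated
#' within county boundaries (a patch cannot straddle counties) and
#' summaries are reported per county; otherwise the whole region is one
#' landscape unit. Nodata cells belong to no patch.
#'
#' @param grid a [lulc_grid()].
#' @param zones optional [zone_grid()].
#' @param connectivity 4 or 8 (default 8, the patch-analysis convention).
#' @return object of class `patch_summary`: list with `units`
#'   (data.frame: `unit`, `n_patches`, `min_patch_km2`, `total_km2`) and
#'   `classes` (data.frame: `unit`, `class`, `n_patches`, `area_km2`,
#'   `share`).
#' @export
label_patches <- function(grid, zones = NULL, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (!is.null(zones)) align_check(list(grid, zones))
  codes <- grid$codes
  nr <- nrow(codes); nc <- ncol(codes)
  zone <- if (is.null(zones)) matrix(1L, nr, nc) else zones$zone_ids
  ok <- codes != grid$nodata & zone != 0L
  idx <- matrix(seq_len(nr * nc), nr, nc)

  pair_edges <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)
    keep <- ok[a] & ok[b] & codes[a] == codes[b] & zone[a] == zone[b]
    cbind(a[keep], b[keep])
  }
  edges <- rbind(
    pair_edges(idx[-nr, ], idx[-1, ]),              # vertical
    pair_edges(idx[, -nc], idx[, -1])               # horizontal
  )
  if (connectivity == 8)
    edges <- rbind(edges,
                   pair_edges(idx[-nr, -nc], idx[-1, -1]),   # diagonal \
                   pair_edges(idx[-nr, -1], idx[-1, -nc]))   # diagonal /
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  lab <- igraph::components(g)$membership
  lab[!ok] <- NA

  cells <- which(ok)
  patch <- lab[cells]
  unit <- zone[cells]
  cls <- codes[cells]
  area <- grid$cell_area

  patch_unit <- tapply(unit, patch, function(u) u[1])
  patch_cls <- tapply(cls, patch, function(u) u[1])
  patch_size <- tabulate(match(patch, names(patch_unit)))
  names(patch_size) <- names(patch_unit)
  pdf <- data.frame(unit = as.integer(patch_unit),
                    class = as.integer(patch_cls),
                    area_km2 = as.numeric(patch_size) * area)

  units <- sort(unique(pdf$unit))
  usum <- do.call(rbind, lapply(units, function(u) {
    p <- pdf[pdf$unit == u, ]
    data.frame(unit = u, n_patches = nrow(p),
               min_patch_km2 = min(p$area_km2),
               total_km2 = sum(p$area_km2))
  }))
  csum <- do.call(rbind, lapply(units, function(u) {
    p <- pdf[pdf$unit == u, ]
    a <- tapply(p$area_km2, p$class, sum)
    n <- tapply(p$area_km2, p$class, length)
    data.frame(unit = u, class = as.integer(names(a)),
               n_patches = as.integer(n), area_km2 = as.numeric(a),
               share = as.numeric(a) / sum(p$area_km2))
  }))
  structure(list(units = usum, classes = csum,
                 connectivity = connectivity, cell_area = area,
                 legend = grid$legend),
            class = "patch_summary")
}

#' @export
print.patch_summary <- function(x, ...) {
  cat("patch_summary over", nrow(x$units), "landscape unit(s),",
      x$connectivity, "-connectivity\n", sep = "")
  print(utils::head(x$units, 10), row.names = FALSE)
  invisible(x)
}

ps_vector <- function(ps, f) {
  v <- vapply(seq_len(nrow(ps$units)), f, numeric(1))
  names(v) <- ps$units$unit
  v
}

#' Landscape fragmentation index
#'
#' \eqn{LFI = (N_t - 1) / N_c} with \eqn{N_t} the total patch count of the
#' landscape unit and \eqn{N_c} the ratio of the minimum patch area to the
#' total area. Dividing by the (small) minimum-area ratio makes LFI large;
#' the index is min-max standardized downstream, so only its ordering
#' matters. `nc_inverse = TRUE` selects the alternative reading
#' \eqn{N_c = A / \min A}, which reverses the scale.
#'
#' @param ps a [patch_summary()][label_patches].
#' @param nc_inverse use total/min instead of min/total for Nc.
#' @return named numeric vector, one value per landscape unit.
#' @export
lfi <- function(ps, nc_inverse = FALSE) {
  ps_vector(ps, function(i) {
    u <- ps$units[i, ]
    if (u$total_km2 <= 0) stop("zero-area landscape unit")
    nc <- if (nc_inverse) u$total_km2 / u$min_patch_km2
          else u$min_patch_km2 / u$total_km2
    (u$n_patches - 1) / nc
  })
}

#' Shannon landscape diversity
#'
#' \eqn{D = -\sum_i S_i \ln S_i} over the classes present in the unit,
#' with \eqn{S_i} the class area shares.
#'
#' @inheritParams lfi
#' @return named numeric vector per landscape unit.
#' @export
shannon_diversity <- function(ps) {
  ps_vector(ps, function(i) {
    s <- ps$classes$share[ps$classes$unit == ps$units$unit[i]]
    s <- s[s > 0]
    -sum(s * log(s))
  })
}

#' Average patch area index
#'
#' \eqn{APAI = A / N}: total landscape area over total patch count
#' (km^2 per patch).
#'
#' @inheritParams lfi
#' @return named numeric vector per landscape unit.
#' @export
apai <- function(ps) {
  ps_vector(ps, function(i) {
    u <- ps$units[i, ]
    if (u$n_patches < 1) stop("no patches in landscape unit")
    u$total_km2 / u$n_patches
  })
}

#' Ecological resilience index
#'
#' \eqn{ER = D \sum_i S_i E_i}: Shannon landscape diversity times the
#' area-weighted mean class resilience.
#'
#' @inheritParams lfi
#' @param resilience named per-class resilience values; names must be class
#'   codes or (when the grid carries a legend) class names. See
#'   [resilience_values()].
#' @return named numeric vector per landscape unit.
#' @export
ecological_resilience <- function(ps, resilience = resilience_values()) {
  d <- shannon_diversity(ps)
  # resolve class codes to the resilience table, via the legend if named
  code_key <- as.character(ps$classes$class)
  if (!is.null(ps$legend) && !all(code_key %in% names(resilience))) {
    nm <- ps$legend$name[match(ps$classes$class, ps$legend$code)]
    code_key <- ifelse(is.na(nm), code_key, nm)
  }
  if (!all(code_key %in% names(resilience)))
    stop("missing resilience value for class(es): ",
         paste(unique(code_key[!code_key %in% names(resilience)]),
               collapse = ", "))
  ei <- resilience[code_key]
  se <- tapply(ps$classes$share * ei, ps$classes$unit, sum)
  d * as.numeric(se[names(d)])
}
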