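#' Synthetic scenario configuration
#'
#' Bundles every parameter of the synthetic study region: lattice size,
#' epochs, class legend, Markov land-use dynamics with a Grain-for-Green
#' (GGP) conversion phase, NDVI trend-break structure, climate field moments
#' and the county layout. Defaults emulate a subtropical, west-to-east
#' sloping region: 54 counties on a 60 x 90 lattice of 1 km^2 cells, six
#' maps 1990-2015, farmland-to-forest conversion starting in 2000 and an
#' annual NDVI series that declines slightly before 2000 and rises after.
#'
#' @param nrow,ncol lattice dimensions (cells).
#' @param cell_area cell area in km^2.
#' @param epochs strictly increasing map years.
#' @param legend class legend, see [default_legend()].
#' @param n_county number of counties (block-partitioned).
#' @param pop_density mean 1990 population density (persons/km^2).
#' @param pop_gradient relative west-to-east density drop (0 = flat).
#' @param pop_growth annual population growth rate.
#' @param gdp_pc regional per-capita GDP in the 2002 reference year (yuan).
#' @param gdp_cn national per-capita GDP in 2002 (yuan).
#' @param engel_rural,engel_urban rural/urban Engel coefficients (2002).
#' @param urban_frac mean urban population fraction (2002).
#' @param forest_gradient west-to-east shift of initial farmland share to
#'   forest share (0 = spatially uniform composition).
#' @param baseline_churn per-epoch probability mass of background churn
#'   among farmland/forest/grassland.
#' @param reclamation pre-GGP per-epoch probability of forest/grassland
#'   reclamation to farmland (the deforestation phase).
#' @param ggp_start first epoch year from which conversion applies.
#' @param conversion_intensity per-epoch probability that a farmland cell is
#'   converted (to forest or grassland) in the first post-GGP interval.
#' @param conversion_grass_frac fraction of conversions that become
#'   grassland rather than forestland.
#' @param conversion_gradient west-to-east slope of county conversion
#'   multipliers (implementation is stronger in the eastern uplands);
#'   multiplier for a county with eastness e is 1 + gradient * (e - 0.5),
#'   floored at 0.
#' @param conversion_decay per-interval decay of conversion intensity after
#'   the GGP start (recycled); the default mirrors a programme that peaks
#'   early then shifts to consolidation.
#' @param transitions optional list of explicit 6 x 6 row-stochastic
#'   transition matrices, one per epoch interval; overrides all built-in
#'   dynamics (churn, reclamation and conversion) when supplied.
#' @param ndvi_years years of the bimonthly NDVI record.
#' @param ndvi_base regional mean growing-season NDVI at the first year.
#' @param ndvi_gradient west-to-east NDVI range (east greener).
#' @param ndvi_slope1,ndvi_slope2 annual NDVI trend before/after the break.
#' @param ndvi_break break year of the piecewise-linear NDVI trend.
#' @param ndvi_noise_sd s.d. of the annual regional NDVI anomaly.
#' @param ndvi_pixel_sd s.d. of independent per-layer pixel noise.
#' @param ndvi_season_amp amplitude of the seasonal cycle.
#' @param pre_mean,pre_sd annual precipitation mean / spatial s.d. (mm).
#' @param tmp_mean,tmp_sd annual temperature mean / spatial s.d. (degC).
#' @param climate_smooth number of 3 x 3 smoothing passes applied to the
#'   climate noise fields (0 = independent cells).
#' @param seed default random seed used when a generator is called without
#'   an explicit one.
#' @return an object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(nrow = 60, ncol = 90, cell_area = 1,
                            epochs = c(1990, 1995, 2000, 2005, 2010, 2015),
                            legend = default_legend(),
                            n_county = 54,
                            pop_density = 300, pop_gradient = 0.8,
                            pop_growth = 0.005,
                            gdp_pc = 9000, gdp_cn = 9398,
                            engel_rural = 0.49, engel_urban = 0.38,
                            urban_frac = 0.3,
                            forest_gradient = 0.35,
                            baseline_churn = 0.006,
                            reclamation = 0.02,
                            ggp_start = 2000,
                            conversion_intensity = 0.10,
                            conversion_grass_frac = 0.3,
                            conversion_gradient = 1.5,
                            conversion_decay = c(1, 0.6, 0.3),
                            transitions = NULL,
                            ndvi_years = 1990:2015,
                            ndvi_base = 0.55, ndvi_gradient = 0.2,
                            ndvi_slope1 = -0.002, ndvi_slope2 = 0.004,
                            ndvi_break = 2000, ndvi_noise_sd = 0.005,
                            ndvi_pixel_sd = 0.01, ndvi_season_amp = 0.25,
                            pre_mean = 1000, pre_sd = 50,
                            tmp_mean = 20, tmp_sd = 1,
                            climate_smooth = 2,
                            seed = 42) {
  if (any(diff(epochs) <= 0)) stop("epochs must be strictly increasing")
  if (n_county < 2) stop("need at least two counties")
  probs <- c(baseline_churn, reclamation, conversion_intensity,
             conversion_grass_frac, conversion_decay)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (!is.null(transitions)) {
    if (length(transitions) != length(epochs) - 1L)
      stop("need one transition matrix per epoch interval")
    lapply(transitions, validate_transition, n_class = nrow(legend))
  }
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

validate_transition <- function(P, n_class = 6L) {
  if (!is.matrix(P) || nrow(P) != n_class || ncol(P) != n_class)
    stop("transition matrix must be ", n_class, " x ", n_class)
  if (any(P < 0) || any(P > 1))
    stop("transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  invisible(TRUE)
}

# county block layout: factor pair of n_county closest to the grid aspect
county_layout <- function(config) {
  n <- config$n_county
  divs <- which(n %% seq_len(n) == 0)
  rs <- divs
  cs <- n / divs
  score <- abs(log((rs / cs) / (config$nrow / config$ncol)))
  r <- rs[which.min(score)]
  c(r, n / r)
}

#' County zone grid of a scenario
#'
#' Counties tile the lattice as a regular grid of blocks, numbered west to
#' east within rows from the north; county 1 is the north-western corner.
#'
#' @param config a [scenario_config()].
#' @return a [zone_grid()] with county names `C01`, `C02`, ...
#' @export
scenario_zones <- function(config) {
  lay <- county_layout(config)
  rbin <- ceiling(seq_len(config$nrow) / (config$nrow / lay[1]))
  cbin <- ceiling(seq_len(config$ncol) / (config$ncol / lay[2]))
  ids <- outer(rbin, cbin, function(r, c) (r - 1L) * lay[2] + c)
  storage.mode(ids) <- "integer"
  nm <- sprintf("C%02d", seq_len(config$n_county))
  names(nm) <- seq_len(config$n_county)
  zone_grid(ids, legend = nm)
}

# eastness (0 west .. 1 east) of each county centroid
county_eastness <- function(config, zones = scenario_zones(config)) {
  colfrac <- (col(zones$zone_ids) - 0.5) / config$ncol
  as.numeric(tapply(colfrac, zones$zone_ids, mean)[as.character(zones$ids)])
}

# built-in transition matrix for interval k (1-based), without the
# county-specific conversion part, which is returned separately
interval_dynamics <- function(config, k) {
  classes <- config$legend$code
  n <- length(classes)
  P <- diag(n)
  churn <- config$baseline_churn / 2
  # background churn among farmland(1)/forestland(2)/grassland(3)
  for (i in 1:3) for (j in 1:3) if (i != j) {
    P[i, j] <- P[i, j] + churn / 2
    P[i, i] <- P[i, i] - churn / 2
  }
  from <- config$epochs[k]
  to <- config$epochs[k + 1L]
  conv <- 0
  if (to <= config$ggp_start) {
    # deforestation/reclamation phase: forest and grassland to farmland
    P[2, 1] <- P[2, 1] + config$reclamation; P[2, 2] <- P[2, 2] - config$reclamation
    P[3, 1] <- P[3, 1] + config$reclamation; P[3, 3] <- P[3, 3] - config$reclamation
  }
  if (from >= config$ggp_start) {
    idx <- sum(config$epochs[config$epochs >= config$ggp_start] <= from)
    decay <- rep_len(config$conversion_decay, length(config$epochs))[idx]
    conv <- config$conversion_intensity * decay
    # mild urbanisation drawing on farmland in later intervals
    P[1, 5] <- P[1, 5] + 0.004
    P[1, 1] <- P[1, 1] - 0.004
  }
  list(P = P, conv = conv)
}

#' Generate a synthetic land-use map series
#'
#' Starting from a west-farmland / east-forest initial map, each cell
#' evolves independently between epochs under a Markov transition matrix.
#' Before the GGP start year the dynamics include reclamation of forest and
#' grassland to farmland; from the GGP start year farmland converts to
#' forestland (and partly grassland) with a county-specific intensity that
#' increases eastward and decays over successive intervals.
#'
#' @param config a [scenario_config()].
#' @param seed random seed (defaults to the config seed).
#' @return list of [lulc_grid()], one per epoch, with attributes
#'   `conversion_log` (data.frame `from_year`, `to_year`, `zone`,
#'   `restored_km2` of realised farmland-to-forest/grassland conversions)
#'   and `zones` (the county [zone_grid()]).
#' @export
generate_lulc_series <- function(config, seed = config$seed) {
  set.seed(seed)
  zones <- scenario_zones(config)
  east <- county_eastness(config, zones)
  nr <- config$nrow; nc <- config$ncol
  ncell <- nr * nc
  n_class <- nrow(config$legend)

  # initial composition per column (west: farmland-heavy, east: forest-heavy)
  e_col <- (seq_len(nc) - 0.5) / nc
  codes <- matrix(0L, nr, nc)
  for (j in seq_len(nc)) {
    shift <- config$forest_gradient * (e_col[j] - 0.5)
    p <- c(0.50 - shift, 0.20 + shift, 0.15, 0.06, 0.05, 0.04)
    p <- pmax(p, 0); p <- p / sum(p)
    codes[, j] <- sample.int(n_class, nr, replace = TRUE, prob = p)
  }

  zvec <- as.vector(zones$zone_ids)
  mult <- pmax(1 + config$conversion_gradient * (east - 0.5), 0)
  grids <- vector("list", length(config$epochs))
  grids[[1L]] <- lulc_grid(codes, config$epochs[1L],
                           cell_area = config$cell_area,
                           legend = config$legend)
  log_rows <- list()

  for (k in seq_len(length(config$epochs) - 1L)) {
    cur <- as.vector(grids[[k]]$codes)
    nxt <- cur
    if (!is.null(config$transitions)) {
      P <- config$transitions[[k]]
      for (cls in seq_len(n_class)) {
        idx <- which(cur == cls)
        if (!length(idx)) next
        cum <- cumsum(P[cls, ])
        cum[length(cum)] <- 1
        u <- stats::runif(length(idx))
        nxt[idx] <- findInterval(u, cum, left.open = TRUE) + 1L
      }
    } else {
      dyn <- interval_dynamics(config, k)
      for (cls in seq_len(n_class)) {
        idx <- which(cur == cls)
        if (!length(idx)) next
        u <- stats::runif(length(idx))
        if (cls == 1L && dyn$conv > 0) {
          # farmland row varies by county through the conversion multiplier
          conv_cell <- dyn$conv * mult[zvec[idx]]
          p_forest <- dyn$P[1, 2] + conv_cell * (1 - config$conversion_grass_frac)
          p_grass <- dyn$P[1, 3] + conv_cell * config$conversion_grass_frac
          rest <- dyn$P[1, ]; rest[1:3] <- 0
          # renormalize cells whose transition mass would exceed 1
          scl <- pmax(p_forest + p_grass + sum(rest), 1)
          p_forest <- p_forest / scl; p_grass <- p_grass / scl
          p_stay <- pmax(1 - p_forest - p_grass - sum(rest) / scl, 0)
          cum <- cbind(p_stay, p_stay + p_forest, p_stay + p_forest + p_grass)
          for (m in seq_along(rest)[-(1:3)])
            cum <- cbind(cum, cum[, ncol(cum)] + rest[m] / scl)
          cum[, ncol(cum)] <- 1
          pick <- rowSums(u > cum) + 1L
          # columns are ordered stay, forest, grass, then classes 4..n
          map <- c(1L, 2L, 3L, seq_len(n_class)[-(1:3)])
          nxt[idx] <- map[pick]
        } else {
          cum <- cumsum(dyn$P[cls, ])
          cum[length(cum)] <- 1
          nxt[idx] <- findInterval(u, cum, left.open = TRUE) + 1L
        }
      }
    }
    restored <- cur == 1L & nxt %in% c(2L, 3L)
    tal <- tapply(restored, zvec, sum)
    log_rows[[k]] <- data.frame(
      from_year = config$epochs[k], to_year = config$epochs[k + 1L],
      zone = zones$ids,
      restored_km2 = as.numeric(tal[as.character(zones$ids)]) *
        config$cell_area
    )
    grids[[k + 1L]] <- lulc_grid(matrix(nxt, nr, nc),
                                 config$epochs[k + 1L],
                                 cell_area = config$cell_area,
                                 legend = config$legend)
  }
  attr(grids, "conversion_log") <- do.call(rbind, log_rows)
  attr(grids, "zones") <- zones
  grids
}

#' Generate a bimonthly NDVI stack with a trend break
#'
#' Per-pixel NDVI is a smooth west-to-east spatial base plus a seasonal
#' cycle (centred so the April-August growing-season mean carries no
#' seasonal offset), a piecewise-linear annual trend that changes slope at
#' the break year, an annual regional anomaly and independent pixel noise.
#' All values are clipped to [-1, 1].
#'
#' @inheritParams generate_lulc_series
#' @return an object of class `ndvi_stack`: list with elements `years` and
#'   `data`, the latter one `nrow x ncol x 12 x 2` array per year
#'   (month, half-month).
#' @export
generate_ndvi_stack <- function(config, seed = config$seed) {
  set.seed(seed)
  nr <- config$nrow; nc <- config$ncol
  e_col <- (seq_len(nc) - 0.5) / nc
  base <- matrix(rep(config$ndvi_base + config$ndvi_gradient * (e_col - 0.5),
                     each = nr), nr, nc)
  season <- -cos(2 * pi * ((1:12) - 1) / 12) * config$ndvi_season_amp
  season <- season - mean(season[4:8])   # growing season carries the trend
  years <- config$ndvi_years
  y0 <- years[1L]
  trend <- ifelse(
    years <= config$ndvi_break,
    config$ndvi_slope1 * (years - y0),
    config$ndvi_slope1 * (config$ndvi_break - y0) +
      config$ndvi_slope2 * (years - config$ndvi_break)
  )
  anom <- stats::rnorm(length(years), 0, config$ndvi_noise_sd)
  data <- vector("list", length(years))
  for (yi in seq_along(years)) {
    arr <- array(0, dim = c(nr, nc, 12, 2))
    for (m in 1:12) for (h in 1:2) {
      noise <- if (config$ndvi_pixel_sd > 0)
        matrix(stats::rnorm(nr * nc, 0, config$ndvi_pixel_sd), nr, nc)
      else 0
      arr[, , m, h] <- base + season[m] + trend[yi] + anom[yi] + noise
    }
    arr[arr > 1] <- 1
    arr[arr < -1] <- -1
    data[[yi]] <- arr
  }
  structure(list(years = years, data = data), class = "ndvi_stack")
}

smooth_field <- function(x, passes) {
  for (i in seq_len(passes)) {
    p <- rbind(x[1, ], x, x[nrow(x), ])
    p <- cbind(p[, 1], p, p[, ncol(p)])
    n <- nrow(x); m <- ncol(x)
    x <- (p[1:n, 1:m] + p[1:n, 2:(m + 1)] + p[1:n, 3:(m + 2)] +
          p[2:(n + 1), 1:m] + p[2:(n + 1), 2:(m + 1)] + p[2:(n + 1), 3:(m + 2)] +
          p[3:(n + 2), 1:m] + p[3:(n + 2), 2:(m + 1)] + p[3:(n + 2), 3:(m + 2)]) / 9
  }
  x
}

#' Generate annual climate surfaces
#'
#' Precipitation and temperature fields are Gaussian noise around the
#' configured means, optionally smoothed (3 x 3 mean filter) and rescaled
#' back to the target marginal s.d. so the fields are spatially coherent
#' without changing their moments. Precipitation is clipped at 0.
#'
#' @inheritParams generate_lulc_series
#' @return list with matrices `pre` (mm) and `tmp` (degC).
#' @export
generate_climate <- function(config, seed = config$seed) {
  set.seed(seed)
  gen <- function(mean, sd) {
    if (sd == 0) return(matrix(mean, config$nrow, config$ncol))
    x <- matrix(stats::rnorm(config$nrow * config$ncol), config$nrow,
                config$ncol)
    if (config$climate_smooth > 0) {
      x <- smooth_field(x, config$climate_smooth)
      x <- x / stats::sd(x)
    }
    mean + sd * x
  }
  pre <- gen(config$pre_mean, config$pre_sd)
  pre[pre < 0] <- 0
  list(pre = pre, tmp = gen(config$tmp_mean, config$tmp_sd))
}

#' Generate per-county socio-economic tables
#'
#' Population density falls from west to east (the plains are the settled
#' grain base); per-capita GDP and urbanisation follow the same gradient
#' while Engel coefficients rise slightly eastward. All socio-economic
#' reference values describe the 2002 base year used by the
#' ecosystem-service valuation.
#'
#' @inheritParams generate_lulc_series
#' @return list with `counties` (data.frame: `zone`, `name`, `area_km2`,
#'   `east_frac`, one `pop_<year>` column per epoch, `gdp_pc`,
#'   `engel_rural`, `engel_urban`, `urban_frac`) and `zones`
#'   (the county [zone_grid()]).
#' @export
generate_county_tables <- function(config, seed = config$seed) {
  zones <- scenario_zones(config)
  east <- county_eastness(config, zones)
  area <- as.numeric(table(factor(zones$zone_ids, levels = zones$ids))) *
    config$cell_area
  density <- config$pop_density * (1 + config$pop_gradient * (0.5 - east))
  counties <- data.frame(
    zone = zones$ids,
    name = sprintf("C%02d", zones$ids),
    area_km2 = area,
    east_frac = east
  )
  for (y in config$epochs)
    counties[[paste0("pop_", y)]] <-
      density * area * (1 + config$pop_growth)^(y - config$epochs[1L])
  counties$gdp_pc <- config$gdp_pc * (1 + 0.4 * (0.5 - east))
  counties$engel_rural <- config$engel_rural + 0.04 * (east - 0.5)
  counties$engel_urban <- config$engel_urban + 0.03 * (east - 0.5)
  counties$urban_frac <- pmin(pmax(config$urban_frac +
                                     0.25 * (0.5 - east), 0), 1)
  list(counties = counties, zones = zones)
}

#' Generate synthetic expert pairwise-comparison matrices
#'
#' Each matrix is built from a common underlying weight vector: entry (i, j)
#' is w_i / w_j perturbed by a multiplicative log-normal factor, with the
#' lower triangle set to exact reciprocals and a unit diagonal. With zero
#' noise every matrix is perfectly consistent (CR = 0); large noise yields
#' matrices that fail the consistency screen.
#'
#' @param n_experts number of matrices.
#' @param true_weights positive weights summing to 1.
#' @param noise s.d. of the log-scale perturbation.
#' @param seed random seed.
#' @return list of reciprocal comparison matrices.
#' @export
generate_expert_matrices <- function(n_experts, true_weights, noise = 0.1,
                                     seed = NULL) {
  if (any(true_weights <= 0) || abs(sum(true_weights) - 1) > 1e-8)
    stop("true_weights must be positive and sum to 1")
  if (!is.null(seed)) set.seed(seed)
  k <- length(true_weights)
  lapply(seq_len(n_experts), function(e) {
    m <- diag(k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      m[i, j] <- true_weights[i] / true_weights[j] *
        exp(stats::rnorm(1, 0, noise))
      m[j, i] <- 1 / m[i, j]
    }
    m
  })
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper drawing independent sub-seeds for the land-use
#' series, NDVI stack, climate surfaces and county tables, so the bundle is
#' reproducible from a single seed.
#'
#' @inheritParams generate_lulc_series
#' @return list with elements `config`, `lulc`, `zones`, `counties`,
#'   `ndvi`, `climate` and `conversion_log`.
#' @export
generate_scenario <- function(config = scenario_config(),
                              seed = config$seed) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 4)
  lulc <- generate_lulc_series(config, seed = seeds[1])
  ct <- generate_county_tables(config, seed = seeds[2])
  ndvi <- generate_ndvi_stack(config, seed = seeds[3])
  climate <- generate_climate(config, seed = seeds[4])
  list(config = config, lulc = lulc, zones = ct$zones,
       counties = ct$counties, ndvi = ndvi, climate = climate,
       conversion_log = attr(lulc, "conversion_log"))
}
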