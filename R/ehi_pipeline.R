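psr_indicators <- c("PD", "LFI", "NDVI", "LDI", "APAI", "ESV", "ER")
psr_orientation <- c(PD = "cost", LFI = "cost", NDVI = "benefit",
                     LDI = "benefit", APAI = "benefit", ESV = "benefit",
                     ER = "benefit")

#' Assemble an indicator panel
#'
#' @param zone county identifiers.
#' @param year epoch years.
#' @param indicator indicator names, a subset of
#'   PD, LFI, NDVI, LDI, APAI, ESV, ER.
#' @param value raw indicator values (PD persons/km^2, APAI km^2, ESV yuan,
#'   others dimensionless).
#' @return data.frame of class `indicator_panel` with an `orientation`
#'   column (`cost` for the pressure loads PD and LFI -- larger is worse --
#'   and `benefit` for the state indicators).
#' @export
indicator_panel <- function(zone, year, indicator, value) {
  bad <- setdiff(unique(indicator), psr_indicators)
  if (length(bad)) stop("unknown indicator(s): ", paste(bad, collapse = ", "))
  out <- data.frame(zone = zone, year = year, indicator = indicator,
                    value = value,
                    orientation = unname(psr_orientation[indicator]),
                    stringsAsFactors = FALSE)
  class(out) <- c("indicator_panel", "data.frame")
  out
}

#' Min-max standardize an indicator panel
#'
#' Benefit indicators map to (x - min)/(max - min), cost indicators to
#' (max - x)/(max - min), with the extremes taken over the pooled sample of
#' all counties and years of each indicator (so standardized values -- and
#' hence EHI values -- are comparable across years). Per-year
#' standardization is available via `by_year = TRUE`. An indicator with no
#' spread standardizes to 0.5 everywhere, with a warning.
#'
#' @param panel an [indicator_panel()].
#' @param by_year standardize within each year instead of pooling.
#' @return the panel with a `std` column in [0, 1].
#' @export
standardize_indicators <- function(panel, by_year = FALSE) {
  key <- if (by_year) paste(panel$indicator, panel$year) else panel$indicator
  panel$std <- NA_real_
  for (g in unique(key)) {
    sel <- key == g
    x <- panel$value[sel]
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("indicator ", g, " is constant; standardized to 0.5")
      panel$std[sel] <- 0.5
    } else {
      s <- (x - rng[1]) / diff(rng)
      if (panel$orientation[sel][1] == "cost") s <- 1 - s
      panel$std[sel] <- s
    }
  }
  panel
}

#' Compose the ecosystem health index
#'
#' \eqn{EHI = \sum_i w_i x_i'} over the standardized indicators, with
#' per-dimension subtotals (pressure = PD + LFI contributions, state = the
#' rest) and the individual contributions \eqn{w_i x_i'} retained so
#' published-style aggregation tables can be emitted. With standardized
#' inputs in [0, 1] and weights summing to 1, EHI lies in [0, 1]; larger
#' values mean better ecosystem health.
#'
#' @param panel a standardized [indicator_panel()]
#'   (see [standardize_indicators()]).
#' @param weights a [weight_set()].
#' @return object of class `ehi_result`: data.frame `zone`, `year`,
#'   `pressure`, `state`, `ehi`, with the contribution long table in
#'   attribute `contributions`.
#' @export
compose_ehi <- function(panel, weights) {
  if (is.null(panel$std))
    stop("panel has no standardized values; run standardize_indicators()")
  miss <- setdiff(psr_indicators, unique(panel$indicator))
  if (length(miss))
    stop("missing indicator(s): ", paste(miss, collapse = ", "))
  w <- weights$weights
  contrib <- panel[, c("zone", "year", "indicator")]
  contrib$contribution <- panel$std * unname(w[panel$indicator])
  dim_of <- weights$dimensions[contrib$indicator]
  agg <- function(sel) {
    a <- stats::aggregate(contribution ~ zone + year, contrib[sel, ], sum)
    a
  }
  pres <- agg(dim_of == "pressure")
  stat <- agg(dim_of == "state")
  names(pres)[3] <- "pressure"
  names(stat)[3] <- "state"
  out <- merge(pres, stat, by = c("zone", "year"), sort = TRUE)
  out$ehi <- out$pressure + out$state
  out <- out[order(out$zone, out$year), ]
  rownames(out) <- NULL
  attr(out, "contributions") <- contrib
  class(out) <- c("ehi_result", "data.frame")
  out
}

#' Grade EHI values
#'
#' Equal-interval classification of the pooled EHI range into ordered
#' grades I (lowest) .. VIII (highest) by default. The grade count is a
#' convention, not part of the index itself.
#'
#' @param res an [compose_ehi()] result (or numeric EHI vector).
#' @param n_classes number of grades (default 8).
#' @return ordered factor of grades, aligned with the rows of `res`.
#' @export
grade_ehi <- function(res, n_classes = 8) {
  x <- if (is.data.frame(res)) res$ehi else res
  labs <- as.character(utils::as.roman(seq_len(n_classes)))
  if (diff(range(x)) == 0)
    return(factor(rep(labs[1], length(x)), levels = labs, ordered = TRUE))
  breaks <- seq(min(x), max(x), length.out = n_classes + 1)
  cut(x, breaks, labels = labs, include.lowest = TRUE, ordered_result = TRUE)
}

#' Regression of EHI change on restored area
#'
#' Ordinary least squares of the county-level EHI change on the restored
#' (farmland to forest/grassland) area, per epoch interval -- the response
#' stage linking the programme's intervention to the health outcome.
#'
#' @param records data.frame with columns `zone`, `interval`, `d_ehi`,
#'   `d_area` (km^2).
#' @return data.frame per interval: `interval`, `n`, `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided t-test on the slope).
#' @export
response_regression <- function(records) {
  out <- lapply(unique(records$interval), function(iv) {
    r <- records[records$interval == iv, ]
    if (nrow(r) < 3) stop("need >= 3 counties per interval (", iv, ")")
    if (stats::var(r$d_area) == 0)
      stop("restored area has zero variance in interval ", iv)
    fit <- stats::lm(d_ehi ~ d_area, data = r)
    sm <- summary(fit)
    data.frame(interval = iv, n = nrow(r),
               slope = sm$coefficients[2, 1],
               intercept = sm$coefficients[1, 1],
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4])
  })
  do.call(rbind, out)
}

#' Compute the seven PSR indicators of a scenario
#'
#' Raw per-county, per-epoch values: population density (PD) from the
#' county tables; fragmentation (LFI), Shannon diversity (LDI), average
#' patch area (APAI) and ecological resilience (ER) from within-county
#' patch delineation of each land-use map; annual NDVI from the composited
#' stack at the epoch years; and the NPP- and development-adjusted
#' ecosystem service value (ESV) from class areas, climate surfaces and the
#' 2002 socio-economic reference columns.
#'
#' @param scenario a [generate_scenario()] bundle.
#' @param connectivity patch connectivity (4 or 8).
#' @param vc per-class service unit values, see [esv_unit_values()].
#' @param resilience per-class resilience values, see
#'   [resilience_values()].
#' @param npp_reference reference climate (list `pre`, `tmp`) defining the
#'   national NPP denominator; defaults to a continental-mean 630 mm /
#'   8 degC.
#' @return an [indicator_panel()].
#' @export
compute_indicators <- function(scenario, connectivity = 8,
                               vc = esv_unit_values(),
                               resilience = resilience_values(),
                               npp_reference = list(pre = 630, tmp = 8)) {
  cfg <- scenario$config
  zones <- scenario$zones
  counties <- scenario$counties
  epochs <- cfg$epochs
  zl <- as.character(zones$ids)

  # climate-driven NPP, per county and for the national reference
  pre_c <- zonal_aggregate(scenario$climate$pre, zones, "mean")$value
  tmp_c <- zonal_aggregate(scenario$climate$tmp, zones, "mean")$value
  npp_s <- npp(actual_evapo(pre_c, evapo_capacity(tmp_c)))
  npp_cn <- npp(actual_evapo(npp_reference$pre,
                             evapo_capacity(npp_reference$tmp)))
  en <- engel_combine(counties$engel_rural, counties$engel_urban,
                      counties$urban_frac)

  nd <- ndvi_series(scenario$ndvi, zones)
  rows <- list()
  for (k in seq_along(epochs)) {
    y <- epochs[k]
    g <- scenario$lulc[[k]]
    ps <- label_patches(g, zones, connectivity)
    v_lfi <- lfi(ps)
    v_ldi <- shannon_diversity(ps)
    v_apai <- apai(ps)
    v_er <- ecological_resilience(ps, resilience)
    pd <- counties[[paste0("pop_", y)]] / counties$area_km2
    nd_y <- nd[nd$year == y & nd$zone != "region", ]
    v_ndvi <- nd_y$ndvi[match(zl, nd_y$zone)]
    # per-county class areas
    zf <- factor(zones$zone_ids, levels = zones$ids)
    cf <- factor(g$codes, levels = cfg$legend$code,
                 labels = cfg$legend$name)
    area_tab <- table(zf, cf) * cfg$cell_area
    v_esv <- vapply(seq_along(zones$ids), function(i) {
      a <- area_tab[i, ]
      esv_total(stats::setNames(as.numeric(a), colnames(area_tab)), vc,
                npp_s = npp_s[i], npp_cn = npp_cn, en = en[i],
                gdp_ms = counties$gdp_pc[i], gdp_m = cfg$gdp_cn)
    }, numeric(1))
    rows[[k]] <- indicator_panel(
      zone = rep(zones$ids, 7),
      year = y,
      indicator = rep(psr_indicators, each = length(zones$ids)),
      value = c(pd, v_lfi[zl], v_ndvi, v_ldi[zl], v_apai[zl], v_esv,
                v_er[zl])
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("indicator_panel", "data.frame")
  out
}

#' Run the full ecosystem-health assessment pipeline
#'
#' Orchestrates one scenario end to end: generate the synthetic inputs;
#' compute transfer matrices, LCDM scores and restored areas per epoch
#' interval; run the sequential Mann-Kendall test and two-period trends on
#' the regional NDVI series; compute and standardize the seven indicators;
#' derive weights (packaged defaults, or AHP + Monte Carlo when expert
#' matrices are supplied); compose and grade the EHI; and regress the EHI
#' change on restored areas over the post-GGP intervals. Optionally writes
#' the tables as CSV files plus a run log.
#'
#' @param config a [scenario_config()].
#' @param seed random seed for the whole run.
#' @param weights a [weight_set()]; defaults to [default_weights()].
#' @param expert_matrices optional list of pairwise matrices; when given,
#'   weights are derived via [screen_experts()] and
#'   [monte_carlo_weights()].
#' @param out_dir optional output directory for CSV tables.
#' @param connectivity patch connectivity (4 or 8).
#' @param vc,resilience valuation/resilience tables (see
#'   [esv_unit_values()], [resilience_values()]).
#' @return list with elements `config`, `seed`, `transfer` (per-interval
#'   [transfer_matrix()] list), `lcdm` (data.frame with `NA` and a note
#'   where no area changed), `restored`, `mk` (regional
#'   [mk_sequential()]), `trends`, `panel`, `weights`, `ehi` (with
#'   `grade`), `response` (records) and `regression`.
#' @export
run_pipeline <- function(config = scenario_config(), seed = config$seed,
                         weights = NULL, expert_matrices = NULL,
                         out_dir = NULL, connectivity = 8,
                         vc = esv_unit_values(),
                         resilience = resilience_values()) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  scenario <- stage("generate", generate_scenario(config, seed))
  epochs <- config$epochs

  tms <- list(); lcdm_rows <- list(); restored_rows <- list()
  for (k in seq_len(length(epochs) - 1L)) {
    g1 <- scenario$lulc[[k]]; g2 <- scenario$lulc[[k + 1L]]
    tm <- stage("transfer", transfer_matrix(g1, g2))
    tms[[k]] <- tm
    val <- tryCatch(lcdm(tm), error = function(e) NA_real_)
    lcdm_rows[[k]] <- data.frame(
      from_year = epochs[k], to_year = epochs[k + 1L], lcdm = val,
      note = if (is.na(val)) "undefined change (A = 0)" else "")
    ra <- stage("restored", restored_area(g1, g2, scenario$zones))
    ra$from_year <- epochs[k]; ra$to_year <- epochs[k + 1L]
    restored_rows[[k]] <- ra
  }
  names(tms) <- paste(epochs[-length(epochs)], epochs[-1], sep = "_")
  lcdm_df <- do.call(rbind, lcdm_rows)
  restored <- do.call(rbind, restored_rows)

  nd <- stage("ndvi", ndvi_series(scenario$ndvi, scenario$zones))
  reg <- nd[nd$zone == "region", ]
  mk <- stage("mk", mk_sequential(reg$ndvi, reg$year))
  break_year <- if (nrow(mk$turning_points))
    mk$turning_points$year[1] else config$ndvi_break
  trends <- stage("trends", piecewise_trends(reg$ndvi, reg$year, break_year))

  panel <- stage("indicators",
                 compute_indicators(scenario, connectivity, vc, resilience))
  panel <- stage("standardize", standardize_indicators(panel))

  if (is.null(weights)) {
    weights <- if (!is.null(expert_matrices)) {
      acc <- stage("ahp", screen_experts(expert_matrices))
      colnames(acc) <- psr_indicators
      # probe for the stability diagnostic: the first county, last epoch
      probe_sel <- panel$zone == panel$zone[1] &
        panel$year == max(panel$year)
      probe <- panel$std[probe_sel][match(psr_indicators,
                                          panel$indicator[probe_sel])]
      stage("monte_carlo",
            monte_carlo_weights(acc, probe = probe, seed = seed)$weights)
    } else default_weights()
  }

  ehi <- stage("ehi", compose_ehi(panel, weights))
  ehi$grade <- grade_ehi(ehi)

  post <- epochs[epochs >= config$ggp_start]
  records <- do.call(rbind, lapply(seq_len(length(post) - 1L), function(i) {
    iv <- paste(post[i], post[i + 1L], sep = "-")
    e1 <- ehi[ehi$year == post[i], ]
    e2 <- ehi[ehi$year == post[i + 1L], ]
    ra <- restored[restored$from_year == post[i] &
                     restored$to_year == post[i + 1L], ]
    data.frame(zone = e1$zone, interval = iv,
               d_ehi = e2$ehi[match(e1$zone, e2$zone)] - e1$ehi,
               d_area = ra$restored_km2[match(e1$zone, ra$zone)])
  }))
  # a scenario without land-cover change has no restored-area signal to
  # regress on; report the gap rather than aborting the whole run
  regression <- tryCatch(response_regression(records), error = function(e) {
    warning("response regression skipped: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })

  out <- list(config = config, seed = seed, transfer = tms, lcdm = lcdm_df,
              restored = restored, mk = mk, trends = trends, panel = panel,
              weights = weights, ehi = ehi, response = records,
              regression = regression,
              conversion_log = scenario$conversion_log)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(out$panel, "indicators.csv")
  ehi <- as.data.frame(out$ehi)
  ehi$grade <- as.character(ehi$grade)
  wr(ehi, "ehi.csv")
  wr(out$lcdm, "lcdm.csv")
  wr(out$restored, "restored.csv")
  wr(data.frame(year = out$mk$years, ndvi = out$mk$x, uf = out$mk$uf,
                ub = out$mk$ub), "mk_region.csv")
  if (!is.null(out$regression)) wr(out$regression, "regression.csv")
  for (nm in names(out$transfer)) {
    f <- out$transfer[[nm]]$flow
    long <- data.frame(from_class = rep(rownames(f), ncol(f)),
                       to_class = rep(colnames(f), each = nrow(f)),
                       area_km2 = as.vector(f))
    wr(long, paste0("transfer_", nm, ".csv"))
  }
  wr(data.frame(indicator = names(out$weights$weights),
                weight = as.numeric(out$weights$weights)), "weights.csv")
  writeLines(c(paste("seed:", out$seed),
               paste("ecohealth version:",
                     as.character(utils::packageVersion("ecohealth"))),
               paste("R version:", R.version.string)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
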