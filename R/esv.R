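#' Annual mean evapotranspiration capacity
#'
#' Temperature-driven evapotranspiration capacity (mm):
#' \eqn{L = 3000 + 25\,T + 0.05\,T^3}.
#'
#' @param tmp annual mean temperature in degC.
#' @return L in mm.
#' @export
evapo_capacity <- function(tmp) {
  3000 + 25 * tmp + 0.05 * tmp^3
}

#' Annual actual evapotranspiration
#'
#' \eqn{v = 1.05\,P / (1 + (1 + 1.05 P / L)^2)} with precipitation P (mm)
#' and capacity L (mm) -- the quadratic-denominator form of the
#' evapotranspiration model. `form = "sqrt"` selects the
#' square-root-denominator variant
#' \eqn{v = 1.05 P / \sqrt{1 + (1.05 P / L)^2}} common in the
#' evapotranspiration literature.
#'
#' @param pre annual precipitation in mm (>= 0).
#' @param L evapotranspiration capacity in mm (> 0), see
#'   [evapo_capacity()].
#' @param form `"quadratic"` (default) or `"sqrt"`.
#' @return actual evapotranspiration v in mm.
#' @export
actual_evapo <- function(pre, L, form = c("quadratic", "sqrt")) {
  form <- match.arg(form)
  if (any(pre < 0)) stop("precipitation must be >= 0")
  if (any(L <= 0)) stop("evapotranspiration capacity must be > 0")
  r <- 1.05 * pre / L
  if (form == "quadratic") 1.05 * pre / (1 + (1 + r)^2)
  else 1.05 * pre / sqrt(1 + r^2)
}

#' Net primary productivity of natural vegetation
#'
#' Exponential saturation in actual evapotranspiration:
#' \eqn{NPP = 3000\,(1 - e^{-0.0009695 (v - 20)})}, floored at 0, with the
#' 3000 t/ha/a asymptote of the underlying productivity model.
#'
#' @param v actual evapotranspiration in mm, see [actual_evapo()].
#' @return NPP in t/ha/a.
#' @export
npp <- function(v) {
  pmax(3000 * (1 - exp(-0.0009695 * (v - 20))), 0)
}

#' Combined Engel coefficient
#'
#' Urban-share weighted mixture of the rural and urban Engel coefficients:
#' \eqn{E_n = E_{nr} (1 - P_u) + E_{nu} P_u}.
#'
#' @param enr,enu rural and urban Engel coefficients in (0, 1).
#' @param pu urban population fraction in [0, 1].
#' @return combined Engel coefficient.
#' @export
engel_combine <- function(enr, enu, pu) {
  if (any(pu < 0 | pu > 1)) stop("urban fraction must lie in [0, 1]")
  enr * (1 - pu) + enu * pu
}

#' Socio-economic development factor
#'
#' Willingness-to-pay adjustment \eqn{2 / (1 + e^{2.5 - 1/E_n})} times the
#' regional-to-national per-capita GDP ratio. At the typical Engel value
#' 0.4 the logistic term is exactly 1; wealthier populations (lower Engel
#' coefficient) value ecosystem services more.
#'
#' @param en combined Engel coefficient, > 0 (see [engel_combine()]).
#' @param gdp_ratio regional over national per-capita GDP (default 1).
#' @return dimensionless adjustment factor.
#' @export
development_factor <- function(en, gdp_ratio = 1) {
  if (any(en <= 0)) stop("Engel coefficient must be > 0")
  2 / (1 + exp(2.5 - 1 / en)) * gdp_ratio
}

#' Default ecosystem-service unit values (synthetic placeholders)
#'
#' Per-class service value per unit area (yuan/ha). The magnitudes follow
#' the usual ordering of equivalent-factor valuations (water bodies highest,
#' built-up land zero) but are editable placeholders, not a reproduction of
#' any published table; analyses should supply their own values.
#'
#' @param ... named overrides, e.g. `forestland = 20000`.
#' @return named numeric vector of unit values in yuan/ha.
#' @export
esv_unit_values <- function(...) {
  vc <- c(farmland = 6100, forestland = 19300, grassland = 6400,
          water_land = 40700, built_up = 0, unused = 400)
  over <- c(...)
  vc[names(over)] <- over
  if (any(vc < 0)) stop("unit values must be >= 0")
  vc
}

#' Ecosystem service value of a county
#'
#' NPP- and development-adjusted valuation:
#' \deqn{ESV = \sum_k A_k\,VC_k\,\frac{NPP_s}{NPP_{cn}}
#'   \left[\frac{2}{1 + e^{2.5 - 1/E_n}}\,\frac{GDP_{ms}}{GDP_m}\right]}
#' with areas \eqn{A_k} (km^2, converted to ha), national unit values
#' \eqn{VC_k} (yuan/ha), the regional-to-national NPP ratio, and the
#' socio-economic factor of [development_factor()] evaluated at the 2002
#' reference Engel coefficient and per-capita GDP.
#'
#' @param areas_km2 named per-class areas (km^2); names must match `vc`.
#' @param vc named per-class unit values (yuan/ha), see
#'   [esv_unit_values()].
#' @param npp_s regional NPP (t/ha/a).
#' @param npp_cn national NPP (t/ha/a).
#' @param en combined Engel coefficient (2002 reference).
#' @param gdp_ms regional per-capita GDP (yuan, 2002 reference).
#' @param gdp_m national per-capita GDP (yuan, 2002 reference).
#' @return total ecosystem service value in yuan.
#' @export
esv_total <- function(areas_km2, vc, npp_s, npp_cn, en, gdp_ms, gdp_m) {
  if (any(areas_km2 < 0)) stop("areas must be >= 0")
  miss <- setdiff(names(areas_km2)[areas_km2 > 0], names(vc))
  if (length(miss))
    stop("missing unit value for class(es): ", paste(miss, collapse = ", "))
  dev <- development_factor(en, gdp_ms / gdp_m)
  a_ha <- areas_km2 * 100
  sum(a_ha * vc[names(areas_km2)] * (npp_s / npp_cn) * dev)
}
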