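---
title: "Assessing ecosystem health of land-use change scenarios with ecohealth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ecosystem health of land-use change scenarios with ecohealth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assessment problem

Large afforestation programmes such as China's Grain for Green Program
(GGP, from 1999) convert steep farmland to forest and grassland. Whether
such a programme actually improves *ecosystem health* — and where — is a
question about the joint movement of human pressure and ecosystem state,
not about any single map. `ecohealth` implements a county-level assessment
built on the Pressure–State–Response (PSR) framework:

* **Pressure** — population density (PD) and landscape fragmentation (LFI):
  the human load on the landscape.
* **State** — vegetation greenness (NDVI), landscape diversity (LDI),
  average patch area (APAI), ecosystem service value (ESV) and ecological
  resilience (ER): the condition of the ecosystem.
* **Response** — the restored area (farmland converted to forest or
  grassland), related to the health change by regression rather than folded
  into the index.

The ecosystem health index of county $c$ in year $t$ is the weighted sum of
min–max standardized indicators,

$$EHI_{ct} = \sum_i w_i\, x'_{i,ct}, \qquad \sum_i w_i = 1,$$

so $EHI \in [0,1]$ and larger is healthier. Three change-accounting stages
surround the index: a land-use **transfer matrix** between map dates; the
**land-cover change direction model**
$LCDM = 100\,\sum_{i\neq j} A_{ij}(D_j - D_i) / A$, which scores the
transitions by the ecological level $D$ of the classes involved (farmland
0.11, forestland 0.245, water 0.282, unused 0.01, ...); and a
**sequential Mann–Kendall** test on the annual NDVI series to ask whether
the vegetation trend changed at all.

## What the synthetic scenario emulates

All stages are exercised on synthetic data generated by
`scenario_config()` / `generate_scenario()`. The default scenario fixes the
study conditions; they are chosen once to mirror a subtropical GGP pilot
region and are not tuned per analysis:

* a 60 × 90 lattice of 1 km² cells partitioned into **54 counties**;
* six land-use maps (1990, 1995, 2000, 2005, 2010, 2015) evolving by
  cell-independent Markov transitions: background churn, pre-2000
  reclamation of forest/grassland to farmland, and from 2000 a
  farmland→forest/grassland conversion whose intensity increases from west
  to east (programme implementation concentrated in the uplands) and decays
  over successive intervals (afforestation first, consolidation later);
* a bimonthly NDVI stack (1990–2015) whose regional growing-season mean is
  piecewise linear: −0.002/yr before 2000, +0.004/yr after, with annual
  anomaly s.d. 0.005 and per-layer pixel noise 0.01;
* smooth climate surfaces around 1000 mm and 20 °C (the region's
  climatology) and county tables with a west-heavy population gradient and
  2002-reference socio-economics (Engel coefficients, urban fraction,
  per-capita GDP) for the valuation stage.

Cell-independent transitions keep all transfer-matrix expectations
analytic (binomial), which is what the tests exploit; the price is no
spatial contagion, so simulated conversion is salt-and-pepper rather than
clustered. The NDVI stack is generated directly on the analysis grid
(there is no cross-resolution resampling), cloud contamination is only
mimicked through the half-month noise that the maximum-value composite
removes, and climate is constant over the epochs. Passing tests therefore
demonstrate the correctness and statistical behaviour of the *methods*
under clean assumptions, not the remote-sensing error structure of real
archives.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `conversion_intensity` | 0.10 | per-epoch farmland conversion probability in the first post-GGP interval |
| `conversion_gradient` | 1.5 | west→east slope of county conversion multipliers (0.25×–1.75×) |
| `conversion_decay` | 1, 0.6, 0.3 | programme intensity across the three post-2000 intervals |
| `ndvi_slope1`, `ndvi_slope2` | −0.002, +0.004 | annual NDVI trend before/after `ndvi_break` (2000) |
| `connectivity` | 8 | patch neighbourhood; 4 is available and changes patch counts |
| `ecological_levels()` | Table of $D$ | drives the LCDM sign and magnitude; grassland maps to the high-density level by default |
| `esv_unit_values()`, `resilience_values()` | packaged defaults | editable per-class tables; the shipped values are placeholders with the conventional ordering, not a reproduction of any published table |

Weights default to the packaged seven-indicator set (pressure 0.3 = PD
0.20 + LFI 0.10; state 0.7 = NDVI 0.24 + LDI 0.09 + APAI 0.05 + ESV 0.22 +
ER 0.10). When expert pairwise matrices are supplied, weights are derived
by the analytic hierarchy process (principal eigenvector, matrices with
consistency ratio ≥ 0.1 rejected) followed by Monte Carlo stabilization:
10,000 weight vectors drawn componentwise from Gaussians with the accepted
experts' means and s.d.s (negatives clipped, vectors renormalized), a
dispersion-versus-sample-size diagnostic, and a final average over 200
pooled draws. The Gaussian/clip/renormalize choice is the simplest
distribution consistent with matching first and second moments; the
dispersion probe must be a heterogeneous standardized profile (a flat
profile makes the EHI weight-invariant), and the pipeline uses the first
county's standardized values at the final epoch.

## Numerical and design choices

* **Standardization** is pooled over all county-years per indicator
  (benefit: $(x-\min)/(\max-\min)$; cost: reversed), so EHI values are
  comparable across years; per-year standardization is available via
  `by_year = TRUE`. A spread-free indicator standardizes to 0.5 with a
  warning.
* **LCDM** excludes unchanged (diagonal) area from both the numerator and
  the total changed area $A$, and raises an error when $A = 0$ so callers
  can distinguish "no change" from "neutral change".
* **LFI** is computed literally as $(N_t-1)/N_c$ with
  $N_c = \min(\text{patch area})/\text{total area}$, which yields large
  magnitudes; downstream min–max standardization absorbs the scale. The
  inverted reading is available (`nc_inverse = TRUE`).
* **Patches** are delineated within county boundaries when zones are
  supplied (a patch cannot straddle counties), by connected components of
  the same-class adjacency graph.
* **Valuation**: the development factor is $2/(1+e^{2.5-1/E_n})$ — the
  only grouping of the exponent under which the typical Engel value 0.4
  gives exactly a unity factor. The actual-evapotranspiration formula defaults to its
  quadratic-denominator form, $v = 1.05P/(1+(1+1.05P/L)^2)$, with a
  square-root-denominator variant (`form = "sqrt"`) because the quadratic
  form plausibly arose from a radical lost in typesetting. NPP is computed per county
  from zonal climate means; the national denominator defaults to the model
  evaluated at a continental reference climate (630 mm, 8 °C) and is
  configurable.
* **Grades** are an equal-interval classification of the pooled EHI range
  into 8 ordered classes (I–VIII); the grade count is a convention and is
  exposed as a parameter.
* **Ties** in the sequential MK statistic contribute nothing to the count
  and the tie-free variance is used; annual NDVI means make exact ties
  practically impossible.

## The turning-point test: what it can and cannot find

`mk_sequential()` computes the forward statistic $UF_k$ from the
concordant-pair count $t_k$ (with $E(t_k) = k(k-1)/4$ and
$Var(t_k) = k(k-1)(2k+5)/72$) and the backward statistic $UB$ from the
reversed series (negated and re-aligned). `detect_turning_points()`
reports every interior sign change of $UF - UB$, interpolated to the
nearer year.

Two properties were established by simulation and shape both the defaults
and the honest limits of the method:

1. **Significance.** Flagging a crossing when $|UF|$ exceeds 1.96
   *anywhere* after it is anti-conservative: on 26-point white noise it
   fires in about 23% of series, because it maximizes over many correlated
   values. The default rule therefore judges the forward statistic at the
   end of the record — the classical Mann–Kendall test — which is
   5%-calibrated by construction; the any-exceedance reading remains
   available (`significance = "max"`).
2. **Location.** The $UF/UB$ intersection locates *mean shifts*: for a
   level step at 2000 it lands within ±2 years in the large majority of
   simulated series. For a *slope* break — the piecewise-linear NDVI
   signal the generator produces — the crossing systematically lags the
   vertex by about a decade (deterministically at 2012 for the default
   noise-free V shape), because the crossing balances cumulative rank
   statistics rather than locating the change in derivative. Users looking
   for slope breaks should read the extremum of $UF$, or fit
   `piecewise_trends()` at candidate years, rather than rely on the
   intersection.

## Problem sizes used by the tests

The packaged test-suite and acceptance script run the full pipeline at the
default study scale (54 counties, 60 × 90 cells, 26 NDVI years) for the
effect-direction and response-regression replications (100 paired seeded
runs), and smaller lattices (20 × 30, 12 × 18) for module-level
simulations where only the regional series or a single mechanism is under
test. These sizes were chosen so a complete replication is a few minutes
of computation on one core while keeping every statistical check at the
scale its expectation was derived for.

## Known limitations

* No reprojection or resampling: all rasters must share one lattice, and
  the TIFF I/O carries no georeferencing tags.
* The Markov land-use generator has no spatial contagion and no
  class-persistence heterogeneity; restored areas are exact bookkeeping of
  realised draws, which real change detection never is.
* Climate (and hence NPP and ESV's climatic part) is constant across
  epochs; ESV dynamics come entirely from class-area change.
* The intersection-based turning-point test lags slope-type breaks, as
  discussed above.
* The unit-value and resilience tables are editable placeholders;
  substantive valuation conclusions require supplying real tables.

## A minimal run

```r
library(ecohealth)
res <- run_pipeline(scenario_config(), seed = 1)
res$lcdm          # change-direction score per epoch interval
res$mk            # sequential MK test of the regional NDVI series
head(res$ehi)     # county EHI, dimension subtotals, grade
res$regression    # EHI change vs restored area, per interval
```

Every table in the result bundle can be written as CSV by passing
`out_dir`, together with a run log recording the seed and package
version.
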