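#' Indicator weight set
#'
#' Weights for the seven pressure/state indicators, grouped by dimension:
#' pressure carries population density (PD) and landscape fragmentation
#' (LFI); state carries NDVI, landscape diversity (LDI), average patch area
#' (APAI), ecosystem service value (ESV) and ecological resilience (ER).
#' Dimension weights are the sums of their indicator weights; all weights
#' must be non-negative and sum to 1.
#'
#' @param weights named numeric vector over the seven indicators.
#' @return object of class `weight_set`.
#' @seealso [default_weights()]
#' @export
weight_set <- function(weights) {
  dims <- c(PD = "pressure", LFI = "pressure", NDVI = "state",
            LDI = "state", APAI = "state", ESV = "state", ER = "state")
  miss <- setdiff(names(dims), names(weights))
  if (length(miss))
    stop("missing indicator weight(s): ", paste(miss, collapse = ", "))
  w <- weights[names(dims)]
  if (any(w < 0)) stop("weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must sum to 1")
  structure(list(weights = w, dimensions = dims,
                 dimension_weights = tapply(w, dims, sum)),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight_set (pressure ", round(x$dimension_weights["pressure"], 3),
      ", state ", round(x$dimension_weights["state"], 3), ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Default indicator weights
#'
#' The packaged final weight set of the seven-indicator PSR system
#' (pressure 0.3: PD 0.20, LFI 0.10; state 0.7: NDVI 0.24, LDI 0.09,
#' APAI 0.05, ESV 0.22, ER 0.10), read from the YAML file shipped in
#' `inst/extdata/default_weights.yaml`. Used whenever no expert elicitation
#' input is supplied.
#'
#' @return a [weight_set()].
#' @export
default_weights <- function() {
  path <- system.file("extdata", "default_weights.yaml",
                      package = "ecohealth")
  w <- unlist(yaml::read_yaml(path)$weights)
  weight_set(w)
}

# Saaty random consistency indices for n = 1..10
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP priority weights and consistency ratio
#'
#' Principal-eigenvector weights of a positive reciprocal pairwise
#' comparison matrix, with Saaty's consistency ratio
#' \eqn{CR = \frac{(\lambda_{max} - n)/(n - 1)}{RI(n)}}.
#'
#' @param pm n x n positive reciprocal matrix, 3 <= n <= 10.
#' @param tol tolerance for the reciprocity check.
#' @return list with `weights` (normalized, summing to 1), `lambda_max`,
#'   `ci` and `cr`.
#' @export
ahp_weights <- function(pm, tol = 1e-8) {
  n <- nrow(pm)
  if (!is.matrix(pm) || ncol(pm) != n) stop("pairwise matrix must be square")
  if (n < 3 || n > 10) stop("pairwise matrix must be 3x3 to 10x10")
  if (any(pm <= 0)) stop("pairwise entries must be positive")
  if (max(abs(pm * t(pm) - 1)) > tol)
    stop("matrix is not reciprocal (m[j,i] must equal 1/m[i,j])")
  e <- eigen(pm)
  k <- which.max(Re(e$values))
  lambda <- Re(e$values[k])
  w <- Re(e$vectors[, k])
  w <- abs(w) / sum(abs(w))
  ci <- (lambda - n) / (n - 1)
  list(weights = w, lambda_max = lambda, ci = ci, cr = ci / saaty_ri[n])
}

#' Screen expert matrices by consistency
#'
#' Keeps the weight vectors of the matrices whose consistency ratio is
#' below the threshold (the conventional CR < 0.1 acceptance rule).
#'
#' @param matrices list of pairwise comparison matrices.
#' @param cr_threshold acceptance threshold (default 0.1).
#' @return matrix of accepted weight vectors (one row per accepted expert),
#'   with attribute `cr` holding all consistency ratios.
#' @export
screen_experts <- function(matrices, cr_threshold = 0.1) {
  if (!length(matrices)) stop("need at least one matrix")
  res <- lapply(matrices, ahp_weights)
  cr <- vapply(res, `[[`, numeric(1), "cr")
  keep <- cr < cr_threshold
  if (!any(keep))
    stop("no expert matrix passed the consistency test (all CR >= ",
         cr_threshold, ")")
  acc <- do.call(rbind, lapply(res[keep], `[[`, "weights"))
  attr(acc, "cr") <- cr
  acc
}

#' Monte Carlo weight stabilization
#'
#' Smooths expert disagreement into a final weight set: (1) a pool of
#' `pool_size` weight vectors is drawn, each component Gaussian with the
#' accepted experts' per-indicator mean and s.d., negative draws clipped to
#' zero and each vector renormalized to sum 1; (2) for each candidate
#' sample size N, `reps` random subsets of N pool vectors are averaged and
#' the dispersion of the EHI they induce on a probe indicator profile is
#' recorded (the box-plot-per-N diagnostic -- dispersion stabilizes as N
#' grows); (3) the final weights are the mean of `final_capacity` pooled
#' draws, renormalized. When the accepted vectors are identical (zero
#' s.d.), the pool is degenerate and the final weights equal them exactly.
#'
#' @param accepted matrix of accepted weight vectors (rows), e.g. from
#'   [screen_experts()]; column names are taken as indicator names (the
#'   seven PSR indicators by default).
#' @param pool_size pool of simulated weight vectors (default 10000).
#' @param sample_sizes candidate sample sizes N (default 8:400).
#' @param reps repetitions per N (default 100).
#' @param final_capacity sample capacity of the final weights
#'   (default 200).
#' @param probe standardized indicator values of the probe landscape unit
#'   used for the EHI-dispersion diagnostic; it must be heterogeneous for
#'   weight variation to move the EHI at all (default: a profile spread
#'   evenly over 0.1..0.9).
#' @param seed random seed.
#' @return list with `weights` (a [weight_set()] when the columns are the
#'   seven PSR indicators, otherwise a named numeric vector), `stability`
#'   (data.frame `n`, `ehi_sd`), `pool_mean` and `pool_sd`.
#' @export
monte_carlo_weights <- function(accepted, pool_size = 10000,
                                sample_sizes = 8:400, reps = 100,
                                final_capacity = 200, probe = NULL,
                                seed = NULL) {
  accepted <- as.matrix(accepted)
  if (nrow(accepted) < 2) stop("need at least two accepted weight vectors")
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(accepted)
  ind <- colnames(accepted) %||% c("PD", "LFI", "NDVI", "LDI", "APAI",
                                   "ESV", "ER")[seq_len(k)]
  if (is.null(probe)) probe <- seq(0.1, 0.9, length.out = k)
  mu <- colMeans(accepted)
  sd_i <- apply(accepted, 2, stats::sd)

  as_weights <- function(w) {
    names(w) <- ind
    if (identical(sort(ind), sort(c("PD", "LFI", "NDVI", "LDI", "APAI",
                                    "ESV", "ER"))))
      weight_set(w) else w
  }

  if (all(sd_i < 1e-12)) {
    final <- mu / sum(mu)
    stability <- data.frame(n = sample_sizes, ehi_sd = 0)
    return(list(weights = as_weights(final), stability = stability,
                pool_mean = mu, pool_sd = sd_i))
  }

  pool <- matrix(stats::rnorm(pool_size * k, rep(mu, each = pool_size),
                              rep(sd_i, each = pool_size)),
                 pool_size, k)
  pool[pool < 0] <- 0
  rs <- rowSums(pool)
  bad <- rs <= 0
  if (any(bad)) { pool[bad, ] <- rep(mu, each = sum(bad)); rs[bad] <- sum(mu) }
  pool <- pool / rs

  ehi_sd <- vapply(sample_sizes, function(N) {
    ehis <- vapply(seq_len(reps), function(r) {
      wbar <- colMeans(pool[sample.int(pool_size, N), , drop = FALSE])
      sum(wbar / sum(wbar) * probe)
    }, numeric(1))
    stats::sd(ehis)
  }, numeric(1))

  final <- colMeans(pool[sample.int(pool_size, final_capacity), ,
                         drop = FALSE])
  final <- final / sum(final)
  list(weights = as_weights(final),
       stability = data.frame(n = sample_sizes, ehi_sd = ehi_sd),
       pool_mean = mu, pool_sd = sd_i)
}
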