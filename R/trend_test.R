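#' Sequential Mann-Kendall test
#'
#' Computes the forward (UF) and backward (UB) sequential Mann-Kendall
#' statistics of an annual series. For the forward pass, with
#' \eqn{t_k = \#\{(i,j): i < j \le k,\; x_j > x_i\}}, the statistic is
#' \deqn{UF_k = \frac{t_k - k(k-1)/4}{\sqrt{k(k-1)(2k+5)/72}}}
#' (with \eqn{UF_1 = 0}). UB is the same statistic computed from the
#' reversed series with its sign negated, re-aligned to the original
#' years. An intersection of the UF and UB traces marks a candidate trend
#' turning point; see [detect_turning_points()]. Ties contribute nothing to
#' \eqn{t_k} and the tie-free variance is used.
#'
#' @param x annual values (no missing values, length >= 4).
#' @param years optional year labels (default `seq_along(x)`).
#' @param alpha significance level of the turning-point test (default 0.05,
#'   critical value 1.96).
#' @return object of class `mk_sequential`: list with `years`, `x`, `uf`,
#'   `ub`, `alpha`, `critical` and `turning_points` (as from
#'   [detect_turning_points()]).
#' @export
mk_sequential <- function(x, years = seq_along(x), alpha = 0.05) {
  if (anyNA(x)) stop("series must not contain missing values")
  n <- length(x)
  if (n < 4L) stop("series too short: need at least 4 values")
  if (length(years) != n) stop("`years` must match the series length")
  critical <- stats::qnorm(1 - alpha / 2)
  seq_stat <- function(v) {
    u <- numeric(n)
    t_k <- 0
    for (k in 2:n) {
      t_k <- t_k + sum(v[k] > v[1:(k - 1)])
      e_k <- k * (k - 1) / 4
      var_k <- k * (k - 1) * (2 * k + 5) / 72
      u[k] <- (t_k - e_k) / sqrt(var_k)
    }
    u
  }
  uf <- seq_stat(x)
  ub <- -rev(seq_stat(rev(x)))
  res <- structure(list(years = years, x = x, uf = uf, ub = ub,
                        alpha = alpha, critical = critical),
                   class = "mk_sequential")
  res$turning_points <- detect_turning_points(res)
  res
}

#' Detect turning points from sequential MK statistics
#'
#' A turning point is reported wherever the difference UF - UB changes sign
#' between consecutive years (or is exactly zero at an interior year). A
#' between-year crossing is placed by linear interpolation and assigned to
#' the nearer year. Crossings resolving to the first or last year are not
#' reported: turning points lie strictly inside the series.
#'
#' Significance at the 95% level is judged, by default, on the forward
#' statistic at the end of the record -- the classical Mann-Kendall test of
#' the full series -- so that on trend-free noise a significant turning
#' point is reported in about 5% of series. `significance = "max"` instead
#' flags a crossing whenever |UF| exceeds the critical value anywhere after
#' it (the visual reading of sequential-MK plots); note that this
#' exceedance rule is anti-conservative on white noise because it takes a
#' maximum over many correlated values.
#'
#' @param res a [mk_sequential()] result.
#' @param significance `"final"` (default) or `"max"`, see Details.
#' @return data.frame with columns `year` and `significant` (logical);
#'   zero rows when the traces never intersect.
#' @export
detect_turning_points <- function(res, significance = c("final", "max")) {
  significance <- match.arg(significance)
  uf <- res$uf; ub <- res$ub; years <- res$years
  n <- length(uf)
  d <- uf - ub
  out <- list()
  for (k in seq_len(n - 1L)) {
    idx <- NULL
    if (d[k] == 0) {
      if (k > 1L) idx <- k
    } else if (d[k] * d[k + 1L] < 0) {
      frac <- d[k] / (d[k] - d[k + 1L])
      idx <- if (frac <= 0.5) k else k + 1L
    }
    if (is.null(idx) || idx <= 1L || idx >= n) next
    post <- uf[(k + 1L):n]
    sig <- if (significance == "max") max(abs(post)) > res$critical
           else abs(uf[n]) > res$critical
    out[[length(out) + 1L]] <- data.frame(year = years[idx],
                                          significant = sig)
  }
  if (!length(out))
    return(data.frame(year = numeric(0), significant = logical(0)))
  tp <- do.call(rbind, out)
  tp[!duplicated(tp$year), , drop = FALSE]
}

#' Two-period linear trends around a break year
#'
#' Ordinary least-squares fits of the series on the years up to and
#' including the break, and from the break onwards.
#'
#' @param x annual values.
#' @param years year labels.
#' @param break_year break year (must leave >= 2 points on each side).
#' @return data.frame with columns `segment`, `from`, `to`, `slope`,
#'   `intercept`.
#' @export
piecewise_trends <- function(x, years, break_year) {
  s1 <- years <= break_year
  s2 <- years >= break_year
  if (sum(s1) < 2L || sum(s2) < 2L)
    stop("need at least 2 points on each side of the break")
  fit <- function(sel) stats::coef(stats::lm(x[sel] ~ years[sel]))
  c1 <- fit(s1); c2 <- fit(s2)
  data.frame(
    segment = c("before", "after"),
    from = c(min(years[s1]), min(years[s2])),
    to = c(max(years[s1]), max(years[s2])),
    slope = c(c1[2], c2[2]),
    intercept = c(c1[1], c2[1]),
    row.names = NULL
  )
}

#' @export
print.mk_sequential <- function(x, ...) {
  cat("Sequential Mann-Kendall test, n =", length(x$x), "\n")
  cat("UF range:", sprintf("%.3f .. %.3f", min(x$uf), max(x$uf)),
      " critical:", x$critical, "\n")
  if (nrow(x$turning_points)) {
    cat("turning points:\n")
    print(x$turning_points, row.names = FALSE)
  } else cat("no turning point (UF and UB do not intersect)\n")
  invisible(x)
}

#' Plot sequential MK statistics
#'
#' UF and UB traces with the significance band and detected turning points.
#'
#' @param x a [mk_sequential()] result.
#' @param ... passed to [plot()].
#' @export
plot.mk_sequential <- function(x, ...) {
  rng <- range(c(x$uf, x$ub, x$critical, -x$critical))
  plot(x$years, x$uf, type = "l", ylim = rng, xlab = "year",
       ylab = "sequential MK statistic", ...)
  graphics::lines(x$years, x$ub, lty = 2)
  graphics::abline(h = c(-x$critical, x$critical), col = "grey60", lty = 3)
  if (nrow(x$turning_points))
    graphics::abline(v = x$turning_points$year, col = "red3", lty = 3)
  graphics::legend("topleft", c("UF", "UB"), lty = 1:2, bty = "n")
  invisible(x)
}
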