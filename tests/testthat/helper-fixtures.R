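# Small, fast scenario used across module tests: 6 counties on a 12 x 18
# lattice, same epoch structure and dynamics as the default scenario.
small_config <- function(...) {
  scenario_config(nrow = 12, ncol = 18, n_county = 6, ...)
}

# Independent flood-fill patch labeller (queue-based), used as the oracle
# for the graph-based implementation in label_patches().
flood_fill_patches <- function(codes, nodata = 0L, connectivity = 8,
                               zone = NULL) {
  nr <- nrow(codes); nc <- ncol(codes)
  if (is.null(zone)) zone <- matrix(1L, nr, nc)
  lab <- matrix(NA_integer_, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (codes[i, j] == nodata || zone[i, j] == 0L || !is.na(lab[i, j])) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        r <- p[1] + nb[q, 1]; s <- p[2] + nb[q, 2]
        if (r < 1 || r > nr || s < 1 || s > nc) next
        if (!is.na(lab[r, s])) next
        if (codes[r, s] != codes[p[1], p[2]]) next
        if (codes[r, s] == nodata || zone[r, s] == 0L) next
        if (zone[r, s] != zone[p[1], p[2]]) next
        lab[r, s] <- cur
        queue[[length(queue) + 1L]] <- c(r, s)
      }
    }
  }
  lab
}

# Brute-force sequential MK statistic by explicit pair enumeration,
# independent of the incremental implementation in mk_sequential().
brute_uf <- function(x) {
  n <- length(x)
  u <- numeric(n)
  for (k in 2:n) {
    t_k <- 0
    for (j in 2:k) for (i in 1:(j - 1)) if (x[j] > x[i]) t_k <- t_k + 1
    u[k] <- (t_k - k * (k - 1) / 4) / sqrt(k * (k - 1) * (2 * k + 5) / 72)
  }
  u
}

# A consistent pairwise matrix built from a weight vector.
consistent_matrix <- function(w) outer(w, w, "/")
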