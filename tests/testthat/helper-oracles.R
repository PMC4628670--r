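# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: the fixpoint check enumerates rules by
# brute force, the boundary checker replays the scan criteria with
# plain arithmetic, and the metric oracles enumerate matrix rows
# directly.

# Count the (cell, range) pairs whose transition rule would fire on a
# static lattice: d(x_i, x_{i+1}) > d(x_i, x_{i+r-1}), indices mod N.
brute_force_triggers <- function(order, D, R) {
  n <- length(order)
  triggers <- 0L
  for (i in seq_len(n)) {
    xi <- order[i]
    xnext <- order[i %% n + 1L]
    for (r in 3:R) {
      xfar <- order[(i + r - 2L) %% n + 1L]
      if (D[xi, xnext] > D[xi, xfar]) triggers <- triggers + 1L
    }
  }
  triggers
}

# Plain re-implementation of one sweep as a loop of apply_rule calls;
# used to pin the compiled sweep to the documented per-cell semantics.
reference_sweep <- function(order, D, R) {
  swaps <- 0L
  for (i in seq_along(order)) {
    for (r in 3:R) {
      res <- apply_rule(order, i, r, D)
      order <- res$order
      if (res$swapped) swaps <- swaps + 1L
    }
  }
  list(order = order, swaps = swaps)
}

# Post-hoc verification that every declared cluster start satisfies the
# three boundary criteria and the minimum-size rule, recomputing the
# running statistics naively from the chainmap.
check_declared_boundaries <- function(cm, starts, min_size) {
  d <- cm$distances
  n <- length(d)
  avg <- cm$avg
  starts <- sort(starts)
  ok <- TRUE
  for (si in seq_along(starts)) {
    i <- starts[si]
    if (i == 1L) next                       # scan origin, not a declared boundary
    prev_start <- max(starts[starts < i])
    # within-cluster consecutive distances of the preceding cluster,
    # excluding the gap that opened it
    vals <- if (i - 1L > prev_start) d[prev_start:(i - 2L)] else numeric(0)
    avg_k <- if (length(vals)) mean(vals) else 0
    sd_k <- if (length(vals)) sqrt(mean((vals - avg_k)^2)) else 0
    d_prev <- d[i - 1L]
    d_here <- d[i]
    d_next <- d[if (i < n) i + 1L else 1L]
    ok <- ok &&
      (i - prev_start) >= min_size &&
      d_here < avg &&
      d_prev > max(avg, avg_k + sd_k) &&
      d_prev > d_here && d_here > d_next
  }
  ok
}

# A random "clusterable" spectrum instance: g well-separated centres on
# the probability simplex with small within-group jitter.  Returns a
# dense distance matrix.
random_cluster_instance <- function(n, g = NULL, dim = 16, jitter = 0.01) {
  if (is.null(g)) g <- sample(2:4, 1)
  centers <- matrix(stats::rgamma(g * dim, 0.5), g)
  centers <- centers / rowSums(centers)
  grp <- sort(sample.int(g, n, replace = TRUE))
  X <- centers[grp, , drop = FALSE] +
    matrix(stats::rnorm(n * dim, 0, jitter), n)
  X <- abs(X)
  X <- X / rowSums(X)
  list(D = as.matrix(stats::dist(X)), group = grp)
}

# Random nucleotide string (unambiguous bases only unless stated).
random_read <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Two-plateau chainmap with a mildly decreasing jitter inside each
# block, so that the strictly-decreasing boundary criterion can fire at
# the block gap: block sizes b1/b2, gap height `gap`, seam entry low.
two_block_chainmap <- function(b1 = 40L, b2 = 40L, gap = 100) {
  base1 <- 1 + 0.01 * rev(seq_len(b1 - 1L)) / b1
  base2 <- 1 + 0.01 * rev(seq_len(b2)) / b2
  d <- c(base1, gap, base2)          # entry b1 is the inter-block gap
  structure(list(distances = d, avg = mean(d)), class = "chainmap")
}
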