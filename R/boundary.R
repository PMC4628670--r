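#' Chainmap of a converged lattice
#'
#' The chainmap is the sequence of distances between the reads at
#' consecutive cells of the (periodic) lattice: entry `i` is
#' `d(x_i, x_{i+1})`, and entry `N` closes the circle with
#' `d(x_N, x_1)`.  Valleys indicate runs of similar reads, spikes are
#' candidate cluster boundaries.  The global mean of the entries (`avg`)
#' anchors the boundary criteria.
#'
#' @inheritParams run_iteration
#' @return object of class `chainmap`: list with numeric `distances`
#'   (length `N`) and scalar `avg`.
#' @export
compute_chainmap <- function(order, d) {
  n <- length(order)
  if (n < 2) stop("need at least 2 cells for a chainmap", call. = FALSE)
  dfun <- as_dist_fun(d)
  nxt <- c(order[-1], order[1])
  dist <- dfun(order, nxt)
  structure(list(distances = as.numeric(dist), avg = mean(dist)),
            class = "chainmap")
}

#' Rotate the lattice so the widest gap becomes the seam
#'
#' The lattice is circular but the boundary scan is linear, so one true
#' cluster could straddle the `c_N`/`c_1` seam.  Rotating the lattice so
#' that the globally largest consecutive-cell distance lies between
#' `c_N` and `c_1` makes the most plausible inter-cluster gap the seam;
#' the scan then starts at `c_1` inside a cluster.  Ties are broken by
#' the smallest original gap index.
#'
#' @inheritParams compute_chainmap
#' @param chainmap the [compute_chainmap()] of `order`.
#' @return list with rotated `order` and consistently rotated
#'   `chainmap`.
#' @export
rotate_to_seam <- function(order, chainmap) {
  n <- length(order)
  cm <- chainmap$distances
  stopifnot(length(cm) == n)
  m <- which.max(cm)            # gap between cells m and m+1; ties -> first
  if (m < n) {
    shift <- m                  # new c_1 is old c_{m+1}
    order <- c(order[(shift + 1):n], order[1:shift])
    cm <- c(cm[(shift + 1):n], cm[1:shift])
  }
  list(order = order,
       chainmap = structure(list(distances = cm, avg = chainmap$avg),
                            class = "chainmap"))
}

#' Cut the chain into clusters
#'
#' Scans the cells left to right, starting the first cluster at `c_1`.
#' A read `x_i` opens a new cluster iff all of the following hold, where
#' `avg` is the global mean consecutive distance and `avg_k`, `sd_k`
#' are the running mean and (population) standard deviation of the
#' consecutive distances inside the current cluster up to `x_{i-1}`:
#'
#' 1. `d(x_i, x_{i+1}) < avg` — the new start sits in a valley;
#' 2. `d(x_{i-1}, x_i) > max(avg, avg_k + sd_k)` — the gap behind it is
#'    large both globally and relative to the current cluster;
#' 3. `d(x_{i-1}, x_i) > d(x_i, x_{i+1}) > d(x_{i+1}, x_{i+2})` — the
#'    distances fall off monotonically across the boundary, filtering
#'    single-cell noise;
#'
#' and additionally `i` is at least `min_cluster_size` cells past the
#' current cluster's start, which suppresses spurious boundaries driven
#' by the near-zero standard deviation of a freshly opened cluster.
#' When `x_i` opens a cluster, `x_{i-1}` closes the previous one and the
#' running statistics reset.  All comparisons are strict, so a chain of
#' identical distances yields a single cluster.  The running statistics
#' cover within-cluster distances only: the gap that opened the current
#' cluster is excluded.  Near the end of the scan, the lookahead
#' distances wrap around the seam.
#'
#' @param chainmap a [compute_chainmap()], normally after
#'   [rotate_to_seam()].
#' @param min_cluster_size minimum cells between consecutive cluster
#'   starts (default 30, a rule of thumb for read data).
#' @return object of class `cluster_assignment`: list with integer
#'   `labels` (one per cell, contiguous runs), `starts` (first cell of
#'   each cluster) and `K`.
#' @export
detect_boundaries <- function(chainmap, min_cluster_size = 30L) {
  cm <- chainmap$distances
  n <- length(cm)
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1",
                                 call. = FALSE)
  avg <- chainmap$avg
  labels <- integer(n)
  starts <- 1L
  k <- 1L                       # current cluster id
  start <- 1L
  cnt <- 0L; mean_k <- 0; m2 <- 0   # Welford running stats
  labels[1] <- 1L
  if (n >= 2) {
    for (i in 2:n) {
      sd_k <- if (cnt > 0) sqrt(m2 / cnt) else 0
      d_prev <- cm[i - 1L]                  # d(x_{i-1}, x_i)
      d_here <- cm[i]                       # d(x_i, x_{i+1})
      d_next <- cm[if (i < n) i + 1L else 1L]  # d(x_{i+1}, x_{i+2})
      is_start <- (i - start) >= min_cluster_size &&
        d_here < avg &&
        d_prev > max(avg, mean_k + sd_k) &&
        d_prev > d_here && d_here > d_next
      if (is_start) {
        k <- k + 1L
        starts <- c(starts, i)
        start <- i
        cnt <- 0L; mean_k <- 0; m2 <- 0
      } else {
        # d_prev is now a within-cluster distance of cluster k
        cnt <- cnt + 1L
        delta <- d_prev - mean_k
        mean_k <- mean_k + delta / cnt
        m2 <- m2 + delta * (d_prev - mean_k)
      }
      labels[i] <- k
    }
  }
  structure(list(labels = labels, starts = starts, K = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster assignment:", length(x$labels), "cells in", x$K,
      "cluster(s)\n")
  cat("cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "),
      "\n")
  invisible(x)
}
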