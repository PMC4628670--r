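#' Initialise the cellular-automaton lattice
#'
#' Places the reads on the one-dimensional periodic lattice in a
#' uniformly random order determined entirely by `seed`.  Cell `i` of
#' the returned vector holds the index of the read occupying it.
#'
#' @param n_reads number of reads (= number of cells).
#' @param seed integer seed; the same seed always yields the same
#'   permutation.
#' @return an integer permutation of `1:n_reads`.
#' @export
init_lattice <- function(n_reads, seed) {
  if (n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  with_seed(seed, sample.int(n_reads))
}

#' Default rule range R from the lattice size
#'
#' The transition rules have ranges `r = 3..R`.  A larger `R` lets
#' larger clusters coalesce but costs more per iteration.  Because a
#' species bin can span a sizeable fraction of the lattice, the rule
#' range must reach well beyond immediate neighbours: the default is
#' `R = max(3, min(N - 1, ceiling(4 * sqrt(N))))`.  On simulated
#' multi-species data this range reliably pulls each species into a
#' contiguous arc, whereas ranges of order `sqrt(N)` leave species
#' fragmented into many short runs and ranges of order `N` churn
#' without converging (see the package vignette for the diagnostics
#' behind this choice).
#'
#' @param n_cells lattice size, at least 4.
#' @return integer rule range `R >= 3`.
#' @export
compute_R <- function(n_cells) {
  if (n_cells < 4) stop("need at least 4 cells (minimum rule range is 3)",
                        call. = FALSE)
  max(3L, min(n_cells - 1L, as.integer(ceiling(4 * sqrt(n_cells)))))
}

#' Apply one transition rule at one cell
#'
#' Rule `phi_r` at cell `i` looks at the reads in cells `i`, `i+1` and
#' `i+r-1` (indices wrap: the lattice is a circle).  If the read next
#' door is strictly farther from the read at `i` than the one at range
#' `r-1`, the two are exchanged, pulling the closer read next to `i`.
#' Equal distances never swap.
#'
#' This reference implementation is the semantic contract; full sweeps
#' run through the compiled core, which must agree with it exactly.
#'
#' @param order integer permutation (the lattice).
#' @param i cell index in `1..N`.
#' @param r rule range, `3 <= r < N`.
#' @param d distance oracle: a function `d(i, j)` over read indices, a
#'   dense distance matrix, or a [kmer_distance_provider()].
#' @return list with the (possibly updated) `order` and logical
#'   `swapped`.
#' @export
apply_rule <- function(order, i, r, d) {
  n <- length(order)
  if (r < 3 || r >= n) stop("rule range r must satisfy 3 <= r < N",
                            call. = FALSE)
  if (i < 1 || i > n) stop("cell index out of range", call. = FALSE)
  d <- as_dist_fun(d)
  inext <- i %% n + 1L
  ifar  <- (i + r - 2L) %% n + 1L
  swapped <- d(order[i], order[inext]) > d(order[i], order[ifar])
  if (swapped) order[c(inext, ifar)] <- order[c(ifar, inext)]
  list(order = order, swapped = swapped)
}

#' Run one full CA iteration
#'
#' Applies every rule `phi_r`, `r = 3..R`, at every cell `i = 1..N`, in
#' a sequential sweep: cells are visited in ascending order and all
#' rules (ascending `r`) are applied at a cell before moving to the
#' next, with each swap taking effect immediately.  An iteration with
#' zero swaps leaves the lattice unchanged and certifies a fixed point.
#'
#' @inheritParams apply_rule
#' @param R maximum rule range; defaults to [compute_R()].
#' @return list with the updated `order` and the integer `swaps` count.
#' @export
run_iteration <- function(order, d, R = compute_R(length(order))) {
  n <- length(order)
  if (n < 4) stop("need at least 4 cells", call. = FALSE)
  if (R < 3 || R >= n) stop("R must satisfy 3 <= R < N", call. = FALSE)
  dmat <- as_dist_matrix(d, n)
  res <- ca_sweep_cpp(order - 1L, dmat, as.integer(R))
  list(order = res$order + 1L, swaps = res$swaps)
}

#' Iterate the CA to convergence
#'
#' Repeats [run_iteration()] until a full iteration performs no swap:
#' the lattice is then a fixed point of every rule, and `converged` is
#' `TRUE`.  The swap dynamics carries no global objective that every
#' swap decreases, so on some inputs it falls into a limit cycle
#' instead; the run then stops as soon as a lattice state repeats (or
#' at `max_iterations`), a warning is issued, `converged` is `FALSE`,
#' and the returned order is the best-sorted state visited — the one
#' with the smallest total consecutive-cell distance — rather than an
#' arbitrary point of the cycle.
#'
#' @inheritParams run_iteration
#' @param max_iterations safety cap on the number of iterations.
#' @param trace keep a per-iteration snapshot of the lattice order
#'   (an `N x iterations` matrix) for diagnostics?  Off by default.
#' @return an object of class `ca_convergence`: list with `order`
#'   (final lattice), `iterations`, `converged`, `stopped` (one of
#'   `"fixpoint"`, `"cycle"`, `"max_iterations"`), `best_iteration`,
#'   `swaps_per_iteration`, `R`, and optionally `trace`.
#' @export
run_to_convergence <- function(order, d, R = compute_R(length(order)),
                               max_iterations = 1000L, trace = FALSE) {
  n <- length(order)
  if (n < 4) stop("need at least 4 cells", call. = FALSE)
  if (R < 3 || R >= n) stop("R must satisfy 3 <= R < N", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  dmat <- as_dist_matrix(d, n)
  res <- ca_converge_cpp(order - 1L, dmat, as.integer(R),
                         as.integer(max_iterations), isTRUE(trace))
  out <- list(order = res$order + 1L,
              iterations = res$iterations,
              converged = res$converged,
              stopped = res$stopped,
              best_iteration = res$best_iteration,
              swaps_per_iteration = res$swaps_per_iteration,
              R = as.integer(R))
  if (isTRUE(trace)) out$trace <- res$trace + 1L
  if (!res$converged)
    warning("lattice did not reach a fixed point (",
            if (res$stopped == "cycle") "entered a limit cycle"
            else paste0("stopped after ", max_iterations, " iterations"),
            "); returning the best-sorted state visited", call. = FALSE)
  structure(out, class = "ca_convergence")
}

#' @export
print.ca_convergence <- function(x, ...) {
  cat("1D-CA run:", length(x$order), "cells, R =", x$R, "\n")
  cat(switch(x$stopped, fixpoint = "converged",
             cycle = "limit cycle detected",
             "iteration cap reached"),
      "after", x$iterations, "iterations;",
      sum(x$swaps_per_iteration), "swaps in total\n")
  invisible(x)
}

# ---- distance-oracle coercion ----------------------------------------

as_dist_fun <- function(d) {
  if (is.function(d)) return(d)
  if (inherits(d, "kmer_dist_provider")) return(d$d)
  if (is.matrix(d)) return(function(i, j) d[cbind(i, j)])
  stop("distance oracle must be a function, matrix, or provider",
       call. = FALSE)
}

as_dist_matrix <- function(d, n) {
  if (is.matrix(d)) {
    if (nrow(d) != n || ncol(d) != n)
      stop("distance matrix must be ", n, " x ", n, call. = FALSE)
    return(d)
  }
  if (inherits(d, "kmer_dist_provider")) {
    if (d$n != n) stop("provider covers ", d$n, " reads, lattice has ", n,
                       call. = FALSE)
    return(d$matrix())
  }
  if (is.function(d)) {
    D <- outer(seq_len(n), seq_len(n), Vectorize(d))
    return(D)
  }
  stop("distance oracle must be a function, matrix, or provider",
       call. = FALSE)
}
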