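#' Confusion matrix of a binning against truth labels
#'
#' Entry `(i, j)` counts the reads assigned to cluster `i` whose truth
#' label is species `j`.  Cluster and species orderings are
#' deterministic: sorted by first appearance in the input.
#'
#' @param cluster integer/character cluster ids, one per read (named by
#'   read id if available).
#' @param truth species labels aligned with `cluster`, or a named vector
#'   matched by read id.
#' @return integer matrix of class `confusion_matrix` with cluster rows
#'   and species columns.
#' @export
confusion_matrix <- function(cluster, truth) {
  ids <- names(cluster)
  if (!is.null(ids) && !is.null(names(truth))) truth <- truth[ids]
  if (length(truth) != length(cluster))
    stop("cluster and truth labels differ in length", call. = FALSE)
  missing <- is.na(truth)
  if (any(missing)) {
    who <- if (is.null(ids)) which(missing) else ids[missing]
    stop("missing truth label for read(s): ",
         paste(utils::head(who, 5), collapse = ", "), call. = FALSE)
  }
  cl <- factor(cluster, levels = unique(cluster))
  sp <- factor(truth, levels = unique(truth))
  m <- unclass(table(cl, sp))
  names(dimnames(m)) <- NULL
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Call a species for every cluster
#'
#' Each cluster is identified as the species contributing the most reads
#' to it (row-wise arg max).  Ties are broken deterministically in
#' favour of the lowest species index.
#'
#' @param cm a confusion matrix (clusters x species).
#' @return list with `calls` (species index per cluster) and
#'   `index_sets` (for each species, the integer ids of clusters called
#'   as that species; possibly empty).
#' @export
call_species <- function(cm) {
  cm <- as_cm(cm)
  calls <- call_species_cpp(cm)
  ns <- ncol(cm)
  sets <- lapply(seq_len(ns), function(s) which(calls == s))
  names(sets) <- colnames(cm)
  if (!is.null(colnames(cm))) names(calls) <- colnames(cm)[calls]
  list(calls = calls, index_sets = sets)
}

#' Binning precision
#'
#' The fraction of reads that fall in the majority species of their
#' cluster: `sum_i max_j R_ij / sum_ij R_ij`.  Equals 1 iff every
#' cluster is pure.  Because this binner assigns every read to some
#' cluster (there are no unclassified reads), sensitivity and F-measure
#' coincide with precision; [sensitivity()] and [f_measure()] are
#' provided as explicit aliases.
#'
#' @inheritParams call_species
#' @return a number in `[0, 1]`.
#' @export
precision <- function(cm) {
  cm <- as_cm(cm)
  if (sum(cm) == 0) stop("confusion matrix counts no reads", call. = FALSE)
  precision_cpp(cm)
}

#' @rdname precision
#' @export
sensitivity <- function(cm) precision(cm)

#' @rdname precision
#' @export
f_measure <- function(cm) precision(cm)

#' Per-species false-positive rate
#'
#' For species `s`, pools all clusters called as `s` and returns the
#' fraction of their reads that actually come from other species.  If no
#' cluster is called as `s` the rate is undefined and `NA` is returned
#' (not 0: claiming perfect specificity for a species the binner never
#' recovered would be vacuous).
#'
#' @inheritParams call_species
#' @param species species index (column) or name; if omitted, rates for
#'   all species are returned.
#' @return numeric vector of rates in `[0, 1)` (or `NA`).
#' @export
fp_rate <- function(cm, species = NULL) {
  cm <- as_cm(cm)
  rates <- fp_rate_cpp(cm)
  names(rates) <- colnames(cm)
  if (is.null(species)) return(rates)
  if (is.character(species)) {
    if (!species %in% colnames(cm))
      stop("unknown species: ", species, call. = FALSE)
    return(rates[[species]])
  }
  if (species < 1 || species > ncol(cm))
    stop("species index out of range", call. = FALSE)
  rates[[species]]
}

#' Evaluate a binning against truth labels
#'
#' Convenience wrapper producing the standard benchmark report: number
#' of clusters, precision, per-species FP rates, and the full confusion
#' matrix.
#'
#' @inheritParams confusion_matrix
#' @return object of class `binning_evaluation`.
#' @export
evaluate_binning <- function(cluster, truth) {
  cm <- confusion_matrix(cluster, truth)
  structure(list(K = nrow(cm),
                 precision = precision(cm),
                 fp_rates = fp_rate(cm),
                 confusion = cm),
            class = "binning_evaluation")
}

#' @export
print.binning_evaluation <- function(x, ...) {
  cat("binning evaluation\n")
  cat("  clusters (K): ", x$K, "\n", sep = "")
  cat("  precision:    ", format(x$precision, digits = 4), "\n", sep = "")
  cat("  FP rate by species:\n")
  print(round(x$fp_rates, 4))
  cat("  confusion matrix (clusters x species):\n")
  print(unclass(x$confusion))
  invisible(x)
}

as_cm <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m)) stop("expected a confusion matrix", call. = FALSE)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("confusion matrix entries must be >= 0",
                       call. = FALSE)
  m
}

# Batch metrics over many flattened confusion matrices (one per row of
# `flat`, column-major K x Ns layout).  Shares its kernels with
# precision()/fp_rate(); used for large simulation sweeps.
#' Batch precision and FP rates
#'
#' Computes [precision()] and [fp_rate()] for many confusion matrices at
#' once.  Each row of `flat` is one `K x Ns` matrix flattened in
#' column-major order.  Runs through the same compiled kernels as the
#' scalar functions.
#'
#' @param flat numeric matrix, one flattened confusion matrix per row.
#' @param K,Ns dimensions of each confusion matrix.
#' @return list with numeric `precision` (one per row) and `fp_rate`
#'   (rows x Ns matrix).
#' @export
metrics_batch <- function(flat, K, Ns) {
  stopifnot(is.matrix(flat), ncol(flat) == K * Ns)
  storage.mode(flat) <- "double"
  metrics_many_cpp(flat, as.integer(K), as.integer(Ns))
}
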