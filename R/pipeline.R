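#' Bin metagenomic reads with the one-dimensional CA
#'
#' Full pipeline: k-mer spectra -> random lattice -> swap-rule CA to
#' convergence -> chainmap -> seam rotation -> boundary detection ->
#' (optionally) evaluation against truth labels.  Reads shorter than
#' `k` are dropped with a warning rather than failing the run.
#'
#' @param reads a [Biostrings::DNAStringSet], character vector of
#'   sequences, or path handled by [read_reads()].
#' @param k k-mer size for the composition signature (default 5).
#' @param R maximum rule range; `NULL` (default) uses [compute_R()].
#' @param min_cluster_size minimum cluster size for boundary candidacy
#'   (default 30).
#' @param max_iterations CA iteration cap (default 1000).
#' @param seed integer seed (required); the lattice initialisation uses
#'   a stream derived from it.
#' @param truth optional named character vector (read id -> species), or
#'   a truth-TSV path; triggers evaluation.
#' @param trace keep the per-iteration lattice snapshots?
#' @param normalize,distance passed to [kmer_distance_provider()].
#' @return object of class `ca_binning`: list with `cluster` (named
#'   integer vector, read id -> cluster id), `order` (final, rotated
#'   lattice of read indices), `chainmap`, `assignment`, `convergence`,
#'   `R`, `K`, `k`, `seed`, `n_dropped`, and (if truth was supplied)
#'   `evaluation`.
#' @examples
#' sim <- simulate_metagenome(n_reads = 120, genome_length = 2e4,
#'                            seed = 7)
#' res <- bin_reads(sim$reads, min_cluster_size = 10, seed = 7,
#'                  truth = sim$truth)
#' res
#' @export
bin_reads <- function(reads, k = 5L, R = NULL, min_cluster_size = 30L,
                      max_iterations = 1000L, seed, truth = NULL,
                      trace = FALSE, normalize = TRUE,
                      distance = c("euclidean", "manhattan")) {
  if (missing(seed)) stop("a seed is required for a reproducible run",
                          call. = FALSE)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_reads(reads)
  reads <- as_dna(reads)
  if (length(reads) == 0) stop("no reads supplied", call. = FALSE)
  if (is.character(truth) && length(truth) == 1 && file.exists(truth))
    truth <- read_truth_tsv(truth)

  short <- Biostrings::width(reads) < k
  n_dropped <- sum(short)
  if (n_dropped > 0) {
    warning("dropping ", n_dropped, " read(s) shorter than k = ", k,
            call. = FALSE)
    reads <- reads[!short]
  }
  n <- length(reads)
  if (n == 0) stop("all reads are shorter than k = ", k, call. = FALSE)
  if (n < 4) stop("need at least 4 usable reads", call. = FALSE)

  provider <- kmer_distance_provider(reads, k = k, normalize = normalize,
                                     method = match.arg(distance))
  if (is.null(R)) R <- compute_R(n)
  lattice <- init_lattice(n, seed = derive_seed(seed, 2L))
  conv <- run_to_convergence(lattice, provider, R = R,
                             max_iterations = max_iterations,
                             trace = trace)
  chain <- compute_chainmap(conv$order, provider)
  rot <- rotate_to_seam(conv$order, chain)
  assignment <- detect_boundaries(rot$chainmap,
                                  min_cluster_size = min_cluster_size)

  cluster <- setNames(integer(n), names(reads))
  cluster[rot$order] <- assignment$labels

  out <- list(cluster = cluster, order = rot$order,
              chainmap = rot$chainmap, assignment = assignment,
              convergence = conv, R = R, K = assignment$K, k = k,
              seed = seed, n_dropped = n_dropped,
              read_ids = names(reads))
  if (!is.null(truth)) out$evaluation <- evaluate_binning(cluster, truth)
  structure(out, class = "ca_binning")
}

#' @export
print.ca_binning <- function(x, ...) {
  cat("1D-CA binning of", length(x$cluster), "reads ",
      sprintf("(k = %d, R = %d, seed = %s)\n", x$k, x$R,
              format(x$seed)))
  cat("  ", if (x$convergence$converged) "converged" else
        "NOT converged", " after ", x$convergence$iterations,
      " iterations\n", sep = "")
  cat("  clusters (K): ", x$K, "; sizes: ",
      paste(tabulate(x$assignment$labels, x$K), collapse = ", "),
      "\n", sep = "")
  if (x$n_dropped > 0)
    cat("  dropped ", x$n_dropped, " read(s) shorter than k\n", sep = "")
  if (!is.null(x$evaluation)) {
    cat("  precision: ", format(x$evaluation$precision, digits = 4),
        "\n", sep = "")
    cat("  FP rates: ",
        paste(sprintf("%s=%s", names(x$evaluation$fp_rates),
                      format(round(x$evaluation$fp_rates, 4))),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write binning outputs as plot-ready TSV files
#'
#' Writes `assignment.tsv` (read_id, cluster_id), `chainmap.tsv`
#' (cell_index, read_id, distance_to_next), optionally `trace.tsv`
#' (iteration, cell, read_id) when the run kept snapshots, and
#' `evaluation.tsv` (metric, value) when truth labels were evaluated.
#'
#' @param result a [bin_reads()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_binning <- function(result, dir) {
  stopifnot(inherits(result, "ca_binning"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(data.frame(read_id = names(result$cluster),
                 cluster_id = unname(result$cluster)),
      "assignment.tsv")
  tsv(data.frame(cell_index = seq_along(result$order),
                 read_id = result$read_ids[result$order],
                 distance_to_next = result$chainmap$distances),
      "chainmap.tsv")
  if (!is.null(result$convergence$trace)) {
    tr <- result$convergence$trace
    tsv(data.frame(iteration = rep(seq_len(ncol(tr)), each = nrow(tr)),
                   cell = rep(seq_len(nrow(tr)), times = ncol(tr)),
                   read_id = result$read_ids[as.vector(tr)]),
        "trace.tsv")
  }
  if (!is.null(result$evaluation)) {
    ev <- result$evaluation
    tsv(data.frame(metric = c("K", "precision",
                              paste0("fp_rate.", names(ev$fp_rates))),
                   value = c(ev$K, ev$precision, unname(ev$fp_rates))),
        "evaluation.tsv")
  }
  invisible(dir)
}
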