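#' k-mer spectrum of a single read
#'
#' Counts every length-`k` window of the sequence whose characters are all
#' unambiguous bases (A, C, G, T; case-insensitive), indexed
#' lexicographically over the `4^k` possible k-mers.  Windows containing
#' any ambiguity code (N, R, Y, ...) are skipped.  With
#' `normalize = TRUE` (the default) counts are divided by the number of
#' valid windows so that reads of different lengths are comparable; a
#' read with no valid window yields the all-zero vector.
#'
#' Reverse complements are *not* collapsed: the spectrum lives in the
#' full `4^k`-dimensional space (1024 dimensions for the default
#' `k = 5`), not the canonical-k-mer space.
#'
#' @param sequence a single nucleotide string (or [Biostrings::DNAString]).
#' @param k word size, an integer in 1..8.
#' @param normalize divide counts by the number of valid windows?
#' @param id optional read identifier used in error messages.
#' @return a named numeric vector of length `4^k`.
#' @examples
#' kmer_spectrum("ACGT", k = 2)   # 1/3 at AC, CG, GT
#' @export
kmer_spectrum <- function(sequence, k = 5L, normalize = TRUE, id = NULL) {
  stopifnot(k >= 1L, k <= 8L)
  seq <- Biostrings::DNAString(as.character(sequence))
  if (length(seq) < k) {
    stop("read ", if (is.null(id)) "" else paste0("'", id, "' "),
         "is shorter than k = ", k, " (length ", length(seq), ")",
         call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(seq, width = k)
  v <- as.numeric(counts)
  names(v) <- names(counts)
  if (normalize) {
    nw <- sum(v)
    if (nw > 0) v <- v / nw
  }
  v
}

#' k-mer spectra of a set of reads
#'
#' Vectorised form of [kmer_spectrum()]: one row per read, `4^k` columns
#' in lexicographic k-mer order.  Reads shorter than `k` are rejected
#' with a message naming the offending ids.
#'
#' @param reads a [Biostrings::DNAStringSet], or a character vector of
#'   sequences (names become read ids).
#' @inheritParams kmer_spectrum
#' @return numeric matrix with one row per read.
#' @export
kmer_spectra <- function(reads, k = 5L, normalize = TRUE) {
  stopifnot(k >= 1L, k <= 8L)
  reads <- as_dna(reads)
  short <- Biostrings::width(reads) < k
  if (any(short)) {
    ids <- names(reads)[short]
    if (is.null(ids)) ids <- which(short)
    stop("reads shorter than k = ", k, ": ",
         paste(utils::head(ids, 5), collapse = ", "),
         if (sum(short) > 5) " ..." else "", call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(reads, width = k)
  m <- matrix(as.numeric(counts), nrow = nrow(counts),
              dimnames = list(names(reads), colnames(counts)))
  if (normalize) {
    nw <- rowSums(m)
    nz <- nw > 0
    m[nz, ] <- m[nz, , drop = FALSE] / nw[nz]
  }
  m
}

#' Distance between two k-mer spectra
#'
#' The dissimilarity between two reads is the norm of the difference of
#' their feature vectors; the Euclidean (L2) norm is the default, with
#' the Manhattan (L1) norm available as a variant.
#'
#' @param a,b numeric feature vectors of identical length.
#' @param method `"euclidean"` (default) or `"manhattan"`.
#' @return a single non-negative number.
#' @export
kmer_distance <- function(a, b, method = c("euclidean", "manhattan")) {
  method <- match.arg(method)
  if (length(a) != length(b))
    stop("feature vectors have different dimensions (",
         length(a), " vs ", length(b), ")", call. = FALSE)
  d <- a - b
  switch(method,
         euclidean = sqrt(sum(d * d)),
         manhattan = sum(abs(d)))
}

#' Pairwise-distance provider over a read set
#'
#' Precomputes the k-mer spectra of all reads once and exposes (i) a
#' distance function `d(i, j)` over read indices and (ii) the full dense
#' distance matrix used by the cellular-automaton core.  Deterministic:
#' repeated calls agree with recomputing [kmer_distance()] from scratch.
#'
#' @inheritParams kmer_spectra
#' @param method distance norm, see [kmer_distance()].
#' @return an object of class `kmer_dist_provider` with elements
#'   `features` (reads x 4^k matrix), `d` (function of two index
#'   vectors), `matrix()` (returns the dense N x N distance matrix,
#'   computed lazily and cached), `n`, `k`, and `method`.
#' @export
kmer_distance_provider <- function(reads, k = 5L, normalize = TRUE,
                                   method = c("euclidean", "manhattan")) {
  method <- match.arg(method)
  X <- kmer_spectra(reads, k = k, normalize = normalize)
  n <- nrow(X)
  cache <- new.env(parent = emptyenv())
  d <- function(i, j) {
    if (any(i < 1 | i > n | j < 1 | j > n))
      stop("read index out of range 1..", n, call. = FALSE)
    D <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    out <- if (method == "euclidean") sqrt(rowSums(D * D))
           else rowSums(abs(D))
    unname(out)
  }
  mat <- function() {
    if (!is.null(cache$D)) return(cache$D)
    D <- if (method == "euclidean") euclidean_matrix(X)
         else as.matrix(stats::dist(X, method = "manhattan"))
    dimnames(D) <- NULL
    cache$D <- D
    D
  }
  structure(list(features = X, d = d, matrix = mat, n = n, k = k,
                 method = method),
            class = "kmer_dist_provider")
}

# Dense Euclidean distance matrix via the Gram-matrix identity
# |x - y|^2 = |x|^2 + |y|^2 - 2 x.y  (BLAS-backed, much faster than
# stats::dist for thousands of kilo-dimensional spectra).
euclidean_matrix <- function(X) {
  G <- tcrossprod(X)
  n2 <- diag(G)
  D2 <- outer(n2, n2, "+") - 2 * G
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  diag(D) <- 0
  D
}

# Coerce character vectors (and friends) to a DNAStringSet, generating
# ids when none are present.
as_dna <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) return(reads)
  x <- Biostrings::DNAStringSet(as.character(reads))
  if (is.null(names(x)) && !is.null(names(reads))) names(x) <- names(reads)
  if (is.null(names(x))) names(x) <- sprintf("read_%06d", seq_along(x))
  x
}
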