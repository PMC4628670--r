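#' Synthesize a random genome with a distinct k-mer composition
#'
#' Draws an order-`markov_order` Markov model over A/C/G/T (transition
#' rows sampled from a flat Dirichlet) and generates a genome from it.
#' Different seeds give compositionally distinct "species", which is
#' what a composition-based binner needs from its test data; none of
#' the biological structure of a real genome (genes, repeats, GC skew)
#' is emulated.
#'
#' @param length genome length in bases.
#' @param markov_order order of the generating chain, 0..3.
#' @param seed integer seed; the genome is a deterministic function of
#'   `(length, markov_order, seed)`.
#' @return a single nucleotide string.
#' @export
synthesize_genome <- function(length, markov_order = 2L, seed) {
  stopifnot(length >= 1, markov_order %in% 0:3)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    m <- as.integer(markov_order)
    nctx <- 4L^m
    # rows of transition probabilities, one per length-m context
    trans <- matrix(stats::rgamma(nctx * 4L, shape = 1), nrow = nctx)
    trans <- trans / rowSums(trans)
    cum <- t(apply(trans, 1L, cumsum))
    out <- integer(length)
    u <- stats::runif(length)
    ctx <- 0L                       # index of current length-m context
    pow <- if (m > 0) 4L^(m - 1L) else 1L
    for (i in seq_len(length)) {
      row <- ctx + 1L
      b <- findInterval(u[i], cum[row, ], left.open = TRUE) + 1L
      out[i] <- b
      if (m > 0) ctx <- (ctx %% pow) * 4L + (b - 1L)
    }
    paste(bases[out], collapse = "")
  })
}

#' Build a set of species models
#'
#' @param n_species number of species.
#' @param abundance positive abundance weights (recycled/normalised).
#' @param genome_length genome length per species, in bases.
#' @param markov_order order of the compositional model per genome.
#' @param seed master seed; each species' genome uses its own derived
#'   seed stream.
#' @return list of species models (`name`, `genome`, `weight`).
#' @export
make_species <- function(n_species = 3L, abundance = c(1, 3, 9),
                         genome_length = 1e5, markov_order = 2L, seed) {
  stopifnot(n_species >= 1, length(abundance) == n_species,
            all(abundance > 0))
  lapply(seq_len(n_species), function(s) {
    list(name = sprintf("sp%d", s),
         genome = synthesize_genome(genome_length, markov_order,
                                    seed = derive_seed(seed, 100L + s)),
         weight = abundance[s])
  })
}

#' Simulate labelled metagenomic reads
#'
#' Emulates a shotgun read simulator: each read's species is drawn from
#' the normalised abundance weights, its start position is uniform on
#' the (linear) genome, its length is a truncated normal, and
#' substitution errors are applied independently per base at
#' `substitution_rate` (no indels: for a composition-based method,
#' substitutions are the dominant perturbation).  The truth label
#' travels with every read.
#'
#' @param species list of species models from [make_species()], or any
#'   list of `list(name=, genome=, weight=)`.
#' @param n_reads number of reads to draw.
#' @param read_length_mean,read_length_sd normal read-length model, in
#'   bases.
#' @param substitution_rate per-base substitution probability in
#'   `[0, 1)`.
#' @param min_length lengths are truncated below at this value (and
#'   above at the genome length).
#' @param seed integer seed; output is a deterministic function of the
#'   arguments.
#' @return object of class `sim_reads`: list with `reads` (a named
#'   [Biostrings::DNAStringSet]), `truth` (named species vector) and
#'   `meta` (data frame: id, species, start, length).
#' @export
simulate_reads <- function(species, n_reads = 5000L,
                           read_length_mean = 1000, read_length_sd = 100,
                           substitution_rate = 0.01, min_length = 5L,
                           seed) {
  stopifnot(n_reads >= 1, substitution_rate >= 0, substitution_rate < 1,
            length(species) >= 1)
  glens <- vapply(species, function(s) nchar(s$genome), numeric(1))
  if (any(glens < read_length_mean))
    stop("genome shorter than the mean read length; shorten reads or ",
         "lengthen genomes", call. = FALSE)
  w <- vapply(species, `[[`, numeric(1), "weight")
  w <- w / sum(w)
  with_seed(seed, {
    sp <- sample.int(length(species), n_reads, replace = TRUE, prob = w)
    len <- round(rnorm(n_reads, read_length_mean, read_length_sd))
    len <- pmin(pmax(len, min_length), glens[sp])
    start <- floor(runif(n_reads) * (glens[sp] - len + 1)) + 1
    seqs <- character(n_reads)
    for (s in seq_along(species)) {
      idx <- which(sp == s)
      if (length(idx))
        seqs[idx] <- substring(species[[s]]$genome, start[idx],
                               start[idx] + len[idx] - 1)
    }
    if (substitution_rate > 0) {
      bases <- c("A", "C", "G", "T")
      nmut <- rbinom(n_reads, size = len, prob = substitution_rate)
      for (i in which(nmut > 0)) {
        pos <- sample.int(len[i], nmut[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        # substitute with a uniformly chosen *different* base
        ch[pos] <- vapply(ch[pos],
                          function(b) sample(setdiff(bases, b), 1L),
                          character(1))
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    ids <- sprintf("read_%06d", seq_len(n_reads))
    labels <- vapply(species, `[[`, character(1), "name")[sp]
    reads <- Biostrings::DNAStringSet(setNames(seqs, ids))
    structure(list(reads = reads,
                   truth = setNames(labels, ids),
                   meta = data.frame(id = ids, species = labels,
                                     start = start, length = len,
                                     stringsAsFactors = FALSE)),
              class = "sim_reads")
  })
}

#' Simulate a complete multi-species dataset
#'
#' One-call generator for the package's standard benchmark layout:
#' three compositionally distinct species, 5,000 reads of average
#' length 1,000 bp with abundance ratio 1:3:9 and a 1% substitution
#' rate.  All sizes are configurable; all randomness flows from `seed`.
#'
#' @inheritParams make_species
#' @inheritParams simulate_reads
#' @param seed master seed for genomes and reads.
#' @return a `sim_reads` object (see [simulate_reads()]); the species
#'   models used are attached as attribute `"species"`.
#' @export
simulate_metagenome <- function(n_species = 3L, abundance = c(1, 3, 9),
                                n_reads = 5000L, genome_length = 1e5,
                                markov_order = 2L,
                                read_length_mean = 1000,
                                read_length_sd = 100,
                                substitution_rate = 0.01, seed) {
  sp <- make_species(n_species, abundance, genome_length, markov_order,
                     seed = seed)
  sim <- simulate_reads(sp, n_reads = n_reads,
                        read_length_mean = read_length_mean,
                        read_length_sd = read_length_sd,
                        substitution_rate = substitution_rate,
                        seed = derive_seed(seed, 1L))
  attr(sim, "species") <- sp
  sim
}

#' Write simulated reads as FASTA plus a truth table
#'
#' The FASTA headers carry the truth label and provenance as
#' `key=value` tokens (`species=`, `pos=`, `len=`), which
#' [truth_from_headers()] can parse back; a plain two-column TSV
#' (`read_id <TAB> species`) is written alongside when `truth_path` is
#' given.
#'
#' @param sim a `sim_reads` object.
#' @param path output FASTA path.
#' @param truth_path optional output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_fasta <- function(sim, path, truth_path = NULL) {
  stopifnot(inherits(sim, "sim_reads"))
  headers <- sprintf("%s species=%s pos=%d len=%d",
                     sim$meta$id, sim$meta$species, sim$meta$start,
                     sim$meta$length)
  lines <- character(2L * nrow(sim$meta))
  lines[c(TRUE, FALSE)] <- paste0(">", headers)
  lines[c(FALSE, TRUE)] <- as.character(sim$reads)
  writeLines(lines, path)
  if (!is.null(truth_path))
    utils::write.table(data.frame(sim$meta$id, sim$meta$species),
                       truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.sim_reads <- function(x, ...) {
  tab <- table(x$truth)
  cat("simulated reads:", length(x$reads), "reads,",
      length(tab), "species\n")
  cat("per-species counts:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
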