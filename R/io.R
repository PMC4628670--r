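#' Read sequencing reads from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that sniffs the
#' format from the first non-empty character (`>` = FASTA, `@` = FASTQ;
#' gzip-compressed files are handled transparently).  Quality scores are
#' ignored: the binner is composition-based.  Only the first
#' whitespace-delimited token of each header is kept as the read id.
#'
#' @param path path to a FASTA or FASTQ file (optionally gzipped).
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  con <- gzfile(path, "r")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stop("input file is empty: ", path, call. = FALSE)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  reads <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(reads) == 0L) stop("no reads in ", path, call. = FALSE)
  full <- names(reads)
  names(reads) <- sub("\\s.*$", "", full)
  attr(reads, "headers") <- full
  reads
}

#' Read truth labels from a two-column TSV
#'
#' @param path TSV with columns `read_id` and `species` (no header
#'   required; a header line is tolerated).
#' @return named character vector mapping read id to species.
#' @export
read_truth_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("read_id", "species"),
                           colClasses = "character")
  if (nrow(tab) && tab$read_id[1] %in% c("read_id", "id"))
    tab <- tab[-1, , drop = FALSE]
  setNames(tab$species, tab$read_id)
}

#' Parse truth labels from FASTA/FASTQ description lines
#'
#' Looks for a `key=value` token (default key `"species"`) in the full
#' header of each read, as written by [write_sim_fasta()].
#'
#' @param reads a `DNAStringSet` as returned by [read_reads()] (its
#'   `"headers"` attribute carries the full description lines).
#' @param key the token key to extract.
#' @return named character vector (read id -> label); reads without the
#'   token get `NA`.
#' @export
truth_from_headers <- function(reads, key = "species") {
  headers <- attr(reads, "headers")
  if (is.null(headers)) headers <- names(reads)
  pat <- paste0(".*\\b", key, "=([^\\s]+).*")
  hit <- grepl(paste0("\\b", key, "="), headers, perl = TRUE)
  lab <- rep(NA_character_, length(reads))
  lab[hit] <- sub(pat, "\\1", headers[hit], perl = TRUE)
  setNames(lab, names(reads))
}
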