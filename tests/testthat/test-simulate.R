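test_that("synthetic genomes are deterministic, well-formed, and distinct", {
  g <- synthesize_genome(100, markov_order = 0, seed = 5)
  expect_equal(nchar(g), 100L)
  expect_true(grepl("^[ACGT]+$", g))
  expect_identical(g, synthesize_genome(100, markov_order = 0, seed = 5))

  a <- synthesize_genome(5000, markov_order = 2, seed = 1)
  b <- synthesize_genome(5000, markov_order = 2, seed = 2)
  expect_gt(kmer_distance(kmer_spectrum(a, 5), kmer_spectrum(b, 5)), 0)
})

test_that("order-0 genomes have stationary base composition", {
  # the two halves of a long i.i.d. genome should agree in composition
  # to within binomial sampling error
  g <- synthesize_genome(40000, markov_order = 0, seed = 8)
  half <- substring(g, c(1, 20001), c(20000, 40000))
  f <- kmer_spectra(half, k = 1, normalize = FALSE)
  p <- (f[1, ] + f[2, ]) / 40000
  z <- abs(f[1, ] - 20000 * p) / sqrt(20000 * p * (1 - p) / 2)
  expect_true(all(z < 5))
})

test_that("read counts follow the abundance weights multinomially", {
  sp <- make_species(3, c(1, 3, 9), genome_length = 2e4, seed = 3)
  sim <- simulate_reads(sp, n_reads = 5000, read_length_mean = 300,
                        read_length_sd = 30, seed = 4)
  counts <- table(factor(sim$truth, levels = c("sp1", "sp2", "sp3")))
  expect_equal(sum(counts), 5000)
  p <- c(1, 3, 9) / 13
  expected <- 5000 * p
  sigma <- sqrt(5000 * p * (1 - p))
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("error-free reads are exact substrings of their genome", {
  sp <- make_species(2, c(1, 1), genome_length = 5000, seed = 9)
  sim <- simulate_reads(sp, n_reads = 50, read_length_mean = 200,
                        read_length_sd = 20, substitution_rate = 0,
                        seed = 10)
  genomes <- setNames(lapply(sp, `[[`, "genome"),
                      vapply(sp, `[[`, "", "name"))
  for (i in seq_len(50)) {
    m <- sim$meta[i, ]
    expect_identical(as.character(sim$reads[[i]]),
                     substring(genomes[[m$species]], m$start,
                               m$start + m$length - 1))
  }
})

test_that("substitutions perturb roughly the configured fraction of bases", {
  sp <- make_species(1, 1, genome_length = 5000, seed = 12)
  sim0 <- simulate_reads(sp, n_reads = 40, read_length_mean = 500,
                         read_length_sd = 1, substitution_rate = 0,
                         seed = 13)
  sim1 <- simulate_reads(sp, n_reads = 40, read_length_mean = 500,
                         read_length_sd = 1, substitution_rate = 0.05,
                         seed = 13)
  # same seed: same positions/lengths, so differences are substitutions
  expect_equal(sim0$meta$start, sim1$meta$start)
  diffs <- mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, as.character(sim0$reads), as.character(sim1$reads))
  rate <- sum(diffs) / sum(sim0$meta$length)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("simulation output is byte-identical across runs with one seed", {
  f1 <- tempfile(fileext = ".fasta"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fasta"); t2 <- tempfile(fileext = ".tsv")
  s1 <- simulate_metagenome(n_reads = 60, genome_length = 5000,
                            read_length_mean = 300, read_length_sd = 30,
                            seed = 14)
  s2 <- simulate_metagenome(n_reads = 60, genome_length = 5000,
                            read_length_mean = 300, read_length_sd = 30,
                            seed = 14)
  write_sim_fasta(s1, f1, t1)
  write_sim_fasta(s2, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("species are more distant between than within, with errors on", {
  sim <- simulate_metagenome(n_reads = 90, genome_length = 2e4,
                             read_length_mean = 500, read_length_sd = 50,
                             seed = 15)
  D <- kmer_distance_provider(sim$reads)$matrix()
  same <- outer(sim$truth, sim$truth, "==")
  ut <- upper.tri(D)
  expect_gt(mean(D[ut & !same]), mean(D[ut & same]))
})

test_that("impossible configurations are rejected", {
  sp <- make_species(1, 1, genome_length = 100, seed = 1)
  expect_error(simulate_reads(sp, n_reads = 5, read_length_mean = 500,
                              seed = 2), "genome shorter")
})

test_that("FASTA round trip preserves sequences and labels", {
  sim <- simulate_metagenome(n_reads = 30, genome_length = 5000,
                             read_length_mean = 200, read_length_sd = 10,
                             seed = 16)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_sim_fasta(sim, fa, tsv)
  back <- read_reads(fa)
  expect_equal(length(back), 30L)
  expect_equal(as.character(back), as.character(sim$reads),
               ignore_attr = TRUE)
  expect_equal(truth_from_headers(back), sim$truth)
  expect_equal(read_truth_tsv(tsv), sim$truth)
})
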