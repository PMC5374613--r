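# shared fixtures, generated in code (no data files)

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(BASES, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_kmers <- function(n_kmers, k, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n_kmers),
           function(i) paste(sample(BASES, k, replace = TRUE), collapse = ""),
           character(1))
  })
}

# the default desk-scale fixture: 100 kb genome, 100 bp reads at 10x
# coverage, 1% substitution errors, 0.1% N-masking; memoised per session
fixture_env <- new.env(parent = emptyenv())

fixture_reads <- function(seed = 42L) {
  key <- paste0("reads_", seed)
  if (is.null(fixture_env[[key]])) {
    genome <- simulate_genome(1e5, seed = seed)
    fixture_env[[key]] <- simulate_reads(genome, read_length = 100L,
                                         coverage = 10, error_rate = 0.01,
                                         n_rate = 0.001, seed = seed + 1L)
  }
  fixture_env[[key]]
}

# plain-R reverse complement, independent of the package's codec
rc_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# sorted (kmer, count) data.frames are comparable with identical()
expect_counts_equal <- function(got, want) {
  expect_identical(got$kmer, want$kmer)
  expect_identical(got$count, want$count)
}
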