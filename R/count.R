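#' Count all k-mers of one or more read files
#'
#' End-to-end two-phase counting. Phase one streams the inputs,
#' decomposes reads into super-mers and distributes them over
#' \code{bins} temporary files keyed by minimizer, recording each bin's
#' total k-mer count n. Phase two counts the bins one after another with
#' open-addressing hash tables: the table for a bin is sized to
#' \code{alpha * n / beta} slots (alpha carried over from the previous
#' bin), a bin whose n exceeds the capacity cap T_max is swept in
#' \code{ceiling(n / T_max)} passes selected by the partition hash, and
#' insertions that exhaust the probe cap \code{i_max} spill to failure
#' buffers that are recounted exactly. The output is invariant to
#' \code{bins}, \code{n_shards}, \code{t_max} and \code{i_max}; those
#' knobs trade memory against speed only.
#'
#' @param inputs Character vector of FASTA/FASTQ(.gz) paths, or a
#'   data.frame of reads with a \code{seq} column.
#' @param k K-mer length (>= m; values in the hundreds are supported).
#' @param output Optional output file; if \code{NULL} the counts are
#'   only returned.
#' @param m Minimizer length (default 7).
#' @param strategy Minimizer ordering strategy (default \code{"kmc2"});
#'   see \code{\link{build_ordering}}.
#' @param canonical Count canonical k-mers (default \code{TRUE}).
#' @param bins Number of temporary files F (default 512).
#' @param memory Memory cap in bytes for one hash table (default 1 GiB);
#'   T_max = memory / slot size, with slot size
#'   \code{8 * ceiling(k/32) + 4} bytes.
#' @param t_max Expert override of T_max (slots); wins over
#'   \code{memory}.
#' @param i_max Probe cap per insertion (default 30).
#' @param beta Target fill level (default 0.4).
#' @param alpha0 Initial distinct/total ratio for the first bin
#'   (default 0.5).
#' @param n_shards Logical shard tables per pass (default 1).
#' @param min_count Suppress k-mers with count below this (default 1,
#'   i.e. no filtering).
#' @param temp_dir Directory for temporary bins.
#' @param keep_temp Keep the bins and manifest (default \code{FALSE}).
#' @param format Output format, \code{"tsv"} (k-mer TAB count, sorted
#'   lexicographically) or \code{"binary"} (see
#'   \code{\link{write_counts}}).
#' @param ordering_seed Seed for the \code{"random"} strategy.
#' @param dfp_pivot,dfp_sample Pivot factor and sample size for the
#'   \code{"dfp"} strategy (frequencies are sampled from the inputs).
#' @return Invisibly (visibly if \code{output} is \code{NULL}), a list
#'   with \code{counts} (data.frame \code{kmer}, \code{count}, sorted)
#'   and \code{report} (per-bin n, distinct, alpha used, passes,
#'   spills, plus totals and parameters).
#' @examples
#' reads <- data.frame(id = "r1", seq = "CAAGAACAGTG")
#' res <- run_count(reads, k = 4, m = 3, strategy = "lex",
#'                  canonical = FALSE, bins = 4)
#' res$counts
#' @export
run_count <- function(inputs, k, output = NULL, m = 7L,
                      strategy = c("kmc2", "lex", "cgat", "roberts",
                                   "random", "dfp"),
                      canonical = TRUE, bins = 512L, memory = 2^30,
                      t_max = NULL, i_max = 30L, beta = 0.4, alpha0 = 0.5,
                      n_shards = 1L, min_count = 1L,
                      temp_dir = tempfile("kmerbin-"), keep_temp = FALSE,
                      format = c("tsv", "binary"), ordering_seed = NULL,
                      dfp_pivot = 0.5, dfp_sample = 1e5) {
  strategy <- match.arg(strategy)
  format <- match.arg(format)
  k <- as.integer(k); m <- as.integer(m)
  if (k < m) stop("k (", k, ") must be >= m (", m, ")")
  if (i_max < 1L) stop("i_max must be >= 1")
  if (min_count < 1L) stop("min_count must be >= 1")
  if (n_shards < 1L) stop("n_shards must be >= 1")
  slot_bytes <- 8 * ceiling(k / 32) + 4
  if (is.null(t_max)) {
    if (memory < slot_bytes)
      stop("memory cap ", memory, " is below one slot (", slot_bytes,
           " bytes)")
    t_max <- max(1, floor(memory / slot_bytes))
  }
  if (t_max < 1) stop("t_max must be >= 1")

  ordering <- if (strategy == "dfp") {
    freqs <- sample_frequencies(gather_seqs(inputs), m, dfp_sample)
    build_ordering("dfp", m = m, pivot = dfp_pivot, frequencies = freqs)
  } else {
    build_ordering(strategy, m = m, seed = ordering_seed)
  }

  cfg <- phase1_config(k = k, m = m, ordering = ordering,
                       canonical = canonical, bins = bins,
                       temp_dir = temp_dir)
  if (!keep_temp) on.exit(unlink(temp_dir, recursive = TRUE), add = TRUE)
  p1 <- run_phase1(inputs, cfg)

  est <- alpha_estimator(alpha0)
  pieces <- vector("list", nrow(p1$bins))
  bin_report <- vector("list", nrow(p1$bins))
  for (i in seq_len(nrow(p1$bins))) {
    b <- p1$bins[i, ]
    if (b$n_kmers == 0) next
    res <- count_bin(b$path, k = k, n_kmers = b$n_kmers,
                     canonical = canonical, alpha = est$alpha, beta = beta,
                     i_max = i_max, t_max = t_max, n_shards = n_shards)
    pieces[[i]] <- res$counts
    bin_report[[i]] <- data.frame(
      file_id = b$file_id, n = res$stats$n, distinct = res$stats$distinct,
      alpha_used = est$alpha, passes = res$stats$passes,
      spilled = res$stats$spilled, mean_probes = res$stats$mean_probes)
    est <- update_alpha(est, res$stats$distinct, res$stats$n)
  }
  counts <- do.call(rbind, pieces)
  if (is.null(counts))
    counts <- data.frame(kmer = character(0), count = numeric(0))
  counts <- counts[order(counts$kmer, method = "radix"), , drop = FALSE]
  rownames(counts) <- NULL
  if (min_count > 1L)
    counts <- counts[counts$count >= min_count, , drop = FALSE]

  bin_report <- do.call(rbind, bin_report)
  report <- list(
    k = k, m = m, strategy = strategy, canonical = canonical, bins = bins,
    t_max = t_max, i_max = i_max, beta = beta, n_shards = n_shards,
    ordering_seed = ordering_seed,
    dfp_pivot = if (strategy == "dfp") dfp_pivot else NULL,
    total_kmers = sum(p1$bins$n_kmers),
    distinct_kmers = nrow(counts),
    total_supermers = sum(p1$bins$n_supermers),
    per_bin = bin_report)

  out <- list(counts = counts, report = report)
  if (!is.null(output)) {
    write_counts(counts, output, format = format)
    out$output <- output
    return(invisible(out))
  }
  out
}

gather_seqs <- function(inputs) {
  if (is.data.frame(inputs)) return(inputs$seq)
  unlist(lapply(inputs, function(p) read_sequences(p)$seq), use.names = FALSE)
}

#' Write a k-mer count table to disk
#'
#' \code{tsv}: one \code{<k-mer>\\t<count>} line per k-mer. \code{binary}:
#' a little-endian u64 record count, then per record ceiling(k/4) bytes
#' of 2-bit packed k-mer followed by a u32 count. Both round-trip via
#' \code{\link{read_counts}}.
#'
#' @param counts data.frame with columns \code{kmer} and \code{count}.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"binary"}.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(sprintf("%s\t%.0f", counts$kmer, counts$count), path)
  } else {
    cpp_write_counts_bin(path, as.character(counts$kmer),
                         as.numeric(counts$count))
  }
  invisible(path)
}

#' Read a k-mer count table written by \code{\link{write_counts}}
#'
#' @param path Input path.
#' @param format \code{"tsv"} or \code{"binary"}.
#' @param k K-mer length; required for \code{"binary"} (the record
#'   layout is k-dependent).
#' @return data.frame with columns \code{kmer}, \code{count}.
#' @export
read_counts <- function(path, format = c("tsv", "binary"), k = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- readLines(path)
    if (length(lines) == 0L)
      return(data.frame(kmer = character(0), count = numeric(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(kmer = vapply(parts, `[[`, character(1), 1L),
               count = as.numeric(vapply(parts, `[[`, character(1), 2L)),
               stringsAsFactors = FALSE)
  } else {
    if (is.null(k)) stop("k is required to read the binary format")
    res <- cpp_read_counts_bin(path, as.integer(k))
    data.frame(kmer = res$kmer, count = res$count, stringsAsFactors = FALSE)
  }
}
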