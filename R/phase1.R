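#' Configuration for the distribution phase
#'
#' @param k K-mer length (>= m).
#' @param m Minimizer length (default 7, a good compromise between
#'   super-mer count and temporary file balance for most data sets).
#' @param ordering A \code{\link{build_ordering}} result (default the
#'   KMC2-style ordering at length \code{m}).
#' @param canonical Count canonical k-mers (default \code{TRUE}).
#' @param bins Number of temporary bin files F (default 512).
#' @param temp_dir Directory for the temporary bin files.
#' @return A list of class \code{phase1_config}.
#' @export
phase1_config <- function(k, m = 7L, ordering = NULL, canonical = TRUE,
                          bins = 512L, temp_dir = tempfile("kmerbin-")) {
  k <- as.integer(k); m <- as.integer(m); bins <- as.integer(bins)
  if (is.null(ordering)) ordering <- build_ordering("kmc2", m = m)
  stopifnot(inherits(ordering, "minimizer_ordering"))
  if (ordering$m != m) stop("ordering was built for m = ", ordering$m,
                            " but config asks for m = ", m)
  if (k < m) stop("k (", k, ") must be >= m (", m, ")")
  if (bins < 1L) stop("bins must be >= 1")
  structure(list(k = k, m = m, ordering = ordering, canonical = canonical,
                 bins = bins, temp_dir = temp_dir),
            class = "phase1_config")
}

#' Assign a minimizer rank to a bin file
#'
#' All super-mers with the same minimizer must land in the same temporary
#' file so that all occurrences of a k-mer are counted within one bin.
#' The map is a fixed multiplicative hash of the rank modulo F: it
#' scatters neighbouring ranks across bins, and over a contiguous rank
#' range its occupancy is exactly balanced whenever F is a power of two,
#' without any runtime feedback.
#'
#' @param rank Minimizer rank(s) in [0, 4^m).
#' @param bins Number of bin files F.
#' @return Integer file id(s) in [0, F).
#' @export
assign_file <- function(rank, bins) {
  vapply(rank, function(r) cpp_assign_file(r, as.integer(bins)), integer(1))
}

#' Append a super-mer record to a bin file
#'
#' Record format (bit-exact): little-endian u16 base length, u32
#' minimizer rank, then ceiling(length/4) bytes of 2-bit packed bases.
#'
#' @param path Bin file path.
#' @param supermer Character vector of super-mer base strings.
#' @param rank Numeric vector of minimizer ranks (recycled if scalar).
#' @param append Append to an existing file (default \code{TRUE}).
#' @export
write_supermers <- function(path, supermer, rank, append = TRUE) {
  rank <- rep_len(as.numeric(rank), length(supermer))
  cpp_write_supermers(path, as.character(supermer), rank, append)
  invisible(path)
}

#' Read all super-mer records from a bin file
#'
#' @param path Bin file path.
#' @return data.frame with columns \code{supermer} and \code{rank}.
#' @export
read_supermers <- function(path) {
  res <- cpp_read_bin(path)
  data.frame(supermer = res$supermer, rank = res$rank,
             stringsAsFactors = FALSE)
}

#' Phase One: distribute reads into minimizer-keyed bin files
#'
#' Streams every input file, splits reads into ACGT fragments, decomposes
#' fragments of length >= k into super-mers, and appends each super-mer
#' to the bin file its minimizer is assigned to. After this phase the
#' bins partition the input: all occurrences of a given k-mer (of its
#' canonical form, in canonical mode) sit in one bin, so bins can be
#' counted independently with small tables. The total k-mer count n per
#' bin is recorded in a sidecar manifest and drives table sizing in the
#' counting phase.
#'
#' @param inputs Character vector of FASTA/FASTQ(.gz) paths, or a
#'   data.frame of reads with a \code{seq} column.
#' @param cfg A \code{\link{phase1_config}}.
#' @return A list with \code{bins} (data.frame: \code{file_id},
#'   \code{path}, \code{n_kmers}, \code{n_supermers}, \code{byte_size})
#'   and \code{manifest} (path of the manifest TSV).
#' @export
run_phase1 <- function(inputs, cfg) {
  stopifnot(inherits(cfg, "phase1_config"))
  dir.create(cfg$temp_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(cfg$temp_dir)) stop("cannot create temp dir ", cfg$temp_dir)
  paths <- file.path(cfg$temp_dir, sprintf("bin-%05d.smr", seq_len(cfg$bins) - 1L))

  n_kmers <- numeric(cfg$bins)
  n_supermers <- numeric(cfg$bins)
  first <- TRUE
  chunks <- if (is.data.frame(inputs)) {
    list(inputs$seq)
  } else {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing) > 0)
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    lapply(inputs, function(p) read_sequences(p)$seq)
  }
  for (seqs in chunks) {
    res <- cpp_phase1_chunk(as.character(seqs), cfg$k, cfg$m,
                            cfg$ordering$rank, cfg$canonical, paths,
                            append = !first)
    n_kmers <- n_kmers + res$n_kmers
    n_supermers <- n_supermers + res$n_supermers
    first <- FALSE
  }
  if (first) {  # no input chunks at all: still create empty bins
    for (p in paths) file.create(p)
  }

  bins <- data.frame(file_id = seq_len(cfg$bins) - 1L, path = paths,
                     n_kmers = n_kmers, n_supermers = n_supermers,
                     byte_size = file.size(paths),
                     stringsAsFactors = FALSE)
  manifest <- file.path(cfg$temp_dir, "manifest.tsv")
  hdr <- c(sprintf("# k=%d m=%d strategy=%s canonical=%s bins=%d",
                   cfg$k, cfg$m, cfg$ordering$strategy,
                   cfg$canonical, cfg$bins),
           if (!is.null(cfg$ordering$params$seed))
             sprintf("# ordering_seed=%d", cfg$ordering$params$seed),
           if (!is.null(cfg$ordering$params$pivot))
             sprintf("# dfp_pivot=%g", cfg$ordering$params$pivot))
  writeLines(c(hdr, "file_id\tn_kmers\tn_supermers",
               sprintf("%d\t%.0f\t%.0f", bins$file_id, bins$n_kmers,
                       bins$n_supermers)),
             manifest)
  list(bins = bins, manifest = manifest)
}
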