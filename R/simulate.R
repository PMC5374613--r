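#' Simulate a random genome
#'
#' Uniform i.i.d. ACGT string, reproducible for a given seed.
#'
#' @param length Genome length in bases (>= 1).
#' @param seed Integer seed.
#' @return Character scalar of \code{length} bases.
#' @export
simulate_genome <- function(length, seed = 1L) {
  stopifnot(length >= 1)
  withr::with_seed(as.integer(seed), {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
}

#' Simulate sequencing reads from a genome
#'
#' Draws \code{ceiling(coverage * nchar(genome) / read_length)} reads of
#' fixed length from uniform random start positions and strands, applies
#' per-base substitution errors at \code{error_rate} and replaces bases
#' by \code{N} at \code{n_rate} (masking, applied after substitutions).
#' Optionally writes a FASTA/FASTQ file (gzipped if the path ends in
#' \code{.gz}); FASTQ qualities are a constant line. Indels and
#' quality-dependent error profiles are deliberately not modelled:
#' substitutions and N-masking are what stress exact counting.
#'
#' @param genome Character scalar (e.g. from
#'   \code{\link{simulate_genome}}).
#' @param read_length Read length (<= genome length), default 100.
#' @param coverage Mean coverage, default 10.
#' @param error_rate Per-base substitution probability, default 0.01.
#' @param n_rate Per-base N-masking probability, default 0.001.
#' @param seed Integer seed.
#' @param path Optional output file path (format from extension:
#'   \code{.fa/.fasta} FASTA, otherwise FASTQ).
#' @return data.frame with columns \code{id}, \code{seq}; if \code{path}
#'   is given it is attached as attribute \code{"path"}.
#' @export
simulate_reads <- function(genome, read_length = 100L, coverage = 10,
                           error_rate = 0.01, n_rate = 0.001, seed = 1L,
                           path = NULL) {
  glen <- nchar(genome)
  stopifnot(read_length >= 1, read_length <= glen,
            coverage > 0, error_rate >= 0, error_rate <= 1,
            n_rate >= 0, n_rate <= 1)
  n_reads <- ceiling(coverage * glen / read_length)
  bases <- c("A", "C", "G", "T")
  reads <- withr::with_seed(as.integer(seed), {
    starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE)
    rev_strand <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)
    seqs <- substring(genome, starts, starts + read_length - 1L)
    if (any(rev_strand))
      seqs[rev_strand] <- vapply(seqs[rev_strand], reverse_complement,
                                 character(1), USE.NAMES = FALSE)
    total <- n_reads * read_length
    mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = read_length)
    if (error_rate > 0) {
      err <- which(stats::runif(total) < error_rate)
      if (length(err) > 0) {
        # substitute with one of the three other bases
        shift <- sample.int(3L, length(err), replace = TRUE)
        old <- match(mat[err], bases) - 1L
        mat[err] <- bases[((old + shift) %% 4L) + 1L]
      }
    }
    if (n_rate > 0) {
      nn <- which(stats::runif(total) < n_rate)
      if (length(nn) > 0) mat[nn] <- "N"
    }
    apply(mat, 2, paste, collapse = "")
  })
  out <- data.frame(id = sprintf("read_%06d", seq_len(n_reads)),
                    seq = reads, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_reads(out, path)
    attr(out, "path") <- path
  }
  out
}

#' Write reads to a FASTA or FASTQ file
#'
#' @param reads data.frame with columns \code{id} and \code{seq}.
#' @param path Output path; \code{.fa/.fasta(.gz)} selects FASTA,
#'   anything else FASTQ; a \code{.gz} suffix gzips the output.
#' @return \code{path}, invisibly.
#' @export
write_reads <- function(reads, path) {
  fasta <- grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (fasta) {
    writeLines(rbind(paste0(">", reads$id), reads$seq), con)
  } else {
    qual <- strrep("I", nchar(reads$seq))
    writeLines(rbind(paste0("@", reads$id), reads$seq, "+", qual), con)
  }
  invisible(path)
}

#' Brute-force dictionary k-mer counter (reference oracle)
#'
#' Counts every ACGT window of length k (reads are split at non-ACGT
#' symbols), canonicalized if requested, with a plain dictionary. Its
#' correctness is immediate from its construction, which is the point:
#' it anchors every exactness test of the hash-table pipeline. It shares
#' no code with that pipeline (character-level, no bit packing).
#'
#' @param reads Character vector of sequences, or a data.frame with a
#'   \code{seq} column, or a FASTA/FASTQ path.
#' @param k K-mer length.
#' @param canonical Merge reverse-complement pairs (default \code{TRUE}).
#' @return data.frame with columns \code{kmer}, \code{count}, sorted
#'   lexicographically by k-mer.
#' @export
oracle_count <- function(reads, k, canonical = TRUE) {
  seqs <- if (is.data.frame(reads)) reads$seq
          else if (length(reads) == 1L && file.exists(reads))
            read_sequences(reads)$seq
          else reads
  res <- cpp_oracle_count(as.character(seqs), as.integer(k), canonical)
  ord <- order(res$kmer, method = "radix")
  data.frame(kmer = res$kmer[ord], count = res$count[ord],
             stringsAsFactors = FALSE)
}
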