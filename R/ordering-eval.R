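#' Evaluate one minimizer ordering on a set of reads
#'
#' Computes, in a single streaming scan, the two quantities that
#' characterize an ordering's practical quality: the total number of
#' super-mers (proportional to temporary disk space, smaller is better)
#' and the maximal number of distinct k-mers that share one minimizer
#' (proxy for the largest bin and hence peak table memory, smaller is
#' better). The two pull in opposite directions, which is why several
#' strategies are worth comparing on the data at hand.
#'
#' @param reads Character vector of sequences, a data.frame with a
#'   \code{seq} column, or a FASTA/FASTQ path.
#' @param k K-mer length.
#' @param ordering A \code{\link{build_ordering}} result.
#' @param canonical Minimize over both strands (default \code{FALSE}).
#' @param detail Also return the per-minimizer distinct counts
#'   (default \code{FALSE}).
#' @return List of class \code{ordering_metrics} with \code{strategy},
#'   \code{total_supermers}, \code{max_distinct_per_minimizer} and
#'   (optionally) \code{per_minimizer} (data.frame \code{rank},
#'   \code{n_distinct}).
#' @export
evaluate_ordering <- function(reads, k, ordering, canonical = FALSE,
                              detail = FALSE) {
  stopifnot(inherits(ordering, "minimizer_ordering"))
  seqs <- if (is.data.frame(reads)) reads$seq
          else if (length(reads) == 1L && file.exists(reads))
            read_sequences(reads)$seq
          else reads
  res <- cpp_evaluate_ordering(as.character(seqs), as.integer(k),
                               ordering$m, ordering$rank, canonical)
  out <- list(strategy = ordering$strategy, m = ordering$m,
              params = ordering$params,
              total_supermers = res$total_supermers,
              max_distinct_per_minimizer = res$max_distinct_per_minimizer)
  if (detail)
    out$per_minimizer <- data.frame(rank = res$minimizer_rank,
                                    n_distinct = res$n_distinct)
  structure(out, class = "ordering_metrics")
}

#' @export
print.ordering_metrics <- function(x, ...) {
  cat(sprintf("<ordering_metrics: %s, m = %d> super-mers: %.0f, max distinct k-mers/minimizer: %.0f\n",
              x$strategy, x$m, x$total_supermers,
              x$max_distinct_per_minimizer))
  invisible(x)
}

#' Compare several ordering strategies on the same reads
#'
#' Evaluates each requested strategy (the distance-from-pivot strategy at
#' every requested pivot, with frequencies sampled once from the input)
#' and returns one row per strategy. Use \code{path} to emit the table as
#' a tab-separated report.
#'
#' @param reads As in \code{\link{evaluate_ordering}}.
#' @param k K-mer length.
#' @param m Minimizer length (default 7).
#' @param strategies Character vector of strategy names (default all).
#' @param dfp_pivots Pivot factors evaluated for \code{"dfp"}
#'   (default \code{c(0, 0.5, 0.8, 1)}).
#' @param seed Seed for the \code{"random"} strategy (default 1).
#' @param canonical Minimize over both strands (default \code{FALSE}).
#' @param sample_size Fragments sampled for dfp frequencies
#'   (default 1e5).
#' @param path Optional output TSV path.
#' @return data.frame with columns \code{strategy}, \code{params},
#'   \code{total_supermers}, \code{max_distinct_per_minimizer}.
#' @export
compare_orderings <- function(reads, k, m = 7L,
                              strategies = c("lex", "cgat", "roberts",
                                             "kmc2", "random", "dfp"),
                              dfp_pivots = c(0, 0.5, 0.8, 1), seed = 1L,
                              canonical = FALSE, sample_size = 1e5,
                              path = NULL) {
  seqs <- if (is.data.frame(reads)) reads$seq
          else if (length(reads) == 1L && file.exists(reads))
            read_sequences(reads)$seq
          else reads
  freqs <- if ("dfp" %in% strategies)
    sample_frequencies(seqs, m, sample_size) else NULL

  rows <- list()
  for (s in strategies) {
    if (s == "dfp") {
      for (p in dfp_pivots) {
        ord <- build_ordering("dfp", m = m, pivot = p, frequencies = freqs)
        met <- evaluate_ordering(seqs, k, ord, canonical)
        rows[[length(rows) + 1L]] <-
          data.frame(strategy = "dfp", params = sprintf("pivot=%g", p),
                     total_supermers = met$total_supermers,
                     max_distinct_per_minimizer =
                       met$max_distinct_per_minimizer,
                     stringsAsFactors = FALSE)
      }
    } else {
      ord <- build_ordering(s, m = m,
                            seed = if (s == "random") seed else NULL)
      met <- evaluate_ordering(seqs, k, ord, canonical)
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = s,
                   params = if (s == "random") sprintf("seed=%d", seed)
                            else "",
                   total_supermers = met$total_supermers,
                   max_distinct_per_minimizer =
                     met$max_distinct_per_minimizer,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
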