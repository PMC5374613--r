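#' Hash table capacity from the linear distinct-ratio model
#'
#' The number of distinct k-mers d in a bin is not known before counting
#' it, but the total n is (from the distribution phase). d is estimated
#' as alpha * n, where alpha is the distinct/total ratio carried over
#' from the previously counted bin, and the table is sized to
#' \code{ceiling(alpha * n / beta)} so that the expected fill level after
#' insertion is about beta. The counting pipeline rounds this up to the
#' next power of two (its slot granularity, which makes the quadratic
#' probe schedule cover every slot).
#'
#' @param n Total k-mers to be inserted.
#' @param alpha Estimated distinct/total ratio in (0, 1].
#' @param beta Target fill level in (0, 1); default 0.4, which balances
#'   probe cost against memory.
#' @return Capacity in slots (>= 1, before granularity rounding).
#' @examples
#' table_size(1000, alpha = 0.15, beta = 0.4)  # 375
#' @export
table_size <- function(n, alpha, beta = 0.4) {
  stopifnot(n >= 0, alpha > 0, alpha <= 1, beta > 0, beta < 1)
  max(1, ceiling(alpha * n / beta))
}

#' Running estimator of the distinct/total ratio
#'
#' @param alpha Initial estimate for the first bin (default 0.5).
#' @return List of class \code{alpha_estimator} with \code{alpha} and
#'   \code{alpha_prev}.
#' @export
alpha_estimator <- function(alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  structure(list(alpha = alpha, alpha_prev = NA_real_),
            class = "alpha_estimator")
}

#' Update the distinct-ratio estimate after a bin
#'
#' Sets alpha to d/n of the bin just counted (bins with n = 0 leave the
#' estimate unchanged); the next bin's table sizing uses the new value.
#'
#' @param est An \code{\link{alpha_estimator}}.
#' @param d Distinct k-mers observed in the bin.
#' @param n Total k-mers in the bin.
#' @return The updated estimator.
#' @export
update_alpha <- function(est, d, n) {
  stopifnot(inherits(est, "alpha_estimator"), d >= 0, n >= 0, d <= n)
  if (n > 0) {
    est$alpha_prev <- est$alpha
    est$alpha <- d / n
  }
  est
}

#' Quadratic probe schedule of a k-mer
#'
#' Probe i of k-mer x lands on slot \code{(h0(x) + (i + i^2)/2) mod
#' capacity}, where h0 mixes successive 64-bit blocks (32 bases each) of
#' the 2-bit packed k-mer through a multiply-xor-shift avalanche; its
#' cost grows linearly with k. The triangular increment visits every slot
#' when the capacity is a power of two.
#'
#' @param kmer Character scalar over ACGT.
#' @param i Probe index (>= 0), may be a vector.
#' @param capacity Table capacity.
#' @return Numeric slot index/indices in [0, capacity).
#' @export
probe_hash <- function(kmer, i, capacity) {
  vapply(i, function(ii) cpp_probe_slot(kmer, ii, capacity), numeric(1))
}

#' Partition hash of a k-mer
#'
#' A cheap constant-time hash over at most the first four 16-bit blocks
#' (8 bases each) of the packed k-mer, mapping into [0, 2^16). It routes
#' k-mers to shards (\code{\link{shard_id}}) and selects the k-mers of
#' each pass in multi-pass counting, independently of the probing hash.
#'
#' @param kmer Character scalar or vector over ACGT.
#' @return Integer value(s) in [0, 65536).
#' @export
part_hash <- function(kmer) {
  vapply(kmer, cpp_part_hash, integer(1), USE.NAMES = FALSE)
}

#' Shard id of a k-mer
#'
#' \code{part_hash(x) mod N}; every occurrence of a k-mer lands in the
#' same shard, so the N shard tables can be counted independently.
#'
#' @param kmer Character scalar or vector.
#' @param n_shards Number of shards N (>= 1).
#' @return Integer shard id(s) in [0, N).
#' @export
shard_id <- function(kmer, n_shards) {
  stopifnot(n_shards >= 1)
  part_hash(kmer) %% as.integer(n_shards)
}

#' Number of counting passes over a bin
#'
#' When a bin holds more k-mers than the maximal table capacity T_max
#' (derived from the memory cap), the bin is swept p = ceiling(n/T_max)
#' times; pass i handles exactly the k-mers with \code{part_hash(x) == i
#' (mod p)}, so the passes partition the bin.
#'
#' @param n Total k-mers in the bin.
#' @param t_max Maximal table capacity.
#' @return List with \code{p} (>= 1).
#' @examples
#' plan_passes(10, 4)$p  # 3
#' @export
plan_passes <- function(n, t_max) {
  stopifnot(n >= 0, t_max >= 1)
  list(p = max(1, ceiling(n / t_max)))
}

#' Create an open-addressing count table
#'
#' Slots hold a packed k-mer key (ceiling(k/32) 64-bit words) and a u32
#' counter that saturates at 2^32 - 1. Collisions are resolved by the
#' quadratic schedule of \code{\link{probe_hash}}; an insertion gives up
#' after \code{i_max} probes and reports failure instead of degrading the
#' whole run (failed k-mers are recounted exactly from failure buffers by
#' the bin pipeline).
#'
#' @param k K-mer length.
#' @param capacity Number of slots (any positive integer; the bin
#'   pipeline uses powers of two).
#' @param i_max Probe cap per insertion (default 30, roughly log2 of
#'   realistic data-set sizes).
#' @return An external pointer of class \code{count_table}.
#' @export
new_count_table <- function(k, capacity, i_max = 30L) {
  ptr <- cpp_table_new(as.integer(k), as.numeric(capacity),
                       as.integer(i_max))
  class(ptr) <- "count_table"
  ptr
}

#' Insert k-mers into a count table
#'
#' @param table A \code{\link{new_count_table}}.
#' @param kmers Character vector of k-mers (length k each; canonicalize
#'   first if strand-neutral counts are wanted).
#' @return Logical vector: \code{TRUE} = counted (new key or counter
#'   bumped), \code{FALSE} = failed after i_max probes (table unchanged
#'   for that k-mer).
#' @export
table_insert <- function(table, kmers) {
  cpp_table_insert(table, as.character(kmers))
}

#' Extract the (k-mer, count) content of a table
#' @param table A \code{\link{new_count_table}}.
#' @return data.frame with columns \code{kmer}, \code{count}.
#' @export
table_counts <- function(table) {
  res <- cpp_table_counts(table)
  data.frame(kmer = res$kmer, count = res$count, stringsAsFactors = FALSE)
}

#' Occupancy statistics of a count table
#' @param table A \code{\link{new_count_table}}.
#' @return List with \code{k}, \code{capacity}, \code{i_max},
#'   \code{inserted}, \code{fill} and \code{mean_probes}.
#' @export
table_stats <- function(table) {
  cpp_table_stats(table)
}

#' Phase Two for one bin: exact counts of all its k-mers
#'
#' Runs \code{plan_passes(n, t_max)} passes over the bin. In each pass
#' the super-mers are split into k-mers, canonicalized if requested,
#' routed to one of \code{n_shards} tables by \code{\link{shard_id}}, and
#' inserted under the probe cap \code{i_max}; k-mers that fail are
#' spilled to a failure buffer and recounted afterwards in dedicated
#' tables sized to the spill (doubling capacity and i_max on repeated
#' failure), so no k-mer is ever lost or double-counted.
#'
#' @param bin Path to a bin file, or one row of the \code{bins}
#'   data.frame of \code{\link{run_phase1}}.
#' @param k K-mer length.
#' @param n_kmers Total k-mers in the bin (from the phase-1 manifest;
#'   taken from \code{bin} if it is a data.frame row).
#' @param canonical Canonicalize k-mers (default \code{TRUE}).
#' @param alpha Distinct/total ratio estimate used for table sizing.
#' @param beta Target fill level (default 0.4).
#' @param i_max Probe cap (default 30).
#' @param t_max Maximal table capacity per pass (default \code{Inf}
#'   behaviour via a very large cap).
#' @param n_shards Logical shard tables N (default 1); results are
#'   identical for any N.
#' @return List with \code{counts} (data.frame \code{kmer},
#'   \code{count}) and \code{stats} (n, distinct, passes, spilled,
#'   drain_rounds, mean_probes, capacity_total).
#' @export
count_bin <- function(bin, k, n_kmers = NULL, canonical = TRUE, alpha = 0.5,
                      beta = 0.4, i_max = 30L, t_max = 2^40, n_shards = 1L) {
  if (is.data.frame(bin)) {
    stopifnot(nrow(bin) == 1L)
    if (is.null(n_kmers)) n_kmers <- bin$n_kmers
    bin <- bin$path
  }
  if (is.null(n_kmers)) stop("n_kmers (from the phase-1 manifest) is required")
  res <- cpp_count_bin(bin, as.numeric(n_kmers), as.integer(k), canonical,
                       alpha, beta, as.integer(i_max), as.numeric(t_max),
                       as.integer(n_shards))
  list(counts = data.frame(kmer = res$kmer, count = res$count,
                           stringsAsFactors = FALSE),
       stats = res$stats)
}
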