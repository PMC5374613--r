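#' Build a total ordering over all 4^m m-mers
#'
#' A minimizer ordering is a bijective rank table over the 4^m strings of
#' length m; the minimizer of a k-mer is its m-mer window of minimal
#' rank. The choice of ordering trades the total number of super-mers
#' (temporary disk space) against the skew of distinct k-mers per
#' minimizer (peak table size). Available strategies:
#' \describe{
#'   \item{lex}{plain lexicographic, A<C<G<T.}
#'   \item{cgat}{lexicographic with base order C<G<A<T.}
#'   \item{roberts}{bases at even positions (0-based) are complemented,
#'     then lexicographic with C<A<T<G, so that rare minimizers such as
#'     CGCGCG are preferred.}
#'   \item{kmc2}{lexicographic A<C<G<T, except that m-mers starting with
#'     AAA or ACA are demoted after all others (relative order within the
#'     demoted class stays lexicographic). This suppresses the very
#'     frequent poly-A-like minimizers. The default.}
#'   \item{random}{a seeded uniform permutation of all m-mers.}
#'   \item{dfp}{distance-from-pivot: m-mers are first sorted ascending by
#'     a sampled frequency (ties lexicographic), then re-sorted by the
#'     absolute difference between that initial position and the pivot
#'     position 4^m * pivot (ties lexicographic). pivot = 0 favours rare
#'     minimizers, pivot = 1 frequent ones.}
#' }
#'
#' @param strategy One of \code{"lex"}, \code{"cgat"}, \code{"roberts"},
#'   \code{"kmc2"}, \code{"random"}, \code{"dfp"}.
#' @param m Minimizer length, between 1 and 15 (the rank table has 4^m
#'   entries and must fit in memory). Default 7.
#' @param seed Integer seed, required for \code{"random"}.
#' @param pivot Pivot factor in [0, 1], required for \code{"dfp"}.
#' @param frequencies Numeric vector of 4^m sampled m-mer frequencies
#'   (see \code{\link{sample_frequencies}}), required for \code{"dfp"}.
#' @return An object of class \code{minimizer_ordering}: list with
#'   \code{strategy}, \code{m}, \code{rank} (integer vector of length
#'   4^m holding ranks in [0, 4^m), indexed by the m-mer's A<C<G<T
#'   value + 1) and \code{params}.
#' @examples
#' ord <- build_ordering("cgat", m = 1)
#' ord$rank  # C=0, G=1, A=2, T=3
#' @export
build_ordering <- function(strategy = c("kmc2", "lex", "cgat", "roberts",
                                        "random", "dfp"),
                           m = 7L, seed = NULL, pivot = NULL,
                           frequencies = NULL) {
  strategy <- match.arg(strategy)
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > 15L)
    stop("m must be an integer in [1, 15], got ", m)
  n <- 4^m
  v <- seq_len(n) - 1  # m-mer values under A<C<G<T digit order

  rank <- switch(strategy,
    lex = v,
    cgat = remap_digits(v, m, c(2, 0, 1, 3)),       # A,C,G,T -> new digit
    roberts = {
      # complement digits at even positions (0-based), then C<A<T<G
      compl <- complement_even_digits(v, m)
      remap_digits(compl, m, c(1, 0, 3, 2))          # A=1, C=0, G=3, T=2
    },
    kmc2 = {
      demoted <- if (m >= 3L) {
        pre <- v %/% 4^(m - 3)                       # first three digits
        pre == mmer_value("AAA") | pre == mmer_value("ACA")
      } else rep(FALSE, n)
      ord <- order(demoted, v)
      r <- numeric(n); r[ord] <- v
      r
    },
    random = {
      if (is.null(seed)) stop("the random strategy requires a seed")
      withr::with_seed(as.integer(seed), sample.int(n) - 1)
    },
    dfp = {
      if (is.null(pivot) || is.null(frequencies))
        stop("the dfp strategy requires both a pivot and frequencies")
      if (length(frequencies) != n)
        stop("frequencies must have 4^m = ", n, " entries")
      stopifnot(pivot >= 0, pivot <= 1)
      ord1 <- order(frequencies, v)                  # ascending frequency
      pos <- numeric(n); pos[ord1] <- v
      ord2 <- order(abs(pos - n * pivot), v)
      r <- numeric(n); r[ord2] <- v
      r
    })

  structure(list(strategy = strategy, m = m,
                 rank = as.integer(rank),
                 params = list(seed = seed, pivot = pivot)),
            class = "minimizer_ordering")
}

# reinterpret each base-4 digit of the m-digit values through `map`
# (map[code+1] = new digit for base code)
remap_digits <- function(v, m, map) {
  out <- numeric(length(v))
  for (pos in seq_len(m)) {
    w <- 4^(m - pos)
    digit <- (v %/% w) %% 4
    out <- out + map[digit + 1] * w
  }
  out
}

complement_even_digits <- function(v, m) {
  out <- numeric(length(v))
  for (pos in seq_len(m)) {
    w <- 4^(m - pos)
    digit <- (v %/% w) %% 4
    if (pos %% 2L == 1L) digit <- 3 - digit  # 0-based even position
    out <- out + digit * w
  }
  out
}

#' @export
print.minimizer_ordering <- function(x, ...) {
  cat(sprintf("<minimizer_ordering: %s, m = %d, 4^m = %d m-mers>\n",
              x$strategy, x$m, length(x$rank)))
  invisible(x)
}

#' Value of an m-mer under the A<C<G<T digit order
#'
#' Maps an m-mer string to its integer value in [0, 4^m), the index used
#' by rank tables (value + 1 in R's 1-based indexing).
#'
#' @param mmer Character scalar over ACGT.
#' @return Numeric value.
#' @export
mmer_value <- function(mmer) {
  codes <- match(strsplit(toupper(mmer), "")[[1]], c("A", "C", "G", "T")) - 1
  if (anyNA(codes)) stop("m-mer contains a non-ACGT base")
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}

#' String form of an m-mer value
#' @param value Numeric value in [0, 4^m).
#' @param m m-mer length.
#' @return Character scalar.
#' @export
value_mmer <- function(value, m) {
  digits <- (value %/% 4^((m - 1):0)) %% 4
  paste(c("A", "C", "G", "T")[digits + 1], collapse = "")
}

#' Sample m-mer frequencies from reads
#'
#' Counts every m-mer window over the first \code{sample_size} ACGT
#' fragments of the given reads; m-mers never seen get count 0. Used to
#' parameterize the distance-from-pivot ordering, whose definition needs
#' (approximate) minimizer frequencies of the data set at hand.
#'
#' @param reads Character vector of read sequences, or a data.frame with
#'   a \code{seq} column as returned by \code{\link{read_sequences}}.
#' @param m Minimizer length.
#' @param sample_size Number of read fragments to scan (default 1e5).
#' @return Numeric vector of 4^m counts indexed by m-mer value + 1.
#' @export
sample_frequencies <- function(reads, m, sample_size = 1e5) {
  stopifnot(sample_size >= 1)
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  cpp_sample_frequencies(as.character(seqs), as.integer(m), sample_size)
}

#' Minimizer of a single k-mer
#'
#' The m-mer window of minimal rank under the given ordering. In
#' canonical mode the minimum is taken over the windows of both the
#' k-mer and its reverse complement. Ties are broken by leftmost
#' position, forward strand preferred.
#'
#' @param kmer Character scalar of length k >= m over ACGT.
#' @param ordering A \code{\link{build_ordering}} result.
#' @param canonical Consider both strands (default \code{FALSE}).
#' @return List with \code{mmer} (the minimizer as a string, in the
#'   orientation in which it won), \code{rank}, \code{pos} (0-based
#'   offset of the occurrence on the forward strand) and \code{strand}
#'   (\code{"+"} or \code{"-"}).
#' @examples
#' ord <- build_ordering("lex", m = 3)
#' minimizer_of("CAAG", ord)$mmer  # "AAG"
#' @export
minimizer_of <- function(kmer, ordering, canonical = FALSE) {
  stopifnot(inherits(ordering, "minimizer_ordering"))
  cpp_minimizer_of(kmer, ordering$m, ordering$rank, canonical)
}

#' Decompose a fragment into super-mers
#'
#' A super-mer is a maximal substring whose k-mer windows all share the
#' same minimizer occurrence; scanning windows left to right, a new
#' super-mer starts exactly when the minimal m-mer occurrence moves
#' (even if the new occurrence spells the same m-mer). Adjacent
#' super-mers overlap by k-1 bases, and the k-mer windows of all
#' super-mers reproduce the fragment's windows exactly once each.
#'
#' @param fragment Character scalar over ACGT with at least k bases.
#' @param k K-mer length (k >= m).
#' @param ordering A \code{\link{build_ordering}} result.
#' @param canonical Minimize over both strands (default \code{FALSE}).
#' @return A data.frame with columns \code{supermer} (bases, read-strand
#'   orientation), \code{rank} (shared minimizer rank), \code{start}
#'   (0-based offset in the fragment) and \code{n_kmers}.
#' @examples
#' ord <- build_ordering("lex", m = 3)
#' super_mers("CAAGAACAGTG", k = 4, ord)$supermer
#' @export
super_mers <- function(fragment, k, ordering, canonical = FALSE) {
  stopifnot(inherits(ordering, "minimizer_ordering"))
  cpp_super_mers(fragment, as.integer(k), ordering$m, ordering$rank,
                 canonical)
}
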