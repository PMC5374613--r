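#' Encode a DNA string into a 2-bit packed representation
#'
#' Bases are coded A=0, C=1, G=2, T=3 (case-insensitive), four bases per
#' byte with the first base of each byte in the most significant bit
#' pair. With this code map, byte-wise comparison of two equal-length
#' packed sequences equals lexicographic comparison with A<C<G<T, so
#' canonicalization reduces to an integer comparison.
#'
#' @param seq A non-empty character scalar over \code{A,C,G,T}
#'   (lower case accepted).
#' @return An object of class \code{encoded_seq}: a list with elements
#'   \code{packed} (raw vector of \code{ceiling(length/4)} bytes) and
#'   \code{length} (number of bases).
#' @examples
#' es <- encode_seq("CAAGAACAGTG")
#' decode_seq(es)
#' @export
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  structure(list(packed = cpp_encode(seq), length = nchar(seq)),
            class = "encoded_seq")
}

#' Decode a packed sequence back to a base string
#'
#' @param x An \code{encoded_seq}.
#' @return Character scalar over \code{A,C,G,T}.
#' @export
decode_seq <- function(x) {
  stopifnot(inherits(x, "encoded_seq"))
  cpp_decode(x$packed, x$length)
}

#' @export
print.encoded_seq <- function(x, ...) {
  s <- decode_seq(x)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<encoded_seq, %d bases> %s\n", x$length, s))
  invisible(x)
}

#' @export
format.encoded_seq <- function(x, ...) decode_seq(x)

as_encoded <- function(x) {
  if (inherits(x, "encoded_seq")) x else encode_seq(x)
}

#' Reverse complement of a DNA sequence
#'
#' Reverses the sequence and swaps A with T and C with G. An
#' \code{encoded_seq} input yields an \code{encoded_seq}; a character
#' input yields a character.
#'
#' @param x An \code{encoded_seq} or character scalar.
#' @return Same type as the input.
#' @examples
#' reverse_complement("AAAA")
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) return(decode_seq(reverse_complement(encode_seq(x))))
  stopifnot(inherits(x, "encoded_seq"))
  structure(list(packed = cpp_revcomp(x$packed, x$length), length = x$length),
            class = "encoded_seq")
}

#' Canonical form of a k-mer
#'
#' The lexicographically lesser (A<C<G<T) of a k-mer and its reverse
#' complement, so that both strands of a double helix count as one
#' entity.
#'
#' @param x An \code{encoded_seq} or character scalar.
#' @return Same type as the input.
#' @examples
#' canonical_kmer("TTTT")
#' @export
canonical_kmer <- function(x) {
  if (is.character(x)) return(decode_seq(canonical_kmer(encode_seq(x))))
  stopifnot(inherits(x, "encoded_seq"))
  structure(list(packed = cpp_canonical(x$packed, x$length), length = x$length),
            class = "encoded_seq")
}

#' Split a read into its maximal ACGT fragments
#'
#' Reads may contain ambiguity symbols (most commonly \code{N}). K-mers
#' spanning such symbols are undefined, so the read is split at every
#' non-ACGT character and each maximal ACGT run is processed on its own.
#' Fragments shorter than k are skipped by downstream callers.
#'
#' @param seq Character scalar; any symbols allowed.
#' @return Character vector of uppercased ACGT fragments (possibly empty).
#' @examples
#' split_fragments("ACGTNACGT")
#' @export
split_fragments <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_fragments(seq)
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}. Gzipped files
#' are decompressed transparently; multi-line FASTA records are
#' concatenated; FASTQ quality lines are ignored (no quality filtering is
#' performed).
#'
#' @param path Path to a (possibly gzipped) FASTA or FASTQ file.
#' @param format One of \code{"auto"}, \code{"fasta"}, \code{"fastq"}.
#'   With \code{"auto"} the format is taken from the file extension,
#'   falling back to the first character of the file.
#' @return A data.frame with columns \code{id} and \code{seq}, one row
#'   per record, in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") format <- detect_format(path)
  recs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("malformed ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  data.frame(id = if (is.null(names(recs))) as.character(seq_along(recs))
             else names(recs),
             seq = as.character(recs),
             stringsAsFactors = FALSE, row.names = NULL)
}

detect_format <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", base))
  if (ext %in% c("fa", "fasta", "fna", "ffn")) return("fasta")
  if (ext %in% c("fq", "fastq")) return("fastq")
  con <- if (grepl("\\.(gz|bgz)$", path, ignore.case = TRUE))
    gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop("empty input file: ", path)
  if (startsWith(first, ">")) "fasta"
  else if (startsWith(first, "@")) "fastq"
  else stop("cannot detect format of '", path,
            "': first line starts with neither '>' nor '@'")
}
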