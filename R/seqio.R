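# Sequence input, letter handling and word-state encoding.

# letter -> base-4 digit lookup, indexed by integer character code + 1.
# A=0, C=1, G=2, T=3; anything else (N, IUPAC ambiguity codes, ...) is -1.
.letter_code_table <- local({
  tab <- rep(-1L, 256L)
  tab[utf8ToInt("A") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L
  tab
})

.letter_codes <- function(char_codes) {
  .letter_code_table[char_codes + 1L]
}

#' Word codec: bijection between m-letter DNA words and state indices
#'
#' Fixes the word length `m` and therefore the state space of the
#' word-transition network: the \eqn{N = 4^m} words over \{A,C,G,T\} are the
#' nodes, numbered 0..N-1 in lexicographic order (A=0, C=1, G=2, T=3,
#' leftmost letter most significant).
#'
#' @param m Word length in letters, between 1 and 10.
#' @return An object of class `word_codec` with elements `m` and `N = 4^m`.
#' @examples
#' codec <- word_codec(6)
#' codec$N  # 4096
#' @export
word_codec <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m != as.integer(m))
    stop("`m` must be a single integer")
  m <- as.integer(m)
  if (m < 1L || m > 10L) stop("`m` must be between 1 and 10")
  structure(list(m = m, N = as.integer(4^m)), class = "word_codec")
}

#' @export
print.word_codec <- function(x, ...) {
  cat(sprintf("<word_codec> m = %d letters, N = 4^%d = %d states\n",
              x$m, x$m, x$N))
  invisible(x)
}

#' Encode m-letter words as state indices
#'
#' @param words Character vector of words, each exactly `codec$m` letters
#'   over \{A,C,G,T\}.
#' @param codec A [word_codec()].
#' @return Integer vector of 0-based state indices in `[0, 4^m)`.
#' @examples
#' encode_word("ACGT", word_codec(4))  # 27
#' @export
encode_word <- function(words, codec) {
  stopifnot(inherits(codec, "word_codec"))
  m <- codec$m
  if (any(is.na(words)) || any(nchar(words) != m))
    stop(sprintf("every word must have exactly %d letters", m))
  pow <- 4^((m - 1L):0)
  out <- vapply(words, function(w) {
    codes <- .letter_codes(utf8ToInt(w))
    if (any(codes < 0L)) stop("words may only contain letters A, C, G, T")
    sum(codes * pow)
  }, numeric(1), USE.NAMES = FALSE)
  as.integer(out)
}

#' Decode state indices back into m-letter words
#'
#' Inverse of [encode_word()].
#'
#' @param idx Integer vector of 0-based state indices.
#' @param codec A [word_codec()].
#' @return Character vector of words.
#' @export
decode_word <- function(idx, codec) {
  stopifnot(inherits(codec, "word_codec"))
  m <- codec$m
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 0L) || any(idx >= codec$N))
    stop("state index out of range [0, N)")
  letters4 <- c("A", "C", "G", "T")
  # digits matrix: m rows (most significant first) x length(idx) cols
  digs <- matrix(0L, nrow = m, ncol = length(idx))
  rem <- idx
  for (pos in m:1) {
    digs[pos, ] <- rem %% 4L
    rem <- rem %/% 4L
  }
  apply(digs, 2, function(d) paste(letters4[d + 1L], collapse = ""))
}

#' Read a FASTA file
#'
#' Reads a (possibly gzip-compressed) FASTA file and returns the raw,
#' uppercased letter strings, one per record, in file order.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @return Named character vector; names are the record headers.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no FASTA records in ", path)
  out <- toupper(as.character(dss))
  names(out) <- names(dss)
  out
}

#' Split a raw letter string into determined segments
#'
#' Undetermined letters (N or any character outside \{A,C,G,T\}) break the
#' sequence: no word is formed across them and no transition is counted over
#' the break. This returns the maximal runs of determined letters, in order,
#' with their 0-based offsets in the source string.
#'
#' @param raw A single letter string (case-insensitive).
#' @param record_id Optional identifier of the source record.
#' @return List of `letter_segment` objects with fields `letters`,
#'   `record_id` and `offset`. Empty list if no determined letters exist.
#' @examples
#' segment_letters("ACGTNNACG")  # two segments at offsets 0 and 6
#' @export
segment_letters <- function(raw, record_id = NA_character_) {
  stopifnot(is.character(raw), length(raw) == 1L)
  raw <- toupper(raw)
  mt <- gregexpr("[ACGT]+", raw)[[1L]]
  if (mt[1L] == -1L) return(list())
  lens <- attr(mt, "match.length")
  starts <- as.integer(mt)
  Map(function(start, len) {
    structure(list(
      letters   = substr(raw, start, start + len - 1L),
      record_id = record_id,
      offset    = start - 1L
    ), class = "letter_segment")
  }, starts, lens)
}

#' Tile a segment into consecutive non-overlapping word states
#'
#' Reads the segment left to right in blocks of `m` letters starting at the
#' first letter (stride `m`, no overlap); a trailing remainder shorter than
#' `m` is discarded.
#'
#' @param segment A `letter_segment` or a plain letter string over
#'   \{A,C,G,T\}.
#' @param codec A [word_codec()].
#' @return Integer vector of `floor(len/m)` state indices (possibly empty).
#' @examples
#' tile_segment("ACGTACGTAC", word_codec(4))  # c(27, 27); tail "AC" dropped
#' @export
tile_segment <- function(segment, codec) {
  stopifnot(inherits(codec, "word_codec"))
  letters <- if (inherits(segment, "letter_segment")) segment$letters else segment
  stopifnot(is.character(letters), length(letters) == 1L)
  codes <- .letter_codes(utf8ToInt(letters))
  if (any(codes < 0L)) stop("segment contains letters outside {A,C,G,T}")
  m <- codec$m
  n <- length(codes) %/% m
  if (n == 0L) return(integer(0))
  mat <- matrix(codes[seq_len(n * m)], nrow = m)
  as.integer(colSums(mat * 4^((m - 1L):0)))
}

#' Tile all determined segments of one or more raw sequences
#'
#' Convenience wrapper: segments every input string on undetermined letters
#' and tiles each segment independently, so that no word or transition spans
#' an undetermined run or a record boundary.
#'
#' @param raw Character vector of raw letter strings (one per record).
#' @param codec A [word_codec()].
#' @return List of integer state-index vectors, one per determined segment.
#' @export
tile_sequences <- function(raw, codec) {
  segs <- unlist(lapply(seq_along(raw), function(i) {
    id <- if (!is.null(names(raw))) names(raw)[i] else as.character(i)
    segment_letters(raw[[i]], record_id = id)
  }), recursive = FALSE)
  lapply(segs, tile_segment, codec = codec)
}

#' Letter composition of raw sequences
#'
#' @param x Character vector of letter strings.
#' @return Named numeric vector of the fractions of A, C, G, T and
#'   undetermined characters; sums to 1.
#' @examples
#' letter_fractions("ACGTN")  # 0.2 each
#' @export
letter_fractions <- function(x) {
  if (length(x) < 1L) stop("empty input")
  codes <- utf8ToInt(toupper(paste(x, collapse = "")))
  if (length(codes) == 0L) stop("empty input")
  lc <- .letter_codes(codes)
  counts <- c(
    A = sum(lc == 0L), C = sum(lc == 1L),
    G = sum(lc == 2L), T = sum(lc == 3L),
    undetermined = sum(lc < 0L)
  )
  counts / length(codes)
}
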