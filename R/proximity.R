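# PageRank proximity between two rankings: (K_A, K_B) diagrams, the
# dispersion correlator D, its random-permutation normalization and the
# dimensionless ratio zeta, plus word-composition annotations.

#' Per-word rank pairs of two rankings
#'
#' Pairs the rank index of each word in ranking A with its rank in ranking
#' B over the common universe of all 4^m words. Identical rankings put all
#' points on the diagonal K_A = K_B.
#'
#' @param rvA,rvB `rank_vector` objects (or plain rank permutations) of the
#'   same length N = 4^m.
#' @param codec A [word_codec()]; taken from `rvA` if absent.
#' @return Data frame with columns `word`, `K_A`, `K_B`, ordered by `K_A`.
#' @export
rank_pairs <- function(rvA, rvB, codec = NULL) {
  KA <- if (inherits(rvA, "rank_vector")) rvA$K else as.integer(rvA)
  KB <- if (inherits(rvB, "rank_vector")) rvB$K else as.integer(rvB)
  if (length(KA) != length(KB))
    stop("rankings must cover the same word universe (same m)")
  if (is.null(codec) && inherits(rvA, "rank_vector")) codec <- rvA$codec
  words <- if (!is.null(codec)) {
    if (codec$N != length(KA)) stop("codec size does not match rankings")
    decode_word(seq_along(KA) - 1L, codec)
  } else {
    as.character(seq_along(KA) - 1L)
  }
  df <- data.frame(word = words, K_A = KA, K_B = KB,
                   stringsAsFactors = FALSE)
  df[order(df$K_A), , drop = FALSE]
}

#' Average rank dispersion between two rankings
#'
#' D = (1/N) sum_w (K_A(w) - K_B(w))^2, in squared-rank units.
#'
#' @param pairs Data frame with columns `K_A`, `K_B` (see [rank_pairs()]).
#' @return The dispersion D >= 0.
#' @export
dispersion <- function(pairs) {
  if (!nrow(pairs)) stop("empty rank pairs")
  mean((pairs$K_A - pairs$K_B)^2)
}

#' Random-model dispersion
#'
#' Expected dispersion when the N points are placed at random in the N x N
#' rank square with exactly one point per row and per column (i.e. the two
#' rankings are independent uniform permutations):
#' D_rnd = (N^2 - 1)/6. Exact closed form; matches exhaustive enumeration
#' over all permutations.
#'
#' @param N Number of words, at least 2.
#' @return D_rnd.
#' @examples
#' random_dispersion(3)  # 4/3
#' random_dispersion(4)  # 2.5
#' @export
random_dispersion <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop("`N` must be a single number >= 2")
  (N^2 - 1) / 6
}

#' Dimensionless proximity correlator zeta
#'
#' zeta = D / D_rnd: 0 for identical rankings, about 1 for unrelated ones.
#' Because D scales as N^2 between word lengths, zeta is nearly independent
#' of m, which is what makes it usable as a proximity measure across word
#' lengths.
#'
#' @param D Dispersion from [dispersion()].
#' @param N Number of words.
#' @return zeta >= 0.
#' @export
zeta <- function(D, N) {
  if (!is.numeric(D) || D < 0) stop("`D` must be nonnegative")
  D / random_dispersion(N)
}

#' Fraction of a word's letters in a given set
#'
#' Used to color proximity diagrams: the purine content is the fraction of
#' letters A or G, the weak (A/T) content the fraction of letters A or T.
#'
#' @param words Character vector of words.
#' @param letter_set Character vector of letters, e.g. `c("A", "G")`.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' word_fraction("GAGGAG", c("A", "G"))  # 1
#' word_fraction("ACGT", c("A", "T"))    # 0.5
#' @export
word_fraction <- function(words, letter_set) {
  if (any(nchar(words) == 0L)) stop("words must be nonempty")
  vapply(strsplit(toupper(words), ""), function(ch) mean(ch %in% letter_set),
         numeric(1))
}

#' PageRank proximity report between two rankings
#'
#' Assembles the full comparison: per-word rank pairs annotated with purine
#' and A/T content, the dispersion D, the random-model value D_rnd, and the
#' dimensionless zeta = D/D_rnd.
#'
#' @param rvA,rvB `rank_vector` objects over the same word universe.
#' @param codec A [word_codec()]; taken from `rvA` if absent.
#' @param ids Character vector of length 2 naming the two inputs.
#' @return Object of class `proximity_report` with fields `ids`, `pairs`
#'   (data frame `word`, `K_A`, `K_B`, `purine_fraction`, `at_fraction`),
#'   `D`, `D_rnd`, `zeta`, `N`.
#' @export
proximity_report <- function(rvA, rvB, codec = NULL, ids = c("A", "B")) {
  pairs <- rank_pairs(rvA, rvB, codec)
  if (is.null(codec) && inherits(rvA, "rank_vector")) codec <- rvA$codec
  if (!is.null(codec)) {
    pairs$purine_fraction <- word_fraction(pairs$word, c("A", "G"))
    pairs$at_fraction <- word_fraction(pairs$word, c("A", "T"))
  }
  N <- nrow(pairs)
  D <- dispersion(pairs)
  structure(list(
    ids = ids, pairs = pairs, D = D,
    D_rnd = random_dispersion(N), zeta = zeta(D, N), N = N
  ), class = "proximity_report")
}

#' @export
print.proximity_report <- function(x, ...) {
  cat(sprintf("<proximity_report> %s vs %s: N = %d words, D = %.4g, D_rnd = %.4g, zeta = %.4g\n",
              x$ids[1L], x$ids[2L], x$N, x$D, x$D_rnd, x$zeta))
  invisible(x)
}

#' Export a proximity report
#'
#' Writes the summary (ids, N, D, D_rnd, zeta) as JSON and, optionally, the
#' per-word rank pairs with composition annotations as TSV, suitable for
#' re-plotting proximity diagrams.
#'
#' @param report A `proximity_report`.
#' @param json_path Output JSON path.
#' @param tsv_path Optional output TSV path for the pair table.
#' @return `json_path`, invisibly.
#' @export
write_proximity <- function(report, json_path, tsv_path = NULL) {
  stopifnot(inherits(report, "proximity_report"))
  jsonlite::write_json(
    list(ids = report$ids, N = report$N, D = report$D,
         D_rnd = report$D_rnd, zeta = report$zeta),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(tsv_path)) {
    utils::write.table(report$pairs, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
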