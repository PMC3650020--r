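# End-to-end orchestration: build the Google matrix and all analyses from
# FASTA input, compare two inputs, and write synthetic FASTA. These back
# the command-line script shipped in inst/cli/seqrank.R.

#' Build the word-transition Google matrix from sequences
#'
#' Runs the core construction: segment on undetermined letters, tile into
#' non-overlapping m-letter words, count transitions, normalize columns
#' (dangling columns uniform) and apply damping.
#'
#' @param x FASTA path(s), or a character vector of raw letter strings.
#' @param m Word length in letters.
#' @param alpha Damping factor (default 0.85).
#' @return List with `codec`, `counts` (`transition_counts`), `S`
#'   (`column_stochastic`), `G` (`google_matrix`), `word_lists`,
#'   `letter_fractions`.
#' @export
sequence_google <- function(x, m, alpha = 0.85) {
  raw <- if (length(x) && all(file.exists(x))) {
    unlist(lapply(x, read_fasta))
  } else {
    x
  }
  if (!length(raw)) stop("no input sequences")
  codec <- word_codec(m)
  word_lists <- tile_sequences(raw, codec)
  counts <- count_transitions(word_lists, codec)
  S <- to_stochastic(counts)
  list(
    codec = codec, counts = counts, S = S, G = to_google(S, alpha),
    word_lists = word_lists, letter_fractions = letter_fractions(raw)
  )
}

#' End-to-end build with artifact output
#'
#' Full analysis of one or more FASTA inputs: transition counts, stochastic
#' and Google matrices, PageRank (top/bottom word tables), the dense
#' spectrum with IPRs (when N is within `dense_cap`), and the integrated
#' element / ingoing-sum distributions. All artifacts are written as plain
#' text: `Q.mtx`, `S.mtx`, `rank.tsv`, `spectrum.csv`, `dist.csv`,
#' `report.json`.
#'
#' @param inputs FASTA path(s).
#' @param m Word length.
#' @param out_dir Output directory (created if needed).
#' @param alpha Damping factor.
#' @param spectrum Compute the dense spectrum? Default: yes when N <=
#'   `dense_cap`.
#' @param dense_cap Dense diagonalization cap (see [full_spectrum()]).
#' @param allow_large_spectrum Override the cap.
#' @param dist_matrix Which element view feeds the distributions: the
#'   damping-free `"S"` (default; every element of G has the floor
#'   (1-alpha)/N, which hides the small-element tail) or `"G"`.
#' @param fit_range Optional `c(gmin, gmax)` power-law fit range for the
#'   element distribution.
#' @param top_n Number of head/tail words reported in `report.json`.
#' @return Invisibly, a list with all computed objects and artifact paths.
#' @export
run_build <- function(inputs, m, out_dir, alpha = 0.85, spectrum = NULL,
                      dense_cap = 4096L, allow_large_spectrum = FALSE,
                      dist_matrix = c("S", "G"), fit_range = NULL,
                      top_n = 10L) {
  dist_matrix <- match.arg(dist_matrix)
  built <- sequence_google(inputs, m, alpha)
  codec <- built$codec
  if (built$counts$N_s == 0L)
    stop("no word transitions in the input (sequences too short for m?)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    Q = file.path(out_dir, "Q.mtx"),
    S = file.path(out_dir, "S.mtx"),
    rank = file.path(out_dir, "rank.tsv"),
    spectrum = file.path(out_dir, "spectrum.csv"),
    dist = file.path(out_dir, "dist.csv"),
    report = file.path(out_dir, "report.json")
  )
  write_counts_mtx(built$counts, paths$Q)
  write_stochastic_mtx(built$S, paths$S)

  rv <- pagerank(built$G)
  ord <- order(rv$K)
  rank_tab <- data.frame(
    K = rv$K[ord],
    word = decode_word(ord - 1L, codec),
    state_index = ord - 1L,
    P = rv$P[ord]
  )
  utils::write.table(rank_tab, paths$rank, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (is.null(spectrum)) spectrum <- codec$N <= dense_cap
  sp <- NULL
  gap <- NULL
  iprs <- NULL
  if (spectrum) {
    sp <- full_spectrum(built$G, dense_cap = dense_cap,
                        allow_large = allow_large_spectrum)
    gap <- spectral_gap(sp)
    iprs <- apply(sp$vectors[, seq_len(min(10L, codec$N)), drop = FALSE],
                  2L, ipr)
    utils::write.table(
      data.frame(index = seq_along(sp$values),
                 re = Re(sp$values), im = Im(sp$values),
                 ipr = apply(sp$vectors, 2L, ipr)),
      paths$spectrum, sep = ",", quote = FALSE, row.names = FALSE
    )
  }

  Mview <- if (dist_matrix == "S") built$S else built$G
  dist <- element_distribution(Mview)
  utils::write.table(
    data.frame(g = dist$grid, fraction = dist$fraction),
    paths$dist, sep = ",", quote = FALSE, row.names = FALSE
  )
  fit <- if (!is.null(fit_range))
    fit_power_law(dist, fit_range[1L], fit_range[2L]) else NULL

  report <- list(
    m = codec$m, N = codec$N, alpha = alpha,
    n_transitions = built$counts$N_s,
    dist_matrix = dist_matrix,
    letter_fractions = as.list(built$letter_fractions),
    pagerank_iterations = rv$iterations,
    top_words = utils::head(rank_tab, top_n),
    bottom_words = utils::tail(rank_tab, top_n),
    spectral_gap = if (!is.null(gap)) gap$gap else NULL,
    lambda2_radius = if (!is.null(gap)) gap$radius else NULL,
    ipr_top_eigenvectors = if (!is.null(iprs)) as.numeric(iprs) else NULL,
    element_exponent_mu = if (!is.null(fit)) fit$exponent else NULL
  )
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(
    codec = codec, counts = built$counts, S = built$S, G = built$G,
    pagerank = rv, spectrum = sp, gap = gap, distribution = dist,
    fit = fit, rank_table = rank_tab, paths = paths,
    letter_fractions = built$letter_fractions
  ))
}

#' Compare the PageRank of two inputs
#'
#' Builds both word rankings at the same word length and writes the
#' proximity report (`proximity.json`, `proximity.tsv`).
#'
#' @param input_a,input_b FASTA paths (or raw letter strings).
#' @param m Word length, shared by both inputs.
#' @param out_dir Output directory.
#' @param alpha Damping factor.
#' @param ids Labels of the two inputs.
#' @return Invisibly, the `proximity_report`.
#' @export
run_compare <- function(input_a, input_b, m, out_dir, alpha = 0.85,
                        ids = c("A", "B")) {
  rvA <- pagerank(sequence_google(input_a, m, alpha)$G)
  rvB <- pagerank(sequence_google(input_b, m, alpha)$G)
  report <- proximity_report(rvA, rvB, ids = ids)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_proximity(report,
                  file.path(out_dir, "proximity.json"),
                  file.path(out_dir, "proximity.tsv"))
  invisible(report)
}

#' Write a synthetic sequence as FASTA
#'
#' @param spec List describing the generator: `kind` (`"iid"` or
#'   `"word_markov"`), `seed`, and either `letter_probs` + `length` (iid)
#'   or `P` + `m` + `n_words` (+ optional `start`) for the word chain;
#'   optional `n_runs` / `run_len` inject runs of undetermined letters.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
run_simulate <- function(spec, path) {
  if (is.null(spec$kind) || is.null(spec$seed)) stop("spec needs `kind` and `seed`")
  letters <- switch(spec$kind,
    iid = iid_sequence(spec$letter_probs, spec$length, spec$seed),
    word_markov = markov_word_sequence(spec$P, word_codec(spec$m),
                                       spec$n_words, spec$seed, spec$start),
    stop("unknown generator kind: ", spec$kind)
  )
  if (!is.null(spec$n_runs) && spec$n_runs > 0L) {
    letters <- inject_ambiguous(letters, spec$n_runs, spec$run_len,
                                seed = spec$seed + 1L)
  }
  header <- sprintf("synthetic kind=%s seed=%d length=%d",
                    spec$kind, spec$seed, nchar(letters))
  dss <- Biostrings::DNAStringSet(letters)
  names(dss) <- header
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
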