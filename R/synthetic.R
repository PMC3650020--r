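# Seeded generators for synthetic sequences and null-model matrices.
# These define the ground truth against which the estimation pipeline is
# validated: i.i.d. letter strings, word-level Markov chains with a known
# transition law, undetermined-letter injection, planted Zipf stationary
# laws, block-structured chains, and the shuffled-element null model.

.LETTERS4 <- c("A", "C", "G", "T")

#' Generate an i.i.d. letter sequence
#'
#' @param letter_probs Probabilities of A, C, G, T (length 4, sum 1).
#' @param L Number of letters, >= 1.
#' @param seed RNG seed; fixed seed gives a bit-identical string.
#' @return A single letter string of length L.
#' @export
iid_sequence <- function(letter_probs, L, seed) {
  if (length(letter_probs) != 4L || any(letter_probs < 0) ||
      abs(sum(letter_probs) - 1) > 1e-12)
    stop("`letter_probs` must be 4 nonnegative values summing to 1")
  if (L < 1L) stop("`L` must be >= 1")
  set.seed(seed)
  codes <- c(65L, 67L, 71L, 84L)[sample.int(4L, L, replace = TRUE,
                                            prob = letter_probs)]
  intToUtf8(codes)
}

#' Stationary vector of a column-stochastic matrix
#'
#' Power iteration on the plain stochastic matrix (no damping).
#'
#' @param P Column-stochastic matrix.
#' @param tol L1 tolerance.
#' @param max_iter Iteration cap.
#' @return Probability vector p with P p = p.
#' @export
stationary_vector <- function(P, tol = 1e-13, max_iter = 100000L) {
  P <- as.matrix(P)
  N <- ncol(P)
  v <- rep(1 / N, N)
  for (it in seq_len(max_iter)) {
    w <- as.vector(P %*% v)
    w <- w / sum(w)
    if (sum(abs(w - v)) <= tol) return(w)
    v <- w
  }
  v
}

#' Generate a word sequence from a known Markov chain
#'
#' Draws `n_words` word states sequentially from the column-stochastic
#' transition law `P_true` (column = source state) and concatenates their
#' decoded letters into one string of `n_words * m` letters. Because the
#' tiling stride equals the word length, feeding the output back through
#' [tile_sequences()] recovers exactly the simulated state sequence, giving
#' clean parameter-recovery semantics for the transition-matrix estimator.
#'
#' @param P_true N x N column-stochastic matrix over the 4^m word states
#'   (plain matrix or `column_stochastic`).
#' @param codec A [word_codec()] with 4^m = N.
#' @param n_words Number of words to draw, >= 2.
#' @param seed RNG seed.
#' @param start Optional 0-based start state; default draws it from the
#'   stationary vector of `P_true`.
#' @return A letter string of `n_words * m` letters.
#' @export
markov_word_sequence <- function(P_true, codec, n_words, seed, start = NULL) {
  stopifnot(inherits(codec, "word_codec"))
  P <- as.matrix(P_true)
  N <- codec$N
  if (nrow(P) != N || ncol(P) != N)
    stop("`P_true` must be 4^m x 4^m")
  if (any(P < 0) || any(abs(colSums(P) - 1) > 1e-12))
    stop("`P_true` must be column-stochastic")
  if (n_words < 2L) stop("`n_words` must be >= 2")
  set.seed(seed)
  cum <- apply(P, 2L, cumsum)
  states <- integer(n_words)
  states[1L] <- if (is.null(start)) {
    pi0 <- stationary_vector(P)
    sample.int(N, 1L, prob = pi0)
  } else {
    if (start < 0L || start >= N) stop("`start` out of range [0, N)")
    as.integer(start) + 1L
  }
  u <- stats::runif(n_words - 1L)
  for (k in 2L:n_words) {
    s <- findInterval(u[k - 1L], cum[, states[k - 1L]]) + 1L
    states[k] <- min(s, N)
  }
  paste(decode_word(states - 1L, codec), collapse = "")
}

#' Insert runs of undetermined letters into a sequence
#'
#' Inserts `n_runs` runs of `run_len` copies of `N` at random (or given)
#' positions between existing letters. The determined-letter content is
#' preserved in order, so segmenting the output reconstructs the input.
#'
#' @param letters A single letter string.
#' @param n_runs Number of runs to insert.
#' @param run_len Length of each run.
#' @param seed RNG seed (ignored when `positions` is given).
#' @param positions Optional 0-based insertion gaps (0 = before the first
#'   letter, `nchar(letters)` = after the last); drawn at random if `NULL`.
#' @return The letter string with runs inserted.
#' @export
inject_ambiguous <- function(letters, n_runs, run_len, seed = NULL,
                             positions = NULL) {
  stopifnot(is.character(letters), length(letters) == 1L)
  L <- nchar(letters)
  if (n_runs == 0L) return(letters)
  if (n_runs * run_len >= L)
    stop("total undetermined length must be smaller than the sequence")
  if (is.null(positions)) {
    if (is.null(seed)) stop("either `seed` or `positions` must be given")
    set.seed(seed)
    positions <- sort(sample(0:L, n_runs, replace = FALSE))
  } else {
    positions <- sort(as.integer(positions))
    if (length(positions) != n_runs || any(positions < 0L) ||
        any(positions > L))
      stop("invalid insertion positions")
  }
  run <- strrep("N", run_len)
  pieces <- character(2L * n_runs + 1L)
  prev <- 0L
  for (k in seq_len(n_runs)) {
    pieces[2L * k - 1L] <- substr(letters, prev + 1L, positions[k])
    pieces[2L * k] <- run
    prev <- positions[k]
  }
  pieces[2L * n_runs + 1L] <- substr(letters, prev + 1L, L)
  paste(pieces, collapse = "")
}

#' Shuffled-element null-model matrix
#'
#' Permutes the multiset of all N^2 element values uniformly over matrix
#' positions, then (by default) renormalizes each column to sum 1 (all-zero
#' columns become uniform). The element-value histogram is preserved
#' exactly before the renormalization step. This is the random-matrix null
#' model: it keeps the value distribution of the original matrix but
#' destroys its structure, which collapses the radius of the eigenvalue
#' cloud relative to a structured chain.
#'
#' @param M Square matrix (or `column_stochastic` / `google_matrix` element
#'   view).
#' @param seed RNG seed.
#' @param renormalize If `FALSE`, return the permuted matrix before column
#'   renormalization (useful for checking value-multiset preservation).
#' @return A dense square matrix.
#' @export
shuffled_value_matrix <- function(M, seed, renormalize = TRUE) {
  M <- .element_view(M)
  N <- nrow(M)
  if (ncol(M) != N) stop("matrix must be square")
  set.seed(seed)
  v <- as.vector(M)
  R <- matrix(v[sample.int(length(v))], N, N)
  if (!renormalize) return(R)
  cs <- colSums(R)
  zero <- cs == 0
  cs[zero] <- 1
  R <- sweep(R, 2L, cs, "/")
  if (any(zero)) R[, zero] <- 1 / N
  R
}

#' Column-stochastic matrix with a planted Zipf stationary law
#'
#' Builds the rank-one transition law whose every column equals the same
#' probability vector p, where p carries mass proportional to K^-beta0
#' over a random permutation of the states. The stationary vector is then
#' exactly p, the PageRank decay follows K^-beta0 by construction, and the
#' ingoing sums are N*p, so the ingoing-sum exponent is nu = 1 + 1/beta0
#' and the scale-free relation beta = 1/(nu - 1) holds identically. Used to
#' validate the exponent-fitting machinery against known truth.
#'
#' @param N Number of states.
#' @param beta0 Target PageRank decay exponent, > 0.
#' @param seed RNG seed for the rank-to-state assignment.
#' @return N x N column-stochastic matrix with attribute `"stationary"`.
#' @export
zipf_planted_matrix <- function(N, beta0, seed) {
  if (beta0 <= 0) stop("`beta0` must be positive")
  set.seed(seed)
  p_ranked <- (seq_len(N))^(-beta0)
  p_ranked <- p_ranked / sum(p_ranked)
  perm <- sample.int(N)
  p <- numeric(N)
  p[perm] <- p_ranked
  M <- matrix(p, N, N)
  attr(M, "stationary") <- p
  M
}

#' Block-structured column-stochastic matrix
#'
#' A planted community chain: each column places weight `within` uniformly
#' on the source state's own block and the remaining mass uniformly on the
#' other states. For `within` close to 1 the blocks are almost decoupled,
#' so the subleading eigenvalues are large; shuffling the element values
#' (see [shuffled_value_matrix()]) destroys the blocks and shrinks them.
#'
#' @param N Number of states.
#' @param n_blocks Number of equal blocks (must divide N).
#' @param within Total within-block column mass, in (0, 1\].
#' @return N x N column-stochastic matrix.
#' @export
block_structured_matrix <- function(N, n_blocks = 2L, within = 0.95) {
  if (N %% n_blocks != 0L) stop("`n_blocks` must divide N")
  if (within <= 0 || within > 1) stop("`within` must be in (0, 1]")
  bs <- N %/% n_blocks
  block_of <- rep(seq_len(n_blocks), each = bs)
  M <- matrix((1 - within) / (N - bs), N, N)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    M[idx, idx] <- within / bs
  }
  if (within == 1) {
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      M[, idx] <- 0
      M[idx, idx] <- 1 / bs
    }
  }
  M
}
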