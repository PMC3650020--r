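# PageRank / CheiRank, full spectrum, spectral gap, eigenvector
# localization (IPR) and top-amplitude word extraction.

#' PageRank of a Google matrix by power iteration
#'
#' Iterates v <- G v from the uniform vector until the L1 residual
#' ||G v - v||_1 drops below `tol`. Because the spectrum of these
#' word-transition Google matrices has a large gap below lambda_1 = 1,
#' convergence is fast; the damping term guarantees a unique fixed point
#' for alpha < 1.
#'
#' @param G A `google_matrix`.
#' @param tol L1 self-consistency tolerance (default 1e-12).
#' @param max_iter Maximum number of iterations (default 10000).
#' @return Object of class `rank_vector`: probabilities `P` (sum 1), rank
#'   permutation `K` (K = 1 marks the largest P; ties broken by ascending
#'   state index), `alpha`, `iterations`, `residual`, `codec`.
#' @export
pagerank <- function(G, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(G, "google_matrix"))
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive")
  N <- G$N
  v <- rep(1 / N, N)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- gm_multiply(G, v)
    w <- w / sum(w)
    res <- sum(abs(w - v))
    v <- w
    if (res <= tol) break
  }
  if (res > tol)
    stop(sprintf("power iteration did not converge in %d iterations (residual %.3e)",
                 max_iter, res))
  structure(list(
    P = v, K = rank_order(v), alpha = G$alpha,
    iterations = it, residual = res, codec = G$codec
  ), class = "rank_vector")
}

#' @export
print.rank_vector <- function(x, ...) {
  cat(sprintf("<rank_vector> N = %d, alpha = %g, %d iterations, residual %.2e\n",
              length(x$P), x$alpha, x$iterations, x$residual))
  invisible(x)
}

#' CheiRank: PageRank of the direction-reversed chain
#'
#' @param tc A `transition_counts` object.
#' @param alpha Damping factor.
#' @param ... Passed to [pagerank()].
#' @return A `rank_vector` for the reversed-transition Google matrix G*.
#' @export
cheirank <- function(tc, alpha = 0.85, ...) {
  pagerank(to_google(to_stochastic(reversed_counts(tc)), alpha), ...)
}

#' Rank permutation of a probability vector
#'
#' @param P Numeric vector of probabilities (or any scores).
#' @return Integer vector `K` with `K[i]` the rank of state i: 1 for the
#'   largest P, ties broken by ascending state index.
#' @examples
#' rank_order(c(0.2, 0.5, 0.3))  # c(3, 1, 2)
#' @export
rank_order <- function(P) {
  if (length(P) < 1L) stop("empty probability vector")
  ord <- order(-P, seq_along(P))
  K <- integer(length(P))
  K[ord] <- seq_along(P)
  K
}

#' Full eigendecomposition of the Google matrix
#'
#' Dense diagonalization of the element view of G. Eigenpairs are sorted by
#' decreasing modulus of the eigenvalue, ties by decreasing real part then
#' increasing imaginary part. Each eigenvector's phase is fixed by rotating
#' its largest-modulus component onto the positive real axis, so conjugate
#' pairs come out reproducibly.
#'
#' @param G A `google_matrix` (or `column_stochastic`, diagonalized as-is).
#' @param dense_cap Refuse matrices larger than this (default 4096, i.e.
#'   word length m = 6); dense nonsymmetric diagonalization beyond that is
#'   hours-scale.
#' @param allow_large Set `TRUE` to override the cap.
#' @return Object of class `gm_spectrum`: complex `values`, matching right
#'   `vectors` (columns), and `lambda1_residual` = |lambda_1 - 1|.
#' @export
full_spectrum <- function(G, dense_cap = 4096L, allow_large = FALSE) {
  N <- if (inherits(G, "google_matrix") || inherits(G, "column_stochastic"))
    G$N else nrow(G)
  if (N > dense_cap && !allow_large)
    stop(sprintf("N = %d exceeds the dense diagonalization cap %d; use word length m <= %d or allow_large = TRUE",
                 N, dense_cap, floor(log(dense_cap, 4))))
  M <- as.matrix(G)
  E <- eigen(M)
  vals <- as.complex(E$values)
  vecs <- matrix(as.complex(E$vectors), nrow = N)
  ord <- order(-Mod(vals), -Re(vals), Im(vals))
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i0 <- which.max(Mod(vecs[, j]))
    ph <- vecs[i0, j] / Mod(vecs[i0, j])
    vecs[, j] <- vecs[, j] / ph
  }
  structure(list(
    values = vals, vectors = vecs,
    lambda1_residual = Mod(vals[1L] - 1)
  ), class = "gm_spectrum")
}

#' @export
print.gm_spectrum <- function(x, ...) {
  cat(sprintf("<gm_spectrum> N = %d eigenvalues; |lambda_1 - 1| = %.2e; |lambda_2| = %.4f\n",
              length(x$values), x$lambda1_residual,
              if (length(x$values) > 1L) Mod(x$values[2L]) else NA_real_))
  invisible(x)
}

#' Spectral gap and radius of the eigenvalue cloud
#'
#' The gap 1 - |lambda_2| measures how fast the Markov chain relaxes; the
#' radius |lambda_2| bounds the circular cloud of non-leading eigenvalues.
#'
#' @param sp A `gm_spectrum`.
#' @return List with `gap` and `radius` (= |lambda_2|).
#' @export
spectral_gap <- function(sp) {
  stopifnot(inherits(sp, "gm_spectrum"))
  if (length(sp$values) < 2L) stop("need N >= 2 eigenvalues")
  r <- Mod(sp$values[2L])
  list(gap = 1 - r, radius = r)
}

#' Inverse participation ratio of an eigenvector
#'
#' xi = (sum |psi_i|^2)^2 / sum |psi_i|^4: the effective number of states
#' supporting the vector, independent of normalization. A delta vector
#' gives 1, a uniform vector gives N.
#'
#' @param psi Numeric or complex vector, not all zero.
#' @return The IPR, a number in \[1, N\].
#' @export
ipr <- function(psi) {
  a2 <- Mod(psi)^2
  s2 <- sum(a2)
  if (s2 == 0) stop("zero vector has no participation ratio")
  s2^2 / sum(a2^2)
}

#' Words with the largest eigenvector amplitudes
#'
#' @param psi Eigenvector (numeric or complex) of length 4^m.
#' @param codec A [word_codec()].
#' @param k Number of words to return; capped at N.
#' @return Data frame with columns `word`, `state`, `amplitude` (= |psi|),
#'   sorted by decreasing amplitude, ties by ascending state index.
#' @export
top_words <- function(psi, codec, k = 10L) {
  stopifnot(inherits(codec, "word_codec"), k >= 1L)
  if (length(psi) != codec$N) stop("vector length must equal 4^m")
  amp <- Mod(psi)
  ord <- order(-amp, seq_along(amp))[seq_len(min(k, length(amp)))]
  data.frame(
    word = decode_word(ord - 1L, codec),
    state = ord - 1L,
    amplitude = amp[ord],
    stringsAsFactors = FALSE
  )
}

#' Empirical word frequencies from tiled word lists
#'
#' Occurrence counts of each state divided by the total number of words.
#' On a circularized chain this vector is an exact fixed point of the
#' stochastic matrix built from the same lists.
#'
#' @param word_lists List of integer state-index vectors.
#' @param codec A [word_codec()].
#' @return Numeric vector of length N summing to 1.
#' @export
word_frequencies <- function(word_lists, codec) {
  stopifnot(inherits(codec, "word_codec"))
  if (!is.list(word_lists)) word_lists <- list(word_lists)
  w <- unlist(word_lists)
  if (!length(w)) stop("no words")
  counts <- tabulate(w + 1L, nbins = codec$N)
  counts / sum(counts)
}
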