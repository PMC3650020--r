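# Transition counting and construction of the column-stochastic matrix S,
# the Google matrix G = alpha*S + (1-alpha)/N, and the reversed-direction
# matrix behind CheiRank.

#' Count word-to-word transitions
#'
#' For each list of word states, every consecutive pair (w_k, w_{k+1}) adds
#' one unit to the count matrix element Q\[w_{k+1}, w_k\] (column = source,
#' row = target). No transition is counted across list boundaries, which is
#' how separation by undetermined letters and by record boundaries enters
#' the construction.
#'
#' @param word_lists A list of integer state-index vectors (or a single
#'   vector), e.g. the output of [tile_sequences()].
#' @param codec A [word_codec()]; fixes the matrix dimension N = 4^m, so
#'   words absent from the input remain as (dangling) states.
#' @param circular If `TRUE`, each list is closed into a cycle by also
#'   counting the transition from its last word back to its first. On a
#'   circularized list the empirical word-frequency vector is an exact
#'   stationary vector of the resulting stochastic matrix, which makes this
#'   a useful exactness oracle.
#' @return Object of class `transition_counts`: sparse N x N count matrix
#'   `Q`, total transition count `N_s`, and the codec.
#' @export
count_transitions <- function(word_lists, codec, circular = FALSE) {
  stopifnot(inherits(codec, "word_codec"))
  if (!is.list(word_lists)) word_lists <- list(word_lists)
  N <- codec$N
  from <- vector("list", length(word_lists))
  to <- vector("list", length(word_lists))
  for (k in seq_along(word_lists)) {
    w <- as.integer(word_lists[[k]])
    if (length(w) && (any(is.na(w)) || any(w < 0L) || any(w >= N)))
      stop("state index out of range [0, N)")
    if (length(w) >= 2L) {
      f <- w[-length(w)]
      t <- w[-1L]
      if (circular) {
        f <- c(f, w[length(w)])
        t <- c(t, w[1L])
      }
      from[[k]] <- f
      to[[k]] <- t
    }
  }
  from <- unlist(from)
  to <- unlist(to)
  n_s <- length(from)
  Q <- if (n_s == 0L) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(N, N))
  } else {
    Matrix::sparseMatrix(i = to + 1L, j = from + 1L, x = 1, dims = c(N, N))
  }
  structure(list(Q = Q, N_s = n_s, codec = codec),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("<transition_counts> N = %d states (m = %d), N_s = %d transitions, %d nonzero elements\n",
              x$codec$N, x$codec$m, x$N_s, Matrix::nnzero(x$Q)))
  invisible(x)
}

#' Reverse the direction of all transitions
#'
#' Returns counts with Q*\[j,i\] = Q\[i,j\], i.e. the chain read from right
#' to left. Feeding the result through [to_stochastic()] and [to_google()]
#' yields the matrix G* whose PageRank is the CheiRank of the original
#' sequence.
#'
#' @param tc A `transition_counts` object.
#' @return A `transition_counts` object with transposed counts; `N_s` is
#'   preserved.
#' @export
reversed_counts <- function(tc) {
  stopifnot(inherits(tc, "transition_counts"))
  structure(list(Q = Matrix::t(tc$Q), N_s = tc$N_s, codec = tc$codec),
            class = "transition_counts")
}

#' Normalize counts into a column-stochastic matrix S
#'
#' Each nonzero column of Q is divided by its sum; columns with no observed
#' outgoing transition (dangling nodes) are replaced by the uniform column
#' 1/N. The dangling replacement is kept implicit: the sparse part `S0`
#' stores only the normalized observed columns and `dangling` records which
#' columns are uniform, so matrix-vector products never densify.
#'
#' @param x A `transition_counts` object, or a plain (dense or sparse)
#'   nonnegative square matrix of counts/weights.
#' @param codec Optional [word_codec()] when `x` is a plain matrix.
#' @return Object of class `column_stochastic` with fields `S0` (sparse
#'   normalized columns, zero on dangling columns), `dangling` (1-based
#'   column indices), `N`, `codec`.
#' @export
to_stochastic <- function(x, codec = NULL) {
  if (inherits(x, "transition_counts")) {
    Q <- x$Q
    codec <- x$codec
  } else {
    Q <- methods::as(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                             "dMatrix"), "generalMatrix"), "CsparseMatrix")
  }
  N <- ncol(Q)
  if (N < 1L || nrow(Q) != N) stop("count matrix must be square, N >= 1")
  cs <- Matrix::colSums(Q)
  dangling <- which(cs == 0)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  S0 <- Q %*% Matrix::Diagonal(N, scale)
  structure(list(S0 = S0, dangling = dangling, N = N, codec = codec),
            class = "column_stochastic")
}

#' @export
print.column_stochastic <- function(x, ...) {
  cat(sprintf("<column_stochastic> N = %d, %d dangling (uniform) columns\n",
              x$N, length(x$dangling)))
  invisible(x)
}

#' Dense element view of a stochastic / Google matrix
#'
#' @param x A `column_stochastic`, `google_matrix`, or plain matrix.
#' @param ... Unused.
#' @return Dense base matrix of the elementwise values.
#' @export
as.matrix.column_stochastic <- function(x, ...) {
  S <- as.matrix(x$S0)
  if (length(x$dangling)) S[, x$dangling] <- 1 / x$N
  unname(S)
}

#' Form the Google matrix G = alpha*S + (1-alpha)/N
#'
#' The damping (teleportation) term makes every element at least
#' (1-alpha)/N, so G is primitive and its leading eigenvalue 1 is simple
#' for alpha < 1. The matrix is stored implicitly through `S`; use
#' [as.matrix()] for the dense element view and [gm_multiply()] for
#' matrix-vector products.
#'
#' @param S A `column_stochastic` object (or a `transition_counts`, which is
#'   normalized first).
#' @param alpha Damping factor in (0, 1]; 0.85 by default.
#' @return Object of class `google_matrix`.
#' @export
to_google <- function(S, alpha = 0.85) {
  if (inherits(S, "transition_counts")) S <- to_stochastic(S)
  stopifnot(inherits(S, "column_stochastic"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("`alpha` must be in (0, 1]")
  structure(list(S = S, alpha = alpha, N = S$N, codec = S$codec),
            class = "google_matrix")
}

#' @export
print.google_matrix <- function(x, ...) {
  cat(sprintf("<google_matrix> N = %d, alpha = %g\n", x$N, x$alpha))
  invisible(x)
}

#' @rdname as.matrix.column_stochastic
#' @export
as.matrix.google_matrix <- function(x, ...) {
  x$alpha * as.matrix(x$S) + (1 - x$alpha) / x$N
}

#' Matrix-vector product with a stochastic or Google matrix
#'
#' Computes `M %*% v` without materializing the dense matrix: the dangling
#' columns contribute `sum(v[dangling])/N` uniformly, and the damping term
#' of a Google matrix contributes `(1-alpha)*sum(v)/N`.
#'
#' @param M A `column_stochastic` or `google_matrix`.
#' @param v Numeric vector of length N.
#' @return Numeric vector `M v`.
#' @export
gm_multiply <- function(M, v) {
  if (inherits(M, "google_matrix")) {
    S <- M$S
    sv <- as.vector(S$S0 %*% v) + sum(v[S$dangling]) / S$N
    return(M$alpha * sv + (1 - M$alpha) * sum(v) / M$N)
  }
  stopifnot(inherits(M, "column_stochastic"))
  as.vector(M$S0 %*% v) + sum(v[M$dangling]) / M$N
}

#' Sum of ingoing matrix elements per node
#'
#' The row sums of the matrix: the weighted analogue of in-degree on a
#' network whose matrix is essentially full. For a column-stochastic input
#' the row sums total N.
#'
#' @param M A `column_stochastic`, `google_matrix`, or plain square matrix.
#' @return Numeric vector of length N of row sums.
#' @export
ingoing_sums <- function(M) {
  if (inherits(M, "google_matrix")) {
    return(M$alpha * ingoing_sums(M$S) + (1 - M$alpha))
  }
  if (inherits(M, "column_stochastic")) {
    return(as.vector(Matrix::rowSums(M$S0)) + length(M$dangling) / M$N)
  }
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  rowSums(M)
}

# --- Matrix Market export -------------------------------------------------

#' Export counts or matrices in Matrix Market format
#'
#' `write_counts_mtx()` and `write_stochastic_mtx()` write sparse coordinate
#' files via [Matrix::writeMM()] (the stochastic export includes the uniform
#' dangling columns explicitly). `write_google_mtx()` writes the dense
#' element view of G in array format with a comment line recording `alpha`
#' and `m`.
#'
#' @param x The object to export.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(x, path) {
  stopifnot(inherits(x, "transition_counts"))
  Matrix::writeMM(methods::as(x$Q, "CsparseMatrix"), path)
  invisible(path)
}

#' @rdname write_counts_mtx
#' @export
write_stochastic_mtx <- function(x, path) {
  stopifnot(inherits(x, "column_stochastic"))
  S <- x$S0
  if (length(x$dangling)) {
    nd <- length(x$dangling)
    U <- Matrix::sparseMatrix(
      i = rep(seq_len(x$N), nd),
      j = rep(x$dangling, each = x$N),
      x = 1 / x$N, dims = c(x$N, x$N)
    )
    S <- S + U
  }
  Matrix::writeMM(methods::as(S, "CsparseMatrix"), path)
  invisible(path)
}

#' @rdname write_counts_mtx
#' @export
write_google_mtx <- function(x, path) {
  stopifnot(inherits(x, "google_matrix"))
  G <- as.matrix(x)
  m <- if (!is.null(x$codec)) x$codec$m else NA_integer_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "%%MatrixMarket matrix array real general",
    sprintf("%% google matrix: alpha=%g m=%s", x$alpha, m),
    sprintf("%d %d", nrow(G), ncol(G))
  ), con)
  writeLines(sprintf("%.17g", as.vector(G)), con)
  invisible(path)
}
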