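# Shared fixtures and independent oracles for the test suite.

# All m-letter words over {A,C,G,T} in lexicographic order (A<C<G<T).
# Independent enumeration oracle for the word <-> index bijection.
all_words_lex <- function(m) {
  letters4 <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  rev(replicate(m, letters4, simplify = FALSE)))
  apply(grid[, rev(seq_len(m)), drop = FALSE], 1, paste, collapse = "")
}

# Random column-stochastic dense matrix.
random_stochastic <- function(N, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(N * N), N, N)
  sweep(M, 2, colSums(M), "/")
}

# All permutations of 1..n (n small), as a list.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Write a temporary FASTA file from named letter strings.
write_temp_fasta <- function(seqs, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fasta.gz" else ".fasta")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  close(con)
  path
}

# Build an integrated_distribution object directly from a known curve
# (for exercising the fitters on exact algebraic inputs).
make_distribution <- function(grid, fraction) {
  structure(list(grid = grid, fraction = fraction, n_total = length(grid)),
            class = "integrated_distribution")
}

# Two clearly distinct letter-level Markov transition laws (column =
# current letter), used for proximity separation / stability checks.
letter_chain_A <- matrix(c(.5, .2, .2, .1,
                           .1, .5, .2, .2,
                           .2, .1, .5, .2,
                           .2, .2, .1, .5), 4, 4)
letter_chain_B <- matrix(c(.1, .3, .3, .3,
                           .3, .1, .3, .3,
                           .3, .3, .1, .3,
                           .3, .3, .3, .1), 4, 4)
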