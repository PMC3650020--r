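test_that("power-iteration PageRank solves small chains exactly", {
  # 2-state swap: symmetric, so P is uniform
  G <- to_google(to_stochastic(matrix(c(0, 1, 1, 0), 2, 2)), 0.85)
  rv <- pagerank(G)
  expect_equal(rv$P, c(0.5, 0.5), tolerance = 1e-12)

  # absorbing top row: fixed point solved by hand is (0.925, 0.075)
  G <- to_google(to_stochastic(matrix(c(1, 0, 1, 0), 2, 2)), 0.85)
  expect_equal(pagerank(G)$P, c(0.925, 0.075), tolerance = 1e-12)

  # uniform S: P uniform for any alpha
  G <- to_google(to_stochastic(matrix(0.25, 4, 4)), 0.6)
  expect_equal(pagerank(G)$P, rep(0.25, 4), tolerance = 1e-12)

  expect_error(pagerank(G, tol = -1), "positive")
  Gslow <- to_google(to_stochastic(matrix(c(9, 1, 2, 8), 2, 2)), 0.85)
  expect_error(pagerank(Gslow, tol = 1e-300, max_iter = 2L), "converge")
})

test_that("PageRank agrees with the leading dense eigenvector and with igraph", {
  for (N in c(16L, 64L)) {
    S <- to_stochastic(random_stochastic(N, seed = N))
    G <- to_google(S, 0.85)
    rv <- pagerank(G)
    sp <- full_spectrum(G)
    v1 <- Re(sp$vectors[, 1])
    v1 <- v1 / sum(v1)
    expect_lt(sum(abs(rv$P - v1)), 1e-8)
  }

  # independent route: igraph's PageRank on the weighted directed graph
  skip_if_not_installed("igraph")
  codec <- word_codec(2)
  words <- tile_segment(iid_sequence(c(.4, .2, .1, .3), 4000, seed = 77), codec)
  tc <- count_transitions(list(words), codec)
  rv <- pagerank(to_google(to_stochastic(tc), 0.85))
  g <- igraph::graph_from_adjacency_matrix(Matrix::t(tc$Q), mode = "directed",
                                           weighted = TRUE)
  pr <- igraph::page_rank(g, damping = 0.85, weights = igraph::E(g)$weight)$vector
  expect_lt(sum(abs(rv$P - pr)), 1e-10)
})

test_that("rank ordering is decreasing in probability with index tie-break", {
  expect_identical(rank_order(c(0.2, 0.5, 0.3)), c(3L, 1L, 2L))
  expect_identical(rank_order(rep(0.25, 4)), 1:4)
  expect_identical(rank_order(c(0.4, 0.3, 0.2, 0.1)), 1:4)
  expect_error(rank_order(numeric(0)), "empty")
})

test_that("full spectrum reproduces closed forms on 2x2 and rank-one matrices", {
  S <- to_stochastic(matrix(c(0, 1, 1, 0), 2, 2))
  sp <- full_spectrum(to_google(S, 0.85))
  expect_equal(sort(Re(sp$values)), c(-0.85, 1), tolerance = 1e-12)
  expect_lt(sp$lambda1_residual, 1e-9)

  sp <- full_spectrum(to_google(to_stochastic(matrix(0.25, 4, 4)), 0.85))
  expect_equal(Mod(sp$values), c(1, 0, 0, 0), tolerance = 1e-12)

  expect_error(full_spectrum(to_google(to_stochastic(diag(5)), 0.85),
                             dense_cap = 4L), "cap")
})

test_that("non-unit eigenvalues scale with alpha while eigenvectors do not", {
  S <- to_stochastic(random_stochastic(32, seed = 5))
  eS <- full_spectrum(S)$values
  spA <- full_spectrum(to_google(S, 0.85))
  spB <- full_spectrum(to_google(S, 0.425))
  expect_lt(max(Mod(spA$values[-1] - 0.85 * eS[-1])), 1e-10)
  expect_lt(max(Mod(spB$values[-1] - 0.425 * eS[-1])), 1e-10)
  # eigenvalues at half the damping are exactly half those at 0.85
  expect_lt(max(Mod(spB$values[-1] - spA$values[-1] / 2)), 1e-10)
  # the second eigenvector is the same at both damping values
  expect_lt(max(Mod(spA$vectors[, 2] - spB$vectors[, 2])), 1e-8)
})

test_that("spectral gap reports 1 - |lambda_2| and the cloud radius", {
  S <- to_stochastic(matrix(c(0, 1, 1, 0), 2, 2))
  g <- spectral_gap(full_spectrum(to_google(S, 0.85)))
  expect_equal(g$gap, 0.15, tolerance = 1e-12)
  expect_equal(g$radius, 0.85, tolerance = 1e-12)

  g <- spectral_gap(full_spectrum(to_google(to_stochastic(matrix(0.25, 4, 4)), 0.85)))
  expect_equal(g$gap, 1, tolerance = 1e-12)

  # reducible two-block chain at alpha = 1 keeps a degenerate lambda = 1
  B <- matrix(0, 4, 4)
  B[1:2, 1:2] <- 0.5
  B[3:4, 3:4] <- 0.5
  g <- spectral_gap(full_spectrum(to_google(to_stochastic(B), 1)))
  expect_equal(g$gap, 0, tolerance = 1e-10)
})

test_that("inverse participation ratio counts the supporting states", {
  expect_equal(ipr(c(1, 0, 0, 0)), 1)
  expect_equal(ipr(rep(0.1, 16)), 16)
  expect_equal(ipr(c(3, 3, 0)), 2)
  expect_equal(ipr(c(1i, 0, 0)), 1)  # modulus-based, complex safe
  expect_error(ipr(c(0, 0)), "zero vector")
})

test_that("top words pick the largest amplitudes with deterministic ties", {
  codec <- word_codec(6)
  psi <- rep(0, codec$N)
  psi[1] <- 1
  tw <- top_words(psi, codec, k = 1)
  expect_identical(tw$word, "AAAAAA")
  expect_equal(tw$amplitude, 1)

  # planted chain whose stationary law favors TTTTTT
  codec2 <- word_codec(2)
  p <- rep(0.01, 16)
  p[16] <- 1 - sum(p[-16])
  rv <- pagerank(to_google(to_stochastic(matrix(p, 16, 16)), 0.85))
  expect_identical(top_words(rv$P, codec2, k = 1)$word, "TT")

  expect_equal(nrow(top_words(psi, codec, k = 10 * codec$N)), codec$N)
})

test_that("PageRank equals CheiRank when counts are symmetric", {
  codec <- word_codec(1)
  # palindromic walk gives exactly symmetric counts
  words <- c(0L, 1L, 2L, 3L, 2L, 1L, 0L)
  tc <- count_transitions(list(words), codec)
  expect_equal(as.matrix(tc$Q), t(as.matrix(tc$Q)))
  pr <- pagerank(to_google(to_stochastic(tc), 0.85))
  cr <- cheirank(tc, 0.85)
  expect_equal(pr$P, cr$P, tolerance = 1e-13)
  expect_identical(pr$K, cr$K)
})

test_that("PageRank at alpha = 1 equals word frequency on circular chains", {
  codec <- word_codec(2)
  words <- tile_segment(iid_sequence(c(.3, .25, .15, .3), 6000, seed = 21), codec)
  tc <- count_transitions(list(words), codec, circular = TRUE)
  f <- word_frequencies(list(words), codec)
  rv <- pagerank(to_google(to_stochastic(tc), 1))
  expect_lt(sum(abs(rv$P - f)), 1e-11)
})
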