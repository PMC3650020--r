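test_that("transition counting follows the word order within each list", {
  codec <- word_codec(4)
  tc <- count_transitions(list(c(27L, 27L)), codec)
  expect_equal(tc$N_s, 1)
  expect_equal(tc$Q[28, 28], 1)

  # "AAACAAAGAAAC" at m=4: words AAAC, AAAG, AAAC
  words <- tile_segment("AAACAAAGAAAC", codec)
  expect_identical(words, encode_word(c("AAAC", "AAAG", "AAAC"), codec))
  tc <- count_transitions(list(words), codec)
  iaaac <- encode_word("AAAC", codec) + 1L
  iaaag <- encode_word("AAAG", codec) + 1L
  expect_equal(tc$N_s, 2)
  expect_equal(tc$Q[iaaag, iaaac], 1)  # AAAC -> AAAG
  expect_equal(tc$Q[iaaac, iaaag], 1)  # AAAG -> AAAC

  # no transitions across separate lists (segment / record separation)
  tc <- count_transitions(list(c(0L, 1L), c(2L, 3L)), word_codec(1))
  expect_equal(tc$N_s, 2)
  expect_equal(tc$Q[3, 2], 0)
  expect_equal(tc$Q[2, 1], 1)
  expect_equal(tc$Q[4, 3], 1)

  expect_error(count_transitions(list(c(0L, 300L)), codec = word_codec(2)),
               "out of range")
})

test_that("column normalization handles observed and dangling columns", {
  # column (2,2,0,0) -> (0.5,0.5,0,0); all-zero column -> uniform 1/N
  Q <- matrix(0, 4, 4)
  Q[1:2, 1] <- 2
  S <- as.matrix(to_stochastic(Q))
  expect_equal(S[, 1], c(0.5, 0.5, 0, 0))
  expect_equal(S[, 2], rep(0.25, 4))  # dangling rule
  expect_equal(to_stochastic(Q)$dangling, 2:4)

  # 2x2 with both rules at once
  Q <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(as.matrix(to_stochastic(Q)),
               matrix(c(1, 0, 0.5, 0.5), 2, 2))
})

test_that("damping mixes S with the uniform matrix elementwise", {
  S <- to_stochastic(matrix(0.5, 2, 2))
  expect_equal(as.matrix(to_google(S, 0.3)), matrix(0.5, 2, 2))

  S <- to_stochastic(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(as.matrix(to_google(S, 0.85)),
               matrix(c(0.075, 0.925, 0.925, 0.075), 2, 2))
  expect_equal(as.matrix(to_google(S, 1)), as.matrix(S))

  expect_error(to_google(S, 0), "alpha")
  expect_error(to_google(S, 1.2), "alpha")
})

test_that("columns of S and G sum to one for arbitrary synthetic inputs", {
  for (seed in 1:5) {
    letters <- inject_ambiguous(iid_sequence(c(.4, .1, .2, .3), 2000, seed),
                                n_runs = 3, run_len = 5, seed = seed + 100)
    built <- sequence_google(letters, m = 2)
    S <- as.matrix(built$S)
    G <- as.matrix(built$G)
    expect_lt(max(abs(colSums(S) - 1)), 1e-12)
    expect_lt(max(abs(colSums(G) - 1)), 1e-12)
    expect_true(all(G >= (1 - 0.85) / built$codec$N - 1e-15))
  }
})

test_that("source and target counts of a single segment differ by at most one", {
  codec <- word_codec(2)
  words <- tile_segment(iid_sequence(rep(0.25, 4), 600, seed = 12), codec)
  tc <- count_transitions(list(words), codec)
  src <- Matrix::colSums(tc$Q)
  tgt <- Matrix::rowSums(tc$Q)
  expect_lte(max(abs(src - tgt)), 1)
  expect_equal(sum(src), tc$N_s)
})

test_that("direction reversal transposes counts and is an involution", {
  codec <- word_codec(1)
  tc <- count_transitions(list(c(0L, 1L)), codec)
  rc <- reversed_counts(tc)
  expect_equal(rc$Q[1, 2], 1)
  expect_equal(rc$N_s, tc$N_s)
  expect_equal(as.matrix(reversed_counts(rc)$Q), as.matrix(tc$Q))

  # symmetric counts are a fixed point
  words <- c(0L, 1L, 0L, 1L, 0L)
  tcs <- count_transitions(list(words), codec)
  expect_equal(as.matrix(tcs$Q), t(as.matrix(tcs$Q)))
  expect_equal(as.matrix(reversed_counts(tcs)$Q), as.matrix(tcs$Q))
})

test_that("circularized counts make word frequencies an exact fixed point", {
  codec <- word_codec(2)
  words <- tile_segment(iid_sequence(c(.3, .2, .2, .3), 5000, seed = 9), codec)
  tc <- count_transitions(list(words), codec, circular = TRUE)
  expect_equal(tc$N_s, length(words))
  S <- to_stochastic(tc)
  f <- word_frequencies(list(words), codec)
  expect_lt(sum(abs(gm_multiply(S, f) - f)), 1e-13)
})

test_that("implicit matrix-vector products agree with the dense views", {
  set.seed(4)
  Q <- matrix(rpois(36, 1.2), 6, 6)
  Q[, 3] <- 0  # force a dangling column
  S <- to_stochastic(Q)
  G <- to_google(S, 0.85)
  v <- runif(6)
  expect_equal(gm_multiply(S, v), as.vector(as.matrix(S) %*% v))
  expect_equal(gm_multiply(G, v), as.vector(as.matrix(G) %*% v))
})

test_that("Matrix Market exports round-trip", {
  codec <- word_codec(2)
  words <- tile_segment(iid_sequence(rep(.25, 4), 400, seed = 3), codec)
  tc <- count_transitions(list(words), codec)
  S <- to_stochastic(tc)
  G <- to_google(S, 0.85)

  qpath <- tempfile(fileext = ".mtx")
  write_counts_mtx(tc, qpath)
  expect_equal(as.matrix(Matrix::readMM(qpath)), as.matrix(tc$Q),
               ignore_attr = TRUE)

  spath <- tempfile(fileext = ".mtx")
  write_stochastic_mtx(S, spath)
  expect_equal(as.matrix(Matrix::readMM(spath)), as.matrix(S),
               ignore_attr = TRUE)

  gpath <- tempfile(fileext = ".mtx")
  write_google_mtx(G, gpath)
  lines <- readLines(gpath)
  expect_match(lines[1], "^%%MatrixMarket matrix array real general$")
  expect_match(lines[2], "alpha=0.85 m=2")
  dims <- scan(text = lines[3], quiet = TRUE)
  vals <- as.numeric(lines[-(1:3)])
  expect_equal(matrix(vals, dims[1], dims[2]), as.matrix(G))
})
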