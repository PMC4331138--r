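test_that("D2 is the inner product of word vectors", {
  x <- c(1, 0, 0); y <- c(1, 0, 0)
  expect_equal(d2(x, y), 1)
  X <- count_kmers("AAA", 2)
  expect_equal(d2(X, X), 4)     # X_AA = 2
  expect_equal(d2(X, numeric(16)), 0)
  expect_error(d2(numeric(4), numeric(16)), "different k")
})

test_that("D2* vanishes at expectation and matches hand arithmetic", {
  # x exactly at its expected count everywhere -> tilde is 0
  p <- c(0.5, 0.5); n <- 10
  x <- n * p
  expect_equal(d2star(x, c(7, 3), p, p, n, n), 0)

  # 2-word toy case, equal n and p on both sides
  x <- c(3, 1); y <- c(2, 2); pw <- c(0.25, 0.75); nn <- 4
  want <- sum((x - nn * pw) * (y - nn * pw) / (nn * pw))
  expect_equal(d2star(x, y, pw, pw, nn, nn), want)

  # geometric-mean denominator reduces to the single-n form when shared
  expect_equal(d2star(x, y, pw, pw, nn, nn),
               oracle_d2star(x, y, pw, pw, nn, nn))
})

test_that("D2s normalises by the self term and is symmetric", {
  # one word with tilde values 3 and 4: 12/5; other word all-zero
  x <- c(3, 0); y <- c(4, 0); pw <- c(0, 0)
  expect_equal(d2s(x, y, pw, pw, 1, 1), 3 * 4 / 5)
  expect_equal(d2s(c(0, 0), c(0, 0), c(0, 0), c(0, 0), 1, 1), 0)

  X <- c(5, 1, 0, 2); Y <- c(1, 4, 2, 0); pw <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(d2s(X, Y, pw, pw, 6, 5), d2s(Y, X, pw, pw, 5, 6))
})

test_that("quality-weighted statistics reduce to classical at correctness 1", {
  reads <- perfect_reads(12, 60, seed = 44)
  p <- kmer_profiles(reads, 2)
  expect_identical(p$qcounts, p$counts * 1)
  E <- estimate_awp(p)$values
  expect_true(all(E == 1))
  i <- 1; j <- 2
  px <- qualmer:::background_word_probs(p$base_freqs[i, ], 2)
  py <- qualmer:::background_word_probs(p$base_freqs[j, ], 2)
  nx <- p$n_windows[i]; ny <- p$n_windows[j]
  expect_identical(d2q(p$qcounts[i, ], p$qcounts[j, ]),
                   d2(p$counts[i, ], p$counts[j, ]))
  expect_identical(d2star_q(p$qcounts[i, ], p$qcounts[j, ], px, py, nx, ny,
                            E, E),
                   d2star(p$counts[i, ], p$counts[j, ], px, py, nx, ny))
  expect_identical(d2s_q(p$qcounts[i, ], p$qcounts[j, ], px, py, nx, ny,
                         E, E),
                   d2s(p$counts[i, ], p$counts[j, ], px, py, nx, ny))
})

test_that("d2q weights shared words by their occurrence probabilities", {
  expect_equal(d2q(c(0.5, 0), c(0.8, 0)), 0.4)
  expect_equal(d2q(c(0, 0), c(1, 1)), 0)
})

test_that("L2, KL and symmetrized KL behave as distances/divergences", {
  x <- c(2, 2, 0, 0); y <- c(2, 2, 0, 0)
  expect_equal(l2_dist(x, y), 0)
  expect_equal(kl_div(x, y), 0)
  expect_equal(sym_kl(x, y), 0)

  # unit difference in one coordinate pair of already-normalised vectors
  a <- c(0.5, 0.5, 0, 0); b <- c(0.5 - 0.1, 0.5 + 0.1, 0, 0)
  expect_equal(l2_dist(a, b), sqrt(2) * 0.1)

  # hand-computed 2-bin case with explicit pseudocount
  fx <- c(3, 1); fy <- c(1, 3); pc <- 0.5
  gx <- (fx + pc) / sum(fx + pc); gy <- (fy + pc) / sum(fy + pc)
  expect_equal(kl_div(fx, fy, pseudocount = pc), sum(gx * log2(gx / gy)))
  expect_equal(sym_kl(fx, fy), sym_kl(fy, fx))

  # triangle inequality for L2 on random triples
  withr::with_seed(1, {
    for (rep in 1:20) {
      v <- matrix(stats::rpois(3 * 8, 4), 3)
      expect_lte(l2_dist(v[1, ], v[3, ]),
                 l2_dist(v[1, ], v[2, ]) + l2_dist(v[2, ], v[3, ]) + 1e-12)
    }
  })
})

test_that("to_dissimilarity is 0 at identity, 1 at orthogonality", {
  expect_equal(to_dissimilarity(5, 5, 5), 0)
  expect_equal(to_dissimilarity(0, 3, 7), 1)
  expect_equal(to_dissimilarity(-6, 6, 6), 2)
  expect_error(to_dissimilarity(1, 0, 1), "positive")
  withr::with_seed(2, {
    x <- stats::runif(16); y <- stats::runif(16)
    sxy <- d2(x, y)
    expect_equal(to_dissimilarity(sxy, d2(x, x), d2(y, y)),
                 1 - sxy / sqrt(d2(x, x) * d2(y, y)))
  })
})

test_that("every pairwise statistic matches its brute-force oracle", {
  reads <- random_reads(12, 60, seed = 55, q_range = c(2L, 38L))
  for (k in 1:3) {
    p <- kmer_profiles(reads, k)
    Ea <- estimate_awp(p)$values
    for (pair in list(c(1, 2), c(3, 4), c(5, 6))) {
      i <- pair[1]; j <- pair[2]
      px <- qualmer:::background_word_probs(p$base_freqs[i, ], k)
      py <- qualmer:::background_word_probs(p$base_freqs[j, ], k)
      nx <- p$n_windows[i]; ny <- p$n_windows[j]
      x <- p$counts[i, ]; y <- p$counts[j, ]
      xq <- p$qcounts[i, ]; yq <- p$qcounts[j, ]
      expect_equal(d2(x, y), oracle_d2(x, y), tolerance = 1e-9)
      expect_equal(d2star(x, y, px, py, nx, ny),
                   oracle_d2star(x, y, px, py, nx, ny), tolerance = 1e-9)
      expect_equal(d2s(x, y, px, py, nx, ny),
                   oracle_d2s(x, y, px, py, nx, ny), tolerance = 1e-9)
      expect_equal(d2q(xq, yq), oracle_d2(xq, yq), tolerance = 1e-9)
      expect_equal(d2star_q(xq, yq, px, py, nx, ny, Ea, Ea),
                   oracle_d2star(xq, yq, px, py, nx, ny, Ea, Ea),
                   tolerance = 1e-9)
      expect_equal(d2s_q(xq, yq, px, py, nx, ny, Ea, Ea),
                   oracle_d2s(xq, yq, px, py, nx, ny, Ea, Ea),
                   tolerance = 1e-9)
      expect_equal(l2_dist(x, y), oracle_l2(x, y), tolerance = 1e-9)
      expect_equal(kl_div(x, y), oracle_kl(x, y), tolerance = 1e-9)
      expect_equal(sym_kl(x, y),
                   (oracle_kl(x, y) + oracle_kl(y, x)) / 2,
                   tolerance = 1e-9)
    }
  }
})

test_that("read_dist produces symmetric matrices with zero diagonal", {
  reads <- random_reads(8, 50, seed = 66)
  p <- kmer_profiles(reads, 2)
  for (m in c("d2", "d2star", "d2s", "l2", "symkl")) {
    D <- read_dist(p, m)
    expect_equal(D, t(D), tolerance = 1e-12)
    expect_equal(unname(diag(D)), rep(0, 8))
    expect_true(all(D >= 0))
  }
  Dq <- read_dist(p, "d2star_q", estimator = "aqp", reads = reads)
  expect_equal(Dq, t(Dq), tolerance = 1e-12)

  # pairwise entries agree with the low-level statistics
  D <- read_dist(p, "d2s")
  i <- 2; j <- 5
  px <- qualmer:::background_word_probs(p$base_freqs[i, ], 2)
  py <- qualmer:::background_word_probs(p$base_freqs[j, ], 2)
  sxy <- d2s(p$counts[i, ], p$counts[j, ], px, py,
             p$n_windows[i], p$n_windows[j])
  sxx <- d2s(p$counts[i, ], p$counts[i, ], px, px,
             p$n_windows[i], p$n_windows[i])
  syy <- d2s(p$counts[j, ], p$counts[j, ], py, py,
             p$n_windows[j], p$n_windows[j])
  expect_equal(unname(D[i, j]), to_dissimilarity(sxy, sxx, syy),
               tolerance = 1e-12)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dist_tsv(D, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$read_id, rownames(D))
  expect_equal(as.matrix(back[, -1]), D, ignore_attr = TRUE)
})

test_that("measure_spec validates estimator/measure combinations", {
  expect_error(measure_spec("d2star_q"), "requires")
  expect_error(measure_spec("d2", estimator = "awp"), "does not use")
  expect_error(measure_spec("nonsense"), "unknown measure")
  expect_error(measure_spec("l2", redistribute = TRUE), "redistribution")
  s <- measure_spec("d2star-q", estimator = "aqp")
  expect_equal(s$name, "d2star_q")
})
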