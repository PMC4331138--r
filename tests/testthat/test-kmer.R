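test_that("count_kmers matches hand enumeration", {
  c1 <- count_kmers("AAA", 2)
  expect_equal(unname(c1["AA"]), 2L)
  expect_equal(sum(c1), 2L)

  c2 <- count_kmers("ACGT", 1)
  expect_equal(unname(c2[c("A", "C", "G", "T")]), rep(1L, 4))

  # windows covering an N are skipped entirely
  c3 <- count_kmers("ACNGT", 2)
  expect_equal(sum(c3), 2L)
  expect_equal(unname(c3[c("AC", "GT")]), c(1L, 1L))

  # k longer than the read gives a flagged all-zero profile
  c4 <- count_kmers("ACG", 5)
  expect_equal(sum(c4), 0L)
  expect_true(attr(c4, "flagged"))
})

test_that("counting agrees with a naive window-scan oracle", {
  reads <- random_reads(30, 120, seed = 5, with_n = TRUE)
  for (k in 1:3) {
    for (i in seq_len(nrow(reads))) {
      expect_equal(
        unname(count_kmers(reads$sequence[i], k)),
        unname(oracle_count_kmers(reads$sequence[i], k))
      )
    }
  }
})

test_that("quality counts reduce to plain counts at perfect quality", {
  reads <- perfect_reads(10, 80, seed = 3)
  for (i in seq_len(nrow(reads))) {
    qc <- quality_counts(reads$sequence[i], reads$qualities[[i]], 3)
    expect_identical(unname(qc), as.numeric(unname(
      count_kmers(reads$sequence[i], 3))))
  }
})

test_that("quality counts without redistribution are bounded by counts", {
  reads <- random_reads(20, 90, seed = 9, with_n = TRUE)
  for (i in seq_len(nrow(reads))) {
    qc <- quality_counts(reads$sequence[i], reads$qualities[[i]], 2)
    ct <- count_kmers(reads$sequence[i], 2)
    expect_true(all(qc >= 0 & qc <= ct + 1e-12))
    expect_lte(sum(qc), sum(ct))
  }
})

test_that("redistribution reproduces the worked single-base example", {
  # word TGACCA, third base 70% correct, all others certain,
  # read base frequencies A=0.2 C=0.3 G=0.3 T=0.2
  q <- c(Inf, Inf, -10 * log10(0.3), Inf, Inf, Inf)
  qc <- quality_counts("TGACCA", q, 6, redistribute = TRUE,
                       base_freqs = c(0.2, 0.3, 0.3, 0.2))
  expect_equal(unname(qc["TGACCA"]), 0.7)
  expect_equal(unname(qc["TGCCCA"]), 0.1125)
  expect_equal(unname(qc["TGGCCA"]), 0.1125)
  expect_equal(unname(qc["TGTCCA"]), 0.075)
  expect_equal(sum(qc), 1)

  m <- redistribute_mass(0.7, "A", c(0.2, 0.3, 0.3, 0.2))
  expect_equal(unname(m), c(0.1125, 0.1125, 0.075))
  expect_equal(sum(m), 0.3)
})

test_that("redistribution agrees with the brute-force oracle", {
  reads <- random_reads(15, 60, seed = 21, q_range = c(2L, 35L))
  for (k in 1:3) {
    for (i in seq_len(nrow(reads))) {
      got <- quality_counts(reads$sequence[i], reads$qualities[[i]], k,
                            redistribute = TRUE)
      want <- oracle_quality_counts(reads$sequence[i],
                                    reads$qualities[[i]], k,
                                    redistribute = TRUE)
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("per-occurrence redistributed mass never exceeds 1", {
  reads <- random_reads(10, 50, seed = 33, q_range = c(2L, 30L))
  k <- 2
  for (i in seq_len(nrow(reads))) {
    qc <- quality_counts(reads$sequence[i], reads$qualities[[i]], k,
                         redistribute = TRUE)
    n_win <- sum(count_kmers(reads$sequence[i], k))
    # total mass = sum over occurrences of (P + credited neighbour mass),
    # each occurrence contributing at most 1
    expect_lte(sum(qc), n_win + 1e-9)
  }
})

test_that("background word probabilities follow the i.i.d. product", {
  expect_equal(background_word_prob(rep(0.25, 4), "AC"), 1 / 16)
  expect_equal(background_word_prob(c(1, 0, 0, 0), "AA"), 1)
  expect_equal(background_word_prob(c(1, 0, 0, 0), "AC"), 0)
  expect_equal(background_word_prob(c(0.2, 0.3, 0.3, 0.2), "TGA"), 0.012)

  f <- c(0.1, 0.4, 0.3, 0.2)
  for (k in 1:3) {
    expect_equal(qualmer:::background_word_probs(f, k),
                 oracle_background_probs(f, k))
  }
})

test_that("profile matrices match the per-read functions", {
  reads <- random_reads(12, 70, seed = 13, with_n = TRUE)
  p <- kmer_profiles(reads, 2, redistribute = TRUE)
  for (i in seq_len(nrow(reads))) {
    expect_equal(unname(p$counts[i, ]),
                 unname(as.integer(count_kmers(reads$sequence[i], 2))))
    expect_equal(unname(p$qcounts[i, ]),
                 unname(quality_counts(reads$sequence[i],
                                       reads$qualities[[i]], 2,
                                       redistribute = TRUE)),
                 tolerance = 1e-12)
    expect_equal(unname(p$qcounts_plain[i, ]),
                 unname(quality_counts(reads$sequence[i],
                                       reads$qualities[[i]], 2)),
                 tolerance = 1e-12)
  }
  expect_equal(p$n_windows, vapply(reads$sequence, function(s)
    sum(count_kmers(s, 2)), 0L, USE.NAMES = FALSE))
})

test_that("reverse-complement pooling maps counts onto canonical words", {
  reads <- tibble::tibble(read_id = "r1", sequence = "ACGT",
                          qualities = list(rep(Inf, 4)))
  p <- kmer_profiles(reads, 2, revcomp = TRUE)
  # AC+GT pool to AC, CG is its own canonical word
  expect_equal(unname(p$counts[1, "AC"]), 2)
  expect_equal(unname(p$counts[1, "GT"]), 0)
  expect_equal(unname(p$counts[1, "CG"]), 1)
  expect_equal(sum(p$counts), 3)
})

test_that("tidy() and the TSV export expose read_id/word/count/qcount", {
  reads <- random_reads(3, 30, seed = 2)
  p <- kmer_profiles(reads, 2)
  td <- tidy(p)
  expect_named(td, c("read_id", "word", "count", "qcount"))
  expect_true(all(td$count > 0 | td$qcount > 0))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profiles_tsv(p, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(td))
})
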