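# Independent brute-force reference implementations used as oracles.
# Deliberately written against string operations (substr / strsplit),
# never sharing the 2-bit-encoding code path of the package.

oracle_count_kmers <- function(sequence, k) {
  words <- all_kmers(k)
  out <- stats::setNames(integer(length(words)), words)
  n <- nchar(sequence)
  if (k > n) return(out)
  for (i in seq_len(n - k + 1)) {
    w <- substr(sequence, i, i + k - 1)
    if (grepl("^[ACGT]+$", w)) out[w] <- out[w] + 1L
  }
  out
}

oracle_quality_counts <- function(sequence, qualities, k,
                                  redistribute = FALSE, base_freqs = NULL) {
  words <- all_kmers(k)
  out <- stats::setNames(numeric(length(words)), words)
  n <- nchar(sequence)
  if (k > n) return(out)
  chars <- strsplit(sequence, "")[[1]]
  probs <- 1 - 10^(-qualities / 10)
  probs[!chars %in% c("A", "C", "G", "T")] <- 0
  if (is.null(base_freqs)) {
    tab <- table(factor(chars[chars %in% c("A", "C", "G", "T")],
                        levels = c("A", "C", "G", "T")))
    tab <- as.numeric(tab)
    if (any(tab == 0)) tab <- tab + 0.5
    f <- tab / sum(tab)
  } else {
    f <- as.numeric(base_freqs)
    if (any(f == 0)) f <- f + 0.5
    f <- f / sum(f)
  }
  names(f) <- c("A", "C", "G", "T")
  for (i in seq_len(n - k + 1)) {
    w <- substr(sequence, i, i + k - 1)
    if (!grepl("^[ACGT]+$", w)) next
    p <- probs[i:(i + k - 1)]
    out[w] <- out[w] + prod(p)
    if (redistribute) {
      wc <- chars[i:(i + k - 1)]
      for (j in seq_len(k)) {
        alts <- setdiff(c("A", "C", "G", "T"), wc[j])
        for (a in alts) {
          nw <- wc; nw[j] <- a
          mass <- (1 - p[j]) * f[a] / sum(f[alts]) * prod(p[-j])
          key <- paste(nw, collapse = "")
          out[key] <- out[key] + mass
        }
      }
    }
  }
  out
}

oracle_d2 <- function(x, y) {
  s <- 0
  for (w in seq_along(x)) s <- s + x[w] * y[w]
  unname(s)
}

oracle_d2star <- function(x, y, px, py, nx, ny, Ex = rep(1, length(x)),
                          Ey = rep(1, length(y))) {
  s <- 0
  for (w in seq_along(x)) {
    dx <- nx * px[w] * Ex[w]
    dy <- ny * py[w] * Ey[w]
    den <- sqrt(dx * dy)
    if (den > 0) s <- s + (x[w] - dx) * (y[w] - dy) / den
  }
  unname(s)
}

oracle_d2s <- function(x, y, px, py, nx, ny, Ex = rep(1, length(x)),
                       Ey = rep(1, length(y))) {
  s <- 0
  for (w in seq_along(x)) {
    xt <- x[w] - nx * px[w] * Ex[w]
    yt <- y[w] - ny * py[w] * Ey[w]
    den <- sqrt(xt^2 + yt^2)
    if (den > 0) s <- s + xt * yt / den
  }
  unname(s)
}

oracle_l2 <- function(x, y) {
  fx <- if (sum(x) > 0) x / sum(x) else x
  fy <- if (sum(y) > 0) y / sum(y) else y
  sqrt(sum((fx - fy)^2))
}

oracle_kl <- function(x, y, pc = 1 / length(x)) {
  fx <- (x + pc) / sum(x + pc)
  fy <- (y + pc) / sum(y + pc)
  sum(fx * log2(fx / fy))
}

oracle_background_probs <- function(base_freqs, k) {
  words <- all_kmers(k)
  f <- stats::setNames(as.numeric(base_freqs), c("A", "C", "G", "T"))
  vapply(words, function(w) {
    prod(f[strsplit(w, "")[[1]]])
  }, 0)
}

# random read tibble with integer phred qualities
random_reads <- function(n, len, seed, q_range = c(2L, 40L),
                         with_n = FALSE) {
  withr::with_seed(seed, {
    alphabet <- if (with_n) c("A", "C", "G", "T", "N") else
      c("A", "C", "G", "T")
    prob <- if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
    tibble::tibble(
      read_id = sprintf("r%03d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(alphabet, len, TRUE, prob), collapse = "")
      }, ""),
      qualities = lapply(seq_len(n), function(i) {
        qs <- q_range[1]:q_range[2]
        qs[sample.int(length(qs), len, replace = TRUE)]
      })
    )
  })
}

# reads whose qualities imply correctness exactly 1
perfect_reads <- function(n, len, seed) {
  r <- random_reads(n, len, seed)
  r$qualities <- lapply(r$qualities, function(q) rep(Inf, length(q)))
  r
}
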