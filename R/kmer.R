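# k-mer counting, quality-weighted counting and quality redistribution.
#
# All count vectors live over Sigma^k in lexicographic order (A<C<G<T); any
# window overlapping a non-ACGT base is excluded from counts and qcounts.

#' Count overlapping k-mers in a sequence
#'
#' @param sequence A single DNA string; characters outside \{A,C,G,T\}
#'   invalidate every window that covers them.
#' @param k Word length.
#' @return Named integer vector of length `4^k` (names from [all_kmers()]).
#'   When `k` exceeds the sequence length the vector is all zero and carries
#'   attribute `flagged = TRUE`.
#' @examples
#' count_kmers("AAA", 2)["AA"]   # 2: overlaps count
#' @export
count_kmers <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L, k >= 1L)
  words <- all_kmers(k)
  bi <- encode_bases(sequence)
  if (k > length(bi)) {
    out <- stats::setNames(integer(length(words)), words)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  idx <- window_indices(bi, k)
  out <- tabulate(idx[!is.na(idx)], nbins = length(words))
  stats::setNames(as.integer(out), words)
}

#' Redistribute the missing quality of a base over the alternative bases
#'
#' A base called with correctness probability `p` leaves mass `1 - p` for
#' the three alternative bases; that mass is split among them in proportion
#' to their frequency in the read. With base frequencies A=0.2, C=0.3,
#' G=0.3, T=0.2 and a call of A at `p = 0.7`, the alternatives receive
#' C = 0.3*0.3/0.8 = 0.1125, G = 0.1125 and T = 0.3*0.2/0.8 = 0.075.
#'
#' @param correct_prob Correctness probability of the called base, in
#'   `[0, 1]`.
#' @param base The called base, one of "A", "C", "G", "T".
#' @param base_freqs Numeric 4-vector of base frequencies (A, C, G, T)
#'   summing to 1. Zero entries receive a pseudocount of 0.5 (per base,
#'   before renormalisation) so the weights are always defined.
#' @return Named numeric vector of length 3: the mass credited to each
#'   alternative base. The masses sum to `1 - correct_prob`.
#' @examples
#' redistribute_mass(0.7, "A", c(0.2, 0.3, 0.3, 0.2))
#' @export
redistribute_mass <- function(correct_prob, base, base_freqs) {
  stopifnot(length(correct_prob) == 1L, correct_prob >= 0, correct_prob <= 1,
            base %in% DNA_BASES, length(base_freqs) == 4L)
  f <- as.numeric(base_freqs)
  if (any(f == 0)) f <- f + 0.5
  f <- f / sum(f)
  names(f) <- DNA_BASES
  alts <- setdiff(DNA_BASES, base)
  w <- f[alts] / sum(f[alts])
  (1 - correct_prob) * w
}

#' Background probability of a word under the i.i.d. null model
#'
#' `p_w` is the product over the letters of `w` of their frequencies.
#'
#' @param base_freqs Numeric 4-vector (A, C, G, T) summing to 1; zeros are
#'   allowed and may make `p_w = 0`.
#' @param word A word over \{A,C,G,T\}.
#' @return Probability in `[0, 1]`.
#' @examples
#' background_word_prob(c(0.2, 0.3, 0.3, 0.2), "TGA")  # 0.012
#' @export
background_word_prob <- function(base_freqs, word) {
  stopifnot(length(base_freqs) == 4L, abs(sum(base_freqs) - 1) < 1e-8)
  bi <- encode_bases(word)
  if (anyNA(bi)) stop("`word` must be over {A,C,G,T}")
  prod(as.numeric(base_freqs)[bi + 1L])
}

# vector of p_w over all of Sigma^k for one frequency 4-vector
background_word_probs <- function(base_freqs, k) {
  f <- as.numeric(base_freqs)
  p <- f
  if (k > 1L) for (j in 2:k) p <- as.vector(outer(f, p))
  # outer(f, p) indexes the *new leading* position slowest, matching the
  # lexicographic layout where position 1 is most significant
  stats::setNames(p, all_kmers(k))
}

# per-window correctness probabilities and, if needed, the leave-one-out
# products used by redistribution. probs: per-base correctness.
window_probs <- function(probs, k) {
  m <- length(probs) - k + 1L
  pm <- vapply(seq_len(k), function(j) probs[j:(m + j - 1L)], numeric(m))
  if (m == 1L) pm <- matrix(pm, nrow = 1L)
  lw <- log(pm)                       # zeros give -Inf, products give 0
  tot <- exp(rowSums(lw))
  list(pm = pm, tot = tot, lw = lw)
}

# leave-one-out product for position j of each window (tolerates zeros)
loo_product <- function(wp, j) {
  out <- exp(rowSums(wp$lw) - wp$lw[, j])
  z <- which(wp$pm[, j] == 0)
  if (length(z)) {
    other <- wp$lw[z, -j, drop = FALSE]
    out[z] <- exp(rowSums(other))
  }
  out
}

#' Quality-weighted k-mer counts of a read
#'
#' Each occurrence of a word contributes its correctness probability (the
#' product of its per-base `1 - 10^(-q/10)`) instead of 1. With
#' `redistribute = TRUE` each occurrence additionally credits, for every
#' base position, the three single-substitution neighbour words: the
#' substituted position carries the redistributed mass of
#' [redistribute_mass()] and the other `k - 1` positions their own
#' correctness probabilities. Only one base is substituted at a time.
#'
#' @param sequence DNA string.
#' @param qualities Numeric vector of phred scores, one per base (`Inf`
#'   allowed, meaning a certainly-correct base).
#' @param k Word length.
#' @param redistribute Credit single-substitution neighbours with the
#'   missing quality mass (default `FALSE`).
#' @param base_freqs Base frequencies used as redistribution weights;
#'   default `NULL` computes them from the read itself.
#' @return Named numeric vector of length `4^k`. Without redistribution
#'   every entry is bounded by the plain count of the word.
#' @examples
#' quality_counts("ACGT", c(30, 30, 30, 30), 2)
#' @export
quality_counts <- function(sequence, qualities, k, redistribute = FALSE,
                           base_freqs = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, k >= 1L)
  if (nchar(sequence) != length(qualities)) {
    stop("sequence and qualities have different lengths")
  }
  words <- all_kmers(k)
  nw <- length(words)
  bi <- encode_bases(sequence)
  if (k > length(bi)) {
    out <- stats::setNames(numeric(nw), words)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  idx <- window_indices(bi, k)
  valid <- !is.na(idx)
  probs <- phred_correct_prob(qualities)
  probs[is.na(bi)] <- 0
  wp <- window_probs(probs, k)

  out <- numeric(nw)
  if (any(valid)) {
    agg <- rowsum(wp$tot[valid], group = idx[valid])
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }

  if (redistribute && any(valid)) {
    f <- if (is.null(base_freqs)) {
      base_frequencies(bi[!is.na(bi)], pseudo = TRUE)
    } else {
      f0 <- as.numeric(base_freqs)
      if (any(f0 == 0)) f0 <- f0 + 0.5
      f0 / sum(f0)
    }
    wm <- window_base_matrix(bi, k)
    pow <- 4L^((k - 1L):0L)
    for (j in seq_len(k)) {
      rest <- loo_product(wp, j)
      b <- wm[, j]
      miss <- 1 - wp$pm[, j]
      denom <- 1 - f[b + 1L]          # sum of alternative-base frequencies
      for (alt in 0:3) {
        sel <- which(valid & b != alt)
        if (!length(sel)) next
        credit <- miss[sel] * (f[alt + 1L] / denom[sel]) * rest[sel]
        nidx <- idx[sel] + (alt - b[sel]) * pow[j]
        agg <- rowsum(credit, group = nidx)
        tgt <- as.integer(rownames(agg))
        out[tgt] <- out[tgt] + agg[, 1L]
      }
    }
  }
  stats::setNames(out, words)
}

#' Build k-mer profiles for a set of reads
#'
#' Computes, for every read, the plain count vector, the quality-weighted
#' count vector (optionally with quality redistribution) and the read's
#' base frequencies, packed into a compact object used by the measure and
#' clustering functions.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `qualities`.
#' @param k Word length.
#' @param redistribute Apply quality redistribution to the quality-weighted
#'   vectors (default `FALSE`). The plain (non-redistributed) quality
#'   vectors are always kept as well, because the expected-word-probability
#'   estimators are defined on them.
#' @param revcomp Pool each word with its reverse complement into the
#'   lexicographically smaller (canonical) word (default `FALSE`).
#' @param freqs `"read"` (default) computes base frequencies per read;
#'   `"dataset"` uses the pooled frequencies of all reads for every read.
#' @return An object of class `kmer_profiles`: a list with matrices
#'   `counts`, `qcounts`, `qcounts_plain` (reads x `4^k`), vector
#'   `n_windows` (valid windows per read), matrix `base_freqs` (reads x 4),
#'   and metadata `k`, `read_ids`, `redistribute`, `revcomp`,
#'   `mean_base_correct`.
#' @seealso [tidy.kmer_profiles()], [read_dist()], [cluster_reads()]
#' @export
kmer_profiles <- function(reads, k, redistribute = FALSE, revcomp = FALSE,
                          freqs = c("read", "dataset")) {
  check_reads(reads)
  freqs <- match.arg(freqs)
  stopifnot(k >= 1L)
  words <- all_kmers(k)
  nw <- length(words)
  n <- nrow(reads)

  enc <- lapply(reads$sequence, encode_bases)
  if (freqs == "dataset") {
    pooled <- base_frequencies(unlist(lapply(enc, function(b) b[!is.na(b)])))
  }

  counts  <- matrix(0L, n, nw, dimnames = list(reads$read_id, words))
  qplain  <- matrix(0,  n, nw, dimnames = list(reads$read_id, words))
  qred    <- if (redistribute) qplain else NULL
  n_win   <- integer(n)
  bfreq   <- matrix(0, n, 4L, dimnames = list(reads$read_id, DNA_BASES))
  csum <- 0; ctot <- 0

  for (i in seq_len(n)) {
    bi <- enc[[i]]
    q <- reads$qualities[[i]]
    pr <- phred_correct_prob(q)
    ok <- !is.na(bi)
    pr[!ok] <- 0
    csum <- csum + sum(pr[ok]); ctot <- ctot + sum(ok)
    bf <- if (freqs == "dataset") pooled else base_frequencies(bi[ok])
    bfreq[i, ] <- bf
    if (k > length(bi)) next
    idx <- window_indices(bi, k)
    valid <- !is.na(idx)
    n_win[i] <- sum(valid)
    if (!n_win[i]) next
    counts[i, ] <- tabulate(idx[valid], nbins = nw)
    wp <- window_probs(pr, k)
    agg <- rowsum(wp$tot[valid], group = idx[valid])
    qplain[i, as.integer(rownames(agg))] <- agg[, 1L]
    if (redistribute) {
      qred[i, ] <- quality_counts(reads$sequence[i], q, k,
                                  redistribute = TRUE,
                                  base_freqs = if (freqs == "dataset") pooled else NULL)
    }
  }

  qcounts <- if (redistribute) qred else qplain
  if (revcomp) {
    map <- canonical_map(k)
    counts  <- pool_canonical(counts, map)
    qplain  <- pool_canonical(qplain, map)
    qcounts <- if (redistribute) pool_canonical(qcounts, map) else qplain
  }

  structure(
    list(counts = counts, qcounts = qcounts, qcounts_plain = qplain,
         n_windows = n_win, base_freqs = bfreq, k = k,
         read_ids = reads$read_id, redistribute = redistribute,
         revcomp = revcomp,
         mean_base_correct = if (ctot > 0) csum / ctot else 1),
    class = "kmer_profiles"
  )
}

# index of the canonical (lexicographically smaller of word / revcomp) word
canonical_map <- function(k) {
  words <- all_kmers(k)
  rc <- vapply(words, function(w) {
    comp <- chartr("ACGT", "TGCA", w)
    paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
  }, "")
  pmin(seq_along(words), match(rc, words))
}

pool_canonical <- function(mat, map) {
  out <- mat * 0
  for (tgt in unique(map)) {
    src <- which(map == tgt)
    out[, tgt] <- rowSums(mat[, src, drop = FALSE])
  }
  out
}

#' @export
print.kmer_profiles <- function(x, ...) {
  cat("<kmer_profiles> ", length(x$read_ids), " reads, k = ", x$k,
      " (", ncol(x$counts), " words)",
      if (x$redistribute) ", quality redistribution on",
      if (x$revcomp) ", canonical (revcomp-pooled) words",
      "\n", sep = "")
  invisible(x)
}

#' Tidy a k-mer profile set into a long tibble
#'
#' @param x A [kmer_profiles()] object.
#' @param ... Unused.
#' @return Tibble with columns `read_id`, `word`, `count`, `qcount`,
#'   one row per (read, word) with a non-zero entry in either vector.
#' @export
tidy.kmer_profiles <- function(x, ...) {
  keep <- x$counts > 0 | x$qcounts > 0
  ij <- which(keep, arr.ind = TRUE)
  ord <- order(ij[, 1L], ij[, 2L])
  ij <- ij[ord, , drop = FALSE]
  tibble::tibble(
    read_id = x$read_ids[ij[, 1L]],
    word = colnames(x$counts)[ij[, 2L]],
    count = x$counts[ij],
    qcount = x$qcounts[ij]
  )
}

#' Export k-mer profiles as TSV
#'
#' Writes the long form of [tidy.kmer_profiles()] (read_id, word, count,
#' qcount) to a tab-separated file.
#'
#' @param profiles A [kmer_profiles()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  readr::write_tsv(tidy.kmer_profiles(profiles), path)
  invisible(path)
}
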