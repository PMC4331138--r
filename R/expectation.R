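# Dataset-level estimators of the expected word probability E(P_w).
#
# Both estimators are defined over the whole read set and are computed from
# non-redistributed occurrence probabilities, even when redistribution is
# enabled for the profile vectors (redistribution modifies X_w^q, not E(P_w)).

new_word_expectation <- function(values, k, estimator, fallback) {
  structure(list(values = values, k = k, estimator = estimator,
                 fallback = fallback),
            class = "word_expectation")
}

#' @export
print.word_expectation <- function(x, ...) {
  cat("<word_expectation> ", toupper(x$estimator), ", k = ", x$k,
      ", fallback = ", signif(x$fallback, 4), "\n", sep = "")
  invisible(x)
}

#' Average word probability (AWP) estimator of E(P_w)
#'
#' Estimates the expected probability that an occurrence of word `w` is
#' correct as the ratio of the dataset-wide quality-weighted count of `w`
#' to its plain count: `E(P_w) ~ sum_x X_w^q / sum_x X_w`.
#'
#' @param profiles A [kmer_profiles()] object (its non-redistributed quality
#'   vectors are used).
#' @param fallback Value used for words never observed in the dataset;
#'   default `NULL` uses the dataset mean per-base correctness probability
#'   raised to the power `k`.
#' @return A `word_expectation` object with a value in `[0, 1]` per word.
#' @examples
#' reads <- tibble::tibble(read_id = "r", sequence = "ACGT",
#'                         qualities = list(c(30, 30, 30, 30)))
#' estimate_awp(kmer_profiles(reads, 2))
#' @export
estimate_awp <- function(profiles, fallback = NULL) {
  stopifnot(inherits(profiles, "kmer_profiles"))
  if (length(profiles$read_ids) == 0L) stop("empty profile collection")
  num <- colSums(profiles$qcounts_plain)
  den <- colSums(profiles$counts)
  if (is.null(fallback)) fallback <- profiles$mean_base_correct^profiles$k
  vals <- ifelse(den > 0, num / den, fallback)
  new_word_expectation(vals, profiles$k, "awp", fallback)
}

#' Average quality probability (AQP) estimator of E(P_w)
#'
#' For each position `j` of word `w`, averages the phred score observed at
#' that position over all occurrences of `w` in the dataset, then combines
#' the per-position averages into
#' `E(P_w) ~ prod_j (1 - 10^(-Qbar_w[j]/10))`.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `qualities`.
#' @param k Word length.
#' @param fallback As in [estimate_awp()].
#' @return A `word_expectation` object.
#' @export
estimate_aqp <- function(reads, k, fallback = NULL) {
  check_reads(reads)
  stopifnot(k >= 1L)
  nw <- 4L^k
  qsum <- matrix(0, nw, k)
  occ <- numeric(nw)
  csum <- 0; ctot <- 0
  for (i in seq_len(nrow(reads))) {
    bi <- encode_bases(reads$sequence[i])
    q <- as.numeric(reads$qualities[[i]])
    ok <- !is.na(bi)
    csum <- csum + sum(phred_correct_prob(q[ok])); ctot <- ctot + sum(ok)
    if (k > length(bi)) next
    idx <- window_indices(bi, k)
    valid <- which(!is.na(idx))
    if (!length(valid)) next
    occ <- occ + tabulate(idx[valid], nbins = nw)
    m <- length(bi) - k + 1L
    for (j in seq_len(k)) {
      qj <- q[j:(m + j - 1L)][valid]
      agg <- rowsum(qj, group = idx[valid])
      tgt <- as.integer(rownames(agg))
      qsum[tgt, j] <- qsum[tgt, j] + agg[, 1L]
    }
  }
  if (is.null(fallback)) {
    fallback <- (if (ctot > 0) csum / ctot else 1)^k
  }
  vals <- rep(fallback, nw)
  obs <- occ > 0
  if (any(obs)) {
    qbar <- qsum[obs, , drop = FALSE] / occ[obs]
    vals[obs] <- apply(phred_correct_prob(qbar), 1L, prod)
  }
  new_word_expectation(stats::setNames(vals, all_kmers(k)), k, "aqp", fallback)
}
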