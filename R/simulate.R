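# Synthetic references and quality-annotated reads with controlled
# mismatch / insertion / deletion rates and phred-consistent qualities.

#' Describe a positional quality profile
#'
#' Mean phred score declining linearly along the read from `mean_start` to
#' `mean_end`, plus integer Gaussian noise with standard deviation `sd`,
#' clamped to `[qmin, qmax]` (default `[2, 40]`, an Illumina-like profile).
#' Use `quality_profile(90, 90, 0, qmax = 93)` for effectively error-free
#' reads.
#'
#' @param mean_start Mean phred at the first base (default 38).
#' @param mean_end Mean phred at the last base (default 20).
#' @param sd Standard deviation of the per-base noise (default 3).
#' @param qmin,qmax Clamp bounds for emitted scores (defaults 2 and 40).
#' @return A `quality_profile` list.
#' @export
quality_profile <- function(mean_start = 38, mean_end = 20, sd = 3,
                            qmin = 2, qmax = 40) {
  stopifnot(mean_start >= 0, mean_end >= 0, sd >= 0,
            qmin >= 0, qmax >= qmin, qmax <= 93)
  structure(list(mean_start = mean_start, mean_end = mean_end, sd = sd,
                 qmin = qmin, qmax = qmax),
            class = "quality_profile")
}

# per-position mean phred curve for a read length
profile_means <- function(profile, len) {
  if (len == 1L) return(profile$mean_start)
  seq(profile$mean_start, profile$mean_end, length.out = len)
}

#' Generate synthetic reference sequences
#'
#' I.i.d. (or order-1 Markov) sequences whose base compositions are
#' jittered per reference so that references are distinguishable by their
#' k-mer spectra. Base weights for reference `j` are
#' `exp(rnorm(4, 0, composition_sd))`, normalised; `composition_sd = 0`
#' makes all references compositionally identical.
#'
#' @param n_refs Number of references.
#' @param length_range Length range in bases, `c(min, max)`
#'   (default `c(500, 10000)`); lengths are drawn uniformly.
#' @param composition_sd Log-scale spread of the per-reference base
#'   weights (default 0.5).
#' @param markov_order 1 (default) or 0. Order 1 additionally jitters the
#'   transition rows with the same spread, giving references dinucleotide
#'   structure beyond plain composition — the signal the background-centred
#'   statistics are built to exploit (real transcripts have such structure;
#'   under an i.i.d. model with per-read backgrounds, centring removes the
#'   only distinguishing signal). Order 0 is kept as a degenerate control.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return Tibble with columns `ref_id`, `sequence`.
#' @export
simulate_references <- function(n_refs, length_range = c(500, 10000),
                                composition_sd = 0.5, markov_order = 1L,
                                seed = NULL) {
  stopifnot(n_refs >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L], length_range[1L] >= 1,
            markov_order %in% c(0L, 1L), composition_sd >= 0)
  gen <- function() {
    lens <- sample.int(length_range[2L] - length_range[1L] + 1L, n_refs,
                       replace = TRUE) + length_range[1L] - 1L
    seqs <- vapply(seq_len(n_refs), function(j) {
      w <- exp(stats::rnorm(4L, 0, composition_sd))
      p <- w / sum(w)
      if (markov_order == 0L) {
        paste(sample(DNA_BASES, lens[j], replace = TRUE, prob = p),
              collapse = "")
      } else {
        trans <- t(vapply(1:4, function(b) {
          wt <- p * exp(stats::rnorm(4L, 0, composition_sd))
          wt / sum(wt)
        }, numeric(4L)))
        out <- integer(lens[j])
        out[1L] <- sample.int(4L, 1L, prob = p)
        for (i in seq_len(lens[j] - 1L)) {
          out[i + 1L] <- sample.int(4L, 1L, prob = trans[out[i], ])
        }
        paste(DNA_BASES[out], collapse = "")
      }
    }, "")
    tibble::tibble(ref_id = sprintf("ref%02d", seq_len(n_refs)),
                   sequence = seqs)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate quality-annotated reads from reference sequences
#'
#' Each reference contributes `reads_per_ref` fixed-length reads with start
#' positions drawn uniformly. Per-base phred scores come from the
#' positional `profile`; every base is substituted with probability equal
#' to its quality-implied error `10^(-Q/10)`, so qualities are informative
#' of the injected errors. A non-zero `mismatch_rate` scales the
#' position-dependent error curve so that the mean per-base substitution
#' probability equals the requested rate, and the emitted qualities
#' re-encode the scaled probabilities (they stay consistent with the
#' errors). Insertions replace an emitted position with a uniform random
#' base with probability `insertion_rate`; deletions skip a reference base
#' with probability `deletion_rate` (the read is extended from the
#' reference to keep its fixed length).
#'
#' @param references Tibble from [simulate_references()] (columns `ref_id`,
#'   `sequence`).
#' @param reads_per_ref Reads simulated from each reference.
#' @param read_length Read length in bases (default 200); must not exceed
#'   the shortest reference.
#' @param mismatch_rate,insertion_rate,deletion_rate Error rates in
#'   `[0, 1)`; their sum must be < 1.
#' @param profile A [quality_profile()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List with `reads` (tibble: `read_id`, `sequence`, `qualities`,
#'   plus bookkeeping columns `n_mismatches`, `n_insertions`,
#'   `n_deletions`) and `truth` (tibble: `read_id`, `source`).
#' @export
simulate_reads <- function(references, reads_per_ref, read_length = 200L,
                           mismatch_rate = 0, insertion_rate = 0,
                           deletion_rate = 0, profile = quality_profile(),
                           seed = NULL) {
  stopifnot(all(c("ref_id", "sequence") %in% names(references)),
            reads_per_ref >= 1L, read_length >= 1L,
            mismatch_rate >= 0, insertion_rate >= 0, deletion_rate >= 0,
            mismatch_rate + insertion_rate + deletion_rate < 1)
  if (read_length > min(nchar(references$sequence))) {
    stop("`read_length` exceeds the shortest reference (",
         min(nchar(references$sequence)), " bases)")
  }
  gen <- function() {
    mu <- profile_means(profile, read_length)
    qlo <- profile$qmin %||% 2; qhi <- profile$qmax %||% 40
    # expected per-position error under the discretized, clamped quality
    # draw (integer grid with Gaussian weights), so that scaling by
    # mismatch_rate / mean(expected error) hits the requested mean rate
    qgrid <- qlo:qhi
    exp_err <- vapply(mu, function(m) {
      if (profile$sd == 0) {
        phred_error_prob(min(max(round(m), qlo), qhi))
      } else {
        up <- stats::pnorm(qgrid + 0.5, m, profile$sd)
        lo <- stats::pnorm(qgrid - 0.5, m, profile$sd)
        w <- up - lo
        w[1L] <- up[1L]                          # lump the tails
        w[length(w)] <- 1 - lo[length(w)]
        sum(w * phred_error_prob(qgrid))
      }
    }, 0)
    err_scale <- if (mismatch_rate > 0) mismatch_rate / mean(exp_err) else 1

    n_total <- nrow(references) * reads_per_ref
    out <- vector("list", n_total)
    r <- 0L
    for (j in seq_len(nrow(references))) {
      refseq <- references$sequence[j]
      ref_len <- nchar(refseq)
      enc <- encode_bases(refseq)
      for (i in seq_len(reads_per_ref)) {
        r <- r + 1L
        # window with margin for deletions
        need <- read_length +
          ceiling(read_length * deletion_rate * 3) + 10L
        need <- min(need, ref_len)
        start <- sample.int(max(ref_len - need + 1L, 1L), 1L)
        win <- enc[start:min(start + need - 1L, ref_len)]

        n_del <- 0L
        if (deletion_rate > 0) {
          keep <- stats::runif(length(win)) >= deletion_rate
          n_del <- sum(!keep[seq_len(min(read_length + 5L, length(win)))])
          win <- win[keep]
        }
        is_ins <- if (insertion_rate > 0) {
          stats::runif(read_length) < insertion_rate
        } else {
          rep(FALSE, read_length)
        }
        n_need <- read_length - sum(is_ins)
        if (length(win) < n_need) {
          # ran out of reference near the end; pad without deletions
          extra <- enc[min(start + need, ref_len):ref_len]
          win <- c(win, extra)
        }
        bases <- integer(read_length)
        bases[is_ins] <- sample.int(4L, sum(is_ins), replace = TRUE) - 1L
        bases[!is_ins] <- win[seq_len(n_need)]

        q <- pmin(pmax(round(mu + stats::rnorm(read_length, 0, profile$sd)),
                       qlo), qhi)
        perr <- pmin(phred_error_prob(q) * err_scale, 0.75)
        if (mismatch_rate > 0) q <- pmax(round(-10 * log10(perr)), 1)
        mism <- stats::runif(read_length) < perr
        mism[is_ins] <- FALSE
        if (any(mism)) {
          shift <- sample.int(3L, sum(mism), replace = TRUE)
          bases[mism] <- (bases[mism] + shift) %% 4L
        }
        out[[r]] <- list(
          read_id = sprintf("%s_read%05d", references$ref_id[j], i),
          sequence = paste(DNA_BASES[bases + 1L], collapse = ""),
          qualities = as.integer(q),
          source = references$ref_id[j],
          n_mismatches = sum(mism),
          n_insertions = sum(is_ins),
          n_deletions = n_del
        )
      }
    }
    reads <- tibble::tibble(
      read_id = vapply(out, `[[`, "", "read_id"),
      sequence = vapply(out, `[[`, "", "sequence"),
      qualities = lapply(out, `[[`, "qualities"),
      n_mismatches = vapply(out, `[[`, 0L, "n_mismatches"),
      n_insertions = vapply(out, `[[`, 0L, "n_insertions"),
      n_deletions = vapply(out, `[[`, 0L, "n_deletions")
    )
    truth <- tibble::tibble(read_id = reads$read_id,
                            source = vapply(out, `[[`, "", "source"))
    list(reads = reads, truth = truth)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
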