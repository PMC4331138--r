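# Pairwise alignment-free statistics, classical and quality-weighted, and
# the similarity -> dissimilarity conversion used by the clustering.

MEASURES <- c("d2", "d2star", "d2s", "d2q", "d2star_q", "d2s_q",
              "l2", "kl", "symkl")

#' Describe a measure configuration
#'
#' Bundles the choice of statistic with its options. An expected-word-
#' probability estimator is required for the centred quality-weighted
#' statistics (`d2star_q`, `d2s_q`) and invalid for the others.
#'
#' @param name One of `r paste0('"', MEASURES, '"', collapse = ", ")`.
#'   The `-` spelling used on the command line (`d2star-q`) is accepted.
#' @param estimator `"awp"`, `"aqp"` or `"none"`.
#' @param redistribute Use quality-redistributed vectors (quality-weighted
#'   statistics only).
#' @param pseudocount Pseudocount added to each word before normalisation in
#'   KL-type measures; default `1 / 4^k` is substituted at evaluation time
#'   when `NULL`.
#' @return A `measure_spec` list.
#' @export
measure_spec <- function(name, estimator = c("none", "awp", "aqp"),
                         redistribute = FALSE, pseudocount = NULL) {
  name <- gsub("-", "_", tolower(name))
  if (!name %in% MEASURES) {
    stop("unknown measure '", name, "'; choose one of: ",
         paste(MEASURES, collapse = ", "))
  }
  estimator <- match.arg(estimator)
  needs_e <- name %in% c("d2star_q", "d2s_q")
  if (needs_e && estimator == "none") {
    stop("measure '", name, "' requires `estimator` \"awp\" or \"aqp\"")
  }
  if (!needs_e && estimator != "none") {
    stop("measure '", name, "' does not use an expectation estimator")
  }
  quality <- name %in% c("d2q", "d2star_q", "d2s_q")
  if (redistribute && !quality) {
    stop("quality redistribution only applies to quality-weighted measures")
  }
  structure(list(name = name, estimator = estimator,
                 redistribute = redistribute, pseudocount = pseudocount,
                 quality = quality),
            class = "measure_spec")
}

#' D2 similarity: inner product of word-count vectors
#'
#' @param x,y Count vectors over the same `Sigma^k` (equal length).
#' @return `sum_w x_w * y_w`.
#' @export
d2 <- function(x, y) {
  if (length(x) != length(y)) stop("count vectors have different k")
  sum(as.numeric(x) * as.numeric(y))
}

#' Quality-weighted D2 similarity
#'
#' Identical formula to [d2()] applied to quality-weighted vectors; kept as
#' a separate entry point for clarity of intent.
#'
#' @param xq,yq Quality-weighted count vectors of equal length.
#' @return `sum_w xq_w * yq_w`.
#' @export
d2q <- function(xq, yq) d2(xq, yq)

# centred vector and its centring term: x - n * p * E
centre_counts <- function(x, p, n, E = 1) {
  den <- n * p * E
  list(tilde = as.numeric(x) - den, den = den)
}

#' Centred and normalised D2* similarity
#'
#' `D2* = sum_w Xt_w Yt_w / denom_w` with `Xt_w = X_w - n_x p_w(x) E_x(w)`.
#' For two reads with different lengths and compositions the denominator is
#' the geometric mean `sqrt(n_x p_x E_x * n_y p_y E_y)`, which reduces to
#' the single-sequence form `(n - k + 1) p_w` when the two sides share
#' `n`, `p` and `E`. Terms with a zero denominator contribute 0.
#'
#' Passing expectation vectors `Ex`, `Ey` (from [estimate_awp()] /
#' [estimate_aqp()]) yields the quality-weighted variant `D2*^q`; the
#' default `E = 1` is the classical statistic.
#'
#' @param x,y (Quality-weighted) count vectors.
#' @param px,py Background word probabilities per word (see
#'   [background_word_prob()]).
#' @param nx,ny Number of valid k-mer windows in each read.
#' @param Ex,Ey Expected word probabilities per word (default 1).
#' @return Similarity value.
#' @export
d2star <- function(x, y, px, py, nx, ny, Ex = 1, Ey = 1) {
  if (length(x) != length(y)) stop("count vectors have different k")
  if (nx <= 0 || ny <= 0) stop("window counts must be positive")
  cx <- centre_counts(x, px, nx, Ex)
  cy <- centre_counts(y, py, ny, Ey)
  den <- sqrt(cx$den * cy$den)
  terms <- ifelse(den > 0, cx$tilde * cy$tilde / den, 0)
  sum(terms)
}

#' @rdname d2star
#' @export
d2star_q <- function(x, y, px, py, nx, ny, Ex, Ey) {
  d2star(x, y, px, py, nx, ny, Ex, Ey)
}

#' Self-standardised D2s similarity
#'
#' `D2s = sum_w Xt_w Yt_w / sqrt(Xt_w^2 + Yt_w^2)`; terms where both
#' centred counts are 0 contribute 0. As in [d2star()], supplying `Ex`,
#' `Ey` gives the quality-weighted `D2^sq`.
#'
#' @inheritParams d2star
#' @return Similarity value.
#' @export
d2s <- function(x, y, px, py, nx, ny, Ex = 1, Ey = 1) {
  if (length(x) != length(y)) stop("count vectors have different k")
  cx <- centre_counts(x, px, nx, Ex)$tilde
  cy <- centre_counts(y, py, ny, Ey)$tilde
  den <- sqrt(cx^2 + cy^2)
  sum(ifelse(den > 0, cx * cy / den, 0))
}

#' @rdname d2s
#' @export
d2s_q <- function(x, y, px, py, nx, ny, Ex, Ey) {
  d2s(x, y, px, py, nx, ny, Ex, Ey)
}

# normalise a count vector to a frequency vector (sum 1); zero vector stays 0
freq_normalise <- function(x) {
  s <- sum(x)
  if (s > 0) as.numeric(x) / s else as.numeric(x)
}

#' L2 (Euclidean) distance between frequency-normalised profiles
#'
#' @param x,y Count vectors; each is normalised to sum 1 before the
#'   Euclidean distance is taken.
#' @return Distance `>= 0`.
#' @export
l2_dist <- function(x, y) {
  if (length(x) != length(y)) stop("count vectors have different k")
  sqrt(sum((freq_normalise(x) - freq_normalise(y))^2))
}

#' Kullback-Leibler divergence between pseudocounted profiles
#'
#' Counts are smoothed with a pseudocount (default `1 / 4^k` per word),
#' normalised to distributions, and compared with
#' `KL(x || y) = sum_w f_x log2(f_x / f_y)`. `sym_kl()` averages the two
#' directions.
#'
#' @param x,y Count vectors.
#' @param pseudocount Added to every word before normalisation; default
#'   `1 / length(x)`.
#' @return Divergence in bits (`>= 0`, 0 iff the smoothed distributions
#'   are equal).
#' @export
kl_div <- function(x, y, pseudocount = NULL) {
  if (length(x) != length(y)) stop("count vectors have different k")
  if (is.null(pseudocount)) pseudocount <- 1 / length(x)
  fx <- as.numeric(x) + pseudocount; fx <- fx / sum(fx)
  fy <- as.numeric(y) + pseudocount; fy <- fy / sum(fy)
  sum(fx * (log2(fx) - log2(fy)))
}

#' @rdname kl_div
#' @export
sym_kl <- function(x, y, pseudocount = NULL) {
  (kl_div(x, y, pseudocount) + kl_div(y, x, pseudocount)) / 2
}

#' Convert a similarity to a dissimilarity
#'
#' `1 - S_xy / sqrt(S_xx * S_yy)`, clamped to `[0, 2]`: the cosine-style
#' dissimilarity used to drive k-means with the D-type similarities.
#'
#' @param s_xy Similarity between the two objects.
#' @param s_xx,s_yy Self-similarities (must be positive).
#' @return Dissimilarity in `[0, 2]`.
#' @export
to_dissimilarity <- function(s_xy, s_xx, s_yy) {
  if (s_xx <= 0 || s_yy <= 0) {
    stop("self-similarities must be positive to form a dissimilarity")
  }
  min(max(1 - s_xy / sqrt(s_xx * s_yy), 0), 2)
}

# ---- dataset-level machinery -------------------------------------------

# resolve the estimator for a measure spec against profiles/reads
resolve_expectation <- function(spec, profiles, reads = NULL) {
  if (spec$estimator == "none") return(NULL)
  if (spec$estimator == "awp") return(estimate_awp(profiles))
  if (is.null(reads)) stop("AQP estimation needs the reads tibble")
  estimate_aqp(reads, profiles$k)
}

# per-read feature representation for a measure:
#  $vec  raw vectors used for centroid averaging (counts or qcounts or freq)
#  $u    transformed vectors for cosine-type measures (NULL for d2s/kl types)
#  $tilde, $selfs for d2s-type
measure_context <- function(profiles, spec, expectation = NULL) {
  V <- if (spec$quality) profiles$qcounts else profiles$counts
  storage.mode(V) <- "double"
  k <- profiles$k
  E <- if (!is.null(expectation)) expectation$values else NULL
  ctx <- list(spec = spec, k = k, V = V, n = profiles$n_windows,
              bfreq = profiles$base_freqs, E = E)
  name <- spec$name
  if (name %in% c("d2", "d2q")) {
    ctx$type <- "cosine"
    ctx$U <- V
  } else if (name %in% c("d2star", "d2star_q")) {
    ctx$type <- "cosine"
    ctx$U <- star_transform(V, profiles$base_freqs, profiles$n_windows, k, E)
  } else if (name %in% c("d2s", "d2s_q")) {
    ctx$type <- "d2s"
    ctx$tilde <- tilde_matrix(V, profiles$base_freqs, profiles$n_windows, k, E)
    ctx$selfs <- rowSums(abs(ctx$tilde)) / sqrt(2)
  } else {
    pc <- spec$pseudocount
    if (is.null(pc)) pc <- 1 / ncol(V)
    if (name == "l2") {
      ctx$type <- "euclid"
      ctx$F <- t(apply(V, 1L, freq_normalise))
    } else {
      ctx$type <- name                       # "kl" or "symkl"
      FF <- V + pc
      ctx$F <- FF / rowSums(FF)
    }
  }
  ctx
}

# matrix of centred counts Xt = X - n * p * E for every read
tilde_matrix <- function(V, bfreq, n, k, E = NULL) {
  nr <- nrow(V)
  out <- V
  for (i in seq_len(nr)) {
    p <- background_word_probs(bfreq[i, ], k)
    den <- n[i] * p
    if (!is.null(E)) den <- den * E
    out[i, ] <- V[i, ] - den
  }
  out
}

# star transform u = (X - n p E) / sqrt(n p E); coordinates with zero
# denominator are dropped to 0 (their terms contribute 0 by convention)
star_transform <- function(V, bfreq, n, k, E = NULL) {
  out <- V
  for (i in seq_len(nrow(V))) {
    p <- background_word_probs(bfreq[i, ], k)
    den <- n[i] * p
    if (!is.null(E)) den <- den * E
    u <- numeric(length(den))
    pos <- den > 0
    u[pos] <- (V[i, pos] - den[pos]) / sqrt(den[pos])
    out[i, ] <- u
  }
  out
}

# star transform of a single pseudo-profile (centroid)
star_transform_one <- function(v, bf, n, k, E = NULL) {
  p <- background_word_probs(bf, k)
  den <- n * p
  if (!is.null(E)) den <- den * E
  u <- numeric(length(den))
  pos <- den > 0
  u[pos] <- (v[pos] - den[pos]) / sqrt(den[pos])
  u
}

#' Pairwise dissimilarity matrix between read profiles
#'
#' Computes the full symmetric matrix of dissimilarities between all reads
#' of a profile set under a configured measure. D-type similarities are
#' converted with [to_dissimilarity()]; `l2`, `kl` and `symkl` are already
#' dissimilarities.
#'
#' @param profiles A [kmer_profiles()] object.
#' @param measure Measure name (see [measure_spec()]).
#' @param estimator Expectation estimator for `d2star_q` / `d2s_q`.
#' @param reads Original reads tibble; only needed for `estimator = "aqp"`.
#' @param pseudocount KL pseudocount (default `1 / 4^k`).
#' @return Numeric matrix with read ids as dimnames.
#' @export
read_dist <- function(profiles, measure = "d2star_q",
                      estimator = c("none", "awp", "aqp"), reads = NULL,
                      pseudocount = NULL) {
  estimator <- match.arg(estimator)
  quality <- gsub("-", "_", tolower(measure)) %in% c("d2q", "d2star_q", "d2s_q")
  spec <- measure_spec(measure, estimator,
                       redistribute = profiles$redistribute && quality,
                       pseudocount = pseudocount)
  expectation <- resolve_expectation(spec, profiles, reads)
  ctx <- measure_context(profiles, spec, expectation)
  n <- nrow(ctx$V)
  D <- matrix(0, n, n,
              dimnames = list(profiles$read_ids, profiles$read_ids))
  if (ctx$type == "cosine") {
    S <- ctx$U %*% t(ctx$U)
    nrm <- sqrt(diag(S))
    nrm[nrm == 0] <- NA_real_
    D <- 1 - S / outer(nrm, nrm)
    D[is.na(D)] <- 1
    D <- pmin(pmax(D, 0), 2)
    diag(D) <- 0
  } else if (ctx$type == "d2s") {
    for (j in seq_len(n)) {
      yt <- ctx$tilde[j, ]
      num <- sweep(ctx$tilde, 2L, yt, `*`)
      den <- sqrt(sweep(ctx$tilde^2, 2L, yt^2, `+`))
      sxy <- rowSums(ifelse(den > 0, num / den, 0))
      sxx <- ctx$selfs; syy <- ctx$selfs[j]
      d <- ifelse(sxx > 0 & syy > 0,
                  pmin(pmax(1 - sxy / sqrt(sxx * syy), 0), 2), 1)
      D[, j] <- d
    }
    diag(D) <- 0
  } else if (ctx$type == "euclid") {
    for (j in seq_len(n)) {
      D[, j] <- sqrt(rowSums(sweep(ctx$F, 2L, ctx$F[j, ])^2))
    }
  } else {
    lF <- log2(ctx$F)
    for (j in seq_len(n)) {
      kl_xy <- rowSums(ctx$F * sweep(lF, 2L, lF[j, ]))
      if (ctx$type == "kl") {
        D[, j] <- kl_xy
      } else {
        kl_yx <- colSums(ctx$F[j, ] * (lF[j, ] - t(lF)))
        D[, j] <- (kl_xy + kl_yx) / 2
      }
    }
  }
  D
}

#' Write a pairwise distance matrix as TSV
#'
#' Square matrix with read ids as the header row and first column.
#'
#' @param D Matrix from [read_dist()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(D, path) {
  df <- tibble::as_tibble(D, rownames = "read_id")
  readr::write_tsv(df, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
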