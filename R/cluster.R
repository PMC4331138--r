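# Centroid-based (k-means) clustering of read profiles under any measure.
#
# Reads are put in a canonical order (sorted by read_id) before anything
# random happens, so results depend on the read set and the seed but not on
# input row order. Initial centroids are drawn uniformly without replacement
# with sub-seed `seed + r` for run r; ties in assignment go to the lowest
# centroid index; empty clusters are reseeded with the read farthest from
# its own centroid. A run stops at an assignment fixpoint, at `max_iter`,
# or after `max_no_improve` iterations without improving the run's best
# distortion (some measures, e.g. symmetrized KL and D2*, need not
# converge). The lowest-distortion solution over `runs` restarts is kept.

# nearest-centroid assignment from a reads x centroids distance matrix;
# ties broken toward the lowest centroid index
assign_nearest <- function(D) {
  max.col(-D, ties.method = "first")
}

# centroid state from a set of member rows (or a single seed read)
centroid_state <- function(ctx, members) {
  st <- list()
  if (ctx$type %in% c("cosine", "d2s")) {
    st$v  <- colMeans(ctx$V[members, , drop = FALSE])
    st$n  <- mean(ctx$n[members])
    st$bf <- colMeans(ctx$bfreq[members, , drop = FALSE])
    if (ctx$spec$name %in% c("d2star", "d2star_q")) {
      st$u <- star_transform_one(st$v, st$bf, st$n, ctx$k, ctx$E)
    } else if (ctx$type == "cosine") {
      st$u <- st$v
    } else {
      p <- background_word_probs(st$bf, ctx$k)
      den <- st$n * p
      if (!is.null(ctx$E)) den <- den * ctx$E
      st$tilde <- st$v - den
    }
  } else {
    st$f <- colMeans(ctx$F[members, , drop = FALSE])
  }
  st
}

update_centroids <- function(ctx, assignment, centers) {
  lapply(seq_len(centers), function(j) {
    centroid_state(ctx, which(assignment == j))
  })
}

# reads x centroids dissimilarity matrix
centroid_dist <- function(ctx, cents) {
  n <- nrow(ctx$V)
  c_ <- length(cents)
  D <- matrix(0, n, c_)
  if (ctx$type == "cosine") {
    Uc <- do.call(rbind, lapply(cents, `[[`, "u"))
    rn <- sqrt(rowSums(ctx$U^2))
    cn <- sqrt(rowSums(Uc^2))
    S <- ctx$U %*% t(Uc)
    D <- 1 - S / outer(rn, cn)
    D[!is.finite(D)] <- 1          # zero-norm read or centroid
    D <- pmin(pmax(D, 0), 2)
  } else if (ctx$type == "d2s") {
    sxx <- ctx$selfs
    for (j in seq_len(c_)) {
      yt <- cents[[j]]$tilde
      num <- sweep(ctx$tilde, 2L, yt, `*`)
      den <- sqrt(sweep(ctx$tilde^2, 2L, yt^2, `+`))
      sxy <- rowSums(ifelse(den > 0, num / den, 0))
      syy <- sum(abs(yt)) / sqrt(2)
      D[, j] <- ifelse(sxx > 0 & syy > 0,
                       pmin(pmax(1 - sxy / sqrt(sxx * syy), 0), 2), 1)
    }
  } else if (ctx$type == "euclid") {
    for (j in seq_len(c_)) {
      D[, j] <- sqrt(rowSums(sweep(ctx$F, 2L, cents[[j]]$f)^2))
    }
  } else {
    lF <- log2(ctx$F)
    for (j in seq_len(c_)) {
      fc <- cents[[j]]$f
      lc <- log2(fc)
      kl_xc <- rowSums(ctx$F * sweep(lF, 2L, lc))
      if (ctx$type == "kl") {
        D[, j] <- kl_xc
      } else {
        kl_cx <- colSums(fc * (lc - t(lF)))
        D[, j] <- (kl_xc + kl_cx) / 2
      }
    }
  }
  D
}

run_kmeans_once <- function(ctx, centers, rseed, max_iter, max_no_improve) {
  n <- nrow(ctx$V)
  init <- withr::with_seed(rseed, sample.int(n, centers))
  cents <- lapply(init, function(i) centroid_state(ctx, i))
  best <- list(distortion = Inf, assignment = NULL, iter = 0L)
  prev <- NULL
  no_improve <- 0L
  iters <- 0L
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    iters <- iter
    D <- centroid_dist(ctx, cents)
    assignment <- assign_nearest(D)
    own <- D[cbind(seq_len(n), assignment)]
    empty <- setdiff(seq_len(centers), unique(assignment))
    if (length(empty)) {
      # reseed each empty cluster with the read farthest from its centroid
      ord <- order(own, decreasing = TRUE)
      taken <- integer(0)
      for (j in empty) {
        rf <- setdiff(ord, taken)[1L]
        assignment[rf] <- j
        own[rf] <- 0
        taken <- c(taken, rf)
      }
    }
    distortion <- sum(own)
    trace <- c(trace, distortion)
    if (distortion < best$distortion) {
      best <- list(distortion = distortion, assignment = assignment,
                   iter = iter)
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    if (!is.null(prev) && all(assignment == prev)) break
    if (no_improve >= max_no_improve) break
    prev <- assignment
    cents <- update_centroids(ctx, assignment, centers)
  }
  best$iterations <- iters
  best$trace <- trace
  best
}

#' Cluster sequencing reads by k-mer profile
#'
#' Centroid-based (k-means) clustering of reads under any of the supported
#' alignment-free measures, with multiple random restarts and a
#' no-improvement stopping rule. Centroids are arithmetic means of the
#' member vectors (quality-weighted vectors for quality measures,
#' frequency-normalised vectors for `l2`/`kl`/`symkl`); for the centred
#' measures the centroid is treated as a pseudo-profile whose expected
#' count term uses the mean of its members' window counts and base
#' frequencies. The expected word probability is estimated once on the
#' whole dataset before clustering.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `qualities`.
#' @param k Word length.
#' @param centers Number of clusters `c` (>= 1, <= number of reads).
#' @param measure Measure name (see [measure_spec()]); default `"d2star_q"`.
#' @param estimator `"awp"` or `"aqp"` for the centred quality measures,
#'   `"none"` otherwise. Defaults to `"aqp"` when required and omitted.
#' @param redistribute Apply quality redistribution to the quality-weighted
#'   vectors.
#' @param runs Number of random restarts; the lowest-distortion solution is
#'   returned (default 5).
#' @param seed Integer seed; run `r` uses `seed + r`. `NULL` draws a seed
#'   from the session RNG and records it in the result.
#' @param max_iter Maximum iterations per run (default 100).
#' @param max_no_improve Stop a run after this many iterations without
#'   improving its best distortion (default 10).
#' @param revcomp Pool reverse-complement words (default `FALSE`).
#' @param freqs Base-frequency scope for background probabilities and
#'   redistribution: `"read"` (default) or `"dataset"`.
#' @param pseudocount KL pseudocount (default `1 / 4^k`).
#' @return An object of class `read_clustering`; see
#'   [tidy.read_clustering()] and [glance.read_clustering()].
#' @examples
#' sim <- simulate_reads(simulate_references(2, c(500, 600), seed = 1),
#'                       reads_per_ref = 30, read_length = 80, seed = 1)
#' cl <- cluster_reads(sim$reads, k = 2, centers = 2, measure = "d2",
#'                     seed = 1)
#' glance(cl)
#' @export
cluster_reads <- function(reads, k, centers, measure = "d2star_q",
                          estimator = NULL, redistribute = FALSE,
                          runs = 5L, seed = NULL, max_iter = 100L,
                          max_no_improve = 10L, revcomp = FALSE,
                          freqs = c("read", "dataset"),
                          pseudocount = NULL) {
  check_reads(reads)
  freqs <- match.arg(freqs)
  if (centers < 1L) stop("`centers` must be >= 1")
  if (centers > nrow(reads)) {
    stop("`centers` (", centers, ") exceeds the number of reads (",
         nrow(reads), ")")
  }
  name <- gsub("-", "_", tolower(measure))
  if (is.null(estimator)) {
    estimator <- if (name %in% c("d2star_q", "d2s_q")) "aqp" else "none"
  }
  spec <- measure_spec(name, estimator, redistribute, pseudocount)

  reads <- dplyr::arrange(reads, .data$read_id)
  profiles <- kmer_profiles(reads, k, redistribute = spec$redistribute,
                            revcomp = revcomp, freqs = freqs)
  expectation <- resolve_expectation(spec, profiles, reads)
  ctx <- measure_context(profiles, spec, expectation)

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - runs, 1L)
  runres <- lapply(seq_len(runs), function(r) {
    run_kmeans_once(ctx, centers, seed + r, max_iter, max_no_improve)
  })
  dists <- vapply(runres, `[[`, 0, "distortion")
  best_run <- which.min(dists)
  best <- runres[[best_run]]
  cents <- update_centroids(ctx, best$assignment, centers)
  cent_mat <- if (ctx$type %in% c("cosine", "d2s")) {
    do.call(rbind, lapply(cents, `[[`, "v"))
  } else {
    do.call(rbind, lapply(cents, `[[`, "f"))
  }
  rownames(cent_mat) <- paste0("cluster", seq_len(centers))

  structure(
    list(read_ids = profiles$read_ids,
         cluster = best$assignment,
         centroids = cent_mat,
         distortion = best$distortion,
         iterations = best$iterations,
         best_run = best_run,
         run_distortions = dists,
         trace = best$trace,
         features = ctx$V,
         k = k, centers = centers, measure = name,
         estimator = spec$estimator, redistribute = spec$redistribute,
         runs = runs, seed = seed),
    class = "read_clustering"
  )
}

#' @export
print.read_clustering <- function(x, ...) {
  cat("<read_clustering> ", length(x$read_ids), " reads into ", x$centers,
      " clusters\n  measure: ", x$measure,
      if (x$estimator != "none") paste0(" (", toupper(x$estimator), ")"),
      if (x$redistribute) " + quality redistribution",
      "\n  distortion ", signif(x$distortion, 6), " (best of ", x$runs,
      " runs, run ", x$best_run, ", ", x$iterations, " iterations)\n",
      sep = "")
  invisible(x)
}

#' Tidy a read clustering into per-read assignments
#'
#' @param x A [cluster_reads()] result.
#' @param ... Unused.
#' @return Tibble with columns `read_id` and `cluster` (1-based index).
#' @export
tidy.read_clustering <- function(x, ...) {
  tibble::tibble(read_id = x$read_ids, cluster = as.integer(x$cluster))
}

#' One-row summary of a read clustering
#'
#' @param x A [cluster_reads()] result.
#' @param ... Unused.
#' @return Tibble with the run configuration, final distortion, iteration
#'   count and the index of the best restart.
#' @export
glance.read_clustering <- function(x, ...) {
  tibble::tibble(
    n_reads = length(x$read_ids), k = x$k, centers = x$centers,
    measure = x$measure, estimator = x$estimator,
    redistribute = x$redistribute, distortion = x$distortion,
    iterations = x$iterations, best_run = x$best_run, runs = x$runs,
    seed = x$seed
  )
}

#' Plot a read clustering in profile space
#'
#' Projects the per-read feature vectors onto their first two principal
#' components and colours reads by assigned cluster.
#'
#' @param object A [cluster_reads()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.read_clustering <- function(object, ...) {
  keep <- apply(object$features, 2L, stats::var) > 0
  pc <- stats::prcomp(object$features[, keep, drop = FALSE], scale. = FALSE)
  df <- tibble::tibble(
    PC1 = pc$x[, 1L],
    PC2 = if (ncol(pc$x) > 1L) pc$x[, 2L] else 0,
    cluster = factor(object$cluster)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      title = paste0("Read clustering (", object$measure,
                     if (object$estimator != "none")
                       paste0(", ", toupper(object$estimator)), ")"),
      colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Write cluster assignments as TSV
#'
#' @param clustering A [cluster_reads()] result (or a tibble with columns
#'   `read_id`, `cluster`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(clustering, path) {
  df <- if (inherits(clustering, "read_clustering")) {
    tidy.read_clustering(clustering)
  } else {
    clustering
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' Split reads into per-cluster FASTQ files
#'
#' @param reads Reads tibble covering every clustered read.
#' @param clustering A [cluster_reads()] result.
#' @param prefix Output prefix; cluster `j` goes to
#'   `<prefix>.cluster<j>.fastq`.
#' @param offset Phred offset for encoding.
#' @return Character vector of written paths, invisibly.
#' @export
write_cluster_fastq <- function(reads, clustering, prefix, offset = 33L) {
  asg <- tidy.read_clustering(clustering)
  paths <- character(0)
  for (j in sort(unique(asg$cluster))) {
    ids <- asg$read_id[asg$cluster == j]
    sub <- dplyr::filter(reads, .data$read_id %in% ids)
    p <- paste0(prefix, ".cluster", j, ".fastq")
    write_fastq(sub, p, offset)
    paths <- c(paths, p)
  }
  invisible(paths)
}
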