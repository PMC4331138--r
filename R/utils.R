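# Shared low-level helpers: 2-bit base encoding, word indexing, seed scoping.

DNA_BASES <- c("A", "C", "G", "T")

# lookup table mapping ASCII codes of A/C/G/T (either case) to 0..3, NA elsewhere
.base_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut
})

#' Enumerate all k-mers in lexicographic order
#'
#' Words over \{A, C, G, T\} of length `k`, ordered lexicographically with
#' A < C < G < T. This is the coordinate system of every count vector in the
#' package: word `w` sits at index `1 + sum_j code(w[j]) * 4^(k-1-j)` with
#' `code(A)=0, ..., code(T)=3`.
#'
#' @param k Word length (positive integer).
#' @return Character vector of length `4^k`.
#' @examples
#' all_kmers(1)
#' head(all_kmers(2))
#' @export
all_kmers <- function(k) {
  stopifnot(length(k) == 1L, k >= 1L)
  g <- do.call(expand.grid, c(rep(list(DNA_BASES), k),
                              list(stringsAsFactors = FALSE)))
  # expand.grid cycles the first column fastest; use it as the last character
  do.call(paste0, rev(unname(as.list(g))))
}

# encode a sequence string as integer codes 0..3 (NA for non-ACGT)
encode_bases <- function(sequence) {
  codes <- utf8ToInt(sequence)
  if (any(codes > 127L)) return(rep(NA_integer_, length(codes)))
  .base_lut[codes]
}

# indices (1-based, into the 4^k coordinate system) of all length-k windows
# of the encoded read; NA where the window overlaps a non-ACGT base.
# Returns integer(0) when k > length(bi).
window_indices <- function(bi, k) {
  n <- length(bi)
  if (k > n) return(integer(0))
  m <- n - k + 1L
  pow <- 4L^((k - 1L):0L)
  idx <- rep(1, m)
  for (j in seq_len(k)) {
    idx <- idx + as.numeric(bi[j:(m + j - 1L)]) * pow[j]
  }
  as.integer(idx)
}

# per-window matrix of encoded bases: m x k (row = window)
window_base_matrix <- function(bi, k) {
  n <- length(bi)
  m <- n - k + 1L
  out <- vapply(seq_len(k), function(j) bi[j:(m + j - 1L)], integer(m))
  if (m == 1L) out <- matrix(out, nrow = 1L)
  out
}

# base frequencies of an encoded read; pseudocount 0.5 per base applied
# (before normalisation) when any base is absent and `pseudo` is TRUE
base_frequencies <- function(bi, pseudo = FALSE) {
  tab <- tabulate(bi + 1L, nbins = 4L)
  if (pseudo && any(tab == 0L)) tab <- tab + 0.5
  tot <- sum(tab)
  if (tot == 0) return(rep(0.25, 4L))
  out <- tab / tot
  names(out) <- DNA_BASES
  out
}

# validate a reads tibble (columns read_id, sequence, qualities)
check_reads <- function(reads, arg = "reads") {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "sequence", "qualities") %in% names(reads))) {
    stop("`", arg, "` must be a data frame with columns ",
         "`read_id`, `sequence`, `qualities`", call. = FALSE)
  }
  if (nrow(reads) == 0L) stop("`", arg, "` contains no reads", call. = FALSE)
  bad <- which(nchar(reads$sequence) != lengths(reads$qualities))
  if (length(bad)) {
    stop("read ", bad[1L], " (", reads$read_id[bad[1L]],
         "): sequence and quality lengths differ", call. = FALSE)
  }
  invisible(reads)
}
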