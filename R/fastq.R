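# FASTQ input/output and phred score semantics.

#' Read a FASTQ file into a tibble of reads
#'
#' Parses 4-line-per-record FASTQ (plain or gzipped) and decodes the quality
#' string into integer phred scores. Sequences are uppercased; bases outside
#' \{A,C,G,T\} (e.g. N) are retained and dealt with at k-mer counting time.
#'
#' @param path Path to a FASTQ file; `.gz` files are read transparently.
#' @param offset Phred encoding offset, 33 (Sanger/Illumina 1.8+, default)
#'   or 64 (old Illumina).
#' @return A tibble with columns `read_id` (character), `sequence`
#'   (character) and `qualities` (list of integer vectors, one score per
#'   base). Decoded scores are capped at 93.
#' @details A decoded score below 0 aborts with an error (almost always a
#'   wrong `offset`); more than 10\% of bases above 60 under offset 33
#'   triggers a warning for the same reason.
#' @seealso [write_fastq()], [phred_correct_prob()]
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!offset %in% c(33L, 64L)) stop("`offset` must be 33 or 64")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  # tolerate trailing blank lines
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ (", length(lines),
         " lines is not a multiple of 4): ", path)
  }
  n <- length(lines) %/% 4L
  hdr  <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("record ", bad[1L], ": header line does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("record ", bad[1L], ": separator line does not start with '+'")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("record ", bad[1L],
         ": sequence and quality strings have different lengths")
  }

  qualities <- lapply(qual, function(s) utf8ToInt(s) - as.integer(offset))
  mins <- vapply(qualities, function(q) if (length(q)) min(q) else 0L, 0L)
  bad <- which(mins < 0L)
  if (length(bad)) {
    stop("record ", bad[1L], ": negative phred score after decoding; ",
         "is `offset = ", offset, "` correct for this file?")
  }
  if (offset == 33L) {
    allq <- unlist(qualities, use.names = FALSE)
    if (length(allq) && mean(allq > 60L) > 0.1) {
      warning("more than 10% of bases have phred > 60 under offset 33; ",
              "the file may be phred+64 encoded")
    }
  }
  qualities <- lapply(qualities, function(q) pmin(q, 93L))

  tibble::tibble(
    read_id   = sub("^@", "", hdr),
    sequence  = toupper(seqs),
    qualities = qualities
  )
}

#' Write a tibble of reads to a FASTQ file
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `qualities`
#'   (as returned by [read_fastq()] or [simulate_reads()]).
#' @param path Output path; a `.gz` suffix produces a gzipped file.
#' @param offset Phred encoding offset (33 or 64).
#' @return `path`, invisibly.
#' @details Scores are clamped to \[0, 93\] before encoding so that every
#'   emitted character is printable ASCII (infinite or out-of-range scores
#'   used in internal computations are representable on disk only up to 93).
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  check_reads(reads)
  qs <- vapply(reads$qualities, function(q) {
    q <- pmin(pmax(round(q), 0L), 93L)
    if (length(q) == 0L) "" else intToUtf8(q + as.integer(offset))
  }, "")
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", qs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Phred score to error / correctness probability
#'
#' A phred score `q` encodes the probability `10^(-q/10)` that the base call
#' is wrong; `q = 30` means a 1-in-1000 chance of error.
#'
#' @param q Numeric vector of phred scores (>= 0; `Inf` allowed and maps to
#'   error probability 0).
#' @return `phred_error_prob()`: the error probability `10^(-q/10)`.
#'   `phred_correct_prob()`: the complementary probability that the call is
#'   correct, strictly increasing in `q` and in `[0, 1]`.
#' @examples
#' phred_error_prob(30)    # 0.001
#' phred_correct_prob(10)  # 0.9
#' @export
phred_error_prob <- function(q) {
  if (any(q < 0, na.rm = TRUE)) stop("phred scores must be >= 0")
  10^(-q / 10)
}

#' @rdname phred_error_prob
#' @export
phred_correct_prob <- function(q) {
  1 - phred_error_prob(q)
}

#' Probability that a word occurrence is correct
#'
#' The probability that the k-mer starting at position `start` of a read is
#' read without error: the product over its bases of `1 - 10^(-q/10)`.
#'
#' @param qualities Numeric vector of per-base phred scores for the read.
#' @param start 1-based start position of the window.
#' @param k Window length.
#' @return Probability in `[0, 1]`.
#' @examples
#' word_correct_prob(c(30, 30), 1, 2)  # 0.999^2
#' @export
word_correct_prob <- function(qualities, start, k) {
  n <- length(qualities)
  if (start < 1L || k < 1L || start + k - 1L > n) {
    stop("window [", start, ", ", start + k - 1L,
         "] out of range for a read of length ", n)
  }
  prod(phred_correct_prob(qualities[start:(start + k - 1L)]))
}
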