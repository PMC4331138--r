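# Recall-rate evaluation of a clustering against known read origins.

#' Per-source recall of a clustering
#'
#' For each source sequence `S`, the cluster `C` holding the plurality of
#' `S`'s reads is located (ties broken toward the lowest cluster index) and
#' the recall of `S` is the fraction of its reads that fall in `C`.
#'
#' @param assignments Tibble with columns `read_id`, `cluster` (e.g.
#'   `tidy()` of a [cluster_reads()] result, or the result itself).
#' @param truth Tibble with columns `read_id`, `source` mapping every read
#'   to its source sequence.
#' @return Tibble with one row per source: `source`, `cluster` (the
#'   plurality cluster), `n_reads`, `recall`.
#' @export
recall_by_source <- function(assignments, truth) {
  if (inherits(assignments, "read_clustering")) {
    assignments <- tidy.read_clustering(assignments)
  }
  if (!all(c("read_id", "cluster") %in% names(assignments))) {
    stop("`assignments` needs columns `read_id` and `cluster`")
  }
  if (!all(c("read_id", "source") %in% names(truth))) {
    stop("`truth` needs columns `read_id` and `source`")
  }
  if (anyDuplicated(truth$read_id)) {
    stop("`truth` lists some read_id more than once")
  }
  if (!setequal(assignments$read_id, truth$read_id)) {
    stop("`assignments` and `truth` do not cover the same read ids")
  }
  dplyr::inner_join(assignments, truth, by = "read_id") |>
    dplyr::count(.data$source, .data$cluster, name = "in_cluster") |>
    dplyr::group_by(.data$source) |>
    dplyr::arrange(dplyr::desc(.data$in_cluster), .data$cluster,
                   .by_group = TRUE) |>
    dplyr::summarise(
      cluster = dplyr::first(.data$cluster),
      n_reads = sum(.data$in_cluster),
      recall = dplyr::first(.data$in_cluster) / sum(.data$in_cluster)
    ) |>
    dplyr::ungroup()
}

#' Mean recall rate of a clustering
#'
#' The unweighted mean of the per-source recalls of [recall_by_source()]:
#' sources count equally regardless of how many reads they contributed.
#'
#' @inheritParams recall_by_source
#' @return A number in `[0, 1]`.
#' @examples
#' asg <- tibble::tibble(read_id = c("a", "b", "c", "d"),
#'                       cluster = c(1L, 1L, 2L, 2L))
#' tru <- tibble::tibble(read_id = c("a", "b", "c", "d"),
#'                       source = c("s1", "s1", "s2", "s2"))
#' recall_rate(asg, tru)  # 1
#' @export
recall_rate <- function(assignments, truth) {
  mean(recall_by_source(assignments, truth)$recall)
}

#' Read / write a truth table as 2-column TSV
#'
#' @param path Path of a tab-separated file with columns `read_id`,
#'   `source` (written with a header line).
#' @return `read_truth_tsv()`: a tibble; `write_truth_tsv()`: `path`,
#'   invisibly.
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(), source = readr::col_character()
  ))
}

#' @rdname read_truth_tsv
#' @param truth Tibble with columns `read_id`, `source`.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth[, c("read_id", "source")], path)
  invisible(path)
}
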