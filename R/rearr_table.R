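# Per-sample rearrangement counting and dominant-clone summaries.

#' Count unique VDJ rearrangements in an annotated sample
#'
#' Tallies how many times each (V, D, J) combination was observed among the
#' annotated reads and derives the per-sample clonality summary: number of
#' unique rearrangements and unique rearrangements per 10^3 mapped reads.
#'
#' @param annotations A `sample_annotation` from [annotate_sample()], or a
#'   data.frame with columns `v_id`, `d_id`, `j_id` (one row per annotated
#'   read).
#' @param sample_id Sample label carried into the table.
#' @return A `rearrangement_table`: list with `sample_id`, `counts`
#'   (data.frame `v_id`, `d_id`, `j_id`, `count`, sorted by decreasing count),
#'   `total_mapped`, `n_unique` and `unique_per_1e3`.
#' @export
count_rearrangements <- function(annotations, sample_id = "sample") {
  df <- if (inherits(annotations, "sample_annotation")) annotations$reads
        else annotations
  if (is.null(df) || nrow(df) == 0L) {
    return(structure(list(
      sample_id = sample_id,
      counts = data.frame(v_id = character(0), d_id = character(0),
                          j_id = character(0), count = integer(0),
                          stringsAsFactors = FALSE),
      total_mapped = 0L, n_unique = 0L, unique_per_1e3 = 0),
      class = "rearrangement_table"))
  }
  key <- paste(df$v_id, df$d_id, df$j_id, sep = "\t")
  tab <- sort(table(key), decreasing = TRUE)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  counts <- data.frame(
    v_id = vapply(parts, `[`, "", 1L),
    d_id = vapply(parts, `[`, "", 2L),
    j_id = vapply(parts, `[`, "", 3L),
    count = as.integer(tab),
    stringsAsFactors = FALSE)
  # deterministic order: count desc, then key asc
  counts <- counts[order(-counts$count, counts$v_id, counts$d_id,
                         counts$j_id), , drop = FALSE]
  rownames(counts) <- NULL
  total <- nrow(df)
  structure(list(sample_id = sample_id, counts = counts,
                 total_mapped = total, n_unique = nrow(counts),
                 unique_per_1e3 = 1000 * nrow(counts) / total),
            class = "rearrangement_table")
}

#' @export
print.rearrangement_table <- function(x, ...) {
  cat(sprintf(
    "rearrangement_table '%s': %d mapped, %d unique (%.2f per 10^3)\n",
    x$sample_id, x$total_mapped, x$n_unique, x$unique_per_1e3))
  invisible(x)
}

#' Dominant rearrangements of a sample
#'
#' Reports the most abundant (V, D, J) combination, and the runner-up when it
#' holds at least `floor_pct` percent of mapped reads -- the "one or two
#' dominant rearrangements" representing the productive and nonproductive
#' alleles of the malignant clone.
#'
#' @param table A non-empty `rearrangement_table`.
#' @param max_n Maximum number of dominants reported.
#' @param floor_pct Dominance floor (percent) applied to ranks beyond the
#'   first.
#' @return data.frame with `v_id`, `d_id`, `j_id`, `count`, `percentage` and
#'   a space-joined `label` (e.g. `"IGHV4-34 IGHD3-22 IGHJ5"`).
#' @export
dominant_rearrangements <- function(table, max_n = 2L, floor_pct = 10) {
  if (table$total_mapped == 0L || nrow(table$counts) == 0L)
    stop("cannot summarise dominants of an empty rearrangement table",
         call. = FALSE)
  top <- utils::head(table$counts, max_n)
  top$percentage <- 100 * top$count / table$total_mapped
  keep <- c(TRUE, top$percentage[-1L] >= floor_pct)
  top <- top[keep, , drop = FALSE]
  top$label <- paste(top$v_id, top$d_id, top$j_id)
  rownames(top) <- NULL
  top
}

#' Write / read a rearrangement table as TSV
#'
#' The TSV holds one row per unique rearrangement (`v_id`, `d_id`, `j_id`,
#' `count`); the serialisation round-trips losslessly.
#'
#' @param table A `rearrangement_table`.
#' @param path Output path.
#' @return `path` invisibly, or the re-read `rearrangement_table`.
#' @export
write_rearrangement_tsv <- function(table, path) {
  utils::write.table(table$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_rearrangement_tsv
#' @param sample_id Sample label for the re-read table.
#' @export
read_rearrangement_tsv <- function(path, sample_id = "sample") {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = c("character", "character",
                                             "character", "integer"))
  df <- counts[rep(seq_len(nrow(counts)), counts$count),
               c("v_id", "d_id", "j_id"), drop = FALSE]
  count_rearrangements(df, sample_id)
}
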