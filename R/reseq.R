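# Ultra-deep targeted amplicon resequencing: allele frequencies, per-class
# background-error models, minor-clone detection and the detection limit.

#' Simulate an ultra-deep amplicon pileup
#'
#' One amplicon of `n_positions` sites sequenced to `depth` reads. Every
#' non-reference substitution arises at `error_rate` per class; small indel
#' noise at `indel_rate`. A minor clone carrying the target variant can be
#' planted at `clone_freq` on top of the background at `target_pos`.
#'
#' @param n_positions Amplicon length (sites).
#' @param depth Total reads per position.
#' @param error_rate Per-class background conversion probability.
#' @param indel_rate Background deletion/insertion probability.
#' @param target_pos Position carrying the planted variant (reference base
#'   forced to `"C"`, variant `"A"`).
#' @param clone_freq Planted minor-clone frequency (0 = no clone).
#' @param seed Integer seed.
#' @return An `amplicon_pileup` data.frame: `amplicon`, `pos`, `A`, `C`,
#'   `G`, `T`, `del`, `ins`, `total`.
#' @export
simulate_amplicon_pileup <- function(n_positions = 30L, depth = 2e6,
                                     error_rate = 3e-4, indel_rate = 4e-5,
                                     target_pos = 15L, clone_freq = 0,
                                     seed = 1L) {
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_positions, replace = TRUE)
    if (!is.null(target_pos)) ref[target_pos] <- "C"
    rows <- lapply(seq_len(n_positions), function(p) {
      counts <- stats::setNames(integer(6), c(bases, "del", "ins"))
      for (b in setdiff(bases, ref[p]))
        counts[b] <- stats::rbinom(1L, depth, error_rate)
      counts["del"] <- stats::rbinom(1L, depth, indel_rate)
      counts["ins"] <- stats::rbinom(1L, depth, indel_rate)
      if (!is.null(target_pos) && p == target_pos && clone_freq > 0)
        counts["A"] <- counts["A"] + stats::rbinom(1L, depth, clone_freq)
      counts[ref[p]] <- depth - sum(counts)
      data.frame(amplicon = "amp1", pos = p, t(counts), total = depth,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("amplicon_pileup", "data.frame"), ref = ref)
  })
}

# Reference allele of each pileup row, inferred as the majority base call.
pileup_reference <- function(pileup) {
  bases <- c("A", "C", "G", "T")
  m <- as.matrix(pileup[, bases])
  bases[max.col(m, ties.method = "first")]
}

#' Allele frequency at a pileup position
#'
#' @param pileup An `amplicon_pileup` data.frame.
#' @param pos Target position.
#' @param allele One of `"A"`, `"C"`, `"G"`, `"T"`, `"del"`, `"ins"`.
#' @return `count(allele) / total` at the position.
#' @export
allele_frequency <- function(pileup, pos, allele) {
  row <- pileup[pileup$pos == pos, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("position %s not found in pileup", pos), call. = FALSE)
  if (row$total == 0)
    stop("allele frequency undefined at zero total reads", call. = FALSE)
  if (!allele %in% c("A", "C", "G", "T", "del", "ins"))
    stop(sprintf("unknown allele '%s'", allele), call. = FALSE)
  row[[allele]] / row$total
}

#' Background error model for a substitution or indel class
#'
#' Mean and sample standard deviation of the per-position error frequency of
#' one conversion class (e.g. `"C>A"`, or `"del"`/`"ins"`), estimated from
#' the non-target positions of the same amplicon whose (majority-inferred)
#' reference base matches the class.
#'
#' @param pileup An `amplicon_pileup`.
#' @param class Conversion class `"REF>ALT"` (e.g. `"C>A"`) or `"del"` /
#'   `"ins"`.
#' @param exclude_pos Positions excluded as targets.
#' @return A `background_model`: list with `class`, `mean`, `sd` and
#'   `n_positions`.
#' @export
estimate_background <- function(pileup, class, exclude_pos = integer(0)) {
  if (class %in% c("del", "ins")) {
    rows <- pileup[!pileup$pos %in% exclude_pos, , drop = FALSE]
    freq <- rows[[class]] / rows$total
  } else {
    parts <- strsplit(class, ">", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("`class` must be 'REF>ALT', 'del' or 'ins'", call. = FALSE)
    ref <- pileup_reference(pileup)
    sel <- ref == parts[1] & !pileup$pos %in% exclude_pos
    rows <- pileup[sel, , drop = FALSE]
    if (nrow(rows) < 2L)
      stop(sprintf("fewer than 2 control positions for class %s", class),
           call. = FALSE)
    freq <- rows[[parts[2]]] / rows$total
  }
  if (length(freq) < 2L)
    stop("fewer than 2 control positions", call. = FALSE)
  structure(list(class = class, mean = mean(freq), sd = stats::sd(freq),
                 n_positions = length(freq)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model %s: %.4f%% +/- %.4f%% (%d positions)\n",
              x$class, 100 * x$mean, 100 * x$sd, x$n_positions))
  invisible(x)
}

#' Detect a minor clone against the background error model
#'
#' A variant frequency is called a real minor clone iff it exceeds the
#' background mean by more than `k` background standard deviations AND is
#' supported by at least `min_support` reads. When the background s.d. is 0,
#' any frequency above the mean (with sufficient support) is detected.
#'
#' @param freq Observed variant allele frequency (fraction).
#' @param support Reads supporting the variant.
#' @param bg A `background_model`.
#' @param k Standard-deviation multiplier (default 3).
#' @param min_support Minimum supporting reads (default 20).
#' @return A `detection_result`: list with `detected`, `frequency`,
#'   `support`, `z` and the background parameters.
#' @export
detect_minor_clone <- function(freq, support, bg, k = 3, min_support = 20L) {
  if (freq < 0 || support < 0 || bg$mean < 0 || bg$sd < 0)
    stop("frequencies, support and background moments must be non-negative",
         call. = FALSE)
  z <- if (bg$sd > 0) (freq - bg$mean) / bg$sd
       else if (freq > bg$mean) Inf else 0
  detected <- (freq > bg$mean + k * bg$sd) && support >= min_support
  structure(list(detected = detected, frequency = freq, support = support,
                 background_mean = bg$mean, background_sd = bg$sd,
                 z = z, k = k, min_support = min_support),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "detection_result: %s (%.4f%% vs background %.4f%% +/- %.4f%%, z=%.1f, %d reads)\n",
    if (x$detected) "DETECTED" else "not detected",
    100 * x$frequency, 100 * x$background_mean, 100 * x$background_sd,
    x$z, x$support))
  invisible(x)
}

#' Minimal detectable minor-allele frequency
#'
#' The smallest frequency observable with `min_support` supporting reads at
#' the given total read count, expressed as a percentage (e.g. 20 reads in
#' two million is 0.001%).
#'
#' @param total_reads Total reads over the amplicon position (> 0).
#' @param min_support Required supporting reads.
#' @return Detection limit in percent.
#' @export
detection_limit <- function(total_reads, min_support = 20L) {
  if (total_reads <= 0) stop("`total_reads` must be positive", call. = FALSE)
  if (min_support < 0) stop("`min_support` must be >= 0", call. = FALSE)
  100 * min_support / total_reads
}

#' Write / read an amplicon pileup as TSV
#'
#' @param pileup An `amplicon_pileup`.
#' @param path Output path.
#' @return `path` invisibly, or the re-read `amplicon_pileup`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("amplicon", "pos", "A", "C", "G", "T", "del", "ins", "total")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: pileup TSV must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  bad <- which(rowSums(df[, c("A", "C", "G", "T", "del", "ins")]) != df$total)
  if (length(bad))
    stop(sprintf("%s: allele counts do not sum to total at row %d", path,
                 bad[1]), call. = FALSE)
  structure(df, class = c("amplicon_pileup", "data.frame"))
}
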