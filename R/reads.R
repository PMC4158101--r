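# Paired-end read simulation and FASTQ handling.

#' Simulate paired-end amplicon reads from a clone population
#'
#' Each read pair is drawn from a clone with probability proportional to its
#' abundance. Mate 1 is the 5' end of the clone template, mate 2 the
#' reverse-complemented 3' end (amplicon geometry: 2 x `read_len` on a 300-350
#' bp product). Sequencing noise is i.i.d. per-base substitution at
#' `error_rate`; base qualities are fixed.
#'
#' @param pop A `clone_population`.
#' @param n_pairs Number of read pairs (> 0).
#' @param read_len Mate length; must not exceed the shortest clone template.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; identical seeds give identical reads.
#' @param qual_char Fixed Phred+33 quality character.
#' @return A `read_pairs` object: list with `id`, `mate1`, `mate2` (character
#'   vectors) and the fixed quality string.
#' @export
simulate_reads <- function(pop, n_pairs, read_len = 150L, error_rate = 0.002,
                           seed = 1L, qual_char = "I") {
  if (n_pairs <= 0) stop("`n_pairs` must be positive", call. = FALSE)
  assert_fraction(error_rate, "error_rate")
  tlen <- nchar(pop$sequence)
  if (any(read_len > tlen))
    stop(sprintf("`read_len` (%d) exceeds shortest clone template (%d nt)",
                 read_len, min(tlen)), call. = FALSE)
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n_pairs, pop$abundance))
    m1 <- substr(pop$sequence, 1L, read_len)
    m2 <- revcomp(substr(pop$sequence, tlen - read_len + 1L, tlen))
    mate1 <- rep(m1, counts)
    mate2 <- rep(m2, counts)
    source_id <- rep(pop$id, counts)

    inject_errors <- function(reads) {
      n_err <- stats::rbinom(length(reads), read_len, error_rate)
      idx <- which(n_err > 0L)
      for (i in idx) {
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        at <- sample.int(read_len, n_err[i])
        ch[at] <- other_base(ch[at])
        reads[i] <- paste(ch, collapse = "")
      }
      reads
    }
    mate1 <- inject_errors(mate1)
    mate2 <- inject_errors(mate2)

    ord <- sample.int(length(mate1))
    structure(
      list(id = sprintf("read%06d", seq_along(ord)),
           mate1 = mate1[ord], mate2 = mate2[ord],
           source = source_id[ord],
           qual = strrep(qual_char, read_len)),
      class = "read_pairs")
  })
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pairs, 2 x %d nt\n",
              length(x$id), nchar(x$mate1[1])))
  invisible(x)
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' Subsample read pairs
#'
#' Keeps each read pair independently with probability `rate` (Bernoulli
#' thinning), as used to assess the robustness of clonality estimates to
#' sequencing depth.
#'
#' @param reads A `read_pairs` object.
#' @param rate Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return A `read_pairs` object with the retained pairs.
#' @export
subsample_reads <- function(reads, rate, seed = 1L) {
  assert_fraction(rate, "rate", open_zero = TRUE)
  with_seed(seed, {
    keep <- stats::runif(length(reads$id)) < rate
    structure(list(id = reads$id[keep], mate1 = reads$mate1[keep],
                   mate2 = reads$mate2[keep],
                   source = reads$source[keep], qual = reads$qual),
              class = "read_pairs")
  })
}

#' Write read pairs as paired FASTQ files
#'
#' @param reads A `read_pairs` object.
#' @param r1_path,r2_path Output paths for mate 1 / mate 2 (Phred+33).
#' @return The two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_one <- function(seqs, ids, qual, path) {
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- ids
    q <- Biostrings::BStringSet(rep(qual, length(seqs)))
    Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = q)
  }
  write_one(reads$mate1, paste0(reads$id, "/1"), reads$qual, r1_path)
  write_one(reads$mate2, paste0(reads$id, "/2"), reads$qual, r2_path)
  invisible(c(r1_path, r2_path))
}

validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("%s: truncated FASTQ record starting at line %d",
                 path, (n %/% 4L) * 4L + 1L), call. = FALSE)
  heads <- seq.int(1L, n, by = 4L)
  bad <- heads[!startsWith(lines[heads], "@")]
  if (length(bad))
    stop(sprintf("%s: malformed FASTQ header at line %d", path, bad[1]),
         call. = FALSE)
  seps <- seq.int(3L, n, by = 4L)
  bad <- seps[!startsWith(lines[seps], "+")]
  if (length(bad))
    stop(sprintf("%s: malformed FASTQ separator at line %d", path, bad[1]),
         call. = FALSE)
  invisible(n %/% 4L)
}

#' Read paired FASTQ files
#'
#' Structural problems (truncated records, bad headers) are reported with the
#' offending file and line number.
#'
#' @param r1_path,r2_path Paths to the mate-1 / mate-2 FASTQ files.
#' @return A `read_pairs` object.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  validate_fastq(r1_path)
  validate_fastq(r2_path)
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop(sprintf("%s and %s differ in record count", r1_path, r2_path),
         call. = FALSE)
  ids <- sub("/1$", "", sub("\\s.*$", "", names(r1)))
  structure(
    list(id = ids, mate1 = unname(as.character(r1)),
         mate2 = unname(as.character(r2)),
         source = rep(NA_character_, length(r1)),
         qual = as.character(S4Vectors::mcols(r1)$qualities[1])),
    class = "read_pairs")
}
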