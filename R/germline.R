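#' Build a toy germline V/D/J segment library
#'
#' Generates a random immunoglobulin heavy-chain germline segment pool in the
#' style of the IMGT reference directory: a set of V (variable), D (diversity)
#' and J (joining) segments with class-typical lengths. The library stands in
#' for a real IGH reference database so that every downstream stage can be
#' exercised with known ground truth; user-supplied segment FASTA files are
#' accepted everywhere a library is, via [read_germline_fasta()].
#'
#' @param n_v,n_d,n_j Number of segments per class (each >= 1).
#' @param seed Integer seed; identical seeds give byte-identical libraries.
#' @param v_len,d_len,j_len Length bounds `c(min, max)` per segment class.
#'   Defaults reflect the approximate lengths of human IGHV (~200-300 nt),
#'   IGHD (~10-40 nt) and IGHJ (~40-70 nt) germline segments.
#' @return A `germline_library`: a data.frame with columns `id`, `class`
#'   (one of `"V"`, `"D"`, `"J"`) and `sequence`.
#' @examples
#' lib <- build_toy_germline(5, 3, 2, seed = 7)
#' table(lib$class)
#' @export
build_toy_germline <- function(n_v, n_d, n_j, seed = 1L,
                               v_len = c(200L, 300L),
                               d_len = c(10L, 40L),
                               j_len = c(40L, 70L)) {
  assert_count(n_v, "n_v"); assert_count(n_d, "n_d"); assert_count(n_j, "n_j")
  with_seed(seed, {
    make <- function(prefix, cls, n, bounds) {
      lens <- sample(seq.int(bounds[1], bounds[2]), n, replace = TRUE)
      data.frame(
        id = sprintf("%s%d-01", prefix, seq_len(n)),
        class = cls,
        sequence = vapply(lens, random_dna, ""),
        stringsAsFactors = FALSE
      )
    }
    lib <- rbind(make("IGHV", "V", n_v, v_len),
                 make("IGHD", "D", n_d, d_len),
                 make("IGHJ", "J", n_j, j_len))
    rownames(lib) <- NULL
    structure(lib, class = c("germline_library", "data.frame"))
  })
}

#' Write a germline library as FASTA
#'
#' @param lib A `germline_library`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(lib, path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(lib$sequence, lib$id))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a germline library from FASTA
#'
#' Segment classes are inferred from the id prefix (`IGHV`/`IGHD`/`IGHJ`,
#' case-insensitive); ids without a recognisable prefix are rejected.
#'
#' @param path FASTA path.
#' @return A `germline_library` data.frame.
#' @export
read_germline_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  cls <- rep(NA_character_, length(ids))
  cls[grepl("^IGHV", ids, ignore.case = TRUE)] <- "V"
  cls[grepl("^IGHD", ids, ignore.case = TRUE)] <- "D"
  cls[grepl("^IGHJ", ids, ignore.case = TRUE)] <- "J"
  if (anyNA(cls))
    stop(sprintf("%s: cannot infer segment class for id '%s'",
                 path, ids[which(is.na(cls))[1]]), call. = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicated segment id '%s'",
                 path, ids[duplicated(ids)][1]), call. = FALSE)
  structure(
    data.frame(id = ids, class = cls, sequence = as.character(seqs),
               stringsAsFactors = FALSE),
    class = c("germline_library", "data.frame")
  )
}

#' Simulate a VDJ rearrangement
#'
#' Draws one segment per class, trims exonuclease-style deletions from the
#' joining ends (V 3', both D ends, J 5') and inserts non-templated N bases at
#' the V-D and D-J junctions, mirroring the junctional diversity generated
#' during heavy-chain recombination.
#'
#' @param lib A `germline_library` with at least one segment per class.
#' @param trim_max Maximum bases trimmed per joining end (uniform on
#'   `0:trim_max`; D-end trims are capped so at least one D base survives).
#' @param insert_max Maximum non-templated insert length per junction
#'   (uniform on `0:insert_max`).
#' @param seed Integer seed.
#' @return A `vdj_rearrangement`: list with `v_id`, `d_id`, `j_id`, `trims`,
#'   `n1`, `n2` and the assembled `sequence`.
#' @export
simulate_rearrangement <- function(lib, trim_max = 6L, insert_max = 8L,
                                   seed = 1L) {
  if (trim_max < 0 || insert_max < 0)
    stop("`trim_max` and `insert_max` must be >= 0", call. = FALSE)
  for (cl in c("V", "D", "J"))
    if (!any(lib$class == cl))
      stop(sprintf("germline library has no class-%s segment", cl),
           call. = FALSE)
  with_seed(seed, {
    pick <- function(cl) {
      rows <- which(lib$class == cl)
      lib[rows[sample.int(length(rows), 1L)], , drop = FALSE]
    }
    v <- pick("V"); d <- pick("D"); j <- pick("J")
    lv <- nchar(v$sequence); ld <- nchar(d$sequence); lj <- nchar(j$sequence)
    tv <- sample.int(trim_max + 1L, 1L) - 1L
    td5 <- sample.int(trim_max + 1L, 1L) - 1L
    td3 <- sample.int(trim_max + 1L, 1L) - 1L
    tj <- sample.int(trim_max + 1L, 1L) - 1L
    tv <- min(tv, lv - 1L)
    tj <- min(tj, lj - 1L)
    # keep at least 10 nt of D (the shortest germline D): junction assays
    # depend on a seedable D remnant
    d_floor <- min(ld, 10L)
    td5 <- min(td5, ld - d_floor)
    td3 <- min(td3, ld - d_floor - td5)
    n1 <- if (insert_max > 0) random_dna(sample.int(insert_max + 1L, 1L) - 1L)
          else ""
    n2 <- if (insert_max > 0) random_dna(sample.int(insert_max + 1L, 1L) - 1L)
          else ""
    seq <- paste0(substr(v$sequence, 1L, lv - tv), n1,
                  substr(d$sequence, td5 + 1L, ld - td3), n2,
                  substr(j$sequence, tj + 1L, lj))
    structure(
      list(v_id = v$id, d_id = d$id, j_id = j$id,
           trims = c(v3 = tv, d5 = td5, d3 = td3, j5 = tj),
           n1 = n1, n2 = n2, sequence = seq),
      class = "vdj_rearrangement"
    )
  })
}

#' @export
print.vdj_rearrangement <- function(x, ...) {
  cat(sprintf("VDJ rearrangement %s %s %s (%d nt; n1=%d nt, n2=%d nt)\n",
              x$v_id, x$d_id, x$j_id, nchar(x$sequence),
              nchar(x$n1), nchar(x$n2)))
  invisible(x)
}
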