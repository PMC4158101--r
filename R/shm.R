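# SHM subclone profiling within the dominant rearrangement.

# Mismatch profile of a read segment against reference coordinates.
# `offset` shifts read positions into reference coordinates (1-based).
diff_profile <- function(read_chars, ref_chars, offset = 0L) {
  n <- length(read_chars)
  rr <- ref_chars[(offset + 1L):(offset + n)]
  idx <- which(read_chars != rr & read_chars != "N" & rr != "N")
  if (length(idx) == 0L) return(character(0))
  format_mutations(idx + offset, rr[idx], read_chars[idx])
}

#' Call the SHM profile of an annotated read against a reference
#'
#' Compares the read-derived sequence with the germline VDJ reference of its
#' dominant rearrangement and reports every substitution as a mutation entry
#' `pos:ref>alt` (1-based reference coordinates). Reads of identical length
#' are compared column-wise; length differences are resolved by a global
#' alignment, with gap columns excluded from the profile. For unmerged pairs
#' the two mates are compared against the reference prefix and suffix (the
#' un-sequenced middle contributes nothing).
#'
#' @param annotation A `vdj_annotation`.
#' @param reference The germline VDJ reference: a `vdj_rearrangement` (its
#'   (V, D, J) key is then checked against the annotation) or a plain
#'   nucleotide string, e.g. from [reconstruct_reference()].
#' @return Character vector of mutations, sorted by position.
#' @export
call_shm_profile <- function(annotation, reference) {
  if (inherits(reference, "vdj_rearrangement")) {
    if (!identical(c(annotation$v$segment_id, annotation$d$segment_id,
                     annotation$j$segment_id),
                   c(reference$v_id, reference$d_id, reference$j_id)))
      stop("annotation rearrangement key does not match the reference",
           call. = FALSE)
    reference <- reference$sequence
  }
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  L <- length(ref_chars)
  if (isTRUE(annotation$merged)) {
    q <- annotation$query
    if (nchar(q) == L) {
      prof <- diff_profile(strsplit(q, "", fixed = TRUE)[[1]], ref_chars)
    } else {
      aln <- Biostrings::pairwiseAlignment(q, reference, type = "global")
      mm <- Biostrings::mismatchTable(aln)
      prof <- if (nrow(mm) == 0L) character(0) else
        format_mutations(mm$SubjectStart, as.character(mm$SubjectSubstring),
                         as.character(mm$PatternSubstring))
    }
    return(sort_profile(unique(prof)))
  }
  c1 <- strsplit(annotation$mate1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(annotation$mate2rc, "", fixed = TRUE)[[1]]
  if (length(c1) > L || length(c2) > L)
    stop("mate longer than reference; inconsistent geometry", call. = FALSE)
  p1 <- diff_profile(c1, ref_chars)
  p2 <- diff_profile(c2, ref_chars, offset = L - length(c2))
  prof <- c(p1, p2)
  pos <- as.integer(sub(":.*$", "", prof))
  prof <- prof[!duplicated(pos)]  # mate 1 wins where mates overlap
  sort_profile(unique(prof))
}

# Germline projection of one annotation onto template coordinates: returns
# `germ` (germline base where a segment hit projects, NA elsewhere) and
# `read` (read base where the template is sequenced, NA elsewhere).
project_germline <- function(annotation, lib, t_len) {
  seg_chars <- function(id) strsplit(lib$sequence[lib$id == id], "",
                                     fixed = TRUE)[[1]]
  vch <- seg_chars(annotation$v$segment_id)
  dch <- seg_chars(annotation$d$segment_id)
  jch <- seg_chars(annotation$j$segment_id)
  germ <- rep(NA_character_, t_len)
  project <- function(hit, seg, q_lo, q_hi, shift = 0L) {
    q <- seq.int(q_lo, q_hi)
    r <- q - hit$diag
    ok <- r >= 1L & r <= length(seg) & (q + shift) >= 1L &
      (q + shift) <= t_len
    germ[q[ok] + shift] <<- seg[r[ok]]
    invisible(NULL)
  }
  if (isTRUE(annotation$merged)) {
    read <- strsplit(annotation$query, "", fixed = TRUE)[[1]]
    project(annotation$v, vch, max(1L, annotation$v$diag + 1L),
            annotation$v$qend)
    project(annotation$d, dch, annotation$d$qstart, annotation$d$qend)
    project(annotation$j, jch, annotation$j$qstart,
            min(t_len, annotation$j$diag + length(jch)))
  } else {
    c1 <- strsplit(annotation$mate1, "", fixed = TRUE)[[1]]
    c2 <- strsplit(annotation$mate2rc, "", fixed = TRUE)[[1]]
    read <- rep(NA_character_, t_len)
    off2 <- t_len - length(c2)
    read[(off2 + 1L):t_len] <- c2
    read[seq_along(c1)] <- c1
    project(annotation$v, vch, max(1L, annotation$v$diag + 1L),
            min(length(c1), annotation$v$diag + length(vch)))
    if (!is.null(annotation$v2))
      project(annotation$v2, vch, max(1L, annotation$v2$diag + 1L),
              annotation$v2$qend, shift = off2)
    project(annotation$d, dch, annotation$d$qstart, annotation$d$qend,
            shift = off2)
    project(annotation$j, jch, annotation$j$qstart,
            min(length(c2), annotation$j$diag + length(jch)), shift = off2)
  }
  list(germ = germ, read = read)
}

#' Reconstruct the germline VDJ reference by consensus over annotated reads
#'
#' Builds the unmutated VDJ reference of a dominant rearrangement from its
#' annotated reads: at every template position the germline segment base is
#' taken wherever any read's V/D/J hit projects onto that position (SHM at a
#' hit boundary of one subclone is bridged by reads of subclones lacking that
#' mutation), by count-weighted majority. Positions never covered by a
#' segment hit -- the non-templated junction bases, shared by all clones of
#' the rearrangement -- use the count-weighted majority read base; positions
#' sequenced by no read are `N` and are skipped during profile calling.
#'
#' @param annotations List of `vdj_annotation`s of one rearrangement (a
#'   single annotation is accepted).
#' @param lib The `germline_library` the annotations were made against.
#' @param t_len Template length (required when unmerged pairs are involved;
#'   defaults to the merged-read length).
#' @param counts Read-count weights parallel to `annotations`.
#' @return Nucleotide string of the reconstructed reference.
#' @export
reconstruct_reference <- function(annotations, lib, t_len = NULL,
                                  counts = NULL) {
  if (inherits(annotations, "vdj_annotation")) annotations <- list(annotations)
  if (is.null(counts)) counts <- rep(1, length(annotations))
  if (is.null(t_len)) {
    merged <- vapply(annotations, function(a) isTRUE(a$merged), TRUE)
    if (!any(merged))
      stop("`t_len` is required when no annotation is merged", call. = FALSE)
    t_len <- nchar(annotations[[which(merged)[1]]]$query)
  }
  lv <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  germ_tab <- matrix(0, nrow = 4L, ncol = t_len)
  read_tab <- matrix(0, nrow = 4L, ncol = t_len)
  for (i in seq_along(annotations)) {
    pr <- project_germline(annotations[[i]], lib, t_len)
    g <- lv[pr$germ]
    ok <- !is.na(g)
    idx <- cbind(g[ok], which(ok))
    germ_tab[idx] <- germ_tab[idx] + counts[i]
    r <- lv[pr$read]
    ok <- !is.na(r)
    idx <- cbind(r[ok], which(ok))
    read_tab[idx] <- read_tab[idx] + counts[i]
  }
  bases <- c("A", "C", "G", "T")
  out <- rep("N", t_len)
  # a column is germline-defined only when the projections carry a
  # non-negligible share of its coverage (stray mis-placed hits of rare
  # reads must not overrule the junction consensus)
  has_germ <- colSums(germ_tab) >= 0.05 * pmax(1e-9, colSums(read_tab))
  out[has_germ] <- bases[max.col(t(germ_tab[, has_germ, drop = FALSE]),
                                 ties.method = "first")]
  fallback <- !has_germ & colSums(read_tab) > 0
  out[fallback] <- bases[max.col(t(read_tab[, fallback, drop = FALSE]),
                                 ties.method = "first")]
  paste(out, collapse = "")
}

#' Build a filtered subclone table from SHM profiles
#'
#' Collapses identical SHM profiles, applies the subclone inclusion filters
#' (at least `min_count` supporting reads and at least `min_identity` sequence
#' similarity to the germline reference, both boundaries inclusive) and
#' renormalises frequencies over the retained subclones.
#'
#' @param profiles List of SHM profiles (character vectors of `pos:ref>alt`).
#' @param counts Integer vector of supporting read counts, parallel to
#'   `profiles`.
#' @param ref_len Length of the germline VDJ reference (identity denominator).
#' @param min_count Minimum supporting reads (default 10).
#' @param min_identity Minimum germline identity (default 0.80).
#' @param sample_id,key Metadata carried as attributes.
#' @return A `subclone_table` data.frame with columns `profile` (rendered
#'   mutation list), `n_mutations`, `count`, `frequency`, `identity` and a
#'   `mutations` list-column; rows sorted by decreasing count. An empty table
#'   (nothing passed the filters) is returned as zero rows, not an error.
#' @export
build_subclone_table <- function(profiles, counts, ref_len,
                                 min_count = 10L, min_identity = 0.80,
                                 sample_id = NULL, key = NULL) {
  if (length(profiles) != length(counts))
    stop("`profiles` and `counts` must be parallel", call. = FALSE)
  profiles <- lapply(profiles, sort_profile)
  if (length(profiles) == 0L) {
    tab <- data.frame(profile = character(0), n_mutations = integer(0),
                      count = integer(0), frequency = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
    tab$mutations <- I(list())
    return(structure(tab, class = c("subclone_table", "data.frame"),
                     sample_id = sample_id, key = key, ref_len = ref_len,
                     min_count = min_count, min_identity = min_identity))
  }
  pstr <- vapply(profiles, paste, "", collapse = ";")
  agg <- tapply(as.integer(counts), pstr, sum)
  ustr <- names(agg)
  umut <- profiles[match(ustr, pstr)]
  nmut <- lengths(umut)
  identity <- 1 - nmut / ref_len
  count <- as.integer(agg)
  keep <- count >= min_count & identity >= min_identity
  tab <- data.frame(profile = ustr[keep], n_mutations = nmut[keep],
                    count = count[keep], identity = identity[keep],
                    stringsAsFactors = FALSE)
  tab$mutations <- I(umut[keep])
  tab$frequency <- if (nrow(tab)) tab$count / sum(tab$count) else numeric(0)
  tab <- tab[order(-tab$count, tab$profile),
             c("profile", "n_mutations", "count", "frequency", "identity",
               "mutations")]
  rownames(tab) <- NULL
  structure(tab, class = c("subclone_table", "data.frame"),
            sample_id = sample_id, key = key, ref_len = ref_len,
            min_count = min_count, min_identity = min_identity)
}

#' @export
print.subclone_table <- function(x, ...) {
  cat(sprintf("subclone_table '%s' (%s): %d subclones, %d reads\n",
              attr(x, "sample_id") %||% "?",
              paste(attr(x, "key"), collapse = " "),
              nrow(x), sum(x$count)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the SHM subclone table of a sample's dominant rearrangement
#'
#' Groups the annotated reads of the dominant (or a given) rearrangement,
#' reconstructs the germline VDJ reference from the most abundant read, calls
#' per-read SHM profiles and applies the subclone filters. Reads whose
#' inferred template geometry disagrees with the sample consensus are left
#' out of the subclone analysis (they still count toward the rearrangement
#' table).
#'
#' @param ann A `sample_annotation`.
#' @param lib The `germline_library` used for annotation.
#' @param key Optional rearrangement key `c(v_id, d_id, j_id)`; defaults to
#'   the most abundant one.
#' @param min_count,min_identity Subclone filters.
#' @param sample_id Sample label.
#' @return A `subclone_table` with the reconstructed reference in
#'   `attr(, "reference")`.
#' @export
sample_subclones <- function(ann, lib, key = NULL, min_count = 10L,
                             min_identity = 0.80, sample_id = "sample") {
  df <- ann$reads
  if (nrow(df) == 0L) stop("no annotated reads", call. = FALSE)
  if (is.null(key)) {
    tab <- count_rearrangements(df, sample_id)
    key <- unlist(tab$counts[1L, c("v_id", "d_id", "j_id")], use.names = FALSE)
  }
  sel <- df$v_id == key[1] & df$d_id == key[2] & df$j_id == key[3]
  sub <- df[sel, , drop = FALSE]
  ucount <- table(sub$uidx)
  uids <- as.integer(names(ucount))
  anns <- ann$annotations[uids]
  counts <- as.integer(ucount)

  # consensus template length: merged reads report it directly, unmerged ones
  # via the V anchor on the reverse mate
  t_of <- vapply(anns, function(a)
    if (isTRUE(a$merged)) nchar(a$query) else as.integer(a$t_est %||% NA),
    0L)
  known <- !is.na(t_of)
  if (!any(known))
    stop("cannot determine the template length of the dominant rearrangement",
         call. = FALSE)
  t_consensus <- as.integer(names(which.max(tapply(counts[known],
                                                   t_of[known], sum))))
  consistent <- is.na(t_of) | t_of == t_consensus

  # consensus reference from the most abundant consistent annotations
  pool <- which(consistent)
  pool <- pool[order(-counts[pool])]
  pool <- pool[seq_len(min(500L, length(pool)))]
  reference <- reconstruct_reference(anns[pool], lib, t_len = t_consensus,
                                     counts = counts[pool])

  use <- which(consistent)
  profiles <- lapply(anns[use], call_shm_profile, reference = reference)
  tab <- build_subclone_table(profiles, counts[use], nchar(reference),
                              min_count = min_count,
                              min_identity = min_identity,
                              sample_id = sample_id, key = key)
  attr(tab, "reference") <- reference
  tab
}

#' Shannon entropy of a subclone distribution
#'
#' Empirical entropy (bits) of the subclone frequencies within the dominant
#' rearrangement; higher entropy corresponds to higher SHM diversity.
#'
#' @param table A non-empty `subclone_table`.
#' @return Entropy in bits.
#' @export
empirical_entropy <- function(table) {
  if (nrow(table) == 0L)
    stop("entropy is undefined for an empty subclone table", call. = FALSE)
  f <- table$frequency
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Mutational distance between two SHM profiles
#'
#' Size of the symmetric difference of the two mutation sets -- the number of
#' SHM events separating two subclones on a shared reference.
#'
#' @param a,b SHM profiles (character vectors of `pos:ref>alt`).
#' @return Non-negative integer count.
#' @export
mutational_distance <- function(a, b) {
  length(setdiff(a, b)) + length(setdiff(b, a))
}

major_profile <- function(table) {
  if (nrow(table) == 0L) stop("empty subclone table", call. = FALSE)
  table$mutations[[1L]]
}

#' Fate of the major diagnosis subclone at relapse
#'
#' Frequency, within the relapse subclone table, of the subclone whose SHM
#' profile exactly equals the major diagnosis subclone's profile; 0 when the
#' profile is absent at relapse.
#'
#' @param diag,relapse `subclone_table`s of the same dominant rearrangement.
#' @return Frequency in `[0, 1]`.
#' @export
major_clone_fate <- function(diag, relapse) {
  if (nrow(diag) == 0L)
    stop("empty diagnosis subclone table", call. = FALSE)
  kd <- attr(diag, "key"); kr <- attr(relapse, "key")
  if (!is.null(kd) && !is.null(kr) && !identical(kd, kr))
    stop("subclone tables are on different dominant rearrangements",
         call. = FALSE)
  target <- diag$profile[1L]
  hit <- match(target, relapse$profile)
  if (is.na(hit)) 0 else relapse$frequency[hit]
}

#' Relapse frequency mass by distance from the diagnosis major
#'
#' Bins the relapse subclone frequencies by their mutational distance to the
#' major diagnosis profile. The bin sums total 1 for a non-empty relapse
#' table.
#'
#' @param relapse A `subclone_table`.
#' @param diag_major SHM profile of the major diagnosis subclone.
#' @return Named numeric vector: names are distances, values summed
#'   frequencies.
#' @export
distance_spectrum <- function(relapse, diag_major) {
  if (nrow(relapse) == 0L) return(stats::setNames(numeric(0), character(0)))
  d <- vapply(relapse$mutations, mutational_distance, 0, b = diag_major)
  out <- tapply(relapse$frequency, d, sum)
  stats::setNames(as.numeric(out), names(out))[order(as.integer(names(out)))]
}

#' Write / read a subclone table as TSV
#'
#' Columns: `profile` (mutation list rendered `pos:ref>alt;...`), `count`,
#' `frequency`, `identity`.
#'
#' @param table A `subclone_table`.
#' @param path Output path.
#' @return `path` invisibly, or the re-read `subclone_table`.
#' @export
write_subclone_tsv <- function(table, path) {
  out <- table[, c("profile", "count", "frequency", "identity")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subclone_tsv
#' @param ref_len,sample_id,key Metadata restored on the re-read table.
#' @export
read_subclone_tsv <- function(path, ref_len, sample_id = NULL, key = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "numeric",
                                         "numeric"))
  profiles <- lapply(df$profile, function(p)
    if (nzchar(p)) strsplit(p, ";", fixed = TRUE)[[1]] else character(0))
  build_subclone_table(profiles, df$count, ref_len,
                       min_count = 1L, min_identity = 0,
                       sample_id = sample_id, key = key)
}
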