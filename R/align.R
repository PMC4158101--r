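# VDJ junction annotation: exact k-mer seeding followed by ungapped extension
# (+1 match / -1 mismatch), one best hit per segment class. D segments are too
# short for typical nucleotide-search word sizes, hence the smaller D seed.

#' Build a k-mer seed index over a germline library
#'
#' @param lib A `germline_library`.
#' @param k_v,k_d,k_j Seed lengths per segment class. The short D seed is the
#'   essential adaptation for the 10-40 nt diversity segments.
#' @return A `kmer_index` used by [annotate_read()].
#' @export
build_kmer_index <- function(lib, k_v = 12L, k_d = 8L, k_j = 12L) {
  ks <- c(V = k_v, D = k_d, J = k_j)
  classes <- lapply(c(V = "V", D = "D", J = "J"), function(cl) {
    segs <- lib[lib$class == cl, , drop = FALSE]
    if (nrow(segs) == 0L)
      stop(sprintf("germline library has no class-%s segment", cl),
           call. = FALSE)
    k <- ks[[cl]]
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(segs))) {
      s <- segs$sequence[i]
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      kmers <- substring(s, starts, starts + k - 1L)
      for (j in seq_along(kmers)) {
        key <- kmers[j]
        env[[key]] <- rbind(env[[key]], c(i, starts[j]))
      }
    }
    list(k = k, env = env, ids = segs$id,
         chars = lapply(segs$sequence, function(s)
           strsplit(s, "", fixed = TRUE)[[1]]))
  })
  structure(classes, class = "kmer_index")
}

# Evaluate `fn` once per unique string in `x`; returns a list parallel to x.
memo_hits <- function(x, fn) {
  first <- !duplicated(x)
  vals <- lapply(x[first], fn)
  vals[match(x, x[first])]
}

# Best ungapped local alignment of the query against one class of the index.
# Seeds give candidate (segment, diagonal) pairs; on each diagonal the
# best-scoring contiguous run is found by a cumulative-sum scan.
best_class_hit <- function(qchars, qseq, cls, max_candidates = 30L) {
  L <- length(qchars)
  k <- cls$k
  if (L < k) return(NULL)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(qseq, starts, starts + k - 1L)
  hits <- mget(kmers, envir = cls$env, ifnotfound = list(NULL))
  nh <- lengths(hits) > 0L
  if (!any(nh)) return(NULL)
  cand <- do.call(rbind, lapply(which(nh), function(j) {
    h <- hits[[j]]
    cbind(seg = h[, 1L], diag = starts[j] - h[, 2L])
  }))
  key <- paste(cand[, 1L], cand[, 2L])
  support <- table(key)
  uniq <- !duplicated(key)
  cand <- cand[uniq, , drop = FALSE]
  ord <- order(-as.vector(support[key[uniq]]))
  cand <- cand[ord, , drop = FALSE]
  if (nrow(cand) > max_candidates)
    cand <- cand[seq_len(max_candidates), , drop = FALSE]

  best <- NULL
  for (r in seq_len(nrow(cand))) {
    seg_i <- cand[r, 1L]
    dg <- cand[r, 2L]
    ref <- cls$chars[[seg_i]]
    Ls <- length(ref)
    q1 <- max(1L, dg + 1L)
    q2 <- min(L, dg + Ls)
    if (q2 - q1 + 1L < k) next
    qq <- qchars[q1:q2]
    rr <- ref[(q1 - dg):(q2 - dg)]
    v <- ifelse(qq == rr & qq != "N" & rr != "N", 1, -1)
    s0 <- c(0, cumsum(v))
    premin <- cummin(s0)
    gain <- s0 - premin
    tt <- which.max(gain)
    score <- gain[tt]
    ss <- match(premin[tt], s0[seq_len(tt - 1L)])
    qstart <- q1 + ss - 1L
    qend <- q1 + tt - 2L
    len <- tt - ss
    identity <- ((len + score) / 2) / len
    cand_hit <- list(segment_id = cls$ids[seg_i], score = score,
                     identity = identity, qstart = qstart, qend = qend,
                     rstart = qstart - dg, rend = qend - dg, diag = dg)
    if (is.null(best) ||
        score > best$score ||
        (score == best$score && identity > best$identity) ||
        (score == best$score && identity == best$identity &&
         cand_hit$segment_id < best$segment_id))
      best <- cand_hit
  }
  best
}

#' Annotate a single sequence with its V, D and J segments
#'
#' For each segment class, the best local hit is found by exact k-mer seeding
#' and ungapped extension (+1 match / -1 mismatch). The read is annotated only
#' if all three classes have a hit at or above the class score minimum and the
#' hits occur in V < D < J order on the query; otherwise the read is filtered
#' (returned as `NULL`), matching the triple-hit filter of the analysis.
#'
#' @param seq Nucleotide string.
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param min_score Named class score minima. The D minimum equals the D seed
#'   length: a single exact seed with no extension suffices.
#' @return A `vdj_annotation` (list with `v`, `d`, `j` hits and the query),
#'   or `NULL` when the read is filtered.
#' @export
annotate_read <- function(seq, index,
                          min_score = c(V = 40, D = 8, J = 20)) {
  qchars <- strsplit(seq, "", fixed = TRUE)[[1]]
  v <- best_class_hit(qchars, seq, index$V)
  if (is.null(v) || v$score < min_score[["V"]]) return(NULL)
  d <- best_class_hit(qchars, seq, index$D)
  if (is.null(d) || d$score < min_score[["D"]]) return(NULL)
  j <- best_class_hit(qchars, seq, index$J)
  if (is.null(j) || j$score < min_score[["J"]]) return(NULL)
  if (!(v$qstart < d$qstart && d$qstart < j$qstart)) return(NULL)
  structure(list(v = v, d = d, j = j, query = seq, merged = TRUE),
            class = "vdj_annotation")
}

# Annotation of an unmerged pair: V from mate 1, D and J from the
# reverse-complemented mate 2. The V 5' end anchors template coordinate 1, so
# a V hit on the reverse mate fixes the template length:
# T = length(mate2) - (qstart - rstart).
annotate_read_pair_hits <- function(m1, m2rc, index,
                                    min_score = c(V = 40, D = 8, J = 20)) {
  q1 <- strsplit(m1, "", fixed = TRUE)[[1]]
  q2 <- strsplit(m2rc, "", fixed = TRUE)[[1]]
  v <- best_class_hit(q1, m1, index$V)
  if (is.null(v) || v$score < min_score[["V"]]) return(NULL)
  d <- best_class_hit(q2, m2rc, index$D)
  if (is.null(d) || d$score < min_score[["D"]]) return(NULL)
  j <- best_class_hit(q2, m2rc, index$J)
  if (is.null(j) || j$score < min_score[["J"]]) return(NULL)
  if (!(d$qstart < j$qstart)) return(NULL)
  v2 <- best_class_hit(q2, m2rc, index$V)
  t_est <- NA_integer_
  if (!is.null(v2) && v2$score >= index$V$k) {
    if (v2$qstart >= d$qstart) v2 <- NULL
    else t_est <- length(q2) - v2$diag
  }
  structure(list(v = v, d = d, j = j, v2 = v2, t_est = t_est,
                 mate1 = m1, mate2rc = m2rc, merged = FALSE),
            class = "vdj_annotation")
}

#' Merge an overlapping read pair into a single amplicon sequence
#'
#' Searches for the best 3' overlap of mate 1 with the reverse complement of
#' mate 2. If an overlap of at least `min_overlap` bases with identity at or
#' above `min_overlap_identity` exists, the merged consensus is returned
#' (mate-1 bases win at disagreements, qualities being flat); otherwise the
#' mates are reported unmerged. 2 x 150 bp reads on a 300-350 bp amplicon
#' frequently do not overlap, so the unmerged outcome is routine, not an
#' error.
#'
#' @param mate1,mate2 The two mate sequences (mate 2 in sequencing
#'   orientation).
#' @param min_overlap Minimum overlap length in bases (>= 1).
#' @param min_overlap_identity Minimum fraction of matching bases within the
#'   overlap.
#' @param mate2_rc Optional precomputed reverse complement of `mate2`.
#' @return A list with `merged` (logical) and, when merged, `sequence` and
#'   `overlap`.
#' @export
merge_read_pair <- function(mate1, mate2, min_overlap = 20L,
                            min_overlap_identity = 0.9, mate2_rc = NULL) {
  if (min_overlap < 1L) stop("`min_overlap` must be >= 1", call. = FALSE)
  rc2 <- if (is.null(mate2_rc)) revcomp(mate2) else mate2_rc
  l1 <- nchar(mate1)
  l2 <- nchar(rc2)
  c1 <- strsplit(mate1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(rc2, "", fixed = TRUE)[[1]]

  check_offset <- function(o) {
    # mate1[o..l1] aligned to rc2[1..ov]
    ov <- l1 - o + 1L
    if (ov < min_overlap || ov > l2) return(NULL)
    matches <- sum(c1[o:l1] == c2[seq_len(ov)])
    ident <- matches / ov
    if (ident >= min_overlap_identity) list(offset = o, overlap = ov,
                                            identity = ident)
    else NULL
  }

  # Candidate offsets come from exact seed matches: prefixes of rc2 searched
  # in mate 1, plus the mate-1 suffix searched in rc2, so a sequencing error
  # inside any single seed still leaves a usable anchor.
  hit <- NULL
  seed_len <- 16L
  offsets <- integer(0)
  for (s in c(1L, 17L)) {
    if (s + seed_len - 1L > l2) break
    seed <- substr(rc2, s, s + seed_len - 1L)
    locs <- gregexpr(seed, mate1, fixed = TRUE)[[1]]
    if (locs[1] != -1L) offsets <- c(offsets, locs - (s - 1L))
  }
  if (l1 >= seed_len) {
    tail_seed <- substr(mate1, l1 - seed_len + 1L, l1)
    locs <- gregexpr(tail_seed, rc2, fixed = TRUE)[[1]]
    if (locs[1] != -1L) offsets <- c(offsets, l1 - (locs + seed_len - 1L) + 1L)
  }
  for (o in sort(unique(offsets[offsets >= 1L]))) {
    hit <- check_offset(o)
    if (!is.null(hit)) break
  }
  if (is.null(hit)) return(list(merged = FALSE))
  merged <- paste0(substr(mate1, 1L, l1),
                   substr(rc2, hit$overlap + 1L, l2))
  list(merged = TRUE, sequence = merged, overlap = hit$overlap,
       identity = hit$identity)
}

#' Annotate every read pair of a sample
#'
#' Pairs are first overlap-merged where possible; merged sequences are
#' annotated directly, unmerged pairs via mate 1 (V) and mate 2 (D, J).
#' Identical pairs are annotated once and the result reused, which makes deep
#' amplicon samples (dominated by a few clones) fast.
#'
#' @param reads A `read_pairs` object.
#' @param index A `kmer_index` (or a `germline_library`, indexed on the fly).
#' @param min_score Class score minima (see [annotate_read()]).
#' @param min_overlap,min_overlap_identity Merge parameters
#'   (see [merge_read_pair()]).
#' @return A `sample_annotation`: list with `reads` (data.frame of `read_id`,
#'   `v_id`, `d_id`, `j_id`, `uidx` per annotated read), `annotations` (unique
#'   annotation objects indexed by `uidx`), `n_input` and `n_filtered`.
#' @export
annotate_sample <- function(reads, index,
                            min_score = c(V = 40, D = 8, J = 20),
                            min_overlap = 20L, min_overlap_identity = 0.9) {
  if (inherits(index, "germline_library")) index <- build_kmer_index(index)
  pair_key <- paste(reads$mate1, reads$mate2, sep = "|")
  first <- !duplicated(pair_key)
  ukeys <- pair_key[first]
  um1 <- reads$mate1[first]
  um2 <- reads$mate2[first]
  um2rc <- revcomp(um2)

  anns <- vector("list", length(ukeys))
  merged_seq <- character(length(ukeys))
  for (i in seq_along(ukeys)) {
    mg <- merge_read_pair(um1[i], um2[i], min_overlap, min_overlap_identity,
                          mate2_rc = um2rc[i])
    if (mg$merged) merged_seq[i] <- mg$sequence
  }
  is_merged <- nzchar(merged_seq)
  for (i in which(is_merged))
    anns[i] <- list(annotate_read(merged_seq[i], index, min_score))

  # Unmerged pairs: memoise per-mate hits (mate 1 carries V, the
  # reverse-complemented mate 2 carries D, J and the V anchor).
  unm <- which(!is_merged)
  if (length(unm)) {
    hit1_of <- memo_hits(um1[unm], function(s) {
      best_class_hit(strsplit(s, "", fixed = TRUE)[[1]], s, index$V)
    })
    hit2_of <- memo_hits(um2rc[unm], function(s) {
      q <- strsplit(s, "", fixed = TRUE)[[1]]
      list(d = best_class_hit(q, s, index$D),
           j = best_class_hit(q, s, index$J),
           v2 = best_class_hit(q, s, index$V))
    })
    for (t in seq_along(unm)) {
      i <- unm[t]
      v <- hit1_of[[t]]
      if (is.null(v) || v$score < min_score[["V"]]) next
      h2 <- hit2_of[[t]]
      d <- h2$d; j <- h2$j; v2 <- h2$v2
      if (is.null(d) || d$score < min_score[["D"]]) next
      if (is.null(j) || j$score < min_score[["J"]]) next
      if (!(d$qstart < j$qstart)) next
      t_est <- NA_integer_
      if (!is.null(v2) && v2$score >= index$V$k && v2$qstart < d$qstart)
        t_est <- nchar(um2rc[i]) - v2$diag
      else v2 <- NULL
      anns[[i]] <- structure(
        list(v = v, d = d, j = j, v2 = v2, t_est = t_est,
             mate1 = um1[i], mate2rc = um2rc[i], merged = FALSE),
        class = "vdj_annotation")
    }
  }
  ok <- !vapply(anns, is.null, TRUE)
  uidx_map <- match(pair_key, ukeys)
  keep <- ok[uidx_map]
  ann_ok <- anns
  res <- data.frame(
    read_id = reads$id[keep],
    v_id = vapply(ann_ok[uidx_map[keep]], function(a) a$v$segment_id, ""),
    d_id = vapply(ann_ok[uidx_map[keep]], function(a) a$d$segment_id, ""),
    j_id = vapply(ann_ok[uidx_map[keep]], function(a) a$j$segment_id, ""),
    uidx = uidx_map[keep],
    stringsAsFactors = FALSE)
  structure(list(reads = res, annotations = anns,
                 n_input = length(reads$id),
                 n_filtered = length(reads$id) - nrow(res)),
            class = "sample_annotation")
}

#' @export
print.sample_annotation <- function(x, ...) {
  cat(sprintf("sample_annotation: %d/%d read pairs annotated (%.1f%%)\n",
              nrow(x$reads), x$n_input,
              100 * nrow(x$reads) / max(1L, x$n_input)))
  invisible(x)
}
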