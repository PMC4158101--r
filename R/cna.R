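# Copy-number analysis on exon-level diagnosis/relapse read counts:
# log2-ratio simulation, outlier smoothing, circular binary segmentation
# (implemented here), gain/loss classification and recurrent-deletion sweep.

#' Simulate exon-level diagnosis/relapse read counts
#'
#' Baseline exons have depth-normalised log2 ratio 0 with the configured
#' Gaussian dispersion; the true copy-number segments in
#' `config$exon_segments` shift the relapse mean count by `2^shift` over
#' their exon ranges. Relapse-vs-diagnosis ratios are normalised by the
#' median per-exon ratio, so baseline exons centre on 0 even when a large
#' fraction of the genome is altered. True breakpoints are recorded.
#'
#' @param config A [simulation_config()]; fields `n_exons`, `exon_depth`,
#'   `dispersion`, `exon_segments` and `seed` are used.
#' @return An `exon_counts` data.frame (`chrom`, `start`, `end` 0-based
#'   half-open, `diag_reads`, `rel_reads`, `log2_ratio`) with the truth
#'   segments in `attr(, "truth")`.
#' @export
simulate_exon_counts <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  validate_simulation_config(config)
  with_seed(derive_seed(config$seed, 43L), {
    n <- config$n_exons
    shift <- numeric(n)
    segs <- config$exon_segments
    for (i in seq_len(nrow(segs)))
      shift[segs$start[i]:segs$end[i]] <- segs$shift[i]
    d <- pmax(1L, stats::rpois(n, config$exon_depth))
    lr_true <- shift + stats::rnorm(n, 0, config$dispersion)
    r <- pmax(0L, as.integer(round(d * 2^lr_true)))
    ratio <- ifelse(d > 0 & r > 0, r / d, NA_real_)
    med <- stats::median(ratio, na.rm = TRUE)
    lr <- log2(ratio / med)
    exon_size <- 1000L
    tab <- data.frame(
      chrom = "chr1",
      start = (seq_len(n) - 1L) * exon_size,
      end = seq_len(n) * exon_size,
      diag_reads = d, rel_reads = r, log2_ratio = lr,
      stringsAsFactors = FALSE)
    truth_segs <- segs
    if (nrow(truth_segs)) {
      truth_segs$chrom <- "chr1"
      truth_segs$start_bp <- (truth_segs$start - 1L) * exon_size
      truth_segs$end_bp <- truth_segs$end * exon_size
    }
    truth <- structure(list(segments = truth_segs, shift = shift),
                       class = "truth_record")
    structure(tab, class = c("exon_counts", "data.frame"), truth = truth)
  })
}

#' Filter and smooth exon log2 ratios
#'
#' Drops exons whose combined diagnosis+relapse read count is not strictly
#' greater than `min_total_reads`, then shrinks outliers: an exon whose ratio
#' deviates from its centred window median by more than `z` local MADs is
#' pulled in to median +/- z*MAD (to the median itself when the local MAD is
#' zero).
#'
#' @param exons An `exon_counts` data.frame sorted by chromosome and start.
#' @param min_total_reads Total-read cutoff (strictly greater-than; default
#'   100).
#' @param window Centred window size (odd; default 5).
#' @param z MAD multiplier (default 3).
#' @return The filtered data.frame with a `log2_smooth` column.
#' @export
smooth_log2 <- function(exons, min_total_reads = 100L, window = 5L, z = 3) {
  keep <- (exons$diag_reads + exons$rel_reads) > min_total_reads &
    !is.na(exons$log2_ratio)
  out <- exons[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$log2_smooth <- out$log2_ratio
  h <- window %/% 2L
  for (chrom in unique(out$chrom)) {
    idx <- which(out$chrom == chrom)
    x <- out$log2_ratio[idx]
    n <- length(x)
    sm <- x
    for (i in seq_len(n)) {
      w <- x[max(1L, i - h):min(n, i + h)]
      med <- stats::median(w)
      mad_w <- stats::median(abs(w - med))
      dev <- x[i] - med
      if (abs(dev) > z * mad_w)
        sm[i] <- med + sign(dev) * z * mad_w
    }
    out$log2_smooth[idx] <- sm
  }
  out
}

# Maximal circular-arc Z statistic over a numeric vector. Arcs are index
# intervals (i, j] with 1 <= j - i <= n - 1; the statistic compares the arc
# mean with the complement mean, standardised by the (permutation-invariant)
# overall s.d.
max_arc_stat <- function(x, pairs) {
  s0 <- c(0, cumsum(x))
  d <- s0[pairs$j + 1L] - s0[pairs$i + 1L]
  tot <- s0[length(s0)]
  diff <- d / pairs$k - (tot - d) / (pairs$nk)
  z <- diff * pairs$invden
  best <- which.max(abs(z))
  list(stat = abs(z[best]), i = pairs$i[best], j = pairs$j[best], z = z)
}

arc_pairs <- function(n, s) {
  i <- rep(0:(n - 1L), times = n:1L)
  j <- unlist(lapply(0:(n - 1L), function(a) (a + 1L):n))
  keep <- !(i == 0L & j == n)
  i <- i[keep]; j <- j[keep]
  k <- j - i
  nk <- n - k
  list(i = i, j = j, k = k, nk = nk,
       invden = 1 / (s * sqrt(1 / k + 1 / nk)))
}

# Permutation p-value for the best arc of segment x, with early stopping once
# the split can no longer reach significance.
cbs_split <- function(x, alpha, nperm) {
  n <- length(x)
  if (n < 4L) return(NULL)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NULL)
  pairs <- arc_pairs(n, s)
  obs <- max_arc_stat(x, pairs)
  exceed <- 0L
  done <- 0L
  limit <- alpha * (nperm + 1) - 1  # beyond this p >= alpha is certain
  block <- 100L
  while (done < nperm) {
    b <- min(block, nperm - done)
    for (r in seq_len(b)) {
      perm <- max_arc_stat(sample(x), pairs)
      if (perm$stat >= obs$stat) exceed <- exceed + 1L
    }
    done <- done + b
    if (exceed > limit) return(NULL)
  }
  p <- (exceed + 1) / (nperm + 1)
  if (p >= alpha) return(NULL)
  list(i = obs$i, j = obs$j, p = p)
}

#' Segment exon log2 ratios by circular binary segmentation
#'
#' Recursive CBS: within each segment the arc maximising the standardised
#' mean-difference statistic is found; the split is accepted when its
#' permutation p-value (label permutations within the segment) is below
#' `alpha`, and recursion continues on the sub-segments. Finally, adjacent
#' segments whose means differ by less than `undo_sd` times the residual
#' standard deviation are merged back ("undo splits").
#'
#' @param exons A smoothed `exon_counts` data.frame (uses `log2_smooth` when
#'   present, `log2_ratio` otherwise), sorted by chromosome and start.
#' @param alpha Permutation significance level for accepting a split.
#' @param nperm Number of permutations.
#' @param undo_sd Undo threshold in residual standard deviations.
#' @param seed Integer seed (permutations are the only randomness).
#' @return A `cna_segments` data.frame: `chrom`, `start`, `end`, `n_exons`,
#'   `mean_log2`. Chromosomes with fewer than 10 exons yield a single segment
#'   with a warning.
#' @export
segment_cna <- function(exons, alpha = 0.01, nperm = 1000L, undo_sd = 1.5,
                        seed = 1L) {
  val_col <- if ("log2_smooth" %in% names(exons)) "log2_smooth"
             else "log2_ratio"
  with_seed(seed, {
    res <- list()
    for (chrom in unique(exons$chrom)) {
      idx <- which(exons$chrom == chrom)
      x <- exons[[val_col]][idx]
      n <- length(x)
      if (n < 10L) {
        warning(sprintf("chromosome %s has only %d exons; returning a single segment",
                        chrom, n))
        bounds <- c(0L, n)
      } else {
        bounds <- sort(unique(c(0L, n, cbs_recurse(x, alpha, nperm))))
      }
      bounds <- undo_splits(x, bounds, undo_sd)
      for (b in seq_len(length(bounds) - 1L)) {
        lo <- bounds[b] + 1L
        hi <- bounds[b + 1L]
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom,
          start = exons$start[idx[lo]],
          end = exons$end[idx[hi]],
          n_exons = hi - lo + 1L,
          mean_log2 = mean(x[lo:hi]),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    structure(out, class = c("cna_segments", "data.frame"))
  })
}

cbs_recurse <- function(x, alpha, nperm, offset = 0L) {
  split <- cbs_split(x, alpha, nperm)
  if (is.null(split)) return(integer(0))
  cuts <- c(split$i, split$j)
  cuts <- cuts[cuts > 0L & cuts < length(x)]
  if (length(cuts) == 0L) return(integer(0))
  bounds <- c(0L, sort(cuts), length(x))
  out <- offset + sort(cuts)
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L
    hi <- bounds[b + 1L]
    if (hi - lo + 1L >= 4L)
      out <- c(out, cbs_recurse(x[lo:hi], alpha, nperm, offset + lo - 1L))
  }
  sort(unique(out))
}

undo_splits <- function(x, bounds, undo_sd) {
  repeat {
    nb <- length(bounds)
    if (nb <= 2L) return(bounds)
    means <- vapply(seq_len(nb - 1L), function(b)
      mean(x[(bounds[b] + 1L):bounds[b + 1L]]), 0)
    fitted <- rep(means, diff(bounds))
    resid_sd <- stats::sd(x - fitted)
    if (!is.finite(resid_sd) || resid_sd == 0) return(bounds)
    gaps <- abs(diff(means))
    worst <- which.min(gaps)
    if (gaps[worst] < undo_sd * resid_sd) {
      bounds <- bounds[-(worst + 1L)]
    } else return(bounds)
  }
}

#' Classify copy-number segments as gain, loss or neutral
#'
#' Strict thresholds: mean log2 ratio greater than `gain_thresh` is a gain,
#' less than `loss_thresh` a loss, anything else (boundaries included)
#' neutral.
#'
#' @param segments A `cna_segments` data.frame.
#' @param gain_thresh,loss_thresh Log2-ratio thresholds (defaults +0.3 /
#'   -0.3).
#' @return The segments with a `class` column.
#' @export
classify_segments <- function(segments, gain_thresh = 0.3,
                              loss_thresh = -0.3) {
  cls <- rep("neutral", nrow(segments))
  cls[segments$mean_log2 > gain_thresh] <- "gain"
  cls[segments$mean_log2 < loss_thresh] <- "loss"
  segments$class <- cls
  segments
}

#' Genomic regions deleted in multiple relapse samples
#'
#' Coordinate sweep over per-sample loss segments: reports the maximal
#' genomic intervals covered by loss segments from at least `min_samples`
#' distinct samples, with the supporting sample ids and the interval rendered
#' 1-based inclusive (`"117064566-117131520"` style).
#'
#' @param losses data.frame of loss segments with columns `sample`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param min_samples Minimum number of distinct supporting samples.
#' @return data.frame `chrom`, `start`, `end`, `n_samples`, `samples`,
#'   `region_1based`; zero rows when no interval qualifies.
#' @export
common_deleted_regions <- function(losses, min_samples = 3L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_samples = integer(0),
                      samples = character(0), region_1based = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(losses) == 0L) return(empty)
  out <- list()
  for (chrom in unique(losses$chrom)) {
    seg <- losses[losses$chrom == chrom, , drop = FALSE]
    cuts <- sort(unique(c(seg$start, seg$end)))
    if (length(cuts) < 2L) next
    lo <- cuts[-length(cuts)]
    hi <- cuts[-1L]
    covering <- lapply(seq_along(lo), function(e)
      sort(unique(seg$sample[seg$start <= lo[e] & seg$end >= hi[e]])))
    ok <- vapply(covering, length, 0L) >= min_samples
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      e1 <- starts[b]; e2 <- ends[b]
      samples <- sort(unique(unlist(covering[e1:e2])))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = lo[e1], end = hi[e2],
        n_samples = length(samples),
        samples = paste(samples, collapse = ","),
        region_1based = sprintf("%d-%d", lo[e1] + 1L, hi[e2]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write CNA segments as BED-like TSV
#'
#' BED convention: 0-based half-open coordinates.
#'
#' @param segments A `cna_segments` data.frame (optionally classified).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
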