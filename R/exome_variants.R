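# Paired diagnosis/relapse variant analysis: depth/VAF filtering, 2x2 tests
# for allele-fraction change, BH control, gained/lost classification.

#' Simulate a paired diagnosis/relapse variant-count table
#'
#' Generates per-site read counts for novel coding SNVs under the configured
#' mode: gained sites have diagnosis alt fraction `minor_fraction` (0 by
#' default) and relapse alt fraction ~0.5; lost sites the reverse; the
#' remainder are shared at ~0.5 in both. Counts are binomial at Poisson
#' per-site depths around `exome_depth`. A small extra set of sites is
#' flagged as known SNPs to exercise the filters. Truth labels are attached.
#'
#' @param config A [simulation_config()]; fields `n_sites`, `frac_gained`,
#'   `frac_lost`, `exome_depth`, `minor_fraction`, `frac_known` and `seed`
#'   are used.
#' @return A `variant_table` data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `d_ref`, `d_alt`, `r_ref`, `r_alt`, `known`, `in_cna`) with the truth in
#'   `attr(, "truth")`.
#' @export
simulate_variant_table <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  if (config$exome_depth < 1L) stop("`exome_depth` must be >= 1", call. = FALSE)
  if (config$frac_gained + config$frac_lost > 1)
    stop("gained + lost fractions must be <= 1", call. = FALSE)
  with_seed(derive_seed(config$seed, 41L), {
    n <- config$n_sites
    n_gain <- round(config$frac_gained * n)
    n_loss <- round(config$frac_lost * n)
    n_known <- round(config$frac_known * n)
    status <- c(rep("gained", n_gain), rep("lost", n_loss),
                rep("shared", n - n_gain - n_loss),
                rep("known_snp", n_known))
    total <- length(status)
    d_vaf <- ifelse(status == "gained", config$minor_fraction,
                    ifelse(status == "lost", 0.5, 0.5))
    r_vaf <- ifelse(status == "gained", 0.5,
                    ifelse(status == "lost", config$minor_fraction, 0.5))
    d_dep <- pmax(1L, stats::rpois(total, config$exome_depth))
    r_dep <- pmax(1L, stats::rpois(total, config$exome_depth))
    d_alt <- stats::rbinom(total, d_dep, d_vaf)
    r_alt <- stats::rbinom(total, r_dep, r_vaf)
    pos <- sort(sample.int(5e7, total))
    tab <- data.frame(
      chrom = sample(paste0("chr", 1:22), total, replace = TRUE),
      pos = pos,
      ref = sample(c("A", "C", "G", "T"), total, replace = TRUE),
      alt = NA_character_,
      d_ref = d_dep - d_alt, d_alt = d_alt,
      r_ref = r_dep - r_alt, r_alt = r_alt,
      known = status == "known_snp",
      in_cna = FALSE,
      stringsAsFactors = FALSE)
    tab$alt <- other_base(tab$ref)
    tab$site_id <- paste0(tab$chrom, ":", tab$pos)
    truth <- structure(
      list(status = stats::setNames(status, tab$site_id),
           gained = tab$site_id[status == "gained"],
           lost = tab$site_id[status == "lost"],
           shared = tab$site_id[status == "shared"]),
      class = "truth_record")
    structure(tab, class = c("variant_table", "data.frame"), truth = truth)
  })
}

#' Filter variant sites by depth, allele fraction and annotation flags
#'
#' Keeps sites where, in at least one of the two samples, depth is at least
#' `min_depth` and the variant allele fraction at least `min_vaf` (so
#' relapse-specific variants with zero diagnosis alt reads survive). Known
#' SNPs and sites inside copy-number-altered regions can be dropped by flag.
#'
#' @param sites A `variant_table`-shaped data.frame.
#' @param min_depth Minimum per-sample depth (default 20).
#' @param min_vaf Minimum per-sample variant allele fraction (default 0.25).
#' @param drop_known,drop_cna Drop sites flagged `known` / `in_cna`.
#' @return The filtered data.frame.
#' @export
filter_variants <- function(sites, min_depth = 20L, min_vaf = 0.25,
                            drop_known = TRUE, drop_cna = TRUE) {
  d_dep <- sites$d_ref + sites$d_alt
  r_dep <- sites$r_ref + sites$r_alt
  d_vaf <- ifelse(d_dep > 0, sites$d_alt / d_dep, 0)
  r_vaf <- ifelse(r_dep > 0, sites$r_alt / r_dep, 0)
  keep <- (d_dep >= min_depth & d_vaf >= min_vaf) |
          (r_dep >= min_depth & r_vaf >= min_vaf)
  if (drop_known && "known" %in% names(sites)) keep <- keep & !sites$known
  if (drop_cna && "in_cna" %in% names(sites)) keep <- keep & !sites$in_cna
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test a site for a diagnosis-to-relapse allele-fraction change
#'
#' P-value for independence on the 2x2 table of (ref, alt) read counts in the
#' diagnosis and relapse samples: Pearson chi-square without continuity
#' correction (default) or the two-sided Fisher exact test.
#'
#' @param d_ref,d_alt,r_ref,r_alt Read counts.
#' @param method `"chi_square"` or `"fisher"`.
#' @return The p-value. A table with a zero margin in the alt (or ref)
#'   dimension carries no signal and returns 1; an all-zero table is an
#'   error.
#' @export
gain_loss_test <- function(d_ref, d_alt, r_ref, r_alt,
                           method = c("chi_square", "fisher")) {
  method <- match.arg(method)
  m <- matrix(c(d_ref, d_alt, r_ref, r_alt), nrow = 2L, byrow = TRUE)
  if (any(m < 0)) stop("negative read counts", call. = FALSE)
  if (sum(m) == 0) stop("all-zero 2x2 table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  p <- if (method == "chi_square") {
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  } else {
    stats::fisher.test(m)$p.value
  }
  min(1, p)  # exact-tail summation can exceed 1 by rounding
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR control: hypothesis i is flagged significant iff its
#' sorted p-value satisfies `p(i) <= (rank/m) * q` after step-up closure,
#' equivalently iff its BH-adjusted value is at most `q`.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.1).
#' @return List with `adjusted` (BH-adjusted p-values) and `significant`
#'   (logical flags).
#' @export
bh_adjust <- function(pvals, q = 0.1) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, significant = adjusted <= q)
}

#' Classify variants as gained or lost at relapse
#'
#' Applies [gain_loss_test()] per site, BH-adjusts across sites, and labels
#' significant sites by the direction of the allele-fraction change: gained
#' when the relapse VAF exceeds the diagnosis VAF, lost for the reverse;
#' non-significant sites are shared.
#'
#' @param sites A filtered variant data.frame.
#' @param method Test method (see [gain_loss_test()]).
#' @param q BH false discovery rate (default 0.1).
#' @return A `variant_calls` list: `calls` (the input plus `p`, `q_adj`,
#'   `status`), `n_gained`, `n_lost` and `ratio` (gained/lost; `Inf` when
#'   nothing was lost but something gained, `NA` when neither).
#' @export
classify_variants <- function(sites, method = c("chi_square", "fisher"),
                              q = 0.1) {
  method <- match.arg(method)
  n <- nrow(sites)
  if (n == 0L) {
    return(structure(list(calls = sites, n_gained = 0L, n_lost = 0L,
                          ratio = NA_real_), class = "variant_calls"))
  }
  p <- vapply(seq_len(n), function(i)
    gain_loss_test(sites$d_ref[i], sites$d_alt[i],
                   sites$r_ref[i], sites$r_alt[i], method = method), 0)
  bh <- bh_adjust(p, q)
  d_vaf <- sites$d_alt / pmax(1L, sites$d_ref + sites$d_alt)
  r_vaf <- sites$r_alt / pmax(1L, sites$r_ref + sites$r_alt)
  status <- rep("shared", n)
  status[bh$significant & r_vaf > d_vaf] <- "gained"
  status[bh$significant & r_vaf < d_vaf] <- "lost"
  calls <- sites
  calls$p <- p
  calls$q_adj <- bh$adjusted
  calls$status <- status
  n_gained <- sum(status == "gained")
  n_lost <- sum(status == "lost")
  ratio <- if (n_gained == 0L && n_lost == 0L) NA_real_
           else if (n_lost == 0L) Inf
           else n_gained / n_lost
  structure(list(calls = calls, n_gained = n_gained, n_lost = n_lost,
                 ratio = ratio), class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("variant_calls: %d gained, %d lost (ratio %s) of %d sites\n",
              x$n_gained, x$n_lost,
              ifelse(is.na(x$ratio), "NA", format(x$ratio, digits = 3)),
              nrow(x$calls)))
  invisible(x)
}

#' Write / read a variant table as TSV
#'
#' @param sites A variant data.frame (optionally with call columns).
#' @param path Output path.
#' @return `path` invisibly, or the re-read data.frame.
#' @export
write_variant_tsv <- function(sites, path) {
  out <- sites
  out$mutations <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_tsv
#' @export
read_variant_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
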