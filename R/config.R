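#' Simulation configuration for a diagnosis-relapse pair
#'
#' Bundles every tunable parameter of the synthetic-data generator. Defaults
#' are the package's study conditions: a deep amplicon experiment on 300-350 bp
#' VDJ products with one dominant malignant rearrangement plus infiltrating
#' polyclonal B cells, SHM accumulating along a discrete-generation genealogy,
#' and paired-exome variant/exon tables with mode-dependent gain/loss balance.
#' The rationale for each default is laid out in the methods vignette.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param mode Relapse mode to simulate: `"late_divergent"` (relapse major
#'   nearly identical to the diagnosis major) or `"early_divergent"` (relapse
#'   lineage branched `divergence_depth` generations before the diagnosis
#'   major's expansion).
#' @param n_subclones Minor SHM subclones per sample within the dominant
#'   rearrangement.
#' @param shm_rate Per-base per-generation somatic hypermutation probability.
#'   When positive, every generation adds at least one mutation to a lineage;
#'   `shm_rate = 0` disables SHM entirely.
#' @param trunk_mutations SHM mutations shared by all tumor cells (acquired
#'   before the clonal expansion).
#' @param divergence_depth Generations separating the relapse lineage from the
#'   diagnosis major clone in early-divergent mode (each generation adds at
#'   least one private mutation to each branch).
#' @param maturation_generations Generations of late SHM on the diagnosis
#'   major lineage in late-divergent mode.
#' @param precursor_freq Frequency at which the relapse major clone is planted
#'   as a minor subclone of the diagnosis sample in early-divergent mode
#'   (default 0.2%, the order of magnitude of minor relapse-precursor clones
#'   detectable by ultra-deep resequencing).
#' @param retention_freq Mean frequency of the diagnosis major profile
#'   retained in the relapse sample under the late-divergent mode.
#' @param residual_freq Frequency of the diagnosis major profile left in the
#'   relapse sample under the early-divergent mode (nearly extinct).
#' @param major_freq_early,major_freq_late Mean frequency of the major
#'   subclone within the dominant rearrangement; early-divergent tumors are
#'   simulated with a flatter subclone distribution (higher diversity).
#' @param background_fraction Fraction of reads drawn from non-malignant
#'   B cells carrying their own rearrangements.
#' @param n_background Number of background B-cell clones.
#' @param n_read_pairs,read_len,error_rate Read simulation: pairs per sample,
#'   mate length (nt) and i.i.d. per-base substitution error probability.
#' @param n_v,n_d,n_j,trim_max,insert_max Germline library and junction
#'   geometry passed to [build_toy_germline()] / [simulate_rearrangement()].
#' @param n_sites,frac_gained,frac_lost,exome_depth,minor_fraction Variant
#'   table simulation: number of coding sites, fractions truly gained/lost at
#'   relapse (defaults depend on `mode`, mirroring the observed gain:loss
#'   imbalance between the two modes), mean per-site depth, and the diagnosis
#'   allele fraction at gained sites (0 = strictly relapse-specific).
#' @param frac_known Fraction of additional simulated sites flagged as known
#'   SNPs (removed by the default filters).
#' @param n_exons,exon_depth,dispersion,exon_segments Exon count simulation:
#'   number of exons, mean diagnosis read count per exon, s.d. of the
#'   per-exon log2 ratio noise, and a data.frame `start`/`end`/`shift` of
#'   true copy-number segments (exon indices, log2 shift).
#' @param amplicon_depth,amplicon_positions,background_rate Ultra-deep
#'   resequencing simulation: reads per amplicon, amplicon length and per-class
#'   background conversion rate.
#' @param min_support,k_sd Minor-clone detection rule: minimum supporting
#'   reads and the number of background s.d. above the mean required.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              mode = c("late_divergent", "early_divergent"),
                              n_subclones = 8L,
                              shm_rate = 0.003,
                              trunk_mutations = 12L,
                              divergence_depth = 6L,
                              maturation_generations = 3L,
                              precursor_freq = 0.002,
                              retention_freq = 0.30,
                              residual_freq = 0.002,
                              major_freq_early = 0.45,
                              major_freq_late = 0.70,
                              background_fraction = 0.30,
                              n_background = 30L,
                              n_read_pairs = 4000L,
                              read_len = 150L,
                              error_rate = 0.002,
                              n_v = 20L, n_d = 10L, n_j = 6L,
                              trim_max = 6L, insert_max = 8L,
                              n_sites = 150L,
                              frac_gained = NULL,
                              frac_lost = NULL,
                              exome_depth = 65L,
                              minor_fraction = 0,
                              frac_known = 0.05,
                              n_exons = 100L,
                              exon_depth = 300L,
                              dispersion = 0.2,
                              exon_segments = data.frame(
                                start = c(21L, 61L), end = c(35L, 80L),
                                shift = c(1, -1)),
                              amplicon_depth = 2e6,
                              amplicon_positions = 30L,
                              background_rate = 3e-4,
                              min_support = 20L,
                              k_sd = 3) {
  mode <- match.arg(mode)
  # Mode-dependent gain/loss balance: late-divergent relapses gain many and
  # lose few SNVs; early-divergent relapses gain and lose comparably.
  if (is.null(frac_gained))
    frac_gained <- if (mode == "late_divergent") 44 / 150 else 32 / 150
  if (is.null(frac_lost))
    frac_lost <- if (mode == "late_divergent") 8 / 150 else 36 / 150
  cfg <- list(seed = as.integer(seed), mode = mode,
              n_subclones = as.integer(n_subclones),
              shm_rate = shm_rate, trunk_mutations = as.integer(trunk_mutations),
              divergence_depth = as.integer(divergence_depth),
              maturation_generations = as.integer(maturation_generations),
              precursor_freq = precursor_freq, retention_freq = retention_freq,
              residual_freq = residual_freq,
              major_freq_early = major_freq_early,
              major_freq_late = major_freq_late,
              background_fraction = background_fraction,
              n_background = as.integer(n_background),
              n_read_pairs = as.integer(n_read_pairs),
              read_len = as.integer(read_len), error_rate = error_rate,
              n_v = as.integer(n_v), n_d = as.integer(n_d),
              n_j = as.integer(n_j), trim_max = as.integer(trim_max),
              insert_max = as.integer(insert_max),
              n_sites = as.integer(n_sites), frac_gained = frac_gained,
              frac_lost = frac_lost, exome_depth = as.integer(exome_depth),
              minor_fraction = minor_fraction, frac_known = frac_known,
              n_exons = as.integer(n_exons), exon_depth = as.integer(exon_depth),
              dispersion = dispersion, exon_segments = exon_segments,
              amplicon_depth = amplicon_depth,
              amplicon_positions = as.integer(amplicon_positions),
              background_rate = background_rate,
              min_support = as.integer(min_support), k_sd = k_sd)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  rates <- c("shm_rate", "precursor_freq", "retention_freq", "residual_freq",
             "major_freq_early", "major_freq_late", "background_fraction",
             "error_rate", "frac_gained", "frac_lost", "minor_fraction",
             "frac_known", "background_rate")
  for (r in rates) assert_fraction(cfg[[r]], r)
  counts <- c("n_subclones", "trunk_mutations", "divergence_depth",
              "maturation_generations", "n_background", "n_read_pairs",
              "read_len", "n_v", "n_d", "n_j", "n_sites", "exome_depth",
              "n_exons", "exon_depth", "min_support")
  for (k in counts)
    if (cfg[[k]] < 1) stop(sprintf("`%s` must be positive", k), call. = FALSE)
  if (cfg$frac_gained + cfg$frac_lost > 1)
    stop("`frac_gained` + `frac_lost` must be <= 1", call. = FALSE)
  if (cfg$n_exons < 10L)
    stop("`n_exons` must be >= 10", call. = FALSE)
  segs <- cfg$exon_segments
  if (nrow(segs)) {
    if (any(segs$start > segs$end) || any(segs$start < 1) ||
        any(segs$end > cfg$n_exons))
      stop("exon segments must lie within 1..n_exons", call. = FALSE)
    o <- order(segs$start)
    if (nrow(segs) > 1 &&
        any(segs$start[o][-1] <= segs$end[o][-nrow(segs)]))
      stop("exon truth segments must not overlap", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: mode=%s seed=%d  %d subclones, SHM %.4f/base/gen\n",
    x$mode, x$seed, x$n_subclones, x$shm_rate))
  cat(sprintf("  reads: %d pairs x 2x%d nt, error %.4f; exome: %d sites at %dX\n",
              x$n_read_pairs, x$read_len, x$error_rate, x$n_sites,
              x$exome_depth))
  invisible(x)
}
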