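# End-to-end driver: simulate a diagnosis-relapse pair, run every analysis
# stage, and assemble the per-pair report.

#' Run the full diagnosis-relapse analysis pipeline on a simulated pair
#'
#' Executes, from a single [simulation_config()]: germline library and tumor
#' pair simulation, paired-read simulation, VDJ annotation, rearrangement
#' counting with dominant-clone summaries, SHM subclone tables, the
#' phylogenetic divergence classification, the paired-exome variant and
#' copy-number analyses, and ultra-deep minor-clone detection. Identical
#' config and seed give an identical report.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, intermediate artifacts
#'   (germline FASTA, paired FASTQ, TSV tables, Newick tree, report JSON)
#'   are written there.
#' @return A `pair_report` list; the simulation truth is kept in
#'   `$truth` for validation.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)

  lib <- build_toy_germline(config$n_v, config$n_d, config$n_j,
                            seed = derive_seed(config$seed, 1L))
  sim <- simulate_tumor_pair(config, lib)
  index <- build_kmer_index(lib)

  analyse_sample <- function(pop, label, seed_offset) {
    reads <- simulate_reads(pop, config$n_read_pairs,
                            read_len = config$read_len,
                            error_rate = config$error_rate,
                            seed = derive_seed(config$seed, seed_offset))
    ann <- annotate_sample(reads, index)
    rtab <- count_rearrangements(ann, label)
    dom <- dominant_rearrangements(rtab)
    sub <- sample_subclones(ann, lib, min_count = 10L, min_identity = 0.80,
                            sample_id = label)
    list(reads = reads, annotation = ann, rearrangements = rtab,
         dominants = dom, subclones = sub)
  }
  diag <- analyse_sample(sim$diagnosis, "diagnosis", 21L)
  relapse <- analyse_sample(sim$relapse, "relapse", 22L)

  pair <- analyze_pair(diag$subclones, relapse$subclones,
                       seed = derive_seed(config$seed, 31L))

  variants <- simulate_variant_table(config)
  filtered <- filter_variants(variants)
  calls <- classify_variants(filtered)

  exons <- simulate_exon_counts(config)
  smoothed <- smooth_log2(exons)
  segments <- classify_segments(
    segment_cna(smoothed, seed = derive_seed(config$seed, 51L)))

  clone_freq <- if (config$mode == "early_divergent") config$precursor_freq
                else 0
  pileup <- simulate_amplicon_pileup(
    n_positions = config$amplicon_positions, depth = config$amplicon_depth,
    error_rate = config$background_rate, target_pos = 15L,
    clone_freq = clone_freq, seed = derive_seed(config$seed, 61L))
  bg <- estimate_background(pileup, "C>A", exclude_pos = 15L)
  freq <- allele_frequency(pileup, 15L, "A")
  detection <- detect_minor_clone(freq, pileup$A[pileup$pos == 15L], bg,
                                  k = config$k_sd,
                                  min_support = config$min_support)

  sample_block <- function(s) {
    list(total_mapped = s$rearrangements$total_mapped,
         unique_rearrangements = s$rearrangements$n_unique,
         unique_per_1e3 = s$rearrangements$unique_per_1e3,
         dominant = s$dominants$label,
         dominant_pct = s$dominants$percentage,
         n_subclones = nrow(s$subclones),
         subclones_per_1e3_dominant =
           1000 * nrow(s$subclones) / max(1L, sum(s$subclones$count)),
         entropy = if (nrow(s$subclones)) empirical_entropy(s$subclones)
                   else NA_real_)
  }
  report <- structure(list(
    seed = config$seed,
    configured_mode = config$mode,
    diagnosis = sample_block(diag),
    relapse = sample_block(relapse),
    pair = list(mode = pair$call$mode,
                mutational_distance = pair$call$distance,
                major_clone_fate = pair$call$major_clone_fate,
                diagnosis_exclusive = pair$call$diagnosis_exclusive,
                relapse_exclusive = pair$call$relapse_exclusive,
                separate_clade = pair$call$separate_clade,
                tree_newick = ape::write.tree(pair$tree)),
    exome = list(n_sites_tested = nrow(filtered),
                 n_gained = calls$n_gained, n_lost = calls$n_lost,
                 gain_loss_ratio = calls$ratio,
                 n_cna_segments = sum(segments$class != "neutral"),
                 n_gain_segments = sum(segments$class == "gain"),
                 n_loss_segments = sum(segments$class == "loss")),
    deep_reseq = list(target_frequency = freq,
                      background_mean = bg$mean, background_sd = bg$sd,
                      detected = detection$detected,
                      detection_limit_pct =
                        detection_limit(config$amplicon_depth,
                                        config$min_support))),
    class = "pair_report")

  result <- list(report = report, truth = sim$truth,
                 library = lib,
                 diagnosis = diag, relapse = relapse, pair = pair,
                 variants = list(table = variants, filtered = filtered,
                                 calls = calls),
                 cna = list(exons = exons, smoothed = smoothed,
                            segments = segments),
                 reseq = list(pileup = pileup, background = bg,
                              detection = detection))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_germline_fasta(lib, file.path(out_dir, "germline.fasta"))
    for (s in list(diag, relapse)) {
      label <- s$rearrangements$sample_id
      write_fastq_pair(s$reads,
                       file.path(out_dir, paste0(label, "_R1.fastq")),
                       file.path(out_dir, paste0(label, "_R2.fastq")))
      write_rearrangement_tsv(s$rearrangements,
                              file.path(out_dir,
                                        paste0(label, "_rearrangements.tsv")))
      write_subclone_tsv(s$subclones,
                         file.path(out_dir, paste0(label, "_subclones.tsv")))
    }
    write_newick(pair$tree, file.path(out_dir, "pair_tree.nwk"))
    write_variant_tsv(calls$calls, file.path(out_dir, "variant_calls.tsv"))
    write_segments_bed(segments, file.path(out_dir, "cna_segments.tsv"))
    write_pileup_tsv(pileup, file.path(out_dir, "amplicon_pileup.tsv"))
    write_report_json(report, file.path(out_dir, "pair_report.json"))
  }
  result
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf("pair_report (seed %d, simulated mode %s)\n", x$seed,
              x$configured_mode))
  cat(sprintf("  diagnosis: %d mapped, %.2f unique/10^3, dominant %s (%.1f%%), %d subclones, entropy %.2f bits\n",
              x$diagnosis$total_mapped, x$diagnosis$unique_per_1e3,
              x$diagnosis$dominant[1], x$diagnosis$dominant_pct[1],
              x$diagnosis$n_subclones, x$diagnosis$entropy))
  cat(sprintf("  relapse:   %d mapped, %.2f unique/10^3, dominant %s (%.1f%%), %d subclones, entropy %.2f bits\n",
              x$relapse$total_mapped, x$relapse$unique_per_1e3,
              x$relapse$dominant[1], x$relapse$dominant_pct[1],
              x$relapse$n_subclones, x$relapse$entropy))
  cat(sprintf("  call: %s (distance %d, fate %.3f)\n", x$pair$mode,
              x$pair$mutational_distance, x$pair$major_clone_fate))
  cat(sprintf("  exome: %d gained / %d lost (ratio %s); %d CNA segments\n",
              x$exome$n_gained, x$exome$n_lost,
              format(x$exome$gain_loss_ratio, digits = 3),
              x$exome$n_cna_segments))
  cat(sprintf("  deep reseq: %.4f%% vs background %.4f%% +/- %.4f%% -> %s\n",
              100 * x$deep_reseq$target_frequency,
              100 * x$deep_reseq$background_mean,
              100 * x$deep_reseq$background_sd,
              if (x$deep_reseq$detected) "detected" else "not detected"))
  invisible(x)
}
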