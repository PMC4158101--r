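# Clone genealogy simulation: SHM accumulates along a discrete-generation
# branching process on top of a single shared VDJ rearrangement, with a
# polyclonal background of non-malignant B cells carrying other rearrangements.

parse_mutations <- function(muts) {
  if (length(muts) == 0L)
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  m <- regmatches(muts, regexec("^([0-9]+):([ACGTN])>([ACGTN])$", muts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop(sprintf("malformed mutation '%s' (expected pos:ref>alt)",
                 muts[bad][1]), call. = FALSE)
  data.frame(pos = as.integer(vapply(m, `[`, "", 2L)),
             ref = vapply(m, `[`, "", 3L),
             alt = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
}

format_mutations <- function(pos, ref, alt) sprintf("%d:%s>%s", pos, ref, alt)

# Apply an SHM profile to a reference sequence.
apply_profile <- function(sequence, profile) {
  if (length(profile) == 0L) return(sequence)
  mut <- parse_mutations(profile)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(mut$pos < 1L | mut$pos > length(ch)))
    stop("mutation position outside sequence", call. = FALSE)
  if (any(ch[mut$pos] != mut$ref))
    stop("mutation reference base does not match sequence", call. = FALSE)
  ch[mut$pos] <- mut$alt
  paste(ch, collapse = "")
}

#' Simulate a matched diagnosis-relapse clone pair
#'
#' Builds the clonal structure of a diagnosis-relapse tumor pair with known
#' ground truth. Both samples share one major VDJ rearrangement; SHM
#' accumulates along a discrete-generation branching genealogy (at least one
#' new mutation per lineage per generation when `shm_rate > 0`; mutation
#' positions are globally unique so set relations between profiles are exact).
#' Under the late-divergent mode the relapse major clone differs from the
#' diagnosis major by at most two substitutions and the diagnosis major
#' profile is retained in the relapse sample; under the early-divergent mode
#' the two majors sit on branches that split `divergence_depth` generations
#' before the diagnosis major's expansion, the relapse major is planted as a
#' minor subclone of the diagnosis sample (default 0.2%), and the diagnosis
#' major is nearly extinct at relapse. A configurable fraction of each sample
#' is polyclonal background carrying distinct rearrangements.
#'
#' @param config A [simulation_config()].
#' @param lib A `germline_library`.
#' @return List with elements `diagnosis` and `relapse` (each a
#'   `clone_population` data.frame with clone id, abundance, rearrangement key,
#'   SHM `profile` list-column and full clone `sequence`) and `truth`, a
#'   `truth_record` holding the simulated mode and the major-clone profiles.
#' @export
simulate_tumor_pair <- function(config, lib) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  assert_fraction(config$shm_rate, "shm_rate")
  with_seed(derive_seed(config$seed, 11L), {
    rearr <- simulate_rearrangement(lib, config$trim_max, config$insert_max,
                                    seed = NULL)
    seq0 <- rearr$sequence
    ch0 <- strsplit(seq0, "", fixed = TRUE)[[1]]
    L <- length(ch0)
    rate <- config$shm_rate

    # Globally unique mutation positions: symmetric differences between
    # profiles then equal the sum of the branches' private mutation counts.
    pool <- sample.int(L)
    ptr <- 0L
    draw <- function(n) {
      if (n <= 0L) return(character(0))
      if (ptr + n > L) stop("SHM position pool exhausted", call. = FALSE)
      idx <- pool[(ptr + 1L):(ptr + n)]
      ptr <<- ptr + n
      format_mutations(idx, ch0[idx], other_base(ch0[idx]))
    }
    gen_muts <- function(generations) {
      if (rate <= 0 || generations <= 0L) return(0L)
      sum(vapply(seq_len(generations),
                 function(i) max(1L, stats::rpois(1L, rate * L)), 0L))
    }
    trunk <- draw(if (rate > 0) config$trunk_mutations else 0L)

    if (config$mode == "late_divergent") {
      diag_lineage <- draw(gen_muts(config$maturation_generations))
      diag_major <- c(trunk, diag_lineage)
      relapse_major <- c(diag_major,
                         draw(if (rate > 0) sample(1:2, 1L) else 0L))
      rel_lineage <- setdiff(relapse_major, trunk)
    } else {
      diag_lineage <- draw(gen_muts(config$divergence_depth))
      diag_major <- c(trunk, diag_lineage)
      rel_lineage <- draw(gen_muts(config$divergence_depth))
      relapse_major <- c(trunk, rel_lineage)
    }

    # Minor subclones: in the early-divergent mode they branch at random
    # depths of the major lineage (divergent, diverse subclonal structure);
    # in the late-divergent mode they are shallow 1-2 mutation variants of
    # the major clone (tight clustering around the major).
    deep_minors <- config$mode == "early_divergent"
    minor_profiles <- function(lineage, n) {
      lapply(seq_len(n), function(i) {
        b <- if (deep_minors) sample.int(length(lineage) + 1L, 1L) - 1L
             else length(lineage)
        extra <- draw(gen_muts(if (rate > 0) sample(1:2, 1L) else 0L))
        c(trunk, lineage[seq_len(b)], extra)
      })
    }
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

    tumor_share <- 1 - config$background_fraction
    build_sample <- function(sample_label, major_profile, major_mean,
                             planted = list()) {
      n_sc <- config$n_subclones
      profs <- minor_profiles(setdiff(major_profile, trunk), n_sc)
      major_f <- clamp(stats::rnorm(1L, major_mean, 0.05), 0.15, 0.90)
      planted_f <- sum(vapply(planted, `[[`, 0, "freq"))
      w <- stats::rgamma(n_sc, shape = 2)
      minor_f <- w / sum(w) * max(0, 1 - major_f - planted_f)
      ids <- c(sprintf("%s_major", sample_label),
               sprintf("%s_sc%02d", sample_label, seq_len(n_sc)),
               vapply(planted, `[[`, "", "id"))
      profiles <- c(list(major_profile), profs,
                    lapply(planted, `[[`, "profile"))
      ab <- c(major_f, minor_f, vapply(planted, `[[`, 0, "freq"))
      data.frame(id = ids, abundance = ab * tumor_share,
                 v_id = rearr$v_id, d_id = rearr$d_id, j_id = rearr$j_id,
                 is_background = FALSE,
                 profile = I(profiles), stringsAsFactors = FALSE)
    }

    planted_d <- list()
    planted_r <- list()
    if (config$mode == "early_divergent") {
      planted_d <- list(list(id = "D_precursor", profile = relapse_major,
                             freq = config$precursor_freq))
      planted_r <- list(list(id = "R_residual", profile = diag_major,
                             freq = config$residual_freq))
    } else {
      planted_r <- list(list(
        id = "R_retained", profile = diag_major,
        freq = clamp(stats::rnorm(1L, config$retention_freq, 0.05),
                     0.10, 0.50)))
    }
    major_mean_d <- if (config$mode == "early_divergent")
      config$major_freq_early else config$major_freq_late
    diag_tumor <- build_sample("D", diag_major, major_mean_d, planted_d)
    rel_tumor <- build_sample("R", relapse_major, 0.50, planted_r)

    # Polyclonal background: normal B cells with their own rearrangements.
    background <- function(sample_label) {
      if (config$background_fraction <= 0 || config$n_background < 1L)
        return(NULL)
      nb <- config$n_background
      rows <- lapply(seq_len(nb), function(i) {
        for (try in 1:25) {
          rr <- simulate_rearrangement(lib, config$trim_max,
                                       config$insert_max, seed = NULL)
          if (!(rr$v_id == rearr$v_id && rr$d_id == rearr$d_id &&
                rr$j_id == rearr$j_id)) break
        }
        data.frame(id = sprintf("%s_bg%02d", sample_label, i),
                   abundance = NA_real_, v_id = rr$v_id, d_id = rr$d_id,
                   j_id = rr$j_id, is_background = TRUE,
                   profile = I(list(character(0))),
                   sequence_ = rr$sequence, stringsAsFactors = FALSE)
      })
      bg <- do.call(rbind, rows)
      w <- stats::rgamma(nb, shape = 1)
      bg$abundance <- w / sum(w) * config$background_fraction
      bg
    }

    finish <- function(tumor, sample_label) {
      tumor$sequence <- vapply(tumor$profile, function(p)
        apply_profile(seq0, p), "")
      bg <- background(sample_label)
      if (!is.null(bg)) {
        bg$sequence <- bg$sequence_
        bg$sequence_ <- NULL
        tumor <- rbind(tumor, bg)
      }
      tumor$abundance <- tumor$abundance / sum(tumor$abundance)
      tumor$sample <- if (sample_label == "D") "diagnosis" else "relapse"
      rownames(tumor) <- NULL
      structure(tumor, class = c("clone_population", "data.frame"),
                rearrangement = rearr,
                sample = tumor$sample[1])
    }

    truth <- structure(
      list(mode = config$mode,
           diag_major_id = "D_major", relapse_major_id = "R_major",
           diag_major_profile = sort_profile(diag_major),
           relapse_major_profile = sort_profile(relapse_major),
           precursor_id = if (config$mode == "early_divergent") "D_precursor"
                          else NA_character_,
           rearrangement = rearr),
      class = "truth_record")

    list(diagnosis = finish(diag_tumor, "D"),
         relapse = finish(rel_tumor, "R"),
         truth = truth)
  })
}

sort_profile <- function(p) {
  if (length(p) == 0L) return(character(0))
  p[order(as.integer(sub(":.*$", "", p)))]
}

#' Subclone table directly from a clone population
#'
#' Draws per-clone read counts from a multinomial over clone abundances
#' (emulating amplicon sampling at a given depth), restricts to the dominant
#' rearrangement and applies the standard subclone filters via
#' [build_subclone_table()]. This is the read-free path used to study the
#' subclone statistics of simulated populations at scale.
#'
#' @param pop A `clone_population`.
#' @param n_reads Total reads sampled across the population.
#' @param seed Integer seed.
#' @param min_count,min_identity Subclone filters (see
#'   [build_subclone_table()]).
#' @return A `subclone_table`.
#' @export
population_subclone_table <- function(pop, n_reads = 20000L, seed = 1L,
                                      min_count = 10L, min_identity = 0.80) {
  rearr <- attr(pop, "rearrangement")
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n_reads, pop$abundance))
    keep <- !pop$is_background & counts > 0L
    build_subclone_table(
      profiles = pop$profile[keep], counts = counts[keep],
      ref_len = nchar(rearr$sequence),
      min_count = min_count, min_identity = min_identity,
      sample_id = attr(pop, "sample"),
      key = c(rearr$v_id, rearr$d_id, rearr$j_id))
  })
}

#' @export
print.clone_population <- function(x, ...) {
  cat(sprintf("clone_population (%s): %d clones (%d tumor, %d background)\n",
              attr(x, "sample"), nrow(x), sum(!x$is_background),
              sum(x$is_background)))
  invisible(x)
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth_record: mode=%s; majors %s (%d SHM) / %s (%d SHM)\n",
              x$mode, x$diag_major_id, length(x$diag_major_profile),
              x$relapse_major_id, length(x$relapse_major_profile)))
  invisible(x)
}
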