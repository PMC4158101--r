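test_that("overlapping pairs merge to the template; disjoint or random mates do not", {
  # 280 nt template, 150 nt mates -> 20 nt true overlap
  tmpl <- with_seed_chars(280, seed = 8)
  m1 <- substr(tmpl, 1, 150)
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(tmpl, 131, 280))))
  mg <- merge_read_pair(m1, m2, min_overlap = 20)
  expect_true(mg$merged)
  expect_identical(mg$sequence, tmpl)
  expect_equal(nchar(mg$sequence), 150 + 150 - mg$overlap)

  rnd <- merge_read_pair(with_seed_chars(150, 1), with_seed_chars(150, 2))
  expect_false(rnd$merged)

  # one disagreement in a 20 nt overlap passes identity 0.9 (19/20 = 0.95)
  m2x <- m2
  substr(m2x, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                   substr(m2, 150, 150))[1]
  mgx <- merge_read_pair(m1, m2x, min_overlap = 20,
                         min_overlap_identity = 0.9)
  expect_true(mgx$merged)
  expect_equal(mgx$identity, 0.95)
})

test_that("error-free reads recover their true rearrangement; corrupted or random reads are filtered", {
  lib <- fixture_library()
  idx <- build_kmer_index(lib)
  cfg <- simulation_config(seed = 2, mode = "late_divergent",
                           background_fraction = 0.5)
  sim <- simulate_tumor_pair(cfg, lib)
  reads <- simulate_reads(sim$diagnosis, 600, error_rate = 0, seed = 3)
  ann <- annotate_sample(reads, idx)
  merged <- merge(ann$reads,
                  data.frame(read_id = reads$id, source = reads$source),
                  by = "read_id")
  truth_key <- setNames(
    paste(sim$diagnosis$v_id, sim$diagnosis$d_id, sim$diagnosis$j_id),
    sim$diagnosis$id)
  got_key <- paste(merged$v_id, merged$d_id, merged$j_id)
  expect_gt(nrow(merged) / length(reads$id), 0.9)
  expect_true(all(got_key == truth_key[merged$source]))

  # a read truncated before the J segment fails the triple-hit filter
  full <- sim$diagnosis$sequence[1]
  trunc <- substr(full, 1, nchar(full) - 80)
  expect_null(annotate_read(trunc, idx))

  # uniform-random sequences essentially never survive the triple-hit filter
  rand <- vapply(1:2000, function(s) with_seed_chars(300, seed = 1000 + s),
                 "")
  n_ann <- sum(!vapply(rand, function(s) is.null(annotate_read(s, idx)),
                       TRUE))
  expect_lte(n_ann, 1)
})

test_that("annotation recovers the true triple at scale, with and without sequencing error", {
  lib <- fixture_library(seed = 4)
  idx <- build_kmer_index(lib)
  cfg <- simulation_config(seed = 9, mode = "early_divergent",
                           n_subclones = 12L)
  sim <- simulate_tumor_pair(cfg, lib)

  check_recovery <- function(error_rate, n, min_acc) {
    reads <- simulate_reads(sim$diagnosis, n, error_rate = error_rate,
                            seed = 31)
    ann <- annotate_sample(reads, idx)
    src_key <- setNames(
      paste(sim$diagnosis$v_id, sim$diagnosis$d_id, sim$diagnosis$j_id),
      sim$diagnosis$id)
    src <- setNames(reads$source, reads$id)
    got <- paste(ann$reads$v_id, ann$reads$d_id, ann$reads$j_id)
    acc <- mean(got == src_key[src[ann$reads$read_id]])
    expect_gte(acc, min_acc)
  }
  check_recovery(0, 5000, 0.999)
  check_recovery(0.01, 5000, 0.99)
})

test_that("raising a class score minimum never increases annotated reads, and counts are conserved", {
  lib <- fixture_library()
  idx <- build_kmer_index(lib)
  sim <- simulate_tumor_pair(simulation_config(seed = 6), lib)
  reads <- simulate_reads(sim$diagnosis, 800, seed = 7)
  base <- annotate_sample(reads, idx)
  stricter <- annotate_sample(reads, idx,
                              min_score = c(V = 80, D = 12, J = 30))
  expect_lte(nrow(stricter$reads), nrow(base$reads))
  tab <- count_rearrangements(base, "s")
  expect_equal(sum(tab$counts$count), nrow(base$reads))
  expect_equal(tab$total_mapped, nrow(base$reads))
})
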