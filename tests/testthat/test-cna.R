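test_that("exon simulation hits its configured segment means and is deterministic", {
  cfg <- simulation_config(seed = 5, n_exons = 100L, exon_depth = 20000L,
                           dispersion = 0.02,
                           exon_segments = data.frame(start = 40L, end = 60L,
                                                      shift = 1))
  a <- simulate_exon_counts(cfg)
  b <- simulate_exon_counts(cfg)
  expect_identical(a$rel_reads, b$rel_reads)
  expect_equal(mean(a$log2_ratio[40:60]), 1, tolerance = 0.1)
  expect_equal(mean(a$log2_ratio[-(40:60)]), 0, tolerance = 0.1)

  flat <- simulate_exon_counts(simulation_config(
    seed = 2, exon_depth = 20000L, dispersion = 1e-4,
    exon_segments = data.frame(start = integer(0), end = integer(0),
                               shift = numeric(0))))
  expect_lt(max(abs(flat$log2_ratio)), 0.05)

  expect_error(simulate_exon_counts(simulation_config(
    seed = 1, exon_segments = data.frame(start = c(10L, 15L),
                                         end = c(20L, 25L),
                                         shift = c(1, -1)))),
    "overlap")
})

test_that("smoothing drops low-coverage exons (strict >100) and shrinks spikes", {
  n <- 41L
  exons <- data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * 10L,
                      end = seq_len(n) * 10L,
                      diag_reads = 100L, rel_reads = 100L,
                      log2_ratio = 0, stringsAsFactors = FALSE)
  exons$log2_ratio[21] <- 3       # spike in a flat profile
  exons$diag_reads[5] <- 50L      # total exactly 100 -> excluded
  exons$rel_reads[5] <- 50L
  sm <- smooth_log2(exons)
  expect_equal(nrow(sm), n - 1L)
  expect_false(40L %in% sm$start)  # exon 5 (total exactly 100) is gone
  spike <- sm$log2_smooth[sm$start == 200L]
  expect_equal(spike, 0)          # window MAD is 0 -> shrunk to the median

  mono <- data.frame(chrom = "chr1", start = 0:19 * 10L, end = 1:20 * 10L,
                     diag_reads = 200L, rel_reads = 200L,
                     log2_ratio = seq(0, 1.9, by = 0.1))
  sm2 <- smooth_log2(mono)
  expect_equal(sm2$log2_smooth, sm2$log2_ratio)  # monotone profile unchanged
})

test_that("CBS finds planted breakpoints, leaves constant profiles whole, and undoes weak splits", {
  set.seed(31)
  flat <- data.frame(chrom = "chr1", start = 0:99 * 10L, end = 1:100 * 10L,
                     diag_reads = 300L, rel_reads = 300L,
                     log2_ratio = rnorm(100, 0, 0.2))
  seg_flat <- segment_cna(flat, seed = 1)
  expect_equal(nrow(seg_flat), 1L)
  expect_equal(sum(seg_flat$n_exons), 100L)

  step <- flat
  step$log2_ratio[51:100] <- step$log2_ratio[51:100] + 1
  seg_step <- segment_cna(step, seed = 2)
  expect_equal(nrow(seg_step), 2L)
  expect_equal(sum(seg_step$n_exons), 100L)   # exons partition exactly
  expect_lte(abs(seg_step$n_exons[1] - 50L), 2L)
  expect_equal(seg_step$mean_log2[2] - seg_step$mean_log2[1], 1,
               tolerance = 0.15)

  # adjacent means 0 and 0.1 with residual sd 0.2: 0.1 < 1.5 * 0.2 -> merged
  weak <- flat
  weak$log2_ratio[51:100] <- weak$log2_ratio[51:100] + 0.1
  seg_weak <- segment_cna(weak, seed = 3)
  expect_equal(nrow(seg_weak), 1L)

  short <- flat[1:5, ]
  expect_warning(seg_short <- segment_cna(short, seed = 4), "single segment")
  expect_equal(nrow(seg_short), 1L)
})

test_that("segment classification applies strict +/-0.3 thresholds", {
  segs <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30, 40),
                     end = c(10, 20, 30, 40, 50), n_exons = 1L,
                     mean_log2 = c(0.35, -0.35, 0.30, -0.30, 0))
  cls <- classify_segments(segs)$class
  expect_equal(cls, c("gain", "loss", "neutral", "neutral", "neutral"))
})

test_that("common deleted regions come from a >=k-sample coordinate sweep", {
  losses <- data.frame(
    sample = c("s1", "s2", "s3"), chrom = "chr1",
    start = c(100L, 150L, 120L), end = c(200L, 250L, 220L),
    stringsAsFactors = FALSE)
  cdr <- common_deleted_regions(losses, min_samples = 3)
  expect_equal(nrow(cdr), 1L)
  expect_equal(cdr$start, 150L)
  expect_equal(cdr$end, 200L)
  expect_equal(cdr$n_samples, 3L)
  expect_equal(cdr$region_1based, "151-200")

  expect_equal(nrow(common_deleted_regions(losses[1:2, ], 3)), 0L)
  disjoint <- data.frame(sample = c("s1", "s2", "s3"), chrom = "chr1",
                         start = c(0L, 300L, 600L), end = c(100L, 400L, 700L))
  expect_equal(nrow(common_deleted_regions(disjoint, 3)), 0L)
})
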