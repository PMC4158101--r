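test_that("allele frequencies are exact ratios that sum to one", {
  pu <- data.frame(amplicon = "amp1", pos = 1L, A = 160L, C = 99640L,
                   G = 100L, T = 100L, del = 0L, ins = 0L, total = 100000L)
  expect_equal(allele_frequency(pu, 1, "A"), 0.0016)
  expect_equal(allele_frequency(pu, 1, "del"), 0)
  tot <- sum(vapply(c("A", "C", "G", "T", "del", "ins"),
                    function(al) allele_frequency(pu, 1, al), 0))
  expect_equal(tot, 1)
  pu0 <- pu; pu0$total <- 0L
  expect_error(allele_frequency(pu0, 1, "A"), "zero total")
  expect_error(allele_frequency(pu, 2, "A"), "not found")
})

test_that("background models reproduce hand-computed means and simulated rates", {
  mk <- function(freqs, depth = 1e6) {
    data.frame(amplicon = "amp1", pos = seq_along(freqs),
               A = as.integer(round(freqs * depth)), C = 0L, G = 0L, T = 0L,
               del = 0L, ins = 0L, total = as.integer(depth))
  }
  pu <- mk(c(3e-4, 3e-4, 3e-4))
  pu$C <- pu$total - pu$A
  bg <- estimate_background(pu, "C>A")
  expect_equal(bg$mean, 3e-4)
  expect_equal(bg$sd, 0)

  pu2 <- mk(c(2e-4, 4e-4))
  pu2$C <- pu2$total - pu2$A
  bg2 <- estimate_background(pu2, "C>A")
  expect_equal(bg2$mean, 3e-4)
  expect_error(estimate_background(pu2[1, ], "C>A"), "fewer than 2")

  sim <- simulate_amplicon_pileup(n_positions = 40, depth = 1e6,
                                  error_rate = 3e-4, target_pos = 15,
                                  clone_freq = 0, seed = 8)
  bg3 <- estimate_background(sim, "C>A", exclude_pos = 15)
  expect_lt(abs(bg3$mean - 3e-4) / 3e-4, 0.2)
})

test_that("the detection rule reproduces the worked examples", {
  bg_snv <- structure(list(class = "C>A", mean = 3e-4, sd = 3e-4,
                           n_positions = 10L), class = "background_model")
  # 0.16% against 0.03% +/- 0.03%: 0.0016 > 0.0003 + 3*0.0003
  expect_true(detect_minor_clone(0.0016, 3200, bg_snv)$detected)
  # 0.05% is below the 0.12% cutoff
  expect_false(detect_minor_clone(5e-4, 1000, bg_snv)$detected)
  bg_indel <- structure(list(class = "del", mean = 4e-5, sd = 1e-4,
                             n_positions = 10L), class = "background_model")
  # 0.04% against 0.004% +/- 0.010%: 0.0004 > 0.00004 + 3*0.0001
  expect_true(detect_minor_clone(4e-4, 800, bg_indel)$detected)
  # support below min_support blocks detection regardless of frequency
  expect_false(detect_minor_clone(0.01, 10, bg_snv)$detected)
  expect_error(detect_minor_clone(-0.1, 100, bg_snv), "non-negative")

  # zero-sd background: any frequency above the mean with support detects
  bg0 <- structure(list(class = "C>A", mean = 1e-4, sd = 0,
                        n_positions = 5L), class = "background_model")
  expect_true(detect_minor_clone(2e-4, 400, bg0)$detected)
  expect_false(detect_minor_clone(5e-5, 400, bg0)$detected)
})

test_that("detection is monotone in frequency and support", {
  bg <- structure(list(class = "C>A", mean = 3e-4, sd = 3e-4,
                       n_positions = 10L), class = "background_model")
  set.seed(4)
  for (t in 1:200) {
    f2 <- runif(1, 0, 0.005); f1 <- f2 + runif(1, 0, 0.005)
    s2 <- sample(0:100, 1); s1 <- s2 + sample(0:100, 1)
    d1 <- detect_minor_clone(f1, s1, bg)$detected
    d2 <- detect_minor_clone(f2, s2, bg)$detected
    expect_true(!d2 || d1)
  }
})

test_that("a planted 0.2% clone is recovered over background, absent clones are not", {
  hits <- 0L; false_hits <- 0L
  n <- 25L
  for (s in seq_len(n)) {
    with_clone <- simulate_amplicon_pileup(n_positions = 30, depth = 1e6,
                                           error_rate = 3e-4,
                                           target_pos = 15,
                                           clone_freq = 0.002, seed = s)
    bg <- estimate_background(with_clone, "C>A", exclude_pos = 15)
    f <- allele_frequency(with_clone, 15, "A")
    hits <- hits + detect_minor_clone(f, with_clone$A[15], bg)$detected
    no_clone <- simulate_amplicon_pileup(n_positions = 30, depth = 1e6,
                                         error_rate = 3e-4, target_pos = 15,
                                         clone_freq = 0, seed = 1000 + s)
    bg0 <- estimate_background(no_clone, "C>A", exclude_pos = 15)
    f0 <- allele_frequency(no_clone, 15, "A")
    false_hits <- false_hits +
      detect_minor_clone(f0, no_clone$A[15], bg0)$detected
  }
  expect_gte(hits / n, 0.95)
  expect_lte(false_hits / n, 0.05)
})

test_that("the detection limit is supporting reads over total reads, in percent", {
  expect_equal(detection_limit(2e6, 20), 0.001)
  expect_equal(detection_limit(1000, 20), 2)
  expect_equal(detection_limit(5000, 0), 0)
  expect_error(detection_limit(0, 20), "positive")
})

test_that("pileups round-trip through TSV and inconsistent counts are rejected", {
  pu <- simulate_amplicon_pileup(n_positions = 10, depth = 5000,
                                 seed = 3, clone_freq = 0.01)
  path <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pu, path)
  back <- read_pileup_tsv(path)
  expect_equal(back$A, pu$A)
  expect_equal(back$total, pu$total)
  bad <- pu; bad$A[2] <- bad$A[2] + 5L
  badpath <- tempfile(fileext = ".tsv")
  write_pileup_tsv(bad, badpath)
  expect_error(read_pileup_tsv(badpath), "row 2")
})
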