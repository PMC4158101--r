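test_that("variant filters honour the depth/VAF boundaries and annotation flags", {
  sites <- data.frame(
    chrom = "chr1", pos = 1:5, ref = "C", alt = "A",
    d_ref = c(15L, 45L, 40L, 30L, 30L),
    d_alt = c(4L,  14L, 20L, 30L, 30L),
    r_ref = c(14L, 45L, 10L, 30L, 30L),
    r_alt = c(5L,  14L, 10L, 30L, 30L),
    known = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    in_cna = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  kept <- filter_variants(sites)
  # site 1: depth 19 in both samples -> removed
  # site 2: VAF 14/59 = 0.237 in both -> removed
  # site 3: VAF 0.333/0.5, depth 60/20 -> kept
  # sites 4, 5: flagged known / in-CNA -> removed
  expect_equal(kept$pos, 3L)
  lax <- filter_variants(sites, drop_known = FALSE, drop_cna = FALSE)
  expect_setequal(lax$pos, c(3L, 4L, 5L))
})

test_that("the 2x2 tests match hand calculations and brute-force oracles", {
  expect_equal(gain_loss_test(30, 30, 30, 30), 1)
  # (0 alt / 60 ref) vs (30 alt / 30 ref): chi-square statistic 40 on 1 df
  p <- gain_loss_test(60, 0, 30, 30)
  expect_equal(p, pchisq(40, 1, lower.tail = FALSE))
  expect_equal(gain_loss_test(60, 0, 30, 30, method = "fisher"),
               oracle_fisher_2x2(matrix(c(60, 0, 30, 30), 2, byrow = TRUE)))
  expect_error(gain_loss_test(0, 0, 0, 0), "zero")

  set.seed(17)
  for (t in 1:300) {
    m <- matrix(rpois(4, sample(c(3, 20, 80), 1)), 2)
    if (sum(m) == 0) next
    expect_equal(gain_loss_test(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 oracle_chisq_2x2(m), tolerance = 1e-12)
    if (sum(m) <= 120)
      expect_equal(gain_loss_test(m[1, 1], m[1, 2], m[2, 1], m[2, 2],
                                  method = "fisher"),
                   oracle_fisher_2x2(m), tolerance = 1e-12)
  }
})

test_that("BH step-up flags match the definition and are monotone in q", {
  res <- bh_adjust(c(0.01, 0.02, 0.04, 0.8), q = 0.1)
  expect_equal(sum(res$significant), 3L)
  expect_equal(bh_adjust(rep(1, 10), 0.1)$significant, rep(FALSE, 10))
  expect_true(bh_adjust(0.05, 0.1)$significant)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(23)
  for (t in 1:50) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p, 0.1)$significant, oracle_bh_flags(p, 0.1))
    n_strict <- sum(bh_adjust(p, 0.05)$significant)
    n_loose <- sum(bh_adjust(p, 0.2)$significant)
    expect_lte(n_strict, n_loose)
  }
})

test_that("gained/lost classification recovers the simulated truth ratio", {
  cfg <- simulation_config(seed = 12, n_sites = 50L,
                           frac_gained = 0.8, frac_lost = 0.2,
                           exome_depth = 200L, frac_known = 0)
  tab <- simulate_variant_table(cfg)
  truth <- attr(tab, "truth")
  expect_equal(length(truth$gained), 40L)
  expect_equal(length(truth$lost), 10L)
  calls <- classify_variants(filter_variants(tab))
  expect_lte(abs(calls$n_gained - 40), 1)
  expect_lte(abs(calls$n_lost - 10), 1)
  expect_equal(calls$ratio, calls$n_gained / calls$n_lost)

  # no significant site: counts zero, ratio undefined
  null_sites <- data.frame(chrom = "chr1", pos = 1:4, ref = "C", alt = "T",
                           d_ref = 30L, d_alt = 30L, r_ref = 30L,
                           r_alt = 30L, stringsAsFactors = FALSE)
  null_calls <- classify_variants(null_sites)
  expect_equal(null_calls$n_gained, 0L)
  expect_equal(null_calls$n_lost, 0L)
  expect_true(is.na(null_calls$ratio))

  expect_error(simulate_variant_table(
    simulation_config(seed = 1, frac_gained = 0.7, frac_lost = 0.5)),
    "<= 1")
})

test_that("variant tables round-trip through TSV", {
  cfg <- simulation_config(seed = 3, n_sites = 30L)
  tab <- simulate_variant_table(cfg)
  path <- tempfile(fileext = ".tsv")
  write_variant_tsv(tab, path)
  back <- read_variant_tsv(path)
  expect_equal(back$pos, tab$pos)
  expect_equal(back$d_alt, tab$d_alt)
  expect_equal(back$known, tab$known)
})
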