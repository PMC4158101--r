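test_that("SHM profiles are called exactly from planted mutations", {
  lib <- fixture_short_library()
  r <- simulate_rearrangement(lib, seed = 2)
  idx <- build_kmer_index(lib)

  ann0 <- annotate_read(r$sequence, idx)
  expect_identical(call_shm_profile(ann0, r), character(0))

  mutated <- r$sequence
  ref57 <- substr(mutated, 57, 57)
  alt57 <- setdiff(c("A", "C", "G", "T"), ref57)[1]
  substr(mutated, 57, 57) <- alt57
  ann1 <- annotate_read(mutated, idx)
  expect_identical(call_shm_profile(ann1, r),
                   sprintf("57:%s>%s", ref57, alt57))

  # clone with 8 SHM in the V region, error-free read: profile equals the
  # clone's SHM set
  set.seed(41)
  ch <- strsplit(r$sequence, "")[[1]]
  pos <- sort(sample(seq_len(120), 8))
  alt <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  truth <- sprintf("%d:%s>%s", pos, ch[pos], alt)
  ch[pos] <- alt
  ann8 <- annotate_read(paste(ch, collapse = ""), idx)
  expect_setequal(call_shm_profile(ann8, r), truth)

  # key mismatch is an argument error
  other <- simulate_rearrangement(lib, seed = 99)
  if (!identical(c(other$v_id, other$d_id, other$j_id),
                 c(r$v_id, r$d_id, r$j_id)))
    expect_error(call_shm_profile(ann0, other), "key")
})

test_that("subclone filters are inclusive at both boundaries and idempotent", {
  ref_len <- 100L
  prof_of <- function(n) sprintf("%d:A>G", seq_len(n))
  profiles <- list(prof_of(2), prof_of(3), prof_of(21), prof_of(20))
  counts <- c(50L, 9L, 50L, 10L)
  tab <- build_subclone_table(profiles, counts, ref_len)
  # count 9 excluded; identity 0.79 (21 mutations) excluded;
  # count 10 at identity 0.80 (20 mutations) included
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$n_mutations, c(2L, 20L))
  expect_equal(sum(tab$frequency), 1)

  again <- build_subclone_table(tab$mutations, tab$count, ref_len)
  expect_equal(again$profile, tab$profile)
  expect_equal(again$frequency, tab$frequency)

  none <- build_subclone_table(profiles, c(1L, 1L, 1L, 1L), ref_len)
  expect_equal(nrow(none), 0L)
})

test_that("entropy matches closed forms and its bounds", {
  mk <- function(counts) {
    build_subclone_table(lapply(seq_along(counts), function(i)
      sprintf("%d:A>C", i)), counts, 1000L, min_count = 1L)
  }
  expect_equal(empirical_entropy(mk(100L)), 0)
  expect_equal(empirical_entropy(mk(rep(25L, 4))), 2)
  expect_equal(empirical_entropy(mk(c(50L, 25L, 25L))), 1.5)
  for (s in 1:10) {
    set.seed(s)
    k <- sample(2:12, 1)
    tab <- mk(sample(10:99, k))
    h <- empirical_entropy(tab)
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
  }
  expect_error(empirical_entropy(mk(integer(0))), "empty")
})

test_that("mutational distance is the symmetric difference and a metric", {
  a <- c("1:A>C", "2:G>T")
  b <- c("2:G>T", "9:C>A")
  expect_equal(mutational_distance(a, a), 0)
  expect_equal(mutational_distance(a, b), 2)
  expect_equal(mutational_distance(c("1:A>C", "2:G>T"),
                                   c("5:A>C", "6:G>T", "7:C>G")), 5)
  set.seed(99)
  pool <- sprintf("%d:A>G", 1:40)
  profs <- lapply(1:30, function(i) sample(pool, sample(0:12, 1)))
  for (t in 1:60) {
    ijk <- sample(30, 3, replace = TRUE)
    x <- profs[[ijk[1]]]; y <- profs[[ijk[2]]]; z <- profs[[ijk[3]]]
    expect_equal(mutational_distance(x, y), mutational_distance(y, x))
    expect_lte(mutational_distance(x, z),
               mutational_distance(x, y) + mutational_distance(y, z))
    expect_true((mutational_distance(x, y) == 0) == setequal(x, y))
  }
})

test_that("major-clone fate and the distance spectrum follow their definitions", {
  mk <- function(profiles, counts)
    build_subclone_table(profiles, counts, 1000L, min_count = 1L)
  diag <- mk(list(c("1:A>C", "2:G>T"), "9:C>A"), c(70L, 30L))
  rel_absent <- mk(list("5:T>G"), 100L)
  expect_equal(major_clone_fate(diag, rel_absent), 0)
  rel_part <- mk(list(c("1:A>C", "2:G>T"), "5:T>G"), c(300L, 700L))
  expect_equal(major_clone_fate(diag, rel_part), 0.3)
  expect_error(major_clone_fate(mk(list(), integer(0)), rel_part), "empty")

  spec0 <- distance_spectrum(mk(list(c("1:A>C", "2:G>T")), 50L),
                             diag_major = c("1:A>C", "2:G>T"))
  expect_equal(spec0, setNames(1, "0"))
  spec <- distance_spectrum(rel_part, major_profile(diag))
  expect_equal(sum(spec), 1)
  expect_equal(unname(spec["3"]), 0.7)
})

test_that("simulated relapse mass sits near the diagnosis major under the late mode and far under the early mode", {
  late <- fixture_pair_tables(21, "late_divergent")
  sp_late <- distance_spectrum(late$relapse, major_profile(late$diag))
  mass_near <- sum(sp_late[as.integer(names(sp_late)) <= 2])
  expect_gte(mass_near, 0.9)

  early <- fixture_pair_tables(22, "early_divergent")
  sp_early <- distance_spectrum(early$relapse, major_profile(early$diag))
  modal <- as.integer(names(sp_early))[which.max(sp_early)]
  expect_gte(modal, 5)
})

test_that("subclone tables round-trip through TSV", {
  tab <- build_subclone_table(
    list(character(0), c("3:A>C", "8:G>A"), "12:T>G"),
    c(500L, 60L, 12L), 300L)
  path <- tempfile(fileext = ".tsv")
  write_subclone_tsv(tab, path)
  back <- read_subclone_tsv(path, ref_len = 300L)
  expect_equal(back$profile, tab$profile)
  expect_equal(back$count, tab$count)
  expect_equal(back$frequency, tab$frequency)
  expect_equal(back$identity, tab$identity)
})
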