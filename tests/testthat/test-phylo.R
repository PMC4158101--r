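test_that("subclone selection saturates small tables, is deterministic and keeps the majors", {
  tabs <- fixture_pair_tables(31, "early_divergent")
  sel <- select_tree_subclones(tabs$diag, tabs$relapse, seed = 5)
  # small tables: every subclone selected once, plus the germline outgroup
  expect_equal(nrow(sel), nrow(tabs$diag) + nrow(tabs$relapse) + 1L)
  expect_false(anyDuplicated(sel$label) > 0)
  expect_equal(sum(sel$is_major & sel$sample == "diagnosis"), 1L)
  expect_equal(sum(sel$is_major & sel$sample == "relapse"), 1L)
  expect_true("GL" %in% sel$label)

  sel2 <- select_tree_subclones(tabs$diag, tabs$relapse, seed = 5)
  expect_identical(sel$label, sel2$label)
  expect_error(select_tree_subclones(tabs$diag[0, ], tabs$relapse),
               "non-empty")
})

test_that("distance matrices are symmetric metrics with zero diagonal", {
  tabs <- fixture_pair_tables(32, "late_divergent")
  sel <- select_tree_subclones(tabs$diag, tabs$relapse, seed = 1)
  m <- pairwise_distance_matrix(sel)
  expect_true(all(diag(m) == 0))
  expect_identical(m, t(m))
  n <- nrow(m)
  for (t in 1:100) {
    ijk <- sample(n, 3)
    expect_lte(m[ijk[1], ijk[3]], m[ijk[1], ijk[2]] + m[ijk[2], ijk[3]])
  }
})

test_that("neighbor joining reproduces the three-taxon closed form", {
  m <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tree <- neighbor_joining(m)
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(bl["A"]), 1)
  expect_equal(unname(bl["B"]), 1)
  expect_equal(unname(bl["C"]), 3)
  expect_error(neighbor_joining(m[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive quartets and quintets exactly", {
  skip_if_not_installed("phangorn")
  # 4-taxon tree ((A,B),(C,D)) with unit branches
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d4 <- tree_distance_matrix(ape::unroot(t4))
  nj4 <- neighbor_joining(d4)
  expect_equal(topo_key(nj4), topo_key(t4))
  expect_equal(tree_distance_matrix(nj4)[rownames(d4), colnames(d4)], d4)

  # 20 random additive 5-taxon matrices: NJ finds the unique fitting
  # topology among all 15, with exact branch lengths
  topos <- oracle_all_quintet_topologies(LETTERS[1:5])
  expect_equal(length(topos), 15L)
  set.seed(7)
  for (rep in 1:20) {
    gen <- topos[[sample(15, 1)]]
    gen$edge.length <- round(runif(nrow(gen$edge), 0.5, 3), 2)
    d <- tree_distance_matrix(gen)
    njt <- neighbor_joining(d)
    expect_equal(topo_key(njt), topo_key(gen))
    expect_equal(tree_distance_matrix(njt)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    # oracle cross-check: the generating topology is the only perfect fit
    rss <- vapply(topos, topology_fit_rss, 0, d = d)
    fits <- which(rss < 1e-9)
    expect_equal(topo_key(topos[[fits]]), topo_key(gen))
  }
})

test_that("identical majors are late-divergent and classification is label-order invariant", {
  tabs <- fixture_pair_tables(33, "late_divergent")
  res <- analyze_pair(tabs$diag, tabs$relapse, seed = 2)
  expect_equal(res$call$mode, "late_divergent")
  expect_lte(res$call$distance, 2)

  # degenerate: relapse major profile equals the diagnosis major
  mk <- function(profiles, counts)
    build_subclone_table(profiles, counts, 1000L, min_count = 1L)
  shared <- list(c("1:A>C", "2:G>T", "3:C>A"), c("1:A>C", "2:G>T"),
                 "9:C>A")
  d <- mk(shared, c(500L, 100L, 50L))
  r <- mk(shared, c(400L, 150L, 60L))
  res0 <- analyze_pair(d, r, seed = 1)
  expect_equal(res0$call$mode, "late_divergent")
  expect_equal(res0$call$distance, 0)

  # permutation invariance of the matrix input
  sel <- select_tree_subclones(tabs$diag, tabs$relapse, seed = 9)
  m <- pairwise_distance_matrix(sel)
  perm <- sample(nrow(m))
  tree_a <- ape::root(neighbor_joining(m), "GL", resolve.root = TRUE)
  tree_b <- ape::root(neighbor_joining(m[perm, perm]), "GL",
                      resolve.root = TRUE)
  call_a <- classify_divergence(tree_a, sel)
  call_b <- classify_divergence(tree_b, sel)
  expect_identical(call_a$mode, call_b$mode)
})

test_that("divergence classification recovers the simulated mode", {
  hits <- 0L
  n <- 12L
  for (s in seq_len(n)) {
    mode <- if (s %% 2 == 0) "early_divergent" else "late_divergent"
    tabs <- fixture_pair_tables(300 + s, mode)
    res <- analyze_pair(tabs$diag, tabs$relapse, seed = s)
    hits <- hits + (res$call$mode == tabs$truth$mode)
  }
  expect_gte(hits / n, 0.9)
})

test_that("trees round-trip through Newick with branch lengths", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(m)
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_equal(tree_distance_matrix(back), tree_distance_matrix(tree))
  expect_error(read_newick(tempfile()), "")
})
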