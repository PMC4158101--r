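# Independent brute-force oracles, deliberately coded without reference to
# the package implementation.

# Pearson chi-square p-value on a 2x2 table, from first principles.
oracle_chisq_2x2 <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) return(1)  # no-signal convention
  e <- outer(rs, cs) / n
  stat <- sum((m - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Two-sided Fisher exact p-value by exhaustive hypergeometric enumeration.
oracle_fisher_2x2 <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) return(1)
  lo <- max(0L, cs[1] - rs[2])
  hi <- min(rs[1], cs[1])
  support <- lo:hi
  logp <- lchoose(rs[1], support) + lchoose(rs[2], cs[1] - support) -
    lchoose(n, cs[1])
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[support == m[1, 1]]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# BH step-up flags, coded directly from the definition.
oracle_bh_flags <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- ps <= (seq_len(m) / m) * q
  flags <- logical(m)
  if (any(ok)) flags[o[seq_len(max(which(ok)))]] <- TRUE
  flags
}

# All 15 labelled unrooted topologies on 5 tips, as ape trees.
oracle_all_quintet_topologies <- function(tips) {
  stopifnot(length(tips) == 5)
  out <- list()
  # unrooted 5-taxon trees correspond to placing tip 5 on any of the 5 edges
  # adjacent to tips, or the 2 internal edges, of each of the 3 quartets;
  # simpler: enumerate via ape by adding tips sequentially on every edge
  base <- ape::read.tree(text = sprintf("(%s,%s,%s);", tips[1], tips[2],
                                        tips[3]))
  base$edge.length <- rep(1, nrow(base$edge))
  grow <- function(tree, tip) {
    res <- list()
    for (e in seq_len(nrow(tree$edge))) {
      res[[length(res) + 1L]] <-
        suppressWarnings(ape::bind.tree(
          tree,
          structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = tip, edge.length = 1, Nnode = 1L),
                    class = "phylo"),
          where = tree$edge[e, 2L], position = 0.5))
    }
    res
  }
  t4 <- grow(base, tips[4])
  for (t in t4) {
    t$edge.length <- rep(1, nrow(t$edge))
    for (t5 in grow(t, tips[5])) out[[length(out) + 1L]] <- t5
  }
  # deduplicate by unrooted topology
  seen <- character(0)
  uniq <- list()
  for (t in out) {
    key <- paste(sort(attr(ape::prop.part(ape::unroot(t)), "labels")),
                 collapse = "")
    split_key <- topo_key(ape::unroot(t))
    if (!split_key %in% seen) {
      seen <- c(seen, split_key)
      uniq[[length(uniq) + 1L]] <- ape::unroot(t)
    }
  }
  uniq
}

# canonical key of an unrooted topology: sorted non-trivial bipartitions
topo_key <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(idx) {
    side <- sort(labs[idx])
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) return(NA_character_)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    paste(sort(c(a, b)), collapse = "|")
  }, "")
  paste(sort(unique(keys[!is.na(keys)])), collapse = ";")
}

# least-squares branch lengths of a fixed topology for a distance matrix;
# returns the fit residual (0 for the generating topology of additive data)
topology_fit_rss <- function(tree, d) {
  tips <- rownames(d)
  n <- length(tips)
  pairs <- utils::combn(n, 2)
  tree <- ape::unroot(tree)
  ne <- nrow(tree$edge)
  # path indicator matrix via node paths from a common traversal
  paths <- ape::nodepath(tree)
  A <- matrix(0, ncol(pairs), ne)
  y <- numeric(ncol(pairs))
  tipidx <- match(tips, tree$tip.label)
  for (p in seq_len(ncol(pairs))) {
    i <- tipidx[pairs[1, p]]
    j <- tipidx[pairs[2, p]]
    np <- ape::nodepath(tree, i, j)
    eidx <- vapply(seq_len(length(np) - 1L), function(s) {
      which((tree$edge[, 1] == np[s] & tree$edge[, 2] == np[s + 1]) |
            (tree$edge[, 2] == np[s] & tree$edge[, 1] == np[s + 1]))
    }, 0L)
    A[p, eidx] <- 1
    y[p] <- d[pairs[1, p], pairs[2, p]]
  }
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

# additive distance matrix of a tree with branch lengths
tree_distance_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[sort(rownames(d)), sort(colnames(d))]
}
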