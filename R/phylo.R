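# Neighbor-joining trees over subclone SHM profiles and the early- vs
# late-divergent classification of a diagnosis-relapse pair.

#' Select subclones for tree building
#'
#' From each sample's subclone table, takes (i) the `top_k` subclones ranked
#' by similarity (Jaccard index of mutation sets) to the *other* sample's
#' major profile, (ii) the `top_k` most abundant subclones, and (iii)
#' `n_random` additional minor subclones drawn uniformly; duplicates are kept
#' once. The germline (empty) profile is appended as an outgroup leaf `GL`.
#'
#' @param diag,relapse Non-empty `subclone_table`s on the same rearrangement.
#' @param top_k Rank depth for the similarity and abundance selections.
#' @param n_random Number of random minor subclones per sample.
#' @param seed Integer seed for the random selection.
#' @return A `tree_selection` data.frame: `label`, `sample`, `profile`,
#'   `count`, `frequency`, `is_major` and a `mutations` list-column.
#' @export
select_tree_subclones <- function(diag, relapse, top_k = 10L, n_random = 5L,
                                  seed = 1L) {
  if (nrow(diag) == 0L || nrow(relapse) == 0L)
    stop("both subclone tables must be non-empty", call. = FALSE)
  jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) 1 else length(intersect(a, b)) / u
  }
  pick_sample <- function(tab, other_major, prefix) {
    sim <- vapply(tab$mutations, jaccard, 0, b = other_major)
    ord_sim <- order(-sim, -tab$count, tab$profile)
    ord_ab <- order(-tab$count, tab$profile)
    chosen <- union(ord_sim[seq_len(min(top_k, nrow(tab)))],
                    ord_ab[seq_len(min(top_k, nrow(tab)))])
    remaining <- setdiff(seq_len(nrow(tab)), chosen)
    if (length(remaining) && n_random > 0L) {
      extra <- remaining[sample.int(length(remaining),
                                    min(n_random, length(remaining)))]
      chosen <- c(chosen, extra)
    }
    chosen <- sort(chosen)
    data.frame(label = sprintf("%s%02d", prefix, chosen),
               sample = if (prefix == "D") "diagnosis" else "relapse",
               profile = tab$profile[chosen],
               count = tab$count[chosen],
               frequency = tab$frequency[chosen],
               is_major = chosen == 1L,
               mutations = I(tab$mutations[chosen]),
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    sel <- rbind(pick_sample(diag, major_profile(relapse), "D"),
                 pick_sample(relapse, major_profile(diag), "R"))
    gl <- data.frame(label = "GL", sample = "germline", profile = "",
                     count = 0L, frequency = 0, is_major = FALSE,
                     mutations = I(list(character(0))),
                     stringsAsFactors = FALSE)
    out <- rbind(sel, gl)
    rownames(out) <- NULL
    structure(out, class = c("tree_selection", "data.frame"))
  })
}

#' Pairwise mutational distance matrix over SHM profiles
#'
#' @param selection A `tree_selection` (or any data.frame with `label` and a
#'   `mutations` list-column).
#' @return Symmetric matrix of symmetric-difference distances with zero
#'   diagonal, labelled by `label`.
#' @export
pairwise_distance_matrix <- function(selection) {
  n <- nrow(selection)
  m <- matrix(0, n, n, dimnames = list(selection$label, selection$label))
  for (i in seq_len(n - 1L)) {
    a <- selection$mutations[[i]]
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- mutational_distance(a, selection$mutations[[j]])
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths
#' are clamped to zero.
#'
#' @param m Symmetric distance matrix with at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`m` must be a square matrix", call. = FALSE)
  if (nrow(m) < 3L)
    stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9 || any(diag(m) != 0))
    stop("`m` must be symmetric with a zero diagonal", call. = FALSE)
  tree <- ape::nj(m)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Tip indices of the clade rooted at `node`.
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    ch <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Classify a diagnosis-relapse pair as early- or late-divergent
#'
#' Operational form of the two relapse scenarios: the pair is called
#' `early_divergent` iff (i) on the germline-rooted tree, the smallest clade
#' containing the relapse major (the clade at its parent node) excludes the
#' diagnosis major and contains no diagnosis subclone within mutational
#' distance `< d_min` of the diagnosis major, AND (ii) both majors carry at
#' least `d_min` mutations exclusive to themselves (mutual divergence).
#' Otherwise the pair is `late_divergent`.
#'
#' @param tree A `phylo` tree over the selection's labels (unrooted trees are
#'   rooted at the germline leaf `GL`).
#' @param selection The `tree_selection` the tree was built from.
#' @param d_min Divergence threshold in mutations (default 3).
#' @param fate Optional major-clone fate carried into the call's metrics.
#' @return A `divergence_call`: list with `mode` and the supporting metrics
#'   (majors' mutational distance, exclusive-mutation counts, separate-clade
#'   indicator, fate).
#' @export
classify_divergence <- function(tree, selection, d_min = 3L, fate = NA_real_) {
  dmaj <- which(selection$is_major & selection$sample == "diagnosis")
  rmaj <- which(selection$is_major & selection$sample == "relapse")
  if (length(dmaj) != 1L || length(rmaj) != 1L)
    stop("selection must contain exactly one major per sample", call. = FALSE)
  dlab <- selection$label[dmaj]
  rlab <- selection$label[rmaj]
  if (!all(c(dlab, rlab, "GL") %in% tree$tip.label))
    stop("majors or germline leaf absent from the tree", call. = FALSE)

  rooted <- if (ape::is.rooted(tree)) tree
            else ape::root(tree, outgroup = "GL", resolve.root = TRUE)
  rtip <- match(rlab, rooted$tip.label)
  parent <- rooted$edge[rooted$edge[, 2L] == rtip, 1L]
  clade <- rooted$tip.label[clade_tips(rooted, parent)]

  dmut <- selection$mutations[[dmaj]]
  rmut <- selection$mutations[[rmaj]]
  in_clade <- selection$label %in% clade
  diag_in_clade <- which(in_clade & selection$sample == "diagnosis")
  near_diag <- vapply(selection$mutations[diag_in_clade],
                      mutational_distance, 0, b = dmut) < d_min
  separate <- !(dlab %in% clade) && !any(near_diag)

  rel_excl <- length(setdiff(rmut, dmut))
  diag_excl <- length(setdiff(dmut, rmut))
  mode <- if (separate && rel_excl >= d_min && diag_excl >= d_min)
    "early_divergent" else "late_divergent"
  structure(
    list(mode = mode,
         distance = mutational_distance(dmut, rmut),
         relapse_exclusive = rel_excl,
         diagnosis_exclusive = diag_excl,
         separate_clade = separate,
         major_clone_fate = fate,
         d_min = d_min),
    class = "divergence_call")
}

#' @export
print.divergence_call <- function(x, ...) {
  cat(sprintf(
    "divergence_call: %s (distance %d; exclusive D=%d R=%d; %s clade; fate %s)\n",
    x$mode, x$distance, x$diagnosis_exclusive, x$relapse_exclusive,
    if (isTRUE(x$separate_clade)) "separate" else "shared",
    ifelse(is.na(x$major_clone_fate), "NA",
           sprintf("%.3f", x$major_clone_fate))))
  invisible(x)
}

#' Full phylogenetic analysis of a diagnosis-relapse pair
#'
#' Convenience wrapper: subclone selection, distance matrix, neighbor-joining
#' tree rooted at the germline, and the divergence classification, with the
#' major-clone fate attached.
#'
#' @inheritParams select_tree_subclones
#' @inheritParams classify_divergence
#' @return List with `selection`, `tree` (germline-rooted `phylo`) and `call`.
#' @export
analyze_pair <- function(diag, relapse, d_min = 3L, top_k = 10L,
                         n_random = 5L, seed = 1L) {
  selection <- select_tree_subclones(diag, relapse, top_k = top_k,
                                     n_random = n_random, seed = seed)
  m <- pairwise_distance_matrix(selection)
  tree <- neighbor_joining(m)
  rooted <- ape::root(tree, outgroup = "GL", resolve.root = TRUE)
  fate <- major_clone_fate(diag, relapse)
  call <- classify_divergence(rooted, selection, d_min = d_min, fate = fate)
  list(selection = selection, tree = rooted, call = call)
}
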