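# Newick / JSON serialisation helpers for trees, calls and reports.

#' Write / read a phylogenetic tree as Newick
#'
#' Branch lengths are preserved; the round trip is lossless for the trees the
#' pipeline emits.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path` invisibly, or the re-read `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path))
    stop(sprintf("%s: no such file", path), call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop(sprintf("%s: not a parseable Newick file", path),
                          call. = FALSE)
  tree
}

#' Serialise a divergence call (or any report list) as JSON
#'
#' @param x A list-like object (`divergence_call`, `pair_report`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# drop S3 classes / AsIs wrappers so jsonlite renders plain structures
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    attributes(x) <- list(names = names(x))
    lapply(x, strip_classes)
  } else {
    attributes(x) <- if (!is.null(names(x))) list(names = names(x)) else NULL
    x
  }
}
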