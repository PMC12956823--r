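#' Read a set of phylogenies from Newick or NEXUS
#'
#' Trees must be rooted and carry branch lengths; posterior samples of
#' language phylogenies are typically distributed as multi-tree NEXUS files.
#' The format is auto-detected (`#NEXUS` magic line), and every tree is
#' checked for rootedness and nonnegative branch lengths.
#'
#' @param path Path to a Newick or NEXUS tree file.
#' @param kind `"posterior_sample"` or `"summary"`; purely descriptive.
#' @return A `phylo_set`: list with elements `trees` (a `multiPhylo`) and
#'   `kind`.
#' @export
read_trees <- function(path, kind = c("posterior_sample", "summary")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) ct_schema_error(paste0("file not found: ", path))
  first <- readLines(path, n = 5L, warn = FALSE)
  is_nexus <- any(grepl("^\\s*#NEXUS", first, ignore.case = TRUE))
  trees <- tryCatch(suppressWarnings({
    if (is_nexus) ape::read.nexus(path) else ape::read.tree(path)
  }), error = function(e) {
    ct_schema_error(paste0("cannot parse tree file ", path, ": ",
                           conditionMessage(e)))
  })
  if (is.null(trees)) ct_schema_error(paste0("cannot parse tree file ", path))
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  phylo_set(trees, kind = kind)
}

#' Construct a validated phylo_set
#'
#' @param trees A `phylo` or `multiPhylo` object.
#' @param kind `"posterior_sample"` or `"summary"`.
#' @return A `phylo_set` object.
#' @export
phylo_set <- function(trees, kind = c("posterior_sample", "summary")) {
  kind <- match.arg(kind)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!inherits(trees, "multiPhylo")) {
    trees <- do.call(c, lapply(trees, identity))
    if (!inherits(trees, "multiPhylo")) {
      ct_validation_error("trees must be phylo or multiPhylo")
    }
  }
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!ape::is.rooted(tr)) {
      ct_validation_error(paste0("tree ", i, " is not rooted"))
    }
    if (is.null(tr$edge.length)) {
      ct_validation_error(paste0("tree ", i, " has no branch lengths"))
    }
    if (any(tr$edge.length < 0)) {
      ct_validation_error(paste0("tree ", i, " has negative branch lengths"))
    }
  }
  structure(list(trees = trees, kind = kind), class = "phylo_set")
}

#' @export
length.phylo_set <- function(x) length(x$trees)

#' @export
print.phylo_set <- function(x, ...) {
  ntips <- vapply(x$trees, function(t) length(t$tip.label), integer(1))
  cat("phylo_set of", length(x$trees), "tree(s), kind =", x$kind, "\n")
  cat("tips per tree:", paste(unique(ntips), collapse = ", "), "\n")
  invisible(x)
}

#' Prune trees to mapped societies and relabel tips
#'
#' Each tree is reduced to exactly the tips named in the taxon map; internal
#' degree-two nodes created by pruning are collapsed with branch lengths
#' summed (so patristic distances among retained tips are preserved), and
#' tips are relabelled from language taxa to society ids so that all
#' downstream objects are keyed consistently.
#'
#' @param physet A [phylo_set].
#' @param map A [taxon_map].
#' @return A [phylo_set] whose trees have one tip per society, labelled by
#'   `society_id`.
#' @export
prune_and_match <- function(physet, map) {
  stopifnot(inherits(physet, "phylo_set"), inherits(map, "taxon_map"))
  pruned <- vector("list", length(physet$trees))
  for (i in seq_along(physet$trees)) {
    tr <- physet$trees[[i]]
    absent <- setdiff(map$tip_label, tr$tip.label)
    if (length(absent) > 0L) {
      ct_alignment_error(paste0("tree ", i, " lacks mapped tip label(s): ",
                                paste(absent, collapse = ", ")))
    }
    tr <- ape::keep.tip(tr, map$tip_label)
    idx <- match(tr$tip.label, map$tip_label)
    tr$tip.label <- map$society_id[idx]
    pruned[[i]] <- tr
  }
  out <- phylo_set(pruned, kind = physet$kind)
  out
}

#' Rescale a tree so that its maximum root-to-tip depth is one
#'
#' Dynamic-model rate parameters are interpreted per unit tree height, so
#' trees are normalized before fitting.
#'
#' @param tree A `phylo`.
#' @return The rescaled tree.
#' @export
rescale_tree_height <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  h <- max(d[seq_len(length(tree$tip.label))])
  if (h <= 0) ct_validation_error("tree has zero height")
  tree$edge.length <- tree$edge.length / h
  tree
}

# Deterministic, order-independent per-tree seed: pooled posteriors over a
# tree sample must not depend on the order trees are listed in.
tree_seed <- function(tree, seed) {
  h <- sum(utf8ToInt(ape::write.tree(tree)) * (seq_len(nchar(
    ape::write.tree(tree))) %% 97L + 1L))
  as.integer((abs(seed) * 131L + h) %% (.Machine$integer.max - 1L)) + 1L
}

#' Write trees to a Newick file
#'
#' @param physet A [phylo_set].
#' @param path Output path.
#' @export
write_trees <- function(physet, path) {
  stopifnot(inherits(physet, "phylo_set"))
  ape::write.tree(physet$trees, file = path)
  invisible(path)
}
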