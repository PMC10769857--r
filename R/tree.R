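#' Prepare a phylogeny for the screen
#'
#' Reads/accepts a Newick tree, midpoint-roots it, resolves polytomies
#' deterministically with zero-length branches, and prunes it to the genome
#' set of the matrix. Genomes missing from the tree are a hard error; extra
#' tips are pruned with a message.
#'
#' @param tree an \code{ape} \code{phylo} object, a Newick string, or a path
#'   to a Newick file.
#' @param genome_ids genome identifiers that must be present as tips.
#' @return a rooted, binary \code{phylo} with non-negative branch lengths.
#' @export
prepare_tree <- function(tree, genome_ids = NULL) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree[1L]) && !grepl("\\(", tree[1L])) {
      ape::read.tree(tree[1L])
    } else {
      ape::read.tree(text = tree[1L])
    }
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (!is.null(genome_ids)) {
    missing <- setdiff(genome_ids, tree$tip.label)
    if (length(missing)) {
      stop("genomes absent from tree: ", paste(missing, collapse = ", "))
    }
    extra <- setdiff(tree$tip.label, genome_ids)
    if (length(extra)) {
      message(length(extra), " tree tip(s) not in the matrix were pruned")
      tree <- ape::keep.tip(tree, genome_ids)
    }
  }
  tree <- phangorn::midpoint(tree)
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Internal traversal scaffold for a rooted binary phylo: postorder list of
# internal nodes with their two children and the child edge lengths.
tree_struct <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop("tree must be rooted and binary; run prepare_tree() first")
  }
  ntip <- length(tree$tip.label)
  tre <- stats::reorder(tree, "postorder")
  edge <- tre$edge
  elen <- tre$edge.length
  nnode <- tre$Nnode
  child1 <- child2 <- len1 <- len2 <- rep(NA_real_, ntip + nnode)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    if (is.na(child1[p])) { child1[p] <- ch; len1[p] <- elen[i] }
    else { child2[p] <- ch; len2[p] <- elen[i] }
  }
  internal_post <- unique(edge[, 1L])  # postorder guarantees children first
  list(tree = tre, ntip = ntip, nnode = nnode,
       tip_labels = tre$tip.label,
       internal_post = internal_post,
       child1 = child1, child2 = child2, len1 = len1, len2 = len2,
       edge = edge, edge_length = elen,
       root = ntip + 1L,
       height = max(ape::node.depth.edgelength(tre)))
}

#' Simulate a random phylogeny
#'
#' Yule (pure-birth) or coalescent topologies with branch lengths rescaled
#' to unit height; the backbone for synthetic benchmarks.
#'
#' @param n_tips number of tips (>= 3); labelled \code{g1..gN}.
#' @param model \code{"yule"} or \code{"coalescent"}.
#' @param seed integer seed; the same seed reproduces the tree exactly.
#' @return a rooted binary \code{phylo} of height 1.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "coalescent"), seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_tips >= 3)
  set.seed(seed)
  tree <- switch(model,
                 yule = ape::rphylo(n_tips, birth = 1, death = 0),
                 coalescent = ape::rcoal(n_tips))
  tree$tip.label <- paste0("g", seq_len(n_tips))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree
}
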