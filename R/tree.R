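#' Parse a Newick string into a phylogeny
#'
#' Thin validating front end to [ape::read.tree()]. The tree is returned as an
#' ape `"phylo"` object, the container used throughout the package. Before
#' handing the string to ape, cheap structural checks are run so that common
#' malformations are reported with a character offset: unbalanced parentheses,
#' a missing terminating semicolon, and duplicate tip labels.
#'
#' Quoted labels and internal (support) labels are preserved; single-tip trees
#' are rejected because no comparative method in the package applies to them.
#'
#' @param text A single Newick statement ending in `";"`.
#' @return An object of class `"phylo"`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by character ",
         length(chars))
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: no terminating ';' (string ends at character ",
         length(chars), ")")
  if (!grepl("\\(", text))
    stop("single-tip trees are not supported")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error: ape could not read the string")
  validate_tree(tree)
  tree
}

#' Serialize a phylogeny to Newick
#'
#' Branch lengths are written with enough digits (12 significant) that a
#' parse/write round trip reproduces them beyond 10 significant digits.
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  validate_tree(tree)
  ape::write.tree(tree, digits = digits)
}

# Structural invariants shared by every consumer: one root, unique non-empty
# tip labels, finite non-negative branch lengths, >= 2 tips.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)))
      stop("non-finite branch length")
    if (any(tree$edge.length < 0))
      stop("negative branch length")
  }
  invisible(tree)
}

#' Resolve polytomies into bifurcations with tiny branches
#'
#' Each multifurcation is broken into a random sequence of bifurcations (as in
#' [ape::multi2di()] with `random = TRUE`); every internal branch created this
#' way receives length `epsilon` rather than zero, so downstream contrast and
#' likelihood computations never divide by a zero branch. A k-way polytomy
#' perturbs any root-to-tip distance by at most `(k - 2) * epsilon`.
#'
#' @param tree A `"phylo"` object.
#' @param epsilon Length assigned to the new internal branches (> 0).
#' @param seed Optional integer; makes the random resolution reproducible
#'   without touching the caller's RNG state.
#' @return A strictly bifurcating `"phylo"` object.
#' @export
resolve_polytomies <- function(tree, epsilon = 1e-4, seed = NULL) {
  validate_tree(tree)
  stopifnot(epsilon > 0)
  if (ape::is.binary(tree) && ape::is.rooted(tree)) return(tree)
  had_zero <- !is.null(tree$edge.length) &&
    any(tree$edge.length[tree$edge[, 1] > ape::Ntip(tree) &
                           tree$edge[, 2] > ape::Ntip(tree)] == 0)
  if (had_zero)
    warning("tree already contains zero-length internal branches; ",
            "these will also be set to epsilon")
  out <- with_local_seed(seed, ape::multi2di(tree, random = TRUE))
  ntip <- ape::Ntip(out)
  new_internal <- out$edge[, 2] > ntip & out$edge.length == 0
  out$edge.length[new_internal] <- epsilon
  out
}

#' Force a tree to be ultrametric
#'
#' Makes all root-to-tip path lengths equal to the current maximum depth.
#' `method = "extend"` lengthens terminal branches only, leaving internal
#' structure untouched. `method = "scale_paths"` rescales depths along each
#' root-to-tip path: every node at depth d with maximum tip depth D below it
#' is moved to depth `d * T / D` (T = target depth), which stretches each
#' path proportionally and never creates a negative branch.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param method `"extend"` (default) or `"scale_paths"`.
#' @return An ultrametric `"phylo"` object with the same topology.
#' @export
force_ultrametric <- function(tree, method = c("extend", "scale_paths")) {
  method <- match.arg(method)
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- node_depths(tree)
  ntip <- ape::Ntip(tree)
  target <- max(depth[seq_len(ntip)])
  if (max(depth[seq_len(ntip)]) - min(depth[seq_len(ntip)]) <
      1e-10 * target)
    return(tree)
  if (method == "extend") {
    term <- tree$edge[, 2] <= ntip
    tip_of_edge <- tree$edge[term, 2]
    tree$edge.length[term] <- tree$edge.length[term] +
      (target - depth[tip_of_edge])
    if (any(tree$edge.length < 0)) stop("internal error: negative branch")
  } else {
    maxdown <- max_tip_depth_below(tree, depth)
    newdepth <- depth * target / maxdown
    newdepth[is.nan(newdepth)] <- 0  # root when depth 0/0 cannot occur; guard
    tree$edge.length <- newdepth[tree$edge[, 2]] - newdepth[tree$edge[, 1]]
    if (any(tree$edge.length < -1e-12)) stop("internal error: negative branch")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# Depth (distance from root) of every node, ape numbering (tips first).
node_depths <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_all)
  root <- ape::Ntip(tree) + 1L
  ord <- reorder_edges_preorder(tree)
  for (k in ord) {
    e <- tree$edge[k, ]
    depth[e[2]] <- depth[e[1]] + tree$edge.length[k]
  }
  depth
}

# For every node, the maximum root-to-tip depth among tips in its subtree
# (for a tip, its own depth; for the root, the tree depth).
max_tip_depth_below <- function(tree, depth = node_depths(tree)) {
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  md <- numeric(n_all)
  md[seq_len(ntip)] <- depth[seq_len(ntip)]
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    e <- post$edge[k, ]
    md[e[1]] <- max(md[e[1]], md[e[2]])
  }
  md
}

# Edge indices of tree$edge in preorder (parent before child).
reorder_edges_preorder <- function(tree) {
  pre <- ape::reorder.phylo(tree, "cladewise")
  match(paste(pre$edge[, 1], pre$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Prune a tree down to a set of taxa
#'
#' Keeps exactly the requested tips, suppressing the resulting degree-2 nodes
#' (their branch lengths are summed), so root-to-tip distances of the kept
#' taxa are preserved exactly.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` object.
#' @export
prune_to <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L)
    stop("need at least 2 taxa to keep, got ", length(keep))
  ape::keep.tip(tree, keep)
}

#' Extract the clade spanned by a set of taxa
#'
#' Returns the subtree rooted at the most recent common ancestor of `taxa`,
#' with all of its descendants (possibly more taxa than requested). If the
#' MRCA is the root of the whole tree the tree is returned as-is with a
#' warning and attribute `spans_root = TRUE`.
#'
#' @param tree A `"phylo"` object.
#' @param taxa Character vector of tip labels (at least 2, typically >= 3).
#' @return A `"phylo"` object for the clade.
#' @export
extract_clade <- function(tree, taxa) {
  validate_tree(tree)
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxa) < 2L) stop("need at least 2 taxa")
  root <- ape::Ntip(tree) + 1L
  mrca <- if (length(taxa) == ape::Ntip(tree)) root else
    ape::getMRCA(tree, taxa)
  if (mrca == root) {
    warning("taxa span the root; returning the whole tree")
    attr(tree, "spans_root") <- TRUE
    return(tree)
  }
  ape::extract.clade(tree, mrca)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths. This is the among-taxa covariance of a
#' unit-rate Brownian trait on the tree, the matrix behind PGLS, Pagel's
#' lambda and phylogenetic PCA. Rows/columns are named by tip label in tree
#' tip order; consumers align by name.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::vcv.phylo(tree)
}

# Evaluate expr with a temporarily-seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
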