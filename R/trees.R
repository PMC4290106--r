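#' Labeled tree object
#'
#' A rooted phylogeny with declared branch-length units, optional internal
#' node support values (0-100), optional internodal time spans (My) and
#' optional per-node trait values (e.g. generation time in years). Branch
#' length units are recorded and never mixed within one tree.
#'
#' @param phylo a rooted `ape::phylo` object with unique tip labels.
#' @param length_units one of `"substitutions"`, `"coalescent"`, `"my"`.
#' @param support numeric vector of internal node support values (length
#'   `phylo$Nnode`) or `NULL`.
#' @param node_traits optional data.frame keyed by `node` (ape node ids)
#'   carrying per-node values such as `generation_time_yr`.
#' @param time_spans optional data.frame with columns `node` (branch
#'   addressed by its child node) and `time_span_my`.
#' @return object of class `labeled_tree`.
#' @export
labeled_tree <- function(phylo, length_units = c("substitutions", "coalescent", "my"),
                         support = NULL, node_traits = NULL, time_spans = NULL) {
  length_units <- match.arg(length_units)
  if (!inherits(phylo, "phylo")) stop_avigc("phylo must be an ape 'phylo' object")
  if (anyDuplicated(phylo$tip.label))
    stop_avigc("duplicate tip labels: ",
               paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]),
                     collapse = ", "))
  if (!ape::is.rooted(phylo)) stop_avigc("tree is not rooted")
  if (!is.null(phylo$edge.length) && any(phylo$edge.length < 0))
    stop_avigc("negative branch lengths")
  if (!is.null(support)) {
    support <- as.numeric(support)
    if (length(support) != phylo$Nnode)
      stop_avigc("support must have one value per internal node")
    if (any(!is.na(support) & (support < 0 | support > 100)))
      stop_avigc("support values must lie in [0, 100]")
  }
  structure(list(phylo = phylo, length_units = length_units,
                 support = support, node_traits = node_traits,
                 time_spans = time_spans),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("<labeled_tree> ", length(x$phylo$tip.label), " tips, units=",
      x$length_units,
      if (!is.null(x$support)) ", with support", "\n", sep = "")
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "labeled_tree")) tree$phylo
  else if (inherits(tree, "phylo")) tree
  else stop_avigc("expected a 'labeled_tree' or ape 'phylo' object")
}

#' Read a rooted tree from Newick
#'
#' Internal node labels, when numeric, are interpreted as support values in
#' \[0, 100\]. Input with a basal trifurcation is rejected unless an
#' `outgroup` is supplied, in which case the tree is rooted on it.
#'
#' @param path Newick file.
#' @param length_units units of the branch lengths (recorded on the object).
#' @param outgroup optional tip label (or vector) used to root unrooted
#'   input.
#' @return a [labeled_tree].
#' @export
read_tree <- function(path, length_units = c("substitutions", "coalescent", "my"),
                      outgroup = NULL) {
  length_units <- match.arg(length_units)
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop_avigc("unparseable Newick in ", path,
                                                 ": ", conditionMessage(e)))
  if (is.null(phy)) stop_avigc("unparseable Newick in ", path)
  if (anyDuplicated(phy$tip.label))
    stop_avigc("duplicate tip labels in ", path, ": ",
               paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                     collapse = ", "))
  if (!ape::is.rooted(phy)) {
    if (is.null(outgroup))
      stop_avigc("tree in ", path,
                 " is unrooted (basal multifurcation); supply an outgroup")
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  support <- NULL
  if (!is.null(phy$node.label)) {
    sv <- suppressWarnings(as.numeric(phy$node.label))
    if (any(!is.na(sv))) {
      if (any(!is.na(sv) & (sv < 0 | sv > 100)))
        stop_avigc("support values outside [0, 100] in ", path)
      support <- sv
    }
  }
  labeled_tree(phy, length_units, support = support)
}

#' Write a tree to Newick
#'
#' Support values, when present, are written as internal node labels.
#'
#' @param tree a [labeled_tree] or `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  phy <- as_phylo(tree)
  if (inherits(tree, "labeled_tree") && !is.null(tree$support))
    phy$node.label <- ifelse(is.na(tree$support), "", format(tree$support))
  ape::write.tree(phy, file = path)
  invisible(path)
}

## parent lookup: parent[node] = parent node id, NA for root
parent_vector <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  p <- rep(NA_integer_, n)
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

root_node <- function(phy) length(phy$tip.label) + 1L

## list of children per node
children_list <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(n)))
}

## internal nodes in post order (all children precede their parent)
postorder_nodes <- function(phy) {
  par <- ape::reorder.phylo(phy, "postorder")$edge[, 1L]
  par[!duplicated(par, fromLast = TRUE)]
}
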