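## Species-tree indexing used by the lineage-counting routines.
## Nodes use ape ids; a branch is addressed by its tipward (child) node.
species_index <- function(sp_phy) {
  ntip <- length(sp_phy$tip.label)
  nnode <- ntip + sp_phy$Nnode
  parent <- parent_vector(sp_phy)
  kids <- children_list(sp_phy)
  ## tip sets per node (logical matrix nodes x tips)
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (nd in postorder_nodes(sp_phy))
    for (ch in kids[[nd]]) below[nd, ] <- below[nd, ] | below[ch, ]
  ## node depths by fix-point over edges (trees are small)
  depth <- integer(nnode)
  repeat {
    d0 <- depth
    depth[sp_phy$edge[, 2L]] <- depth[sp_phy$edge[, 1L]] + 1L
    if (identical(d0, depth)) break
  }
  list(ntip = ntip, nnode = nnode, parent = parent, kids = kids,
       below = below, depth = depth, tips = sp_phy$tip.label)
}

## LCA of a set of species-tree nodes, by walking up from the deepest
lca_nodes <- function(idx, nodes) {
  cur <- nodes[1L]
  for (nd in nodes[-1L]) {
    a <- cur; b <- nd
    while (a != b) {
      if (idx$depth[a] >= idx$depth[b]) a <- idx$parent[a] else b <- idx$parent[b]
    }
    cur <- a
  }
  cur
}

## node heights above the tips (assumes an ultrametric tree)
node_heights <- function(phy) {
  d <- ape::node.depth.edgelength(phy)
  max(d) - d
}

#' Gene-lineage counts at both ends of every species-tree branch
#'
#' Maps each gene-tree node to a species-tree branch and counts, for every
#' species-tree branch, the number of gene lineages present at its
#' rootward and tipward ends. Two reconciliations are available:
#' `"lca"` is strictly topological — a gene node maps to the most recent
#' species node containing all its descendant species, so a coalescence
#' that happens above a branch but still between that branch's two
#' lineages is indistinguishable from a within-branch coalescence.
#' `"temporal"` additionally uses node times: when the gene tree is
#' ultrametric on the same time axis as the species tree (e.g. dated gene
#' trees, or trees from [simulate_gene_trees()]), each coalescence is
#' placed in the species branch whose time interval contains it, which
#' resolves those hidden deep coalescences. `"auto"` (default) picks
#' temporal whenever both trees carry usable heights. Species missing from
#' the gene tree are allowed; branches for which the gene tree retains no
#' species on one descendant side are reported as NA.
#'
#' @param species_tree [labeled_tree] or rooted `phylo`.
#' @param gene_tree [labeled_tree] or rooted `phylo`; tips must be species
#'   ids present in the species tree (one sampled lineage per species).
#' @param idx optional precomputed index from repeated calls (internal).
#' @param mapping `"auto"`, `"temporal"` or `"lca"`.
#' @param species_heights optional species node heights on the gene-tree
#'   time axis (defaults to heights of `species_tree`, which must then be
#'   ultrametric with branch lengths in time units).
#' @return data.frame with one row per species-tree branch: `node` (the
#'   branch's tipward node), `is_tip`, `rootward`, `tipward` lineage
#'   counts, and `polytomy` (TRUE when an unresolved gene-tree node maps
#'   inside the branch).
#' @export
count_branch_lineages <- function(species_tree, gene_tree, idx = NULL,
                                  mapping = c("auto", "temporal", "lca"),
                                  species_heights = NULL) {
  mapping <- match.arg(mapping)
  sp <- as_phylo(species_tree)
  gt <- as_phylo(gene_tree)
  if (is.null(idx)) idx <- species_index(sp)
  unknown <- setdiff(gt$tip.label, idx$tips)
  if (length(unknown))
    stop_avigc("gene-tree tips not in the species tree: ",
               paste(unknown, collapse = ", "))
  gntip <- length(gt$tip.label)
  gnn <- gntip + gt$Nnode
  gkids <- children_list(gt)
  ## LCA map for every gene-tree node
  map <- integer(gnn)
  map[seq_len(gntip)] <- match(gt$tip.label, idx$tips)
  for (nd in postorder_nodes(gt))
    map[nd] <- lca_nodes(idx, map[gkids[[nd]]])
  if (mapping != "lca") {
    sp_ok <- !is.null(species_heights) ||
      (!is.null(sp$edge.length) &&
         isTRUE(all.equal(ape::is.ultrametric(sp, option = 2), TRUE)))
    have_times <- !is.null(gt$edge.length) && sp_ok
    if (mapping == "temporal" && !have_times)
      stop_avigc("temporal mapping needs node times on both trees ",
                 "(an ultrametric species tree or explicit species_heights)")
    if (have_times) {
      if (is.null(species_heights)) species_heights <- node_heights(sp)
      gh <- node_heights(gt)
      tol <- 1e-9 * max(species_heights, 1)
      for (nd in (gntip + 1L):gnn) {
        cur <- map[nd]
        while (!is.na(idx$parent[cur]) &&
               gh[nd] > species_heights[idx$parent[cur]] + tol)
          cur <- idx$parent[cur]
        map[nd] <- cur
      }
    }
  }
  polytomy_at <- rep(FALSE, idx$nnode)
  for (nd in postorder_nodes(gt))
    if (length(gkids[[nd]]) > 2L) polytomy_at[map[nd]] <- TRUE
  top <- integer(idx$nnode); bottom <- integer(idx$nnode)
  ## walk the species path for each gene edge: the edge (u -> w) crosses
  ## the rootward end of every branch whose child node lies in
  ## [map(w), map(u)) and the tipward end of branches in (map(w), map(u)];
  ## a gene TIP additionally enters the bottom of its terminal branch.
  for (e in seq_len(nrow(gt$edge))) {
    u <- gt$edge[e, 1L]; w <- gt$edge[e, 2L]
    mw <- map[w]; mu <- map[u]
    if (w <= gntip) bottom[mw] <- bottom[mw] + 1L
    nd <- mw
    while (nd != mu) {
      top[nd] <- top[nd] + 1L
      nd <- idx$parent[nd]
      bottom[nd] <- bottom[nd] + 1L
    }
  }
  nodes <- setdiff(seq_len(idx$nnode), root_node(sp))
  ## a branch is informative for this gene tree only when both descendant
  ## sides of its tipward node retain at least one sampled species
  present <- idx$tips %in% gt$tip.label
  ok <- vapply(nodes, function(nd) {
    if (nd <= idx$ntip) return(present[nd])
    all(vapply(idx$kids[[nd]],
               function(ch) any(idx$below[ch, ] & present), logical(1)))
  }, logical(1))
  data.frame(node = nodes, is_tip = nodes <= idx$ntip,
             rootward = ifelse(ok, top[nodes], NA_integer_),
             tipward = ifelse(ok, bottom[nodes], NA_integer_),
             polytomy = polytomy_at[nodes],
             stringsAsFactors = FALSE)
}

#' Coalescent-unit branch lengths from gene-tree discordance
#'
#' For every internal species-tree branch, aggregates over gene trees the
#' count n12 of trees with one lineage at the rootward end and two at the
#' tipward end (coalescence inside the branch) and nkk of trees with k >= 2
#' lineages at both ends (no coalescence; all k pooled). The branch length
#' in coalescent units is log((n12 + nkk)/nkk), natural log. nkk = 0 gives
#' +Inf (flagged); an uninformative branch (n12 + nkk = 0) and terminal
#' branches (always one lineage per species) are NA. Gene trees whose
#' unresolved (polytomous) nodes map inside a branch are counted as failing
#' to coalesce there (nkk), a conservative choice.
#'
#' @param species_tree [labeled_tree] (support values, if present, are
#'   propagated to the output) or rooted `phylo`.
#' @param gene_trees list of rooted `phylo`/[labeled_tree] gene trees.
#' @param mapping reconciliation mode, see [count_branch_lineages()].
#' @param time_tree optional `phylo` with the species topology and branch
#'   lengths on the gene-tree time axis (for temporal mapping when the
#'   species tree itself is in coalescent units and not ultrametric).
#' @return data.frame with one row per internal branch: `node`, `label`,
#'   `is_cherry`, `support`, `n12`, `nkk`, `n_trees_used`,
#'   `coalescent_length`, `flag`.
#' @export
coalescent_branch_lengths <- function(species_tree, gene_trees,
                                      mapping = c("auto", "temporal", "lca"),
                                      time_tree = NULL) {
  mapping <- match.arg(mapping)
  if (length(gene_trees) < 1L) stop_avigc("need at least one gene tree")
  sp <- as_phylo(species_tree)
  idx <- species_index(sp)
  sph <- if (!is.null(time_tree)) node_heights(as_phylo(time_tree)) else NULL
  internal <- setdiff((idx$ntip + 1L):idx$nnode, root_node(sp))
  n12 <- setNames(integer(length(internal)), internal)
  nkk <- n12; used <- n12
  for (gt in gene_trees) {
    cb <- count_branch_lineages(sp, gt, idx = idx, mapping = mapping,
                                species_heights = sph)
    cb <- cb[!cb$is_tip & !is.na(cb$tipward), ]
    for (i in seq_len(nrow(cb))) {
      key <- as.character(cb$node[i])
      top <- cb$rootward[i]; bot <- cb$tipward[i]
      if (cb$polytomy[i] && top >= 1L && bot >= 2L) {
        nkk[key] <- nkk[key] + 1L; used[key] <- used[key] + 1L
      } else if (top == 1L && bot == 2L) {
        n12[key] <- n12[key] + 1L; used[key] <- used[key] + 1L
      } else if (top == bot && top >= 2L) {
        nkk[key] <- nkk[key] + 1L; used[key] <- used[key] + 1L
      }
    }
  }
  len <- ifelse(n12 + nkk == 0, NA_real_,
                ifelse(nkk == 0, Inf, log((n12 + nkk) / nkk)))
  flag <- ifelse(n12 + nkk == 0, "uninformative",
                 ifelse(nkk == 0, "infinite", ""))
  kids <- idx$kids
  is_cherry <- vapply(internal, function(nd)
    all(kids[[nd]] <= idx$ntip) && length(kids[[nd]]) == 2L, logical(1))
  lab <- vapply(internal, function(nd) {
    tips <- idx$tips[idx$below[nd, ]]
    if (length(tips) <= 2L) paste(tips, collapse = "|")
    else paste0(tips[1L], "|...|", tips[length(tips)])
  }, character(1))
  support <- rep(NA_real_, length(internal))
  if (inherits(species_tree, "labeled_tree") && !is.null(species_tree$support))
    support <- species_tree$support[internal - idx$ntip]
  data.frame(node = internal, label = lab, is_cherry = is_cherry,
             support = support, n12 = as.integer(n12), nkk = as.integer(nkk),
             n_trees_used = as.integer(used), coalescent_length = unname(len),
             flag = unname(flag), stringsAsFactors = FALSE)
}

#' Reconstruct ancestral effective population size for a branch
#'
#' N = internodal time span / (2 x coalescent branch length x generation
#' time), with generation time the mean of the values at the branch's two
#' ends. Zero or infinite coalescent lengths leave N undefined (flagged).
#' These reconstructions are overestimates when generation time is proxied
#' by age at first maturity and are intended to be read as rank order; the
#' output carries a `rank` column (1 = largest N).
#'
#' @param coalescent_length branch length(s) in coalescent units.
#' @param time_span internodal time span(s), years.
#' @param generation_time_rootward,generation_time_tipward generation times
#'   (years) at the rootward and tipward nodes.
#' @return data.frame with `coalescent_length`, `time_span`,
#'   `generation_time`, `n_hat`, `rank`, `flag`.
#' @export
reconstruct_ne <- function(coalescent_length, time_span,
                           generation_time_rootward, generation_time_tipward) {
  if (any(time_span <= 0, na.rm = TRUE)) stop_avigc("time spans must be positive")
  if (any(c(generation_time_rootward, generation_time_tipward) <= 0, na.rm = TRUE))
    stop_avigc("generation times must be positive")
  g <- (generation_time_rootward + generation_time_tipward) / 2
  bad <- is.na(coalescent_length) | coalescent_length <= 0 |
    !is.finite(coalescent_length)
  n_hat <- ifelse(bad, NA_real_, time_span / (2 * coalescent_length * g))
  flag <- ifelse(is.na(coalescent_length), "undefined_length",
          ifelse(!is.finite(coalescent_length), "infinite_length",
          ifelse(coalescent_length <= 0, "zero_length", "")))
  rank_out <- rep(NA_integer_, length(n_hat))
  okv <- which(!is.na(n_hat))
  rank_out[okv] <- as.integer(rank(-n_hat[okv], ties.method = "first"))
  data.frame(coalescent_length = coalescent_length, time_span = time_span,
             generation_time = g, n_hat = n_hat, rank = rank_out,
             flag = flag, stringsAsFactors = FALSE)
}

#' Filter branch statistics the way the downstream analyses require
#'
#' Keeps branches with coalescent length at least `min_coal_length`, node
#' support at least `min_support` (branches without support pass when
#' `min_support` is NA), and, when `cherry_only`, only branches whose tipward node has two
#' leaf children (effective sizes are undetermined for terminal branches
#' and unreliable for the very short deep branches).
#'
#' @param stats data.frame from [coalescent_branch_lengths()] (optionally
#'   augmented with Ne columns).
#' @param min_coal_length minimum coalescent length (default 0.1).
#' @param min_support minimum bootstrap support (default 50); `NA` disables.
#' @param cherry_only keep only branches subtending two terminal branches
#'   (default TRUE).
#' @return the filtered data.frame (possibly empty, with a warning).
#' @export
filter_branches <- function(stats, min_coal_length = 0.1, min_support = 50,
                            cherry_only = TRUE) {
  keep <- !is.na(stats$coalescent_length) &
    is.finite(stats$coalescent_length) &
    stats$coalescent_length >= min_coal_length
  if (!is.na(min_support) && "support" %in% names(stats))
    keep <- keep & (is.na(stats$support) | stats$support >= min_support)
  if (cherry_only && "is_cherry" %in% names(stats))
    keep <- keep & stats$is_cherry
  out <- stats[keep, , drop = FALSE]
  if (nrow(out) == 0L) warn_avigc("no branches pass the filters")
  out
}
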