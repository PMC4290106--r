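W_STATES <- c(1L, 4L)  # A, T
S_STATES <- c(2L, 3L)  # C, G

#' Map expected W->S and S->W substitution counts onto branches
#'
#' Computes, for every branch, the expected number of weak-to-strong
#' (A/T -> G/C) and strong-to-weak substitutions given the data and a
#' fitted T92 model, via inside-outside (pruning plus downward) passes.
#' The default `"endpoint"` rule counts the joint posterior probability of
#' a weak parent state and strong child state (and vice versa), summed over
#' sites — adequate for the short branches typical of dense phylogenies.
#' The `"integrated"` mode computes the analytic expected number of labeled
#' substitutions along the branch (Simpson quadrature over the transition
#' kernel), which also counts multiple and reversing events.
#'
#' Branch class occupancies (expected numbers of weak and strong sites,
#' averaged over the two branch ends) are returned so that equilibrium-GC
#' calculations can normalize counts into per-site rates; see [gc3_star()].
#'
#' @param states integer state matrix (species x sites) or an
#'   [ortholog_alignment].
#' @param tree [labeled_tree] or rooted `phylo`, branch lengths in
#'   substitutions/site.
#' @param model a [t92_model] (typically from [fit_t92()]).
#' @param mode `"endpoint"` or `"integrated"`.
#' @param scale global branch-length multiplier (e.g. from a fit).
#' @param quad_points quadrature points for the integrated mode (odd).
#' @return data.frame of class `branch_substitution_counts`: one row per
#'   branch (`node` = tipward node, `parent`, `is_tip`, `label`, `length`,
#'   `sites`, `e_ws`, `e_sw`, `e_total`, `w_occ`, `s_occ`). The species
#'   tree is attached as attribute `"phylo"`.
#' @export
map_ws_substitutions <- function(states, tree, model,
                                 mode = c("endpoint", "integrated"),
                                 scale = 1, quad_points = 21L) {
  mode <- match.arg(mode)
  if (inherits(states, "ortholog_alignment"))
    states <- if (states$kind == "coding") third_position_states(states)
              else encode_states(states$matrix)
  phy <- as_phylo(tree)
  pp <- pruning_pass(states, phy, model, scale)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  nsites <- ncol(states)
  kids <- pp$kids
  ## downward (outside) pass
  Fm <- vector("list", nnode)   # outside x sibling messages, per branch
  O <- vector("list", nnode)
  O[[pp$root]] <- matrix(model$pi, 4, nsites)
  for (nd in c(pp$root, rev(postorder_nodes(phy))[-1L])) {
    for (ch in kids[[nd]]) {
      f <- O[[nd]]
      for (sib in setdiff(kids[[nd]], ch)) f <- f * pp$M[[sib]]
      Fm[[ch]] <- f
      O[[ch]] <- crossprod(pp$P[[ch]], f)
    }
  }
  Q <- t92_rate_matrix(model)
  branch_nodes <- phy$edge[, 2L]
  out <- lapply(branch_nodes, function(ch) {
    Pc <- pp$P[[ch]]
    Lc <- pp$L[[ch]]
    f <- Fm[[ch]]
    sl <- pp$site_lik
    t_br <- unname(pp$elen[[as.character(ch)]])
    if (mode == "endpoint" || t_br == 0) {
      ## joint posterior over (parent, child) state pairs
      Epair <- matrix(0, 4, 4)
      for (x in 1:4) for (y in 1:4)
        Epair[x, y] <- sum(f[x, ] * Pc[x, y] * Lc[y, ] / sl)
    } else {
      ## expected labeled substitutions: q_xy * int_0^t P(s)[,x] P(t-s)[y,] ds
      m <- if (quad_points %% 2L == 0L) quad_points + 1L else quad_points
      sq <- seq(0, t_br, length.out = m)
      wq <- c(1, rep(c(4, 2), length.out = m - 2L), 1)
      wq <- wq * (t_br / (m - 1)) / 3
      Pq <- lapply(sq, function(s) t92_transition_matrix(model, s))
      Epair <- matrix(0, 4, 4)
      for (x in 1:4) for (y in 1:4) {
        if (x == y) next
        A <- matrix(0, 4, 4)
        for (i in seq_len(m))
          A <- A + wq[i] * outer(Pq[[i]][, x], Pq[[m + 1L - i]][y, ])
        Epair[x, y] <- Q[x, y] * sum(colSums(f * (A %*% Lc)) / sl)
      }
    }
    e_ws <- sum(Epair[W_STATES, S_STATES])
    e_sw <- sum(Epair[S_STATES, W_STATES])
    e_total <- sum(Epair) - sum(diag(Epair))
    ## class occupancy at branch midpoint (mean of end marginals)
    pmarg <- f * pp$M[[ch]] / rep(sl, each = 4)
    cmarg <- O[[ch]] * Lc / rep(sl, each = 4)
    wocc <- (sum(pmarg[W_STATES, ]) + sum(cmarg[W_STATES, ])) / 2
    socc <- (sum(pmarg[S_STATES, ]) + sum(cmarg[S_STATES, ])) / 2
    data.frame(node = ch, parent = phy$edge[phy$edge[, 2L] == ch, 1L],
               is_tip = ch <= ntip,
               label = if (ch <= ntip) phy$tip.label[ch] else as.character(ch),
               length = t_br, sites = nsites,
               e_ws = e_ws, e_sw = e_sw, e_total = e_total,
               w_occ = wocc, s_occ = socc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "phylo") <- phy
  class(res) <- c("branch_substitution_counts", class(res))
  res
}

#' Equilibrium GC3 (GC3*) from mapped substitution counts
#'
#' GC3* is the composition expected on an infinitely long branch. With
#' `normalize = TRUE` (default) counts are first converted to per-site
#' rates using the branch class occupancies — u = E(W->S)/weak-site
#' exposure, v = E(S->W)/strong-site exposure — and GC3* = u/(u + v), the
#' equilibrium of the two-state weak/strong dynamic. `normalize = FALSE`
#' gives the plain ratio of summed counts E_WS/(E_WS + E_SW), which equals
#' 1/2 for data at compositional equilibrium and is retained for
#' comparison.
#'
#' @param counts a `branch_substitution_counts` from
#'   [map_ws_substitutions()].
#' @param scope `"per_tip_root_path"` sums counts and exposures over all
#'   branches from the root to each tip before forming the ratio;
#'   `"per_branch"` gives branch-wise values; `"whole_tree"` pools every
#'   branch.
#' @param normalize convert counts to class-normalized rates (default
#'   TRUE).
#' @return data.frame with `unit` (tip label, branch node, or `"tree"`),
#'   `gc3_star`, `e_ws`, `e_sw`, `flag` (`"undefined"` when no
#'   substitutions are expected).
#' @export
gc3_star <- function(counts,
                     scope = c("per_tip_root_path", "per_branch", "whole_tree"),
                     normalize = TRUE) {
  scope <- match.arg(scope)
  stopifnot(inherits(counts, "branch_substitution_counts"))
  phy <- attr(counts, "phylo")
  ratio <- function(ws, sw, wexp, sexp) {
    if (!is.finite(ws + sw) || ws + sw <= 0) return(NA_real_)
    if (normalize) {
      if (wexp <= 0 || sexp <= 0) return(NA_real_)
      u <- ws / wexp; v <- sw / sexp
      u / (u + v)
    } else ws / (ws + sw)
  }
  if (scope == "per_branch") {
    g <- mapply(ratio, counts$e_ws, counts$e_sw,
                counts$w_occ * pmax(counts$length, .Machine$double.eps),
                counts$s_occ * pmax(counts$length, .Machine$double.eps))
    return(data.frame(unit = counts$label, node = counts$node,
                      gc3_star = g, e_ws = counts$e_ws, e_sw = counts$e_sw,
                      flag = ifelse(is.na(g), "undefined", ""),
                      stringsAsFactors = FALSE))
  }
  if (scope == "whole_tree") {
    g <- ratio(sum(counts$e_ws), sum(counts$e_sw),
               sum(counts$w_occ * counts$length),
               sum(counts$s_occ * counts$length))
    return(data.frame(unit = "tree", gc3_star = g,
                      e_ws = sum(counts$e_ws), e_sw = sum(counts$e_sw),
                      flag = ifelse(is.na(g), "undefined", ""),
                      stringsAsFactors = FALSE))
  }
  ## per tip: sum over the root-to-tip path
  par <- parent_vector(phy)
  root <- root_node(phy)
  idx <- setNames(seq_len(nrow(counts)), counts$node)
  out <- lapply(seq_along(phy$tip.label), function(tp) {
    path <- integer(0)
    nd <- tp
    while (!is.na(par[nd])) {
      path <- c(path, idx[[as.character(nd)]])
      nd <- par[nd]
    }
    ws <- sum(counts$e_ws[path]); sw <- sum(counts$e_sw[path])
    g <- ratio(ws, sw, sum(counts$w_occ[path] * counts$length[path]),
               sum(counts$s_occ[path] * counts$length[path]))
    data.frame(unit = phy$tip.label[tp], gc3_star = g, e_ws = ws, e_sw = sw,
               flag = ifelse(is.na(g), "undefined", ""),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Observed per-species GC fraction from a state matrix
#'
#' Companion to [gc3_star()] for GC3*-vs-GC3 comparisons.
#'
#' @param states integer state matrix (species x sites) or
#'   [ortholog_alignment].
#' @return data.frame with `species` and `gc`.
#' @export
tip_gc <- function(states) {
  if (inherits(states, "ortholog_alignment"))
    states <- if (states$kind == "coding") third_position_states(states)
              else encode_states(states$matrix)
  gc <- rowSums(states == 2L | states == 3L, na.rm = TRUE)
  tot <- rowSums(!is.na(states))
  data.frame(species = rownames(states),
             gc = ifelse(tot > 0, gc / tot, NA_real_),
             stringsAsFactors = FALSE)
}
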