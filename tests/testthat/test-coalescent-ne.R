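sp3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("lineage counts match hand reconciliation on 3-taxon cases", {
  ab_node <- ape::getMRCA(sp3, c("A", "B"))
  ## concordant gene tree: coalescence inside the AB branch
  conc <- ape::read.tree(text = "((A,B),C);")
  cb <- count_branch_lineages(sp3, conc, mapping = "lca")
  row <- cb[cb$node == ab_node, ]
  expect_equal(row$rootward, 1L)
  expect_equal(row$tipward, 2L)
  ## discordant topology forces deep coalescence: 2 at both ends
  disc <- ape::read.tree(text = "((A,C),B);")
  cb2 <- count_branch_lineages(sp3, disc, mapping = "lca")
  row2 <- cb2[cb2$node == ab_node, ]
  expect_equal(row2$rootward, 2L)
  expect_equal(row2$tipward, 2L)
  ## terminal branches always carry exactly one lineage
  expect_true(all(cb$tipward[cb$is_tip] == 1L))
})

test_that("gene-tree tips must be known species; missing species skip branches", {
  expect_error(
    count_branch_lineages(sp3, ape::read.tree(text = "((A,X),C);")),
    "not in the species tree")
  ## gene tree lacking B: the AB branch is uninformative (NA)
  gt <- ape::read.tree(text = "(A,C);")
  cb <- count_branch_lineages(sp3, gt, mapping = "lca")
  ab_node <- ape::getMRCA(sp3, c("A", "B"))
  expect_true(is.na(cb$tipward[cb$node == ab_node]))
})

test_that("lineage counts equal a brute-force clade-set oracle on 6 taxa", {
  ## oracle: a gene edge (u,w) covers the rootward end of branch C iff the
  ## species clade of C contains w's mapped clade and not u's, computed
  ## directly from tip-descendant sets
  set.seed(55)
  sp6 <- ape::rcoal(6, tip.label = LETTERS[1:6])
  tipsets <- function(phy) {
    n <- length(phy$tip.label)
    sets <- c(as.list(phy$tip.label),
              lapply(n + seq_len(phy$Nnode), function(nd)
                phy$tip.label[unlist(ape::prop.part(phy)[[nd - n]])]))
    sets
  }
  for (rep in 1:20) {
    gt <- ape::rcoal(6, tip.label = sample(LETTERS[1:6]))
    gt$edge.length <- NULL
    cb <- count_branch_lineages(sp6, gt, mapping = "lca")
    ssets <- tipsets(sp6); gsets <- tipsets(gt)
    ## species LCA-mapped clade of each gene node = smallest species clade
    ## containing its species set
    mapclade <- function(gset) {
      sizes <- vapply(ssets, length, integer(1))
      cand <- which(vapply(ssets, function(s) all(gset %in% s), logical(1)))
      ssets[[cand[which.min(sizes[cand])]]]
    }
    for (i in seq_len(nrow(cb))) {
      cl <- ssets[[cb$node[i]]]
      top <- 0L; bot <- 0L
      for (e in seq_len(nrow(gt$edge))) {
        wclade <- mapclade(gsets[[gt$edge[e, 2]]])
        uclade <- mapclade(gsets[[gt$edge[e, 1]]])
        inC_w <- all(wclade %in% cl); inC_u <- all(uclade %in% cl)
        if (inC_w && !inC_u) top <- top + 1L
        is_leaf <- gt$edge[e, 2] <= 6
        strict_w <- inC_w && length(wclade) < length(cl)
        u_at_or_above <- !inC_u || setequal(uclade, cl)
        if ((strict_w && u_at_or_above) ||
            (is_leaf && setequal(wclade, cl)))
          bot <- bot + 1L
      }
      expect_equal(cb$rootward[i], top)
      expect_equal(cb$tipward[i], bot)
    }
  }
})

test_that("coalescent branch lengths follow the n12/nkk count formula", {
  ## n12 = nkk gives ln 2; n12 = 0 gives length 0; nkk = 0 gives +Inf
  gts <- c(replicate(5, ape::read.tree(text = "((A,B),C);"), simplify = FALSE),
           replicate(5, ape::read.tree(text = "((A,C),B);"), simplify = FALSE))
  st <- coalescent_branch_lengths(sp3, gts, mapping = "lca")
  expect_equal(st$n12, 5L); expect_equal(st$nkk, 5L)
  expect_equal(st$coalescent_length, log(2))
  st0 <- coalescent_branch_lengths(sp3, gts[6:10], mapping = "lca")
  expect_equal(st0$coalescent_length, 0)
  stInf <- coalescent_branch_lengths(sp3, gts[1:5], mapping = "lca")
  expect_true(is.infinite(stInf$coalescent_length))
  expect_equal(stInf$flag, "infinite")
})

test_that("topology-only counting reproduces the (2/3)e^-T discordance and
          temporal counting removes the hidden-coalescence bias", {
  set.seed(71)
  n <- 6000
  gts <- simulate_gene_trees(sp3, n, seed = 17)   # time-calibrated
  lca <- coalescent_branch_lengths(sp3, gts, mapping = "lca")
  tmp <- coalescent_branch_lengths(sp3, gts, mapping = "temporal")
  p_disc <- (2 / 3) * exp(-1)
  expect_lt(abs(lca$nkk / n - p_disc), 3 * sqrt(p_disc * (1 - p_disc) / n))
  p_fail <- exp(-1)
  expect_lt(abs(tmp$nkk / n - p_fail), 3 * sqrt(p_fail * (1 - p_fail) / n))
  ## the topology route agrees with direct discordance counting
  disc <- sum(vapply(gts, function(g) !ape::is.monophyletic(g, c("A", "B")),
                     logical(1)))
  expect_equal(lca$nkk, disc)
})

test_that("adding discordant gene trees never increases the estimate", {
  gts <- simulate_gene_trees(sp3, 300, seed = 23)
  st <- coalescent_branch_lengths(sp3, gts)
  extra <- ape::read.tree(text = "((A:0.5,C:0.5):1.5,B:2);")
  st2 <- coalescent_branch_lengths(sp3, c(gts, list(extra)))
  expect_lte(st2$coalescent_length, st$coalescent_length)
})

test_that("gene-tree polytomies count conservatively as non-coalescence", {
  sp4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  ## rooted gene tree with an unresolved (A,B,C) node, built by hand
  poly <- list(edge = rbind(c(5L, 6L), c(6L, 1L), c(6L, 2L), c(6L, 3L),
                            c(5L, 4L)),
               Nnode = 2L, tip.label = c("A", "B", "C", "D"))
  class(poly) <- "phylo"
  st <- coalescent_branch_lengths(sp4, list(poly), mapping = "lca")
  abc <- ape::getMRCA(sp4, c("A", "B", "C"))
  ## the unresolved node maps into the ABC branch (1 above, 3 below);
  ## the conservative rule books it as a failure to coalesce
  expect_equal(st$nkk[st$node == abc], 1L)
  expect_equal(st$n12[st$node == abc], 0L)
})

test_that("Ne reconstruction arithmetic, flags and ranks", {
  ne <- reconstruct_ne(0.5, 1e7, 2, 2)
  expect_equal(ne$n_hat, 5e6)
  ne2 <- reconstruct_ne(c(0.5, Inf, NA, 0.2), rep(1e7, 4), rep(2, 4), rep(2, 4))
  expect_true(is.na(ne2$n_hat[2])); expect_equal(ne2$flag[2], "infinite_length")
  expect_true(is.na(ne2$n_hat[3]))
  expect_equal(ne2$rank[c(1, 4)], c(2L, 1L))
  expect_error(reconstruct_ne(0.5, -1, 2, 2), "positive")
  ## rank order invariant under common generation-time rescaling
  ne3 <- reconstruct_ne(c(0.4, 0.2, 0.9), rep(1e7, 3), rep(3, 3), rep(3, 3))
  ne4 <- reconstruct_ne(c(0.4, 0.2, 0.9), rep(1e7, 3), rep(6, 3), rep(6, 3))
  expect_equal(ne3$rank, ne4$rank)
})

test_that("branch filters apply length, support and cherry rules", {
  stats <- data.frame(node = 1:4,
                      coalescent_length = c(0.05, 0.5, 0.5, 0.5),
                      support = c(90, 49, 90, 90),
                      is_cherry = c(TRUE, TRUE, FALSE, TRUE))
  f <- filter_branches(stats, min_coal_length = 0.1, min_support = 50,
                       cherry_only = TRUE)
  expect_equal(f$node, 4L)
  ## disabling the support filter retains the low-support branch
  f2 <- filter_branches(stats, min_coal_length = 0.1, min_support = NA,
                        cherry_only = TRUE)
  expect_setequal(f2$node, c(2L, 4L))
  expect_warning(filter_branches(stats, min_coal_length = 10), "no branches")
})
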