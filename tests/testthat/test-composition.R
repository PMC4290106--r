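test_that("GC by position class matches hand counts and excludes gaps", {
  a <- aln_from("g", "coding", s1 = "ATGGCC")
  expect_equal(gc_by_class(a, "c1")$gc_fraction, 0.5)   # A,G
  expect_equal(gc_by_class(a, "c2")$gc_fraction, 0.5)   # T,C
  expect_equal(gc_by_class(a, "c3")$gc_fraction, 1.0)   # G,C
  ## gap codon: third positions G and A -> 0.5 over two counted sites
  b <- aln_from("g2", "coding", s1 = "ATG---GCA")
  d <- gc_by_class(b, "c3")
  expect_equal(d$gc_fraction, 0.5)
  expect_equal(d$counted_sites, 2L)
  ## zero counted sites is NA, not 0
  z <- aln_from("g3", "coding", s1 = "--N")
  expect_true(is.na(gc_by_class(z, "c3")$gc_fraction))
})

test_that("GC counting equals a naive per-column oracle on random data", {
  a <- random_alignment("r", 6, 300, seed = 42)
  for (cl in c("c1", "c2", "c3", "c12", "c123")) {
    cols <- avigc:::class_columns(a, cl)
    oracle <- naive_gc(a, cols)
    got <- gc_by_class(a, cl)
    expect_equal(got$gc_count, unname(oracle["gc", got$species]))
    expect_equal(got$counted_sites, unname(oracle["counted", got$species]))
  }
})

test_that("gc123 count identity holds exactly", {
  for (seed in 1:5) {
    a <- random_alignment(paste0("r", seed), 4, 50, seed = seed, gap_frac = 0.2)
    d1 <- gc_by_class(a, "c1"); d2 <- gc_by_class(a, "c2")
    d3 <- gc_by_class(a, "c3"); d123 <- gc_by_class(a, "c123")
    expect_identical(d123$gc_count, d1$gc_count + d2$gc_count + d3$gc_count)
    expect_identical(d123$counted_sites,
                     d1$counted_sites + d2$counted_sites + d3$counted_sites)
  }
})

test_that("pooled GC is count-weighted, not a mean of fractions", {
  ## GC3 counts 3/3 and 0/300 must pool to 3/303, not 0.5
  g1 <- aln_from("a", "coding", s = "AAGAACAAC")             # c3: G,C,C
  g2 <- aln_from("b", "coding",
                 s = paste(rep("AAA", 300), collapse = ""))
  p <- pooled_gc(list(g1, g2), "c3")
  expect_equal(p$gc_fraction, 3 / 303)
  ## single gene reduces to gc_by_class
  expect_equal(pooled_gc(list(g1), "c3")$gc_fraction,
               gc_by_class(g1, "c3")$gc_fraction)
})

test_that("pooled GC equals the concatenate-then-count oracle", {
  set.seed(7)
  alns <- lapply(1:50, function(i) random_alignment(sprintf("g%02d", i), 5, 30,
                                                    seed = 1000 + i))
  p <- pooled_gc(alns, "c3")
  big <- do.call(cbind, lapply(alns, function(a)
    a$matrix[p$species, avigc:::class_columns(a, "c3"), drop = FALSE]))
  concat <- ortholog_alignment("cat", "c3", big)
  q <- gc_by_class(concat, "c3")
  expect_equal(p$gc_fraction, q$gc_fraction)
  expect_equal(p$counted_sites, q$counted_sites)
})

test_that("pooled GC refuses orthologs missing a species", {
  g1 <- aln_from("a", "coding", s1 = "ATG", s2 = "ATG")
  g2 <- aln_from("b", "coding", s1 = "ATG")
  expect_error(pooled_gc(list(g1, g2), "c3"), "missing species")
})

test_that("universal ortholog set equals a brute-force membership scan", {
  set.seed(3)
  roster <- sprintf("sp%02d", 1:8)
  alns <- lapply(1:100, function(i) {
    keep <- roster[runif(8) > 0.1]
    if (length(keep) == 0L) keep <- roster[1]
    m <- matrix("A", length(keep), 3, dimnames = list(keep, NULL))
    ortholog_alignment(sprintf("g%03d", i), "coding", m)
  })
  got <- universal_ortholog_set(alns, roster)
  oracle <- sort(unlist(lapply(alns, function(a)
    if (all(roster %in% a$species)) a$ortholog_id else NULL)))
  expect_identical(got, oracle)
  ## dropping one species everywhere empties the set with a warning
  expect_warning(universal_ortholog_set(alns, c(roster, "ghost")), "no ortholog")
})

test_that("variance partition ranks, tie-breaks and matches a sort oracle", {
  comp <- data.frame(
    ortholog_id = rep(c("gA", "gB", "gC"), each = 3),
    species = rep(c("x", "y", "z"), 3),
    class = "c3",
    gc_fraction = c(0.5, 0.5, 0.5,    # var 0
                    0.4, 0.5, 0.6,    # var 0.01
                    0.3, 0.5, 0.7))   # var 0.04
  vp <- variance_partition(comp, k = 1)
  expect_identical(vp$high, "gC")
  expect_identical(vp$low, "gA")
  expect_equal(vp$ranked$variance[1], var(c(0.3, 0.5, 0.7)))
  ## equal variances: deterministic lexicographic tie-break
  comp$gc_fraction <- rep(c(0.4, 0.5, 0.6), 3)
  vp2 <- variance_partition(comp, k = 1)
  expect_identical(vp2$high, "gA")
  expect_identical(vp2$low, "gC")
  expect_error(variance_partition(comp, k = 2), "k must satisfy")
  ## random table equals brute-force sort
  set.seed(9)
  ids <- sprintf("g%03d", 1:40)
  rc <- data.frame(ortholog_id = rep(ids, each = 6),
                   species = rep(sprintf("s%d", 1:6), 40),
                   class = "c3", gc_fraction = runif(240))
  vp3 <- variance_partition(rc, k = 10)
  v <- sapply(split(rc$gc_fraction, rc$ortholog_id), var)
  ord <- order(-v, names(v))
  expect_identical(vp3$high, names(v)[ord][1:10])
  expect_identical(vp3$low, rev(names(v)[ord])[1:10])
})

test_that("homogeneity classifier flags heterogeneous composition", {
  ## identical counts: statistic 0, homogenous
  a <- aln_from("h1", "coding", s1 = "AAGAAC", s2 = "AAGAAC")
  h <- classify_homogeneity(a)
  expect_equal(h$label, "homogenous")
  expect_equal(unname(h$statistic), 0)
  ## 90 GC / 10 AT vs 10 GC / 90 AT at 100 third positions: compare to a
  ## direct chi-square on the 2x2 table
  mk <- function(ngc) paste0(strrep("AAG", ngc), strrep("AAA", 100 - ngc))
  b <- aln_from("h2", "coding", s1 = mk(90), s2 = mk(10))
  h2 <- classify_homogeneity(b, alpha = 0.01)
  oracle <- chisq.test(rbind(c(90, 10), c(10, 90)), correct = FALSE)
  expect_equal(h2$label, "non-homogenous")
  expect_equal(h2$p_value, oracle$p.value)
  expect_equal(h2$df, 1L)
  ## a single informative site cannot reject; flagged low-count
  c3 <- aln_from("h3", "coding", s1 = "AAG", s2 = "AAA")
  h3 <- classify_homogeneity(c3)
  expect_equal(h3$label, "homogenous")
  expect_true(h3$low_counts)
  ## species with no counted third positions are excluded with a warning
  d <- aln_from("h4", "coding", s1 = "AAG", s2 = "AA-", s3 = "AAC")
  expect_warning(h4 <- classify_homogeneity(d), "excluded")
  expect_setequal(h4$species_used, c("s1", "s3"))
  expect_error(suppressWarnings(
    classify_homogeneity(aln_from("h5", "coding", s1 = "AAG", s2 = "AA-"))),
    "fewer than 2")
})

test_that("homogeneity false-rejection rate is near alpha when species are
          compositionally exchangeable", {
  ## deep star phylogeny: third-position states nearly independent across
  ## species, all at the same equilibrium
  star <- ape::read.tree(text = "(a:3,b:3,c:3,d:3,e:3,f:3):0;")
  star <- ape::root(star, outgroup = "a", resolve.root = TRUE)
  th <- flat_theta(0.45, star$tip.label)
  n_rep <- 400
  set.seed(202)
  sim <- simulate_alignments(star, th[rep(1, n_rep), , drop = FALSE], 0.45,
                             kappa = 2, sites = 150, kind = "c3")
  rej <- mean(vapply(sim$alignments, function(a)
    classify_homogeneity(a, alpha = 0.05)$label == "non-homogenous",
    logical(1)))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej - 0.05), 3 * se + 1e-9)
})
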