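test_that("generators are deterministic under (config, seed)", {
  cfg <- simulation_config(n_species = 8, n_genes = 12, codons = 30,
                           n_introns = 4, intron_length = 60, n_gene_trees = 10)
  d1 <- simulate_dataset(cfg, seed = 5)
  d2 <- simulate_dataset(cfg, seed = 5)
  expect_identical(d1$species$traits, d2$species$traits)
  expect_identical(d1$theta_tip, d2$theta_tip)
  expect_identical(lapply(d1$coding, `[[`, "matrix"),
                   lapply(d2$coding, `[[`, "matrix"))
  expect_identical(ape::write.tree(d1$gene_trees[[3]]),
                   ape::write.tree(d2$gene_trees[[3]]))
  expect_identical(d1$recomb$map1, d2$recomb$map1)
  ## different seed changes the draws
  d3 <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(d1$species$traits, d3$species$traits))
  ## substreams: growing the gene count leaves the trait table untouched
  cfg2 <- simulation_config(n_species = 8, n_genes = 24, codons = 30,
                            n_introns = 4, intron_length = 60, n_gene_trees = 10)
  d4 <- simulate_dataset(cfg2, seed = 5)
  expect_identical(d1$species$traits, d4$species$traits)
})

test_that("species system: mass-theta coupling responds to the effect switch", {
  cfg_on <- simulation_config(n_species = 40)
  cfg_off <- simulation_config(n_species = 40, mass_effect = 0)
  rho_on <- rho_off <- numeric(12)
  for (s in seq_len(12)) {
    on <- simulate_species_system(cfg_on, seed = 100 + s)
    off <- simulate_species_system(cfg_off, seed = 100 + s)
    rho_on[s] <- cor(on$traits$body_mass_g, on$theta_species[on$traits$species],
                     method = "spearman")
    rho_off[s] <- suppressWarnings(
      cor(off$traits$body_mass_g, off$theta_species[off$traits$species],
          method = "spearman"))
  }
  expect_true(all(rho_on < -0.5))
  expect_true(all(is.na(rho_off) | abs(rho_off) < 0.3))
  ## life-history scaling: maturity increases with mass on average
  on <- simulate_species_system(cfg_on, seed = 1)
  expect_gt(cor(log(on$traits$body_mass_g), log(on$traits$age_first_maturity_yr)),
            0.5)
  ## Ne decreases with body mass (exact power law on terminal branches)
  nt <- on$node_table[on$node_table$is_tip, ]
  tipmass <- on$traits$body_mass_g[match(
    on$tree_my$phylo$tip.label[nt$node], on$traits$species)]
  expect_equal(cor(log(nt$ne_branch), log(tipmass)), -1)
  ## and the coalescent lengths satisfy T = span / (2 Ne g) by construction
  g <- (nt$generation_time_rootward + nt$generation_time_tipward) / 2
  expect_equal(nt$coal_length_true,
               nt$time_span_my * 1e6 / (2 * nt$ne_branch * g))
})

test_that("MSC gene trees: discordance decays as expected and vanishes for
          long branches", {
  sp <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  gts <- simulate_gene_trees(sp, 3000, seed = 12)
  disc <- mean(vapply(gts, function(g) !ape::is.monophyletic(g, c("A", "B")),
                      logical(1)))
  p <- (2 / 3) * exp(-1)
  expect_lt(abs(disc - p), 3 * sqrt(p * (1 - p) / 3000))
  ## T = 10: discordance essentially gone
  sp10 <- ape::read.tree(text = "((A:10,B:10):10,C:20);")
  gts10 <- simulate_gene_trees(sp10, 2000, seed = 13)
  disc10 <- mean(vapply(gts10, function(g)
    !ape::is.monophyletic(g, c("A", "B")), logical(1)))
  expect_lt(disc10, 0.005)
  ## fixed seed: identical tree sequence
  gts_a <- simulate_gene_trees(sp, 5, seed = 3)
  gts_b <- simulate_gene_trees(sp, 5, seed = 3)
  expect_identical(lapply(gts_a, ape::write.tree), lapply(gts_b, ape::write.tree))
  ## time calibration: gene trees are ultrametric and no coalescence sits
  ## below its clade's species node
  h <- avigc:::node_heights(gts_a[[1]])
  expect_true(all(abs(h[1:3]) < 1e-9))
})

test_that("alignment simulator: stationary mean GC3 matches theta and the
          event log is consistent", {
  tre <- ape::read.tree(text = "((a:0.08,b:0.08):0.04,(c:0.08,d:0.08):0.04);")
  th <- flat_theta(0.42, tre$tip.label)
  sim <- simulate_alignments(tre, th[rep(1, 40), , drop = FALSE], 0.42,
                             kappa = 2, sites = 300, kind = "c3", seed = 21)
  p <- pooled_gc(sim$alignments, "c3")
  expect_true(all(abs(p$gc_fraction - 0.42) < 0.015))
  ## event logging: realized event count scales with length x sites
  sim2 <- simulate_alignments(tre, th[rep(1, 10), , drop = FALSE], 0.42,
                              kappa = 2, sites = 2000, kind = "c3", seed = 22,
                              log_events = TRUE)
  ev <- sim2$events
  expect_equal(sort(ev$node), sort(tre$edge[, 2]))
  elen <- setNames(tre$edge.length, tre$edge[, 2])
  for (i in seq_len(nrow(ev))) {
    lambda <- elen[as.character(ev$node[i])] * 20000
    expect_lt(abs(ev$n_events[i] - lambda), 4 * sqrt(lambda))
  }
  ## byte-identical FASTA under a fixed seed
  f1 <- tempfile(); f2 <- tempfile()
  s1 <- simulate_alignments(tre, th, 0.42, sites = 50, kind = "c3", seed = 9)
  s2 <- simulate_alignments(tre, th, 0.42, sites = 50, kind = "c3", seed = 9)
  write_alignment(s1$alignments[[1]], f1); write_alignment(s2$alignments[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("coding alignments interleave positions with a compressed GC1/GC2
          range", {
  cfg <- simulation_config(n_species = 10, n_genes = 150, codons = 60,
                           n_introns = 0, n_gene_trees = 0)
  ds <- simulate_dataset(cfg, seed = 33)
  expect_equal(ds$coding[[1]]$kind, "coding")
  expect_equal(ds$coding[[1]]$length, 180L)
  p1 <- pooled_gc(ds$coding, "c1")$gc_fraction
  p2 <- pooled_gc(ds$coding, "c2")$gc_fraction
  p3 <- pooled_gc(ds$coding, "c3")$gc_fraction
  expect_gt(sd(p3), sd(p1))
  expect_gt(sd(p3), sd(p2))
})

test_that("recombination system hits the configured cross-map correlation and
          couples multipliers to window rates", {
  cfg <- simulation_config(n_genes = 1500)
  rec <- simulate_recomb_system(cfg, seed = 44)
  rho <- cor(rec$map1$rate_cm_mb, rec$map2$rate_cm_mb, method = "spearman")
  expect_lt(abs(rho - cfg$cross_map_rho), 0.1)
  ## small chromosomes recombine faster
  small <- rec$map1$chrom %in% as.character(10:28)
  expect_gt(median(rec$map1$rate_cm_mb[small]),
            median(rec$map1$rate_cm_mb[!small]))
  ## the per-gene multiplier reflects the window's shared rate
  expect_gt(cor(rec$multiplier,
                rec$true_rate[rec$window_of_gene]), 0.99)
  expect_equal(mean(rec$multiplier), 1, tolerance = 0.05)
  ## locations fall inside their windows and validate as a table
  f <- tempfile(); write_table(rec$locations, f)
  expect_silent(loc <- read_locations(f))
  expect_true(all(loc$end - loc$start > 0))
})

test_that("generated data satisfy the reader invariants without special cases", {
  cfg <- simulation_config(n_species = 6, n_genes = 8, codons = 20,
                           n_introns = 3, intron_length = 40, n_gene_trees = 6)
  ds <- simulate_dataset(cfg, seed = 55)
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  coding <- lapply(list.files(file.path(dir, "coding"), full.names = TRUE),
                   read_alignment, kind = "coding")
  expect_length(coding, 8L)
  expect_true(all(vapply(coding, function(a) a$length %% 3L == 0L, logical(1))))
  tt <- read_trait_table(file.path(dir, "traits.tsv"))
  expect_equal(nrow(tt), 6L)
  mp <- read_recomb_map(file.path(dir, "recomb_map_ref1.tsv"))
  expect_gt(nrow(mp), 100L)
  tr <- read_tree(file.path(dir, "species_tree_my.nwk"), "my")
  expect_equal(sort(tr$phylo$tip.label), sort(tt$species))
  gts <- ape::read.tree(file.path(dir, "gene_trees.nwk"))
  expect_length(gts, 6L)
})
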