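mk_map <- function(chrom, starts, width = 1e6, rates = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = starts,
                   end = starts + width,
                   rate_cm_mb = rates %||% seq_along(starts),
                   stringsAsFactors = FALSE)
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("window assignment: containment, majority overlap, drops", {
  map <- mk_map("1", c(0, 1e6, 2e6))
  loc <- data.frame(ortholog_id = c("gA", "gB", "gC"), genome = "ref",
                    chrom = "1",
                    start = c(1500000, 1940000, 9e6),
                    end = c(1520000, 2040000, 9.1e6))
  expect_message(j <- assign_windows(loc, map), "1 ortholog")
  expect_equal(j$win_start[j$ortholog_id == "gA"], 1e6)
  ## gB spans the 2 Mb boundary 60/40: majority window wins
  expect_equal(j$win_start[j$ortholog_id == "gB"], 1e6)
  expect_false("gC" %in% j$ortholog_id)
  ## exact 50/50 tie goes to the lower start
  loc2 <- data.frame(ortholog_id = "gT", genome = "ref", chrom = "1",
                     start = 1990000, end = 2010000)
  j2 <- assign_windows(loc2, map)
  expect_equal(j2$win_start, 1e6)
  ## genome mismatch is refused
  attr(map, "genome") <- "chicken"
  expect_error(assign_windows(loc, map), "mismatch")
})

test_that("window assignment equals a brute-force interval-overlap oracle", {
  set.seed(66)
  map <- do.call(rbind, lapply(1:3, function(ch) mk_map(ch, (0:19) * 1e6,
                                                        rates = runif(20))))
  n <- 200
  loc <- data.frame(ortholog_id = sprintf("g%03d", 1:n), genome = "ref",
                    chrom = as.character(sample(1:3, n, TRUE)),
                    start = floor(runif(n, 0, 19.9e6)))
  loc$end <- loc$start + sample(1e4:2e6, n, TRUE)
  j <- assign_windows(loc, map)
  for (i in sample(n, 40)) {
    w <- map[map$chrom == loc$chrom[i], ]
    ov <- pmax(0, pmin(loc$end[i], w$end) - pmax(loc$start[i], w$start))
    best <- w[which(ov == max(ov)), ][1, ]
    got <- j[j$ortholog_id == loc$ortholog_id[i], ]
    if (max(ov) == 0) expect_equal(nrow(got), 0L)
    else expect_equal(got$win_start, best$start)
  }
  ## assignment is a function: one window per retained ortholog
  expect_equal(anyDuplicated(j$ortholog_id), 0L)
})

test_that("window statistics: sd/mean columns, intron floor, correlations", {
  map <- mk_map("1", c(0, 1e6), rates = c(1, 5))
  loc <- data.frame(ortholog_id = c("gA", "gB"), genome = "ref", chrom = "1",
                    start = c(100, 1000100), end = c(1100, 1001100))
  j <- assign_windows(loc, map)
  comp <- data.frame(
    ortholog_id = rep(c("gA", "gB"), each = 3),
    species = rep(c("x", "y", "z"), 2), class = "c3",
    gc_fraction = c(0.5, 0.5, 0.5, 0.3, 0.5, 0.7),
    gc_count = 0, counted_sites = 10)
  ws <- window_statistics(j, comp)
  expect_equal(ws$per_ortholog$sd_gc3[ws$per_ortholog$ortholog_id == "gA"], 0)
  expect_equal(ws$per_ortholog$sd_gc3[ws$per_ortholog$ortholog_id == "gB"],
               sd(c(0.3, 0.5, 0.7)))
  ## windows below the intron floor are suppressed
  icomp <- data.frame(
    ortholog_id = rep(c("gA", "gB"), each = 2),
    species = rep(c("x", "y"), 2), class = "intron",
    gc_fraction = 0.5, gc_count = 5, counted_sites = 10)
  ws2 <- window_statistics(j, rbind(comp, icomp), min_introns = 10)
  expect_true(is.null(ws2$per_window_intron) || nrow(ws2$per_window_intron) == 0)
  ws3 <- window_statistics(j, rbind(comp, icomp), min_introns = 1)
  expect_equal(nrow(ws3$per_window_intron), 2L)
})

test_that("high-recombination genes show larger between-species GC3 spread
          with generator defaults", {
  cfg <- simulation_config(n_species = 12, n_genes = 600, codons = 120,
                           n_introns = 0, n_gene_trees = 0,
                           positions = "third_only")
  ds <- simulate_dataset(cfg, seed = 77)
  comp <- composition_table(ds$coding)
  j <- assign_windows(ds$recomb$locations, ds$recomb$map1)
  ws <- window_statistics(j, comp)
  sd_row <- ws$correlations[ws$correlations$stat == "sd" &
                              ws$correlations$class == "c3", ]
  expect_gt(sd_row$rho, 0)
  expect_lt(sd_row$p_value, 0.01)
})

test_that("null coupling leaves the sd-rate test at its nominal size", {
  ## switch off both the mass effect and the recombination shift: theta no
  ## longer depends on the window, so sd(GC3) vs rate is a null test
  n_rep <- 60
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(n_species = 8, n_genes = 150, codons = 60,
                             n_introns = 0, n_gene_trees = 0,
                             positions = "third_only",
                             mass_effect = 0, terminal_shift = 0,
                             gene_species_noise = 0)
    ds <- simulate_dataset(cfg, seed = 500 + r)
    comp <- composition_table(ds$coding)
    j <- assign_windows(ds$recomb$locations, ds$recomb$map1)
    ws <- window_statistics(j, comp)
    pvals[r] <- ws$correlations$p_value[ws$correlations$stat == "sd"]
  }
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)
})

test_that("chromosome classes: toy medians and the small>large pattern", {
  map <- rbind(mk_map("2", 0, rates = 1), mk_map("11", 0, rates = 8))
  loc <- data.frame(ortholog_id = c("g1", "g2", "g3", "g4"), genome = "ref",
                    chrom = c("2", "2", "11", "11"),
                    start = c(0, 100, 0, 100), end = c(50, 150, 50, 150))
  comp <- data.frame(
    ortholog_id = rep(c("g1", "g2", "g3", "g4"), each = 2),
    species = rep(c("x", "y"), 4), class = "c3",
    gc_fraction = c(0.40, 0.42, 0.44, 0.40, 0.50, 0.58, 0.52, 0.60),
    gc_count = 0, counted_sites = 10)
  j <- assign_windows(loc, map)
  cc <- chromosome_class_compare(j, comp)
  mg <- cc[cc$statistic == "mean_gc", ]
  expect_equal(mg$median_small, median(c(0.54, 0.56)))
  expect_equal(mg$median_large, median(c(0.41, 0.42)))
  expect_error(chromosome_class_compare(j, comp, large_chroms = "7"),
               "empty chromosome class")
  ## generator defaults: small-chromosome orthologs have higher median GC3
  cfg <- simulation_config(n_species = 10, n_genes = 500, codons = 100,
                           n_introns = 0, n_gene_trees = 0,
                           positions = "third_only")
  ds <- simulate_dataset(cfg, seed = 88)
  comp2 <- composition_table(ds$coding)
  j2 <- assign_windows(ds$recomb$locations, ds$recomb$map1)
  cc2 <- chromosome_class_compare(j2, comp2,
                                  large_chroms = as.character(1:9),
                                  small_chroms = as.character(10:28))
  m2 <- cc2[cc2$statistic == "mean_gc", ]
  expect_gt(m2$median_small, m2$median_large)
  expect_lt(m2$wilcoxon_p, 0.05)
})

test_that("cross-map correlation: identity and generator recovery", {
  map <- mk_map("1", (0:9) * 1e6, rates = runif(10))
  loc <- data.frame(ortholog_id = sprintf("g%02d", 1:10), genome = "ref",
                    chrom = "1", start = (0:9) * 1e6 + 100,
                    end = (0:9) * 1e6 + 2000)
  j <- assign_windows(loc, map)
  r <- cross_map_correlation(j, j)
  expect_equal(r$estimate, 1)
  expect_error(cross_map_correlation(j[1:2, ], j[1:2, ]), "fewer than 3")
  ## two generator maps joined over the simulated orthologs
  cfg <- simulation_config(n_genes = 1500)
  rec <- simulate_recomb_system(cfg, seed = 99)
  j1 <- assign_windows(rec$locations, rec$map1)
  j2 <- assign_windows(rec$locations, rec$map2)
  xr <- cross_map_correlation(j1, j2)
  expect_lt(abs(xr$estimate - cfg$cross_map_rho), 0.12)
})
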