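#' Simulation configuration
#'
#' Defaults describe the study conditions the package's analyses assume: a
#' 40-species, 100-My radiation-shaped phylogeny, 1,500 coding orthologs of
#' 300 codons plus 404 introns of 500 bp, an ancestral third-position
#' equilibrium GC (theta) of 0.42 shifted upward by 0.08 on terminal
#' branches (recent GC gains), a negative body-mass effect on theta of
#' rank-based spread 0.2, per-gene recombination multipliers tied to window
#' rates, branch effective sizes decreasing with body mass, and a target
#' cross-map recombination correlation of 0.4. See the methods vignette for
#' the rationale behind each value.
#'
#' @param ... overrides of the defaults, by name.
#' @return named list of parameters.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_species = 40L, n_genes = 1500L, codons = 300L,
    n_introns = 404L, intron_length = 500L, n_gene_trees = 500L,
    depth_my = 100, radiation = 0.3, subst_per_my = 0.002,
    theta_base = 0.42, terminal_shift = 0.08,
    mass_effect = 1, theta_spread = 0.2, gene_species_noise = 0.02,
    intron_shift = 0.05, intron_attenuation = 0.7,
    kappa = 2, compress12 = 0.15,
    mass_log10_mean = 2.5, mass_log10_sd = 1, mass_rank_noise = 0.3,
    maturity_coef = 0.3, maturity_exp = 0.25, maturity_noise = 0.3,
    longevity_coef = 3, longevity_exp = 0.2, longevity_noise = 0.3,
    ne_ref = 5e5, ne_mass_exp = 0.3,
    n_large_chrom = 9L, n_small_chrom = 19L, window_bp = 1e6,
    rate_base = 0.8, rate_per_chrom = 60, rate_sigma = 0.5,
    cross_map_rho = 0.4,
    positions = "all")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_avigc("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(n_species >= 4, n_genes >= 1, codons >= 1, depth_my > 0,
              subst_per_my > 0, theta_base > 0, theta_base < 1, kappa > 0,
              ne_ref > 0, window_bp > 0)
  })
  cfg
}

## ultrametric species tree with node heights pushed toward the root
## (power < 1 mimics a rapid radiation: short deep internodes, long
## terminal branches)
sim_species_tree <- function(n, depth_my, radiation) {
  phy <- ape::rcoal(n, tip.label = sprintf("sp%02d", seq_len(n)))
  bt <- ape::branching.times(phy)
  h <- numeric(n + phy$Nnode)
  h[as.integer(names(bt))] <- depth_my * (bt / max(bt))^radiation
  phy$edge.length <- h[phy$edge[, 1L]] - h[phy$edge[, 2L]]
  attr(phy, "heights_my") <- h
  phy
}

#' Simulate the species-level system: tree, traits, population sizes
#'
#' Body mass is log-normal across species; age at first maturity and
#' longevity increase with mass (power laws with noise); the terminal
#' theta deviation is a noisy rank of 1/mass scaled by
#' `mass_effect * theta_spread` (so the mass-theta association is negative
#' with configurable strength); branch effective sizes decrease with the
#' mass of the descendant clade. Branch lengths in coalescent units are
#' time span / (2 Ne g).
#'
#' @param config from [simulation_config()].
#' @param seed RNG seed for this generator's stream.
#' @return list with `tree_my` ([labeled_tree], My), `subst_tree` (`phylo`,
#'   substitutions/site), `coal_tree` (`phylo`, coalescent units),
#'   `traits` (data.frame), `theta_dev`, `theta_species` (expected
#'   terminal theta per species), `node_table` (per-branch time spans,
#'   generation times, Ne) and `generation_time` (per species, yr).
#' @export
simulate_species_system <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_species
  phy <- sim_species_tree(n, config$depth_my, config$radiation)
  sp <- phy$tip.label
  log10_mass <- rnorm(n, config$mass_log10_mean, config$mass_log10_sd)
  mass <- 10^log10_mass
  maturity <- config$maturity_coef * mass^config$maturity_exp *
    exp(rnorm(n, 0, config$maturity_noise))
  longevity <- pmax(config$longevity_coef * mass^config$longevity_exp *
                      exp(rnorm(n, 0, config$longevity_noise)), maturity * 1.5)
  traits <- data.frame(species = sp, body_mass_g = mass,
                       max_longevity_yr = longevity,
                       age_first_maturity_yr = maturity,
                       stringsAsFactors = FALSE)
  ## negative mass-theta association through a noisy mass rank
  noisy <- log10_mass + rnorm(n, 0, config$mass_rank_noise)
  dev <- config$mass_effect * config$theta_spread *
    (rank(-noisy) - (n + 1) / 2) / n
  names(dev) <- sp
  gen_time <- pmax(0.4, maturity)
  names(gen_time) <- sp
  ## per-node aggregates over descendant tips
  idx <- species_index(phy)
  node_g <- vapply(seq_len(idx$nnode), function(nd)
    mean(gen_time[idx$tips[idx$below[nd, ]]]), numeric(1))
  node_mass <- vapply(seq_len(idx$nnode), function(nd)
    exp(mean(log(mass[match(idx$tips[idx$below[nd, ]], sp)]))), numeric(1))
  node_ne <- config$ne_ref * (node_mass / 1000)^(-config$ne_mass_exp)
  ## branch tables (branch = child node)
  child <- phy$edge[, 2L]; parent <- phy$edge[, 1L]
  span_my <- phy$edge.length
  g_branch <- (node_g[child] + node_g[parent]) / 2
  ne_branch <- node_ne[child]
  coal_len <- span_my * 1e6 / (2 * ne_branch * g_branch)
  coal_tree <- phy
  coal_tree$edge.length <- coal_len
  subst_tree <- phy
  subst_tree$edge.length <- phy$edge.length * config$subst_per_my
  node_table <- data.frame(node = child, parent = parent,
                           is_tip = child <= n,
                           time_span_my = span_my,
                           generation_time_rootward = node_g[parent],
                           generation_time_tipward = node_g[child],
                           ne_branch = ne_branch,
                           coal_length_true = coal_len,
                           stringsAsFactors = FALSE)
  list(tree_my = labeled_tree(phy, "my",
                              support = rep(100, phy$Nnode)),
       subst_tree = subst_tree, coal_tree = coal_tree,
       traits = traits, theta_dev = dev,
       theta_species = clamp01(config$theta_base + config$terminal_shift + dev),
       generation_time = gen_time, node_table = node_table)
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One sampled lineage per species. Within each species-tree branch of
#' coalescent length T, k lineages coalesce at rate k(k-1)/2 per unit;
#' survivors merge rootward, and everything coalesces above the root.
#' When a `time_tree` (same topology, branch lengths on a time axis, e.g.
#' My) is supplied — or when the coalescent-unit tree is itself
#' ultrametric and can serve as its own time axis — gene trees are
#' returned time-calibrated (ultrametric edge lengths recording every
#' coalescence time), which enables the temporal reconciliation of
#' [count_branch_lineages()]. Otherwise plain topologies are returned.
#'
#' @param coal_tree rooted `phylo` (or [labeled_tree]) with branch lengths
#'   in coalescent units.
#' @param n_genes number of gene trees.
#' @param seed RNG seed.
#' @param time_tree optional `phylo` with identical topology and node ids,
#'   branch lengths in time units.
#' @return list of rooted binary `phylo` objects.
#' @export
simulate_gene_trees <- function(coal_tree, n_genes, seed = NULL,
                                time_tree = NULL) {
  phy <- as_phylo(coal_tree)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(phy$tip.label)
  kids <- children_list(phy)
  elen <- setNames(phy$edge.length, phy$edge[, 2L])
  post <- postorder_nodes(phy)
  root <- root_node(phy)
  if (is.null(time_tree) &&
      isTRUE(all.equal(ape::is.ultrametric(phy, option = 2), TRUE)))
    time_tree <- phy
  timed <- !is.null(time_tree)
  if (timed) {
    tphy <- as_phylo(time_tree)
    if (!identical(dim(tphy$edge), dim(phy$edge)))
      stop_avigc("time_tree must share the species-tree topology")
    sph <- node_heights(tphy)
    tlen <- setNames(tphy$edge.length, tphy$edge[, 2L])
    ## time per coalescent unit, per branch (root: scale of longest branch)
    conv <- tlen / pmax(elen[names(tlen)], .Machine$double.xmin)
    conv_root <- stats::median(conv[is.finite(conv) & conv > 0])
  }
  one_tree <- function() {
    m <- 2L * ntip - 1L
    par <- integer(m)            # gene-tree parent pointers
    hts <- numeric(m)            # gene node heights on the time axis
    nxt <- ntip + 1L             # next internal id, root created last
    sets <- vector("list", ntip + phy$Nnode)
    for (tp in seq_len(ntip)) sets[[tp]] <- tp
    coalesce <- function(lin, Tlen, t0, cv) {
      k <- length(lin)
      t <- 0
      while (k >= 2L) {
        t <- t + rexp(1L, k * (k - 1L) / 2)
        if (t > Tlen) break
        pair <- sample(k, 2L)
        par[lin[pair]] <<- nxt
        if (timed) hts[nxt] <<- t0 + t * cv
        lin <- c(lin[-pair], nxt)
        nxt <<- nxt + 1L
        k <- k - 1L
      }
      lin
    }
    for (nd in post) {
      lin <- unlist(lapply(kids[[nd]], function(ch) {
        key <- as.character(ch)
        coalesce(sets[[ch]], elen[[key]],
                 t0 = if (timed) sph[ch] else 0,
                 cv = if (timed) conv[[key]] else 1)
      }))
      sets[[nd]] <- lin
    }
    lin <- coalesce(sets[[root]], Inf,
                    t0 = if (timed) sph[root] else 0,
                    cv = if (timed) conv_root else 1)
    ## renumber internals so the gene-tree root is ntip+1 (ape convention)
    created <- seq(ntip + 1L, nxt - 1L)
    newid <- c(seq_len(ntip), rev(seq(ntip + 1L, length.out = length(created))))
    nonroot <- seq_len(nxt - 2L)
    edge <- cbind(newid[par[nonroot]], newid[nonroot])
    gt <- list(edge = edge, Nnode = ntip - 1L, tip.label = phy$tip.label)
    if (timed) {
      h <- numeric(m); h[newid[seq_len(nxt - 1L)]] <- hts[seq_len(nxt - 1L)]
      gt$edge.length <- h[edge[, 1L]] - h[edge[, 2L]]
    }
    class(gt) <- "phylo"
    gt
  }
  lapply(seq_len(n_genes), function(i) one_tree())
}

## Exact stochastic simulation of T92 evolution along one branch with
## event counting (Gillespie); theta varies by gene, kappa scalar.
gillespie_branch <- function(st, gene, theta, kappa, t_len) {
  b <- 1 / (kappa * theta * (1 - theta) + 0.5)
  rW <- b * (theta * (1 + kappa) / 2 + (1 - theta) / 2)  # out of A or T
  rS <- b * ((1 - theta) * (1 + kappa) / 2 + theta / 2)  # out of C or G
  t_rem <- rep(t_len, length(st))
  e_ws <- 0; e_sw <- 0; n_ev <- 0
  active <- seq_along(st)
  while (length(active)) {
    g <- gene[active]; s <- st[active]
    weak <- s == 1L | s == 4L
    rt <- ifelse(weak, rW[g], rS[g])
    dt <- rexp(length(active)) / rt
    jump <- dt < t_rem[active]
    keep <- active[jump]
    if (!length(keep)) break
    t_rem[keep] <- t_rem[keep] - dt[jump]
    gj <- gene[keep]; sj <- st[keep]
    th <- theta[gj]
    u <- runif(length(keep))
    new <- integer(length(keep))
    ## relative target rates, given the source state
    ## from A: C th/2, G k*th/2, T (1-th)/2 ; from T: C k*th/2, G th/2, A (1-th)/2
    ## from C: A (1-th)/2, G th/2, T k*(1-th)/2 ; from G: A k*(1-th)/2, C th/2, T (1-th)/2
    for (s0 in 1:4) {
      i <- which(sj == s0)
      if (!length(i)) next
      thi <- th[i]
      p <- switch(s0,
        cbind(thi / 2, kappa * thi / 2, (1 - thi) / 2),            # A -> C,G,T
        cbind((1 - thi) / 2, thi / 2, kappa * (1 - thi) / 2),      # C -> A,G,T
        cbind(kappa * (1 - thi) / 2, thi / 2, (1 - thi) / 2),      # G -> A,C,T
        cbind((1 - thi) / 2, kappa * thi / 2, thi / 2))            # T -> A,C,G
      tgt <- switch(s0, c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
      cp <- p / rowSums(p)
      pick <- 1L + (u[i] > cp[, 1]) + (u[i] > cp[, 1] + cp[, 2])
      new[i] <- tgt[pick]
    }
    oldW <- sj == 1L | sj == 4L
    newW <- new == 1L | new == 4L
    e_ws <- e_ws + sum(oldW & !newW)
    e_sw <- e_sw + sum(!oldW & newW)
    n_ev <- n_ev + length(keep)
    st[keep] <- new
    active <- keep
  }
  list(states = st, e_ws = e_ws, e_sw = e_sw, n_events = n_ev)
}

## simulate one position class for all genes along the tree; returns tip
## state matrix (species x n_genes*sites) and, optionally, true per-branch
## event counts
simulate_class_states <- function(phy, theta_tip, theta_internal, kappa,
                                  sites, log_events = FALSE) {
  phy <- ape::reorder.phylo(phy, "cladewise")  # parents before children
  n_genes <- nrow(theta_tip)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  total <- n_genes * sites
  gene <- rep(seq_len(n_genes), each = sites)
  th_int <- rep(theta_internal, length.out = n_genes)
  root <- root_node(phy)
  states <- vector("list", nnode)
  pgc <- th_int[gene]
  u1 <- runif(total); u2 <- runif(total)
  states[[root]] <- ifelse(u1 < pgc, ifelse(u2 < 0.5, 2L, 3L),
                           ifelse(u2 < 0.5, 1L, 4L))
  ev <- if (log_events)
    data.frame(node = phy$edge[, 2L], e_ws = 0, e_sw = 0, n_events = 0)
  else NULL
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    t_br <- phy$edge.length[e]
    th <- if (ch <= ntip) theta_tip[, phy$tip.label[ch]] else th_int
    if (log_events) {
      res <- gillespie_branch(states[[par]], gene, th, kappa, t_br)
      states[[ch]] <- res$states
      i <- which(ev$node == ch)
      ev$e_ws[i] <- res$e_ws; ev$e_sw[i] <- res$e_sw
      ev$n_events[i] <- res$n_events
    } else {
      states[[ch]] <- evolve_states_cpp(states[[par]], gene,
                                        t92_cum_rows(th, kappa, t_br))
    }
  }
  tips <- do.call(rbind, states[seq_len(ntip)])
  rownames(tips) <- phy$tip.label
  list(tips = tips, events = ev)
}

#' Simulate ortholog alignments under branch-specific T92 models
#'
#' Third positions evolve under a branch-specific T92 equilibrium GC:
#' `theta_internal` (per gene) on internal branches and the per-gene,
#' per-species `theta_tip` on terminal branches — a recent-shift
#' nonstationarity. First and second positions (when `positions = "all"`)
#' evolve with the theta range compressed toward 0.5 by `compress12`,
#' mimicking the narrower GC1/GC2 ranges of constrained sites. Sites are
#' independent; there is no codon model, indels or CpG effect. With
#' `log_events = TRUE` (single-class modes) evolution is simulated
#' event-by-event and true per-branch W->S / S->W counts are returned.
#'
#' @param tree rooted `phylo`/[labeled_tree], branch lengths in
#'   substitutions/site.
#' @param theta_tip matrix (n_genes x n_species; columns named by tip
#'   label) of terminal-branch equilibrium GC values.
#' @param theta_internal scalar or per-gene vector for internal branches.
#' @param kappa transition/transversion ratio.
#' @param sites third-position count per gene (codons) for coding, total
#'   length for introns.
#' @param kind `"coding"` (returns in-frame alignments), `"c3"` (pre-
#'   extracted third positions only) or `"intron"`.
#' @param compress12 shrinkage of first/second-position theta toward 0.5.
#' @param seed RNG seed.
#' @param log_events record true substitution events (kinds `"c3"` and
#'   `"intron"` only).
#' @param ids ortholog ids.
#' @return list with `alignments` (list of [ortholog_alignment]) and
#'   `events` (per-branch true counts, or NULL).
#' @export
simulate_alignments <- function(tree, theta_tip, theta_internal, kappa = 2,
                                sites = 300L, kind = c("coding", "c3", "intron"),
                                compress12 = 0.15, seed = NULL,
                                log_events = FALSE, ids = NULL) {
  kind <- match.arg(kind)
  phy <- as_phylo(tree)
  if (!is.null(seed)) set.seed(seed)
  n_genes <- nrow(theta_tip)
  if (is.null(colnames(theta_tip)) ||
      !setequal(colnames(theta_tip), phy$tip.label))
    stop_avigc("theta_tip columns must be named by the tree's tip labels")
  theta_tip <- theta_tip[, phy$tip.label, drop = FALSE]
  if (is.null(ids)) ids <- sprintf("g%04d", seq_len(n_genes))
  if (log_events && kind == "coding")
    stop_avigc("event logging is supported for single-class simulations ",
               "(kind 'c3' or 'intron')")
  sim3 <- simulate_class_states(phy, theta_tip, theta_internal, kappa,
                                sites, log_events)
  if (kind != "coding") {
    chars <- decode_states(sim3$tips)
    alns <- lapply(seq_len(n_genes), function(g) {
      cols <- (g - 1L) * sites + seq_len(sites)
      new_ortholog_alignment(ids[g], if (kind == "intron") "intron" else "c3",
                             chars[, cols, drop = FALSE])
    })
    return(list(alignments = alns, events = sim3$events))
  }
  shrink <- function(th) 0.5 + compress12 * (th - 0.5)
  sim1 <- simulate_class_states(phy, shrink(theta_tip),
                                shrink(theta_internal), kappa, sites, FALSE)
  sim2 <- simulate_class_states(phy, shrink(theta_tip),
                                shrink(theta_internal), kappa, sites, FALSE)
  nsp <- nrow(sim3$tips)
  alns <- lapply(seq_len(n_genes), function(g) {
    cols <- (g - 1L) * sites + seq_len(sites)
    m <- matrix("N", nsp, 3L * sites)
    rownames(m) <- rownames(sim3$tips)
    m[, seq(1L, 3L * sites, by = 3L)] <- decode_states(sim1$tips[, cols, drop = FALSE])
    m[, seq(2L, 3L * sites, by = 3L)] <- decode_states(sim2$tips[, cols, drop = FALSE])
    m[, seq(3L, 3L * sites, by = 3L)] <- decode_states(sim3$tips[, cols, drop = FALSE])
    new_ortholog_alignment(ids[g], "coding", m)
  })
  list(alignments = alns, events = NULL)
}

#' Simulate recombination maps, ortholog locations and gBGC multipliers
#'
#' Builds a karyotype of `n_large_chrom` large and `n_small_chrom` small
#' chromosomes cut into fixed-width windows. The chromosome-level rate
#' follows the "at least one crossover per chromosome" heuristic
#' (`rate_base + rate_per_chrom/size_Mb`), so small chromosomes recombine
#' faster. Two maps are generated as noisy log-normal observations of a
#' shared window-level rate, with the shared-noise weight solved so the
#' cross-map rank correlation approximates `cross_map_rho`. Orthologs are
#' placed uniformly across windows and receive a gBGC multiplier
#' proportional to their window's true (shared) rate, normalized to mean 1.
#'
#' @param config from [simulation_config()].
#' @param seed RNG seed.
#' @param n_genes number of ortholog locations (default from config).
#' @return list with `map1`, `map2` (window data.frames), `locations`,
#'   `multiplier` (named per-gene), `true_rate` (per window) and
#'   `chrom_sizes_mb`.
#' @export
simulate_recomb_system <- function(config = simulation_config(), seed = 1L,
                                   n_genes = config$n_genes) {
  set.seed(seed)
  nl <- config$n_large_chrom; ns <- config$n_small_chrom
  sizes <- c(round(seq(190, 40, length.out = nl)),
             round(seq(20, 5, length.out = ns)))
  chrom <- as.character(seq_len(nl + ns))
  win <- do.call(rbind, lapply(seq_along(chrom), function(i) {
    nw <- max(1L, floor(sizes[i] * 1e6 / config$window_bp))
    data.frame(chrom = chrom[i],
               start = (seq_len(nw) - 1) * config$window_bp,
               end = seq_len(nw) * config$window_bp,
               stringsAsFactors = FALSE)
  }))
  size_of <- setNames(sizes, chrom)
  base <- config$rate_base + config$rate_per_chrom / size_of[win$chrom]
  nwin <- nrow(win)
  z0 <- rnorm(nwin); z1 <- rnorm(nwin); z2 <- rnorm(nwin)
  sig <- config$rate_sigma
  var_c <- var(log(base))
  V <- var_c + sig^2
  w <- (config$cross_map_rho * V - var_c) / sig^2
  w <- min(max(w, 0), 1)
  lr_true <- log(base) + sig * sqrt(w) * z0
  rate1 <- exp(lr_true + sig * sqrt(1 - w) * z1)
  rate2 <- exp(lr_true + sig * sqrt(1 - w) * z2)
  ## the two maps describe the same (conserved) karyotype and coordinates,
  ## so locations apply to both; no genome tag is attached
  map1 <- cbind(win, rate_cm_mb = unname(rate1))
  map2 <- cbind(win, rate_cm_mb = unname(rate2))
  ids <- sprintf("g%04d", seq_len(n_genes))
  wsel <- sample.int(nwin, n_genes, replace = TRUE)
  glen <- 2e4
  gstart <- win$start[wsel] +
    floor(runif(n_genes, 0, config$window_bp - glen))
  locations <- data.frame(ortholog_id = ids, genome = "shared",
                          chrom = win$chrom[wsel], start = gstart,
                          end = gstart + glen, stringsAsFactors = FALSE)
  true_rate <- exp(lr_true)
  multiplier <- true_rate[wsel] / mean(true_rate)
  names(multiplier) <- ids
  list(map1 = map1, map2 = map2, locations = locations,
       multiplier = multiplier, true_rate = unname(true_rate),
       window_of_gene = wsel, chrom_sizes_mb = size_of)
}

#' Simulate a complete analysis-ready dataset
#'
#' Orchestrates the generators with one master seed split into named
#' substreams (species system, recombination system, gene trees, coding
#' alignments, introns), so that e.g. changing the gene count does not
#' perturb the trait draws. Terminal theta for gene g in species s is
#' `clamp(theta_base + m_g (terminal_shift + dev_s + eps_gs))`, with m the
#' window-linked recombination multiplier, dev the mass-linked deviation
#' and eps gene-by-species noise — so high-recombination genes both gain
#' GC and express the between-species signal more strongly.
#'
#' @param config from [simulation_config()].
#' @param seed master seed.
#' @return list with elements `species`, `recomb`, `gene_trees`, `coding`
#'   (alignments), `introns`, `theta_tip`, `config`, `seed`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 5L)
  sys <- simulate_species_system(config, seeds[1])
  rec <- simulate_recomb_system(config, seeds[2], config$n_genes)
  gts <- simulate_gene_trees(sys$coal_tree, config$n_gene_trees, seeds[3],
                             time_tree = sys$tree_my$phylo)
  sp <- sys$tree_my$phylo$tip.label
  set.seed(seeds[4])
  m <- rec$multiplier
  eps <- matrix(rnorm(config$n_genes * length(sp), 0, config$gene_species_noise),
                config$n_genes, length(sp), dimnames = list(NULL, sp))
  theta_tip <- clamp01(config$theta_base +
    m * (config$terminal_shift + rep(sys$theta_dev[sp], each = config$n_genes) + eps))
  coding <- simulate_alignments(sys$subst_tree, theta_tip,
                                theta_internal = config$theta_base,
                                kappa = config$kappa, sites = config$codons,
                                kind = if (identical(config$positions, "all"))
                                  "coding" else "c3",
                                compress12 = config$compress12,
                                seed = seeds[4], ids = names(m))
  introns <- NULL
  if (config$n_introns > 0) {
    set.seed(seeds[5])
    ni <- min(config$n_introns, config$n_genes)
    iid <- names(m)[seq_len(ni)]
    mi <- m[seq_len(ni)]
    epsi <- matrix(rnorm(ni * length(sp), 0, config$gene_species_noise),
                   ni, length(sp), dimnames = list(NULL, sp))
    theta_i <- clamp01(config$theta_base +
      mi * (config$intron_shift +
              config$intron_attenuation * rep(sys$theta_dev[sp], each = ni) +
              epsi))
    introns <- simulate_alignments(sys$subst_tree, theta_i,
                                   theta_internal = config$theta_base,
                                   kappa = config$kappa,
                                   sites = config$intron_length,
                                   kind = "intron", seed = seeds[5],
                                   ids = iid)
  }
  list(species = sys, recomb = rec, gene_trees = gts,
       coding = coding$alignments,
       introns = if (is.null(introns)) NULL else introns$alignments,
       theta_tip = theta_tip, config = config, seed = seed)
}

#' Write a simulated dataset to disk in the formats the readers consume
#'
#' @param dataset from [simulate_dataset()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cdir <- file.path(dir, "coding"); dir.create(cdir, showWarnings = FALSE)
  for (a in dataset$coding) write_alignment(a, file.path(cdir, paste0(a$ortholog_id, ".fa")))
  if (!is.null(dataset$introns)) {
    idir <- file.path(dir, "introns"); dir.create(idir, showWarnings = FALSE)
    for (a in dataset$introns)
      write_alignment(a, file.path(idir, paste0(a$ortholog_id, ".fa")))
  }
  write_tree(labeled_tree(dataset$species$subst_tree, "substitutions",
                          support = dataset$species$tree_my$support),
             file.path(dir, "species_tree_subst.nwk"))
  write_tree(labeled_tree(dataset$species$tree_my$phylo, "my",
                          support = dataset$species$tree_my$support),
             file.path(dir, "species_tree_my.nwk"))
  gts <- dataset$gene_trees
  class(gts) <- "multiPhylo"
  ape::write.tree(gts, file.path(dir, "gene_trees.nwk"))
  write_table(dataset$species$traits, file.path(dir, "traits.tsv"))
  write_table(dataset$species$node_table, file.path(dir, "node_table.tsv"))
  write_table(dataset$recomb$map1, file.path(dir, "recomb_map_ref1.tsv"))
  write_table(dataset$recomb$map2, file.path(dir, "recomb_map_ref2.tsv"))
  write_table(dataset$recomb$locations, file.path(dir, "locations.tsv"))
  invisible(dir)
}
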