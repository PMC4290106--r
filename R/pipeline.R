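#' Read and validate a pipeline run configuration
#'
#' The configuration is a flat YAML file (or list) with an `out_dir`, a
#' `stages` block of logical toggles (`composition`, `traits`, `gamma`,
#' `ne`, `gcstar`, `recomb`), an `inputs` block of paths and a `params`
#' block (`k`, `alpha`, `min_coal_length`, `min_support`, `min_introns`,
#' `seed`). Referenced paths must exist and parameter ranges are enforced
#' before any stage runs.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_avigc("config must be a list or a YAML path")
  config$stages <- utils::modifyList(
    list(composition = TRUE, traits = TRUE, gamma = FALSE, ne = FALSE,
         gcstar = FALSE, recomb = FALSE), config$stages %||% list())
  config$params <- utils::modifyList(
    list(k = 830L, alpha = 0.01, min_coal_length = 0.1, min_support = 50,
         min_introns = 10L, seed = 1L), config$params %||% list())
  p <- config$params
  if (p$alpha <= 0 || p$alpha >= 1) stop_avigc("alpha must be in (0,1)")
  if (p$k < 1) stop_avigc("k must be >= 1")
  if (p$min_coal_length < 0) stop_avigc("min_coal_length must be >= 0")
  if (is.null(config$out_dir)) stop_avigc("config needs an out_dir")
  ins <- config$inputs %||% list()
  need <- character(0)
  st <- config$stages
  if (st$composition) need <- c(need, "coding_dir")
  if (st$traits) need <- c(need, "traits")
  if (st$gamma) need <- c(need, "pairs")
  if (st$ne) need <- c(need, "species_tree", "gene_trees", "node_table")
  if (st$gcstar) need <- c(need, "species_tree_subst")
  if (st$recomb) need <- c(need, "recomb_maps", "locations")
  miss <- setdiff(need, names(ins))
  if (length(miss)) stop_avigc("missing inputs for enabled stages: ",
                               paste(miss, collapse = ", "))
  for (nm in need) {
    for (pth in unlist(ins[[nm]]))
      if (!file.exists(pth)) stop_avigc("input path does not exist: ", pth)
  }
  config
}

read_alignment_dir <- function(dir, kind) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  lapply(files, read_alignment, kind = kind)
}

#' Run the full analysis pipeline from a single configuration
#'
#' Executes the enabled stages in dependency order (composition -> trait
#' correlations -> GC3 conservation -> ancestral Ne -> GC3* mapping ->
#' recombination joins), writing flat TSV outputs keyed by
#' ortholog/species/branch ids, a timestamped log and a machine-readable
#' JSON report (per-stage row counts, parameter echo, seed, timings).
#' Re-running with an identical config and inputs reproduces identical
#' stage tables. A stage failure aborts its dependents; the report records
#' partial completion.
#'
#' @param config path to YAML or list, see [read_run_config()].
#' @return the run report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  logmsg <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "INFO", ..., "\n",
        file = logfile, append = TRUE)
  }
  report <- list(package_version = as.character(utils::packageVersion("avigc")),
                 params = config$params, stages = list())
  logmsg("pipeline start; seed =", config$params$seed)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, deps, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    failed_dep <- any(vapply(deps, function(d)
      !is.null(report$stages[[d]]) && report$stages[[d]]$status != "ok",
      logical(1)))
    if (failed_dep) {
      report$stages[[name]] <<- list(status = "skipped_failed_dependency")
      logmsg("stage", name, "skipped (failed dependency)")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    res <- tryCatch(list(status = "ok", detail = fun()),
                    error = function(e) list(status = "error",
                                             detail = conditionMessage(e)))
    el <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    report$stages[[name]] <<- c(res["status"],
                                list(detail = res$detail, seconds = el))
    logmsg("stage", name, res$status, paste0("(", el, "s)"))
  }

  run_stage("composition", character(0), function() {
    ins <- config$inputs
    coding <- read_alignment_dir(ins$coding_dir, "coding")
    introns <- if (!is.null(ins$intron_dir))
      read_alignment_dir(ins$intron_dir, "intron") else list()
    comp <- composition_table(c(coding, introns))
    write_table(comp, file.path(out, "composition.tsv"))
    uni <- universal_ortholog_set(coding)
    cu <- coding[vapply(coding, `[[`, character(1), "ortholog_id") %in% uni]
    pooled <- do.call(rbind, lapply(c("c1", "c2", "c3", "c12", "c123"),
      function(cl) cbind(class = cl, pooled_gc(cu, cl))))
    if (length(introns)) {
      uni_i <- universal_ortholog_set(introns)
      iu <- introns[vapply(introns, `[[`, character(1), "ortholog_id") %in% uni_i]
      if (length(iu))
        pooled <- rbind(pooled, cbind(class = "intron", pooled_gc(iu, "intron")))
    }
    write_table(pooled, file.path(out, "pooled_composition.tsv"))
    k <- min(config$params$k,
             floor(length(unique(comp$ortholog_id[comp$class == "c3"])) / 2))
    vp <- variance_partition(comp, k)
    rk <- vp$ranked
    rk$set <- ifelse(rk$ortholog_id %in% vp$high, "high",
                     ifelse(rk$ortholog_id %in% vp$low, "low", ""))
    hom <- do.call(rbind, lapply(cu, function(a) {
      h <- classify_homogeneity(a, config$params$alpha)
      data.frame(ortholog_id = a$ortholog_id, label = h$label,
                 p_value = h$p_value, stringsAsFactors = FALSE)
    }))
    write_table(rk, file.path(out, "variance_partition.tsv"))
    if (!is.null(hom)) write_table(hom, file.path(out, "homogeneity.tsv"))
    state$comp <- comp; state$pooled <- pooled; state$vp <- vp
    list(orthologs = length(coding), introns = length(introns),
         universal = length(uni), k = k)
  })

  run_stage("traits", "composition", function() {
    traits <- read_trait_table(config$inputs$traits)
    pooled <- state$pooled
    if (is.null(pooled)) stop("composition stage outputs required")
    rows <- list()
    for (cl in unique(pooled$class)) {
      pc <- pooled[pooled$class == cl, ]
      x <- setNames(pc$gc_fraction, pc$species)
      for (tr in c("body_mass_g", "max_longevity_yr", "age_first_maturity_yr")) {
        y <- setNames(traits[[tr]], traits$species)
        sp <- intersect(names(x), names(y))
        sp <- sp[!is.na(x[sp]) & !is.na(y[sp])]
        if (length(sp) < 3L) next
        r <- rank_correlation(y[sp], x[sp], "spearman")
        rows[[paste(cl, tr)]] <- data.frame(
          class = cl, trait = tr, method = "spearman", rho = r$estimate,
          p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
      }
    }
    tc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (!is.null(config$inputs$tree_my)) {
      tre <- read_tree(config$inputs$tree_my, "my")
      pc <- pooled[pooled$class == "c3", ]
      x <- setNames(pc$gc_fraction, pc$species)
      y <- setNames(log10(traits$body_mass_g), traits$species)
      sp <- intersect(tre$phylo$tip.label, intersect(names(x), names(y)))
      if (length(sp) >= 4L && all(tre$phylo$tip.label %in% sp)) {
        cc <- contrast_correlation(tre, y[sp], x[sp])
        tc <- rbind(tc, data.frame(class = "c3", trait = "body_mass_g",
                                   method = "pic", rho = cc$r,
                                   p_value = cc$p_value, n = cc$n))
      }
    }
    write_table(tc, file.path(out, "trait_correlations.tsv"))
    state$traits <- traits
    list(tests = nrow(tc))
  })

  run_stage("gamma", c("composition", "traits"), function() {
    pairs <- read.delim(config$inputs$pairs, sep = "\t",
                        stringsAsFactors = FALSE)
    comp <- state$comp[state$comp$class == "c3", ]
    if (!is.null(state$vp))
      comp <- comp[comp$ortholog_id %in% state$vp$high, ]
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      s1 <- pairs$species1[i]; s2 <- pairs$species2[i]
      g1 <- setNames(comp$gc_fraction, comp$ortholog_id)[comp$species == s1]
      g2 <- setNames(comp$gc_fraction, comp$ortholog_id)[comp$species == s2]
      pc <- gc3_conservation_index(g1, g2, pairs$divergence_time_my[i])
      data.frame(species1 = s1, species2 = s2,
                 t_my = pairs$divergence_time_my[i], tau = pc$tau,
                 gamma = pc$gamma, n_genes = pc$n_genes,
                 stringsAsFactors = FALSE)
    })
    gdf <- do.call(rbind, rows)
    if (!is.null(state$traits)) {
      mass <- setNames(state$traits$body_mass_g, state$traits$species)
      gdf$mean_mass_g <- (mass[gdf$species1] + mass[gdf$species2]) / 2
    }
    write_table(gdf, file.path(out, "gamma.tsv"))
    list(pairs = nrow(gdf))
  })

  run_stage("ne", character(0), function() {
    ins <- config$inputs
    sp <- read_tree(ins$species_tree, "my")
    gts <- ape::read.tree(ins$gene_trees)
    if (inherits(gts, "phylo")) gts <- list(gts)
    nt <- read.delim(ins$node_table, sep = "\t", stringsAsFactors = FALSE)
    stats <- coalescent_branch_lengths(sp, gts)
    m <- merge(stats, nt, by = "node")
    ne <- reconstruct_ne(m$coalescent_length, m$time_span_my * 1e6,
                         m$generation_time_rootward, m$generation_time_tipward)
    res <- cbind(m[, c("node", "label", "is_cherry", "support", "n12", "nkk",
                       "coalescent_length")],
                 ne[, c("n_hat", "rank", "flag")])
    filt <- filter_branches(res, config$params$min_coal_length,
                            config$params$min_support, cherry_only = TRUE)
    res$passes_filters <- res$node %in% filt$node
    write_table(res, file.path(out, "ancestral_ne.tsv"))
    list(branches = nrow(res), retained = nrow(filt),
         gene_trees = length(gts))
  })

  run_stage("gcstar", "composition", function() {
    ins <- config$inputs
    tre <- read_tree(ins$species_tree_subst, "substitutions")
    coding <- read_alignment_dir(ins$coding_dir, "coding")
    uni <- universal_ortholog_set(coding)
    cu <- coding[vapply(coding, `[[`, character(1), "ortholog_id") %in% uni]
    states <- do.call(cbind, lapply(cu, third_position_states))
    states <- states[tre$phylo$tip.label, , drop = FALSE]
    fit <- fit_t92(states, tre)
    counts <- map_ws_substitutions(states, tre, fit$model)
    gs <- gc3_star(counts, "per_tip_root_path")
    obs <- tip_gc(states)
    tab <- merge(gs, obs, by.x = "unit", by.y = "species")
    names(tab)[names(tab) == "gc"] <- "gc3"
    write_table(tab, file.path(out, "gcstar.tsv"))
    write_table(as.data.frame(counts), file.path(out, "branch_counts.tsv"))
    list(theta = fit$theta, kappa = fit$kappa, tips = nrow(tab))
  })

  run_stage("recomb", "composition", function() {
    ins <- config$inputs
    loc <- read_locations(ins$locations)
    maps <- lapply(unlist(ins$recomb_maps), read_recomb_map)
    comp <- state$comp
    joins <- lapply(maps, function(mp) assign_windows(loc, mp))
    for (i in seq_along(joins)) {
      ws <- window_statistics(joins[[i]], comp, config$params$min_introns)
      if (!is.null(ws$correlations))
        write_table(cbind(map = i, ws$correlations),
                    file.path(out, sprintf("recomb_correlations_map%d.tsv", i)))
      cc <- chromosome_class_compare(joins[[i]], comp)
      write_table(cbind(map = i, cc),
                  file.path(out, sprintf("chromosome_classes_map%d.tsv", i)))
    }
    xm <- if (length(joins) >= 2L) cross_map_correlation(joins[[1]], joins[[2]])
          else NULL
    if (!is.null(xm))
      write_table(data.frame(rho = xm$estimate, p_value = xm$p_value, n = xm$n),
                  file.path(out, "cross_map_correlation.tsv"))
    list(maps = length(maps),
         cross_map_rho = if (is.null(xm)) NA else xm$estimate)
  })

  report$completed <- sum(vapply(report$stages, function(s)
    identical(s$status, "ok"), logical(1)))
  logmsg("pipeline end;", report$completed, "stage(s) completed")
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
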