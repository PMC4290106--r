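#' Assign orthologs to recombination-map windows
#'
#' Each ortholog is assigned to the window with which it shares the most
#' base pairs (ties broken toward the lower start coordinate); orthologs
#' overlapping no window are dropped, with the count reported in a
#' message. Coordinates are 0-based half-open on both sides.
#'
#' @param locations data.frame from [read_locations()] (or equivalent).
#' @param map data.frame from [read_recomb_map()].
#' @return data.frame join skeleton: `ortholog_id`, `chrom`, `win_start`,
#'   `win_end`, `rate_cm_mb`, `overlap_bp`.
#' @export
assign_windows <- function(locations, map) {
  gen_l <- unique(locations$genome)
  gen_m <- attr(map, "genome")
  if (!is.null(gen_m) && length(gen_l) == 1L && !is.na(gen_l) &&
      !identical(as.character(gen_l), as.character(gen_m)))
    stop_avigc("reference genome mismatch: locations are on '", gen_l,
               "', map is for '", gen_m, "'")
  ## 0-based half-open -> IRanges closed integer intervals
  q <- GenomicRanges::GRanges(locations$chrom,
                              IRanges::IRanges(locations$start + 1, locations$end))
  s <- GenomicRanges::GRanges(map$chrom,
                              IRanges::IRanges(map$start + 1, map$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(q[qh], s[sh]))
  ## maximal overlap per ortholog; ties -> lower window start
  ord <- order(qh, -ov, map$start[sh])
  qh <- qh[ord]; sh <- sh[ord]; ov <- ov[ord]
  first <- !duplicated(qh)
  dropped <- nrow(locations) - sum(first)
  if (dropped > 0L)
    message(dropped, " ortholog(s) overlap no window and were dropped")
  data.frame(ortholog_id = locations$ortholog_id[qh[first]],
             chrom = map$chrom[sh[first]],
             win_start = map$start[sh[first]], win_end = map$end[sh[first]],
             rate_cm_mb = map$rate_cm_mb[sh[first]],
             overlap_bp = ov[first], stringsAsFactors = FALSE)
}

per_ortholog_gc3_stats <- function(composition) {
  comp <- composition[composition$class == "c3" & !is.na(composition$gc_fraction), ]
  n <- tapply(comp$gc_fraction, comp$ortholog_id, length)
  keep <- names(n)[n >= 2L]
  comp <- comp[comp$ortholog_id %in% keep, ]
  data.frame(ortholog_id = keep,
             mean_gc3 = as.numeric(tapply(comp$gc_fraction, comp$ortholog_id, mean)[keep]),
             sd_gc3 = as.numeric(tapply(comp$gc_fraction, comp$ortholog_id, sd)[keep]),
             stringsAsFactors = FALSE)
}

#' Per-ortholog and per-window composition statistics against recombination
#'
#' For coding orthologs: the between-species standard deviation (n-1) and
#' mean of GC3, joined to the ortholog's window rate, with Spearman
#' correlations of both against the rate. For introns: per-window GC is
#' pooled (counts summed across the window's introns per species before
#' dividing) and reported only for windows holding at least `min_introns`
#' introns, to avoid noise from low site counts.
#'
#' @param join window join from [assign_windows()] (coding orthologs; the
#'   same join is reused for introns via their host gene's id).
#' @param composition long table from [composition_table()] carrying class
#'   `"c3"` rows and, optionally, class `"intron"` rows with counts.
#' @param min_introns minimum introns per window (default 10).
#' @return list with `per_ortholog` (ortholog, window, rate, sd, mean),
#'   `per_window_intron` (window, n_introns, sd, mean of pooled intron
#'   GC), and `correlations` (data.frame of Spearman tests).
#' @export
window_statistics <- function(join, composition, min_introns = 10L) {
  stats <- per_ortholog_gc3_stats(composition)
  per_orth <- merge(join, stats, by = "ortholog_id")
  cors <- list()
  if (nrow(per_orth) >= 3L) {
    cs <- rank_correlation(per_orth$sd_gc3, per_orth$rate_cm_mb)
    cm <- rank_correlation(per_orth$mean_gc3, per_orth$rate_cm_mb)
    cors[["gc3_sd"]] <- data.frame(class = "c3", stat = "sd", rho = cs$estimate,
                                   p_value = cs$p_value, n = cs$n)
    cors[["gc3_mean"]] <- data.frame(class = "c3", stat = "mean", rho = cm$estimate,
                                     p_value = cm$p_value, n = cm$n)
  }
  per_win_intron <- NULL
  icomp <- composition[composition$class == "intron", ]
  if (nrow(icomp) > 0L) {
    ij <- merge(icomp, join[, c("ortholog_id", "chrom", "win_start", "win_end",
                                "rate_cm_mb")], by = "ortholog_id")
    ij$window <- paste0(ij$chrom, ":", ij$win_start)
    nint <- tapply(ij$ortholog_id, ij$window, function(x) length(unique(x)))
    keep <- names(nint)[nint >= min_introns]
    ij <- ij[ij$window %in% keep, ]
    if (nrow(ij) > 0L) {
      agg <- stats::aggregate(cbind(gc_count, counted_sites) ~ window + species,
                              data = ij, FUN = sum)
      agg$gc <- ifelse(agg$counted_sites > 0, agg$gc_count / agg$counted_sites,
                       NA_real_)
      per_win_intron <- data.frame(
        window = names(tapply(agg$gc, agg$window, mean)),
        n_introns = as.integer(nint[names(tapply(agg$gc, agg$window, mean))]),
        mean_gci = as.numeric(tapply(agg$gc, agg$window, mean, na.rm = TRUE)),
        sd_gci = as.numeric(tapply(agg$gc, agg$window, sd)),
        rate_cm_mb = as.numeric(tapply(ij$rate_cm_mb, ij$window, `[`, 1L)[
          names(tapply(agg$gc, agg$window, mean))]),
        stringsAsFactors = FALSE)
      if (nrow(per_win_intron) >= 3L) {
        cs <- rank_correlation(per_win_intron$sd_gci, per_win_intron$rate_cm_mb)
        cm <- rank_correlation(per_win_intron$mean_gci, per_win_intron$rate_cm_mb)
        cors[["gci_sd"]] <- data.frame(class = "intron", stat = "sd",
                                       rho = cs$estimate, p_value = cs$p_value,
                                       n = cs$n)
        cors[["gci_mean"]] <- data.frame(class = "intron", stat = "mean",
                                         rho = cm$estimate, p_value = cm$p_value,
                                         n = cm$n)
      }
    }
  }
  list(per_ortholog = per_orth, per_window_intron = per_win_intron,
       correlations = if (length(cors)) do.call(rbind, c(cors, list(make.row.names = FALSE)))
                      else NULL)
}

#' Compare GC statistics between chromosome size classes
#'
#' Small avian chromosomes recombine faster (at least one crossover per
#' chromosome), so orthologs on them are expected to show higher median GC
#' and higher between-species heterogeneity. Reports the class medians of
#' per-ortholog mean and sd of GC3 (and of intron GC when present) with
#' two-sided Wilcoxon rank-sum tests between classes.
#'
#' @param join window join from [assign_windows()].
#' @param composition long composition table.
#' @param large_chroms,small_chroms chromosome label sets (defaults 1-9
#'   and 10-40, the chicken-like convention).
#' @return data.frame, one row per (site class, statistic): class medians
#'   and the Wilcoxon p-value.
#' @export
chromosome_class_compare <- function(join, composition,
                                     large_chroms = as.character(1:9),
                                     small_chroms = as.character(10:40)) {
  res <- list()
  for (cls in c("c3", "intron")) {
    comp <- composition[composition$class == cls & !is.na(composition$gc_fraction), ]
    if (nrow(comp) == 0L) next
    n <- tapply(comp$gc_fraction, comp$ortholog_id, length)
    comp <- comp[comp$ortholog_id %in% names(n)[n >= 2L], ]
    st <- data.frame(
      ortholog_id = sort(unique(comp$ortholog_id)),
      mean_gc = as.numeric(tapply(comp$gc_fraction, comp$ortholog_id, mean)),
      sd_gc = as.numeric(tapply(comp$gc_fraction, comp$ortholog_id, sd)),
      stringsAsFactors = FALSE)
    st <- merge(st, join[, c("ortholog_id", "chrom")], by = "ortholog_id")
    st$class <- ifelse(st$chrom %in% large_chroms, "large",
                ifelse(st$chrom %in% small_chroms, "small", NA))
    st <- st[!is.na(st$class), ]
    if (!any(st$class == "large") || !any(st$class == "small"))
      stop_avigc("empty chromosome class for site class ", cls)
    for (what in c("mean_gc", "sd_gc")) {
      a <- st[[what]][st$class == "small"]; b <- st[[what]][st$class == "large"]
      wt <- wilcoxon_rank_sum(a, b)
      res[[paste(cls, what)]] <- data.frame(
        site_class = cls, statistic = what,
        median_small = median(a), median_large = median(b),
        n_small = length(a), n_large = length(b),
        wilcoxon_p = wt$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) stop_avigc("no usable composition rows")
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out
}

#' Correlation of two recombination maps over a shared ortholog set
#'
#' Spearman correlation of the window rates assigned to the same orthologs
#' under two maps (e.g. two reference species) — a measure of conservation
#' of the recombination landscape for the loci analyzed.
#'
#' @param join_map1,join_map2 joins from [assign_windows()].
#' @return a `correlation_result` from [rank_correlation()].
#' @export
cross_map_correlation <- function(join_map1, join_map2) {
  m <- merge(join_map1[, c("ortholog_id", "rate_cm_mb")],
             join_map2[, c("ortholog_id", "rate_cm_mb")],
             by = "ortholog_id", suffixes = c("_1", "_2"))
  if (nrow(m) < 3L) stop_avigc("fewer than 3 shared orthologs")
  rank_correlation(m$rate_cm_mb_1, m$rate_cm_mb_2)
}
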