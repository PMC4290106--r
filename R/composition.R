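class_columns <- function(aln, class) {
  L <- aln$length
  if (aln$kind == "intron") {
    if (class != "intron")
      stop_avigc("class '", class, "' requested for an intron alignment")
    return(seq_len(L))
  }
  if (aln$kind == "c3") {
    if (class != "c3")
      stop_avigc("a third-position alignment only carries class 'c3'")
    return(seq_len(L))
  }
  if (class == "intron")
    stop_avigc("class 'intron' requested for a coding alignment")
  switch(class,
         c1 = seq(1L, L, by = 3L),
         c2 = seq(2L, L, by = 3L),
         c3 = seq(3L, L, by = 3L),
         c12 = sort(c(seq(1L, L, by = 3L), seq(2L, L, by = 3L))),
         c123 = seq_len(L),
         stop_avigc("unknown position class: ", class))
}

gc_counts_matrix <- function(m) {
  cnt <- gc_at_counts_cpp(m)
  cbind(gc = cnt[, 1L], counted = cnt[, 1L] + cnt[, 2L])
}

#' GC fraction by position class for one alignment
#'
#' Counts G+C over the selected columns per species and divides by the
#' number of unambiguous (non-gap, non-N) sites. Gaps and N are excluded
#' from numerator and denominator; a codon containing a gap still
#' contributes its non-gap positions. A species with zero counted sites is
#' reported as `NA` (a flagged missing value), never as 0.
#'
#' @param aln an [ortholog_alignment].
#' @param class one of `"c1"`, `"c2"`, `"c3"`, `"c12"`, `"c123"`,
#'   `"intron"`.
#' @return data.frame with columns `species`, `gc_fraction`, `gc_count`,
#'   `counted_sites`.
#' @export
gc_by_class <- function(aln, class = c("c3", "c1", "c2", "c12", "c123", "intron")) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  class <- match.arg(class)
  cols <- class_columns(aln, class)
  cnt <- gc_counts_matrix(aln$matrix[, cols, drop = FALSE])
  data.frame(species = aln$species,
             gc_fraction = ifelse(cnt[, "counted"] > 0,
                                  cnt[, "gc"] / cnt[, "counted"], NA_real_),
             gc_count = cnt[, "gc"], counted_sites = cnt[, "counted"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-ortholog, per-species composition table
#'
#' Long-format table of GC fractions with their counted-site denominators,
#' for every requested position class. Coding alignments get the codon
#' position classes; intron alignments get class `"intron"`.
#'
#' @param alignments list of [ortholog_alignment] objects.
#' @param classes classes computed for coding alignments.
#' @return data.frame with columns `ortholog_id`, `species`, `class`,
#'   `gc_fraction`, `gc_count`, `counted_sites`.
#' @export
composition_table <- function(alignments,
                              classes = c("c1", "c2", "c3", "c12", "c123")) {
  out <- lapply(alignments, function(a) {
    cls <- switch(a$kind, intron = "intron", c3 = "c3", classes)
    do.call(rbind, lapply(cls, function(cl) {
      d <- gc_by_class(a, cl)
      cbind(ortholog_id = a$ortholog_id, d, class = cl,
            stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  res <- res[, c("ortholog_id", "species", "class", "gc_fraction",
                 "gc_count", "counted_sites")]
  rownames(res) <- NULL
  res
}

#' Orthologs present in all species
#'
#' @param alignments list of [ortholog_alignment] objects.
#' @param roster species universe; defaults to the union of species over all
#'   alignments.
#' @return character vector of ortholog ids whose alignments contain every
#'   species in the roster. Empty result triggers a warning.
#' @export
universal_ortholog_set <- function(alignments, roster = NULL) {
  if (is.null(roster))
    roster <- sort(unique(unlist(lapply(alignments, `[[`, "species"))))
  keep <- vapply(alignments, function(a) all(roster %in% a$species), logical(1))
  ids <- vapply(alignments[keep], `[[`, character(1), "ortholog_id")
  if (length(ids) == 0L) warn_avigc("no ortholog contains all species")
  sort(ids)
}

#' Pooled per-species GC over an ortholog set
#'
#' Counts are summed across orthologs per species before the division
#' (length-weighted pooling, not a mean of per-gene fractions), so short
#' sequences do not add noise. Every alignment must contain every species
#' considered; pre-filter with [universal_ortholog_set()].
#'
#' @param alignments list of [ortholog_alignment] objects.
#' @param class position class, as in [gc_by_class()].
#' @param species species to pool; defaults to the species of the first
#'   alignment.
#' @return data.frame with `species`, `gc_fraction`, `gc_count`,
#'   `counted_sites`.
#' @export
pooled_gc <- function(alignments, class = "c3", species = NULL) {
  stopifnot(length(alignments) >= 1L)
  if (is.null(species)) species <- alignments[[1L]]$species
  gc <- setNames(numeric(length(species)), species)
  counted <- gc
  for (a in alignments) {
    if (!all(species %in% a$species))
      stop_avigc("ortholog '", a$ortholog_id, "' is missing species ",
                 paste(setdiff(species, a$species), collapse = ", "),
                 "; restrict to the universal ortholog set first")
    cols <- class_columns(a, class)
    sub <- if (identical(species, a$species) && length(cols) == ncol(a$matrix))
      a$matrix else a$matrix[species, cols, drop = FALSE]
    cnt <- gc_counts_matrix(sub)
    gc <- gc + cnt[, "gc"]
    counted <- counted + cnt[, "counted"]
  }
  data.frame(species = species,
             gc_fraction = ifelse(counted > 0, gc / counted, NA_real_),
             gc_count = unname(gc), counted_sites = unname(counted),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank orthologs by between-species GC3 variance and split top/bottom k
#'
#' Uses the sample variance (denominator n-1) of per-species GC3 within
#' each ortholog. Ties are broken by ortholog id (lexicographic) so the
#' partition is deterministic.
#'
#' @param comp long composition table from [composition_table()] (class
#'   `"c3"` rows are used), or any data.frame with `ortholog_id`, `species`,
#'   `gc_fraction` and optionally `class`.
#' @param k set size for each of the high- and low-variance sets.
#' @return list with `ranked` (data.frame of `ortholog_id`, `variance`,
#'   `n_species`, sorted high to low), `high` and `low` (character vectors
#'   of ids) and `k`.
#' @export
variance_partition <- function(comp, k) {
  if ("class" %in% names(comp)) comp <- comp[comp$class == "c3", ]
  if (!all(c("ortholog_id", "gc_fraction") %in% names(comp)))
    stop_avigc("comp must carry ortholog_id and gc_fraction")
  v <- tapply(comp$gc_fraction, comp$ortholog_id,
              function(x) var(x[!is.na(x)]))
  n <- tapply(!is.na(comp$gc_fraction), comp$ortholog_id, sum)
  ranked <- data.frame(ortholog_id = names(v), variance = as.numeric(v),
                       n_species = as.integer(n), stringsAsFactors = FALSE)
  ranked <- ranked[!is.na(ranked$variance), ]
  if (k <= 0 || 2 * k > nrow(ranked))
    stop_avigc("k must satisfy 0 < 2k <= number of orthologs with a variance (",
               nrow(ranked), ")")
  ord <- order(-ranked$variance, ranked$ortholog_id)
  ranked <- ranked[ord, ]
  rownames(ranked) <- NULL
  list(ranked = ranked,
       high = ranked$ortholog_id[seq_len(k)],
       low = rev(ranked$ortholog_id)[seq_len(k)],
       k = as.integer(k))
}

#' Classify an ortholog as compositionally homogenous between species
#'
#' A light-weight stand-in for nonstationary-vs-stationary model comparison:
#' a chi-square contingency test of species x \{strong, weak\} counts at
#' third codon positions (df = number of species - 1, no continuity
#' correction). The ortholog is labeled `"homogenous"` when p >= alpha.
#' Species with zero counted third positions are excluded with a warning; a
#' `low_counts` flag is set when any expected cell count is below 5.
#'
#' @param aln coding [ortholog_alignment] with at least 2 usable species.
#' @param alpha rejection level (default 0.01).
#' @return list with `label`, `p_value`, `statistic`, `df`, `low_counts`,
#'   `species_used`.
#' @export
classify_homogeneity <- function(aln, alpha = 0.01) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  if (!aln$kind %in% c("coding", "c3"))
    stop_avigc("homogeneity test requires third codon positions")
  d <- gc_by_class(aln, "c3")
  usable <- d$counted_sites > 0
  if (any(!usable))
    warn_avigc("species with zero counted third positions excluded: ",
               paste(d$species[!usable], collapse = ", "))
  d <- d[usable, ]
  if (nrow(d) < 2L) stop_avigc("fewer than 2 usable species")
  tab <- cbind(S = d$gc_count, W = d$counted_sites - d$gc_count)
  if (sum(tab[, "S"]) == 0 || sum(tab[, "W"]) == 0) {
    ## degenerate: no variation between classes at all
    return(list(label = "homogenous", p_value = 1, statistic = 0,
                df = nrow(d) - 1L, low_counts = TRUE,
                species_used = d$species))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(label = if (ct$p.value >= alpha) "homogenous" else "non-homogenous",
       p_value = unname(ct$p.value), statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       low_counts = any(ct$expected < 5),
       species_used = d$species)
}
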