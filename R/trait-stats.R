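## all permutations of 1..n as a matrix (n! rows); n <= 9
all_permutations <- function(n) {
  P <- matrix(1L, nrow = 1L, ncol = 1L)
  for (k in 2:n) {
    m <- nrow(P)
    out <- matrix(0L, nrow = m * k, ncol = k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L)]
      out[rows, pos] <- k
      if (pos < k) out[rows, seq(pos + 1L, k)] <- P[, seq(pos, k - 1L)]
    }
    P <- out
  }
  P
}

## exact two-sided Spearman p by full enumeration (no ties, n <= 9)
spearman_exact_p <- function(xr, yr) {
  n <- length(xr)
  P <- all_permutations(n)
  ## rho = 1 - 6*sum(d^2)/(n(n^2-1)); enumerate permutations of y ranks
  yperm <- matrix(yr[P], nrow = nrow(P))
  s <- yperm %*% cbind(xr)
  const <- sum(xr^2) + sum(yr^2)
  d2 <- const - 2 * s
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  obs <- 1 - 6 * sum((xr - yr)^2) / (n * (n^2 - 1))
  mean(abs(rho) >= abs(obs) - 1e-12)
}

## exact two-sided Kendall p via the inversion-count distribution
## (equivalent to enumerating all n! permutations; no ties, n <= 9)
kendall_exact_p <- function(xr, yr) {
  n <- length(xr)
  ## number of discordant pairs of the observed data
  o <- order(xr)
  y2 <- yr[o]
  disc <- 0L
  for (i in seq_len(n - 1L))
    disc <- disc + sum(y2[(i + 1L):n] < y2[i])
  ## distribution of inversion counts over all permutations
  counts <- 1
  for (k in 2:n) counts <- stats::convolve(counts, rev(rep(1, k)), type = "open")
  counts <- pmax(round(counts), 0)
  npairs <- n * (n - 1) / 2
  tau_all <- 1 - 4 * (0:npairs) / (n * (n - 1))
  tau_obs <- 1 - 4 * disc / (n * (n - 1))
  sum(counts[abs(tau_all) >= abs(tau_obs) - 1e-12]) / sum(counts)
}

#' Kendall's tau-b
#'
#' Pairwise concordance count with the tie-corrected (tau-b) denominator.
#'
#' @param x,y numeric vectors of equal length.
#' @return tau-b estimate (NA if either vector is constant).
#' @export
kendall_tau_b <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  iu <- upper.tri(dx)
  num <- sum(dx[iu] * dy[iu])
  n0 <- n * (n - 1) / 2
  t1 <- sum(dx[iu] == 0); t2 <- sum(dy[iu] == 0)
  den <- sqrt((n0 - t1) * (n0 - t2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Rank (or Pearson) correlation with principled small-sample p-values
#'
#' Spearman uses average ranks for ties. Two-sided p-values are exact by
#' enumeration over all permutations for n <= 9 tie-free pairs (Spearman by
#' direct enumeration, Kendall via the inversion-count distribution), and
#' asymptotic with tie corrections otherwise. Incomplete pairs are dropped.
#'
#' @param x,y numeric vectors (may carry NA).
#' @param method `"spearman"`, `"kendall"` or `"pearson"`.
#' @return object of class `correlation_result`: list with `method`,
#'   `estimate`, `p_value`, `n`, `exact`, `flags`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "kendall", "pearson")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_avigc("need at least 3 complete pairs, got ", n)
  flags <- character(0)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(list(method = method, estimate = NA_real_,
                          p_value = NA_real_, n = n, exact = FALSE,
                          flags = "constant_input"),
                     class = "correlation_result"))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 9L && !ties && method != "pearson"
  est <- switch(method,
                spearman = cor(x, y, method = "spearman"),
                kendall = kendall_tau_b(x, y),
                pearson = cor(x, y))
  if (exact) {
    xr <- rank(x); yr <- rank(y)
    p <- if (method == "spearman") spearman_exact_p(xr, yr)
         else kendall_exact_p(xr, yr)
  } else {
    p <- suppressWarnings(
      cor.test(x, y, method = method, exact = FALSE)$p.value)
    if (ties) flags <- c(flags, "ties_asymptotic")
  }
  structure(list(method = method, estimate = unname(est),
                 p_value = unname(p), n = n, exact = exact, flags = flags),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: estimate = %.4f, p = %.4g, n = %d%s\n",
              x$method, x$estimate, x$p_value, x$n,
              if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Exact by enumeration when both samples have at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections. When every value in both samples is
#' identical the test is degenerate: the statistic sits at its null center
#' and p = 1, flagged.
#'
#' @param a,b numeric vectors.
#' @param exact_max maximum per-sample size for the exact test (default 8).
#' @return list with `statistic` (Mann-Whitney U of sample `a`), `p_value`,
#'   `exact`, `flags`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) stop_avigc("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                exact = FALSE, flags = "all_tied"))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = unname(wt$p.value),
       exact = exact, flags = if (ties) "ties_asymptotic" else character(0))
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts after Felsenstein, computed with `ape::pic`.
#' Downstream correlation between two traits' contrasts should be forced
#' through the origin; see [contrast_correlation()].
#'
#' @param tree a [labeled_tree] or `phylo` with positive branch lengths.
#' @param x named numeric vector of tip trait values (names = tip labels).
#' @return numeric vector of n-1 standardized contrasts (named by node id).
#' @export
independent_contrasts <- function(tree, x) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop_avigc("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop_avigc("negative branch lengths")
  ## a pair of zero-length sister terminal branches leaves the contrast
  ## variance undefined
  par <- phy$edge[, 1L]
  zero_child <- phy$edge[, 2L][phy$edge.length == 0]
  if (length(zero_child)) {
    zp <- par[match(zero_child, phy$edge[, 2L])]
    if (anyDuplicated(zp))
      stop_avigc("sister branches with both lengths zero: contrast undefined")
  }
  if (is.null(names(x))) stop_avigc("trait values must be named by tip label")
  miss <- setdiff(phy$tip.label, names(x))
  if (length(miss)) stop_avigc("trait missing for tips: ",
                               paste(miss, collapse = ", "))
  ape::pic(x[phy$tip.label], phy)
}

#' Correlation of two traits' independent contrasts (through the origin)
#'
#' @param tree a [labeled_tree] or `phylo`.
#' @param x,y named numeric tip trait vectors.
#' @return list with `r` (origin-constrained correlation), `p_value`
#'   (t test on the slope through the origin), `n` contrasts.
#' @export
contrast_correlation <- function(tree, x, y) {
  cx <- independent_contrasts(tree, x)
  cy <- independent_contrasts(tree, y)
  fit <- summary(stats::lm(cy ~ cx + 0))
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  list(r = r, p_value = unname(fit$coefficients[1, 4]), n = length(cx))
}

#' Gene-subset randomization test
#'
#' Draws `subset_size` genes without replacement from `gene_ids`, `n_reps`
#' times, recomputes the statistic on each subset, and returns the
#' one-sided empirical p-value with the add-one correction (r+1)/(n+1).
#' Replicates on which the callback fails are dropped (with a warning) and
#' reported in `n_failed`.
#'
#' @param gene_ids vector of gene identifiers (the set B).
#' @param subset_size number of genes drawn per replicate.
#' @param observed_stat the observed statistic being calibrated.
#' @param statistic function taking a vector of gene ids, returning a
#'   single number.
#' @param n_reps number of randomizations.
#' @param seed optional seed for the randomization stream.
#' @param direction `"le"` counts replicates with statistic <= observed
#'   (one-sided low tail); `"ge"` the opposite.
#' @return list with `p_value`, `n_used`, `n_failed`, `replicates`.
#' @export
subset_randomization <- function(gene_ids, subset_size, observed_stat,
                                 statistic, n_reps = 10000L, seed = NULL,
                                 direction = c("le", "ge")) {
  direction <- match.arg(direction)
  if (subset_size > length(gene_ids))
    stop_avigc("subset_size exceeds the number of genes")
  if (n_reps < 1L) stop_avigc("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(i) {
    ids <- sample(gene_ids, subset_size)
    tryCatch(as.numeric(statistic(ids)), error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(reps))
  if (n_failed > 0L) warn_avigc(n_failed, " replicate(s) failed and were dropped")
  ok <- reps[!is.na(reps)]
  r <- if (direction == "le") sum(ok <= observed_stat) else sum(ok >= observed_stat)
  list(p_value = (r + 1) / (length(ok) + 1), n_used = length(ok),
       n_failed = n_failed, replicates = ok)
}

#' Time-corrected GC3 conservation index for a species pair
#'
#' gamma = -t / log(tau), where t is the divergence time of the pair and
#' tau the Kendall (tau-b) correlation of per-gene GC3 between the two
#' species over their shared genes. Natural log. tau <= 0 leaves gamma
#' undefined (flag `"no_conservation_signal"`); tau = 1 gives +Inf (flag
#' `"perfectly_conserved"`). Units of `t` pass through, so gamma values are
#' comparable only within a run.
#'
#' @param gc3_a,gc3_b named numeric vectors of per-gene GC3 (names = gene
#'   ids) for the two species.
#' @param t divergence time (> 0).
#' @param min_genes minimum number of shared genes (default 10).
#' @return object of class `pair_conservation`: list with `tau`, `t`,
#'   `gamma`, `n_genes`, `flags`.
#' @export
gc3_conservation_index <- function(gc3_a, gc3_b, t, min_genes = 10L) {
  if (t <= 0) stop_avigc("divergence time must be positive")
  shared <- intersect(names(gc3_a), names(gc3_b))
  shared <- shared[!is.na(gc3_a[shared]) & !is.na(gc3_b[shared])]
  if (length(shared) < min_genes)
    stop_avigc("only ", length(shared), " shared genes; need >= ", min_genes)
  tau <- kendall_tau_b(gc3_a[shared], gc3_b[shared])
  flags <- character(0)
  if (is.na(tau)) {
    gamma <- NA_real_; flags <- "undefined_tau"
  } else if (tau <= 0) {
    gamma <- NA_real_; flags <- "no_conservation_signal"
  } else if (tau >= 1) {
    gamma <- Inf; flags <- "perfectly_conserved"
  } else {
    gamma <- -t / log(tau)
  }
  structure(list(tau = tau, t = t, gamma = gamma, n_genes = length(shared),
                 flags = flags),
            class = "pair_conservation")
}

#' @export
print.pair_conservation <- function(x, ...) {
  cat(sprintf("gamma = %.4g (tau = %.4f, t = %g, %d genes)%s\n",
              x$gamma, x$tau, x$t, x$n_genes,
              if (length(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Select non-overlapping species pairs for conservation analyses
#'
#' Policy helper: from a candidate table of pairs it greedily keeps pairs
#' so that no species is reused, after excluding listed species and
#' dropping pairs below a minimum divergence time; among the remaining
#' candidates, pairs with deeper splits are preferred. This mirrors the
#' practice of excluding extreme-contrast lineages and intra-genus pairs
#' with very short divergence times; it is policy, fully configurable.
#'
#' @param candidates data.frame with columns `species1`, `species2`,
#'   `divergence_time`.
#' @param exclude species ids never used.
#' @param min_time minimum divergence time retained (default 0).
#' @return subset of `candidates`, one row per retained pair.
#' @export
select_species_pairs <- function(candidates, exclude = character(0),
                                 min_time = 0) {
  stopifnot(all(c("species1", "species2", "divergence_time") %in%
                  names(candidates)))
  cand <- candidates[!(candidates$species1 %in% exclude) &
                       !(candidates$species2 %in% exclude) &
                       candidates$divergence_time >= min_time, , drop = FALSE]
  cand <- cand[order(-cand$divergence_time), , drop = FALSE]
  used <- character(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sp <- c(cand$species1[i], cand$species2[i])
    if (!any(sp %in% used)) {
      keep[i] <- TRUE
      used <- c(used, sp)
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
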