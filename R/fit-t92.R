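## Felsenstein pruning log-likelihood machinery shared by the fitter and
## the substitution mapper. `states` is an integer matrix (species x sites,
## 1..4 = A,C,G,T, NA = gap/unknown); `phy` a rooted phylo with branch
## lengths in substitutions/site.

tip_likelihoods <- function(states, phy) {
  nsites <- ncol(states)
  lapply(phy$tip.label, function(sp) {
    if (!sp %in% rownames(states))
      stop_avigc("no sequence for tip ", sp)
    s <- states[sp, ]
    L <- matrix(0, 4, nsites)
    ok <- !is.na(s)
    L[cbind(s[ok], which(ok))] <- 1
    L[, !ok] <- 1
    L
  })
}

## upward (pruning) pass; returns per-node partials L, per-edge messages
## M[[child]] = P_child %*% L[[child]], and per-edge transition matrices
pruning_pass <- function(states, phy, model, scale = 1) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  L <- vector("list", nnode)
  L[seq_len(ntip)] <- tip_likelihoods(states, phy)
  Pm <- vector("list", nnode)   # transition matrix of the branch above node
  M <- vector("list", nnode)    # message from node to its parent
  kids <- children_list(phy)
  elen <- setNames(phy$edge.length * scale, phy$edge[, 2L])
  for (nd in postorder_nodes(phy)) {
    part <- NULL
    for (ch in kids[[nd]]) {
      Pm[[ch]] <- t92_transition_matrix(model, elen[[as.character(ch)]])
      M[[ch]] <- Pm[[ch]] %*% L[[ch]]
      part <- if (is.null(part)) M[[ch]] else part * M[[ch]]
    }
    L[[nd]] <- part
  }
  root <- root_node(phy)
  site_lik <- colSums(model$pi * L[[root]])
  list(L = L, M = M, P = Pm, site_lik = site_lik,
       loglik = sum(log(site_lik)), root = root, kids = kids,
       elen = elen)
}

t92_loglik <- function(states, phy, theta, kappa, scale = 1) {
  pruning_pass(states, phy, t92_model(theta, kappa), scale)$loglik
}

observed_gc <- function(states) {
  n_gc <- sum(states == 2L | states == 3L, na.rm = TRUE)
  n_all <- sum(!is.na(states))
  if (n_all == 0L) stop_avigc("alignment has no unambiguous sites")
  n_gc / n_all
}

#' Fit a homogeneous T92 model to third-position data on a fixed tree
#'
#' Maximizes the pruning-algorithm likelihood over (theta, kappa) — and
#' optionally a global branch-length scale — with bounded quasi-Newton
#' (L-BFGS-B) from fixed deterministic starting points (theta = observed GC
#' fraction, kappa = 2, scale = 1), so the fit is reproducible given the
#' inputs. An alignment without variable sites short-circuits to the
#' observed-frequency theta with a warning.
#'
#' @param states integer state matrix (species x sites, 1..4 = A,C,G,T, NA
#'   for gap/N), e.g. from [third_position_states()], or an
#'   [ortholog_alignment] of kind `"c3"`/`"coding"`.
#' @param tree [labeled_tree] or rooted `phylo` with branch lengths in
#'   substitutions/site covering all alignment species.
#' @param fit_scale also fit a global branch-length multiplier.
#' @param kappa_start starting kappa.
#' @return list of class `t92_fit`: `model` (a [t92_model]), `theta`,
#'   `kappa`, `scale`, `loglik`, `convergence`, `flags`.
#' @export
fit_t92 <- function(states, tree, fit_scale = FALSE, kappa_start = 2) {
  if (inherits(states, "ortholog_alignment"))
    states <- if (states$kind == "coding") third_position_states(states)
              else encode_states(states$matrix)
  phy <- as_phylo(tree)
  if (length(phy$tip.label) < 2L) stop_avigc("need at least 2 species")
  gc0 <- observed_gc(states)
  theta0 <- min(max(gc0, 0.02), 0.98)
  ## variable sites?
  n_state <- apply(states, 2L, function(col) length(unique(col[!is.na(col)])))
  if (all(n_state <= 1L)) {
    warn_avigc("no variable sites; returning observed-frequency theta")
    model <- t92_model(theta0, kappa_start)
    return(structure(list(model = model, theta = theta0, kappa = kappa_start,
                          scale = 1, loglik = NA_real_, convergence = 0L,
                          flags = "no_variable_sites"), class = "t92_fit"))
  }
  ## compress duplicate site patterns for speed
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  wts <- as.vector(table(factor(key, levels = key[first])))
  st <- states[, first, drop = FALSE]
  negll <- function(par) {
    th <- plogis(par[1]); ka <- exp(par[2])
    sc <- if (fit_scale) exp(par[3]) else 1
    pp <- tryCatch(pruning_pass(st, phy, t92_model(th, ka), sc),
                   error = function(e) NULL)
    if (is.null(pp) || !all(is.finite(pp$site_lik)) || any(pp$site_lik <= 0))
      return(1e10)
    -sum(wts * log(pp$site_lik))
  }
  par0 <- c(qlogis(theta0), log(kappa_start), if (fit_scale) 0)
  opt <- optim(par0, negll, method = "L-BFGS-B",
               lower = c(qlogis(0.01), log(0.05), if (fit_scale) log(0.05)),
               upper = c(qlogis(0.99), log(200), if (fit_scale) log(20)),
               control = list(factr = 1e7, maxit = 500))
  if (opt$convergence != 0L)
    stop_avigc("T92 fit did not converge: code ", opt$convergence,
               " (", opt$message, ")")
  theta <- plogis(opt$par[1]); kappa <- exp(opt$par[2])
  scale <- if (fit_scale) exp(opt$par[3]) else 1
  structure(list(model = t92_model(theta, kappa), theta = theta,
                 kappa = kappa, scale = scale, loglik = -opt$value,
                 convergence = opt$convergence, flags = character(0)),
            class = "t92_fit")
}

#' @export
print.t92_fit <- function(x, ...) {
  cat(sprintf("<t92_fit> theta = %.4f, kappa = %.3f, scale = %.3f, logL = %.2f\n",
              x$theta, x$kappa, x$scale, x$loglik))
  invisible(x)
}
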