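#' Fixation probability of a new mutant under gBGC
#'
#' Kimura-form fixation probability for a new mutant whose transmission is
#' distorted by gene conversion with selection-equivalent coefficient `b`
#' (haploid-equivalent bookkeeping with 2Ne copies):
#' P = (1 - exp(-2b)) / (1 - exp(-4 Ne b)) for b != 0, and the neutral
#' 1/(2 Ne) for b = 0. Overflow-guarded for large |Ne b|.
#'
#' @param Ne effective population size (>= 1); vectorized.
#' @param b conversion coefficient (can be negative for the disfavored
#'   allele); vectorized.
#' @return fixation probability/probabilities.
#' @export
fixation_probability <- function(Ne, b) {
  if (any(Ne < 1)) stop_avigc("Ne must be >= 1")
  n <- max(length(Ne), length(b))
  Ne <- rep_len(Ne, n); b <- rep_len(b, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (b[i] == 0) {
      out[i] <- 1 / (2 * Ne[i])
    } else if (4 * Ne[i] * b[i] > 700) {
      ## denominator is 1 to machine precision
      out[i] <- -expm1(-2 * b[i])
    } else if (4 * Ne[i] * b[i] < -700) {
      ## both tails explode; work in logs of absolute values
      lognum <- 2 * abs(b[i]) + log1p(-exp(-2 * abs(b[i])))
      logden <- 4 * Ne[i] * abs(b[i]) + log1p(-exp(-4 * Ne[i] * abs(b[i])))
      out[i] <- exp(lognum - logden)
    } else {
      out[i] <- expm1(-2 * b[i]) / expm1(-4 * Ne[i] * b[i])
    }
  }
  out
}

#' Approach of GC content to its gBGC equilibrium
#'
#' Two-state (weak/strong) dynamic for the GC content of a sequence class:
#' with per-generation W->S substitution rate `u` per weak site and S->W
#' rate `v` per strong site, g(t) = g* + (g0 - g*) exp(-(u+v) t), with
#' equilibrium g* = u/(u+v). Rates may be given directly or derived from a
#' population layer: u = 2 Ne mu_ws P_fix(Ne, +b) and
#' v = 2 Ne mu_sw P_fix(Ne, -b) (per-site, per-generation substitution
#' rates of new mutants under the conversion bias).
#'
#' @param g0 current GC content in \[0, 1\].
#' @param u,v per-generation substitution rates (alternatively supply the
#'   population layer).
#' @param Ne,mu_ws,mu_sw,b optional population layer: effective size,
#'   W->S and S->W mutation rates per site per generation, conversion
#'   coefficient.
#' @return object of class `gbgc_dynamics`: list with `g0`, `u`, `v`,
#'   `g_star`, `rate` (= u+v), `t_half`, and `trajectory(t)` returning
#'   g(t) for generation times `t`.
#' @export
gbgc_dynamics <- function(g0, u = NULL, v = NULL, Ne = NULL,
                          mu_ws = NULL, mu_sw = NULL, b = NULL) {
  if (g0 < 0 || g0 > 1) stop_avigc("g0 must lie in [0, 1]")
  if (is.null(u) || is.null(v)) {
    if (is.null(Ne) || is.null(mu_ws) || is.null(mu_sw) || is.null(b))
      stop_avigc("supply either (u, v) or the population layer (Ne, mu_ws, mu_sw, b)")
    u <- 2 * Ne * mu_ws * fixation_probability(Ne, b)
    v <- 2 * Ne * mu_sw * fixation_probability(Ne, -b)
  }
  if (u < 0 || v < 0) stop_avigc("rates must be non-negative")
  rate <- u + v
  g_star <- if (rate > 0) u / rate else NA_real_
  traj <- function(t) {
    if (rate == 0) return(rep(g0, length(t)))
    g_star + (g0 - g_star) * exp(-rate * t)
  }
  structure(list(g0 = g0, u = u, v = v, g_star = g_star, rate = rate,
                 t_half = if (rate > 0) log(2) / rate else Inf,
                 trajectory = traj,
                 flags = if (rate == 0) "zero_rate" else character(0)),
            class = "gbgc_dynamics")
}

#' @export
print.gbgc_dynamics <- function(x, ...) {
  cat(sprintf(
    "<gbgc_dynamics> g0 = %.4f, g* = %.4f, u = %.3g, v = %.3g, t_half = %.4g generations\n",
    x$g0, x$g_star, x$u, x$v, x$t_half))
  invisible(x)
}

#' Generations needed to halve the distance between GC and its equilibrium
#'
#' t_half = ln 2 / (u + v); independent of the current composition g0 and
#' exactly inversely proportional to the total substitution rate.
#'
#' @param dynamics a [gbgc_dynamics] object.
#' @return half-life in generations (+Inf, flagged upstream, when u+v = 0).
#' @export
gc_halving_time <- function(dynamics) {
  stopifnot(inherits(dynamics, "gbgc_dynamics"))
  dynamics$t_half
}
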