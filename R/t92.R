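#' Tamura (1992) substitution model
#'
#' Two-parameter model with equilibrium GC content `theta` and
#' transition/transversion rate ratio `kappa`. Stationary frequencies are
#' fG = fC = theta/2 and fA = fT = (1-theta)/2; the rate matrix is scaled
#' so the mean substitution rate at stationarity is 1, i.e. branch lengths
#' are expected substitutions per site.
#'
#' @param theta equilibrium GC content, in (0, 1).
#' @param kappa transition/transversion rate ratio, > 0.
#' @return object of class `t92_model` with fields `theta`, `kappa`, `pi`
#'   (stationary frequencies in A,C,G,T order), `beta` (the rate scaler),
#'   `u` (W->S rate per weak site) and `v` (S->W rate per strong site).
#' @export
t92_model <- function(theta, kappa = 2) {
  if (!is.finite(theta) || theta <= 0 || theta >= 1)
    stop_avigc("theta must lie strictly in (0, 1)")
  if (!is.finite(kappa) || kappa <= 0) stop_avigc("kappa must be positive")
  beta <- 1 / (kappa * theta * (1 - theta) + 0.5)
  structure(list(theta = theta, kappa = kappa,
                 pi = c(A = (1 - theta) / 2, C = theta / 2,
                        G = theta / 2, T = (1 - theta) / 2),
                 beta = beta,
                 u = beta * theta * (1 + kappa) / 2,
                 v = beta * (1 - theta) * (1 + kappa) / 2),
            class = "t92_model")
}

#' @export
print.t92_model <- function(x, ...) {
  cat(sprintf("<t92_model> theta = %.4f, kappa = %.3f\n", x$theta, x$kappa))
  invisible(x)
}

#' T92 instantaneous rate matrix
#'
#' @param model a [t92_model].
#' @return 4x4 rate matrix (A,C,G,T order), rows summing to 0, mean rate 1.
#' @export
t92_rate_matrix <- function(model) {
  stopifnot(inherits(model, "t92_model"))
  p <- model$pi; k <- model$kappa; b <- model$beta
  Q <- b * matrix(c(0,        p["C"],     k * p["G"], p["T"],
                    p["A"],   0,          p["G"],     k * p["T"],
                    k * p["A"], p["C"],   0,          p["T"],
                    p["A"],   k * p["C"], p["G"],     0),
                  nrow = 4, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  Q
}

#' T92 transition probability matrix
#'
#' Closed-form solution of the T92 rate matrix (the purine and pyrimidine
#' frequency classes are symmetric, so the TN93 spectral form collapses to
#' two decay modes). Rows sum to 1 to within 1e-12.
#'
#' @param model a [t92_model].
#' @param branch_length expected substitutions per site, >= 0.
#' @return 4x4 stochastic matrix in A,C,G,T order.
#' @export
t92_transition_matrix <- function(model, branch_length) {
  stopifnot(inherits(model, "t92_model"))
  if (!is.finite(branch_length) || branch_length < 0)
    stop_avigc("branch_length must be finite and >= 0")
  th <- model$theta; k <- model$kappa; b <- model$beta
  pA <- (1 - th) / 2; pC <- th / 2; pG <- th / 2; pT <- (1 - th) / 2
  E1 <- exp(-b * branch_length)
  E2 <- exp(-b * (k + 1) * branch_length / 2)
  P <- matrix(c(
    pA * (1 + E1) + 2 * pG * E2, pC * (1 - E1), pG * (1 + E1) - 2 * pG * E2, pT * (1 - E1),
    pA * (1 - E1), pC * (1 + E1) + 2 * pT * E2, pG * (1 - E1), pT * (1 + E1) - 2 * pT * E2,
    pA * (1 + E1) - 2 * pA * E2, pC * (1 - E1), pG * (1 + E1) + 2 * pA * E2, pT * (1 - E1),
    pA * (1 - E1), pC * (1 + E1) - 2 * pC * E2, pG * (1 - E1), pT * (1 + E1) + 2 * pC * E2),
    nrow = 4, byrow = TRUE)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

## Vectorized transition probabilities over genes: returns the full set of
## row-wise cumulative probabilities used by the C++ branch-evolution
## kernel. theta may vary by gene; kappa and t are scalars.
t92_cum_rows <- function(theta, kappa, t) {
  b <- 1 / (kappa * theta * (1 - theta) + 0.5)
  pA <- (1 - theta) / 2; pC <- theta / 2; pG <- theta / 2; pT <- (1 - theta) / 2
  E1 <- exp(-b * t)
  E2 <- exp(-b * (kappa + 1) * t / 2)
  n <- length(theta)
  ## P[parent, child] per gene; rows (gene-1)*4 + parent, A,C,G,T order
  P <- matrix(0, nrow = 4 * n, ncol = 4)
  iA <- seq(1L, 4L * n, by = 4L); iC <- iA + 1L; iG <- iA + 2L; iT <- iA + 3L
  P[iA, 1] <- pA * (1 + E1) + 2 * pG * E2; P[iA, 2] <- pC * (1 - E1)
  P[iA, 3] <- pG * (1 + E1) - 2 * pG * E2; P[iA, 4] <- pT * (1 - E1)
  P[iC, 1] <- pA * (1 - E1); P[iC, 2] <- pC * (1 + E1) + 2 * pT * E2
  P[iC, 3] <- pG * (1 - E1); P[iC, 4] <- pT * (1 + E1) - 2 * pT * E2
  P[iG, 1] <- pA * (1 + E1) - 2 * pA * E2; P[iG, 2] <- pC * (1 - E1)
  P[iG, 3] <- pG * (1 + E1) + 2 * pA * E2; P[iG, 4] <- pT * (1 - E1)
  P[iT, 1] <- pA * (1 - E1); P[iT, 2] <- pC * (1 + E1) - 2 * pC * E2
  P[iT, 3] <- pG * (1 - E1); P[iT, 4] <- pT * (1 + E1) + 2 * pC * E2
  cum <- P
  cum[, 2] <- cum[, 1] + P[, 2]
  cum[, 3] <- cum[, 2] + P[, 3]
  cum[, 4] <- 1
  cum[, 1:3, drop = FALSE]
}
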