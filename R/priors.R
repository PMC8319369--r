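# Prior densities and prior simulation for the spatiotemporal model.
#
# Precisions carry penalized-complexity (PC) priors: an exponential prior on
# the standard deviation sd = 1/sqrt(tau), parameterised by P(sd > u) = alpha,
# transformed to the precision scale. The BYM2 mixing parameter phi carries a
# Beta(1, log(3)/log(2)) prior calibrated so that P(phi < 0.5) = 2/3, and the
# AR1 coefficient rho a standard Normal prior on atanh(rho) (so P(rho>0)=1/2).

# log density of the PC precision prior, P(sd > u) = alpha
log_pc_prec <- function(tau, u = 1, alpha = 0.01) {
  lambda <- -log(alpha) / u
  log(lambda / 2) - 1.5 * log(tau) - lambda / sqrt(tau)
}

log_phi_prior <- function(phi, shape2 = log(3) / log(2)) {
  stats::dbeta(phi, 1, shape2, log = TRUE)
}

log_rho_prior <- function(rho, sd = 1) {
  # density on the rho scale: Normal on z = atanh(rho) plus Jacobian dz/drho
  stats::dnorm(atanh(rho), 0, sd, log = TRUE) - log(1 - rho^2)
}

# Stationary AR1 prior precision matrix: tau * K(rho), marginal variance
# 1 / (tau * (1 - rho^2)).
ar1_structure <- function(n_time, rho) {
  if (n_time == 1L) return(matrix(1 - rho^2, 1, 1))
  K <- diag(c(1, rep(1 + rho^2, n_time - 2L), 1))
  K[cbind(1:(n_time - 1L), 2:n_time)] <- -rho
  K[cbind(2:n_time, 1:(n_time - 1L))] <- -rho
  K
}

# log density of B under the stationary AR1 prior (direct, no matrices)
log_ar1_density <- function(B, tau, rho) {
  n <- length(B)
  ll <- stats::dnorm(B[1], 0, sqrt(1 / (tau * (1 - rho^2))), log = TRUE)
  if (n > 1L) {
    ll <- ll + sum(stats::dnorm(B[-1], rho * B[-n], sqrt(1 / tau), log = TRUE))
  }
  ll
}

#' Draws from the scaled ICAR prior
#'
#' Samples the structured BYM2 component u* (unit generalized marginal
#' variance) under the per-component sum-to-zero constraint, via the
#' eigendecomposition of the scaled structure matrix. Singleton components
#' are fixed at zero.
#'
#' @param n_draws number of draws
#' @param spatial a \code{\link{spatial_structure}}
#' @return matrix n_draws x n_regions
#' @export
ricar_scaled <- function(n_draws, spatial) {
  Qs <- as.matrix(spatial$Q_scaled)
  n <- nrow(Qs)
  out <- matrix(0, n_draws, n)
  colnames(out) <- spatial$region_ids
  for (k in unique(spatial$component)) {
    ids <- which(spatial$component == k)
    if (length(ids) < 2L) next
    e <- eigen(Qs[ids, ids, drop = FALSE], symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    z <- matrix(stats::rnorm(n_draws * sum(pos)), n_draws, sum(pos))
    out[, ids] <- z %*% (t(e$vectors[, pos, drop = FALSE]) / sqrt(e$values[pos]))
  }
  out
}

#' Draws from the BYM2 spatial prior
#'
#' The BYM2 effect is A = (1/sqrt(tau)) * (sqrt(1-phi) v + sqrt(phi) u*),
#' with v iid standard Normal and u* the scaled ICAR. At phi = 0 it reduces
#' to an iid effect with precision tau; at phi = 1 to the scaled ICAR.
#'
#' @param n_draws number of draws
#' @param spatial a \code{\link{spatial_structure}}
#' @param tau marginal precision
#' @param phi mixing parameter in [0, 1]
#' @return matrix n_draws x n_regions
#' @export
rbym2 <- function(n_draws, spatial, tau, phi) {
  stopifnot(tau > 0, phi >= 0, phi <= 1)
  n <- length(spatial$region_ids)
  v <- matrix(stats::rnorm(n_draws * n), n_draws, n)
  u <- if (phi > 0) ricar_scaled(n_draws, spatial) else matrix(0, n_draws, n)
  (sqrt(1 - phi) * v + sqrt(phi) * u) / sqrt(tau)
}

#' Draws from the stationary AR1 prior
#'
#' First-order autoregression with coefficient rho and innovation precision
#' tau: stationary variance 1/(tau (1 - rho^2)) and lag-k autocorrelation
#' rho^k.
#'
#' @param n_draws number of draws
#' @param n_time series length
#' @param tau innovation precision
#' @param rho autoregressive coefficient, |rho| < 1
#' @return matrix n_draws x n_time
#' @export
rar1 <- function(n_draws, n_time, tau, rho) {
  stopifnot(tau > 0, abs(rho) < 1)
  out <- matrix(0, n_draws, n_time)
  out[, 1] <- stats::rnorm(n_draws, 0, sqrt(1 / (tau * (1 - rho^2))))
  if (n_time > 1L) {
    sd_innov <- sqrt(1 / tau)
    for (t in 2:n_time) {
      out[, t] <- rho * out[, t - 1L] + stats::rnorm(n_draws, 0, sd_innov)
    }
  }
  out
}
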