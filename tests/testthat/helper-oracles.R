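# Independent oracles and small fixtures shared across tests.

# eigen-based Moore-Penrose pseudo-inverse (independent of the package's
# generalized-inverse path)
pinv_eigen <- function(M, tol = 1e-10) {
  e <- eigen(as.matrix(M), symmetric = TRUE)
  pos <- abs(e$values) > max(abs(e$values)) * tol
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# tiny path-graph world: 4 regions in a chain, 3 time points, full grid
toy_design <- function(seed = 42) {
  g <- build_region_graph(
    data.frame(a = c("r1", "r2", "r3"), b = c("r2", "r3", "r4")),
    c("r1", "r2", "r3", "r4")
  )
  sp <- spatial_structure(g)
  set.seed(seed)
  grid <- expand.grid(region = 1:4, time = 1:3)
  X <- cbind(intercept = 1, x1 = rnorm(12))
  y <- rnorm(12)
  stmobility:::model_design(y, X, grid$region, grid$time, sp, n_time = 3)
}

toy_hyper <- function() {
  list(tau_eps = 2, tau_A = 1.5, phi = 0.4, tau_B = 1.2, rho = 0.5,
       tau_C = 0.8)
}

toy_state <- function(design, hyper = toy_hyper(), seed = 7) {
  set.seed(seed)
  st <- list(beta = rnorm(ncol(design$X)),
             ustar = rnorm(design$n_region),
             v = rnorm(design$n_region),
             B = rnorm(design$n_time),
             C = rnorm(length(design$y)))
  st$A <- sqrt(hyper$phi / hyper$tau_A) * st$ustar +
    sqrt((1 - hyper$phi) / hyper$tau_A) * st$v
  st
}

# Independent derivation of every Gaussian full conditional: build the joint
# posterior precision over w = (beta, ustar, v, B, C) from the model's
# densities, then read each block conditional off the partitioned Gaussian:
# z_S | rest ~ N(P_SS^{-1} (b_S - P_{S,rest} w_rest), P_SS^{-1}).
joint_conditional_oracle <- function(design, state, hyper, priors) {
  n <- length(design$y)
  p <- ncol(design$X)
  nr <- design$n_region
  nt <- design$n_time
  bs <- sqrt(hyper$phi / hyper$tau_A)
  bu <- sqrt((1 - hyper$phi) / hyper$tau_A)
  ZA <- matrix(0, n, nr); ZA[cbind(1:n, design$region)] <- 1
  ZB <- matrix(0, n, nt); ZB[cbind(1:n, design$time)] <- 1
  Z <- cbind(design$X, bs * ZA, bu * ZA, ZB, diag(n))
  Pprior <- as.matrix(Matrix::bdiag(
    diag(1 / priors$beta_sd^2, p),
    as.matrix(design$spatial$Q_scaled),
    diag(nr),
    hyper$tau_B * stmobility:::ar1_structure(nt, hyper$rho),
    diag(hyper$tau_C, n)
  ))
  P <- Pprior + hyper$tau_eps * crossprod(Z)
  b <- hyper$tau_eps * drop(crossprod(Z, design$y))
  blocks <- list(beta = 1:p, ustar = p + 1:nr, v = p + nr + 1:nr,
                 B = p + 2 * nr + 1:nt, C = p + 2 * nr + nt + 1:n)
  w <- c(state$beta, state$ustar, state$v, state$B, state$C)
  lapply(blocks, function(S) {
    rest <- setdiff(seq_along(w), S)
    shift <- b[S] - P[S, rest, drop = FALSE] %*% w[rest]
    list(P = P[S, S, drop = FALSE], b = drop(shift),
         mean = drop(solve(P[S, S, drop = FALSE], shift)))
  })
}

# direct-formula validation oracle
score_oracle <- function(obs, fit) {
  n <- length(obs)
  mae <- sum(abs(obs - fit)) / n
  rmse <- sqrt(sum((obs - fit)^2) / n)
  mo <- sum(obs) / n; mf <- sum(fit) / n
  r <- sum((obs - mo) * (fit - mf)) /
    sqrt(sum((obs - mo)^2) * sum((fit - mf)^2))
  list(mae = mae, rmse = rmse, r2 = r^2)
}

# small monthly panel builder: one origin, one destination per month
simple_panel <- function(region, year, counts, dest = region) {
  data.frame(origin_id = region, dest_id = dest, year = year,
             month = seq_along(counts), count = counts,
             stringsAsFactors = FALSE)
}
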