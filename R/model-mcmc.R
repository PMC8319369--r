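# Metropolis-within-Gibbs sampler for the spatiotemporal change-ratio model.
#
# Gaussian blocks (beta, structured spatial u*, unstructured spatial v,
# temporal B, interaction C) are updated by conjugate draws from their full
# conditionals via precision solves; hyperparameters move by random-walk
# Metropolis on transformed scales (log precisions, logit phi, Fisher-z rho).
# The sum-to-zero constraint on u* (per graph component) is re-imposed at
# every update by conditioning-by-kriging, which is exact for Gaussian draws.

sum_by <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Precomputed quantities reused across iterations
design_precompute <- function(design) {
  sp <- design$spatial
  ns <- which(!sp$singleton)
  Qns <- as.matrix(sp$Q_scaled)[ns, ns, drop = FALSE]
  comp_ns <- sp$component[ns]
  Acon <- t(vapply(unique(comp_ns), function(k) as.numeric(comp_ns == k),
                   numeric(length(ns))))
  # per-column structure used by the translation sweeps: a fixed-effect
  # column that is constant within region (or within time) defines a
  # likelihood-invariant direction shared with v (or B)
  p <- ncol(design$X)
  x_reg <- matrix(NA_real_, design$n_region, p)
  x_time <- matrix(NA_real_, design$n_time, p)
  reg_const <- time_const <- logical(p)
  for (j in seq_len(p)) {
    xj <- design$X[, j]
    by_reg <- tapply(xj, design$region, function(z) {
      if (max(z) - min(z) < 1e-12) z[1] else NA_real_
    })
    reg_const[j] <- !anyNA(by_reg)
    if (reg_const[j]) x_reg[as.integer(names(by_reg)), j] <- by_reg
    by_time <- tapply(xj, design$time, function(z) {
      if (max(z) - min(z) < 1e-12) z[1] else NA_real_
    })
    time_const[j] <- !anyNA(by_time)
    if (time_const[j]) x_time[as.integer(names(by_time)), j] <- by_time
  }
  list(
    XtX = crossprod(design$X),
    m_reg = tabulate(design$region, design$n_region),
    m_time = tabulate(design$time, design$n_time),
    ns = ns, Qns = Qns, Acon = Acon,
    reg_const = reg_const, time_const = time_const,
    x_reg = x_reg, x_time = x_time
  )
}

# Exact Gibbs moves along likelihood-invariant directions: shifting a fixed
# effect while compensating in v, B or C leaves eta unchanged, so the
# conditional of the shift is Gaussian in the priors alone. These
# interweaving sweeps remove the slow mixing caused by the confounding of
# fixed effects with the unstructured random-effect levels.
translation_sweep <- function(design, pre, state, hyper, priors, spec) {
  sb2 <- priors$beta_sd^2
  for (j in seq_len(ncol(design$X))) {
    if (spec$use_spatial && pre$reg_const[j] && hyper$phi < 1) {
      bu <- sqrt((1 - hyper$phi) / hyper$tau_A)
      xj <- pre$x_reg[, j]
      prec <- 1 / sb2 + sum(xj^2) / bu^2
      mean_d <- (-state$beta[j] / sb2 + sum(state$v * xj) / bu) / prec
      d <- stats::rnorm(1, mean_d, sqrt(1 / prec))
      state$beta[j] <- state$beta[j] + d
      state$v <- state$v - d * xj / bu
    }
    if (spec$use_temporal && pre$time_const[j]) {
      xj <- pre$x_time[, j]
      K <- ar1_structure(design$n_time, hyper$rho)
      Kx <- drop(K %*% xj)
      prec <- 1 / sb2 + hyper$tau_B * sum(xj * Kx)
      mean_d <- (-state$beta[j] / sb2 + hyper$tau_B * sum(state$B * Kx)) /
        prec
      d <- stats::rnorm(1, mean_d, sqrt(1 / prec))
      state$beta[j] <- state$beta[j] + d
      state$B <- state$B - d * xj
    }
    if (spec$use_interaction) {
      xj <- design$X[, j]
      prec <- 1 / sb2 + hyper$tau_C * sum(xj^2)
      mean_d <- (-state$beta[j] / sb2 + hyper$tau_C * sum(state$C * xj)) /
        prec
      d <- stats::rnorm(1, mean_d, sqrt(1 / prec))
      state$beta[j] <- state$beta[j] + d
      state$C <- state$C - d * xj
    }
  }
  state
}

# Sample x ~ N(P^{-1} b, P^{-1}) given dense precision P
draw_mvn_prec <- function(P, b) {
  U <- chol(P)
  mean <- backsolve(U, backsolve(U, b, transpose = TRUE))
  list(draw = drop(mean + backsolve(U, stats::rnorm(length(b)))),
       mean = drop(mean), U = U)
}

# Conditioning-by-kriging correction enforcing Acon %*% x = 0
constrain_kriging <- function(x, U, Acon) {
  W <- backsolve(U, backsolve(U, t(Acon), transpose = TRUE))   # P^{-1} A'
  drop(x - W %*% solve(Acon %*% W, Acon %*% x))
}

bym2_weights <- function(hyper) {
  list(bs = sqrt(hyper$phi / hyper$tau_A),
       bu = sqrt((1 - hyper$phi) / hyper$tau_A))
}

# --- full conditionals of the Gaussian blocks (precision P, shift b) -------
# Each returns the conditional as N(solve(P, b), solve(P)); diagonal blocks
# return P as a vector. Kept as separate functions so that they can be
# checked against an independently derived joint-Gaussian oracle.

fc_beta <- function(design, pre, state, hyper, priors) {
  r <- design$y - state$A[design$region] - state$B[design$time] - state$C
  P <- hyper$tau_eps * pre$XtX +
    diag(1 / priors$beta_sd^2, ncol(design$X))
  b <- hyper$tau_eps * drop(crossprod(design$X, r))
  list(P = P, b = b)
}

fc_ustar <- function(design, pre, state, hyper) {
  w <- bym2_weights(hyper)
  r <- design$y - drop(design$X %*% state$beta) -
    w$bu * state$v[design$region] - state$B[design$time] - state$C
  sb <- sum_by(r, design$region, design$n_region)[pre$ns]
  P <- pre$Qns + diag(w$bs^2 * hyper$tau_eps * pre$m_reg[pre$ns],
                      length(pre$ns))
  list(P = P, b = w$bs * hyper$tau_eps * sb)
}

fc_v <- function(design, pre, state, hyper) {
  w <- bym2_weights(hyper)
  r <- design$y - drop(design$X %*% state$beta) -
    w$bs * state$ustar[design$region] - state$B[design$time] - state$C
  P <- 1 + w$bu^2 * hyper$tau_eps * pre$m_reg
  list(P = P, b = w$bu * hyper$tau_eps * sum_by(r, design$region,
                                                design$n_region))
}

fc_B <- function(design, pre, state, hyper) {
  r <- design$y - drop(design$X %*% state$beta) - state$A[design$region] -
    state$C
  P <- hyper$tau_B * ar1_structure(design$n_time, hyper$rho) +
    diag(hyper$tau_eps * pre$m_time, design$n_time)
  list(P = P, b = hyper$tau_eps * sum_by(r, design$time, design$n_time))
}

fc_C <- function(design, pre, state, hyper) {
  r <- design$y - drop(design$X %*% state$beta) - state$A[design$region] -
    state$B[design$time]
  P <- rep(hyper$tau_C + hyper$tau_eps, length(design$y))
  list(P = P, b = hyper$tau_eps * r)
}

# ---------------------------------------------------------------------------

linpred <- function(design, state) {
  drop(design$X %*% state$beta) + state$A[design$region] +
    state$B[design$time] + state$C
}

gauss_loglik <- function(y, eta, tau_eps) {
  sum(stats::dnorm(y, eta, sqrt(1 / tau_eps), log = TRUE))
}

.hyper_names <- c("tau_eps", "tau_A", "phi", "tau_B", "rho", "tau_C")

run_chain <- function(design, spec, pre) {
  y <- design$y
  n <- length(y)
  p <- ncol(design$X)
  priors <- spec$priors
  fixed <- spec$fixed

  hyper <- list(tau_eps = 1 / max(stats::var(y), 1e-6), tau_A = 4, phi = 0.5,
                tau_B = 4, rho = 0.5, tau_C = 4)
  for (nm in names(fixed)) hyper[[nm]] <- fixed[[nm]]
  state <- list(beta = drop(qr.coef(qr(design$X), y)),
                ustar = numeric(design$n_region),
                v = numeric(design$n_region),
                B = numeric(design$n_time),
                C = numeric(n),
                A = numeric(design$n_region))

  sampled <- setdiff(.hyper_names, names(fixed))
  if (!spec$use_spatial) sampled <- setdiff(sampled, c("tau_A", "phi"))
  if (!spec$use_temporal) sampled <- setdiff(sampled, c("tau_B", "rho"))
  if (!spec$use_interaction) sampled <- setdiff(sampled, "tau_C")
  step <- stats::setNames(rep(0.4, length(sampled)), sampled)
  acc <- stats::setNames(numeric(length(sampled)), sampled)
  acc_total <- stats::setNames(numeric(length(sampled)), sampled)
  batch <- 50L

  total <- spec$n_burn + spec$n_iter
  beta_draws <- matrix(NA_real_, spec$n_iter, p,
                       dimnames = list(NULL, colnames(design$X)))
  hyper_draws <- matrix(NA_real_, spec$n_iter, length(.hyper_names),
                        dimnames = list(NULL, .hyper_names))
  A_draws <- matrix(NA_real_, spec$n_iter, design$n_region)
  B_draws <- matrix(NA_real_, spec$n_iter, design$n_time)
  deviance <- numeric(spec$n_iter)
  eta_sum <- numeric(n)
  C_sum <- numeric(n)

  mh <- function(nm, cur, logpost) {
    prop <- cur + stats::rnorm(1, 0, step[[nm]])
    lr <- logpost(prop) - logpost(cur)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      acc[[nm]] <<- acc[[nm]] + 1
      acc_total[[nm]] <<- acc_total[[nm]] + 1
      prop
    } else cur
  }

  for (iter in seq_len(total)) {
    # fixed effects
    fc <- fc_beta(design, pre, state, hyper, priors)
    state$beta <- draw_mvn_prec(fc$P, fc$b)$draw

    if (spec$use_spatial) {
      w <- bym2_weights(hyper)
      fc <- fc_ustar(design, pre, state, hyper)
      d <- draw_mvn_prec(fc$P, fc$b)
      state$ustar[pre$ns] <- constrain_kriging(d$draw, d$U, pre$Acon)
      fc <- fc_v(design, pre, state, hyper)
      state$v <- stats::rnorm(design$n_region, fc$b / fc$P, sqrt(1 / fc$P))
      state$A <- w$bs * state$ustar + w$bu * state$v
    }

    if (spec$use_temporal) {
      fc <- fc_B(design, pre, state, hyper)
      d <- draw_mvn_prec(fc$P, fc$b)
      state$B <- if (spec$sum_to_zero_B) {
        constrain_kriging(d$draw, d$U, matrix(1, 1, design$n_time))
      } else d$draw
    }

    if (spec$use_interaction) {
      fc <- fc_C(design, pre, state, hyper)
      state$C <- stats::rnorm(n, fc$b / fc$P, sqrt(1 / fc$P))
    }

    state <- translation_sweep(design, pre, state, hyper, priors, spec)
    if (spec$use_spatial) {
      w <- bym2_weights(hyper)
      state$A <- w$bs * state$ustar + w$bu * state$v
    }

    # hyperparameters: random-walk Metropolis on transformed scales
    eta_minus_A <- drop(design$X %*% state$beta) + state$B[design$time] +
      state$C
    eta <- eta_minus_A + state$A[design$region]

    if ("tau_eps" %in% sampled) {
      lt <- mh("tau_eps", log(hyper$tau_eps), function(th) {
        gauss_loglik(y, eta, exp(th)) +
          log_pc_prec(exp(th), priors$pc_u, priors$pc_alpha) + th
      })
      hyper$tau_eps <- exp(lt)
    }
    if ("tau_A" %in% sampled) {
      Araw <- sqrt(hyper$phi) * state$ustar + sqrt(1 - hyper$phi) * state$v
      lt <- mh("tau_A", log(hyper$tau_A), function(th) {
        gauss_loglik(y, eta_minus_A +
                       (Araw / sqrt(exp(th)))[design$region],
                     hyper$tau_eps) +
          log_pc_prec(exp(th), priors$pc_u, priors$pc_alpha) + th
      })
      hyper$tau_A <- exp(lt)
    }
    if ("phi" %in% sampled) {
      lt <- mh("phi", stats::qlogis(hyper$phi), function(th) {
        ph <- stats::plogis(th)
        A_ph <- (sqrt(ph) * state$ustar + sqrt(1 - ph) * state$v) /
          sqrt(hyper$tau_A)
        gauss_loglik(y, eta_minus_A + A_ph[design$region], hyper$tau_eps) +
          log_phi_prior(ph, priors$phi_shape2) + log(ph) + log(1 - ph)
      })
      hyper$phi <- stats::plogis(lt)
    }
    if (spec$use_spatial) {
      w <- bym2_weights(hyper)
      state$A <- w$bs * state$ustar + w$bu * state$v
      eta <- eta_minus_A + state$A[design$region]
    }
    if ("tau_B" %in% sampled) {
      lt <- mh("tau_B", log(hyper$tau_B), function(th) {
        log_ar1_density(state$B, exp(th), hyper$rho) +
          log_pc_prec(exp(th), priors$pc_u, priors$pc_alpha) + th
      })
      hyper$tau_B <- exp(lt)
    }
    if ("rho" %in% sampled) {
      zt <- mh("rho", atanh(hyper$rho), function(th) {
        log_ar1_density(state$B, hyper$tau_B, tanh(th)) +
          stats::dnorm(th, 0, priors$rho_sd, log = TRUE)
      })
      hyper$rho <- tanh(zt)
    }
    if ("tau_C" %in% sampled) {
      lt <- mh("tau_C", log(hyper$tau_C), function(th) {
        sum(stats::dnorm(state$C, 0, sqrt(1 / exp(th)), log = TRUE)) +
          log_pc_prec(exp(th), priors$pc_u, priors$pc_alpha) + th
      })
      hyper$tau_C <- exp(lt)
    }

    # step-size adaptation during burn-in only (frozen afterwards)
    if (iter <= spec$n_burn && iter %% batch == 0L && length(sampled)) {
      rate <- acc / batch
      step <- pmin(pmax(step * exp(rate - 0.44), 1e-3), 10)
      acc[] <- 0
    }

    dev <- -2 * gauss_loglik(y, eta, hyper$tau_eps)
    if (!is.finite(dev)) {
      stop("divergent chain at iteration ", iter,
           ": non-finite log-density (tau_eps = ", format(hyper$tau_eps),
           ", max |eta| = ", format(max(abs(eta))), ")")
    }

    if (iter > spec$n_burn) {
      k <- iter - spec$n_burn
      beta_draws[k, ] <- state$beta
      hyper_draws[k, ] <- unlist(hyper[.hyper_names])
      A_draws[k, ] <- state$A
      B_draws[k, ] <- state$B
      deviance[k] <- dev
      eta_sum <- eta_sum + eta
      C_sum <- C_sum + state$C
    }
    if (spec$verbose && iter %% 100L == 0L) {
      message("iter ", iter, "/", total, " | deviance ", round(dev, 2),
              " | acc ", paste(sprintf("%s=%.2f", names(acc_total),
                                       acc_total / iter), collapse = " "))
    }
  }

  list(beta = beta_draws, hyper = hyper_draws, A = A_draws, B = B_draws,
       deviance = deviance, eta_mean = eta_sum / spec$n_iter,
       C_mean = C_sum / spec$n_iter,
       acceptance = if (length(sampled)) acc_total / total else numeric(0),
       step = step)
}

#' Sample the posterior of the spatiotemporal model by MCMC
#'
#' Runs Metropolis-within-Gibbs chains for the Gaussian change-ratio model
#' with BYM2 spatial, AR1 temporal and iid space-time interaction random
#' effects: conjugate block updates through sparse/dense precision solves for
#' all Gaussian blocks and random-walk Metropolis on transformed
#' hyperparameters. Sum-to-zero constraints on the structured spatial effect
#' are re-imposed exactly at each update. Chains are a deterministic function
#' of the seed.
#'
#' @param design a \code{mobility_design}
#' @param spec a \code{\link{model_spec}}
#' @return object of class \code{stmob_fit}: list of per-chain draws plus the
#'   design and spec
#' @export
sample_posterior <- function(design, spec = model_spec()) {
  stopifnot(inherits(design, "mobility_design"), inherits(spec, "model_spec"))
  if (spec$n_iter + spec$n_burn < 2L) stop("n_iter must exceed n_burn")
  pre <- design_precompute(design)
  set.seed(spec$seed)
  chains <- lapply(seq_len(spec$n_chains), function(i) {
    run_chain(design, spec, pre)
  })
  structure(list(chains = chains, design = design, spec = spec),
            class = "stmob_fit")
}

#' @export
print.stmob_fit <- function(x, ...) {
  cat("Spatiotemporal mobility model fit:", length(x$chains), "chain(s) x",
      x$spec$n_iter, "post-burn-in draws,",
      length(x$design$y), "observations\n")
  invisible(x)
}
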