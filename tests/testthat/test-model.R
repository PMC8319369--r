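test_that("design construction logs ratios and orders covariates canonically", {
  g <- kenya_graph()
  tr <- synthetic_truth(g, seed = 5)
  panel <- simulate_panel(tr, seed = 5)
  ch <- panel$truth_changes
  design <- build_design(ch, tr$covariates, g)
  expect_equal(length(design$y), 1128L)
  expect_equal(colnames(design$X),
               c("intercept", "accessibility", "education",
                 "school_holidays", "ntl", "poverty", "temperature",
                 "urbanicity"))
  # ratio 1 -> log ratio 0
  expect_true(all(design$y[ch$month == 1] == 0))
  # excluding january drops exactly the baseline rows
  d2 <- build_design(ch, tr$covariates, g, include_january = FALSE)
  expect_equal(length(d2$y), 1128L - 94L)

  # dropping one county-month leaves the others unchanged
  ch3 <- ch[!(ch$region_id == "nairobi" & ch$year == 2018 & ch$month == 2), ]
  d3 <- build_design(ch3, tr$covariates, g)
  expect_equal(length(d3$y), 1127L)

  ch_bad <- ch
  ch_bad$ratio[5] <- -1
  expect_error(build_design(ch_bad, tr$covariates, g), "non-positive")

  # rank-deficient X is refused with the dependency named
  cov_bad <- tr$covariates
  cov_bad$dynamic$ntl <- 2 * cov_bad$dynamic$temperature_C
  expect_error(build_design(ch, cov_bad, g), "rank deficient")
})

test_that("Gibbs full conditionals match the joint-Gaussian oracle", {
  design <- toy_design()
  hyper <- toy_hyper()
  state <- toy_state(design)
  priors <- model_spec()$priors
  pre <- stmobility:::design_precompute(design)
  oracle <- joint_conditional_oracle(design, state, hyper, priors)

  fb <- stmobility:::fc_beta(design, pre, state, hyper, priors)
  expect_equal(unname(fb$P), unname(oracle$beta$P), tolerance = 1e-8)
  expect_equal(unname(drop(solve(fb$P, fb$b))), unname(oracle$beta$mean),
               tolerance = 1e-8)

  fu <- stmobility:::fc_ustar(design, pre, state, hyper)
  expect_equal(unname(fu$P), unname(oracle$ustar$P), tolerance = 1e-8)
  expect_equal(unname(drop(solve(fu$P, fu$b))), unname(oracle$ustar$mean),
               tolerance = 1e-8)

  fv <- stmobility:::fc_v(design, pre, state, hyper)
  expect_equal(unname(fv$P), unname(diag(oracle$v$P)), tolerance = 1e-8)
  expect_equal(unname(fv$b / fv$P), unname(oracle$v$mean), tolerance = 1e-8)

  fB <- stmobility:::fc_B(design, pre, state, hyper)
  expect_equal(unname(fB$P), unname(oracle$B$P), tolerance = 1e-8)
  expect_equal(unname(drop(solve(fB$P, fB$b))), unname(oracle$B$mean),
               tolerance = 1e-8)

  fC <- stmobility:::fc_C(design, pre, state, hyper)
  expect_equal(unname(fC$P), unname(diag(oracle$C$P)), tolerance = 1e-8)
  expect_equal(unname(fC$b / fC$P), unname(oracle$C$mean), tolerance = 1e-8)

  # kriging constraint matches the closed-form constrained mean
  U <- chol(fu$P)
  m <- drop(solve(fu$P, fu$b))
  mc <- stmobility:::constrain_kriging(m, U, pre$Acon)
  V <- solve(fu$P)
  A <- pre$Acon
  mc_oracle <- m - drop(V %*% t(A) %*% solve(A %*% V %*% t(A), A %*% m))
  expect_equal(unname(mc), unname(mc_oracle), tolerance = 1e-10)
  expect_equal(max(abs(rowsum(mc, design$spatial$component))), 0,
               tolerance = 1e-10)
})

test_that("posterior mean of beta matches the conjugate GLS closed form", {
  design <- toy_design()
  set.seed(88)
  g <- kenya_graph()
  tr <- synthetic_truth(g, seed = 12)
  sim <- simulate_outcomes(tr, seed = 13)
  big <- stmobility:::model_design(sim$y, tr$X, tr$region, tr$time,
                                   tr$spatial, tr$n_time)
  spec <- model_spec(n_iter = 20000, n_burn = 500, seed = 2,
                     spatial = FALSE, temporal = FALSE,
                     interaction_on = FALSE, fixed = list(tau_eps = 4))
  fit <- sample_posterior(big, spec)
  P <- 4 * crossprod(big$X) + diag(1 / 100, ncol(big$X))
  b_exact <- drop(solve(P, 4 * crossprod(big$X, big$y)))
  draws <- fit$chains[[1]]$beta
  diff <- colMeans(draws) - b_exact
  # draws are iid here, so the Monte-Carlo standard error is sd/sqrt(n)
  z <- abs(diff) / (apply(draws, 2, sd) / sqrt(nrow(draws)))
  expect_lt(max(z), 4)
  # coefficients with small posterior sd agree to 3 decimals
  tight <- apply(draws, 2, sd) < 0.05
  expect_true(any(tight))
  expect_lt(max(abs(diff[tight])), 5e-4)

  # intercept-only model recovers the sample mean
  y0 <- sim$y
  d0 <- stmobility:::model_design(y0, matrix(1, length(y0), 1,
                                             dimnames = list(NULL, "intercept")),
                                  tr$region, tr$time, tr$spatial, tr$n_time)
  fit0 <- sample_posterior(d0, model_spec(n_iter = 5000, n_burn = 200,
                                          seed = 3, spatial = FALSE,
                                          temporal = FALSE,
                                          interaction_on = FALSE,
                                          fixed = list(tau_eps = 1)))
  expect_equal(mean(fit0$chains[[1]]$beta), mean(y0), tolerance = 0.01)
})

test_that("chains are a deterministic function of the seed", {
  design <- toy_design()
  spec <- model_spec(n_iter = 200, n_burn = 100, seed = 77)
  f1 <- sample_posterior(design, spec)
  f2 <- sample_posterior(design, spec)
  expect_identical(f1$chains[[1]]$beta, f2$chains[[1]]$beta)
  expect_identical(f1$chains[[1]]$hyper, f2$chains[[1]]$hyper)
  f3 <- sample_posterior(design, model_spec(n_iter = 200, n_burn = 100,
                                            seed = 78))
  expect_false(identical(f1$chains[[1]]$beta, f3$chains[[1]]$beta))
})

test_that("posterior summaries report quantiles, significance and rhat", {
  design <- toy_design()
  fit <- sample_posterior(design, model_spec(n_iter = 1500, n_burn = 300,
                                             seed = 9, n_chains = 2))
  s <- summarize_posterior(fit)
  expect_true(all(s$fixed$lower <= s$fixed$mean &
                    s$fixed$mean <= s$fixed$upper))
  # quantiles match a sort-based oracle
  beta <- stmobility:::pooled_draws(fit, "beta")
  x <- sort(beta[, 1])
  expect_equal(s$fixed$lower[1],
               unname(quantile(x, 0.025, type = 7)), tolerance = 1e-12)

  # constant chain: degenerate summaries; symmetric chain: non-significant
  fake <- fit
  fake$chains <- lapply(fake$chains, function(ch) {
    ch$beta[, 1] <- 3.5
    ch$beta[, 2] <- c(-abs(ch$beta[, 2][1:750]), abs(ch$beta[, 2][1:750]))
    ch
  })
  s2 <- summarize_posterior(fake)
  expect_equal(s2$fixed$mean[1], 3.5)
  expect_equal(s2$fixed$lower[1], 3.5)
  expect_equal(s2$fixed$upper[1], 3.5)
  expect_true(s2$fixed$significant[1])
  expect_false(s2$fixed$significant[2])

  empty <- fit
  empty$chains <- lapply(empty$chains, function(ch) {
    ch$beta <- ch$beta[0, , drop = FALSE]; ch
  })
  expect_error(summarize_posterior(empty), "empty chains")
})

test_that("DIC follows Spiegelhalter's construction", {
  design <- toy_design()
  fit <- sample_posterior(design, model_spec(n_iter = 2000, n_burn = 500,
                                             seed = 10))
  dic <- compute_dic(fit)
  # independent recomputation from the stored draws
  dev <- fit$chains[[1]]$deviance
  eta_mean <- fit$chains[[1]]$eta_mean
  tau_mean <- mean(fit$chains[[1]]$hyper[, "tau_eps"])
  dhat <- -2 * sum(dnorm(design$y, eta_mean, sqrt(1 / tau_mean), log = TRUE))
  pd_oracle <- mean(dev) - dhat
  expect_equal(dic$pd, pd_oracle, tolerance = 1e-10)
  expect_equal(dic$dic, dhat + 2 * pd_oracle, tolerance = 1e-10)
  # algebraic identity DIC = mean(D) + pD
  expect_equal(dic$dic, mean(dev) + dic$pd, tolerance = 1e-10)

  # well-behaved fit: pD near the number of free fixed effects
  g <- kenya_graph()
  tr <- synthetic_truth(g, seed = 17)
  sim <- simulate_outcomes(tr, seed = 18)
  dd <- stmobility:::model_design(sim$y, tr$X, tr$region, tr$time,
                                  tr$spatial, tr$n_time)
  fitb <- sample_posterior(dd, model_spec(n_iter = 3000, n_burn = 500,
                                          seed = 19, spatial = FALSE,
                                          temporal = FALSE,
                                          interaction_on = FALSE,
                                          fixed = list(tau_eps = 3.8)))
  pdb <- compute_dic(fitb)$pd
  expect_gt(pdb, 4)
  expect_lt(pdb, 12)

  # degenerate chain: every draw identical -> pD = 0, DIC = that deviance
  degen <- fit
  degen$chains <- lapply(degen$chains, function(ch) {
    ch$hyper[, "tau_eps"] <- 2
    ch$deviance <- rep(-2 * sum(dnorm(design$y, ch$eta_mean, sqrt(0.5),
                                      log = TRUE)), length(ch$deviance))
    ch
  })
  ddic <- compute_dic(degen)
  expect_equal(ddic$pd, 0, tolerance = 1e-8)
  expect_equal(ddic$dic, degen$chains[[1]]$deviance[1], tolerance = 1e-8)
})

test_that("fitted values sit on the ratio scale and track strong signal", {
  # null model on y = 0: fitted ratios = 1
  design <- toy_design()
  d0 <- stmobility:::model_design(rep(0, 12), design$X[, 1, drop = FALSE],
                                  design$region, design$time,
                                  design$spatial, design$n_time)
  fit0 <- sample_posterior(d0, model_spec(n_iter = 2000, n_burn = 200,
                                          seed = 4, spatial = FALSE,
                                          temporal = FALSE,
                                          interaction_on = FALSE))
  expect_equal(predict_fitted(fit0)$fitted, rep(1, 12), tolerance = 0.01)

  # high signal-to-noise synthetic panel: correlation(fitted, truth) > 0.95
  g <- kenya_graph()
  tr <- synthetic_truth(g, tau_eps = 100, tau_C = 100, seed = 6)
  sim <- simulate_outcomes(tr, seed = 8)
  dd <- stmobility:::model_design(sim$y, tr$X, tr$region, tr$time,
                                  tr$spatial, tr$n_time)
  fit <- sample_posterior(dd, model_spec(n_iter = 2000, n_burn = 500,
                                         seed = 8))
  expect_gt(cor(predict_fitted(fit)$fitted, exp(sim$eta)), 0.95)
})
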