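#' Validation metrics for fitted change ratios
#'
#' MAE, RMSE and a pseudo-R-squared between observed and fitted values.
#' Scoring is on the ratio scale by default (set \code{scale = "log"} to
#' score log ratios). Pseudo-R-squared is the squared Pearson correlation
#' between observed and fitted by default; \code{r2_method = "ss"} selects
#' 1 - SSE/SST instead.
#'
#' @param observed,fitted numeric vectors of equal length >= 2
#' @param scale \code{"ratio"} (default) or \code{"log"}
#' @param r2_method \code{"cor"} (default) or \code{"ss"}
#' @return object of class \code{validation_report}: list with \code{mae},
#'   \code{rmse}, \code{pseudo_r2} (NA if either vector is constant),
#'   \code{n}, \code{scale}, \code{r2_method}
#' @export
score_fit <- function(observed, fitted, scale = c("ratio", "log"),
                      r2_method = c("cor", "ss")) {
  scale <- match.arg(scale)
  r2_method <- match.arg(r2_method)
  if (length(observed) != length(fitted)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least two observations")
  if (any(!is.finite(observed)) || any(!is.finite(fitted))) {
    stop("non-finite values")
  }
  if (scale == "log") {
    observed <- log(observed)
    fitted <- log(fitted)
  }
  e <- observed - fitted
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  pseudo_r2 <- if (stats::sd(observed) == 0 || stats::sd(fitted) == 0) {
    warning("constant observed or fitted vector: pseudo-R2 undefined")
    NA_real_
  } else if (r2_method == "cor") {
    stats::cor(observed, fitted)^2
  } else {
    1 - sum(e^2) / sum((observed - mean(observed))^2)
  }
  structure(list(mae = mae, rmse = rmse, pseudo_r2 = pseudo_r2,
                 n = length(observed), scale = scale,
                 r2_method = r2_method),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat("Validation (", x$scale, " scale, n = ", x$n, "): MAE ",
      round(x$mae, digits), " | RMSE ", round(x$rmse, digits),
      " | pseudo-R2 ", round(x$pseudo_r2, digits), "\n", sep = "")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates log change-ratio panels from the model equation at known
#' parameter values, refits each with the MCMC sampler, and scores fixed-
#' effect recovery: empirical bias, 95\% credible-interval coverage, and
#' sign agreement for strongly identified effects (posterior
#' |truth| / sd > 2). Random effects are re-drawn for every replicate from
#' the truth's hyperparameters. Replicates whose chains fail the split-Rhat
#' convergence screen (> 1.05 on any fixed effect) are excluded and counted.
#'
#' @param truth a \code{\link{synthetic_truth}} (carries beta,
#'   hyperparameters, graph, covariates and panel length)
#' @param n_replicates number of simulated panels
#' @param seed integer master seed; replicate k uses seed + k
#' @param spec \code{\link{model_spec}} used for every fit (its seed is
#'   overridden per replicate)
#' @return object of class \code{recovery_report}: list with \code{table}
#'   (per fixed effect: truth, mean posterior mean, bias, coverage, sign
#'   agreement among strong replicates), \code{replicates} (long per
#'   replicate x parameter data frame), \code{n_excluded} and
#'   \code{manifest} (seeds and sampler settings)
#' @export
recovery_experiment <- function(truth, n_replicates = 20L, seed = 1L,
                                spec = model_spec()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- list()
  n_excluded <- 0L
  seeds <- seed + seq_len(n_replicates)
  for (k in seq_len(n_replicates)) {
    sim <- simulate_outcomes(truth, seed = seeds[k], new_effects = TRUE)
    design <- model_design(y = sim$y, X = truth$X, region = truth$region,
                           time = truth$time, spatial = truth$spatial,
                           n_time = truth$n_time)
    spec_k <- spec
    spec_k$seed <- seeds[k]
    fit <- sample_posterior(design, spec_k)
    beta <- pooled_draws(fit, "beta")
    rh <- vapply(seq_len(ncol(beta)), function(j) {
      split_rhat(lapply(fit$chains, function(ch) ch$beta[, j]))
    }, numeric(1))
    if (any(rh > 1.05, na.rm = TRUE)) {
      n_excluded <- n_excluded + 1L
      next
    }
    qs <- apply(beta, 2, stats::quantile, c(0.025, 0.975))
    pm <- colMeans(beta)
    psd <- apply(beta, 2, stats::sd)
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = k, parameter = colnames(beta), truth = unname(truth$beta),
      post_mean = unname(pm), post_sd = unname(psd),
      lower = qs[1, ], upper = qs[2, ],
      covered = truth$beta >= qs[1, ] & truth$beta <= qs[2, ],
      strong = abs(truth$beta) / psd > 2,
      sign_match = sign(pm) == sign(truth$beta),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no replicate converged")
  reps <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(reps, reps$parameter), function(d) {
    data.frame(parameter = d$parameter[1], truth = d$truth[1],
               mean_post_mean = mean(d$post_mean),
               bias = mean(d$post_mean - d$truth),
               coverage = mean(d$covered),
               n_strong = sum(d$strong),
               sign_match_strong = if (any(d$strong)) {
                 mean(d$sign_match[d$strong])
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[match(colnames(truth$X), tab$parameter), ]
  rownames(tab) <- NULL
  structure(
    list(table = tab, replicates = reps, n_excluded = n_excluded,
         manifest = list(master_seed = seed, replicate_seeds = seeds,
                         n_iter = spec$n_iter, n_burn = spec$n_burn,
                         n_chains = spec$n_chains)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat("Parameter recovery over",
      length(unique(x$replicates$replicate)), "converged replicate(s)",
      sprintf("(%d excluded):\n", x$n_excluded))
  print(cbind(x$table[1], round(x$table[2:5], digits), x$table[6:7]),
        row.names = FALSE)
  invisible(x)
}
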