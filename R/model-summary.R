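# Posterior summaries, DIC and fitted values

pooled_draws <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, `[[`, what))
}

# split-chain potential scale reduction factor for one parameter
split_rhat <- function(chains_list) {
  halves <- unlist(lapply(chains_list, function(x) {
    n <- length(x) %/% 2L
    if (n < 2L) return(NULL)
    list(x[1:n], x[(n + 1L):(2L * n)])
  }), recursive = FALSE)
  if (length(halves) < 2L) return(NA_real_)
  n <- length(halves[[1]])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize a spatiotemporal model fit
#'
#' Pools post-burn-in draws across chains and reports, per fixed effect, the
#' posterior mean with equal-tailed 95\% credible interval and a significance
#' flag (interval excludes zero); per hyperparameter, the posterior mean, sd
#' and credible interval; plus DIC, the effective number of parameters pD,
#' split-chain potential scale reduction factors and Metropolis acceptance
#' rates.
#'
#' @param fit a \code{stmob_fit}
#' @param prob credible interval probability, default 0.95
#' @return object of class \code{stmob_summary} with elements \code{fixed},
#'   \code{hyper}, \code{dic}, \code{pd}, \code{rhat}, \code{acceptance},
#'   \code{n_draws}
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "stmob_fit"))
  beta <- pooled_draws(fit, "beta")
  hyper <- pooled_draws(fit, "hyper")
  if (is.null(beta) || nrow(beta) == 0L) stop("empty chains")
  if (nrow(beta) < 1000L) {
    warning("only ", nrow(beta),
            " post-burn-in draws pooled; summaries may be unstable")
  }
  a <- (1 - prob) / 2
  qs <- function(x) stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  fq <- t(apply(beta, 2, qs))
  fixed <- data.frame(
    parameter = colnames(beta),
    mean = colMeans(beta), lower = fq[, 1], upper = fq[, 2],
    significant = sign(fq[, 1]) == sign(fq[, 2]) & fq[, 1] != 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  hq <- t(apply(hyper, 2, qs))
  hyp <- data.frame(
    parameter = colnames(hyper),
    mean = colMeans(hyper), sd = apply(hyper, 2, stats::sd),
    lower = hq[, 1], upper = hq[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  dic <- compute_dic(fit)
  rhat <- c(
    vapply(seq_len(ncol(beta)), function(j) {
      split_rhat(lapply(fit$chains, function(ch) ch$beta[, j]))
    }, numeric(1)),
    vapply(seq_len(ncol(hyper)), function(j) {
      split_rhat(lapply(fit$chains, function(ch) ch$hyper[, j]))
    }, numeric(1))
  )
  names(rhat) <- c(colnames(beta), colnames(hyper))
  structure(
    list(fixed = fixed, hyper = hyp, dic = dic$dic, pd = dic$pd,
         rhat = rhat,
         acceptance = fit$chains[[1]]$acceptance,
         n_draws = nrow(beta)),
    class = "stmob_summary"
  )
}

#' @export
print.stmob_summary <- function(x, digits = 3, ...) {
  cat("Fixed effects (posterior mean, 95% CI):\n")
  print(cbind(x$fixed[1], round(x$fixed[2:4], digits),
              x$fixed[5]), row.names = FALSE)
  cat("\nHyperparameters:\n")
  print(cbind(x$hyper[1], signif(x$hyper[2:5], digits)), row.names = FALSE)
  cat("\nDIC ", round(x$dic, 2), " | pD ", round(x$pd, 2),
      " | pooled draws ", x$n_draws, "\n", sep = "")
  if (length(x$rhat)) {
    cat("max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}

#' Deviance information criterion of a fit
#'
#' Uses the per-draw deviance D = -2 log L under the Gaussian likelihood:
#' pD = mean(D) - D(posterior mean of parameters) and
#' DIC = D(posterior mean) + 2 pD = mean(D) + pD, with the posterior mean
#' plugged in through the mean linear predictor and mean noise precision.
#'
#' @param fit a \code{stmob_fit}
#' @return list with \code{dic}, \code{pd}, \code{dbar} (mean posterior
#'   deviance) and \code{dhat} (deviance at the posterior mean)
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "stmob_fit"))
  dev <- unlist(lapply(fit$chains, `[[`, "deviance"))
  if (!length(dev)) stop("empty chains")
  if (any(!is.finite(dev))) stop("non-finite deviance draws")
  eta_mean <- Reduce(`+`, lapply(fit$chains, `[[`, "eta_mean")) /
    length(fit$chains)
  tau_mean <- mean(pooled_draws(fit, "hyper")[, "tau_eps"])
  dhat <- -2 * gauss_loglik(fit$design$y, eta_mean, tau_mean)
  dbar <- mean(dev)
  pd <- dbar - dhat
  list(dic = dhat + 2 * pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Fitted change ratios from a model fit
#'
#' Posterior-mean fitted values on the ratio scale:
#' exp(mean of beta0 + A_i + B_t + C_it + X'_it beta), alongside the observed
#' ratios, per (region, time) row of the design.
#'
#' @param fit a \code{stmob_fit}
#' @return data frame with the design's row labels (if available), plus
#'   \code{observed} and \code{fitted} ratios
#' @export
predict_fitted <- function(fit) {
  stopifnot(inherits(fit, "stmob_fit"))
  eta_mean <- Reduce(`+`, lapply(fit$chains, `[[`, "eta_mean")) /
    length(fit$chains)
  out <- data.frame(observed = exp(fit$design$y), fitted = exp(eta_mean))
  if (!is.null(fit$design$meta)) out <- cbind(fit$design$meta, out)
  rownames(out) <- NULL
  out
}
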