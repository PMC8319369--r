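# Design construction for the spatiotemporal change-ratio regression
#
# The model is
#   log(y_it) = beta0 + A_i + B_t + C_it + X'_it beta + eps_it
# with A a BYM2 spatial effect on the county graph, B a stationary AR1 over
# the monthly index, C an iid space-time interaction and eps Gaussian noise.

# model-facing covariate name -> (table, column) mapping
.covariate_map <- list(
  accessibility = c("static", "accessibility_minutes"),
  education     = c("static", "no_primary_education_share"),
  poverty       = c("static", "poverty_share"),
  urbanicity    = c("static", "urban_share"),
  school_holidays = c("dynamic", "school_holidays_days"),
  temperature   = c("dynamic", "temperature_C"),
  aridity       = c("dynamic", "aridity"),
  precipitation = c("dynamic", "precipitation_mm"),
  evi           = c("dynamic", "evi"),
  ntl           = c("dynamic", "ntl")
)

# fixed column order mirroring the reporting layout
.covariate_order <- c("accessibility", "education", "school_holidays", "ntl",
                      "poverty", "temperature", "urbanicity",
                      "aridity", "precipitation", "evi")

#' Low-level model design constructor
#'
#' Assembles a design object from already-built parts. Most users should call
#' \code{\link{build_design}}; this constructor is the entry point for
#' simulation studies where the response is generated directly from the
#' model.
#'
#' @param y numeric response (log change ratios)
#' @param X fixed-effect matrix including the intercept column
#' @param region integer region index (1..n_region) per row
#' @param time integer time index (1..n_time) per row
#' @param spatial a \code{\link{spatial_structure}}
#' @param n_time number of time points (defaults to \code{max(time)})
#' @param meta optional data frame of row labels (region_id, year, month)
#' @return object of class \code{mobility_design}
#' @export
model_design <- function(y, X, region, time, spatial, n_time = max(time),
                         meta = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(region) == n, length(time) == n,
            inherits(spatial, "spatial_structure"))
  if (any(!is.finite(y))) stop("non-finite response values")
  n_region <- length(spatial$region_ids)
  if (max(region) > n_region || min(region) < 1L) stop("region index out of bounds")
  if (min(time) < 1L) stop("time index out of bounds")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect matrix is rank deficient; linearly dependent column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(
    list(y = y, X = X, region = as.integer(region), time = as.integer(time),
         spatial = spatial, n_region = n_region, n_time = as.integer(n_time),
         meta = meta),
    class = "mobility_design"
  )
}

#' Build the model design from change ratios and covariates
#'
#' Takes the mobility change series and the county covariate table, applies
#' the log transformation to the ratios, expands static covariates over
#' months, and assembles the fixed-effect matrix in the canonical reporting
#' order (intercept, accessibility, education, school holidays, night-time
#' lights, poverty, temperature, urbanicity).
#'
#' @param changes a \code{mobility_change} data frame from
#'   \code{\link{compute_change_ratios}} (columns \code{region_id},
#'   \code{year}, \code{month}, \code{ratio})
#' @param covariates covariate table: list with \code{static} (one row per
#'   region) and \code{dynamic} (one row per region-month) data frames, as
#'   produced by \code{\link{simulate_covariates}}
#' @param graph a \code{region_graph}; region order fixes the spatial index
#' @param retained model-facing covariate names to include, typically the
#'   output of the collinearity screen
#' @param include_january keep baseline-month rows (ratio 1, log ratio 0) in
#'   the fit; default TRUE (a complete 2-year panel then has 1128 rows)
#' @param baseline_month the baseline month (rows dropped when
#'   \code{include_january = FALSE}); default 1
#' @param standardize z-score the covariate columns; default FALSE (fits on
#'   the natural scale)
#' @return a \code{mobility_design}
#' @export
build_design <- function(changes, covariates, graph,
                         retained = c("accessibility", "education",
                                      "school_holidays", "ntl", "poverty",
                                      "temperature", "urbanicity"),
                         include_january = TRUE, baseline_month = 1L,
                         standardize = FALSE) {
  stopifnot(all(c("region_id", "year", "month", "ratio") %in% names(changes)))
  ch <- as.data.frame(changes)
  if (!include_january) ch <- ch[ch$month != baseline_month, , drop = FALSE]
  bad <- ch$ratio <= 0 | !is.finite(ch$ratio)
  if (any(bad)) {
    off <- ch[bad, c("region_id", "year", "month")]
    stop("non-positive change ratio(s) at: ",
         paste(paste(off$region_id, off$year, off$month, sep = "-"),
               collapse = ", "))
  }
  unknown <- setdiff(ch$region_id, graph$region_ids)
  if (length(unknown)) stop("region(s) not in graph: ",
                            paste(unknown, collapse = ", "))
  ch <- ch[order(ch$region_id, ch$year, ch$month), , drop = FALSE]
  time_table <- unique(ch[order(ch$year, ch$month), c("year", "month")])
  time_table$t <- seq_len(nrow(time_table))
  tt_key <- paste(time_table$year, time_table$month)
  retained <- match.arg(retained, names(.covariate_map), several.ok = TRUE)
  Xcols <- lapply(retained, function(v) {
    loc <- .covariate_map[[v]]
    tab <- covariates[[loc[1]]]
    if (is.null(tab) || !loc[2] %in% names(tab)) {
      stop("covariate table lacks ", loc[2], " (needed for '", v, "')")
    }
    if (loc[1] == "static") {
      val <- tab[[loc[2]]][match(ch$region_id, tab$region_id)]
    } else {
      val <- tab[[loc[2]]][match(paste(ch$region_id, ch$year, ch$month),
                                 paste(tab$region_id, tab$year, tab$month))]
    }
    if (anyNA(val)) stop("missing covariate values for '", v, "'")
    val
  })
  X <- do.call(cbind, c(list(intercept = rep(1, nrow(ch))), Xcols))
  colnames(X) <- c("intercept", retained)
  ord <- c("intercept", intersect(.covariate_order, retained))
  X <- X[, ord, drop = FALSE]
  if (standardize && ncol(X) > 1L) {
    X[, -1] <- scale(X[, -1, drop = FALSE])
  }
  model_design(
    y = log(ch$ratio), X = X,
    region = match(ch$region_id, graph$region_ids),
    time = match(paste(ch$year, ch$month), tt_key),
    spatial = spatial_structure(graph),
    n_time = nrow(time_table),
    meta = ch[, c("region_id", "year", "month")]
  )
}

#' @export
print.mobility_design <- function(x, ...) {
  cat("Spatiotemporal model design:", length(x$y), "rows,",
      x$n_region, "regions,", x$n_time, "time points,",
      ncol(x$X) - 1L, "covariates\n")
  invisible(x)
}

#' Sampler settings and priors for the spatiotemporal model
#'
#' @param n_iter post-burn-in iterations per chain
#' @param n_burn burn-in iterations (step sizes adapt here, then freeze)
#' @param n_chains number of chains (run sequentially from one seed)
#' @param seed RNG seed; identical seeds give bit-identical chains
#' @param priors list: \code{beta_sd} (Gaussian sd of fixed effects, 10),
#'   \code{pc_u}, \code{pc_alpha} (PC prior on every random-effect and noise
#'   sd: P(sd > pc_u) = pc_alpha, defaults 1 and 0.01), \code{phi_shape2}
#'   (Beta(1, .) prior on the BYM2 mixing, default gives P(phi<0.5)=2/3),
#'   \code{rho_sd} (Normal sd on atanh(rho), 1)
#' @param interaction space-time interaction type; \code{"type1"} (iid) is
#'   the implemented structure
#' @param spatial,temporal,interaction_on logical switches for the three
#'   random-effect blocks (all TRUE for the full model)
#' @param fixed named list of hyperparameters to hold fixed instead of
#'   sampling, e.g. \code{list(tau_eps = 4)}
#' @param sum_to_zero_B impose a sum-to-zero constraint on the temporal
#'   effect (off by default; the AR1 prior is proper)
#' @param verbose log progress and acceptance rates every 100 iterations
#' @return object of class \code{model_spec}
#' @export
model_spec <- function(n_iter = 5000L, n_burn = 1000L, n_chains = 1L,
                       seed = 1L, priors = list(), interaction = "type1",
                       spatial = TRUE, temporal = TRUE, interaction_on = TRUE,
                       fixed = list(), sum_to_zero_B = FALSE,
                       verbose = FALSE) {
  if (!identical(interaction, "type1")) {
    stop("only the type1 (iid) space-time interaction is implemented")
  }
  defaults <- list(beta_sd = 10, pc_u = 1, pc_alpha = 0.01,
                   phi_shape2 = log(3) / log(2), rho_sd = 1)
  priors <- utils::modifyList(defaults, priors)
  if (n_iter < 1L || n_burn < 0L) stop("invalid iteration counts")
  structure(
    list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
         n_chains = as.integer(n_chains), seed = as.integer(seed),
         priors = priors, interaction = interaction,
         use_spatial = isTRUE(spatial), use_temporal = isTRUE(temporal),
         use_interaction = isTRUE(interaction_on),
         fixed = fixed, sum_to_zero_B = isTRUE(sum_to_zero_B),
         verbose = isTRUE(verbose)),
    class = "model_spec"
  )
}
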