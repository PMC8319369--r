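# Synthetic-data generator emulating the structure of an aggregated,
# differentially-private mobility release: 47 counties over 24 months, three
# trip classes, weekly flows passed through Laplace noise and small-count
# suppression, covariates within realistic ranges with the climate variables
# strongly tied to temperature, and log-ratio outcomes generated from the
# spatiotemporal model equation at known parameters.

# national school-holiday calendar (days per month, identical both years):
# term breaks in April, August and November-December
.school_holiday_calendar <- c(2, 0, 0, 21, 0, 0, 0, 31, 0, 0, 14, 31)

#' Simulate the county covariate table
#'
#' Static covariates (urban share, poverty, female no-primary-education
#' share, accessibility) are drawn within the observed ranges of the real
#' covariate sources. Monthly temperature follows a county-specific seasonal
#' sinusoid; aridity, precipitation and EVI are affine functions of
#' temperature plus noise (so the collinearity screen has real structure to
#' find); night-time lights track urbanicity; school holidays follow a fixed
#' national monthly calendar independent of temperature.
#'
#' @param graph a \code{region_graph}
#' @param n_time number of months, default 24 (two years from
#'   \code{start_year})
#' @param seed integer seed
#' @param start_year first calendar year, default 2018
#' @param climate_noise relative noise of the climate-covariate links;
#'   default 1 keeps |cor(temperature, aridity)| well above 0.7
#' @return list with \code{static} (one row per county) and \code{dynamic}
#'   (one row per county-month) data frames
#' @export
simulate_covariates <- function(graph, n_time = 24L, seed = 1L,
                                start_year = 2018L, climate_noise = 1) {
  set.seed(as.integer(seed))
  ids <- graph$region_ids
  n <- length(ids)
  static <- data.frame(
    region_id = ids,
    urban_share = pmin(pmax(stats::rbeta(n, 1.5, 5) * 0.946 + 0.001,
                            0.001), 0.947),
    poverty_share = stats::rbeta(n, 2, 2) * 0.818 + 0.099,
    no_primary_education_share = stats::runif(n, 0.032, 0.17),
    accessibility_minutes = stats::rbeta(n, 1.5, 3) * 376.29 + 4.37,
    stringsAsFactors = FALSE
  )
  months <- data.frame(
    year = start_year + (seq_len(n_time) - 1L) %/% 12L,
    month = (seq_len(n_time) - 1L) %% 12L + 1L
  )
  temp_mean <- stats::runif(n, 18, 25.5)
  temp_amp <- stats::runif(n, 1.5, 3)
  temp_phase <- stats::runif(n, 0, 2 * pi)
  grid <- expand.grid(t = seq_len(n_time), i = seq_len(n))[, 2:1]
  tempC <- temp_mean[grid$i] +
    temp_amp[grid$i] * cos(2 * pi * (months$month[grid$t] - 1) / 12 -
                             temp_phase[grid$i]) +
    stats::rnorm(nrow(grid), 0, 0.3)
  tempC <- pmin(pmax(tempC, 14.7), 28.8)
  affine <- function(lo, hi, noise_sd) {
    val <- hi - (tempC - 14.7) * (hi - lo) / (28.8 - 14.7) +
      stats::rnorm(nrow(grid), 0, noise_sd * climate_noise)
    pmin(pmax(val, lo), hi)
  }
  # night-time lights track urbanicity only loosely (r ~ 0.4), so the
  # collinearity screen keeps both, as in the real covariate set
  ntl_base <- 0.246 + 15 * (0.45 * static$urban_share +
                              0.55 * stats::runif(n))
  dynamic <- data.frame(
    region_id = ids[grid$i],
    year = months$year[grid$t],
    month = months$month[grid$t],
    school_holidays_days =
      .school_holiday_calendar[months$month[grid$t]],
    temperature_C = tempC,
    aridity = affine(96.65, 223.1, 8),
    precipitation_mm = affine(1.70, 266.9, 17),
    evi = affine(1325, 4914, 230),
    ntl = pmin(pmax(ntl_base[grid$i] * exp(stats::rnorm(nrow(grid), 0, 0.05)),
                    0.246), 15.27),
    stringsAsFactors = FALSE
  )
  list(static = static, dynamic = dynamic)
}

#' Generating truth for the synthetic mobility world
#'
#' Bundles everything needed to simulate log change-ratio panels from the
#' model equation: true fixed effects and hyperparameters (defaulting to the
#' magnitudes reported for the Kenya analysis), the county graph and its
#' spatial structure, the covariate table and the assembled fixed-effect
#' matrix, plus realized random-effect vectors drawn at the truth seed.
#'
#' @param graph a \code{region_graph}; default the bundled Kenya fixture
#' @param covariates covariate table; simulated at \code{seed} when NULL
#' @param n_time panel length in months, default 24
#' @param beta named true fixed effects (intercept first)
#' @param tau_eps,tau_A,phi,tau_B,rho,tau_C true hyperparameters
#' @param seed integer seed for covariates and realized effects
#' @return object of class \code{synthetic_truth}
#' @export
synthetic_truth <- function(graph = kenya_graph(), covariates = NULL,
                            n_time = 24L,
                            beta = c(intercept = 1.037,
                                     accessibility = 0.002,
                                     education = 5.337,
                                     school_holidays = 0.007,
                                     ntl = 0.04, poverty = -1.098,
                                     temperature = -0.052,
                                     urbanicity = -0.236),
                            tau_eps = 3.838, tau_A = 12.875, phi = 0.209,
                            tau_B = 18791.48, rho = -0.229, tau_C = 10,
                            seed = 2018L) {
  if (is.null(covariates)) {
    covariates <- simulate_covariates(graph, n_time, seed = seed)
  }
  stopifnot(tau_eps > 0, tau_A > 0, tau_B > 0, tau_C > 0,
            phi >= 0, phi <= 1, abs(rho) < 1)
  retained <- setdiff(names(beta), "intercept")
  # unit-ratio dummy panel to assemble X in canonical order
  dyn <- covariates$dynamic
  dummy <- data.frame(region_id = dyn$region_id, year = dyn$year,
                      month = dyn$month, ratio = 1)
  design <- build_design(dummy, covariates, graph, retained = retained)
  stopifnot(identical(colnames(design$X),
                      c("intercept", intersect(.covariate_order, retained))))
  beta <- beta[colnames(design$X)]
  set.seed(as.integer(seed))
  effects <- list(
    u_star = drop(ricar_scaled(1, design$spatial)),
    v = stats::rnorm(design$n_region),
    B = drop(rar1(1, n_time, tau_B, rho)),
    C = stats::rnorm(length(design$y), 0, sqrt(1 / tau_C))
  )
  structure(
    list(beta = beta, tau_eps = tau_eps, tau_A = tau_A, phi = phi,
         tau_B = tau_B, rho = rho, tau_C = tau_C,
         graph = graph, covariates = covariates, spatial = design$spatial,
         X = design$X, region = design$region, time = design$time,
         meta = design$meta, n_time = as.integer(n_time),
         effects = effects, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Simulate log change-ratio outcomes from the model equation
#'
#' Draws (or reuses) the random effects and forms
#' y = X beta + A_i + B_t + C_it + eps_it on the log-ratio scale over the
#' full county x month grid of the truth.
#'
#' @param truth a \code{\link{synthetic_truth}}
#' @param seed seed for this realization
#' @param new_effects draw fresh random effects from the truth
#'   hyperparameters (TRUE, e.g. for recovery replicates) or reuse the
#'   truth's realized vectors (FALSE)
#' @param zero_noise set the Gaussian observation noise to zero (useful for
#'   degenerate-limit checks)
#' @return list with \code{y}, \code{eta} (identical unless noise is
#'   suppressed separately), \code{effects}, and index vectors
#' @export
simulate_outcomes <- function(truth, seed = truth$seed, new_effects = TRUE,
                              zero_noise = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(as.integer(seed))
  eff <- if (new_effects) {
    list(u_star = drop(ricar_scaled(1, truth$spatial)),
         v = stats::rnorm(length(truth$spatial$region_ids)),
         B = drop(rar1(1, truth$n_time, truth$tau_B, truth$rho)),
         C = stats::rnorm(nrow(truth$X), 0, sqrt(1 / truth$tau_C)))
  } else truth$effects
  A <- (sqrt(truth$phi) * eff$u_star + sqrt(1 - truth$phi) * eff$v) /
    sqrt(truth$tau_A)
  eta <- drop(truth$X %*% truth$beta) + A[truth$region] +
    eff$B[truth$time] + eff$C
  eps <- if (zero_noise) 0 else
    stats::rnorm(length(eta), 0, sqrt(1 / truth$tau_eps))
  list(y = eta + eps, eta = eta, effects = c(eff, list(A = A)),
       region = truth$region, time = truth$time)
}

# integer apportionment of `total` across `weights`, conserving the total
largest_remainder <- function(total, weights) {
  if (total <= 0 || sum(weights) <= 0) return(numeric(length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- round(total - sum(base))
  if (short > 0) {
    top <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  base
}

#' Simulate a raw weekly origin-destination flow panel
#'
#' Runs the model equation generatively and turns it into flow records:
#' each county's January outward flow is set to a county-level base, monthly
#' outward totals follow the generated change ratios (January ratio is 1 by
#' construction, so the metrics stage recovers the generated ratios exactly),
#' totals are split into within-county, domestic and international records
#' (gravity-style destination allocation over synthetic coordinates; a fixed
#' 10-country international list weighted toward East Africa), and months are
#' disaggregated into calendar weeks by largest-remainder apportionment
#' proportional to week length.
#'
#' @param truth a \code{\link{synthetic_truth}}
#' @param seed seed for base flows, coordinates and allocation
#' @param base_flow median January outward flow per county (users)
#' @param class_shares named shares of \code{within}, \code{domestic},
#'   \code{international} travel, summing to 1; the default keeps
#'   within-county travel dominant
#' @param n_domestic_dest number of gravity-ranked domestic destinations per
#'   origin
#' @param calendar week calendar, default \code{make_week_calendar} over the
#'   truth's years
#' @param integer_counts round record counts to whole users via
#'   largest-remainder apportionment (default TRUE); FALSE keeps real-valued
#'   counts so generative identities hold to machine precision
#' @param use_truth_effects reuse the truth's realized random effects
#'   (default TRUE; FALSE redraws)
#' @return list with \code{weekly} (raw weekly records), \code{monthly_raw}
#'   (realized monthly records), \code{truth_changes} (change series implied
#'   by the realized flows), \code{intended} (model-equation ratios before
#'   integer rounding) and \code{truth}
#' @export
simulate_panel <- function(truth, seed = truth$seed, base_flow = 5e5,
                           class_shares = c(within = 0.65, domestic = 0.25,
                                            international = 0.10),
                           n_domestic_dest = 12L,
                           calendar = NULL,
                           integer_counts = TRUE,
                           use_truth_effects = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(base_flow <= 0)) stop("base_flow must be positive")
  stopifnot(abs(sum(class_shares) - 1) < 1e-8)
  out <- simulate_outcomes(truth, seed = seed,
                           new_effects = !use_truth_effects)
  meta <- truth$meta
  years <- sort(unique(meta$year))
  if (is.null(calendar)) calendar <- make_week_calendar(years)
  ratio <- ifelse(meta$month == 1L, 1, exp(out$y))
  ids <- truth$graph$region_ids
  n <- length(ids)
  set.seed(as.integer(seed) + 1L)
  base_i <- if (length(base_flow) == n) base_flow else
    base_flow * exp(stats::rnorm(n, 0, 0.4))
  coords <- cbind(stats::runif(n), stats::runif(n))
  pop <- base_i
  intl <- data.frame(
    dest_id = c("TZ", "UG", "ET", "AE", "QA", "ZA", "GB", "FR", "NL", "US"),
    w = c(0.30, 0.25, 0.15, 0.07, 0.05, 0.05, 0.05, 0.03, 0.03, 0.02)
  )
  monthly_total <- base_i[match(meta$region_id, ids)] * ratio

  rec <- vector("list", nrow(meta))
  for (r in seq_len(nrow(meta))) {
    i <- match(meta$region_id[r], ids)
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2
    gw <- pop / pmax(d2, 1e-4)
    gw[i] <- 0
    dom <- order(gw, decreasing = TRUE)[seq_len(min(n_domestic_dest, n - 1L))]
    dests <- c(ids[i], ids[dom], intl$dest_id)
    wts <- c(class_shares[["within"]],
             class_shares[["domestic"]] * gw[dom] / sum(gw[dom]),
             class_shares[["international"]] * intl$w)
    counts <- if (integer_counts) {
      largest_remainder(round(monthly_total[r]), wts)
    } else monthly_total[r] * wts / sum(wts)
    rec[[r]] <- data.frame(origin_id = meta$region_id[r], dest_id = dests,
                           year = meta$year[r], month = meta$month[r],
                           count = counts, stringsAsFactors = FALSE)
  }
  monthly_raw <- do.call(rbind, rec)
  monthly_raw <- monthly_raw[monthly_raw$count > 0, , drop = FALSE]

  # month -> weeks, proportional to week length
  wk <- vector("list", nrow(monthly_raw))
  calkey <- split(seq_len(nrow(calendar)),
                  paste(calendar$year, calendar$month))
  for (r in seq_len(nrow(monthly_raw))) {
    widx <- calkey[[paste(monthly_raw$year[r], monthly_raw$month[r])]]
    days <- calendar$days[widx]
    cnt <- if (integer_counts) {
      largest_remainder(monthly_raw$count[r], days)
    } else monthly_raw$count[r] * days / sum(days)
    wk[[r]] <- data.frame(origin_id = monthly_raw$origin_id[r],
                          dest_id = monthly_raw$dest_id[r],
                          year = calendar$year[widx],
                          week = calendar$week[widx],
                          count = cnt, stringsAsFactors = FALSE)
  }
  weekly <- do.call(rbind, wk)
  weekly <- weekly[weekly$count > 0, , drop = FALSE]
  rownames(weekly) <- NULL

  truth_changes <- compute_change_ratios(monthly_raw)
  intended <- cbind(meta, data.frame(eta = out$y, ratio = ratio))
  list(weekly = weekly, monthly_raw = monthly_raw,
       truth_changes = truth_changes, intended = intended,
       effects = out$effects, truth = truth)
}

#' Apply the differentially-private release to a weekly panel
#'
#' Composition of the release mechanism: Laplace noise on every weekly
#' count, suppression of noisy counts below the threshold, then aggregation
#' of the surviving weeks to months.
#'
#' @param weekly raw weekly flow records
#' @param params \code{\link{privacy_params}}
#' @param seed integer seed for the noise draw
#' @param calendar week calendar; default rebuilt from the weekly years
#' @return released monthly flow records (columns \code{origin_id},
#'   \code{dest_id}, \code{year}, \code{month}, \code{count})
#' @export
apply_release <- function(weekly, params = privacy_params(), seed,
                          calendar = NULL) {
  if (missing(seed)) stop("seed is required for a reproducible release")
  if (is.null(calendar)) calendar <- make_week_calendar(sort(unique(weekly$year)))
  noisy <- weekly
  noisy$count <- add_laplace_noise(weekly$count, params, seed = seed)
  kept <- suppress_small_flows(noisy, params)
  aggregate_weeks_to_months(kept, calendar)
}
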