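#' Parameters of the differentially-private flow release
#'
#' Weekly origin-destination user counts are released through a Laplace
#' mechanism: zero-mean Laplace noise of scale \code{noise_scale} is added to
#' each count, and noisy counts below \code{threshold} are removed. With
#' per-user count sensitivity \code{sensitivity}, the mechanism's privacy
#' budget is \code{epsilon = sensitivity / noise_scale}; the default scale
#' 1/0.66 gives epsilon = 0.66. \code{delta} is carried as metadata only (it
#' arises from the data provider's composition accounting, which is not
#' reproducible from the release parameters alone).
#'
#' @param noise_scale Laplace scale b > 0; default 1/0.66
#' @param sensitivity per-user count sensitivity; default 1
#' @param threshold minimum retained noisy count; default 100 (noisy counts
#'   strictly below the threshold are suppressed)
#' @param delta nominal DP failure probability, metadata only
#' @return object of class \code{privacy_params}
#' @export
privacy_params <- function(noise_scale = 1 / 0.66, sensitivity = 1,
                           threshold = 100, delta = 2.1e-29) {
  if (!is.numeric(noise_scale) || length(noise_scale) != 1L || noise_scale <= 0) {
    stop("noise_scale must be a positive scalar")
  }
  if (threshold < 0) stop("threshold must be non-negative")
  if (sensitivity <= 0) stop("sensitivity must be positive")
  structure(
    list(noise_scale = noise_scale, sensitivity = sensitivity,
         threshold = threshold, delta = delta,
         epsilon = sensitivity / noise_scale),
    class = "privacy_params"
  )
}

#' @export
print.privacy_params <- function(x, ...) {
  cat("Laplace release mechanism: scale", format(x$noise_scale),
      "| suppression threshold", x$threshold,
      "| epsilon", format(x$epsilon), "\n")
  invisible(x)
}

#' Privacy budget of a Laplace release
#'
#' @param params a \code{\link{privacy_params}} object
#' @return epsilon = sensitivity / noise_scale
#' @export
privacy_epsilon <- function(params) {
  if (params$noise_scale <= 0) stop("noise_scale must be positive")
  params$sensitivity / params$noise_scale
}

#' Laplace random deviates
#'
#' Inverse-CDF sampler for the zero-location Laplace (double exponential)
#' distribution with the given scale; mean 0, variance 2 * scale^2.
#'
#' @param n number of deviates
#' @param scale positive scale parameter
#' @return numeric vector of length n
#' @export
rlaplace <- function(n, scale = 1) {
  if (scale <= 0) stop("scale must be positive")
  u <- stats::runif(n, -0.5, 0.5)
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Add Laplace noise to counts
#'
#' @param counts numeric vector of raw counts
#' @param params \code{\link{privacy_params}}
#' @param seed integer seed; required so that a release is reproducible
#' @return noisy counts (real-valued; no rounding is applied)
#' @export
add_laplace_noise <- function(counts, params = privacy_params(), seed) {
  if (missing(seed)) stop("seed is required for a reproducible release")
  stopifnot(inherits(params, "privacy_params"))
  if (length(counts) == 0L) return(numeric(0))
  if (any(counts < 0, na.rm = TRUE)) stop("raw counts must be non-negative")
  set.seed(as.integer(seed))
  counts + rlaplace(length(counts), scale = params$noise_scale)
}

#' Suppress small noisy flows
#'
#' Removes every record whose noisy count is strictly below the suppression
#' threshold ("lower than" read as strict: a noisy count exactly equal to the
#' threshold is retained). Record order is preserved.
#'
#' @param noisy_records data frame with a \code{count} column of noisy
#'   counts, or a bare numeric vector of noisy counts
#' @param params \code{\link{privacy_params}}
#' @return the retained records (same type as the input)
#' @export
suppress_small_flows <- function(noisy_records, params = privacy_params()) {
  stopifnot(inherits(params, "privacy_params"))
  if (is.numeric(noisy_records)) {
    return(noisy_records[noisy_records >= params$threshold])
  }
  stopifnot(is.data.frame(noisy_records), "count" %in% names(noisy_records))
  noisy_records[noisy_records$count >= params$threshold, , drop = FALSE]
}

#' Study week calendar
#'
#' Deterministic week grid used for weekly flow records: each year is split
#' into 52 consecutive weeks starting 1 January; weeks 1..51 have 7 days and
#' week 52 absorbs the remaining 8 (or 9) days. A week is assigned to the
#' month containing its start date; weeks straddling a month boundary are not
#' split.
#'
#' @param years integer vector of years
#' @return data frame with columns \code{year}, \code{week}, \code{month}
#'   (month of the week's start date) and \code{days} (week length in days)
#' @export
make_week_calendar <- function(years) {
  out <- lapply(years, function(yr) {
    start <- as.Date(sprintf("%d-01-01", yr)) + 7L * (0:51)
    days <- rep(7L, 52L)
    days[52L] <- as.integer(as.Date(sprintf("%d-01-01", yr + 1L)) - start[52L])
    data.frame(year = yr, week = 1:52,
               month = as.integer(format(start, "%m")), days = days)
  })
  do.call(rbind, out)
}

#' Aggregate released weekly flows to months
#'
#' Monthly count for an (origin, destination, year, month) cell is the sum of
#' the retained weekly counts whose week maps to that month. Pairs with no
#' surviving weeks are absent from the output.
#'
#' @param weekly data frame with columns \code{origin_id}, \code{dest_id},
#'   \code{year}, \code{week}, \code{count}
#' @param calendar week-to-month map from \code{\link{make_week_calendar}}
#' @return data frame with columns \code{origin_id}, \code{dest_id},
#'   \code{year}, \code{month}, \code{count}
#' @export
aggregate_weeks_to_months <- function(weekly, calendar) {
  needed <- c("origin_id", "dest_id", "year", "week", "count")
  stopifnot(all(needed %in% names(weekly)))
  if (nrow(weekly) == 0L) {
    return(data.frame(origin_id = character(0), dest_id = character(0),
                      year = integer(0), month = integer(0),
                      count = numeric(0)))
  }
  key <- paste(weekly$year, weekly$week)
  calkey <- paste(calendar$year, calendar$week)
  hit <- match(key, calkey)
  if (anyNA(hit)) {
    stop("week(s) not covered by the calendar: ",
         paste(unique(key[is.na(hit)]), collapse = ", "))
  }
  month <- calendar$month[hit]
  agg <- stats::aggregate(
    weekly$count,
    by = list(origin_id = weekly$origin_id, dest_id = weekly$dest_id,
              year = weekly$year, month = month),
    FUN = sum
  )
  names(agg)[names(agg) == "x"] <- "count"
  agg <- agg[order(agg$origin_id, agg$dest_id, agg$year, agg$month), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
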