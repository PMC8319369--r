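#' Zonal mean of a gridded covariate
#'
#' Arithmetic mean of the non-missing grid cells falling in each zone
#' (administrative unit). Zones with no valid cell are omitted from the
#' result and reported via a warning, never filled with zeros.
#'
#' @param values numeric matrix of grid values; \code{NA} marks missing cells
#' @param zones matrix of the same shape with a zone label per cell
#'   (\code{NA} cells are outside every zone)
#' @return named numeric vector of per-zone means
#' @export
zonal_mean <- function(values, zones) {
  if (!all(dim(values) == dim(zones))) {
    stop("values and zones grids must have the same shape")
  }
  ok <- !is.na(values) & !is.na(zones)
  all_zones <- sort(unique(as.vector(zones[!is.na(zones)])))
  if (!any(ok)) stop("no valid cells")
  means <- tapply(values[ok], as.vector(zones[ok]), mean)
  means <- stats::setNames(as.numeric(means), names(means))
  missing_zones <- setdiff(all_zones, names(means))
  if (length(missing_zones)) {
    warning("zone(s) with no valid cells omitted: ",
            paste(missing_zones, collapse = ", "))
  }
  means[order(names(means))]
}

#' Urban population share per zone
#'
#' Combines a settlement classification with gridded population: cells
#' classed \code{"urban"} or \code{"peri-urban"} form the urban extent, and
#' the share is urban-extent population over total population in the zone.
#'
#' @param population non-negative numeric population grid
#' @param settlement_class character grid with values \code{"rural"},
#'   \code{"peri-urban"}, \code{"urban"}
#' @param zones zone-label grid, same shape
#' @return named numeric vector of shares in [0, 1]; zones with zero total
#'   population are omitted with a warning
#' @export
urban_population_share <- function(population, settlement_class, zones) {
  if (!all(dim(population) == dim(zones)) ||
      !all(dim(settlement_class) == dim(zones))) {
    stop("all grids must have the same shape")
  }
  cls <- as.vector(settlement_class)
  known <- is.na(cls) | cls %in% c("rural", "peri-urban", "urban")
  if (!all(known)) {
    stop("unknown settlement class(es): ",
         paste(unique(cls[!known]), collapse = ", "))
  }
  ok <- !is.na(population) & !is.na(zones) & !is.na(settlement_class)
  z <- as.vector(zones[ok])
  pop <- as.vector(population[ok])
  urb <- pop * (as.vector(settlement_class[ok]) %in% c("urban", "peri-urban"))
  tot <- tapply(pop, z, sum)
  urb_tot <- tapply(urb, z, sum)
  zero <- tot <= 0
  if (any(zero)) {
    warning("zone(s) with zero total population omitted: ",
            paste(names(tot)[zero], collapse = ", "))
  }
  share <- (urb_tot / tot)[!zero]
  share <- stats::setNames(as.numeric(share), names(tot)[!zero])
  share[order(names(share))]
}

#' Collinearity screen over a covariate table
#'
#' Computes pairwise Pearson correlations between candidate covariates over
#' all region-months and, within any group of variables correlated above the
#' threshold, keeps a single representative chosen by a fixed priority list
#' (temperature first among the climate variables). Constant covariates have
#' undefined correlations; they are flagged and excluded from the screen.
#'
#' @param x data frame or matrix of covariate columns (one row per
#'   region-month)
#' @param threshold absolute correlation above which variables are treated as
#'   collinear; default 0.7
#' @param priority character vector giving the order in which representatives
#'   are chosen; variables absent from the list rank after it, in column
#'   order
#' @return list with \code{retained} (character vector), \code{dropped}
#'   (data frame: variable, representative, r), \code{constant} (flagged
#'   variables) and \code{correlation} (full correlation matrix)
#' @export
collinearity_screen <- function(x, threshold = 0.7,
                                priority = c("temperature", "aridity",
                                             "precipitation", "evi")) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need at least two covariates")
  if (nrow(x) < 3L) stop("need at least three observations")
  sds <- vapply(x, stats::sd, numeric(1))
  constant <- names(x)[sds == 0 | is.na(sds)]
  if (length(constant)) {
    warning("constant covariate(s) excluded from screen: ",
            paste(constant, collapse = ", "))
    x <- x[, setdiff(names(x), constant), drop = FALSE]
  }
  cm <- stats::cor(x)
  order_rank <- c(intersect(priority, colnames(cm)),
                  setdiff(colnames(cm), priority))
  remaining <- order_rank
  retained <- character(0)
  dropped <- data.frame(variable = character(0), representative = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  while (length(remaining)) {
    rep_var <- remaining[1]
    retained <- c(retained, rep_var)
    remaining <- remaining[-1]
    hit <- remaining[abs(cm[rep_var, remaining]) >= threshold]
    if (length(hit)) {
      dropped <- rbind(dropped, data.frame(
        variable = hit, representative = rep_var, r = cm[rep_var, hit],
        stringsAsFactors = FALSE))
      remaining <- setdiff(remaining, hit)
    }
  }
  rownames(dropped) <- NULL
  list(retained = retained[order(match(retained, colnames(cm)))],
       dropped = dropped, constant = constant, correlation = cm)
}

#' Independence check between school holidays and climate covariates
#'
#' Pearson correlation t-tests between the school-holiday covariate and each
#' climate covariate present, with Bonferroni correction across the tested
#' pairs (adjusted p = min(1, m * p)). Used to confirm that the holiday
#' calendar carries signal not already captured by temperature seasonality.
#'
#' @param x data frame with a \code{school_holidays} column and one or more
#'   of \code{temperature}, \code{aridity}, \code{precipitation}, \code{evi}
#' @param alpha familywise significance level, default 0.05
#' @return data frame with one row per pair: \code{variable}, \code{r},
#'   \code{t}, \code{df}, \code{p}, \code{p_adjusted}, \code{significant}
#' @export
holiday_temperature_independence <- function(x, alpha = 0.05) {
  x <- as.data.frame(x)
  if (!"school_holidays" %in% names(x)) stop("school_holidays column required")
  partners <- intersect(c("temperature", "aridity", "precipitation", "evi"),
                        names(x))
  if (!length(partners)) stop("no climate covariate present")
  if (nrow(x) < 3L) stop("need at least three paired observations")
  m <- length(partners)
  rows <- lapply(partners, function(v) {
    tt <- stats::cor.test(x$school_holidays, x[[v]])
    data.frame(variable = v, r = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adjusted = min(1, m * tt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
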