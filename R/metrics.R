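#' Classify trips as within-county, domestic or international
#'
#' A flow record whose origin and destination county coincide is
#' within-county; different counties in the same country is domestic; a
#' destination outside the origin's country is international. Destinations
#' are resolved first against the county metadata and, failing that, treated
#' as a foreign country code.
#'
#' @param records data frame with \code{origin_id} and \code{dest_id}
#' @param region_meta data frame with \code{region_id} and
#'   \code{country_code} (as from \code{\link{kenya_region_metadata}})
#' @return character vector, one of \code{"within_county"},
#'   \code{"domestic"}, \code{"international"} per record
#' @export
classify_trip <- function(records, region_meta) {
  stopifnot(all(c("origin_id", "dest_id") %in% names(records)))
  oc <- region_meta$country_code[match(records$origin_id, region_meta$region_id)]
  if (anyNA(oc)) {
    stop("unresolvable origin id(s): ",
         paste(unique(records$origin_id[is.na(oc)]), collapse = ", "))
  }
  dc <- region_meta$country_code[match(records$dest_id, region_meta$region_id)]
  # destinations absent from the county table are taken as foreign country codes
  foreign <- is.na(dc)
  dc[foreign] <- records$dest_id[foreign]
  out <- ifelse(dc != oc, "international",
                ifelse(records$origin_id == records$dest_id,
                       "within_county", "domestic"))
  if (any(foreign & dc == oc)) {
    stop("destination(s) resolve to the origin country but are not known counties: ",
         paste(unique(records$dest_id[foreign & dc == oc]), collapse = ", "))
  }
  out
}

#' Total outward flow of a county in a month
#'
#' Sum of counts over all records with the given origin and period, to all
#' destinations. By default within-county records are included: the monthly
#' total is the flow to all destinations, of which within-county travel is
#' typically the dominant class.
#'
#' @param panel monthly flow data frame (\code{origin_id}, \code{dest_id},
#'   \code{year}, \code{month}, \code{count})
#' @param region origin region id
#' @param year,month period
#' @param include_within include records with origin == destination
#' @return scalar total; 0 with attribute \code{no_records = TRUE} (and a
#'   warning) if the panel has no rows for the request
#' @export
total_outward_flow <- function(panel, region, year, month,
                               include_within = TRUE) {
  sel <- panel$origin_id == region & panel$year == year & panel$month == month
  if (!include_within) sel <- sel & panel$origin_id != panel$dest_id
  if (!any(sel)) {
    warning("no records for (", region, ", ", year, "-", month, ")")
    return(structure(0, no_records = TRUE))
  }
  sum(panel$count[sel])
}

#' Monthly mobility change ratios against a January baseline
#'
#' For each county and year, the change ratio of month m is the county's
#' total outward flow in m divided by its total outward flow in the baseline
#' month (January by default) of the same year. Baseline-month entries are
#' emitted with ratio exactly 1, so a complete two-year, 47-county panel
#' yields 47 x 24 = 1128 observations. County-years whose baseline flow is
#' missing or non-positive are excluded and reported via the
#' \code{"excluded"} attribute and a warning.
#'
#' @param panel monthly flow data frame (\code{origin_id}, \code{dest_id},
#'   \code{year}, \code{month}, \code{count})
#' @param baseline_month month used as baseline (default 1)
#' @param include_within include within-county records in the totals
#' @return object of class \code{mobility_change}: data frame with columns
#'   \code{region_id}, \code{year}, \code{month}, \code{outward_flow},
#'   \code{baseline_flow}, \code{ratio}
#' @export
compute_change_ratios <- function(panel, baseline_month = 1L,
                                  include_within = TRUE) {
  stopifnot(all(c("origin_id", "dest_id", "year", "month", "count") %in%
                  names(panel)))
  if (!include_within) {
    panel <- panel[panel$origin_id != panel$dest_id, , drop = FALSE]
  }
  if (nrow(panel) == 0L) stop("empty panel")
  tot <- stats::aggregate(
    panel$count,
    by = list(region_id = panel$origin_id, year = panel$year,
              month = panel$month),
    FUN = sum
  )
  names(tot)[names(tot) == "x"] <- "outward_flow"
  base <- tot[tot$month == baseline_month,
              c("region_id", "year", "outward_flow")]
  names(base)[3] <- "baseline_flow"
  out <- merge(tot, base, by = c("region_id", "year"), all.x = TRUE)
  bad <- is.na(out$baseline_flow) | out$baseline_flow <= 0
  excluded <- unique(out[bad, c("region_id", "year")])
  if (nrow(excluded)) {
    warning("excluding ", nrow(excluded),
            " county-year(s) with missing or non-positive baseline flow: ",
            paste(paste(excluded$region_id, excluded$year), collapse = ", "))
  }
  out <- out[!bad, , drop = FALSE]
  out$ratio <- out$outward_flow / out$baseline_flow
  out$ratio[out$month == baseline_month] <- 1
  out <- out[order(out$region_id, out$year, out$month),
             c("region_id", "year", "month", "outward_flow",
               "baseline_flow", "ratio")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("mobility_change", "data.frame")
  out
}

#' Directed origin-destination matrix by region group
#'
#' Aggregates a monthly flow panel into a square matrix of directed flows
#' between region groups (e.g. counties grouped into provinces). Entry (P, Q)
#' is the total count with origin in group P and destination in group Q; the
#' grand total of the matrix equals the grouped panel total.
#'
#' @param panel monthly flow data frame
#' @param grouping data frame with \code{region_id} and \code{group_id}
#'   mapping every domestic county to a group
#' @return square numeric matrix, rows = origin group, columns = destination
#'   group. Records whose destination is not in the grouping (international
#'   flows) are dropped.
#' @export
od_matrix_by_region_group <- function(panel, grouping) {
  stopifnot(all(c("region_id", "group_id") %in% names(grouping)))
  og <- grouping$group_id[match(panel$origin_id, grouping$region_id)]
  if (anyNA(og)) {
    stop("origin county not covered by grouping: ",
         paste(unique(panel$origin_id[is.na(og)]), collapse = ", "))
  }
  dg <- grouping$group_id[match(panel$dest_id, grouping$region_id)]
  keep <- !is.na(dg)
  groups <- sort(unique(grouping$group_id))
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(origin = groups, dest = groups))
  if (any(keep)) {
    agg <- stats::aggregate(panel$count[keep],
                            by = list(o = og[keep], d = dg[keep]), FUN = sum)
    m[cbind(match(agg$o, groups), match(agg$d, groups))] <- agg$x
  }
  m
}

#' Outward flow shares of one region group
#'
#' Divides one row of an origin-destination matrix by its row total, giving
#' the proportion of the group's outward movement going to each destination
#' group.
#'
#' @param od_matrix square matrix from \code{\link{od_matrix_by_region_group}}
#' @param group origin group id (row name)
#' @return named numeric vector of proportions summing to 1
#' @export
outward_share <- function(od_matrix, group) {
  if (!group %in% rownames(od_matrix)) stop("unknown group: ", group)
  row <- od_matrix[group, ]
  tot <- sum(row)
  if (tot <= 0) stop("zero outward flow for group ", group,
                     ": shares undefined")
  row / tot
}
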