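# Plain-text readers/writers for the package's external interfaces

#' Read an edge list file
#'
#' Two-column delimited text (region_id_a, region_id_b) with a header;
#' lines starting with '#' are comments.
#'
#' @param path file path
#' @return data frame with two character columns
#' @export
read_edge_list <- function(path) {
  el <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(el) < 2L) stop("edge list needs two columns")
  el[, 1:2]
}

#' Read a region metadata file
#'
#' Delimited text with columns region_id, province_id, country_code.
#'
#' @param path file path
#' @return data frame
#' @export
read_region_metadata <- function(path) {
  meta <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("region_id", "province_id", "country_code")
  if (!all(needed %in% names(meta))) {
    stop("region metadata needs columns: ", paste(needed, collapse = ", "))
  }
  meta
}

#' Read a flow file
#'
#' Delimited text with columns origin_id, dest_id, year, week (weekly files)
#' or month (monthly files), and count.
#'
#' @param path file path
#' @return data frame
#' @export
read_flows <- function(path) {
  fl <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("origin_id", "dest_id", "year", "count")
  if (!all(needed %in% names(fl)) ||
      !any(c("week", "month") %in% names(fl))) {
    stop("flow file needs columns origin_id, dest_id, year, week|month, count")
  }
  fl
}

#' Read a plain-text grid file
#'
#' Minimal gridded-covariate format for zonal statistics: a header line
#' \code{nrows ncols na_value} followed by the values in row-major order,
#' whitespace-separated. Cells equal to the sentinel become \code{NA}.
#'
#' @param path file path
#' @return numeric matrix (character matrix for zone-label grids read with
#'   \code{character = TRUE})
#' @param character read the grid as zone labels instead of numbers
#' @export
read_grid <- function(path, character = FALSE) {
  header <- scan(path, what = numeric(), nlines = 1, quiet = TRUE)
  if (length(header) < 3L) stop("grid header must be: nrows ncols na_value")
  vals <- scan(path, what = if (character) character() else numeric(),
               skip = 1, quiet = TRUE)
  if (length(vals) != header[1] * header[2]) {
    stop("grid has ", length(vals), " cells, header promises ",
         header[1] * header[2])
  }
  m <- matrix(vals, nrow = header[1], ncol = header[2], byrow = TRUE)
  m[m == (if (character) as.character(header[3]) else header[3])] <- NA
  m
}

#' Write a flow file
#'
#' @param flows flow data frame
#' @param path output path
#' @param released mark records as released (adds a released=TRUE column)
#' @export
write_flows <- function(flows, path, released = FALSE) {
  if (released) flows$released <- TRUE
  utils::write.csv(flows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
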