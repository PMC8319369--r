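#' Build a region adjacency graph
#'
#' Constructs the county contiguity graph that feeds the intrinsic CAR (ICAR)
#' precision of the BYM2 spatial random effect. Edges are undirected and
#' deduplicated; connected components are computed so that disconnected
#' study areas (island regions) can be handled per component downstream.
#'
#' @param edge_list two-column data frame or matrix of region id pairs
#'   (character). Each row is one undirected contiguity edge. Self-loops are
#'   dropped with a warning.
#' @param region_ids character vector of all region identifiers, in the order
#'   that fixes the row/column order of every spatial matrix built from the
#'   graph. Must be unique.
#' @return an object of class \code{region_graph}: a list with
#'   \code{region_ids}, \code{edges} (two-column character matrix, each row
#'   sorted, unique), \code{component} (integer component label per region)
#'   and \code{n_components}.
#' @examples
#' g <- build_region_graph(data.frame(a = "A", b = "B"), c("A", "B", "C"))
#' g$n_components  # 2: {A,B} and {C}
#' @export
build_region_graph <- function(edge_list, region_ids) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) {
    stop("duplicate region ids: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  }
  if (length(region_ids) == 0L) stop("region_ids must be non-empty")
  el <- as.matrix(edge_list)
  if (ncol(el) < 2L && nrow(el) > 0L) stop("edge_list needs two columns")
  edges <- matrix(character(0), 0, 2)
  if (nrow(el) > 0L) {
    a <- as.character(el[, 1]); b <- as.character(el[, 2])
    unknown <- setdiff(c(a, b), region_ids)
    if (length(unknown)) {
      stop("unknown region id(s) in edge list: ",
           paste(unknown, collapse = ", "))
    }
    self <- a == b
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped from edge list")
      a <- a[!self]; b <- b[!self]
    }
    edges <- unique(cbind(pmin(a, b), pmax(a, b)))
  }
  ig <- igraph::graph_from_data_frame(
    d = as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = region_ids, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(ig)
  component <- comp$membership[region_ids]
  names(component) <- region_ids
  structure(
    list(region_ids = region_ids,
         edges = edges,
         component = as.integer(component),
         n_components = comp$no),
    class = "region_graph"
  )
}

#' @export
print.region_graph <- function(x, ...) {
  cat("Region adjacency graph\n")
  cat("  regions:   ", length(x$region_ids), "\n")
  cat("  edges:     ", nrow(x$edges), "\n")
  cat("  components:", x$n_components, "\n")
  invisible(x)
}

#' ICAR structure matrix of a region graph
#'
#' The intrinsic conditional autoregressive (ICAR) structure matrix is
#' degree-minus-adjacency: \code{Q[i,i] = degree(i)}, \code{Q[i,j] = -1} iff
#' i and j are neighbours. Rows sum to zero, so Q is singular with rank
#' n - (number of connected components).
#'
#' @param graph a \code{region_graph}
#' @return sparse symmetric \code{\link[Matrix]{Matrix}} (n x n), rows and
#'   columns ordered as \code{graph$region_ids}
#' @export
icar_structure <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  n <- length(graph$region_ids)
  idx <- match(graph$edges[, 1], graph$region_ids)
  jdx <- match(graph$edges[, 2], graph$region_ids)
  A <- Matrix::sparseMatrix(i = c(idx, jdx), j = c(jdx, idx),
                            x = 1, dims = c(n, n))
  Q <- Matrix::Diagonal(n, x = Matrix::rowSums(A)) - A
  dimnames(Q) <- list(graph$region_ids, graph$region_ids)
  Matrix::forceSymmetric(Q)
}

# Blockwise constrained generalized inverse of an ICAR structure matrix:
# per connected component, the Moore-Penrose pseudo-inverse, which equals the
# covariance of the ICAR under the per-component sum-to-zero constraint.
# Singleton components contribute zero variance and are skipped.
icar_generalized_inverse <- function(Q, component) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  V <- matrix(0, n, n)
  for (k in unique(component)) {
    ids <- which(component == k)
    if (length(ids) < 2L) next
    e <- eigen(Q[ids, ids, drop = FALSE], symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    Vk <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
    V[ids, ids] <- Vk
  }
  dimnames(V) <- dimnames(Q)
  V
}

#' BYM2 scaling factor
#'
#' The BYM2 parameterisation requires the structured (ICAR) component to have
#' generalized marginal variance one, so that its precision parameter is
#' interpretable on the same scale as the unstructured part. The scaling
#' factor is the geometric mean of the marginal variances of the ICAR under
#' its sum-to-zero constraint (the diagonal of the blockwise generalized
#' inverse of Q); multiplying Q by this factor gives marginal variances with
#' geometric mean one. Disconnected graphs are handled per component;
#' singleton components carry no structured variation and are excluded.
#'
#' @param Q_icar ICAR structure matrix from \code{\link{icar_structure}}
#' @param component integer component label per region (from the graph)
#' @return positive scalar scaling factor
#' @export
bym2_scaling_factor <- function(Q_icar, component) {
  n <- nrow(Q_icar)
  stopifnot(length(component) == n)
  nonsing <- which(tabulate(component)[component] > 1L)
  if (length(nonsing) == 0L) {
    stop("all components are singletons: no structured spatial variation definable")
  }
  V <- icar_generalized_inverse(Q_icar, component)
  mv <- diag(V)[nonsing]
  exp(mean(log(mv)))
}

#' Full spatial structure for the BYM2 component
#'
#' Convenience wrapper bundling the ICAR structure matrix, its BYM2 scaling
#' factor and the scaled matrix \code{Q_scaled = scaling_factor * Q_icar}
#' used as the prior precision structure of the structured spatial effect.
#'
#' @param graph a \code{region_graph}
#' @return object of class \code{spatial_structure}: list with
#'   \code{Q_icar}, \code{scaling_factor}, \code{Q_scaled}, \code{component},
#'   \code{region_ids}, and \code{singleton} (logical per region).
#' @export
spatial_structure <- function(graph) {
  Q <- icar_structure(graph)
  sf <- bym2_scaling_factor(Q, graph$component)
  structure(
    list(Q_icar = Q,
         scaling_factor = sf,
         Q_scaled = sf * Q,
         component = graph$component,
         region_ids = graph$region_ids,
         singleton = tabulate(graph$component)[graph$component] == 1L),
    class = "spatial_structure"
  )
}

#' Load the bundled Kenya county contiguity fixture
#'
#' A hand-curated, approximate queen-contiguity edge list for Kenya's 47
#' counties (post-2013 devolution), shipped as a plain-text fixture. It is an
#' approximation for testing and demonstration, not an authoritative
#' geographic product; any user-supplied edge list is accepted by
#' \code{\link{build_region_graph}}.
#'
#' @return a \code{region_graph} over the 47 counties
#' @export
kenya_graph <- function() {
  meta <- kenya_region_metadata()
  el <- utils::read.csv(system.file("extdata", "kenya_county_adjacency.csv",
                                    package = "stmobility"),
                        comment.char = "#", stringsAsFactors = FALSE)
  build_region_graph(el, meta$region_id)
}

#' Bundled Kenya county metadata (county, former province, country)
#'
#' @return data frame with columns \code{region_id}, \code{province_id},
#'   \code{country_code}
#' @export
kenya_region_metadata <- function() {
  utils::read.csv(system.file("extdata", "kenya_region_metadata.csv",
                              package = "stmobility"),
                  comment.char = "#", stringsAsFactors = FALSE)
}
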