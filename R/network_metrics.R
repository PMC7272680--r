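# graphs are undirected and simple: symmetric 0/1 matrix, zero diagonal.
.check_adjacency <- function(adjacency) {
  a <- unclass(adjacency)
  if (!is.matrix(a) || nrow(a) != ncol(a))
    .err("adjacency must be a square matrix")
  if (!all(a %in% c(0L, 1L))) .err("adjacency entries must be 0/1")
  if (any(a != t(a))) .err("adjacency must be symmetric")
  if (any(diag(a) != 0)) .err("adjacency must have a zero diagonal")
  a
}

#' Node degree of every region
#'
#' The number of edges incident to each node of the binarized network.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal (e.g. from
#'   [threshold_adjacency()]).
#' @return named integer vector of degrees in `[0, N - 1]`.
#' @export
node_degree <- function(adjacency) {
  a <- .check_adjacency(adjacency)
  deg <- as.integer(rowSums(a))
  names(deg) <- rownames(a)
  deg
}

#' Global network density
#'
#' Realized edges as a proportion of the `N (N - 1) / 2` possible edges for
#' the node count; isolated regions stay in the denominator so densities
#' are comparable across groups.
#'
#' @inheritParams node_degree
#' @return density in `[0, 1]`.
#' @export
network_density <- function(adjacency) {
  a <- .check_adjacency(adjacency)
  n <- nrow(a)
  if (n < 2L) .err("network density needs at least 2 regions (got %d)", n)
  sum(a) / 2 / (n * (n - 1) / 2)
}

#' Summarise one group's network
#'
#' @inheritParams node_degree
#' @param group group label carried into the summary.
#' @param focal focal region whose degree is reported separately
#'   (default `"DG"`).
#' @return object of class `network_summary`: list with `group`, `degree`,
#'   `n_edges`, `density`, `focal_degree`.
#' @export
network_summary <- function(adjacency, group = "group", focal = "DG") {
  a <- .check_adjacency(adjacency)
  if (!focal %in% rownames(a))
    .err("focal region '%s' not among the network's regions", focal)
  deg <- node_degree(adjacency)
  structure(list(group = group, degree = deg,
                 n_edges = sum(a) %/% 2L,
                 density = network_density(adjacency),
                 focal_degree = deg[[focal]]),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network '%s': %d edges, density %.3f, focal degree %d\n",
              x$group, x$n_edges, x$density, x$focal_degree))
  invisible(x)
}

#' Export a network as an edge list (optionally GraphML)
#'
#' Emits the undirected edge list with a flag on edges incident to the
#' highlighted (focal) region, the convention used to draw the dentate
#' gyrus connections in a distinct colour. The number of flagged edges
#' equals the focal region's node degree.
#'
#' @inheritParams node_degree
#' @param highlight region label to flag; must be a region of the network.
#' @param file optional path for a comma-separated edge list.
#' @param graphml optional path for a GraphML file (written via igraph).
#' @return data.frame with columns `from`, `to`, `focal` (invisible when
#'   written to file).
#' @export
export_graph <- function(adjacency, highlight, file = NULL, graphml = NULL) {
  a <- .check_adjacency(adjacency)
  regions <- rownames(a)
  if (is.null(regions)) .err("adjacency must carry region dimnames")
  if (!highlight %in% regions)
    .err("unknown highlight region '%s'", highlight)
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  edges <- data.frame(from = regions[idx[, 1L]], to = regions[idx[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges$focal <- edges$from == highlight | edges$to == highlight
  if (!is.null(file)) utils::write.csv(edges, file, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    igraph::V(g)$focal <- regions == highlight
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (is.null(file) && is.null(graphml)) edges else invisible(edges)
}

#' Rebuild an adjacency matrix from an exported edge list
#'
#' Inverse of [export_graph()]: given the edge list and the full region
#' panel (isolated regions do not appear in the edge list), reconstructs
#' the symmetric 0/1 matrix exactly.
#'
#' @param edges data.frame with columns `from`, `to`, or a path to a CSV
#'   written by [export_graph()].
#' @param regions character vector of all region labels.
#' @return symmetric 0/1 integer matrix with `regions` dimnames.
#' @export
edges_to_adjacency <- function(edges, regions) {
  if (is.character(edges)) edges <- utils::read.csv(edges,
                                                    stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(edges)))
  unknown <- setdiff(c(edges$from, edges$to), regions)
  if (length(unknown)) .err("edge list references unknown region(s): %s",
                            paste(unique(unknown), collapse = ", "))
  a <- matrix(0L, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (i in seq_len(nrow(edges))) {
    a[edges$from[i], edges$to[i]] <- 1L
    a[edges$to[i], edges$from[i]] <- 1L
  }
  a
}
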