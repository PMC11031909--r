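#' Construct a protein interaction network
#'
#' A `pin` is a simple undirected graph over opaque protein identifiers:
#' self-loops are dropped, each unordered pair is stored once (endpoints
#' sorted lexicographically within a pair, rows sorted), and isolated nodes
#' are first-class members of the node set. This is the container for the
#' static network (S-PIN) and for every refined variant derived from it
#' (D-PIN, RD-PIN, CM-PIN), all of which share the same node set and shrink
#' only the edge set.
#'
#' @param nodes Character vector of protein ids (may be empty; the final node
#'   set is the union of `nodes` and all edge endpoints).
#' @param edges Two-column character matrix (or a vector coercible to one) of
#'   protein-id pairs; `NULL` for an edgeless network.
#' @return An object of class `pin` with components `nodes` (sorted character
#'   vector) and `edges` (two-column character matrix in canonical order).
#' @examples
#' net <- pin(edges = cbind(c("A", "B", "C"), c("B", "C", "A")))
#' n_edges(net)
#' @export
pin <- function(nodes = character(), edges = NULL) {
  nodes <- as.character(nodes)
  if (is.null(edges) || length(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- matrix(as.character(edges), ncol = 2L)
    em <- em[em[, 1L] != em[, 2L], , drop = FALSE]
    swap <- em[, 1L] > em[, 2L]
    em[swap, ] <- em[swap, c(2L, 1L), drop = FALSE]
    em <- unique(em)
    if (nrow(em) > 1L) {
      em <- em[order(em[, 1L], em[, 2L], method = "radix"), , drop = FALSE]
    }
  }
  nodes <- sort(unique(c(nodes, as.vector(em))), method = "radix")
  structure(list(nodes = nodes, edges = em), class = "pin")
}

#' @export
print.pin <- function(x, ...) {
  cat(sprintf("<pin> %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges in a network
#'
#' @param net A [pin()] network.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node degrees
#'
#' @param net A [pin()] network.
#' @return Named integer vector over all nodes (isolated nodes have 0).
#' @export
pin_degree <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges[, 1L], net$edges[, 2L]))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Convert to an igraph object
#'
#' Preserves isolated nodes. Used where standard graph algorithms
#' (components, shortest paths, PageRank) are delegated to igraph.
#'
#' @param net A [pin()] network.
#' @return An undirected `igraph` graph whose vertex `name` attribute holds
#'   the protein ids.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(from = net$edges[, 1L], to = net$edges[, 2L],
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

# Integer adjacency list: element i holds the indices (into net$nodes) of the
# neighbours of node i. Internal workhorse for the hand-written centralities
# and for fast unfolding.
adjacency_list <- function(net) {
  n <- length(net$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(net$edges) > 0L) {
    ei <- match(net$edges[, 1L], net$nodes)
    ej <- match(net$edges[, 2L], net$nodes)
    both <- split(c(ej, ei), c(ei, ej))
    idx <- as.integer(names(both))
    for (k in seq_along(both)) adj[[idx[k]]] <- sort(both[[k]])
  }
  adj
}

# Subgraph induced by a set of node ids: keeps those nodes and every edge
# with both endpoints inside.
induced_subnetwork <- function(net, keep) {
  keep <- intersect(net$nodes, keep)
  if (nrow(net$edges) == 0L) return(pin(nodes = keep))
  inside <- net$edges[, 1L] %in% keep & net$edges[, 2L] %in% keep
  pin(nodes = keep, edges = net$edges[inside, , drop = FALSE])
}
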