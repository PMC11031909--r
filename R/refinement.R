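#' Per-protein activity threshold from an expression profile
#'
#' A protein is called active at a time point when its expression exceeds a
#' protein-specific threshold set one standard deviation above its own mean,
#' tau = mu + sigma, with the population form of the standard deviation
#' (divide by n, not n - 1). This is the classical three-component rule used
#' to binarise time-course expression for dynamic PIN construction.
#'
#' @param expr Numeric vector of expression values over n time points.
#' @return List with components `mean`, `sd` (population) and `threshold`.
#' @examples
#' activity_threshold(c(1, 2, 3))
#' @export
activity_threshold <- function(expr) {
  if (length(expr) == 0L) stop("activity threshold needs at least one time point")
  if (any(!is.finite(expr))) stop("expression values must be finite")
  mu <- mean(expr)
  sigma <- sqrt(mean((expr - mu)^2))
  list(mean = mu, sd = sigma, threshold = mu + sigma)
}

# Boolean activity matrix for the proteins present in the expression matrix:
# TRUE where expression strictly exceeds the protein's own threshold.
activity_matrix <- function(expr) {
  mu <- rowMeans(expr)
  sigma <- sqrt(rowMeans((expr - mu)^2))
  expr > (mu + sigma)
}

#' Build the dynamic PIN (D-PIN)
#'
#' Keeps an interaction of the static network only if its two proteins are
#' active simultaneously at some time point of the expression time course
#' (activity per [activity_threshold()]). Proteins absent from the
#' expression matrix are treated as never active, so their interactions are
#' removed. The node set is preserved.
#'
#' @param spin Static network, a [pin()].
#' @param expr Numeric expression matrix (rows = proteins, columns = time
#'   points), as from [read_expression_matrix()].
#' @return A [pin()] with `V` unchanged and the co-activity-filtered edges.
#' @export
build_dpin <- function(spin, expr) {
  if (nrow(spin$edges) == 0L) return(spin)
  act <- activity_matrix(expr)
  u <- spin$edges[, 1L]
  v <- spin$edges[, 2L]
  iu <- match(u, rownames(act))
  iv <- match(v, rownames(act))
  keep <- !is.na(iu) & !is.na(iv)
  if (any(keep)) {
    co <- rowSums(act[iu[keep], , drop = FALSE] &
                  act[iv[keep], , drop = FALSE]) > 0L
    keep[keep] <- co
  }
  pin(nodes = spin$nodes, edges = spin$edges[keep, , drop = FALSE])
}

#' Build the twice-refined PIN (RD-PIN)
#'
#' Keeps an interaction of the D-PIN only if its two proteins share at least
#' one subcellular compartment (both have a positive evidence count in the
#' same compartment column). Proteins absent from the localization table
#' have all-zero counts and so lose their interactions. The node set is
#' preserved.
#'
#' @param dpin Dynamic network, a [pin()].
#' @param loc Integer localization count matrix (rows = proteins, columns =
#'   compartments), as from [read_localization_table()].
#' @return A [pin()] with `V` unchanged and the co-localization-filtered
#'   edges.
#' @export
build_rdpin <- function(dpin, loc) {
  if (nrow(dpin$edges) == 0L) return(dpin)
  present <- loc > 0L
  iu <- match(dpin$edges[, 1L], rownames(loc))
  iv <- match(dpin$edges[, 2L], rownames(loc))
  keep <- !is.na(iu) & !is.na(iv)
  if (any(keep)) {
    shared <- rowSums(present[iu[keep], , drop = FALSE] &
                      present[iv[keep], , drop = FALSE]) > 0L
    keep[keep] <- shared
  }
  pin(nodes = dpin$nodes, edges = dpin$edges[keep, , drop = FALSE])
}

#' Extract the maximal connected subgraph
#'
#' Real PINs are disconnected, with nearly all interactions inside one giant
#' component; module discovery is run on that component only. Returns the
#' subgraph induced by the largest connected component (nodes and edges).
#' Among equally large components the one containing the lexicographically
#' smallest node id is taken, a deterministic tie-break that never fires on
#' real data.
#'
#' @param net A [pin()] network.
#' @return A [pin()] holding only the largest component; an empty network
#'   maps to an empty network.
#' @export
maximal_connected_subgraph <- function(net) {
  if (length(net$nodes) == 0L) return(net)
  comp <- igraph::components(as_igraph(net))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest member id decides; membership order follows net$nodes
    first_member <- vapply(best, function(b) {
      min(net$nodes[comp$membership == b])
    }, character(1L))
    best <- best[order(first_member, method = "radix")][1L]
  }
  induced_subnetwork(net, net$nodes[comp$membership == best])
}
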