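# Node-ranking (centrality) registry. Each method maps a network to a
# score per protein; proteins are then ranked by descending score with ties
# broken by ascending id, so every ranking is a deterministic permutation
# of V. Standard path/eigenvector centralities are delegated to igraph;
# the neighbourhood methods (LAC, NC, DMNC) and LeaderRank are written out
# because no installed package provides them under these definitions.

centrality_registry <- new.env(parent = emptyenv())

#' Register a centrality method
#'
#' Extension point for additional node-ranking methods (e.g. the
#' expression-weighted PeC/WDC family): supply a function taking a [pin()]
#' and returning a named numeric score vector over all nodes.
#'
#' @param name Method name (case sensitive, conventionally upper case).
#' @param fn `function(net, ...)` returning a named numeric vector covering
#'   every node of `net`.
#' @return Invisibly, `name`.
#' @export
register_centrality <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = centrality_registry)
  invisible(name)
}

#' List registered centrality methods
#'
#' @return Sorted character vector of method names.
#' @export
centrality_methods <- function() {
  sort(ls(envir = centrality_registry))
}

#' Score proteins with a centrality method
#'
#' @param net A [pin()] network.
#' @param method Registered method name; see [centrality_methods()]. Built
#'   in: `DC` (degree), `CC` (Wasserman-Faust component-scaled closeness),
#'   `BC` (Brandes betweenness, normalized), `PR` (PageRank, damping 0.85),
#'   `LR` (LeaderRank with a ground node), `LAC` (local average
#'   connectivity), `NC` (node clustering via edge clustering
#'   coefficients), `DMNC` (density of the maximum neighbourhood component,
#'   epsilon = 1.7).
#' @param ... Passed to the method function.
#' @return Object of class `ranking_result`: list with `method`, `scores`
#'   (named numeric over V) and `ordering` (protein ids, best first).
#' @examples
#' star <- pin(edges = cbind(rep("hub", 3), c("a", "b", "c")))
#' compute_centrality(star, "DC")$ordering[1]
#' @export
compute_centrality <- function(net, method, ...) {
  if (!exists(method, envir = centrality_registry, inherits = FALSE)) {
    stop("unknown centrality method '", method, "'; registered: ",
         paste(centrality_methods(), collapse = ", "))
  }
  fn <- get(method, envir = centrality_registry)
  scores <- fn(net, ...)
  scores <- scores[net$nodes]
  if (anyNA(scores)) stop("method '", method, "' left nodes unscored")
  ordering <- net$nodes[order(-scores, net$nodes, method = "radix")]
  structure(list(method = method, scores = scores, ordering = ordering),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s over %d proteins; top: %s\n",
              x$method, length(x$scores),
              paste(utils::head(x$ordering, 3L), collapse = ", ")))
  invisible(x)
}

#' Top-k proteins of a ranking
#'
#' @param result A `ranking_result` from [compute_centrality()].
#' @param k Number of proteins to return, at most `|V|`.
#' @return Character vector of the first `k` protein ids of the
#'   deterministic ordering.
#' @export
rank_proteins <- function(result, k) {
  if (k > length(result$ordering)) {
    stop("k = ", k, " exceeds the number of proteins (",
         length(result$ordering), ")")
  }
  result$ordering[seq_len(k)]
}

# --- built-in methods -------------------------------------------------------

centrality_dc <- function(net, ...) {
  s <- as.numeric(pin_degree(net))
  names(s) <- net$nodes
  s
}

# Wasserman-Faust closeness: (r/(n-1)) * (r / sum of distances to the r
# reachable others); handles the disconnected refined networks where plain
# closeness is undefined. Isolated nodes score 0.
centrality_cc <- function(net, ...) {
  n <- length(net$nodes)
  s <- numeric(n)
  names(s) <- net$nodes
  if (n <= 1L || nrow(net$edges) == 0L) return(s)
  d <- igraph::distances(as_igraph(net))
  d <- d[net$nodes, net$nodes]
  for (v in seq_len(n)) {
    dv <- d[v, -v]
    reach <- is.finite(dv)
    r <- sum(reach)
    if (r > 0L) s[v] <- (r / (n - 1)) * (r / sum(dv[reach]))
  }
  s
}

centrality_bc <- function(net, ...) {
  g <- as_igraph(net)
  s <- igraph::betweenness(g, normalized = TRUE)
  s[net$nodes]
}

centrality_pr <- function(net, damping = 0.85, ...) {
  g <- as_igraph(net)
  s <- igraph::page_rank(g, damping = damping)$vector
  s[net$nodes]
}

# LeaderRank: add a ground node linked to every protein, iterate the
# uniform random-walk scores s_i <- sum_{j ~ i} s_j / k_j to convergence,
# then redistribute the ground node's score equally over all proteins.
centrality_lr <- function(net, tol = 1e-10, max_iter = 100000L, ...) {
  n <- length(net$nodes)
  s <- numeric(n)
  names(s) <- net$nodes
  if (n == 0L) return(s)
  a <- match(net$edges[, 1L], net$nodes)
  b <- match(net$edges[, 2L], net$nodes)
  g <- n + 1L
  from <- c(a, b, seq_len(n), rep(g, n))
  to <- c(b, a, rep(g, n), seq_len(n))
  k <- tabulate(from, nbins = g)
  sc <- c(rep(1, n), 0)
  contrib_idx <- from
  for (it in seq_len(max_iter)) {
    out <- sc[contrib_idx] / k[contrib_idx]
    new <- numeric(g)
    acc <- rowsum(out, to)
    new[as.integer(rownames(acc))] <- acc[, 1L]
    if (max(abs(new - sc)) < tol) {
      sc <- new
      break
    }
    sc <- new
  }
  s[] <- sc[seq_len(n)] + sc[g] / n
  s
}

# Local average connectivity: mean degree of the subgraph induced by the
# neighbourhood of v; 0 for isolated nodes.
centrality_lac <- function(net, ...) {
  adj <- adjacency_list(net)
  n <- length(net$nodes)
  s <- numeric(n)
  names(s) <- net$nodes
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    dv <- length(nb)
    if (dv == 0L) next
    internal <- vapply(nb, function(u) {
      length(intersect_sorted(adj[[u]], nb))
    }, integer(1L))
    s[v] <- sum(internal) / dv
  }
  s
}

# Node clustering centrality: NC(v) = sum over neighbours u of the edge
# clustering coefficient ECC(v,u) = |N(v) & N(u)| / min(deg v - 1,
# deg u - 1), taken as 0 when the denominator is 0.
centrality_nc <- function(net, ...) {
  adj <- adjacency_list(net)
  n <- length(net$nodes)
  deg <- lengths(adj)
  s <- numeric(n)
  names(s) <- net$nodes
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) == 0L) next
    s[v] <- sum(vapply(nb, function(u) {
      den <- min(deg[v] - 1L, deg[u] - 1L)
      if (den <= 0L) return(0)
      length(intersect_sorted(adj[[v]], adj[[u]])) / den
    }, numeric(1L)))
  }
  s
}

# Density of the maximum neighbourhood component: the neighbourhood of v
# induces a subgraph whose largest connected component M (by node count,
# ties by edge count then smallest node index) is scored |E(M)| /
# |V(M)|^eps with eps = 1.7.
centrality_dmnc <- function(net, eps = 1.7, ...) {
  adj <- adjacency_list(net)
  n <- length(net$nodes)
  s <- numeric(n)
  names(s) <- net$nodes
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 2L) next
    sub <- lapply(nb, function(u) intersect_sorted(adj[[u]], nb))
    names(sub) <- as.character(nb)
    comp <- components_from_adj(nb, sub)
    best <- NULL
    best_key <- c(-1, -1)
    for (cc in comp) {
      ne <- sum(lengths(sub[as.character(cc)])) / 2
      key <- c(length(cc), ne)
      if (key[1L] > best_key[1L] ||
          (key[1L] == best_key[1L] && key[2L] > best_key[2L])) {
        best <- cc
        best_key <- key
      }
    }
    ne <- sum(lengths(sub[as.character(best)])) / 2
    s[v] <- ne / length(best)^eps
  }
  s
}

# Intersection of two sorted integer vectors.
intersect_sorted <- function(x, y) x[match(x, y, nomatch = 0L) > 0L]

# Connected components of a small induced subgraph given as node ids `nb`
# and an adjacency list `sub` keyed by as.character(node id).
components_from_adj <- function(nb, sub) {
  seen <- logical(length(nb))
  names(seen) <- as.character(nb)
  out <- list()
  for (start in nb) {
    if (seen[[as.character(start)]]) next
    queue <- start
    comp <- integer()
    seen[[as.character(start)]] <- TRUE
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      comp <- c(comp, v)
      for (u in sub[[as.character(v)]]) {
        if (!seen[[as.character(u)]]) {
          seen[[as.character(u)]] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

local({
  register_centrality("DC", centrality_dc)
  register_centrality("CC", centrality_cc)
  register_centrality("BC", centrality_bc)
  register_centrality("PR", centrality_pr)
  register_centrality("LR", centrality_lr)
  register_centrality("LAC", centrality_lac)
  register_centrality("NC", centrality_nc)
  register_centrality("DMNC", centrality_dmnc)
})
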