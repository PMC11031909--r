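# Shared fixtures and independent oracles. The oracles deliberately use
# different computation routes (dense adjacency matrices, exhaustive
# enumeration, stats::cor, igraph) from the package implementations they
# check.

edge_keys_t <- function(net) {
  if (nrow(net$edges) == 0L) return(character())
  paste(net$edges[, 1L], net$edges[, 2L])
}

temp_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

make_triangle <- function() {
  pin(edges = cbind(c("A", "B", "C"), c("B", "C", "A")))
}

# two triangles joined by one bridge edge C-D (|E| = 7)
make_bowtie <- function() {
  pin(edges = cbind(c("A", "A", "B", "C", "D", "D", "E"),
                    c("B", "C", "C", "D", "E", "F", "F")))
}

make_path <- function(ids = c("A", "B", "C")) {
  pin(edges = cbind(ids[-length(ids)], ids[-1L]))
}

make_star <- function(n_leaves = 4L) {
  pin(edges = cbind(rep("hub", n_leaves), sprintf("leaf%d", seq_len(n_leaves))))
}

make_complete <- function(n) {
  ids <- sprintf("K%02d", seq_len(n))
  pairs <- t(combn(ids, 2L))
  pin(edges = pairs)
}

# Erdos-Renyi G(n, p) over zero-padded ids; optionally guarantees >= 1 edge.
random_gnp <- function(n, p, seed, min_edges = 1L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    ids <- sprintf("N%03d", seq_len(n))
    pairs <- t(combn(ids, 2L))
    repeat {
      sel <- runif(nrow(pairs)) < p
      if (sum(sel) >= min_edges) break
    }
    pin(nodes = ids, edges = pairs[sel, , drop = FALSE])
  })
}

dense_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    for (r in seq_len(nrow(net$edges))) {
      A[net$edges[r, 1L], net$edges[r, 2L]] <- 1
      A[net$edges[r, 2L], net$edges[r, 1L]] <- 1
    }
  }
  A
}

# Modularity straight from the pairwise definition
# Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) [same module], an independent
# route from the package's per-module e_ii - a_i^2 sums.
naive_modularity <- function(net, membership) {
  A <- dense_adjacency(net)
  k <- rowSums(A)
  m2 <- sum(k)
  mem <- membership[net$nodes]
  same <- outer(mem, mem, "==")
  sum((A - outer(k, k) / m2)[same]) / m2
}

# All set partitions of n labelled items as membership vectors (restricted
# growth strings); Bell(8) = 4140.
all_set_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  res
}

# Exhaustive maximum modularity over every partition of the node set.
brute_max_modularity <- function(net) {
  A <- dense_adjacency(net)
  k <- rowSums(A)
  m2 <- sum(k)
  B <- A - outer(k, k) / m2
  best <- -Inf
  for (mem in all_set_partitions(length(net$nodes))) {
    q <- sum(B[outer(mem, mem, "==")]) / m2
    if (q > best) best <- q
  }
  best
}

naive_lac <- function(net) {
  A <- dense_adjacency(net)
  sapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1)
    if (length(nb) == 0L) return(0)
    mean(rowSums(A[nb, nb, drop = FALSE]))
  }) -> s
  names(s) <- net$nodes
  s
}

naive_nc <- function(net) {
  A <- dense_adjacency(net)
  deg <- rowSums(A)
  s <- numeric(nrow(A))
  names(s) <- net$nodes
  for (v in seq_len(nrow(A))) {
    for (u in which(A[v, ] == 1)) {
      den <- min(deg[v] - 1, deg[u] - 1)
      if (den > 0) s[v] <- s[v] + sum(A[v, ] & A[u, ]) / den
    }
  }
  s
}

naive_dmnc <- function(net, eps = 1.7) {
  A <- dense_adjacency(net)
  s <- numeric(nrow(A))
  names(s) <- net$nodes
  for (v in seq_len(nrow(A))) {
    nb <- which(A[v, ] == 1)
    if (length(nb) < 2L) next
    sub <- A[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(g)
    cand <- which(comp$csize == max(comp$csize))
    ne_of <- function(cc) sum(sub[comp$membership == cc,
                                  comp$membership == cc]) / 2
    nes <- vapply(cand, ne_of, numeric(1L))
    s[v] <- max(nes) / max(comp$csize)^eps
  }
  s
}

# Normalized mutual information between two labelings over the same nodes.
nmi <- function(mem_a, mem_b) {
  nodes <- intersect(names(mem_a), names(mem_b))
  igraph::compare(as.integer(factor(mem_a[nodes])),
                  as.integer(factor(mem_b[nodes])), method = "nmi")
}

# A small annotated planted fixture for refinement-chain tests.
small_fixture <- function(seed) {
  cfg <- synthetic_config(module_sizes = rep(10L, 4L), p_in = 0.4,
                          p_out = 0.05)
  planted <- generate_network(cfg, seed)
  bundle <- generate_annotations(planted, cfg, seed)
  list(cfg = cfg, planted = planted, bundle = bundle)
}

# Ranking over an explicit ordering, for evaluation tests that need exact
# control of the permutation.
manual_ranking <- function(ordering, scores = NULL) {
  if (is.null(scores)) {
    scores <- seq(length(ordering), 1)
    names(scores) <- ordering
  }
  structure(list(method = "manual", scores = scores, ordering = ordering),
            class = "ranking_result")
}

# Node-set Jaccard index between two module selections.
node_jaccard <- function(part_a, mods_a, part_b, mods_b) {
  na <- names(part_a$membership)[part_a$membership %in% mods_a]
  nb <- names(part_b$membership)[part_b$membership %in% mods_b]
  length(intersect(na, nb)) / length(union(na, nb))
}
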