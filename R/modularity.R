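#' Modularity of a partition
#'
#' Newman's partition quality Q = sum_i (e_ii - a_i^2), where e_ii is the
#' fraction of edges with both endpoints inside module i and a_i is the
#' fraction of edge endpoints (half the summed degree over 2|E|) attached to
#' module i. Q lies in [-0.5, 1]; larger values mean connectivity is denser
#' inside modules than a degree-preserving random graph would give.
#'
#' @param net A [pin()] network with at least one edge.
#' @param membership A [module_partition()] or a named vector mapping every
#'   node of `net` to a module label.
#' @return The modularity Q as a single number.
#' @examples
#' tri <- pin(edges = cbind(c("A", "B", "C"), c("B", "C", "A")))
#' modularity_q(tri, c(A = 1, B = 1, C = 1)) # 0
#' @export
modularity_q <- function(net, membership) {
  if (inherits(membership, "module_partition")) {
    membership <- membership$membership
  }
  m <- nrow(net$edges)
  if (m == 0L) stop("modularity is undefined for a network with no edges")
  if (!all(net$nodes %in% names(membership))) {
    stop("every node of the network must be assigned to a module")
  }
  mem <- membership[net$nodes]
  mods <- sort(unique(as.character(mem)))
  mi <- match(as.character(mem), mods)
  names(mi) <- net$nodes
  e1 <- mi[net$edges[, 1L]]
  e2 <- mi[net$edges[, 2L]]
  within <- tabulate(e1[e1 == e2], nbins = length(mods))
  endpoint <- tabulate(c(e1, e2), nbins = length(mods))
  e_ii <- within / m
  a_i <- endpoint / (2 * m)
  sum(e_ii - a_i^2)
}

#' Canonical module partition
#'
#' Wraps a node-to-module assignment as a `module_partition`: module ids are
#' renumbered to the contiguous integers 1..m, ordered by the
#' lexicographically smallest node id each module contains, so partitions
#' are comparable across runs and node relabelings.
#'
#' @param membership Named vector (names = node ids) of module labels.
#' @param net Optional [pin()]; when given, the partition's modularity on
#'   `net` is computed and stored.
#' @return Object of class `module_partition` with components `membership`
#'   (named integer vector, canonical ids), `n_modules` and `modularity`.
#' @export
module_partition <- function(membership, net = NULL) {
  nodes <- names(membership)
  if (is.null(nodes) || any(!nzchar(nodes))) {
    stop("membership must be named by node id")
  }
  groups <- split(nodes, as.character(membership))
  mins <- vapply(groups, min, character(1L))
  relabel <- integer(length(groups))
  relabel[order(mins, method = "radix")] <- seq_along(groups)
  mem <- relabel[match(as.character(membership), names(groups))]
  names(mem) <- nodes
  mem <- mem[order(nodes, method = "radix")]
  q <- if (is.null(net)) NA_real_ else modularity_q(net, mem)
  structure(list(membership = mem,
                 n_modules = length(groups),
                 modularity = q),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d nodes in %d modules (Q = %s)\n",
              length(x$membership), x$n_modules,
              formatC(x$modularity, digits = 4, format = "f")))
  invisible(x)
}

#' Module discovery by fast unfolding (Louvain)
#'
#' Greedy two-phase modularity optimisation: (1) local moving - nodes are
#' repeatedly offered to the neighbouring module with the best modularity
#' gain, and a move is accepted only when the gain is strictly positive;
#' (2) aggregation - modules are collapsed to super-nodes (internal edges
#' become self-loops) and phase 1 is repeated on the smaller graph, until a
#' whole level makes no move. The per-move gain uses the standard
#' constant-time Louvain formula; the running Q is recorded after every
#' accepted move and is strictly increasing, which both bounds the runtime
#' and exposes the optimisation trace for verification.
#'
#' @param net A connected [pin()] with at least one edge (apply
#'   [maximal_connected_subgraph()] first; disconnected input is still
#'   processed but the method is defined on the giant component).
#' @param seed Integer seed controlling the visit order when
#'   `order = "shuffled"`; ignored for `order = "sorted"`.
#' @param order `"sorted"` visits nodes in lexicographic id order
#'   (deterministic without a seed); `"shuffled"` draws a fresh seeded
#'   permutation each sweep.
#' @return A [module_partition()] over the nodes of `net` with components
#'   `modularity` (equal to [modularity_q()] on the result) and `trace`
#'   (numeric vector of Q after each accepted move).
#' @examples
#' bowtie <- pin(edges = cbind(c("A", "A", "B", "C", "D", "D", "E"),
#'                             c("B", "C", "C", "D", "E", "F", "F")))
#' part <- fast_unfolding(bowtie)
#' part$modularity # 5/14
#' @export
fast_unfolding <- function(net, seed = 1L, order = c("sorted", "shuffled")) {
  order <- match.arg(order)
  if (nrow(net$edges) == 0L) {
    stop("fast unfolding is undefined for a network with no edges")
  }
  nodes <- net$nodes
  n0 <- length(nodes)
  a <- match(net$edges[, 1L], nodes)
  b <- match(net$edges[, 2L], nodes)
  w <- rep(1, length(a))
  m <- sum(w)

  # singleton-partition modularity of the original graph
  deg0 <- numeric(n0)
  tmp <- rowsum(c(w, w), c(a, b))
  deg0[as.integer(rownames(tmp))] <- tmp[, 1L]
  q <- -sum((deg0 / (2 * m))^2)

  node_comm <- seq_len(n0) # original node -> current super-node
  nv <- n0
  trace <- numeric()
  sweep_counter <- 0L

  repeat {
    lvl <- louvain_level(nv, a, b, w, m, q, order, seed, sweep_counter)
    q <- lvl$q
    trace <- c(trace, lvl$trace)
    sweep_counter <- lvl$sweep_counter
    if (!lvl$moved) break
    comm <- match(lvl$comm, sort(unique(lvl$comm)))
    node_comm <- comm[node_comm]
    nc <- max(comm)
    if (nc == nv) break
    # aggregate: module -> super-node, internal edges -> self-loops
    lo <- pmin(comm[a], comm[b])
    hi <- pmax(comm[a], comm[b])
    agg <- rowsum(w, paste(lo, hi))
    pair <- strsplit(rownames(agg), " ", fixed = TRUE)
    a <- vapply(pair, function(p) as.integer(p[1L]), integer(1L))
    b <- vapply(pair, function(p) as.integer(p[2L]), integer(1L))
    w <- agg[, 1L]
    nv <- nc
  }

  names(node_comm) <- nodes
  part <- module_partition(node_comm, net = net)
  part$trace <- trace
  part$order <- order
  part$seed <- as.integer(seed)
  part
}

# One local-moving level of fast unfolding on a (possibly weighted,
# self-looped) graph with nv super-nodes. Returns the super-node community
# assignment, the updated global Q, the per-move Q trace, and whether any
# move was accepted.
louvain_level <- function(nv, a, b, w, m, q0, order, seed, sweep_counter) {
  sl <- a == b
  self_w <- numeric(nv)
  if (any(sl)) {
    acc <- rowsum(w[sl], a[sl])
    self_w[as.integer(rownames(acc))] <- acc[, 1L]
  }
  aa <- a[!sl]
  bb <- b[!sl]
  ww <- w[!sl]
  k <- 2 * self_w
  if (length(aa)) {
    tmp <- rowsum(c(ww, ww), c(aa, bb))
    k[as.integer(rownames(tmp))] <- k[as.integer(rownames(tmp))] + tmp[, 1L]
  }
  nbr <- vector("list", nv)
  nbw <- vector("list", nv)
  if (length(aa)) {
    all_from <- c(aa, bb)
    all_to <- c(bb, aa)
    all_w <- c(ww, ww)
    sp <- split(seq_along(all_from), all_from)
    for (nm in names(sp)) {
      i <- as.integer(nm)
      nbr[[i]] <- all_to[sp[[nm]]]
      nbw[[i]] <- all_w[sp[[nm]]]
    }
  }

  comm <- seq_len(nv)
  comm_k <- k
  q <- q0
  trace <- numeric()
  moved_any <- FALSE
  tol <- 1e-12

  repeat {
    moved_pass <- FALSE
    visit <- if (order == "sorted") {
      seq_len(nv)
    } else {
      sweep_counter <- sweep_counter + 1L
      with_seed(derive_seed(seed, "shuffle") + sweep_counter, sample.int(nv))
    }
    for (v in visit) {
      nb <- nbr[[v]]
      if (length(nb) == 0L) next
      cv <- comm[v]
      wsum <- rowsum(nbw[[v]], comm[nb])
      cand <- as.integer(rownames(wsum))
      wvec <- wsum[, 1L]
      own <- match(cv, cand)
      w_own <- if (is.na(own)) 0 else wvec[own]
      comm_k[cv] <- comm_k[cv] - k[v] # take v out of its community
      gains <- unname(wvec / m - k[v] * comm_k[cand] / (2 * m * m))
      gain_stay <- unname(w_own / m - k[v] * comm_k[cv] / (2 * m * m))
      best <- which(gains == max(gains))
      best <- best[which.min(cand[best])]
      dq <- gains[best] - gain_stay
      if (cand[best] != cv && dq > tol) {
        comm[v] <- cand[best]
        comm_k[cand[best]] <- comm_k[cand[best]] + k[v]
        q <- q + dq
        trace <- c(trace, q)
        moved_pass <- TRUE
        moved_any <- TRUE
      } else {
        comm_k[cv] <- comm_k[cv] + k[v]
      }
    }
    if (!moved_pass) break
  }
  list(comm = comm, q = q, trace = trace, moved = moved_any,
       sweep_counter = sweep_counter)
}
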