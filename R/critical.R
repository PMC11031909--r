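#' Orthology correlation score of each module
#'
#' For each module, the Pearson correlation PC between the module's 0/1
#' membership indicator and the vector of orthology scores, both taken over
#' the clustered proteins (the nodes the partition covers). Essential
#' proteins are evolutionarily conserved, so modules whose members carry
#' high orthology scores are candidate critical modules. Proteins absent
#' from the score table count as score 0. The correlation is undefined
#' (reported `NA`) when either vector is constant - a module covering all
#' or none of the clustered nodes, or a constant score vector.
#'
#' @param part A [module_partition()].
#' @param orth Named integer vector of orthology scores, as from
#'   [read_orthology_scores()].
#' @return Named numeric vector, one PC per module id.
#' @export
orthology_correlation <- function(part, orth) {
  nodes <- names(part$membership)
  y <- unname(orth[nodes])
  y[is.na(y)] <- 0
  vapply(seq_len(part$n_modules), function(i) {
    pearson_raw(as.numeric(part$membership == i), y)
  }, numeric(1L))
}

# Pearson correlation from its raw sum definition; NA when either argument
# has zero variance. Kept separate so tests can compare against stats::cor.
pearson_raw <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sum((x - mx) * (y - my)) / sqrt(sxx * syy)
}

#' Nuclear localization score of each module
#'
#' NSL(c) = N(c) / n(c): the summed nucleus evidence count of the module's
#' proteins divided by the module size. Proteins (and essential proteins in
#' particular) are most widely distributed in the nucleus, so a high NSL
#' flags a candidate critical module. Counts may exceed 1 per protein, so
#' NSL is not bounded by 1. Proteins missing from the table count 0.
#'
#' @param part A [module_partition()].
#' @param loc Localization count matrix, as from
#'   [read_localization_table()].
#' @param nucleus Name of the nucleus compartment column.
#' @return Named numeric vector, one NSL per module id.
#' @export
nucleus_score <- function(part, loc, nucleus = "nucleus") {
  if (!nucleus %in% colnames(loc)) {
    stop("no compartment named '", nucleus, "' in the localization table")
  }
  nodes <- names(part$membership)
  counts <- loc[match(nodes, rownames(loc)), nucleus]
  counts[is.na(counts)] <- 0L
  sums <- rowsum(as.numeric(counts), part$membership)
  sizes <- tabulate(part$membership, nbins = part$n_modules)
  out <- numeric(part$n_modules)
  out[as.integer(rownames(sums))] <- sums[, 1L]
  out / sizes
}

#' Topology score of each module
#'
#' TF(c) = (I(c) - O(c)) / n(c), with I the number of interactions inside
#' the module and O the number crossing its boundary. Densely
#' self-connected modules score high; modules dominated by boundary edges
#' score low (TF may be negative) and are candidate non-critical modules.
#'
#' @param net The clustered [pin()] (the graph the partition was computed
#'   on).
#' @param part A [module_partition()].
#' @return Named numeric vector, one TF per module id.
#' @export
topology_score <- function(net, part) {
  io <- module_edge_counts(net, part)
  (io$internal - io$boundary) / io$size
}

# Internal/boundary edge counts and sizes per module of a partition.
module_edge_counts <- function(net, part) {
  mem <- part$membership
  e1 <- mem[net$edges[, 1L]]
  e2 <- mem[net$edges[, 2L]]
  ok <- !is.na(e1) & !is.na(e2)
  e1 <- e1[ok]
  e2 <- e2[ok]
  nm <- part$n_modules
  internal <- tabulate(e1[e1 == e2], nbins = nm)
  cross <- e1 != e2
  boundary <- tabulate(c(e1[cross], e2[cross]), nbins = nm)
  size <- tabulate(mem, nbins = nm)
  list(internal = internal, boundary = boundary, size = size)
}

#' Score every module of a partition
#'
#' Convenience wrapper assembling the per-module score table used for
#' critical-module selection: size, internal edges I, boundary edges O, the
#' orthology correlation PC, the nuclear localization score NSL and the
#' topology score TF.
#'
#' @inheritParams orthology_correlation
#' @inheritParams nucleus_score
#' @param net The clustered [pin()] the partition was computed on.
#' @return `data.frame` with columns `module`, `size`, `I`, `O`, `PC`,
#'   `NSL`, `TF`.
#' @export
module_scores <- function(net, part, orth, loc, nucleus = "nucleus") {
  io <- module_edge_counts(net, part)
  data.frame(
    module = seq_len(part$n_modules),
    size = io$size,
    I = io$internal,
    O = io$boundary,
    PC = orthology_correlation(part, orth),
    NSL = nucleus_score(part, loc, nucleus),
    TF = topology_score(net, part)
  )
}

#' Select critical modules from a score table
#'
#' Applies the three threshold rules and combines them:
#' `C_orth = {PC >= th1}` (modules with undefined PC are excluded),
#' `C_sub = {NSL >= th2}`, `C_topo = {TF <= th3}` (potentially
#' non-critical), and the final set
#' `C_critical = C_orth | (C_sub \ C_topo)`. All inequalities are
#' inclusive; `th3` is typically small and may be negative.
#'
#' @param scores Score table from [module_scores()].
#' @param th1 PC cutoff for the orthology rule.
#' @param th2 NSL cutoff for the localization rule.
#' @param th3 TF cutoff below which a module is potentially non-critical.
#' @return Object of class `critical_module_set`: list with integer-vector
#'   components `C_orth`, `C_sub`, `C_topo`, `C_critical` and the thresholds
#'   used.
#' @export
select_critical_modules <- function(scores, th1 = 0.1, th2 = 2, th3 = 0.25) {
  stopifnot(is.finite(th1), is.finite(th2), is.finite(th3))
  c_orth <- scores$module[!is.na(scores$PC) & scores$PC >= th1]
  c_sub <- scores$module[scores$NSL >= th2]
  c_topo <- scores$module[scores$TF <= th3]
  structure(list(
    C_orth = c_orth,
    C_sub = c_sub,
    C_topo = c_topo,
    C_critical = sort(union(c_orth, setdiff(c_sub, c_topo))),
    thresholds = c(th1 = th1, th2 = th2, th3 = th3)
  ), class = "critical_module_set")
}

#' @export
print.critical_module_set <- function(x, ...) {
  cat(sprintf(
    "<critical_module_set> %d critical (orth %d, sub %d, topo %d) at th = (%g, %g, %g)\n",
    length(x$C_critical), length(x$C_orth), length(x$C_sub), length(x$C_topo),
    x$thresholds[["th1"]], x$thresholds[["th2"]], x$thresholds[["th3"]]))
  invisible(x)
}

#' Build the critical-module PIN (CM-PIN)
#'
#' The refined network keeps an interaction if and only if both endpoints
#' lie in critical modules (the two endpoints may sit in two different
#' critical modules). Edges with an endpoint outside the clustered
#' component, or in a non-critical module, are removed. The node set is
#' unchanged, so proteins stripped of all interactions remain as isolated
#' nodes.
#'
#' @param original The network being refined (typically the S-PIN, D-PIN or
#'   RD-PIN the partition's component was extracted from).
#' @param part The [module_partition()] of the maximal connected subgraph of
#'   `original`.
#' @param critical A `critical_module_set` from
#'   [select_critical_modules()], or an integer vector of module ids.
#' @return A [pin()] with `V` unchanged and only critical-module edges.
#' @export
build_cmpin <- function(original, part, critical) {
  if (inherits(critical, "critical_module_set")) {
    critical <- critical$C_critical
  }
  if (nrow(original$edges) == 0L) return(original)
  mem <- part$membership
  m1 <- mem[original$edges[, 1L]]
  m2 <- mem[original$edges[, 2L]]
  keep <- !is.na(m1) & !is.na(m2) & m1 %in% critical & m2 %in% critical
  pin(nodes = original$nodes, edges = original$edges[keep, , drop = FALSE])
}

#' Sweep the selection thresholds over a grid
#'
#' Evaluates every combination of the supplied `th1`, `th2`, `th3` values,
#' reporting the number of critical modules selected and, optionally,
#' metrics of the resulting CM-PIN computed by a caller-supplied hook.
#'
#' @inheritParams build_cmpin
#' @param scores Score table from [module_scores()].
#' @param th1,th2,th3 Numeric vectors of candidate thresholds.
#' @param metrics Optional `function(cmpin)` returning a named numeric
#'   vector appended to each row (e.g. essential-protein counts of a
#'   ranking run on the refined network).
#' @return `data.frame` with one row per threshold combination: `th1`,
#'   `th2`, `th3`, `n_critical`, plus any metric columns.
#' @export
threshold_sweep <- function(original, part, scores, th1, th2, th3,
                            metrics = NULL) {
  stopifnot(length(th1) > 0L, length(th2) > 0L, length(th3) > 0L)
  grid <- expand.grid(th1 = th1, th2 = th2, th3 = th3,
                      KEEP.OUT.ATTRS = FALSE)
  extra <- NULL
  n_crit <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    sel <- select_critical_modules(scores, grid$th1[r], grid$th2[r],
                                   grid$th3[r])
    n_crit[r] <- length(sel$C_critical)
    if (!is.null(metrics)) {
      vals <- metrics(build_cmpin(original, part, sel))
      if (is.null(extra)) {
        extra <- matrix(NA_real_, nrow(grid), length(vals),
                        dimnames = list(NULL, names(vals)))
      }
      extra[r, ] <- vals
    }
  }
  out <- cbind(grid, n_critical = n_crit)
  if (!is.null(extra)) out <- cbind(out, as.data.frame(extra))
  out
}
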