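#' Run the full refinement and evaluation pipeline
#'
#' Chains the whole method: (optionally) refine the static network into the
#' D-PIN and RD-PIN, extract the maximal connected subgraph, partition it
#' by fast unfolding, score the modules, select the critical modules, build
#' the CM-PIN, rank proteins on both the base network and the CM-PIN with
#' the requested centrality methods, and evaluate each ranking against the
#' essential-protein reference (confusion metrics at K = P, top-k counts,
#' jackknife and precision-recall curves). All inputs may be given as file
#' paths (read with the package readers) or as in-memory objects.
#'
#' @param network A [pin()] or edge-list path (the S-PIN).
#' @param orthology Named integer vector or orthology TSV path.
#' @param localization Integer count matrix or localization TSV path.
#' @param essential Character vector or protein-list path.
#' @param expression Numeric matrix or expression TSV path; required when
#'   `refine` is `"dpin"` or `"rdpin"`.
#' @param refine Which refined variant to partition and build the CM-PIN
#'   from: `"none"` (the S-PIN itself), `"dpin"` or `"rdpin"`.
#' @param th1,th2,th3 Critical-module selection thresholds, see
#'   [select_critical_modules()].
#' @param methods Character vector of centrality methods to run.
#' @param topk Integer cutoffs for the top-k essential counts.
#' @param nucleus Nucleus compartment column name.
#' @param seed,order Passed to [fast_unfolding()].
#' @param out_dir Optional directory; when given, the partition, module
#'   scores, CM-PIN edge list, per-method rankings and a JSON report are
#'   written there.
#' @return Object of class `cmpin_report`: list with the networks
#'   (`base`, `cmpin`), `partition`, `scores`, `selection`, and per-method
#'   `rankings` / `evaluation` (each evaluation holds the base-network and
#'   CM-PIN metrics, top-k counts and PRAUC side by side).
#' @export
run_pipeline <- function(network, orthology, localization, essential,
                         expression = NULL,
                         refine = c("none", "dpin", "rdpin"),
                         th1 = 0.1, th2 = 2, th3 = 0.25,
                         methods = c("DC", "LAC"),
                         topk = c(25L, 50L, 100L),
                         nucleus = "nucleus",
                         seed = 1L, order = "sorted",
                         out_dir = NULL) {
  refine <- match.arg(refine)
  if (is.character(network)) network <- read_edge_list(network)
  if (is.character(orthology)) orthology <- read_orthology_scores(orthology)
  if (is.character(localization)) {
    localization <- read_localization_table(localization)
  }
  # `essential` in memory is itself a character vector of ids; only a
  # single existing path is read as a file
  if (is.character(essential) && length(essential) == 1L &&
      file.exists(essential)) {
    essential <- read_protein_list(essential)
  }
  if (is.character(expression)) expression <- read_expression_matrix(expression)

  base <- network
  if (refine %in% c("dpin", "rdpin")) {
    if (is.null(expression)) {
      stop("pipeline stage dpin: an expression matrix is required")
    }
    base <- build_dpin(base, expression)
  }
  if (refine == "rdpin") base <- build_rdpin(base, localization)

  core <- maximal_connected_subgraph(base)
  if (n_edges(core) == 0L) {
    stop("pipeline stage modules: the maximal connected subgraph has no edges")
  }
  part <- fast_unfolding(core, seed = seed, order = order)
  scores <- module_scores(core, part, orthology, localization, nucleus)
  selection <- select_critical_modules(scores, th1, th2, th3)
  cmpin <- build_cmpin(base, part, selection)

  rankings <- list()
  evaluation <- list()
  for (mth in methods) {
    rk_base <- compute_centrality(base, mth)
    rk_cm <- compute_centrality(cmpin, mth)
    rankings[[mth]] <- list(base = rk_base, cmpin = rk_cm)
    evaluation[[mth]] <- list(
      base = evaluate_ranking(rk_base, essential, topk),
      cmpin = evaluate_ranking(rk_cm, essential, topk)
    )
  }

  report <- structure(list(
    refine = refine, base = base, cmpin = cmpin, partition = part,
    scores = scores, selection = selection, rankings = rankings,
    evaluation = evaluation,
    summary = list(
      n_proteins = n_nodes(base), n_edges_base = n_edges(base),
      n_edges_cmpin = n_edges(cmpin), n_modules = part$n_modules,
      modularity = part$modularity,
      n_critical = length(selection$C_critical))
  ), class = "cmpin_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# One ranking's evaluation block: confusion metrics at K = P, top-k
# counts, PRAUC and the jackknife curve.
evaluate_ranking <- function(ranking, essential, topk) {
  ess <- essential_in(ranking, essential)
  p <- length(ess)
  out <- list(P = p, topk = topk_counts(ranking, essential,
                                        pmin(topk, length(ranking$ordering))))
  if (p > 0L) {
    out$metrics <- classification_metrics(confusion_at_k(ranking, essential, p))
    out$prauc <- pr_curve(ranking, essential)$prauc
    out$jackknife <- jackknife_curve(ranking, essential)
  }
  out
}

# Write pipeline artifacts: partition and score tables, the CM-PIN edge
# list, per-method rankings, and a JSON report of the summary numbers.
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  part <- report$partition
  writeLines(c("protein\tmodule",
               paste(names(part$membership), part$membership, sep = "\t")),
             file.path(out_dir, "partition.tsv"))
  utils::write.table(report$scores, file.path(out_dir, "module_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(report$cmpin, file.path(out_dir, "cmpin.tsv"))
  for (mth in names(report$rankings)) {
    rk <- report$rankings[[mth]]$cmpin
    writeLines(c("rank\tprotein\tscore",
                 paste(seq_along(rk$ordering), rk$ordering,
                       as.character(unname(rk$scores[rk$ordering])),
                       sep = "\t")),
               file.path(out_dir, paste0("ranks_", mth, ".tsv")))
  }
  json <- list(summary = report$summary,
               selection = report$selection[c("C_orth", "C_sub", "C_topo",
                                              "C_critical")],
               evaluation = lapply(report$evaluation, function(ev) {
                 lapply(ev, function(side) {
                   side[c("P", "topk", "metrics", "prauc")]
                 })
               }))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cmpin_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cmpin_report> %s base: %d proteins, %d edges -> CM-PIN %d edges; %d modules (Q = %.4f), %d critical\n",
    x$refine, s$n_proteins, s$n_edges_base, s$n_edges_cmpin, s$n_modules,
    s$modularity, s$n_critical))
  invisible(x)
}
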