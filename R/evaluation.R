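# Evaluation of rankings against a reference essential-protein set:
# confusion matrices at a cutoff, the seven derived metrics, top-k counts,
# jackknife curves, precision-recall curves with average precision, and
# pairwise overlap analysis.

# Positives are network-relative by default: essential proteins absent from
# the ranked network cannot be retrieved and are excluded from P.
essential_in <- function(ranking, essential, network_relative = TRUE) {
  if (network_relative) intersect(essential, ranking$ordering) else essential
}

#' Confusion matrix at a ranking cutoff
#'
#' The top `k` proteins of the ranking are predicted essential; the rest
#' non-essential. `TP` counts reference essentials inside the top `k`,
#' `FP = k - TP`, `FN = P - TP`, `TN = N - k - FN`, where `P` is the number
#' of reference essentials in the network and `N` the number of proteins.
#'
#' @param ranking A `ranking_result` from [compute_centrality()].
#' @param essential Character vector of reference essential protein ids.
#' @param k Cutoff, at most `|V|`.
#' @param network_relative If `TRUE` (default) essentials absent from the
#'   network are excluded from `P`.
#' @return Object of class `confusion_matrix`: list with `TP`, `FP`, `TN`,
#'   `FN`, `K`, `P`, `N`.
#' @export
confusion_at_k <- function(ranking, essential, k, network_relative = TRUE) {
  n <- length(ranking$ordering)
  if (k > n) stop("k = ", k, " exceeds the number of proteins (", n, ")")
  ess <- essential_in(ranking, essential, network_relative)
  p <- length(ess)
  tp <- sum(ranking$ordering[seq_len(k)] %in% ess)
  confusion_matrix(TP = tp, FP = k - tp, FN = p - tp, TN = n - k - (p - tp))
}

#' Assemble a confusion matrix from its cells
#'
#' @param TP,FP,FN,TN Nonnegative integer cell counts.
#' @return Object of class `confusion_matrix` with the cells plus the
#'   derived `K = TP + FP`, `P = TP + FN` and `N` (total).
#' @export
confusion_matrix <- function(TP, FP, FN, TN) {
  cells <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be nonnegative integers")
  }
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 K = TP + FP, P = TP + FN, N = TP + FP + FN + TN),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FP %d  FN %d  TN %d  (K = %d, P = %d, N = %d)\n",
              x$TP, x$FP, x$FN, x$TN, x$K, x$P, x$N))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' The seven standard metrics: sensitivity `SN = TP/(TP+FN)`, specificity
#' `SP = TN/(FP+TN)`, positive predictive value `PPV = TP/(TP+FP)`,
#' negative predictive value `NPV = TN/(TN+FN)`, F-measure
#' `FM = 2*SN*PPV/(SN+PPV)`, Matthews correlation coefficient `MCC` and
#' accuracy `ACC`. When the cutoff equals the number of positives
#' (`K = P`), the identities `FP = FN` force `SN = PPV = FM` and
#' `SP = NPV`. A metric whose denominator is zero is reported `NA`.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector `SN`, `SP`, `PPV`, `NPV`, `FM`, `MCC`,
#'   `ACC`.
#' @examples
#' classification_metrics(confusion_matrix(TP = 567, FP = 563,
#'                                         FN = 563, TN = 3053))
#' @export
classification_metrics <- function(cm) {
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sn <- frac(cm$TP, cm$TP + cm$FN)
  sp <- frac(cm$TN, cm$FP + cm$TN)
  ppv <- frac(cm$TP, cm$TP + cm$FP)
  npv <- frac(cm$TN, cm$TN + cm$FN)
  # TP = 0 gives SN = PPV = 0 and a 0/0 harmonic mean; the ranked-retrieval
  # convention scores that F-measure as 0
  fm <- if (is.na(sn) || is.na(ppv)) NA_real_ else {
    if ((sn + ppv) == 0) 0 else 2 * sn * ppv / (sn + ppv)
  }
  mcc_den <- sqrt(prod(c(cm$TP + cm$FP, cm$TP + cm$FN,
                         cm$TN + cm$FP, cm$TN + cm$FN)))
  mcc <- if (mcc_den == 0) NA_real_ else {
    (cm$TP * cm$TN - cm$FP * cm$FN) / mcc_den
  }
  acc <- frac(cm$TP + cm$TN, cm$N)
  c(SN = sn, SP = sp, PPV = ppv, NPV = npv, FM = fm, MCC = mcc, ACC = acc)
}

#' Essential-protein counts at several cutoffs
#'
#' @param ranking A `ranking_result`.
#' @param essential Character vector of reference essential ids.
#' @param ks Integer vector of cutoffs (each at most `|V|`).
#' @inheritParams confusion_at_k
#' @return Named integer vector of essential counts within each top-k
#'   prefix; non-decreasing in `k`.
#' @export
topk_counts <- function(ranking, essential, ks,
                        network_relative = TRUE) {
  ess <- essential_in(ranking, essential, network_relative)
  cum <- cumsum(ranking$ordering %in% ess)
  out <- integer(length(ks))
  names(out) <- as.character(ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k > length(cum)) stop("k = ", k, " exceeds the number of proteins")
    out[i] <- if (k == 0L) 0L else cum[k]
  }
  out
}

#' Jackknife curve of a ranking
#'
#' Cumulative count of reference essential proteins versus rank position,
#' over the full ordering; the final value is the number of essentials in
#' the network. Plotting several methods' curves on one set of axes is the
#' classical jackknife comparison.
#'
#' @inheritParams topk_counts
#' @return `data.frame` with columns `rank` (1..|V|) and `essential_count`.
#' @export
jackknife_curve <- function(ranking, essential, network_relative = TRUE) {
  ess <- essential_in(ranking, essential, network_relative)
  data.frame(rank = seq_along(ranking$ordering),
             essential_count = cumsum(ranking$ordering %in% ess))
}

#' Precision-recall curve and average precision
#'
#' One point per ranked prefix k = 1..|V| with precision `TP/k` and recall
#' `TP/P`. The area under the curve (PRAUC) is computed by the step-wise
#' average-precision rule of ranked retrieval: the mean, over the `P`
#' positives, of the precision at each positive's rank (positives never
#' retrieved contribute 0).
#'
#' @inheritParams topk_counts
#' @return List with `points` (`data.frame` of `recall`, `precision`) and
#'   `prauc`.
#' @export
pr_curve <- function(ranking, essential, network_relative = TRUE) {
  ess <- essential_in(ranking, essential, network_relative)
  p <- length(ess)
  if (p == 0L) stop("precision-recall curve needs at least one positive")
  hit <- ranking$ordering %in% ess
  tp <- cumsum(hit)
  kk <- seq_along(hit)
  precision <- tp / kk
  recall <- tp / p
  prauc <- sum(precision[hit]) / p
  list(points = data.frame(recall = recall, precision = precision),
       prauc = prauc)
}

#' Overlap of the essential hits of two rankings
#'
#' Compares the reference essentials retrieved in the top `k` of two
#' rankings: which are found by both, and which are unique to either - the
#' analysis used to show that a refined network surfaces essential proteins
#' the unrefined one misses.
#'
#' @param rank_a,rank_b `ranking_result` objects over comparable node sets.
#' @param essential Character vector of reference essential ids.
#' @param k Cutoff applied to both rankings.
#' @return List with `shared`, `unique_a`, `unique_b` (character vectors)
#'   and `ratios` (fractions of each ranking's hits that are unique).
#' @export
overlap_analysis <- function(rank_a, rank_b, essential, k) {
  hits_a <- intersect(rank_proteins(rank_a, k), essential)
  hits_b <- intersect(rank_proteins(rank_b, k), essential)
  shared <- intersect(hits_a, hits_b)
  ua <- setdiff(hits_a, hits_b)
  ub <- setdiff(hits_b, hits_a)
  ratio <- function(u, h) if (length(h) == 0L) 0 else length(u) / length(h)
  list(shared = sort(shared), unique_a = sort(ua), unique_b = sort(ub),
       ratios = c(unique_a = ratio(ua, hits_a), unique_b = ratio(ub, hits_b)))
}
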