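test_that("confusion matrix at k counts hits and preserves identities", {
  ids <- sprintf("P%d", 1:6)
  rk <- manual_ranking(ids)
  ess <- c("P2", "P6")
  cm <- confusion_at_k(rk, ess, 3)
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN), c(1, 2, 1, 2))
  expect_equal(cm$K, 3)
  expect_equal(cm$P, 2)
  expect_equal(cm$N, 6)

  perfect <- manual_ranking(c("P2", "P6", "P1", "P3", "P4", "P5"))
  cmp <- confusion_at_k(perfect, ess, 2)
  expect_equal(c(cmp$FP, cmp$FN), c(0, 0))

  worst <- confusion_at_k(manual_ranking(ids), c("P5", "P6"), 2)
  expect_equal(c(worst$TP, worst$FP), c(0, 2))

  expect_error(confusion_at_k(rk, ess, 7), "exceeds")
  expect_error(confusion_matrix(-1, 0, 0, 0), "nonnegative")
})

test_that("essentials absent from the network are excluded from P by default", {
  rk <- manual_ranking(c("A", "B"))
  cm <- confusion_at_k(rk, c("A", "GHOST"), 1)
  expect_equal(cm$P, 1)
  cm2 <- confusion_at_k(rk, c("A", "GHOST"), 1, network_relative = FALSE)
  expect_equal(cm2$P, 2)
})

test_that("classification metrics reproduce degenerate closed forms", {
  perfect <- classification_metrics(confusion_matrix(5, 0, 0, 5))
  expect_equal(unname(perfect), rep(1, 7))

  chance <- classification_metrics(confusion_matrix(3, 3, 3, 3))
  expect_equal(unname(chance["MCC"]), 0)
  expect_equal(unname(chance["ACC"]), 0.5)

  # with FP = FN, MCC reduces to (TP*TN - FP^2) / ((TP+FP)(TN+FP))
  m <- classification_metrics(confusion_matrix(40, 10, 10, 90))
  expect_equal(unname(m["MCC"]), (40 * 90 - 100) / ((40 + 10) * (90 + 10)))

  none <- classification_metrics(confusion_matrix(0, 0, 0, 4))
  expect_true(is.na(none["SN"]))
  expect_equal(unname(none["SP"]), 1)
})

test_that("cutting at K = P forces SN = PPV = FM and SP = NPV", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:200, 1)
    ids <- sprintf("P%03d", seq_len(n))
    ess <- sample(ids, sample(2:(n - 2), 1))
    rk <- manual_ranking(sample(ids))
    m <- classification_metrics(confusion_at_k(rk, ess, length(ess)))
    expect_equal(m[["SN"]], m[["PPV"]])
    expect_equal(m[["SN"]], m[["FM"]])
    expect_equal(m[["SP"]], m[["NPV"]])
  }
})

test_that("top-k counts are prefix sums consistent with the confusion matrix", {
  set.seed(42)
  ids <- sprintf("P%03d", 1:100)
  ess <- sample(ids, 30)
  rk <- manual_ranking(sample(ids))
  ks <- c(0, 10, 25, 50, 100)
  counts <- topk_counts(rk, ess, ks)
  expect_equal(unname(counts[1]), 0)
  expect_true(all(diff(counts) >= 0))
  for (k in ks[-1]) {
    expect_equal(unname(counts[as.character(k)]),
                 confusion_at_k(rk, ess, k)$TP)
  }
  expect_error(topk_counts(rk, ess, 101), "exceeds")
})

test_that("jackknife curve accumulates essentials over the ordering", {
  ids <- sprintf("P%d", 1:6)
  ess <- c("P1", "P2")
  perfect <- manual_ranking(c("P1", "P2", "P3", "P4", "P5", "P6"))
  jc <- jackknife_curve(perfect, ess)
  expect_equal(jc$essential_count, c(1, 2, 2, 2, 2, 2))
  expect_equal(jc$essential_count[6], length(ess))

  empty <- jackknife_curve(manual_ranking(ids), character())
  expect_equal(empty$essential_count, rep(0, 6))

  # counting from the tail mirrors counting from the head
  rk <- manual_ranking(sample(ids))
  rev_rk <- manual_ranking(rev(rk$ordering))
  a <- jackknife_curve(rk, ess)$essential_count
  b <- jackknife_curve(rev_rk, ess)$essential_count
  expect_equal(diff(c(0, a)), rev(diff(c(0, b))))
})

test_that("average precision matches hand-computed cases", {
  rk <- manual_ranking(c("pos1", "neg1", "pos2"))
  pr <- pr_curve(rk, c("pos1", "pos2"))
  expect_equal(pr$prauc, 5 / 6)
  expect_equal(pr$points$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(pr$points$recall, c(1 / 2, 1 / 2, 1))

  ids <- sprintf("P%d", 1:8)
  front <- manual_ranking(ids)
  expect_equal(pr_curve(front, ids[1:3])$prauc, 1)

  expect_error(pr_curve(front, character()), "positive")
})

test_that("promoting a positive to the top never lowers average precision", {
  set.seed(7)
  for (rep in 1:10) {
    ids <- sprintf("P%03d", 1:40)
    ess <- sample(ids, 8)
    ord <- sample(ids)
    base <- pr_curve(manual_ranking(ord), ess)$prauc
    hit <- ord[ord %in% ess][3]
    promoted <- manual_ranking(c(hit, setdiff(ord, hit)))
    expect_gte(pr_curve(promoted, ess)$prauc, base)
    expect_lte(base, 1)
    expect_gt(base, 0)
  }
})

test_that("overlap analysis separates shared and unique essential hits", {
  ess <- c("E1", "E2", "E3", "E4")
  a <- manual_ranking(c("E1", "E2", "X1", "E3", "X2", "E4"))
  b <- manual_ranking(c("E1", "X1", "E4", "E2", "X2", "E3"))
  ov <- overlap_analysis(a, b, ess, 3)
  expect_equal(ov$shared, "E1")
  expect_equal(ov$unique_a, "E2")
  expect_equal(ov$unique_b, "E4")
  expect_equal(unname(ov$ratios), c(1 / 2, 1 / 2))

  same <- overlap_analysis(a, a, ess, 4)
  expect_equal(length(same$unique_a), 0)
  expect_equal(length(same$unique_b), 0)

  disj <- overlap_analysis(manual_ranking(c("E1", "X1", "X2", "E2")),
                           manual_ranking(c("E2", "X1", "X2", "E1")),
                           c("E1", "E2"), 1)
  expect_equal(disj$unique_a, "E1")
  expect_equal(disj$unique_b, "E2")
  expect_equal(length(disj$shared), 0)
})
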