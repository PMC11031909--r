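part4 <- function() module_partition(c(P1 = 1, P2 = 1, P3 = 2, P4 = 2))

test_that("orthology correlation matches hand-evaluated indicator cases", {
  part <- part4()
  aligned <- c(P1 = 3, P2 = 3, P3 = 1, P4 = 1)
  pc <- orthology_correlation(part, aligned)
  expect_equal(pc[1], 1)
  expect_equal(pc[2], -1)

  cross <- module_partition(c(P1 = 1, P2 = 2, P3 = 1, P4 = 2))
  expect_equal(orthology_correlation(cross, aligned), c(0, 0))

  constant <- c(P1 = 2, P2 = 2, P3 = 2, P4 = 2)
  expect_true(all(is.na(orthology_correlation(part, constant))))
})

test_that("orthology correlation agrees with stats::cor on random fixtures", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:30, 1)
    ids <- sprintf("P%02d", seq_len(n))
    mem <- sample(1:4, n, replace = TRUE)
    names(mem) <- ids
    if (length(unique(mem)) < 2) next
    part <- module_partition(mem)
    y <- rpois(n, 3)
    names(y) <- ids
    pc <- orthology_correlation(part, y)
    for (i in seq_len(part$n_modules)) {
      expected <- suppressWarnings(
        stats::cor(as.numeric(part$membership == i), y[names(part$membership)]))
      if (is.na(expected)) expect_true(is.na(pc[i]))
      else expect_equal(pc[i], unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("missing proteins count as orthology score zero", {
  part <- part4()
  pc <- orthology_correlation(part, c(P1 = 5, P2 = 5))  # P3, P4 absent -> 0
  expect_equal(pc[1], 1)
})

test_that("nucleus score is the mean nucleus count of the module", {
  mem <- module_partition(c(a = 1, b = 1, c = 1, d = 1, e = 2))
  loc <- rbind(a = c(2L, 7L), b = c(3L, 0L), c = c(0L, 1L), d = c(1L, 0L),
               e = c(0L, 5L))
  colnames(loc) <- c("nucleus", "cytosol")
  nsl <- nucleus_score(mem, loc)
  expect_equal(nsl[1], 6 / 4)  # counts [2,3,0,1] over 4 proteins
  expect_equal(nsl[2], 0)
  expect_error(nucleus_score(mem, loc, nucleus = "nucleolus"), "compartment")
  # missing protein -> count 0
  nsl2 <- nucleus_score(mem, loc[c("a", "b"), , drop = FALSE])
  expect_equal(nsl2[1], 5 / 4)
})

test_that("topology score balances internal against boundary edges", {
  bow <- make_bowtie()
  part <- module_partition(c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2))
  tf <- topology_score(bow, part)
  expect_equal(tf, c(2 / 3, 2 / 3))  # I=3, O=1, n=3 each side

  star <- make_star(4)
  singleton <- module_partition(
    c(hub = 1, leaf1 = 2, leaf2 = 2, leaf3 = 2, leaf4 = 2))
  expect_equal(topology_score(star, singleton)[1], -4)  # (0 - 4) / 1

  whole <- module_partition(setNames(rep(1, 6), make_bowtie()$nodes))
  expect_equal(topology_score(bow, whole), 7 / 6)  # O = 0 -> |E| / |V|
})

test_that("critical-module selection implements C_orth | (C_sub \\ C_topo)", {
  scores <- data.frame(module = 1:3,
                       size = c(3, 3, 3), I = c(3, 3, 3), O = c(1, 1, 1),
                       PC = c(0.5, 0.3, -0.2),
                       NSL = c(0.1, 2.5, 3.0),
                       TF = c(1.0, 1.0, 0.1))
  sel <- select_critical_modules(scores, th1 = 0.4, th2 = 2, th3 = 0.25)
  expect_equal(sel$C_orth, 1L)
  expect_equal(sel$C_sub, c(2L, 3L))
  expect_equal(sel$C_topo, 3L)
  expect_equal(sel$C_critical, c(1L, 2L))

  # inclusive inequalities exactly at the threshold
  at <- select_critical_modules(scores, th1 = 0.5, th2 = 2.5, th3 = 0.1)
  expect_equal(at$C_orth, 1L)
  expect_true(2L %in% at$C_sub)
  expect_true(3L %in% at$C_topo)

  # a module with undefined PC can enter only through the C_sub branch
  scores$PC[2] <- NA
  sel2 <- select_critical_modules(scores, th1 = -1, th2 = 2, th3 = 0.25)
  expect_false(2L %in% sel2$C_orth)
  expect_true(2L %in% sel2$C_critical)

  # vacuous thresholds select everything
  all3 <- select_critical_modules(scores, th1 = -1, th2 = -1e9, th3 = -1e9)
  expect_equal(all3$C_critical, 1:3)
  expect_error(select_critical_modules(scores, th1 = Inf), "finite")
})

test_that("CM-PIN keeps edges iff both endpoints sit in critical modules", {
  # bowtie plus a detached edge X-Y (outside the clustered component)
  net <- pin(edges = rbind(make_bowtie()$edges, c("X", "Y")))
  part <- module_partition(c(A = 1, B = 1, C = 1, D = 2, E = 2, F = 2))

  both <- build_cmpin(net, part, critical = c(1L, 2L))
  expect_identical(both$nodes, net$nodes)        # V unchanged
  expect_true("C D" %in% edge_keys_t(both))      # endpoints in two criticals
  expect_false("X Y" %in% edge_keys_t(both))     # unclustered component
  expect_equal(n_edges(both), 7L)

  one <- build_cmpin(net, part, critical = 1L)
  expect_setequal(edge_keys_t(one), c("A B", "A C", "B C"))
  expect_identical(one$nodes, net$nodes)

  # idempotent: refining the refined network changes nothing
  again <- build_cmpin(one, part, critical = 1L)
  expect_identical(again$edges, one$edges)
})

test_that("threshold sweep enumerates the grid and respects monotonicity", {
  fx <- small_fixture(3)
  core <- maximal_connected_subgraph(fx$planted$network)
  part <- fast_unfolding(core)
  scores <- module_scores(core, part, fx$bundle$orthology,
                          fx$bundle$localization)
  sweep <- threshold_sweep(fx$planted$network, part, scores,
                           th1 = c(-0.5, 0, 0.5), th2 = c(0.5, 2),
                           th3 = c(0.1, 0.5),
                           metrics = function(cm) c(edges = n_edges(cm)))
  expect_equal(nrow(sweep), 12L)
  expect_true(all(c("th1", "th2", "th3", "n_critical", "edges") %in%
                  colnames(sweep)))

  # vacuous row reproduces the clustered component's edge count
  vac <- threshold_sweep(fx$planted$network, part, scores,
                         th1 = -1, th2 = -1e9, th3 = -1e9,
                         metrics = function(cm) c(edges = n_edges(cm)))
  expect_equal(vac$edges, n_edges(core))

  # monotonicity over random score tables
  for (seed in 1:20) {
    set.seed(seed)
    sc <- data.frame(module = 1:8, size = 5, I = 5, O = 2,
                     PC = runif(8, -1, 1), NSL = runif(8, 0, 4),
                     TF = runif(8, -2, 3))
    t1 <- sort(runif(2, -1, 1))
    a <- select_critical_modules(sc, t1[1], 2, 0.25)
    b <- select_critical_modules(sc, t1[2], 2, 0.25)
    expect_true(all(b$C_orth %in% a$C_orth))
    expect_lte(length(b$C_critical), length(a$C_critical))
    t2 <- sort(runif(2, 0, 4))
    a <- select_critical_modules(sc, 0.1, t2[1], 0.25)
    b <- select_critical_modules(sc, 0.1, t2[2], 0.25)
    expect_lte(length(b$C_critical), length(a$C_critical))
    t3 <- sort(runif(2, -2, 3))
    a <- select_critical_modules(sc, 0.1, 2, t3[1])
    b <- select_critical_modules(sc, 0.1, 2, t3[2])
    expect_gte(length(a$C_critical), length(b$C_critical))
  }
})
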