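test_that("configuration invariants are enforced", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.2), "p_out < p_in")
  expect_error(synthetic_config(lambda_hi = 1, lambda_lo = 2), "lambda_hi")
  expect_error(synthetic_config(nu_hi = 0.1, nu_lo = 0.5), "nu_hi")
  expect_error(synthetic_config(module_sizes = integer()), "positive")
  expect_error(synthetic_config(critical_fraction = 0), "critical_fraction")
})

test_that("network generation is deterministic given the seed", {
  cfg <- synthetic_config()
  a <- generate_network(cfg, 5)
  b <- generate_network(cfg, 5)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$critical, b$critical)
  c <- generate_network(cfg, 6)
  expect_false(identical(a$network$edges, c$network$edges))
})

test_that("the dense limit yields planted cliques that Louvain recovers exactly", {
  cfg <- synthetic_config(module_sizes = rep(8L, 3L), p_in = 1, p_out = 0.05)
  planted <- generate_network(cfg, 2)
  deg <- pin_degree(planted$network)
  expect_true(all(deg >= 7))  # every within-module edge is present
  core <- maximal_connected_subgraph(planted$network)
  part <- fast_unfolding(core)
  expect_equal(nmi(part$membership, planted$partition$membership), 1)
})

test_that("within-module edge counts match the binomial expectation", {
  cfg <- synthetic_config(module_sizes = c(10L, 10L), p_in = 0.3,
                          p_out = 0.05)
  first_module <- sprintf("P%04d", 1:10)
  counts <- vapply(1:100, function(s) {
    net <- generate_network(cfg, s)$network
    sum(net$edges[, 1] %in% first_module & net$edges[, 2] %in% first_module)
  }, numeric(1))
  expected <- 0.3 * choose(10, 2)
  se <- sqrt(choose(10, 2) * 0.3 * 0.7 / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("orthology scores are elevated in critical modules", {
  cfg <- synthetic_config(module_sizes = rep(25L, 8L),
                          critical_fraction = 0.5)
  planted <- generate_network(cfg, 11)
  bundle <- generate_annotations(planted, cfg, 11)
  in_crit <- planted$partition$membership %in% planted$critical
  mu_crit <- mean(bundle$orthology[in_crit])   # 100 critical proteins
  mu_bg <- mean(bundle$orthology[!in_crit])
  expect_lt(abs(mu_crit - cfg$lambda_hi), 3 * sqrt(cfg$lambda_hi / sum(in_crit)))
  expect_lt(abs(mu_bg - cfg$lambda_lo), 3 * sqrt(cfg$lambda_lo / sum(!in_crit)))
})

test_that("zero essentiality enrichment gives uniform labels", {
  cfg <- synthetic_config(module_sizes = rep(50L, 4L),
                          essential_rate_critical = 0.3,
                          essential_rate_background = 0.3)
  planted <- generate_network(cfg, 3)
  bundle <- generate_annotations(planted, cfg, 3)
  in_crit <- planted$partition$membership %in% planted$critical
  ids <- names(planted$partition$membership)
  rate_crit <- mean(ids[in_crit] %in% bundle$essential)
  rate_bg <- mean(ids[!in_crit] %in% bundle$essential)
  expect_lt(abs(rate_crit - rate_bg), 0.2)
})

test_that("the yeast-like default emits a 36-point expression course", {
  cfg <- synthetic_config()
  planted <- generate_network(cfg, 1)
  bundle <- generate_annotations(planted, cfg, 1)
  expect_equal(ncol(bundle$expression), 36L)
  expect_equal(ncol(bundle$localization), 11L)
  expect_true("nucleus" %in% colnames(bundle$localization))
})

test_that("fixtures round-trip through the readers and are reproducible", {
  cfg <- synthetic_config(module_sizes = rep(10L, 3L), p_in = 0.5,
                          p_out = 0.05)
  planted <- generate_network(cfg, 9)
  bundle <- generate_annotations(planted, cfg, 9)
  d1 <- file.path(tempfile(), "fx1")
  paths <- write_fixture(planted, bundle, d1)
  expect_length(paths, 5L)
  expect_true(all(file.exists(paths)))

  back_net <- read_edge_list(paths[["network"]])
  expect_identical(back_net$nodes, planted$network$nodes)
  expect_identical(back_net$edges, planted$network$edges)
  expect_equal(read_expression_matrix(paths[["expression"]]),
               bundle$expression)
  expect_identical(read_localization_table(paths[["localization"]]),
                   bundle$localization)
  expect_identical(read_orthology_scores(paths[["orthology"]]),
                   bundle$orthology)
  expect_identical(read_protein_list(paths[["essential"]]),
                   sort(bundle$essential))

  # same seed -> byte-identical files
  d2 <- file.path(tempfile(), "fx2")
  paths2 <- write_fixture(planted, generate_annotations(planted, cfg, 9), d2)
  for (nm in names(paths)) {
    expect_identical(readLines(paths2[[nm]]), readLines(paths[[nm]]),
                     label = nm)
  }
})
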