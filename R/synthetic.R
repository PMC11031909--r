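# Synthetic fixture generator. Emulates the signal structure the refinement
# method exploits: a modular (planted-partition) interaction network in
# which a subset of modules is "critical" - their proteins are
# evolutionarily conserved (high orthology scores), nucleus-localized, and
# enriched in essential proteins, and their interactions are co-active in
# the expression time course. Every stage of the pipeline is testable
# against the planted ground truth without any external database.

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe the strong-signal regime the package's validation
#' runs use: eight planted modules of 20 proteins, within-module edge
#' probability 0.3 against 0.01 between modules, a quarter of the modules
#' critical, Poisson orthology means 8 (critical) vs 1 (background),
#' Poisson nucleus-count means 3 vs 0.3, a 36-point expression time course
#' (one protein-activity window of 6 points per module), and essentiality
#' rates 0.5 in critical vs 0.1 in background modules.
#'
#' @param module_sizes Integer vector of planted module sizes.
#' @param p_in,p_out Within/between-module edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param critical_fraction Fraction of modules planted as critical (at
#'   least one).
#' @param lambda_hi,lambda_lo Poisson means of orthology scores in critical
#'   vs background modules, `lambda_hi > lambda_lo >= 0`.
#' @param nu_hi,nu_lo Poisson means of nucleus evidence counts in critical
#'   vs background modules, `nu_hi > nu_lo >= 0`.
#' @param nu_other Poisson mean of the evidence counts in the ten
#'   non-nucleus compartments.
#' @param n_timepoints Number of expression time points (36 matches a yeast
#'   metabolic-cycle course; 64 a human multi-tissue course).
#' @param window_length Length of each module's shared activity window.
#' @param co_active_critical,co_active_background Probability that a
#'   protein follows its module's activity window rather than a private
#'   one.
#' @param essential_rate_critical,essential_rate_background Essentiality
#'   probability per protein by module type.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(module_sizes = rep(20L, 8L),
                             p_in = 0.3,
                             p_out = 0.01,
                             critical_fraction = 0.25,
                             lambda_hi = 8,
                             lambda_lo = 1,
                             nu_hi = 3,
                             nu_lo = 0.3,
                             nu_other = 0.3,
                             n_timepoints = 36L,
                             window_length = 6L,
                             co_active_critical = 0.95,
                             co_active_background = 0.5,
                             essential_rate_critical = 0.5,
                             essential_rate_background = 0.1) {
  cfg <- list(module_sizes = as.integer(module_sizes), p_in = p_in,
              p_out = p_out, critical_fraction = critical_fraction,
              lambda_hi = lambda_hi, lambda_lo = lambda_lo,
              nu_hi = nu_hi, nu_lo = nu_lo, nu_other = nu_other,
              n_timepoints = as.integer(n_timepoints),
              window_length = as.integer(window_length),
              co_active_critical = co_active_critical,
              co_active_background = co_active_background,
              essential_rate_critical = essential_rate_critical,
              essential_rate_background = essential_rate_background)
  if (length(cfg$module_sizes) < 1L || any(cfg$module_sizes < 1L)) {
    stop("module_sizes must be positive integers")
  }
  if (!(cfg$p_out >= 0 && cfg$p_out < cfg$p_in && cfg$p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (!(cfg$lambda_hi > cfg$lambda_lo && cfg$lambda_lo >= 0)) {
    stop("need lambda_hi > lambda_lo >= 0")
  }
  if (!(cfg$nu_hi > cfg$nu_lo && cfg$nu_lo >= 0)) {
    stop("need nu_hi > nu_lo >= 0")
  }
  if (cfg$critical_fraction <= 0 || cfg$critical_fraction > 1) {
    stop("critical_fraction must be in (0, 1]")
  }
  if (cfg$window_length > cfg$n_timepoints) {
    stop("window_length cannot exceed n_timepoints")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a planted-partition interaction network
#'
#' Draws a stochastic block model with the configured module sizes and edge
#' probabilities, marks a random subset of modules critical, and verifies
#' that the largest connected component covers at least 95% of the nodes
#' (regenerating from a derived seed otherwise, so the default
#' configuration always yields a giant component).
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; the draw is deterministic given `(cfg, seed)`.
#' @return List with `network` (a [pin()]), `partition` (the planted
#'   [module_partition()]) and `critical` (integer vector of planted
#'   critical module ids, in canonical numbering).
#' @export
generate_network <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sizes <- cfg$module_sizes
  nmod <- length(sizes)
  n <- sum(sizes)
  ids <- sprintf("P%04d", seq_len(n))
  block <- rep(seq_len(nmod), sizes)
  names(block) <- ids

  n_crit <- max(1L, round(cfg$critical_fraction * nmod))
  crit <- with_seed(derive_seed(seed, "modules"),
                    sort(sample.int(nmod, n_crit)))

  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  p <- ifelse(block[ii] == block[jj], cfg$p_in, cfg$p_out)

  for (attempt in 0:19) {
    sel <- with_seed(derive_seed(seed, "network") + attempt,
                     stats::runif(length(p)) < p)
    net <- pin(nodes = ids, edges = cbind(ids[ii[sel]], ids[jj[sel]]))
    comp <- maximal_connected_subgraph(net)
    if (n_nodes(comp) >= 0.95 * n) {
      part <- module_partition(block)
      # planted critical ids in the canonical numbering of the partition
      crit_canon <- sort(unique(part$membership[names(block)[block %in% crit]]))
      return(list(network = net, partition = part, critical = crit_canon))
    }
  }
  stop("could not generate a network whose giant component covers 95% of nodes; ",
       "the configuration is too sparse")
}

#' Generate annotations for a planted network
#'
#' Draws the four annotation inputs consistently with the planted critical
#' modules: Poisson orthology scores (mean `lambda_hi` in critical modules,
#' `lambda_lo` elsewhere), Poisson localization counts over 11 compartments
#' with elevated nucleus means in critical modules, an expression time
#' course in which each module has a shared activity window (critical
#' modules' proteins follow it with high probability, so their interactions
#' survive the co-activity filter), and essential labels enriched in
#' critical modules. Expression values are rounded to 4 decimals so the
#' TSV fixtures round-trip exactly.
#'
#' @param planted Output of [generate_network()].
#' @param cfg The [synthetic_config()] used to generate it.
#' @param seed Integer seed; each annotation draws from its own derived
#'   stream, so the draws are independent of one another.
#' @return Object of class `annotation_bundle`: list with `expression`
#'   (numeric matrix), `localization` (integer matrix), `orthology` (named
#'   integer vector), `essential` (character vector) and `nucleus` (the
#'   nucleus compartment name).
#' @export
generate_annotations <- function(planted, cfg, seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  part <- planted$partition
  ids <- names(part$membership)
  n <- length(ids)
  in_crit <- part$membership %in% planted$critical

  orth <- with_seed(derive_seed(seed, "orthology"), {
    stats::rpois(n, ifelse(in_crit, cfg$lambda_hi, cfg$lambda_lo))
  })
  names(orth) <- ids

  compartments <- c("nucleus", "cytosol", "mitochondrion",
                    "endoplasmic_reticulum", "golgi", "vacuole",
                    "peroxisome", "plasma_membrane", "cytoskeleton",
                    "endosome", "extracellular")
  loc <- with_seed(derive_seed(seed, "localization"), {
    nuc <- stats::rpois(n, ifelse(in_crit, cfg$nu_hi, cfg$nu_lo))
    rest <- matrix(stats::rpois(n * (length(compartments) - 1L),
                                cfg$nu_other),
                   nrow = n)
    cbind(nuc, rest)
  })
  dimnames(loc) <- list(ids, compartments)
  storage.mode(loc) <- "integer"

  nt <- cfg$n_timepoints
  wl <- cfg$window_length
  expr <- with_seed(derive_seed(seed, "expression"), {
    mod_start <- sample.int(nt - wl + 1L, part$n_modules, replace = TRUE)
    follow_p <- ifelse(in_crit, cfg$co_active_critical,
                       cfg$co_active_background)
    follows <- stats::runif(n) < follow_p
    own_start <- sample.int(nt - wl + 1L, n, replace = TRUE)
    start <- ifelse(follows, mod_start[part$membership], own_start)
    baseline <- stats::rnorm(n, mean = 5, sd = 0.5)
    e <- matrix(stats::rnorm(n * nt, sd = 0.25), nrow = n) + baseline
    for (i in seq_len(n)) {
      win <- start[i]:(start[i] + wl - 1L)
      e[i, win] <- e[i, win] + 5
    }
    round(e, 4L)
  })
  dimnames(expr) <- list(ids, sprintf("t%02d", seq_len(nt)))

  essential <- with_seed(derive_seed(seed, "essential"), {
    rate <- ifelse(in_crit, cfg$essential_rate_critical,
                   cfg$essential_rate_background)
    ids[stats::runif(n) < rate]
  })

  structure(list(expression = expr, localization = loc, orthology = orth,
                 essential = essential, nucleus = "nucleus"),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(
    "<annotation_bundle> %d proteins, %d time points, %d compartments, %d essential\n",
    nrow(x$expression), ncol(x$expression), ncol(x$localization),
    length(x$essential)))
  invisible(x)
}

#' Write a synthetic fixture to disk
#'
#' Emits the five pipeline input files (edge list, expression matrix,
#' localization table, orthology scores, essential list) in the package's
#' TSV formats; the files round-trip losslessly through the corresponding
#' readers and are byte-identical across runs with the same seed.
#'
#' @param planted Output of [generate_network()].
#' @param bundle Output of [generate_annotations()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the five file paths (`network`,
#'   `expression`, `localization`, `orthology`, `essential`).
#' @export
write_fixture <- function(planted, bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             localization = file.path(dir, "localization.tsv"),
             orthology = file.path(dir, "orthology.tsv"),
             essential = file.path(dir, "essential.txt"))
  write_edge_list(planted$network, paths[["network"]])
  write_expression_matrix(bundle$expression, paths[["expression"]])
  write_localization_table(bundle$localization, paths[["localization"]])
  write_orthology_scores(bundle$orthology, paths[["orthology"]])
  write_protein_list(bundle$essential, paths[["essential"]])
  paths
}
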