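#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by every generator: a multi-population
#' gut-metagenome survey with long-tailed MAG abundances and
#' Dirichlet-multinomial count overdispersion. Defaults are chosen as
#' realistic desk-scale stool-metagenome conditions: 2 populations of 20
#' samples, 200 MAG features whose baseline proportions follow a log-normal
#' (sigma 1) sorted in decreasing abundance, 100,000 reads per sample on
#' average, and concentration 50 (overdispersion theta ~= 0.02, typical of
#' stool surveys).
#'
#' @param n_populations number of host populations (>= 2); default 2.
#' @param samples_per_population samples per population (>= 3); default 20.
#' @param n_features number of MAG/taxon features; default 200.
#' @param depth_mean expected reads per sample; default 1e5.
#' @param concentration Dirichlet-multinomial concentration (> 0; larger =
#'   less overdispersed); default 50.
#' @param sigma_log log-normal sigma of the baseline proportions; default 1.
#' @param genes_per_sample CAZyme genes per sample for
#'   [generate_cazyme_table()]; default 2000.
#' @param seed integer RNG seed; identical seeds reproduce identical outputs.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_populations = 2L, samples_per_population = 20L,
                         n_features = 200L, depth_mean = 1e5,
                         concentration = 50, sigma_log = 1,
                         genes_per_sample = 2000L, seed = 1L) {
  stopifnot(n_populations >= 2, samples_per_population >= 3,
            n_features >= 1, depth_mean > 0, concentration > 0,
            sigma_log >= 0, genes_per_sample >= 1)
  structure(list(n_populations = as.integer(n_populations),
                 samples_per_population = as.integer(samples_per_population),
                 n_features = as.integer(n_features),
                 depth_mean = depth_mean, concentration = concentration,
                 sigma_log = sigma_log,
                 genes_per_sample = as.integer(genes_per_sample),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Planted ground-truth signal for the generators
#'
#' @param differential_features data.frame with columns `feature` (index or
#'   id), `population` (target population name or index) and `lfc` (log2
#'   fold-change applied to the baseline proportion in that population), or
#'   NULL for no differential features.
#' @param substrate_shifts data.frame with columns `substrate`, `host_group`
#'   and `enrichment` (> 0 multiplicative factor), or NULL.
#' @param tree_signal_strength within-population clustering dial in \[0, 1\]:
#'   0 = topology random with respect to population, 1 = perfect population
#'   monophyly with vanishing within-population branches.
#' @return list of class `planted_signal`.
#' @export
planted_signal <- function(differential_features = NULL,
                           substrate_shifts = NULL,
                           tree_signal_strength = 0) {
  if (!is.null(differential_features)) {
    stopifnot(all(c("feature", "population", "lfc") %in%
                    names(differential_features)),
              all(is.finite(differential_features$lfc)))
  }
  if (!is.null(substrate_shifts)) {
    stopifnot(all(c("substrate", "host_group", "enrichment") %in%
                    names(substrate_shifts)),
              all(substrate_shifts$enrichment > 0))
  }
  stopifnot(tree_signal_strength >= 0, tree_signal_strength <= 1)
  structure(list(differential_features = differential_features,
                 substrate_shifts = substrate_shifts,
                 tree_signal_strength = tree_signal_strength),
            class = "planted_signal")
}

# Population names Pop1..PopK; host groups: first half Homo, second half Pan.
synth_populations <- function(config) {
  pops <- paste0("Pop", seq_len(config$n_populations))
  half <- ceiling(config$n_populations / 2)
  host <- rep(c("Homo", "Pan"), c(half, config$n_populations - half))
  list(populations = pops, host_group = stats::setNames(host, pops))
}

#' Generate a synthetic count table with planted fold-changes
#'
#' Draws a Dirichlet-multinomial count table around population baselines.
#' Baseline proportions are log-normal and sorted in decreasing order (so
#' feature `F0001` is always the most abundant and planted feature indices
#' are interpretable); for each planted differential feature the target
#' population's baseline proportion is multiplied by `2^lfc` before
#' renormalization. Feature lengths (kb) and Lander-Waterman-style coverage
#' fractions (expected = 1 - exp(-per-base depth); observed = expected times
#' beta-distributed noise) are attached so the coverage filter is
#' exercisable.
#'
#' @param config a [synth_config()].
#' @param signal a [planted_signal()]; default: no signal.
#' @return list with `counts` (a [count_matrix()]), `design` (a
#'   [population_design()]) and `truth` (data.frame of per-population feature
#'   proportions and planted log2 fold-changes).
#' @export
generate_count_table <- function(config, signal = planted_signal()) {
  stopifnot(inherits(config, "synth_config"))
  df <- signal$differential_features
  if (!is.null(df) && nrow(df) > config$n_features)
    stop("more planted differential features than features")
  set.seed(config$seed)
  nf <- config$n_features
  pop <- synth_populations(config)
  features <- sprintf("F%04d", seq_len(nf))
  base <- sort(stats::rlnorm(nf, 0, config$sigma_log), decreasing = TRUE)
  base <- base / sum(base)
  props <- sapply(pop$populations, function(p) base)  # nf x k
  rownames(props) <- features
  lfc <- matrix(0, nf, config$n_populations,
                dimnames = dimnames(props))
  if (!is.null(df)) {
    fi <- if (is.numeric(df$feature)) as.integer(df$feature)
          else match(df$feature, features)
    pi <- if (is.numeric(df$population)) as.integer(df$population)
          else match(df$population, pop$populations)
    if (anyNA(fi) || anyNA(pi)) stop("unknown feature or population in signal")
    for (r in seq_len(nrow(df))) {
      props[fi[r], pi[r]] <- props[fi[r], pi[r]] * 2^df$lfc[r]
      lfc[fi[r], pi[r]] <- df$lfc[r]
    }
    props <- sweep(props, 2, colSums(props), "/")
  }
  n <- config$n_populations * config$samples_per_population
  samples <- sprintf("S%03d", seq_len(n))
  populations <- rep(pop$populations, each = config$samples_per_population)
  counts <- matrix(0L, n, nf, dimnames = list(samples, features))
  for (i in seq_len(n)) {
    alpha <- config$concentration * props[, populations[i]]
    w <- stats::rgamma(nf, shape = alpha)
    if (sum(w) == 0) w[1] <- 1
    depth <- stats::rpois(1, config$depth_mean)
    counts[i, ] <- stats::rmultinom(1, depth, w / sum(w))
  }
  lengths_kb <- stats::setNames(stats::rlnorm(nf, log(2500), 0.3), features)
  per_base <- sweep(counts * 150, 2, lengths_kb * 1000, "/")
  cov_exp <- 1 - exp(-per_base)
  cov_obs <- cov_exp * matrix(stats::rbeta(n * nf, 20, 1), n, nf)
  design <- population_design(samples, populations,
                              pop$host_group[populations])
  truth <- data.frame(feature = rep(features, config$n_populations),
                      population = rep(pop$populations, each = nf),
                      proportion = as.vector(props),
                      lfc = as.vector(lfc), stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, lengths_kb, cov_exp, cov_obs),
       design = design, truth = truth)
}

#' Generate a synthetic CAZyme gene table with planted substrate shifts
#'
#' Each sample receives exactly `config$genes_per_sample` CAZyme genes,
#' multinomially distributed over the (family, EC) rows of the substrate map
#' with log-normal base weights shared across populations. For every planted
#' shift, the weights of all map rows belonging to the shifted substrate are
#' multiplied by the enrichment factor in samples of the target host group.
#'
#' @param config a [synth_config()].
#' @param signal a [planted_signal()] (only `substrate_shifts` is used).
#' @param substrate_map substrate map data.frame; default
#'   [default_substrate_map()].
#' @return list with `genes` (long data.frame: `family`, `ec`, `substrate`,
#'   `source`, `sample`, `population`, `host_group`, `count`), `design`, and
#'   `truth` (the shift table, possibly empty).
#' @export
generate_cazyme_table <- function(config, signal = planted_signal(),
                                  substrate_map = default_substrate_map()) {
  stopifnot(inherits(config, "synth_config"))
  validate_substrate_map(substrate_map)
  shifts <- signal$substrate_shifts
  if (!is.null(shifts) &&
      !all(shifts$substrate %in% substrate_map$substrate))
    stop("shifted substrate absent from map: ",
         paste(setdiff(shifts$substrate, substrate_map$substrate),
               collapse = ", "))
  set.seed(config$seed + 7L)
  pop <- synth_populations(config)
  n <- config$n_populations * config$samples_per_population
  samples <- sprintf("S%03d", seq_len(n))
  populations <- rep(pop$populations, each = config$samples_per_population)
  hosts <- pop$host_group[populations]
  nr <- nrow(substrate_map)
  base_w <- stats::rlnorm(nr, 0, 1)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- base_w
    if (!is.null(shifts)) {
      for (r in seq_len(nrow(shifts))) {
        if (hosts[i] == shifts$host_group[r]) {
          hit <- substrate_map$substrate == shifts$substrate[r]
          w[hit] <- w[hit] * shifts$enrichment[r]
        }
      }
    }
    cnt <- as.vector(stats::rmultinom(1, config$genes_per_sample, w / sum(w)))
    rows[[i]] <- data.frame(family = substrate_map$family,
                            ec = substrate_map$ec,
                            substrate = substrate_map$substrate,
                            source = substrate_map$source,
                            sample = samples[i],
                            population = populations[i],
                            host_group = unname(hosts[i]),
                            count = cnt, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  genes <- genes[genes$count > 0, , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes,
       design = population_design(samples, populations, hosts),
       truth = if (is.null(shifts))
         data.frame(substrate = character(), host_group = character(),
                    enrichment = numeric()) else shifts)
}

#' Generate sample-labelled trees with tunable host-population signal
#'
#' Builds one tree per requested replicate over all samples of the design.
#' Construction: a pure-birth backbone over the populations (rescaled to unit
#' depth), with a within-population coalescent subtree grafted at each
#' backbone tip; within-population branch lengths are scaled by
#' `(1 - strength) * 0.5 + 0.01`, and after grafting each tip independently
#' enters a shuffle pool with probability `1 - strength`, within which labels
#' are permuted. At strength 1 each population is a tight monophyletic clade;
#' at strength 0 all labels are randomly permuted, so topology carries no
#' population information.
#'
#' @param config a [synth_config()].
#' @param signal a [planted_signal()] (only `tree_signal_strength` is used).
#' @param n_trees number of trees to generate (>= 1).
#' @return a [labeled_tree_set()] with trees named `tree_1`, ...
#' @export
generate_population_trees <- function(config, signal = planted_signal(),
                                      n_trees = 1L) {
  stopifnot(inherits(config, "synth_config"), n_trees >= 1)
  if (config$n_populations < 2) stop("fewer than 2 populations")
  s <- signal$tree_signal_strength
  pop <- synth_populations(config)
  n_per <- config$samples_per_population
  samples <- sprintf("S%03d",
                     seq_len(config$n_populations * n_per))
  populations <- rep(pop$populations, each = n_per)
  design <- population_design(samples, populations,
                              pop$host_group[populations])
  set.seed(config$seed + 13L)
  trees <- lapply(seq_len(n_trees), function(t) {
    backbone <- ape::rphylo(config$n_populations, birth = 1, death = 0)
    # backbone depth scales with the signal: at strength 0 the population
    # split is star-like, at 1 populations are deeply separated
    backbone$edge.length <- backbone$edge.length /
      max(ape::node.depth.edgelength(backbone)) * (s + 0.02)
    backbone$tip.label <- pop$populations
    tree <- backbone
    within_scale <- (1 - s) * 0.5 + 0.01
    for (p in pop$populations) {
      sub <- ape::rcoal(n_per)
      sub$edge.length <- sub$edge.length /
        max(ape::node.depth.edgelength(sub)) * within_scale
      sub$tip.label <- samples[populations == p]
      tree <- ape::bind.tree(tree, sub,
                             where = which(tree$tip.label == p))
    }
    shuffle <- stats::runif(length(tree$tip.label)) < (1 - s)
    if (sum(shuffle) > 1)
      tree$tip.label[shuffle] <- sample(tree$tip.label[shuffle])
    tree
  })
  names(trees) <- paste0("tree_", seq_len(n_trees))
  labeled_tree_set(trees, tip_map = stats::setNames(samples, samples),
                   design = design)
}
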