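#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end synthetic workflow with
#' the package defaults: coverage-ratio threshold 0.5, CLR pseudocount 1e-6,
#' 10,000 bootstrap replicates, effect-size call threshold 1, gene-screen R^2
#' threshold 0.5, at most 100 ordination features, density truncation 0.10.
#'
#' @param out_dir output directory for the stage TSVs and the run manifest.
#' @param synth a [synth_config()] defining the simulated dataset.
#' @param signal a [planted_signal()].
#' @param n_trees gene trees to simulate and screen; default 5.
#' @param depth rarefaction depth (`NULL` = minimum sample total).
#' @param coverage_threshold coverage-ratio threshold; default 0.5.
#' @param pseudo CLR pseudocount; default 1e-6.
#' @param n_boot bootstrap replicates; default 10000.
#' @param effect_threshold absolute effect-size call threshold; default 1.
#' @param r2_threshold gene-screen R^2 threshold; default 0.5.
#' @param max_features ordination feature cap; default 100.
#' @param truncation density-contour truncation fraction; default 0.10.
#' @param n_permutations PERMANOVA permutations; default 999.
#' @param n_mc Dirichlet Monte-Carlo instances; default 128.
#' @param prevalence core-community prevalence fraction; default 1.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, synth = synth_config(),
                       signal = planted_signal(), n_trees = 5L,
                       depth = NULL, coverage_threshold = 0.5,
                       pseudo = 1e-6, n_boot = 10000L,
                       effect_threshold = 1.0, r2_threshold = 0.5,
                       max_features = 100L, truncation = 0.10,
                       n_permutations = 999L, n_mc = 128L,
                       prevalence = 1.0, seed = 1L) {
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1, pseudo > 0,
            n_boot >= 1, effect_threshold >= 0, r2_threshold >= 0,
            r2_threshold <= 1, max_features >= 2, truncation >= 0,
            truncation <= 1, n_permutations >= 1, n_mc >= 1,
            prevalence > 0, prevalence <= 1)
  cfg <- as.list(environment())
  cfg$synth$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Run the full synthetic workflow
#'
#' Executes every stage in order on a freshly simulated dataset —
#' abundance construction (coverage filter, rarefaction, TPM), diversity and
#' core-community statistics, differential abundance, CLR-PCA ordination,
#' tree-based PERMANOVA screening, and the CAZyme bootstrap comparison —
#' writing one tidy TSV per stage plus a JSON manifest of parameters, seeds
#' and per-stage row counts. Re-running with an identical configuration
#' reproduces every output byte for byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  log_stage <- function(...) message("[codivkit] ", ...)
  manifest <- list(package_version = as.character(
    utils::packageVersion("codivkit")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("synth", "signal"))],
    stages = list())
  manifest$parameters$out_dir <- NULL
  manifest$parameters$synth <- unclass(config$synth)
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  log_stage("simulate: counts, cazyme table, trees (seed ", config$seed, ")")
  sim <- generate_count_table(config$synth, config$signal)
  caz <- generate_cazyme_table(config$synth, config$signal)
  trees <- generate_population_trees(config$synth, config$signal,
                                     n_trees = config$n_trees)
  write_count_tsv(sim$counts, out("counts.tsv"), out("lengths.tsv"),
                  out("coverage.tsv"))
  write_tsv(sim$design, out("design.tsv"))
  write_tsv(sim$truth, out("truth_counts.tsv"))
  write_tsv(caz$genes, out("cazyme.tsv"))
  write_newick_set(trees, out("trees"))
  note("simulate", n_samples = nrow(sim$counts$counts),
       n_features = ncol(sim$counts$counts), n_trees = config$n_trees)

  log_stage("abundance: coverage filter, rarefy, TPM")
  filtered <- coverage_filter(sim$counts, config$coverage_threshold)
  rare <- rarefy(filtered, depth = config$depth, seed = config$seed + 1L)
  tpm <- tpm_transform(rare)
  write_tsv(data.frame(sample = rownames(tpm), tpm, check.names = FALSE),
            out("tpm.tsv"))
  note("abundance", depth = min(rowSums(rare$counts)),
       dropped_samples = as.list(attr(rare, "dropped_samples")),
       n_rows = nrow(tpm))

  log_stage("diversity: richness, Shannon, pairwise Wilcoxon + BH")
  design <- sim$design[sim$design$sample %in% rownames(tpm), ]
  rich <- stats::setNames(richness(tpm), rownames(tpm))
  shan <- stats::setNames(as.numeric(shannon(tpm)), rownames(tpm))
  div <- data.frame(sample = rownames(tpm), richness = rich,
                    shannon = shan)
  write_tsv(div, out("diversity.tsv"))
  div_tests <- rbind(
    cbind(metric = "richness", pairwise_wilcoxon_bh(rich, design)),
    cbind(metric = "shannon", pairwise_wilcoxon_bh(shan, design)))
  write_tsv(div_tests, out("diversity_tests.tsv"))
  core <- core_membership(rare$counts, design,
                          prevalence = config$prevalence)
  write_tsv(data.frame(feature = core$core %||% character(0)),
            out("core_features.tsv"))
  note("diversity", n_pairs = nrow(div_tests) / 2,
       n_core = length(core$core))

  log_stage("diffabund: Dirichlet CLR instances + effect sizes")
  da <- diff_abundance(rare, design, column = "host_group",
                       n_mc = config$n_mc, seed = config$seed + 2L)
  write_tsv(as.data.frame(da), out("diffabund.tsv"))
  note("diffabund", n_features = nrow(da),
       n_significant = sum(abs(da$effect) >= config$effect_threshold))

  log_stage("ordination: CLR-PCA + density contours")
  clr <- clr_transform(replace_zeros_bayesian(tpm))
  clr_f <- filter_features(clr, config$max_features)
  pca <- pca_svd(clr_f)
  write_tsv(data.frame(sample = rownames(pca$scores),
                       pca$scores[, 1:2, drop = FALSE]), out("scores.tsv"))
  write_tsv(data.frame(feature = rownames(pca$loadings),
                       pca$loadings[, 1:2, drop = FALSE]),
            out("loadings.tsv"))
  write_tsv(data.frame(component = names(pca$explained_variance),
                       explained = pca$explained_variance),
            out("variance.tsv"))
  cont <- density_contours(pca$scores, design,
                           truncation = config$truncation)
  grid_df <- do.call(rbind, lapply(names(cont$populations), function(p) {
    z <- cont$populations[[p]]
    data.frame(population = p,
               x = rep(cont$grid$x, times = length(cont$grid$y)),
               y = rep(cont$grid$y, each = length(cont$grid$x)),
               density = as.vector(z$density),
               masked = as.vector(!z$mask))
  }))
  write_tsv(grid_df, out("contours.tsv"))
  note("ordination", n_features = ncol(clr_f),
       explained_pc12 = sum(pca$explained_variance[1:2]),
       n_outliers = nrow(cont$outliers))

  log_stage("phylosym: PERMANOVA screen over ", config$n_trees, " trees")
  screen <- gene_screen(trees, r2_threshold = config$r2_threshold,
                        n_permutations = config$n_permutations,
                        seed = config$seed + 3L)
  write_tsv(screen, out("phylosym.tsv"))
  note("phylosym", n_trees = nrow(screen),
       skipped = as.list(attr(screen, "skipped")),
       mean_R2 = attr(screen, "mean_R2"))

  log_stage("cazstats: bootstrap CLR differences (", config$n_boot,
            " replicates)")
  ann <- assign_substrates(caz$genes)
  frac <- sample_substrate_fractions(ann)
  boot <- bootstrap_group_difference(frac, caz$design,
                                     column = "host_group",
                                     n_boot = config$n_boot,
                                     pseudo = config$pseudo,
                                     seed = config$seed + 4L)
  write_tsv(as.data.frame(boot), out("cazstats.tsv"))
  write_tsv(population_relative_abundance(ann), out("caz_abundance.tsv"))
  note("cazstats", n_substrates = nrow(boot),
       n_significant = sum(boot$significant),
       unmapped_genes = attr(ann, "unmapped"))

  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  log_stage("done: outputs in ", config$out_dir)
  invisible(list(counts = sim, cazyme = caz, trees = trees, tpm = tpm,
                 diversity = div, diversity_tests = div_tests, core = core,
                 diffabund = da, pca = pca, contours = cont,
                 phylosym = screen, cazstats = boot, manifest = manifest))
}
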