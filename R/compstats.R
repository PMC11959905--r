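#' Bayesian-multiplicative zero replacement
#'
#' Count zeros in compositional data are sampling zeros, not structural ones;
#' before a log-ratio transform they are replaced by a Bayesian posterior
#' point estimate rather than an arbitrary constant. Each zero in a row with
#' total t is replaced by t * s / (t + S), where s is the per-feature prior
#' strength and S = s * n_features the total prior mass (a
#' Jeffreys-like multiplicative replacement). Non-zero entries are shrunk
#' multiplicatively so the row keeps its original total, and every output
#' entry is strictly positive.
#'
#' @param x non-negative numeric matrix (samples x features), counts or
#'   abundances.
#' @param strength per-feature prior strength; default 0.5.
#' @return matrix of the same shape, strictly positive, rows preserving their
#'   input totals.
#' @export
replace_zeros_bayesian <- function(x, strength = 0.5) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("input must be non-negative")
  tot <- rowSums(x)
  if (any(tot == 0)) stop("all-zero row(s): ",
                          paste(which(tot == 0), collapse = ", "))
  S <- strength * ncol(x)
  out <- x
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (!any(z)) next
    repl_prop <- strength / (tot[i] + S)        # posterior proportion per zero
    shrink <- 1 - sum(z) * repl_prop            # mass left for observed parts
    out[i, z] <- tot[i] * repl_prop
    out[i, !z] <- x[i, !z] * shrink
  }
  out
}

#' Pseudocount zero replacement
#'
#' Replaces exact zeros by a fixed small constant (default 1e-6), leaving all
#' other entries untouched. Used ahead of the CLR transform on relative
#' abundances where a fixed detection floor is wanted.
#'
#' @param x non-negative numeric matrix or vector.
#' @param pseudo replacement value for zeros; default `1e-6`.
#' @return object of the same shape, strictly positive wherever input was 0.
#' @export
replace_zeros_pseudocount <- function(x, pseudo = 1e-6) {
  if (any(x < 0)) stop("input must be non-negative")
  if (pseudo <= 0) stop("pseudo must be positive")
  x[x == 0] <- pseudo
  x
}

#' Centred log-ratio (CLR) transform
#'
#' Maps each composition (row) to unconstrained coordinates:
#' clr_i = ln(x_i) - mean_j ln(x_j), i.e. the log of each part over the row's
#' geometric mean. Rows of the result sum to zero, and the transform is
#' invariant to rescaling a row by a positive constant.
#'
#' @param x strictly positive numeric matrix (samples x features) or vector.
#' @return matrix of CLR coordinates with the input's dimnames.
#' @export
clr_transform <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list("1", names(x)))
  x <- as.matrix(x)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive entry at sample '",
         rownames(x)[bad[1, 1]] %||% bad[1, 1], "', feature '",
         colnames(x)[bad[1, 2]] %||% bad[1, 2],
         "'; replace zeros before the CLR transform")
  lx <- log(x)
  lx - rowMeans(lx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over the non-zero proportions of each sample.
#'
#' @param x abundance matrix (samples x features) or a single abundance vector.
#' @return numeric vector of Shannon indices in nats.
#' @export
shannon <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  vegan::diversity(x, index = "shannon")
}

#' Observed richness
#'
#' Number of features with strictly positive abundance per sample.
#'
#' @param x abundance matrix (samples x features) or vector.
#' @return integer vector of richness values.
#' @export
richness <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.integer(rowSums(x > 0))
}

#' Pairwise Wilcoxon rank-sum tests with BH correction
#'
#' Tests a per-sample scalar (richness, Shannon index, ...) between every
#' unordered pair of populations with a two-sided Wilcoxon (Mann-Whitney)
#' rank-sum test, exact where sample sizes permit, and adjusts the p-values
#' across all pairs with the Benjamini-Hochberg procedure.
#'
#' @param values named numeric vector, one value per sample.
#' @param design a [population_design()] covering the samples.
#' @param column design column to group by; default `"population"`.
#' @return data.frame with columns `group1`, `group2`, `p`, `q`.
#' @export
pairwise_wilcoxon_bh <- function(values, design, column = "population") {
  pairwise_test_bh(values, design, column, function(a, b)
    suppressWarnings(stats::wilcox.test(a, b))$p.value)
}

#' Pairwise Kolmogorov-Smirnov tests with BH correction
#'
#' Two-sample KS test of the per-sample value distributions between every
#' unordered pair of populations (used for e.g. phylum abundance
#' distributions), BH-adjusted across pairs.
#'
#' @inheritParams pairwise_wilcoxon_bh
#' @return data.frame with columns `group1`, `group2`, `D`, `p`, `q`.
#' @export
pairwise_ks_bh <- function(values, design, column = "population") {
  out <- pairwise_test_bh(values, design, column, function(a, b) {
    ks <- suppressWarnings(stats::ks.test(a, b))
    c(D = unname(ks$statistic), p = ks$p.value)
  }, stat_names = c("D", "p"))
  out
}

# Shared driver for the pairwise two-sample tests.
pairwise_test_bh <- function(values, design, column, test, stat_names = "p") {
  groups <- design_groups(design, names(values), column)
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need at least two groups")
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    test(values[groups == pr[1]], values[groups == pr[2]])
  })
  res <- matrix(res, ncol = ncol(pairs),
                dimnames = list(stat_names, NULL))
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t(res), stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min_(j >= i) p_(j) * m / j, capped at 1.
#' Thin wrapper over [stats::p.adjust()] kept as a named operation because
#' every multiple-testing step in the package routes through it.
#'
#' @param p numeric vector of p-values.
#' @return vector of BH-adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Core-community membership
#'
#' A feature is core to a population when it is detected (abundance strictly
#' above `min_abundance`) in at least a `prevalence` fraction of that
#' population's samples; the cross-population core is the intersection of the
#' per-population cores. Both the prevalence fraction and the detection
#' threshold are explicit parameters (defaults: present in every sample at
#' any abundance).
#'
#' @param abund abundance or count matrix (samples x features).
#' @param design a [population_design()] covering the rows of `abund`.
#' @param prevalence required fraction of samples, in (0, 1]; default 1.
#' @param min_abundance detection threshold (exclusive); default 0.
#' @return list with `per_population` (named list of core feature-id vectors)
#'   and `core` (features core to every population).
#' @export
core_membership <- function(abund, design, prevalence = 1.0, min_abundance = 0) {
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must lie in (0, 1]")
  abund <- as.matrix(abund)
  groups <- design_groups(design, rownames(abund))
  lev <- sort(unique(groups))
  per_pop <- lapply(lev, function(g) {
    sub <- abund[groups == g, , drop = FALSE]
    prev <- colMeans(sub > min_abundance)
    colnames(sub)[prev >= prevalence]
  })
  names(per_pop) <- lev
  list(per_population = per_pop, core = Reduce(intersect, per_pop))
}
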