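#' Join CAZyme gene records to glycan substrate groups
#'
#' Annotates a gene-level CAZyme table with substrate group and source
#' category by joining on (family, EC). A gene with no exact (family, EC)
#' match falls back to a family-level map row (blank EC); genes matching
#' neither get `NA` substrate/source, are counted in the unmapped audit, and
#' stay in the table so they still contribute to total-CAZyme denominators.
#'
#' @param genes data.frame with at least `family`, `ec`, `sample` (or
#'   `population`) and `count` columns, e.g. from [generate_cazyme_table()].
#' @param map substrate map data.frame (`family`, `ec`, `substrate`,
#'   `source`); default [default_substrate_map()].
#' @return `genes` with `substrate` and `source` columns added;
#'   `attr(, "unmapped")` holds the number of unmapped gene counts.
#' @export
assign_substrates <- function(genes, map = default_substrate_map()) {
  validate_substrate_map(map)
  if (!all(c("family", "ec", "count") %in% names(genes)))
    stop("genes must have family, ec and count columns")
  exact <- match(paste(genes$family, genes$ec), paste(map$family, map$ec))
  fam_map <- map[map$ec == "", , drop = FALSE]
  fallback <- match(genes$family, fam_map$family)
  use_exact <- !is.na(exact)
  substrate <- ifelse(use_exact, map$substrate[exact],
                      fam_map$substrate[fallback])
  source <- ifelse(use_exact, map$source[exact], fam_map$source[fallback])
  out <- genes
  out$substrate <- substrate
  out$source <- source
  attr(out, "unmapped") <- sum(out$count[is.na(out$substrate)])
  out
}

#' Population-level relative abundance of CAZyme functions
#'
#' For each host population (or any design grouping), the gene count
#' attributed to each substrate (or family) is divided by the *total* CAZyme
#' gene count of that population — unmapped genes inflate the denominator but
#' contribute no substrate row, so the mapped fractions plus the unmapped
#' share sum to one.
#'
#' @param annotated output of [assign_substrates()], with a `population` (or
#'   `sample`) column.
#' @param level `"substrate"` (default), `"source"` or `"family"`.
#' @param by grouping column; default `"population"`.
#' @param scope optional filter: keep only genes whose `genus` column (or
#'   `mag` prefix) equals this value before computing fractions, mirroring
#'   per-genus functional profiles.
#' @return data.frame with columns `group`, `level` value, `count`,
#'   `fraction`.
#' @export
population_relative_abundance <- function(annotated,
                                          level = c("substrate", "source",
                                                    "family"),
                                          by = "population", scope = NULL) {
  level <- match.arg(level)
  if (!by %in% names(annotated)) stop("column '", by, "' absent from table")
  if (!is.null(scope)) {
    if (!"genus" %in% names(annotated))
      stop("scope filtering needs a 'genus' column")
    annotated <- annotated[annotated$genus == scope, , drop = FALSE]
  }
  tot <- tapply(annotated$count, annotated[[by]], sum)
  mapped <- annotated[!is.na(annotated[[level]]), , drop = FALSE]
  agg <- stats::aggregate(mapped$count,
                          by = list(group = mapped[[by]],
                                    value = mapped[[level]]), FUN = sum)
  names(agg)[3] <- "count"
  agg$fraction <- agg$count / as.numeric(tot[agg$group])
  names(agg)[2] <- level
  agg[order(agg$group, -agg$fraction), ]
}

#' Per-sample substrate fraction matrix
#'
#' Spreads an annotated gene table into a samples x substrates matrix of
#' within-sample fractions (gene count on the substrate over the sample's
#' total CAZyme gene count), the input [bootstrap_group_difference()] expects.
#'
#' @inheritParams population_relative_abundance
#' @return numeric matrix, rows = samples, columns = substrates, entries in
#'   \[0, 1\].
#' @export
sample_substrate_fractions <- function(annotated, level = "substrate") {
  if (!"sample" %in% names(annotated))
    stop("table needs a 'sample' column for per-sample fractions")
  samples <- sort(unique(annotated$sample))
  tot <- tapply(annotated$count, annotated$sample, sum)[samples]
  mapped <- annotated[!is.na(annotated[[level]]), , drop = FALSE]
  vals <- sort(unique(mapped[[level]]))
  m <- matrix(0, length(samples), length(vals),
              dimnames = list(samples, vals))
  agg <- stats::aggregate(mapped$count,
                          by = list(s = mapped$sample, v = mapped[[level]]),
                          FUN = sum)
  m[cbind(match(agg$s, samples), match(agg$v, vals))] <- agg$x
  m / as.numeric(tot)
}

#' Bootstrap CI for CLR-transformed substrate differences between host groups
#'
#' Tests, substrate by substrate, whether two host groups differ in their
#' CLR-transformed substrate usage. Zeros are first replaced by a fixed
#' pseudocount (default 1e-6), each sample's substrate fractions are
#' CLR-transformed (by default across substrates within the sample; set
#' `clr_axis = "substrate"` to centre each substrate across hosts instead),
#' and the observed statistic is the difference of group means per substrate.
#' `n_boot` bootstrap replicates resample samples with replacement within
#' each group (stratified, preserving group sizes); the CI is the empirical
#' (alpha/2, 1-alpha/2) percentile interval of the replicate differences, and
#' a substrate is flagged significant when its CI excludes zero.
#'
#' @param fractions samples x substrates matrix, e.g. from
#'   [sample_substrate_fractions()].
#' @param design a [population_design()] covering the rows.
#' @param groups length-2 character vector of host groups to contrast
#'   (difference is group2 minus group1); default: the two groups present.
#' @param column design column holding the grouping; default `"host_group"`.
#' @param n_boot bootstrap replicates; default 10000.
#' @param alpha CI level is 1 - alpha; default 0.05.
#' @param pseudo pseudocount replacing zeros; default 1e-6.
#' @param seed RNG seed.
#' @param clr_axis `"sample"` (CLR across substrates within each sample,
#'   default) or `"substrate"` (CLR across hosts within each substrate).
#' @return data.frame of class `bootstrap_ci`: `substrate`, `estimate`,
#'   `ci_lower`, `ci_upper`, `n_replicates`, `significant`.
#' @export
bootstrap_group_difference <- function(fractions, design, groups = NULL,
                                       column = "host_group",
                                       n_boot = 10000L, alpha = 0.05,
                                       pseudo = 1e-6, seed = 1L,
                                       clr_axis = c("sample", "substrate")) {
  clr_axis <- match.arg(clr_axis)
  fractions <- as.matrix(fractions)
  grp <- design_groups(design, rownames(fractions), column)
  if (is.null(groups)) groups <- sort(unique(grp))
  if (length(groups) != 2) stop("exactly two groups required")
  ia <- which(grp == groups[1]); ib <- which(grp == groups[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  x <- replace_zeros_pseudocount(fractions, pseudo)
  clr <- if (clr_axis == "sample") clr_transform(x) else t(clr_transform(t(x)))
  stat <- function(wa, wb) {
    (wb %*% clr[ib, , drop = FALSE]) / length(ib) -
      (wa %*% clr[ia, , drop = FALSE]) / length(ia)
  }
  est <- colMeans(clr[ib, , drop = FALSE]) - colMeans(clr[ia, , drop = FALSE])
  # Resampling weights are drawn per group level in sorted-level order, so
  # swapping the contrast negates the replicates and mirrors the CI exactly.
  sizes <- list(); sizes[[groups[1]]] <- length(ia); sizes[[groups[2]]] <- length(ib)
  set.seed(seed)
  w <- lapply(sizes[sort(groups)], function(ng)
    t(vapply(seq_len(n_boot), function(i)
      tabulate(sample.int(ng, replace = TRUE), ng), integer(ng))))
  wa <- w[[groups[1]]]; wb <- w[[groups[2]]]
  boots <- stat(wa, wb)                      # n_boot x substrates
  ci <- apply(boots, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  out <- data.frame(substrate = colnames(fractions),
                    estimate = unname(est),
                    ci_lower = ci[1, ], ci_upper = ci[2, ],
                    n_replicates = as.integer(n_boot),
                    stringsAsFactors = FALSE)
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  attr(out, "groups") <- groups
  class(out) <- c("bootstrap_ci", "data.frame")
  out
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  gr <- attr(x, "groups")
  cat("bootstrap_ci:", nrow(x), "substrates, contrast", gr[2], "vs", gr[1],
      "-", sum(x$significant), "significant (CI excludes 0)\n")
  NextMethod()
}
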