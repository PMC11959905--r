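#' Monte-Carlo Dirichlet CLR instances
#'
#' The differential-abundance machinery treats each sample's counts as a draw
#' from an underlying composition and propagates the count uncertainty by
#' Monte Carlo: for each sample, `n_mc` Dirichlet realizations with a uniform
#' prior of `prior` added to every count cell, each realization CLR-transformed.
#' Because the CLR subtracts the row mean log, the Dirichlet normalization
#' cancels and each instance is computed directly from independent Gamma draws.
#'
#' @param m a [count_matrix()] or a bare counts matrix (samples x features).
#' @param n_mc number of Monte-Carlo instances; default 128.
#' @param prior Dirichlet prior added to each count cell; default 0.5.
#' @param seed integer RNG seed.
#' @return numeric array `samples x features x n_mc` of CLR values (each row of
#'   every instance sums to 0), with sample/feature dimnames.
#' @export
dirichlet_clr_instances <- function(m, n_mc = 128L, prior = 0.5, seed = 1L) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (n_mc < 1) stop("n_mc must be >= 1")
  n <- nrow(counts); f <- ncol(counts)
  shape <- counts + prior
  out <- array(NA_real_, dim = c(n, f, n_mc),
               dimnames = list(rownames(counts), colnames(counts), NULL))
  set.seed(seed)
  for (k in seq_len(n_mc)) {
    g <- matrix(stats::rgamma(n * f, shape = shape), n, f)
    lg <- log(g)
    out[, , k] <- lg - rowMeans(lg)
  }
  out
}

#' ALDEx-style effect size between two host groups
#'
#' For every feature, summarizes how far apart two groups' CLR distributions
#' are relative to the within-group spread. Per Monte-Carlo instance, samples
#' are randomly paired across groups to give signed between-group differences,
#' and randomly paired within each group to give absolute within-group
#' differences. Then, per feature:
#' \itemize{
#'   \item `diff_btw` — median of all between-group differences
#'     (group2 minus group1), over pairs and instances;
#'   \item `diff_win` — median over instances of the larger of the two
#'     within-group median absolute differences;
#'   \item `effect = diff_btw / diff_win`.
#' }
#' An absolute effect of at least 1 is the conventional call threshold. When
#' the within-group spread is exactly zero the effect is 0 if `diff_btw` is
#' also 0 and otherwise `sign(diff_btw) * max_effect`.
#'
#' Welch's t-test and a Wilcoxon rank-sum test are run per feature on the
#' CLR values averaged over instances, each BH-corrected across features.
#'
#' @param instances array from [dirichlet_clr_instances()].
#' @param design a [population_design()] covering the samples.
#' @param groups length-2 character vector naming the two groups to contrast
#'   (values of `column`); default: the two groups present, sorted.
#' @param column design column holding the grouping; default `"host_group"`.
#' @param seed RNG seed for the random pairings.
#' @param max_effect cap used for the zero-denominator sentinel; default 20.
#' @return data.frame of class `effect_result` with one row per feature:
#'   `feature`, `diff_btw`, `diff_win`, `effect`, `welch_p`, `welch_q`,
#'   `wilcoxon_p`, `wilcoxon_q`, `significant` (|effect| >= 1).
#' @export
effect_size <- function(instances, design, groups = NULL,
                        column = "host_group", seed = 1L, max_effect = 20) {
  samples <- dimnames(instances)[[1]]
  grp <- design_groups(design, samples, column)
  if (is.null(groups)) groups <- sort(unique(grp))
  if (length(groups) != 2 || groups[1] == groups[2])
    stop("exactly two distinct groups required")
  ia <- which(grp == groups[1]); ib <- which(grp == groups[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  n_mc <- dim(instances)[3]; f <- dim(instances)[2]
  n_pairs <- max(length(ia), length(ib))
  btw <- array(NA_real_, dim = c(n_pairs, f, n_mc))
  win <- matrix(NA_real_, n_mc, f)
  # Random pairings are drawn per group level in sorted-level order, so the
  # draw stream does not depend on which group is named first: swapping the
  # contrast exactly negates the effect.
  idx_of <- list(); idx_of[[groups[1]]] <- ia; idx_of[[groups[2]]] <- ib
  lev_sorted <- sort(groups)
  set.seed(seed)
  for (k in seq_len(n_mc)) {
    prm1 <- lapply(idx_of[lev_sorted], sample)
    prm2 <- lapply(idx_of[lev_sorted], sample)
    pa <- rep_len(prm1[[groups[1]]], n_pairs)
    pb <- rep_len(prm1[[groups[2]]], n_pairs)
    btw[, , k] <- instances[pb, , k, drop = FALSE] -
      instances[pa, , k, drop = FALSE]
    wa <- abs(instances[prm1[[groups[1]]], , k, drop = FALSE] -
                instances[prm2[[groups[1]]], , k, drop = FALSE])
    wb <- abs(instances[prm1[[groups[2]]], , k, drop = FALSE] -
                instances[prm2[[groups[2]]], , k, drop = FALSE])
    win[k, ] <- pmax(apply(wa, 2, stats::median), apply(wb, 2, stats::median))
  }
  diff_btw <- apply(btw, 2, stats::median)
  diff_win <- apply(win, 2, stats::median)
  effect <- ifelse(diff_win > 0, diff_btw / diff_win,
                   ifelse(diff_btw == 0, 0, sign(diff_btw) * max_effect))
  effect <- pmin(pmax(effect, -max_effect), max_effect)

  mean_clr <- rowMeans(instances, dims = 2)
  welch_p <- vapply(seq_len(f), function(j)
    safe_p(stats::t.test(mean_clr[ib, j], mean_clr[ia, j])), numeric(1))
  wilcoxon_p <- vapply(seq_len(f), function(j)
    safe_p(suppressWarnings(stats::wilcox.test(mean_clr[ib, j],
                                               mean_clr[ia, j]))),
    numeric(1))
  out <- data.frame(
    feature = dimnames(instances)[[2]] %||% as.character(seq_len(f)),
    diff_btw = diff_btw, diff_win = diff_win, effect = effect,
    welch_p = welch_p, welch_q = bh_adjust(welch_p),
    wilcoxon_p = wilcoxon_p, wilcoxon_q = bh_adjust(wilcoxon_p),
    significant = abs(effect) >= 1, stringsAsFactors = FALSE)
  attr(out, "groups") <- groups
  class(out) <- c("effect_result", "data.frame")
  out
}

# Constant data make t.test error; report NA for such features instead.
safe_p <- function(expr) tryCatch(expr$p.value, error = function(e) NA_real_)

#' Welch's t-test per feature on Monte-Carlo-averaged CLR values
#'
#' @inheritParams effect_size
#' @return data.frame with `feature`, `welch_p`, `welch_q`.
#' @export
welch_t <- function(instances, design, groups = NULL, column = "host_group") {
  samples <- dimnames(instances)[[1]]
  grp <- design_groups(design, samples, column)
  if (is.null(groups)) groups <- sort(unique(grp))
  if (length(groups) != 2) stop("exactly two groups required")
  mean_clr <- rowMeans(instances, dims = 2)
  ia <- grp == groups[1]; ib <- grp == groups[2]
  p <- apply(mean_clr, 2, function(v) safe_p(stats::t.test(v[ib], v[ia])))
  data.frame(feature = colnames(mean_clr) %||%
               as.character(seq_len(ncol(mean_clr))),
             welch_p = unname(p), welch_q = bh_adjust(unname(p)),
             stringsAsFactors = FALSE)
}

#' Select and rank significant features by effect size
#'
#' @param result an `effect_result` from [effect_size()].
#' @param effect_threshold minimum absolute effect; default 1.
#' @param k optional cap: return at most the top `k` features.
#' @return the rows of `result` with |effect| >= threshold, ordered by
#'   decreasing |effect|.
#' @export
call_significant <- function(result, effect_threshold = 1.0, k = NULL) {
  hits <- result[abs(result$effect) >= effect_threshold, , drop = FALSE]
  hits <- hits[order(-abs(hits$effect)), , drop = FALSE]
  if (!is.null(k)) hits <- utils::head(hits, k)
  hits
}

#' One-call differential abundance between two host groups
#'
#' Convenience wrapper: builds the Dirichlet CLR instances and computes the
#' effect-size table in one step.
#'
#' @inheritParams dirichlet_clr_instances
#' @inheritParams effect_size
#' @export
diff_abundance <- function(m, design, groups = NULL, column = "host_group",
                           n_mc = 128L, prior = 0.5, seed = 1L,
                           max_effect = 20) {
  inst <- dirichlet_clr_instances(m, n_mc = n_mc, prior = prior, seed = seed)
  effect_size(inst, design, groups = groups, column = column,
              seed = seed + 1L, max_effect = max_effect)
}

#' @export
print.effect_result <- function(x, ...) {
  gr <- attr(x, "groups")
  cat("effect_result:", nrow(x), "features, contrast",
      gr[2], "vs", gr[1], "\n")
  cat("  ", sum(x$significant), "feature(s) with |effect| >= 1\n")
  NextMethod()
}
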