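#' Patristic distance matrix of a tree
#'
#' Pairwise tip-to-tip distances, each the sum of branch lengths along the
#' unique path joining two tips.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  stats::cophenetic(tree)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the squared distances among tips (or samples) into between- and
#' within-group components:
#' SS_total = (1/n) * sum_{i<j} d_ij^2,
#' SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2,
#' SS_between = SS_total - SS_within,
#' R^2 = SS_between / SS_total, and
#' pseudo-F = (SS_between / (k - 1)) / (SS_within / (n - k)).
#' The p-value comes from shuffling group labels; when the number of distinct
#' label arrangements is at most `exact_limit` every arrangement is enumerated
#' instead and the p-value is exact.
#'
#' Here R^2 reads as the fraction of tree (distance) variation explained by
#' host population — the phylosymbiosis signal of interest.
#'
#' @param d distance matrix (square symmetric, or a `dist`).
#' @param groups grouping vector aligned with the rows of `d` (or with the
#'   dimnames of `d` if named).
#' @param n_permutations number of label shuffles; default 999.
#' @param seed RNG seed for the shuffles.
#' @param exact_limit enumerate all arrangements when their count is at most
#'   this; default 10000.
#' @return object of class `permanova`: list with `R2`, `pseudo_F`, `p_value`,
#'   `n_permutations` (0 when exact), `exact`, `n`, `groups` (group sizes).
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L,
                      exact_limit = 10000L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(names(groups)) && !is.null(rownames(d)))
    groups <- groups[rownames(d)]
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must align with the distance matrix")
  sizes <- table(groups)
  k <- length(sizes)
  if (k < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members")
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  stat <- function(g) {
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ss_b <- ss_total - ss_w
    c(R2 = ss_b / ss_total,
      F = (ss_b / (k - 1)) / (ss_w / (n - k)))
  }
  obs <- stat(groups)
  n_arr <- choose_multinomial(as.integer(sizes))
  if (n_arr <= exact_limit) {
    perms <- enumerate_groupings(groups)
    f_all <- vapply(perms, function(g) stat(g)[["F"]], numeric(1))
    p <- mean(f_all >= obs[["F"]] - 1e-12)
    n_perm <- 0L
    exact <- TRUE
  } else {
    set.seed(seed)
    f_perm <- vapply(seq_len(n_permutations),
                     function(i) stat(sample(groups))[["F"]], numeric(1))
    p <- (1 + sum(f_perm >= obs[["F"]] - 1e-12)) / (1 + n_permutations)
    n_perm <- as.integer(n_permutations)
    exact <- FALSE
  }
  structure(list(R2 = unname(obs[["R2"]]), pseudo_F = unname(obs[["F"]]),
                 p_value = p, n_permutations = n_perm, exact = exact,
                 n = n, groups = sizes),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p %s %.4g (%s)\n",
              x$R2, x$pseudo_F, "=", x$p_value,
              if (x$exact) "exact" else
                paste(x$n_permutations, "permutations")))
  cat("  n =", x$n, "tips;", length(x$groups), "groups (",
      paste(names(x$groups), x$groups, sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

# Number of distinct label arrangements n! / prod(n_g!).
choose_multinomial <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# All distinct assignments of the multiset `groups` to positions 1..n.
enumerate_groupings <- function(groups) {
  lev <- unique(groups)
  n <- length(groups)
  recurse <- function(positions, remaining) {
    if (length(remaining) == 1) {
      g <- character(n)
      g[positions[[1]]] <- remaining[1]
      return(list(stats::setNames(g, NULL)))
    }
    lev1 <- remaining[1]
    n1 <- sum(groups == lev1)
    free <- positions[[1]]
    picks <- utils::combn(free, n1, simplify = FALSE)
    out <- list()
    for (pk in picks) {
      rest <- recurse(list(setdiff(free, pk)), remaining[-1])
      out <- c(out, lapply(rest, function(g) { g[pk] <- lev1; g }))
    }
    out
  }
  recurse(list(seq_len(n)), lev)
}

#' Screen a set of gene (or strain) trees for host-population signal
#'
#' Runs [permanova()] on the patristic distances of every tree in a
#' [labeled_tree_set()], BH-adjusts the p-values across trees, and flags
#' trees whose R^2 exceeds `r2_threshold` as showing strong host-population
#' specificity. Trees are skipped (with a recorded reason) when they are not
#' amenable to the test: fewer than 2 populations with at least 2 tips each,
#' or fewer than 4 tips overall. A sample represented by several tips in one
#' tree is collapsed to the copy closest to the tree-wide tip centroid
#' (`multi_copy = "closest"`) or kept as is (`"keep_all"`, in which case every
#' copy carries its sample's population label).
#'
#' @param treeset a [labeled_tree_set()].
#' @param design optional [population_design()]; defaults to the design
#'   stored in the tree set.
#' @param r2_threshold R^2 above which a tree passes; default 0.5.
#' @param n_permutations,seed,exact_limit passed to [permanova()].
#' @param multi_copy how to handle multiple tips per sample.
#' @return data.frame with one row per analyzed tree (`tree`, `n_tips`, `R2`,
#'   `pseudo_F`, `p`, `q`, `pass`); skipped trees and reasons in
#'   `attr(, "skipped")`, mean R^2 across analyzed trees in
#'   `attr(, "mean_R2")`.
#' @export
gene_screen <- function(treeset, design = NULL, r2_threshold = 0.5,
                        n_permutations = 999L, seed = 1L,
                        exact_limit = 10000L,
                        multi_copy = c("closest", "keep_all")) {
  multi_copy <- match.arg(multi_copy)
  design <- design %||% treeset$design
  rows <- list(); skipped <- list()
  for (nm in names(treeset$trees)) {
    tree <- treeset$trees[[nm]]
    samples <- treeset$tip_map[tree$tip.label]
    if (anyNA(samples)) {
      skipped[[nm]] <- "unmapped tip labels"; next
    }
    d <- patristic_distances(tree)
    if (multi_copy == "closest" && anyDuplicated(samples)) {
      centro <- colMeans(d)  # mean distance to all tips: centrality
      keep <- vapply(split(seq_along(samples), samples),
                     function(ix) ix[which.min(centro[ix])],
                     integer(1))
      d <- d[keep, keep, drop = FALSE]
      samples <- samples[keep]
    }
    pops <- design_groups(design, samples)
    sizes <- table(pops)
    if (length(samples) < 4) {
      skipped[[nm]] <- "fewer than 4 tips"; next
    }
    if (sum(sizes >= 2) < 2) {
      skipped[[nm]] <- "fewer than 2 populations with >= 2 tips"; next
    }
    usable <- pops %in% names(sizes)[sizes >= 2]
    pm <- permanova(d[usable, usable, drop = FALSE], pops[usable],
                    n_permutations = n_permutations, seed = seed,
                    exact_limit = exact_limit)
    rows[[nm]] <- data.frame(tree = nm, n_tips = sum(usable), R2 = pm$R2,
                             pseudo_F = pm$pseudo_F, p = pm$p_value,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(tree = character(), n_tips = integer(), R2 = numeric(),
               pseudo_F = numeric(), p = numeric())
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out$pass <- out$R2 > r2_threshold
  attr(out, "skipped") <- unlist(skipped) %||% character(0)
  attr(out, "mean_R2") <- if (nrow(out) > 0) mean(out$R2) else NA_real_
  out
}
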