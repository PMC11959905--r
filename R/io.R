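#' Labelled tree set
#'
#' Bundles a list of trees with the tip-label-to-sample mapping and the
#' sample-to-population design, the unit of input for the phylosymbiosis
#' screen.
#'
#' @param trees named list of [ape::phylo] trees (names default to
#'   `tree_1`, ...).
#' @param tip_map named character vector mapping tip labels to sample ids;
#'   default: identity over all tip labels seen.
#' @param design a [population_design()] covering the mapped samples.
#' @return list of class `labeled_tree_set` with elements `trees`, `tip_map`,
#'   `design`.
#' @export
labeled_tree_set <- function(trees, tip_map = NULL, design = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(all(vapply(trees, inherits, logical(1), "phylo")))
  if (is.null(names(trees)))
    names(trees) <- paste0("tree_", seq_along(trees))
  tips <- unique(unlist(lapply(trees, `[[`, "tip.label")))
  if (is.null(tip_map)) tip_map <- stats::setNames(tips, tips)
  unmapped <- setdiff(tips, names(tip_map))
  if (length(unmapped) > 0)
    warning("unmapped tip labels: ",
            paste(utils::head(unmapped, 5), collapse = ", "))
  structure(list(trees = trees, tip_map = tip_map, design = design),
            class = "labeled_tree_set")
}

#' @export
print.labeled_tree_set <- function(x, ...) {
  cat("labeled_tree_set:", length(x$trees), "tree(s),",
      length(unique(x$tip_map)), "samples\n")
  invisible(x)
}

#' Read a counts TSV into a count matrix
#'
#' Expects a tab-delimited file with a header row of feature ids and a first
#' column of sample ids. Companion files may supply feature lengths
#' (`feature`, `length_kb`) and coverage fractions
#' (`sample`, `feature`, `expected`, `observed`).
#'
#' @param path counts TSV path.
#' @param lengths_path optional lengths TSV path.
#' @param coverage_path optional coverage TSV path.
#' @return a [count_matrix()].
#' @export
read_count_tsv <- function(path, lengths_path = NULL, coverage_path = NULL) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr[-1]))
    stop("duplicate feature ids in header of ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts TSV needs a sample column plus features")
  samples <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("missing/non-numeric cell at sample '", samples[bad[1, 1]],
         "', feature '", colnames(m)[bad[1, 2]], "'")
  if (any(m < 0)) stop("negative count in ", path)
  if (any(m != round(m))) stop("non-integer count in ", path)
  rownames(m) <- samples
  lengths_kb <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
    lengths_kb <- stats::setNames(lt$length_kb, lt$feature)
  }
  cov_e <- cov_o <- NULL
  if (!is.null(coverage_path)) {
    ct <- utils::read.delim(coverage_path, stringsAsFactors = FALSE)
    cov_e <- cov_o <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    idx <- cbind(match(ct$sample, rownames(m)), match(ct$feature, colnames(m)))
    if (anyNA(idx)) stop("coverage TSV references unknown sample/feature")
    cov_e[idx] <- ct$expected
    cov_o[idx] <- ct$observed
  }
  count_matrix(m, lengths_kb, cov_e, cov_o)
}

#' Write a count matrix (and companions) as TSV
#'
#' @param m a [count_matrix()].
#' @param path counts TSV path.
#' @param lengths_path,coverage_path optional companion output paths.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(m, path, lengths_path = NULL,
                            coverage_path = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  tab <- data.frame(sample = rownames(m$counts), m$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path) && !is.null(m$lengths_kb))
    utils::write.table(
      data.frame(feature = names(m$lengths_kb), length_kb = m$lengths_kb),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coverage_path) && !is.null(m$coverage_expected)) {
    grid <- expand.grid(sample = rownames(m$counts),
                        feature = colnames(m$counts),
                        stringsAsFactors = FALSE)
    utils::write.table(
      data.frame(grid, expected = as.vector(m$coverage_expected),
                 observed = as.vector(m$coverage_observed)),
      coverage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a design TSV
#'
#' Tab-delimited with columns `sample`, `population` and optionally
#' `host_group`.
#'
#' @param path design TSV path.
#' @return a [population_design()] data.frame.
#' @export
read_design_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(tab)))
    stop("design TSV needs 'sample' and 'population' columns")
  population_design(tab$sample, tab$population, tab$host_group)
}

#' Read newick trees into a labelled tree set
#'
#' Accepts a single newick file (one or many trees) or a directory of `.nwk`
#' files (one record per tree, named after the file).
#'
#' @param path newick file or directory.
#' @param tip_map optional named vector mapping tip labels to sample ids.
#' @param design optional [population_design()].
#' @return a [labeled_tree_set()].
#' @export
read_newick_set <- function(path, tip_map = NULL, design = NULL) {
  parse_file <- function(f) {
    parsed <- ape::read.tree(f)
    if (is.null(parsed)) stop("could not parse newick in ", f)
    if (inherits(parsed, "phylo")) list(parsed) else unclass(parsed)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nwk$|\\.tre$|\\.newick$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no newick files in ", path)
    trees <- list()
    for (f in files) {
      parsed <- parse_file(f)
      stem <- sub("\\.[^.]+$", "", basename(f))
      names(parsed) <- if (length(parsed) == 1) stem
                       else paste0(stem, "_", seq_along(parsed))
      trees <- c(trees, parsed)
    }
  } else {
    trees <- parse_file(path)
    names(trees) <- paste0("tree_", seq_along(trees))
  }
  labeled_tree_set(trees, tip_map = tip_map, design = design)
}

#' Write a labelled tree set as newick files
#'
#' @param treeset a [labeled_tree_set()].
#' @param dir output directory (created if absent); one `.nwk` per tree.
#' @return the directory, invisibly.
#' @export
write_newick_set <- function(treeset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(treeset$trees))
    ape::write.tree(treeset$trees[[nm]], file.path(dir, paste0(nm, ".nwk")))
  invisible(dir)
}

# Internal tidy-TSV writer shared by the pipeline stages.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
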