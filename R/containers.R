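#' Construct a sample-by-feature count matrix
#'
#' The basic container for MAG (or taxon) read counts: a samples x features
#' matrix of non-negative integers, optionally carrying per-feature genome
#' lengths (kilobases) and per-cell genome coverage fractions. All downstream
#' abundance operations ([rarefy()], [coverage_filter()], [tpm_transform()])
#' consume this container.
#'
#' @param counts numeric matrix, samples in rows, features in columns, with
#'   dimnames. Values must be non-negative and finite.
#' @param lengths_kb optional named numeric vector of feature lengths in
#'   kilobases (> 0), names matching `colnames(counts)`.
#' @param coverage_expected,coverage_observed optional matrices with the same
#'   dimensions as `counts`, giving the expected and observed covered fraction
#'   of each genome in each sample, both in \[0, 1\].
#' @return an object of class `count_matrix`: a list with elements `counts`,
#'   `lengths_kb`, `coverage_expected`, `coverage_observed`.
#' @export
count_matrix <- function(counts, lengths_kb = NULL,
                         coverage_expected = NULL, coverage_observed = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and feature colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!is.null(lengths_kb)) {
    lengths_kb <- lengths_kb[colnames(counts)]
    if (anyNA(lengths_kb))
      stop("lengths_kb missing for some features")
    if (any(lengths_kb <= 0))
      stop("lengths_kb must be strictly positive")
  }
  for (nm in c("coverage_expected", "coverage_observed")) {
    cov <- get(nm)
    if (!is.null(cov)) {
      cov <- as.matrix(cov)
      if (!identical(dim(cov), dim(counts)))
        stop(nm, " must match the dimensions of counts")
      if (any(cov < 0 | cov > 1, na.rm = TRUE))
        stop(nm, " fractions must lie in [0, 1]")
      assign(nm, cov)
    }
  }
  if (xor(is.null(coverage_expected), is.null(coverage_observed)))
    stop("coverage_expected and coverage_observed must be supplied together")
  structure(list(counts = counts, lengths_kb = lengths_kb,
                 coverage_expected = coverage_expected,
                 coverage_observed = coverage_observed),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "samples x", ncol(x$counts), "features\n")
  cat("  total reads:", format(sum(x$counts), big.mark = ","),
      "| lengths:", if (is.null(x$lengths_kb)) "absent" else "present",
      "| coverage:", if (is.null(x$coverage_expected)) "absent" else "present",
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a sample-to-population design table
#'
#' Maps each sample to its host population and (optionally) a coarser host
#' group such as the host genus (`Homo` vs `Pan`). This is the grouping factor
#' for every comparative statistic in the package.
#'
#' @param sample character vector of unique sample ids.
#' @param population character/factor of host population per sample.
#' @param host_group optional character/factor of coarser host grouping;
#'   defaults to the population itself.
#' @return data.frame with columns `sample`, `population`, `host_group`.
#' @export
population_design <- function(sample, population, host_group = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("duplicate sample ids in design")
  population <- as.character(population)
  if (length(population) != length(sample))
    stop("population must have one entry per sample")
  if (is.null(host_group)) host_group <- population
  host_group <- as.character(host_group)
  if (length(host_group) != length(sample))
    stop("host_group must have one entry per sample")
  data.frame(sample = sample, population = population,
             host_group = host_group, stringsAsFactors = FALSE)
}

# Internal: look up a grouping vector for a set of sample ids.
design_groups <- function(design, samples, column = "population") {
  idx <- match(samples, design$sample)
  if (anyNA(idx))
    stop("samples missing from design: ",
         paste(utils::head(samples[is.na(idx)], 5), collapse = ", "))
  design[[column]][idx]
}
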