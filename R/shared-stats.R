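## Shared statistics: BH-FDR, catalog intersection, sample QC, zero filter.

#' Benjamini-Hochberg q-values
#'
#' Step-up BH false-discovery-rate adjustment, returned in input order.
#' A validated wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0, 1\]; `NaN` is an error.
#' @return Numeric vector of q-values, same length and order as `pvals`.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.5)) # 0.04 0.04 0.04 0.50
#' @export
bhFdr <- function(pvals) {
  if (any(is.nan(pvals))) stop("NaN p-values are not allowed", call. = FALSE)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Intersect two gene-symbol catalogs
#'
#' Sorted, deduplicated intersection of two symbol lists, with the sizes a
#' cross-species analysis reports (both inputs, union, intersection).
#'
#' @param symbolsA,symbolsB character vectors of gene symbols.
#' @return Sorted character vector of shared symbols; attribute `"sizes"` is
#'   a named vector (`a`, `b`, `union`, `intersection`).
#' @export
intersectCatalogs <- function(symbolsA, symbolsB) {
  a <- unique(trimws(as.character(symbolsA)))
  b <- unique(trimws(as.character(symbolsB)))
  shared <- sort(intersect(a, b))
  attr(shared, "sizes") <- c(a = length(a), b = length(b),
                             union = length(union(a, b)),
                             intersection = length(shared))
  shared
}

#' Within-group pairwise-correlation sample QC
#'
#' Computes Pearson correlations of log2(count + 1) between every pair of
#' samples within each experimental group (samples equal in species, sex,
#' status and tissue). A sample fails when any of its within-group pairs
#' drops below `threshold`; samples in singleton groups are untestable.
#'
#' @param counts a [CountMatrix-class].
#' @param threshold minimum admissible pairwise Pearson r (default 0.90).
#' @return data.frame with one row per sample: `sample`, `group`, `min_r`
#'   (NA for singletons), `pass` (logical, NA when untestable).
#' @export
qcSampleCorrelation <- function(counts, threshold = 0.90) {
  cts <- log2(counts(counts) + 1)
  meta <- sampleData(counts)
  grp <- interaction(meta$species, meta$sex, meta$status, meta$tissue,
                     drop = TRUE)
  min_r <- rep(NA_real_, ncol(cts))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    r <- cor(cts[, idx, drop = FALSE])
    diag(r) <- NA
    min_r[idx] <- apply(r, 2, min, na.rm = TRUE)
  }
  data.frame(sample = colnames(cts), group = as.character(grp),
             min_r = min_r, pass = ifelse(is.na(min_r), NA, min_r >= threshold))
}

#' Remove genes with zero counts in every sample
#'
#' @param counts a [CountMatrix-class].
#' @return A [CountMatrix-class] without all-zero genes; attribute
#'   `"n_removed"` counts the removed genes.
#' @export
zeroFilter <- function(counts) {
  keep <- rowSums(counts(counts)) > 0
  out <- CountMatrix(counts(counts)[keep, , drop = FALSE], sampleData(counts))
  attr(out, "n_removed") <- sum(!keep)
  out
}
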