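## Central S4 containers. All matrices are genes x tissues (TissuePanel) or
## genes x samples (CountMatrix); gene symbols are row names and the single
## source of identity (case-sensitive, whitespace-stripped at ingest).

#' TissuePanel: per-gene, per-tissue differential-expression summaries
#'
#' Holds, for one contrast (condition of interest over reference), three
#' aligned genes x tissues matrices: the DE p-value, the log2 fold-change,
#' and the normalized mean expression across all groups. Missing (gene,
#' tissue) entries are `NA` and are skipped, never imputed, by downstream
#' statistics.
#'
#' @slot p numeric matrix of p-values in (0, 1], `NA` allowed.
#' @slot log2fc numeric matrix of log2 fold-changes, `NA` allowed.
#' @slot meanExpr numeric matrix of nonnegative normalized mean expression,
#'   `NA` allowed.
#'
#' @seealso [TissuePanel()], [readDETable()], [mergePanels()]
#' @export
setClass("TissuePanel",
  representation(p = "matrix", log2fc = "matrix", meanExpr = "matrix"))

setValidity("TissuePanel", function(object) {
  msg <- character()
  dims <- list(dim(object@p), dim(object@log2fc), dim(object@meanExpr))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    msg <- c(msg, "p, log2fc and meanExpr must share dimensions")
  gn <- rownames(object@p)
  tn <- colnames(object@p)
  if (is.null(gn) || is.null(tn))
    msg <- c(msg, "matrices must carry gene rownames and tissue colnames")
  if (!is.null(gn) && anyDuplicated(gn))
    msg <- c(msg, paste("duplicate gene symbols:",
                        paste(unique(gn[duplicated(gn)]), collapse = ", ")))
  for (s in c("log2fc", "meanExpr")) {
    if (!identical(rownames(slot(object, s)), gn) ||
        !identical(colnames(slot(object, s)), tn))
      msg <- c(msg, sprintf("dimnames of '%s' disagree with 'p'", s))
  }
  pv <- object@p
  if (any(pv <= 0 | pv > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (any(object@meanExpr < 0, na.rm = TRUE))
    msg <- c(msg, "meanExpr must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a TissuePanel
#'
#' @param p,log2fc,meanExpr genes x tissues numeric matrices with identical
#'   dimnames (gene symbols as rownames, tissue names as colnames).
#' @return A [TissuePanel-class] object.
#' @examples
#' m <- matrix(c(0.01, 0.5), 2, 1, dimnames = list(c("A", "B"), "liver"))
#' TissuePanel(p = m, log2fc = m * 0, meanExpr = m * 0 + 10)
#' @export
TissuePanel <- function(p, log2fc, meanExpr) {
  new("TissuePanel", p = as.matrix(p), log2fc = as.matrix(log2fc),
      meanExpr = as.matrix(meanExpr))
}

#' @rdname accessors
#' @export
setMethod("geneIds", "TissuePanel", function(x) rownames(x@p))

#' @rdname accessors
#' @export
setMethod("tissueNames", "TissuePanel", function(x) colnames(x@p))

#' @rdname accessors
#' @export
setMethod("pValues", "TissuePanel", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("foldChanges", "TissuePanel", function(x) x@log2fc)

#' @rdname accessors
#' @export
setMethod("meanExpr", "TissuePanel", function(x) x@meanExpr)

setMethod("show", "TissuePanel", function(object) {
  cat(sprintf("TissuePanel: %d genes x %d tissues\n",
              nrow(object@p), ncol(object@p)))
  cat(" tissues:", paste(head(tissueNames(object), 8), collapse = ", "),
      if (ncol(object@p) > 8) "...", "\n")
  cat(sprintf(" missing entries: %d of %d\n",
              sum(is.na(object@p)), length(object@p)))
})

#' GeneSetCollection: named sets of gene symbols
#'
#' @slot sets named list; each element a character vector of unique, nonempty
#'   gene symbols.
#' @slot description named character vector of per-set descriptions (may be
#'   empty strings).
#' @seealso [readGMT()], [writeGMT()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
      msg <- c(msg, "all sets must be named")
    sizes <- lengths(object@sets)
    if (any(sizes < 1L)) msg <- c(msg, "sets must be nonempty")
    ok <- vapply(object@sets,
                 function(s) is.character(s) && all(nzchar(s)), logical(1))
    if (!all(ok)) msg <- c(msg, "set members must be nonempty strings")
    if (!identical(names(object@description), names(object@sets)))
      msg <- c(msg, "description names must match set names")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols; duplicate
#'   members within a set are removed.
#' @param description optional character vector of per-set descriptions.
#' @return A [GeneSetCollection-class].
#' @examples
#' GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C", "D")))
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  if (is.null(description)) description <- rep("", length(sets))
  names(description) <- names(sets)
  new("GeneSetCollection", sets = sets, description = description)
}

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @param i set name or index.
#' @rdname GeneSetCollection
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %s\n", length(object@sets),
              if (length(object@sets))
                paste(range(lengths(object@sets)), collapse = "-") else "-"))
})

#' CountMatrix: raw read counts with sample metadata
#'
#' @slot counts nonnegative integer-valued genes x samples matrix.
#' @slot sampleData data.frame with one row per sample and columns
#'   `species`, `sex`, `status`, `tissue` (complete, no `NA`).
#' @seealso [zeroFilter()], [qcSampleCorrelation()]
#' @export
setClass("CountMatrix",
  representation(counts = "matrix", sampleData = "data.frame"))

setValidity("CountMatrix", function(object) {
  msg <- character()
  cts <- object@counts
  if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be finite nonnegative integers")
  need <- c("species", "sex", "status", "tissue")
  if (!all(need %in% colnames(object@sampleData)))
    msg <- c(msg, paste("sampleData must contain columns:",
                        paste(need, collapse = ", ")))
  else if (anyNA(object@sampleData[need]))
    msg <- c(msg, "sampleData metadata must be complete for every sample")
  if (nrow(object@sampleData) != ncol(cts))
    msg <- c(msg, "one sampleData row required per counts column")
  if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts genes x samples matrix of nonnegative integers.
#' @param sampleData data.frame with columns `species`, `sex`, `status`,
#'   `tissue`, one row per sample (in column order of `counts`).
#' @return A [CountMatrix-class].
#' @export
CountMatrix <- function(counts, sampleData) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must carry gene rownames")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (nrow(sampleData) == ncol(counts))
    rownames(sampleData) <- colnames(counts)
  new("CountMatrix", counts = counts, sampleData = sampleData)
}

#' @rdname accessors
#' @export
setMethod("geneIds", "CountMatrix", function(x) rownames(x@counts))

#' Counts and metadata accessors
#'
#' @param x a [CountMatrix-class].
#' @return `counts()` the genes x samples matrix; `sampleData()` the sample
#'   metadata data.frame.
#' @export
counts <- function(x) {
  stopifnot(is(x, "CountMatrix"))
  x@counts
}

#' @rdname counts
#' @export
sampleData <- function(x) {
  stopifnot(is(x, "CountMatrix"))
  x@sampleData
}

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix: %d genes x %d samples (%d groups)\n",
              nrow(object@counts), ncol(object@counts),
              nrow(unique(object@sampleData[c("species", "sex", "status",
                                              "tissue")]))))
})

#' TOMatrix: signed topological overlap matrix
#'
#' Symmetric gene x gene topological-overlap values in \[0, 1\], diagonal 1,
#' together with the network parameters that produced it.
#'
#' @slot tom symmetric numeric matrix in \[0, 1\] with unit diagonal.
#' @slot beta soft-threshold power used for the signed adjacency.
#' @slot corType correlation used ("bicor" or "pearson").
#' @seealso [signedTOM()], [setConnectivity()], [connectivityP()]
#' @export
setClass("TOMatrix",
  representation(tom = "matrix", beta = "numeric", corType = "character"))

setValidity("TOMatrix", function(object) {
  msg <- character()
  tm <- object@tom
  if (nrow(tm) != ncol(tm)) msg <- c(msg, "tom must be square")
  if (max(abs(tm - t(tm))) > 1e-10) msg <- c(msg, "tom must be symmetric")
  if (any(tm < -1e-12 | tm > 1 + 1e-12)) msg <- c(msg, "tom must lie in [0, 1]")
  if (any(abs(diag(tm) - 1) > 1e-12)) msg <- c(msg, "tom diagonal must be 1")
  if (length(object@beta) != 1L || object@beta <= 0)
    msg <- c(msg, "beta must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("tomValues", "TOMatrix", function(x) x@tom)

#' @rdname accessors
#' @export
setMethod("geneIds", "TOMatrix", function(x) rownames(x@tom))

setMethod("show", "TOMatrix", function(object) {
  off <- object@tom[upper.tri(object@tom)]
  cat(sprintf("TOMatrix: %d genes, beta = %g (%s), off-diagonal range [%.3g, %.3g]\n",
              nrow(object@tom), object@beta, object@corType,
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
})

#' CohortTable: per-individual status episodes with terminal events
#'
#' One row per status episode. Episodes of an individual must be ordered,
#' non-overlapping and contiguous from the first observation age up to the
#' terminal (death or censoring) age, which every row of the individual
#' repeats in `event`/`event_age`.
#'
#' @slot table data.frame with columns `id`, `status`, `start`, `end`,
#'   `event` ("death" or "censored"), `event_age`.
#' @seealso [statusExposure()], [simulateCohort()], [readCohort()]
#' @export
setClass("CohortTable", representation(table = "data.frame"))

setValidity("CohortTable", function(object) {
  tab <- object@table
  need <- c("id", "status", "start", "end", "event", "event_age")
  if (!all(need %in% colnames(tab)))
    return(paste("missing columns:", paste(setdiff(need, colnames(tab)),
                                           collapse = ", ")))
  msg <- character()
  if (any(tab$start < 0)) msg <- c(msg, "ages must be nonnegative")
  if (any(tab$end <= tab$start)) msg <- c(msg, "episodes must have end > start")
  if (!all(tab$event %in% c("death", "censored")))
    msg <- c(msg, "event must be 'death' or 'censored'")
  for (id in unique(tab$id)) {
    ep <- tab[tab$id == id, ]
    ep <- ep[order(ep$start), ]
    if (nrow(ep) > 1 && any(abs(ep$end[-nrow(ep)] - ep$start[-1]) > 1e-9))
      msg <- c(msg, sprintf("episodes of individual '%s' overlap or leave gaps", id))
    if (abs(ep$end[nrow(ep)] - ep$event_age[1]) > 1e-9)
      msg <- c(msg, sprintf("episodes of '%s' do not reach the terminal age", id))
    if (length(unique(ep$event)) > 1 || length(unique(ep$event_age)) > 1)
      msg <- c(msg, sprintf("inconsistent terminal event for '%s'", id))
  }
  if (length(msg)) head(msg, 5) else TRUE
})

#' Construct a CohortTable
#'
#' @param table data.frame of status episodes; see [CohortTable-class].
#' @return A [CohortTable-class].
#' @export
CohortTable <- function(table) new("CohortTable", table = as.data.frame(table))

#' Episode table accessor
#'
#' @param x a [CohortTable-class].
#' @return The episode data.frame.
#' @export
cohortEpisodes <- function(x) {
  stopifnot(is(x, "CohortTable"))
  x@table
}

setMethod("show", "CohortTable", function(object) {
  tab <- object@table
  one <- tab[!duplicated(tab$id), ]
  cat(sprintf("CohortTable: %d individuals, %d episodes, %d deaths / %d censored\n",
              length(unique(tab$id)), nrow(tab),
              sum(one$event == "death"), sum(one$event == "censored")))
})
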