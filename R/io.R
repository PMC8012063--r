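## Readers/writers for the package's delimited interchange formats.
## DE tables are TSV with header columns gene/pvalue/log2fc/base_mean;
## gene sets are standard GMT; counts are TSV plus a sample-metadata TSV;
## cohorts are episode TSVs. Outputs carry a provenance comment line.

.P_CLAMP <- 1e-300  # p = 0 from upstream DE tools is clamped here before any log

provenance_line <- function(seed = NA, confHash = NA) {
  sprintf("# xtenrich %s seed=%s config=%s",
          as.character(packageVersion("xtenrich")),
          as.character(seed), as.character(confHash))
}

write_tsv_prov <- function(df, path, seed = NA, confHash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(seed, confHash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-tissue differential-expression summary table
#'
#' Reads a DESeq2-style TSV with header columns `gene`, `pvalue`, `log2fc`,
#' `base_mean` and returns a one-tissue [TissuePanel-class]. Rows whose
#' p-value is non-numeric or outside \[0, 1\] are rejected and reported; a
#' p-value of exactly 0 (as DE tools emit for extreme genes) is clamped to
#' 1e-300 with a message so that log p stays finite downstream.
#'
#' @param path file path of the delimited table.
#' @param tissue tissue name for the single column of the returned panel.
#' @return A [TissuePanel-class] with one tissue. The attribute `"rejected"`
#'   holds the rejected rows (with a `reason` column), `"n_clamped"` the
#'   number of zero p-values clamped.
#' @seealso [writeDETable()], [mergePanels()]
#' @export
readDETable <- function(path, tissue) {
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("gene", "pvalue", "log2fc", "base_mean")
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols))
    stop("DE table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$gene <- trimws(as.character(tab$gene))
  p <- suppressWarnings(as.numeric(tab$pvalue))
  bad <- is.na(p) & !is.na(tab$pvalue) & nzchar(tab$pvalue)
  oob <- !is.na(p) & (p < 0 | p > 1)
  rejected <- tab[bad | oob, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(bad[bad | oob], "non-numeric p", "p outside [0, 1]")
  keep <- !(bad | oob)
  tab <- tab[keep, , drop = FALSE]
  p <- p[keep]
  dup <- unique(tab$gene[duplicated(tab$gene)])
  if (length(dup))
    stop("duplicate gene symbols in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  n_clamped <- sum(p == 0, na.rm = TRUE)
  if (n_clamped) {
    message(n_clamped, " zero p-value(s) clamped to ", .P_CLAMP)
    p[!is.na(p) & p == 0] <- .P_CLAMP
  }
  dn <- list(tab$gene, tissue)
  panel <- TissuePanel(
    p = matrix(p, ncol = 1, dimnames = dn),
    log2fc = matrix(as.numeric(tab$log2fc), ncol = 1, dimnames = dn),
    meanExpr = matrix(as.numeric(tab$base_mean), ncol = 1, dimnames = dn))
  attr(panel, "rejected") <- rejected
  attr(panel, "n_clamped") <- n_clamped
  panel
}

#' Write a one-or-more-tissue panel back to DE tables
#'
#' Inverse of [readDETable()]: writes one TSV per tissue with the standard
#' header and a provenance comment line.
#'
#' @param panel a [TissuePanel-class].
#' @param paths character vector of output paths, one per tissue.
#' @param seed,confHash provenance fields recorded in the header comment.
#' @return Invisibly, the paths written.
#' @export
writeDETable <- function(panel, paths, seed = NA, confHash = NA) {
  stopifnot(length(paths) == length(tissueNames(panel)))
  for (k in seq_along(paths)) {
    keep <- !is.na(pValues(panel)[, k])
    df <- data.frame(gene = geneIds(panel)[keep],
                     pvalue = pValues(panel)[keep, k],
                     log2fc = foldChanges(panel)[keep, k],
                     base_mean = meanExpr(panel)[keep, k])
    write_tsv_prov(df, paths[k], seed, confHash)
  }
  invisible(paths)
}

#' Merge single-tissue panels into one multi-tissue panel
#'
#' Takes the union of gene symbols across panels; (gene, tissue) cells absent
#' from a contributing panel become `NA` and are flagged as missing.
#'
#' @param panels list of [TissuePanel-class] objects with distinct tissues.
#' @return A merged [TissuePanel-class].
#' @export
mergePanels <- function(panels) {
  stopifnot(length(panels) >= 1L)
  tissues <- unlist(lapply(panels, tissueNames))
  if (anyDuplicated(tissues))
    stop("tissue names must be distinct across panels", call. = FALSE)
  genes <- sort(unique(unlist(lapply(panels, geneIds))))
  blank <- matrix(NA_real_, length(genes), length(tissues),
                  dimnames = list(genes, tissues))
  p <- fc <- ex <- blank
  col <- 0L
  for (pan in panels) {
    idx <- match(geneIds(pan), genes)
    for (k in seq_along(tissueNames(pan))) {
      col <- col + 1L
      p[idx, col] <- pValues(pan)[, k]
      fc[idx, col] <- foldChanges(pan)[, k]
      ex[idx, col] <- meanExpr(pan)[, k]
    }
  }
  TissuePanel(p = p, log2fc = fc, meanExpr = ex)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: per line a set name, a description, then tab-separated
#' member symbols. Duplicate members within a set are deduplicated; empty
#' sets are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A [GeneSetCollection-class].
#' @seealso [writeGMT()]
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(GeneSetCollection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " of '", path, "' has fewer than 3 fields",
         call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty set(s) dropped: ",
            paste(nm[empty], collapse = ", "))
    sets <- sets[!empty]; nm <- nm[!empty]; desc <- desc[!empty]
  }
  names(sets) <- nm
  GeneSetCollection(sets, description = desc)
}

#' Write a GeneSetCollection as GMT
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection@description[[nm]], collection[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a counts matrix plus sample metadata
#'
#' @param countsPath TSV of genes x samples read counts (first column `gene`).
#' @param metaPath TSV with columns `sample`, `species`, `sex`, `status`,
#'   `tissue`.
#' @return A [CountMatrix-class].
#' @export
readCounts <- function(countsPath, metaPath) {
  cts <- read.delim(countsPath, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  meta <- read.delim(metaPath, sep = "\t", header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
  genes <- trimws(cts[[1]])
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- genes
  idx <- match(colnames(m), meta$sample)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  CountMatrix(m, meta[idx, c("species", "sex", "status", "tissue")])
}

#' Read a cohort episode table
#'
#' TSV with columns `id`, `status`, `start`, `end`, `event`, `event_age`
#' (ages in years).
#'
#' @param path file path.
#' @return A [CohortTable-class].
#' @export
readCohort <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  CohortTable(tab)
}
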