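#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 containers.
#' `geneIds()` returns the gene symbols of an object, `tissueNames()` the
#' tissue names of a [TissuePanel-class], `pValues()`, `foldChanges()` and
#' `meanExpr()` its three summary matrices, `geneSets()` the named list of a
#' [GeneSetCollection-class], and `tomValues()` the numeric matrix of a
#' [TOMatrix-class].
#'
#' @param x an object.
#' @return The slot contents (see above); accessors never expose slots
#'   directly to user code.
#' @name accessors
#' @aliases geneIds tissueNames pValues foldChanges meanExpr geneSets tomValues
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("tissueNames", function(x) standardGeneric("tissueNames"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @rdname accessors
#' @export
setGeneric("meanExpr", function(x) standardGeneric("meanExpr"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("tomValues", function(x) standardGeneric("tomValues"))
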