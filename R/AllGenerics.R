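#' @rdname VariantTable-accessors
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @rdname VariantTable-accessors
#' @export
setGeneric("depths", function(x, ...) standardGeneric("depths"))

#' @rdname VariantTable-accessors
#' @export
setGeneric("altReads", function(x, ...) standardGeneric("altReads"))

#' @rdname VariantTable-accessors
#' @export
setGeneric("siteQual", function(x, ...) standardGeneric("siteQual"))

#' @rdname VariantTable-accessors
#' @export
setGeneric("isIndel", function(x, ...) standardGeneric("isIndel"))

#' @rdname VariantTable-accessors
#' @export
setGeneric("sampleClasses", function(x, ...) standardGeneric("sampleClasses"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("exonRanges", function(x, ...) standardGeneric("exonRanges"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("cdsRanges", function(x, ...) standardGeneric("cdsRanges"))

#' @rdname SimScreen-accessors
#' @export
setGeneric("screenVariants", function(x, ...) standardGeneric("screenVariants"))

#' @rdname SimScreen-accessors
#' @export
setGeneric("screenTruth", function(x, ...) standardGeneric("screenTruth"))

#' @rdname SimScreen-accessors
#' @export
setGeneric("screenExclusions", function(x, ...)
    standardGeneric("screenExclusions"))

#' @rdname SimScreen-accessors
#' @export
setGeneric("screenAlignments", function(x, ...)
    standardGeneric("screenAlignments"))

#' @rdname SimScreen-accessors
#' @export
setGeneric("screenGenes", function(x, ...) standardGeneric("screenGenes"))

#' Accessors for \code{VariantTable}
#'
#' `genotypes()` returns the alt-dosage matrix (0 = hom-ref, 1 = het,
#' 2 = hom-alt, NA = missing), `depths()` and `altReads()` the read-count
#' matrices, `siteQual()` the site QUAL vector, `isIndel()` the indel flag,
#' and `sampleClasses()` the phenotype class label per sample.
#'
#' @param x a `VariantTable`
#' @param ... unused
#' @return matrix or vector aligned with the rows/columns of `x`.
#' @name VariantTable-accessors
NULL

#' @rdname VariantTable-accessors
#' @export
setMethod("genotypes", "VariantTable", function(x, ...) assay(x, "geno"))

#' @rdname VariantTable-accessors
#' @export
setMethod("depths", "VariantTable", function(x, ...) assay(x, "depth"))

#' @rdname VariantTable-accessors
#' @export
setMethod("altReads", "VariantTable", function(x, ...) assay(x, "altReads"))

#' @rdname VariantTable-accessors
#' @export
setMethod("siteQual", "VariantTable", function(x, ...)
    mcols(rowRanges(x))$qual)

#' @rdname VariantTable-accessors
#' @export
setMethod("isIndel", "VariantTable", function(x, ...)
    mcols(rowRanges(x))$indel)

#' @rdname VariantTable-accessors
#' @export
setMethod("sampleClasses", "VariantTable", function(x, ...) {
    cl <- colData(x)$class
    names(cl) <- colnames(x)
    cl
})

#' Samples belonging to a phenotype class
#'
#' @param x a `VariantTable`
#' @param class phenotype class label(s) as in the manifest
#' @return character vector of sample ids.
#' @export
samplesOf <- function(x, class) {
    stopifnot(is(x, "VariantTable"))
    colnames(x)[colData(x)$class %in% class]
}

#' Accessors for \code{GeneModel}
#'
#' @param x a `GeneModel`
#' @param ... unused
#' @name GeneModel-accessors
NULL

#' @rdname GeneModel-accessors
#' @export
setMethod("exonRanges", "GeneModel", function(x, ...) x@exons)

#' @rdname GeneModel-accessors
#' @export
setMethod("cdsRanges", "GeneModel", function(x, ...) x@cds)

#' Accessors for \code{SimScreen}
#'
#' @param x a `SimScreen`
#' @param ... unused
#' @name SimScreen-accessors
NULL

#' @rdname SimScreen-accessors
#' @export
setMethod("screenVariants", "SimScreen", function(x, ...) x@variants)

#' @rdname SimScreen-accessors
#' @export
setMethod("screenTruth", "SimScreen", function(x, ...) x@truth)

#' @rdname SimScreen-accessors
#' @export
setMethod("screenExclusions", "SimScreen", function(x, ...) x@exclusions)

#' @rdname SimScreen-accessors
#' @export
setMethod("screenAlignments", "SimScreen", function(x, ...) x@alignments)

#' @rdname SimScreen-accessors
#' @export
setMethod("screenGenes", "SimScreen", function(x, ...) x@genes)
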