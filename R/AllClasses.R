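#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame queryHits subjectHits
#' @importFrom IRanges IRanges CharacterList overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqlevels keepSeqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowRanges<- colData colData<- assay assays
NULL

# Genotype dosage coding used throughout: integer copies of the alternate
# allele per sample (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing call).

#' Container for multi-sample SNV calls of a screen cohort
#'
#' `VariantTable` extends `RangedSummarizedExperiment`: rows are biallelic
#' variant records (multiallelic sites are split per alternate allele), columns
#' are samples. Assays are `geno` (alt-allele dosage, 0/1/2/NA), `depth`
#' (total reads) and `altReads` (reads supporting the alternate allele).
#' `rowRanges()` carries `ref`, `alt`, `qual` (site-level phred-scaled
#' quality) and `indel` metadata columns; `colData()` carries the sample
#' manifest (`class`, `pedigree`).
#'
#' @export
setClass("VariantTable", contains = "RangedSummarizedExperiment")

setValidity("VariantTable", function(object) {
    msg <- character()
    need <- c("geno", "depth", "altReads")
    if (!all(need %in% names(assays(object))))
        msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
    else {
        g <- assay(object, "geno"); d <- assay(object, "depth")
        a <- assay(object, "altReads")
        if (any(g[!is.na(g)] < 0L | g[!is.na(g)] > 2L))
            msg <- c(msg, "geno dosages must be 0, 1, 2 or NA")
        ok <- !is.na(d) & !is.na(a)
        if (any(a[ok] > d[ok]) || any(a[ok] < 0L) || any(d[ok] < 0L))
            msg <- c(msg, "altReads must satisfy 0 <= altReads <= depth")
    }
    cols <- c("ref", "alt", "qual", "indel")
    if (!all(cols %in% names(mcols(rowRanges(object)))))
        msg <- c(msg, paste("rowRanges mcols must include",
                            paste(cols, collapse = ", ")))
    if (!all(c("class", "pedigree") %in% names(colData(object))))
        msg <- c(msg, "colData must include 'class' and 'pedigree'")
    if (length(msg)) msg else TRUE
})

#' Exclusion sets for putative ENU SNV filtering
#'
#' Named collections of genomic evidence that a variant is *not* a fresh ENU
#' lesion: interval sets (repeat regions and other positional masks) and site
#' sets (dbSNP-like catalogs, strain variants, in-house pedigrees). Interval
#' membership is positional; site membership is allele-aware per category
#' when `alleleAware[category]` is `TRUE`.
#'
#' @slot intervals `GRangesList`, one element per interval category.
#' @slot sites `GRangesList`, one element per site category; each `GRanges`
#'   has an `alt` metadata column.
#' @slot alleleAware named `logical`, one entry per site category.
#' @export
setClass("ExclusionSet",
    representation(intervals = "GRangesList", sites = "GRangesList",
                   alleleAware = "logical"))

setValidity("ExclusionSet", function(object) {
    msg <- character()
    if (length(object@sites) &&
        !all(vapply(object@sites, function(g) "alt" %in% names(mcols(g)),
                    logical(1))))
        msg <- c(msg, "every site set needs an 'alt' metadata column")
    if (!identical(sort(names(object@alleleAware)),
                   sort(names(object@sites))))
        msg <- c(msg, "alleleAware must be named after the site categories")
    if (anyDuplicated(c(names(object@intervals), names(object@sites))))
        msg <- c(msg, "category names must be unique across intervals/sites")
    if (length(msg)) msg else TRUE
})

#' Exon/CDS gene model used for positional effect classification
#'
#' @slot exons `GRanges` of exon intervals with `gene` and `transcript`
#'   metadata columns.
#' @slot cds `GRanges` of coding-sequence intervals with the same columns.
#' @export
setClass("GeneModel", representation(exons = "GRanges", cds = "GRanges"))

setValidity("GeneModel", function(object) {
    if (length(object@exons) && any(width(object@exons) < 1L))
        "exon intervals must have positive width" else TRUE
})

#' Configuration of a simulated inbred ENU screen
#'
#' Defines the breeding design and sequencing model: genome extents, expected
#' founder heterozygous ENU load (Poisson), genetic map density, the causal
#' locus, optional planted deletion and dominant modifier, cohort size,
#' sequencing depth/error, and background contamination injected per
#' exclusion category (false SNVs that a real caller would emit and the
#' exclusion filters should remove).
#'
#' @export
setClass("SimConfig",
    representation(genome = "Seqinfo", enuLoad = "numeric",
                   cmPerMb = "numeric", causalChrom = "character",
                   causalPos = "integer", deletion = "list",
                   modifier = "list", nAffected = "integer",
                   meanDepth = "numeric", errorRate = "numeric",
                   contamRates = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    sl <- seqlengths(object@genome)
    if (!object@causalChrom %in% names(sl))
        msg <- c(msg, "causal chromosome not in genome")
    else if (object@causalPos < 1L || object@causalPos > sl[object@causalChrom])
        msg <- c(msg, "causal position outside its chromosome")
    if (length(object@deletion)) {
        d <- object@deletion
        if (!all(c("chrom", "start", "end") %in% names(d)) ||
            d$start >= d$end)
            msg <- c(msg, "deletion must have chrom, start < end")
    }
    if (object@enuLoad < 0 || object@meanDepth <= 0 ||
        object@errorRate < 0 || object@cmPerMb < 0 ||
        any(object@contamRates < 0))
        msg <- c(msg, "rates and depths must be non-negative")
    if (length(msg)) msg else TRUE
})

#' A simulated screen with its ground truth
#'
#' Holds the emitted `VariantTable`, the founder variant set, raw inherited
#' dosages (before read sampling), the exclusion sets that the contamination
#' was drawn from, soft-clipped alignments over any planted deletion, a toy
#' gene model placing the causal variant in coding sequence, and a `truth`
#' list naming the causal variant, deletion breakpoints and planted modifier.
#'
#' @export
setClass("SimScreen",
    representation(variants = "VariantTable", founder = "GRanges",
                   dosage = "matrix", exclusions = "ExclusionSet",
                   alignments = "data.frame", genes = "GeneModel",
                   truth = "list", config = "SimConfig"))

setValidity("SimScreen", function(object) {
    msg <- character()
    tr <- object@truth
    if (!is.null(tr$causal_id) && nrow(object@dosage)) {
        i <- match(tr$causal_id, rownames(object@dosage))
        if (is.na(i)) msg <- c(msg, "truth causal_id absent from dosage rows")
        else {
            aff <- tr$affected_samples
            if (length(aff) && any(object@dosage[i, aff] != 2L))
                msg <- c(msg, "affected samples must be hom-alt at the causal variant")
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "VariantTable", function(object) {
    cat("VariantTable:", nrow(object), "variant records x", ncol(object),
        "samples\n")
    cl <- table(colData(object)$class)
    cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
    cat("  indels flagged:", sum(mcols(rowRanges(object))$indel), "\n")
})

setMethod("show", "ExclusionSet", function(object) {
    cat("ExclusionSet\n  interval categories:",
        paste(names(object@intervals), collapse = ", "), "\n  site categories:",
        paste(names(object@sites), collapse = ", "), "\n")
})

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel:", length(unique(object@exons$gene)), "genes,",
        length(object@exons), "exons,", length(object@cds), "CDS intervals\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", length(seqlengths(object@genome)), "chromosomes,",
        "ENU load", object@enuLoad, ", causal", object@causalChrom, ":",
        object@causalPos, ", n affected", object@nAffected, ", depth",
        object@meanDepth, "x\n")
})

setMethod("show", "SimScreen", function(object) {
    cat("SimScreen:", ncol(object@variants), "samples,",
        nrow(object@variants), "emitted variant records\n")
    cat("  causal:", object@truth$causal_id, "\n")
    if (!is.null(object@truth$deletion))
        cat("  planted deletion:", object@truth$deletion$chrom, ":",
            object@truth$deletion$start, "-", object@truth$deletion$end, "\n")
})
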