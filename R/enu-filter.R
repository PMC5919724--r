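# Fixed attribution order for audit counts: exclusion categories first (in
# the order below when present), then quality, then depth.
.AUDIT_ORDER <- c("dbsnp", "strain", "pedigree", "repeats")

#' Filtering parameters for putative ENU SNVs
#'
#' @param minSiteQual minimum site QUAL (phred-scaled), default 30.
#' @param minDepth minimum read depth, default 5; interpreted per
#'   `depthMode` of [filterEnuSnps].
#' @param categories exclusion categories to apply; `NULL` (default) applies
#'   every category present in the [ExclusionSet].
#' @return a list of class `FilterParams`.
#' @export
filterParams <- function(minSiteQual = 30, minDepth = 5, categories = NULL) {
    stopifnot(minSiteQual >= 0, minDepth >= 0)
    structure(list(minSiteQual = minSiteQual, minDepth = minDepth,
                   categories = categories), class = "FilterParams")
}

.failReasons <- function(x, excl, params, depthMode, samples) {
    hits <- if (is.null(excl)) {
        matrix(FALSE, nrow(x), 0L)
    } else exclusionHits(excl, x, params$categories)
    cats <- colnames(hits)
    ord <- c(intersect(.AUDIT_ORDER, cats), setdiff(cats, .AUDIT_ORDER))
    hits <- hits[, ord, drop = FALSE]

    qual <- siteQual(x)
    qualFail <- is.na(qual) | qual < params$minSiteQual
    dp <- depths(x)[, samples, drop = FALSE]
    depthFail <- if (depthMode == "per_sample_min") {
        apply(dp, 1L, min) < params$minDepth
    } else rowSums(dp) < params$minDepth

    reasons <- vector("list", nrow(x))
    for (i in seq_len(nrow(x))) {
        r <- as.character(colnames(hits)[hits[i, ]])
        if (qualFail[i]) r <- c(r, "quality")
        if (depthFail[i]) r <- c(r, "depth")
        reasons[[i]] <- r
    }
    CharacterList(reasons)
}

#' Filter a VariantTable down to high-quality putative ENU SNVs
#'
#' Retains records that are in no enabled exclusion category, have site
#' quality at or above `minSiteQual`, and meet the depth criterion. Every
#' input record's failure reasons are tallied into an audit table stored in
#' `metadata(result)$filterAudit` (first-reason attribution in a fixed
#' category order, so audits are deterministic); the retained records carry
#' an empty `failReasons` column.
#'
#' @param x a [VariantTable].
#' @param excl an [ExclusionSet], or `NULL` to skip exclusion screening.
#' @param params a [filterParams] list.
#' @param depthMode `"per_sample_min"` (every analyzed sample must reach
#'   `minDepth`; the per-individual workflow) or `"pooled_total"` (summed
#'   depth across analyzed samples; the combined-reads workflow).
#' @param samples samples whose depths are checked (default: all).
#' @return the filtered [VariantTable].
#' @export
filterEnuSnps <- function(x, excl = NULL, params = filterParams(),
                          depthMode = c("per_sample_min", "pooled_total"),
                          samples = colnames(x)) {
    depthMode <- match.arg(depthMode)
    if (nrow(x) == 0L) {
        metadata(x)$filterAudit <- .auditTable(CharacterList())
        return(x)
    }
    reasons <- .failReasons(x, excl, params, depthMode, samples)
    keep <- S4Vectors::elementNROWS(reasons) == 0L
    out <- x[keep, ]
    mcols(rowRanges(out))$failReasons <- reasons[keep]
    metadata(out)$filterAudit <- .auditTable(reasons)
    out
}

.auditTable <- function(reasons) {
    first <- vapply(reasons, function(r)
        if (length(r)) r[1] else "retained", character(1))
    lv <- c(.AUDIT_ORDER, "quality", "depth", "retained")
    extra <- setdiff(unique(first), lv)
    tab <- table(factor(first, levels = c(setdiff(lv, "retained"), extra,
                                          "retained")))
    data.frame(reason = names(tab), n = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Audit of the last filtering pass
#'
#' Counts of removed records per first failure reason plus the retained
#' count; the column sums to the size of the filter input.
#'
#' @param x a [VariantTable] returned by [filterEnuSnps].
#' @return `data.frame` with columns `reason`, `n`.
#' @export
auditFilter <- function(x) {
    a <- metadata(x)$filterAudit
    if (is.null(a)) stop("no filter audit present; run filterEnuSnps() first")
    a
}
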