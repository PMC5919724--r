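#' Positional effect classification of a variant
#'
#' A variant is `coding` when its position falls inside any CDS interval,
#' `splice_proximal` when it lies outside every exon but within
#' `spliceMargin` bases of an exon boundary (distance 1 = the base adjacent
#' to the exon edge; strand is ignored), and `other` otherwise.
#'
#' @param v `GRanges` of variant positions (width 1), e.g.
#'   `rowRanges(x)`, or a [VariantTable].
#' @param genes a [GeneModel].
#' @param spliceMargin splice-proximity margin in bases (default 10).
#' @return `data.frame` with columns `effect` (factor: coding,
#'   splice_proximal, other) and `distance` (bases to the nearest exon; 0
#'   inside an exon, NA when the chromosome has no exons).
#' @export
annotateEffect <- function(v, genes, spliceMargin = 10) {
    gr <- if (is(v, "VariantTable")) rowRanges(v) else v
    exons <- exonRanges(genes); cds <- cdsRanges(genes)
    noModel <- !(as.character(seqnames(gr)) %in%
                 as.character(unique(seqnames(exons))))
    if (any(noModel))
        warning(sum(noModel),
                " variant(s) on chromosomes absent from the gene model")
    inCds <- suppressWarnings(overlapsAny(gr, cds, ignore.strand = TRUE))
    inExon <- suppressWarnings(overlapsAny(gr, exons, ignore.strand = TRUE))
    dist <- rep(NA_real_, length(gr))
    if (length(exons)) {
        nr <- suppressWarnings(
            distanceToNearest(gr, exons, ignore.strand = TRUE))
        # GenomicRanges distance counts gap bases; base-adjacent = gap 0 =
        # distance 1 in the splice-margin convention used here
        dist[queryHits(nr)] <- mcols(nr)$distance +
            ifelse(inExon[queryHits(nr)], 0L, 1L)
    }
    dist[inExon] <- 0
    effect <- rep("other", length(gr))
    effect[!is.na(dist) & !inExon & dist >= 1 & dist <= spliceMargin] <-
        "splice_proximal"
    effect[inCds] <- "coding"
    data.frame(effect = factor(effect,
                               c("coding", "splice_proximal", "other")),
               distance = dist)
}

#' Candidate variants within called regions
#'
#' Restricts an ENU-filtered table to variants inside any called region that
#' are homozygous-alt in every listed sample and classified `coding` or
#' `splice_proximal`. Rows are ordered by region rank, then position.
#'
#' @param x ENU-filtered [VariantTable].
#' @param regions ranked `GRanges` from [callRegions].
#' @param genes a [GeneModel].
#' @param samples samples that must all be homozygous (default: all).
#' @param spliceMargin see [annotateEffect].
#' @return `GRanges` of candidates with `ref`, `alt`, `qual`, `gene`,
#'   `effect`, `distance`, `region_rank` metadata columns.
#' @export
candidatesInRegions <- function(x, regions, genes, samples = colnames(x),
                                spliceMargin = 10) {
    gr <- rowRanges(x)
    if (!length(regions) || nrow(x) == 0L) return(gr[integer(0)])
    ov <- findOverlaps(gr, regions, ignore.strand = TRUE)
    rank <- rep(NA_integer_, length(gr))
    # keep the best (lowest) region rank when regions overlap
    for (i in rev(seq_along(regions)))
        rank[queryHits(ov)[subjectHits(ov) == i]] <- i
    hom <- .homMatrix(x, samples)
    keep <- !is.na(rank) & rowSums(hom) == length(samples)
    eff <- annotateEffect(gr[keep], genes, spliceMargin)
    sel <- eff$effect %in% c("coding", "splice_proximal")
    out <- gr[keep][sel]
    exons <- exonRanges(genes)
    gene <- rep(NA_character_, length(out))
    if (length(exons) && length(out)) {
        nr <- distanceToNearest(out, exons, ignore.strand = TRUE)
        gene[queryHits(nr)] <- mcols(exons)$gene[subjectHits(nr)]
    }
    keepCols <- intersect(c("ref", "alt", "qual", "id"), names(mcols(out)))
    mcols(out) <- cbind(mcols(out)[keepCols],
                        DataFrame(gene = gene,
                                  effect = as.character(eff$effect)[sel],
                                  distance = eff$distance[sel],
                                  region_rank = rank[keep][sel]))
    out[order(mcols(out)$region_rank, as.integer(seqnames(out)), start(out))]
}

#' Score validation genotypes against candidates
#'
#' Mirrors follow-up genotyping of additional affected embryos: a candidate
#' is `excluded` as soon as any validation sample is not homozygous-alt,
#' `supported` otherwise.
#'
#' @param candidates `GRanges` from [candidatesInRegions] (names or
#'   `chrom:pos:alt` keys identify variants).
#' @param validation `data.frame` with columns `variant` (key
#'   `chrom:pos:alt`), `sample`, `geno` (alt dosage 0/1/2 or NA).
#' @return `data.frame` per candidate: `variant`, `n_concordant`,
#'   `n_discordant`, `verdict`.
#' @export
genotypeConcordance <- function(candidates, validation) {
    key <- paste(as.character(seqnames(candidates)), start(candidates),
                 mcols(candidates)$alt, sep = ":")
    unknown <- setdiff(validation$variant, key)
    if (length(unknown))
        stop("validation rows reference unknown variant(s): ",
             paste(unknown, collapse = ", "))
    res <- lapply(key, function(k) {
        rows <- validation[validation$variant == k, , drop = FALSE]
        conc <- sum(!is.na(rows$geno) & rows$geno == 2L)
        disc <- nrow(rows) - conc
        data.frame(variant = k, n_concordant = conc, n_discordant = disc,
                   verdict = if (disc > 0L) "excluded" else "supported",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
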