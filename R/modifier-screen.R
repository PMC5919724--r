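#' Shared heterozygous/homozygous candidates for a dominant modifier
#'
#' Per-individual procedure: retain variants at which every case sample has
#' depth at or above `minDepth` and carries the alternate allele (het or
#' hom-alt), while no contrast sample carries it. With
#' `contrastMode = "het_only"` only heterozygous contrast carriers exclude a
#' variant (the permissive reading); the default `"any_alt"` excludes on any
#' alternate copy.
#'
#' @param x ENU-filtered [VariantTable].
#' @param cases case sample ids (must be non-empty).
#' @param contrasts contrast sample ids (may be empty).
#' @param minDepth per-case-sample depth floor (default 5 reads).
#' @param contrastMode `"any_alt"` (default) or `"het_only"`.
#' @return [VariantTable] subset in deterministic position order.
#' @export
sharedDominantCandidates <- function(x, cases, contrasts = character(),
                                     minDepth = 5,
                                     contrastMode = c("any_alt", "het_only")) {
    contrastMode <- match.arg(contrastMode)
    if (!length(cases)) stop("case class must contain at least one sample")
    unknown <- setdiff(c(cases, contrasts), colnames(x))
    if (length(unknown))
        stop("sample id(s) not in the table: ",
             paste(unknown, collapse = ", "))
    g <- genotypes(x); dp <- depths(x)
    gc <- g[, cases, drop = FALSE]
    carrier <- gc >= 1L; carrier[is.na(carrier)] <- FALSE
    dpOk <- dp[, cases, drop = FALSE] >= minDepth
    keep <- rowSums(carrier & dpOk) == length(cases)
    if (length(contrasts)) {
        gx <- g[, contrasts, drop = FALSE]
        bad <- if (contrastMode == "any_alt") gx >= 1L else gx == 1L
        bad[is.na(bad)] <- FALSE
        keep <- keep & rowSums(bad) == 0L
    }
    out <- x[keep, ]
    out[order(as.integer(seqnames(rowRanges(out))), start(rowRanges(out))), ]
}

#' Class-specific sliding-window SNP counts
#'
#' Combined-reads procedure: for each phenotype class, keep SNVs with site
#' quality at or above `minQual` and class-pooled depth at or above
#' `minDepth` that are present in that class (at least one member carries
#' the alternate allele) and absent from every other class, then count them
#' per sliding window. Class-specific sets are pairwise disjoint by
#' construction.
#'
#' @param x ENU-filtered [VariantTable].
#' @param windows `GRanges` from [makeWindows] (10 Mb / 1 Mb by default in
#'   the published procedure).
#' @param classes named list of sample-id vectors; default: the phenotype
#'   classes of the manifest (at least 2 required).
#' @param minQual site quality floor (default 30).
#' @param minDepth class-pooled depth floor (default 5).
#' @param presenceMode carriage by called genotype (`"genotype"`, default)
#'   or by any supporting read (`"reads"`).
#' @return `GRanges` of windows with one count column per class.
#' @export
classSpecificWindowCounts <- function(x, windows, classes = NULL,
                                      minQual = 30, minDepth = 5,
                                      presenceMode = c("genotype", "reads")) {
    presenceMode <- match.arg(presenceMode)
    if (is.null(classes)) {
        cl <- sampleClasses(x)
        classes <- split(names(cl), cl)
    }
    if (length(classes) < 2L)
        stop("need at least two phenotype classes")
    qualOk <- !is.na(siteQual(x)) & siteQual(x) >= minQual
    pres <- vapply(classes, function(s) {
        m <- if (presenceMode == "genotype") .carrierMatrix(x, s)
             else altReads(x)[, s, drop = FALSE] > 0L
        rowSums(m) > 0L
    }, logical(nrow(x)))
    counts <- lapply(names(classes), function(cl) {
        others <- setdiff(names(classes), cl)
        dpOk <- rowSums(depths(x)[, classes[[cl]], drop = FALSE]) >= minDepth
        spec <- qualOk & dpOk & pres[, cl] &
            rowSums(pres[, others, drop = FALSE]) == 0L
        ov <- findOverlaps(rowRanges(x)[spec], windows, ignore.strand = TRUE)
        tabulate(subjectHits(ov), nbins = length(windows))
    })
    out <- granges(windows)
    mcols(out) <- DataFrame(setNames(counts, names(classes)))
    out
}

#' Validate modifier candidates against follow-up genotypes
#'
#' Strict co-segregation: a candidate is `rejected` if any with-phenotype
#' validation sample lacks the alternate allele or any without-phenotype
#' sample carries it; otherwise `compatible`.
#'
#' @param candidates a [VariantTable] (e.g. from
#'   [sharedDominantCandidates]) or `GRanges` with `alt` column.
#' @param validation `data.frame` with columns `variant` (`chrom:pos:alt`),
#'   `sample`, `phenotype` (logical: feature present), `geno` (dosage).
#' @return `data.frame`: `variant`, `verdict`.
#' @export
modifierValidation <- function(candidates, validation) {
    gr <- if (is(candidates, "VariantTable")) rowRanges(candidates)
          else candidates
    key <- paste(as.character(seqnames(gr)), start(gr), mcols(gr)$alt,
                 sep = ":")
    verdict <- vapply(key, function(k) {
        rows <- validation[validation$variant == k, , drop = FALSE]
        carries <- !is.na(rows$geno) & rows$geno >= 1L
        if (any(rows$phenotype & !carries) || any(!rows$phenotype & carries))
            "rejected" else "compatible"
    }, character(1))
    data.frame(variant = key, verdict = verdict, row.names = NULL,
               stringsAsFactors = FALSE)
}
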