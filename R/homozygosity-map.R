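#' Tile sliding windows over a genome
#'
#' Windows start at 0, `step`, 2*`step`, ... on each chromosome (reported as
#' 1-based closed `GRanges`). With `tail = "truncate"` additional clipped
#' windows are appended until the chromosome tail is covered; with `"drop"`
#' only full-width windows are kept. Following the published mapping
#' parameters, "10 Mb windows with a 1 Mb overlap" is realized as
#' `windowSize = 1e7, step = 1e6` (consecutive windows share 9 Mb); the
#' 50 kb refinement ("window and overlap size 50 kb") is `5e4/5e4`, a
#' non-overlapping tiling.
#'
#' @param genome a `Seqinfo` (see [genomeBuild]).
#' @param windowSize window width in bp (default 10 Mb).
#' @param step slide in bp (default 1 Mb); must satisfy `0 < step <=
#'   windowSize`.
#' @param tail `"truncate"` (default) or `"drop"`.
#' @return `GRanges` of windows, ordered by chromosome then start.
#' @export
makeWindows <- function(genome, windowSize = 1e7, step = 1e6,
                        tail = c("truncate", "drop")) {
    tail <- match.arg(tail)
    if (step <= 0) stop("step must be positive")
    if (step > windowSize) stop("step must not exceed windowSize")
    sl <- seqlengths(genome)
    out <- lapply(names(sl), function(chr) {
        len <- sl[[chr]]
        starts0 <- seq(0, max(0, len - 1), by = step)
        full <- starts0 + windowSize <= len
        if (tail == "drop") {
            starts0 <- starts0[full]
        } else {
            # keep full windows, then append clipped tail windows stepping
            # on from the last full start until the chromosome is covered
            sel <- starts0[full]
            covered <- if (length(sel)) sel[length(sel)] + windowSize else 0
            nxt <- if (length(sel)) sel[length(sel)] + step else 0
            while (covered < len) {
                sel <- c(sel, nxt)
                covered <- min(nxt + windowSize, len)
                nxt <- nxt + step
            }
            starts0 <- sel
        }
        if (!length(starts0)) return(GRanges(seqinfo = genome))
        ends <- pmin(starts0 + windowSize, len)
        GRanges(chr, IRanges(start = starts0 + 1, end = ends),
                seqinfo = genome)
    })
    sort(do.call(c, out), ignore.strand = TRUE)
}

.homMatrix <- function(x, samples) {
    g <- genotypes(x)[, samples, drop = FALSE]
    hom <- g == 2L; hom[is.na(hom)] <- FALSE
    hom
}

.carrierMatrix <- function(x, samples) {
    g <- genotypes(x)[, samples, drop = FALSE]
    cr <- g >= 1L; cr[is.na(cr)] <- FALSE
    cr
}

#' Per-window homozygosity statistics
#'
#' For each window computes the three mapping statistics: `n_snps` (filtered
#' ENU SNVs in the window), `hom_count` (SNVs homozygous-alt in *every*
#' analyzed sample; a missing genotype never counts as homozygous),
#' `hom_pct` (100 * hom_count / n_snps, 0 for empty windows) and `avg_naf`
#' (novel allele frequency: per SNV, reads are pooled across the analyzed
#' samples and the alt-read fraction taken; these per-SNV fractions are then
#' averaged unweighted over the window). With `nafMode = "per_sample"` the
#' per-sample fractions are averaged instead of pooling reads.
#'
#' By default (`segregatingOnly = TRUE`) only SNVs at which at least one
#' analyzed sample carries the alternate allele enter `n_snps` and
#' `avg_naf`: a joint cohort VCF contains sites private to other pedigrees
#' at which the analyzed subset is uniformly hom-ref, and those carry no
#' mapping information for this subset.
#'
#' @param x an ENU-filtered [VariantTable].
#' @param windows `GRanges` from [makeWindows].
#' @param samples analyzed sample ids (default: all).
#' @param segregatingOnly count only SNVs segregating in `samples`.
#' @param nafMode `"pooled"` (default) or `"per_sample"`.
#' @return `GRanges` of the windows with metadata columns `n_snps`,
#'   `hom_count`, `hom_pct`, `avg_naf`, `empty`; the analyzed samples are in
#'   `metadata()$samples`.
#' @export
windowStats <- function(x, windows, samples = colnames(x),
                        segregatingOnly = TRUE,
                        nafMode = c("pooled", "per_sample")) {
    nafMode <- match.arg(nafMode)
    stopifnot(length(samples) >= 1L)
    hom <- .homMatrix(x, samples)
    homAll <- rowSums(hom) == length(samples)
    seg <- if (segregatingOnly) rowSums(.carrierMatrix(x, samples)) > 0L
           else rep(TRUE, nrow(x))
    dp <- depths(x)[, samples, drop = FALSE]
    ar <- altReads(x)[, samples, drop = FALSE]
    naf <- if (nafMode == "pooled") {
        den <- rowSums(dp)
        ifelse(den > 0, rowSums(ar) / den, 0)
    } else {
        frac <- ifelse(dp > 0, ar / dp, NA_real_)
        out <- rowMeans(frac, na.rm = TRUE)
        out[is.nan(out)] <- 0
        out
    }
    ov <- findOverlaps(rowRanges(x), windows, ignore.strand = TRUE)
    q <- queryHits(ov); s <- subjectHits(ov)
    use <- seg[q]
    nSnps <- tabulate(s[use], nbins = length(windows))
    homCount <- tabulate(s[use & homAll[q]], nbins = length(windows))
    nafSum <- rep(0, length(windows))
    if (any(use)) {
        agg <- rowsum(naf[q[use]], group = s[use])
        nafSum[as.integer(rownames(agg))] <- agg[, 1L]
    }
    out <- granges(windows)
    mcols(out) <- DataFrame(
        n_snps = nSnps, hom_count = homCount,
        hom_pct = ifelse(nSnps > 0, 100 * homCount / nSnps, 0),
        avg_naf = ifelse(nSnps > 0, nafSum / nSnps, 0),
        empty = nSnps == 0L)
    metadata(out)$samples <- samples
    out
}

.defaultMinHomCount <- function(stats)
    max(5, 0.5 * mean(mcols(stats)$hom_count))

.qualifies <- function(stats, minHomCount, minHomPct, minAvgNaf) {
    m <- mcols(stats)
    !m$empty & m$hom_count >= minHomCount & m$hom_pct >= minHomPct &
        m$avg_naf >= minAvgNaf
}

#' Call candidate causal regions from window statistics
#'
#' Windows passing all three thresholds are merged when overlapping or
#' adjacent; each region carries the statistics of its peak window. Regions
#' are ranked by peak `hom_count`, ties broken by `hom_pct`, then `avg_naf`,
#' then coordinate.
#'
#' @param stats output of [windowStats].
#' @param minHomCount minimum homozygous count; default
#'   `max(5, 0.5 * mean(hom_count))` over all windows of the scan.
#' @param minHomPct minimum homozygous percentage (default 80).
#' @param minAvgNaf minimum average novel allele frequency (default 0.8).
#' @return `GRanges` of regions ordered by rank, with peak statistics, the
#'   count of qualifying windows and the supporting samples in
#'   `mcols()$samples`.
#' @export
callRegions <- function(stats, minHomCount = NULL, minHomPct = 80,
                        minAvgNaf = 0.8) {
    if (is.null(minHomCount)) minHomCount <- .defaultMinHomCount(stats)
    q <- .qualifies(stats, minHomCount, minHomPct, minAvgNaf)
    samples <- metadata(stats)$samples
    if (!any(q)) {
        out <- GRanges()
        mcols(out) <- DataFrame(peak_hom_count = integer(),
                                peak_hom_pct = numeric(),
                                peak_avg_naf = numeric(),
                                n_windows = integer())
        metadata(out)$samples <- samples
        return(out)
    }
    qw <- stats[q]
    regions <- reduce(granges(qw), min.gapwidth = 1L, ignore.strand = TRUE)
    ov <- findOverlaps(qw, regions, ignore.strand = TRUE)
    m <- mcols(qw)
    peak <- vapply(seq_along(regions), function(i) {
        idx <- queryHits(ov)[subjectHits(ov) == i]
        idx[order(-m$hom_count[idx], -m$hom_pct[idx], -m$avg_naf[idx],
                  start(qw)[idx])][1L]
    }, integer(1))
    mcols(regions) <- DataFrame(
        peak_hom_count = m$hom_count[peak], peak_hom_pct = m$hom_pct[peak],
        peak_avg_naf = m$avg_naf[peak],
        n_windows = as.integer(table(factor(subjectHits(ov),
                                            seq_along(regions)))))
    ord <- order(-regions$peak_hom_count, -regions$peak_hom_pct,
                 -regions$peak_avg_naf, as.integer(seqnames(regions)),
                 start(regions))
    out <- regions[ord]
    metadata(out)$samples <- samples
    out
}

.jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) 0 else length(intersect(a, b)) / u
}

#' Partition a cohort whose samples map to more than one locus
#'
#' Phenotypically identical cohorts can hide two distinct mutations. Each
#' sample is mapped alone and its set of qualifying windows recorded;
#' samples are then grouped by greedy average-linkage agglomeration on the
#' Jaccard similarity of those window sets. Because a single embryo (three
#' informative meioses) carries chance chromosome-scale homozygous runs,
#' window sets alone can collide across pedigrees, so every proposed merge
#' is verified by re-mapping the merged group jointly -- two pedigrees are
#' homozygous for different variants even when their windows coincide, so a
#' spurious merge loses all qualifying regions and is rejected (the
#' iterative sample-combination strategy, made explicit). Groups of at
#' least `minGroup` samples are reported with their joint regions; smaller
#' groups, and groups with no qualifying region, are unresolved.
#'
#' @param x ENU-filtered [VariantTable].
#' @param windows `GRanges` from [makeWindows].
#' @param samples samples to partition (default: all; at least 3).
#' @param minGroup smallest group reported as resolved (default 2).
#' @param simCutoff stop merging when the best between-group similarity
#'   falls below this (default 0.05: the cutoff is only a shortlist heuristic --
#'   joint-map verification decides every merge).
#' @param minHomCount,minHomPct,minAvgNaf region thresholds as in
#'   [callRegions], applied per sample and per group.
#' @return list with one element per group: `samples`, `regions`
#'   (a [callRegions] result or `NULL`), and `resolved` flag. Groups are
#'   ordered by decreasing size, then first sample id.
#' @export
partitionSamples <- function(x, windows, samples = colnames(x), minGroup = 2,
                             simCutoff = 0.05, minHomCount = NULL,
                             minHomPct = 80, minAvgNaf = 0.8) {
    if (length(samples) < 3L)
        stop("partitioning needs at least 3 samples")
    qualSet <- function(smp) {
        st <- windowStats(x, windows, smp)
        mhc <- if (is.null(minHomCount)) .defaultMinHomCount(st)
               else minHomCount
        which(.qualifies(st, mhc, minHomPct, minAvgNaf))
    }
    winsets <- lapply(samples, qualSet)
    names(winsets) <- samples
    groups <- as.list(samples)
    vetoed <- character()   # "i|j" group-pair keys already rejected
    pairKey <- function(a, b) paste(sort(c(paste(sort(a), collapse = ","),
                                           paste(sort(b), collapse = ","))),
                                    collapse = "|")
    repeat {
        if (length(groups) < 2L) break
        cand <- NULL
        for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
            if (pairKey(groups[[i]], groups[[j]]) %in% vetoed) next
            sim <- mean(outer(groups[[i]], groups[[j]],
                              Vectorize(function(a, b)
                                  .jaccard(winsets[[a]], winsets[[b]]))))
            if (sim >= simCutoff && (is.null(cand) || sim > cand$sim))
                cand <- list(sim = sim, i = i, j = j)
        }
        if (is.null(cand)) break
        merged <- c(groups[[cand$j]], groups[[cand$i]])
        if (length(qualSet(merged)) > 0L) {
            groups[[cand$j]] <- merged
            groups[[cand$i]] <- NULL
        } else {
            vetoed <- c(vetoed, pairKey(groups[[cand$i]], groups[[cand$j]]))
        }
    }
    groups <- groups[order(-lengths(groups),
                           vapply(groups, function(g) sort(g)[1],
                                  character(1)))]
    lapply(groups, function(g) {
        if (length(g) < minGroup)
            return(list(samples = g, regions = NULL, resolved = FALSE))
        st <- windowStats(x, windows, g)
        rg <- callRegions(st, minHomCount = minHomCount,
                          minHomPct = minHomPct, minAvgNaf = minAvgNaf)
        list(samples = g, regions = rg, resolved = length(rg) > 0L)
    })
}

#' Re-tile a called region at finer resolution
#'
#' Re-computes [windowStats] inside `region` with a smaller window/step
#' (default the 50 kb non-overlapping refinement). Shrinking the window
#' trades marker numbers for resolution, so region calling on refined
#' windows should use a proportionally lower `minHomCount`.
#'
#' @param x ENU-filtered [VariantTable].
#' @param region a single `GRanges` interval.
#' @param windowSize,step refinement tiling (defaults 50 kb / 50 kb).
#' @param samples analyzed samples.
#' @param ... passed on to [windowStats].
#' @return `GRanges` of refined windows with the same statistics columns.
#' @export
refineRegion <- function(x, region, windowSize = 5e4, step = 5e4,
                         samples = colnames(x), ...) {
    stopifnot(length(region) == 1L)
    chr <- as.character(seqnames(region))
    local <- genomeBuild(chr, width(region))
    w <- makeWindows(local, windowSize, step, tail = "truncate")
    w <- GRanges(chr, IRanges(start(w) + start(region) - 1L,
                              end(w) + start(region) - 1L),
                 seqinfo = GenomeInfoDb::seqinfo(rowRanges(x)))
    windowStats(x, w, samples = samples, ...)
}

#' Write window statistics as TSV
#'
#' Columns `chrom start end n_snps hom_count hom_pct avg_naf`; coordinates
#' are written 0-based half-open (BED-like), converted from the 1-based
#' internal representation at this boundary.
#'
#' @param stats output of [windowStats].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeWindowStats <- function(stats, path) {
    df <- data.frame(chrom = as.character(seqnames(stats)),
                     start = start(stats) - 1L, end = end(stats),
                     n_snps = stats$n_snps, hom_count = stats$hom_count,
                     hom_pct = stats$hom_pct, avg_naf = stats$avg_naf)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Three-track homozygosity map plot
#'
#' Plots homozygous count, homozygous percentage and average novel allele
#' frequency per window along one chromosome.
#'
#' @param stats output of [windowStats].
#' @param chrom chromosome to plot (default: first present).
#' @return invisibly, the plotted data frame.
#' @importFrom graphics par plot
#' @export
plotWindowStats <- function(stats, chrom = NULL) {
    if (is.null(chrom)) chrom <- as.character(seqnames(stats))[1]
    s <- stats[seqnames(stats) == chrom]
    mid <- (start(s) + end(s)) / 2 / 1e6
    old <- par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
    on.exit(par(old))
    plot(mid, s$hom_count, type = "h", ylab = "hom count", xlab = "")
    plot(mid, s$hom_pct, type = "h", ylab = "hom %", xlab = "", ylim = c(0, 100))
    plot(mid, s$avg_naf, type = "h", ylab = "avg naf", xlab = paste(chrom, "(Mb)"),
         ylim = c(0, 1))
    invisible(as.data.frame(s))
}
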