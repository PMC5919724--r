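#' @importFrom Rsamtools scanBam ScanBamParam scanBamFlag asBam
#' @importFrom stats setNames
NULL

.cigarOps <- function(cigar) {
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
    list(lens = lens, ops = ops)
}

.refSpan <- function(cigar) {
    co <- .cigarOps(cigar)
    sum(co$lens[co$ops %in% c("M", "D", "N", "=", "X")])
}

.clipsFromAlignment <- function(sample, chrom, pos, cigar, remap = NA) {
    co <- .cigarOps(cigar)
    n <- length(co$ops)
    span <- sum(co$lens[co$ops %in% c("M", "D", "N", "=", "X")])
    out <- list()
    if (n && co$ops[1] == "S")
        out[[length(out) + 1L]] <- data.frame(
            sample = sample, chrom = chrom, alnStart = pos,
            alnEnd = pos + span - 1L, side = "left", clipPos = pos,
            clipLen = co$lens[1], remapPos = remap,
            stringsAsFactors = FALSE)
    if (n && co$ops[n] == "S")
        out[[length(out) + 1L]] <- data.frame(
            sample = sample, chrom = chrom, alnStart = pos,
            alnEnd = pos + span - 1L, side = "right", clipPos = pos + span,
            clipLen = co$lens[n], remapPos = remap,
            stringsAsFactors = FALSE)
    out
}

#' Read the plain-text alignment dialect
#'
#' Tab-separated with header `sample chrom pos cigar` and an optional
#' `remap` column giving where the clipped tail re-aligns.
#'
#' @param path TSV file.
#' @return `data.frame` of alignments.
#' @export
readAlignmentsTsv <- function(path) {
    a <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample", "chrom", "pos", "cigar")
    if (!all(need %in% names(a)))
        stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
    if (is.null(a$remap)) a$remap <- NA_integer_
    a
}

.alignmentsFromBam <- function(path, region = NULL) {
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = ".bam")
        path <- asBam(path, sub("\\.bam$", "", dest), overwrite = TRUE,
                      indexDestination = TRUE)
    }
    param <- if (!is.null(region)) {
        ScanBamParam(what = c("rname", "pos", "cigar"),
                     flag = scanBamFlag(isUnmappedQuery = FALSE),
                     which = region)
    } else ScanBamParam(what = c("rname", "pos", "cigar"),
                        flag = scanBamFlag(isUnmappedQuery = FALSE))
    res <- scanBam(path, param = param)
    do.call(rbind, lapply(res, function(r)
        data.frame(sample = basename(path), chrom = as.character(r$rname),
                   pos = r$pos, cigar = r$cigar, remap = NA_integer_,
                   stringsAsFactors = FALSE)))
}

#' Collect soft-clipped read ends
#'
#' Scans alignments for reads whose CIGAR carries a leading or trailing
#' soft clip: a trailing clip (`kM nS`) records a right-clip at the 1-based
#' boundary after the last aligned base; a leading clip (`nS kM`) records a
#' left-clip at the alignment start. Fully aligned reads contribute nothing;
#' unmapped reads are skipped.
#'
#' @param alignments a `data.frame` (columns `sample`, `chrom`, `pos`,
#'   `cigar`, optional `remap`), or a path to a SAM/BAM file or to the TSV
#'   dialect.
#' @param region optional `GRanges`; only clips whose position falls inside
#'   are kept.
#' @return `data.frame` of clipped read ends: `sample`, `chrom`,
#'   `alnStart`, `alnEnd`, `side`, `clipPos`, `clipLen`, `remapPos`.
#' @export
collectClipped <- function(alignments, region = NULL) {
    if (is.character(alignments)) {
        alignments <- if (grepl("\\.(sam|bam)$", alignments,
                                ignore.case = TRUE))
            .alignmentsFromBam(alignments, region)
        else readAlignmentsTsv(alignments)
    }
    if (is.null(alignments$remap)) alignments$remap <- NA_integer_
    rows <- list()
    for (i in seq_len(nrow(alignments))) {
        rows <- c(rows, .clipsFromAlignment(
            alignments$sample[i], alignments$chrom[i], alignments$pos[i],
            alignments$cigar[i], alignments$remap[i]))
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(sample = character(), chrom = character(),
                   alnStart = integer(), alnEnd = integer(),
                   side = character(), clipPos = integer(),
                   clipLen = integer(), remapPos = integer())
    if (!is.null(region) && nrow(out)) {
        gr <- GRanges(out$chrom, IRanges(out$clipPos, width = 1L))
        out <- out[overlapsAny(gr, region, ignore.strand = TRUE), ,
                   drop = FALSE]
        rownames(out) <- NULL
    }
    out
}

#' Cluster clipped reads by trimmed location
#'
#' Clips sharing an exact (chromosome, position, side) are grouped; only
#' clusters supported by at least `minReads` reads are emitted. The default
#' of 6 realizes the "more than five reads with the same trimmed location"
#' rule. `tol > 0` additionally merges clip positions within `tol` bp
#' (greedy, ascending position) for noisier aligners.
#'
#' @param clips output of [collectClipped].
#' @param minReads minimum supporting reads per cluster (default 6).
#' @param tol position tolerance in bp (default 0 = exact).
#' @return `data.frame`: `chrom`, `pos`, `side`, `n_reads`, `samples`
#'   (comma-collapsed), `remapPos` (modal remap of members, NA if none).
#' @export
clusterClips <- function(clips, minReads = 6, tol = 0) {
    if (!nrow(clips))
        return(data.frame(chrom = character(), pos = integer(),
                          side = character(), n_reads = integer(),
                          samples = character(), remapPos = integer()))
    clips <- clips[order(clips$chrom, clips$side, clips$clipPos), ]
    grp <- if (tol > 0) {
        key <- paste(clips$chrom, clips$side)
        g <- integer(nrow(clips)); gid <- 0L
        lastKey <- ""; lastPos <- -Inf
        for (i in seq_len(nrow(clips))) {
            if (key[i] != lastKey || clips$clipPos[i] - lastPos > tol) {
                gid <- gid + 1L; lastKey <- key[i]
            }
            lastPos <- clips$clipPos[i]
            g[i] <- gid
        }
        g
    } else as.integer(factor(paste(clips$chrom, clips$side, clips$clipPos)))
    res <- lapply(split(seq_len(nrow(clips)), grp), function(idx) {
        cc <- clips[idx, , drop = FALSE]
        rp <- cc$remapPos[!is.na(cc$remapPos)]
        data.frame(chrom = cc$chrom[1],
                   pos = as.integer(round(mean(cc$clipPos))),
                   side = cc$side[1], n_reads = nrow(cc),
                   samples = paste(sort(unique(cc$sample)), collapse = ","),
                   remapPos = if (length(rp))
                       as.integer(names(sort(table(rp),
                                             decreasing = TRUE))[1])
                   else NA_integer_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out <- out[out$n_reads >= minReads, , drop = FALSE]
    out <- out[order(out$chrom, out$pos, out$side), ]
    rownames(out) <- NULL
    out
}

#' Pair clip clusters into deletion calls
#'
#' Each right-clip cluster is paired with the nearest downstream left-clip
#' cluster on the same chromosome (within `maxSpan`); ambiguous pairings
#' are resolved nearest-first and leftovers stay unpaired. The deleted
#' segment is the half-open interval `[start, end)` between the right-clip
#' and left-clip positions, so `length = end - start` (the published
#' 58,012,626-58,014,322 coordinates yield 1696 bp under this convention).
#'
#' @param clusters output of [clusterClips].
#' @param maxSpan maximum deletion span considered (default `Inf`).
#' @param requireSamples optional sample ids that must support both
#'   breakpoints.
#' @return `data.frame`: `chrom`, `start`, `end`, `length`, `n_right`,
#'   `n_left`, `samples`.
#' @export
pairBreakpoints <- function(clusters, maxSpan = Inf,
                            requireSamples = NULL) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), length = integer(),
                        n_right = integer(), n_left = integer(),
                        samples = character())
    rt <- clusters[clusters$side == "right", , drop = FALSE]
    lf <- clusters[clusters$side == "left", , drop = FALSE]
    if (!nrow(rt) || !nrow(lf)) return(empty)
    cand <- do.call(rbind, lapply(seq_len(nrow(rt)), function(i) {
        j <- which(lf$chrom == rt$chrom[i] & lf$pos > rt$pos[i] &
                   lf$pos - rt$pos[i] <= maxSpan)
        if (!length(j)) return(NULL)
        data.frame(i = i, j = j, span = lf$pos[j] - rt$pos[i])
    }))
    if (is.null(cand)) return(empty)
    cand <- cand[order(cand$span, rt$pos[cand$i]), , drop = FALSE]
    usedR <- logical(nrow(rt)); usedL <- logical(nrow(lf))
    calls <- list()
    for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (usedR[i] || usedL[j]) next
        sup <- intersect(strsplit(rt$samples[i], ",")[[1]],
                         strsplit(lf$samples[j], ",")[[1]])
        if (!is.null(requireSamples) &&
            !all(requireSamples %in% sup)) next
        usedR[i] <- TRUE; usedL[j] <- TRUE
        calls[[length(calls) + 1L]] <- data.frame(
            chrom = rt$chrom[i], start = rt$pos[i], end = lf$pos[j],
            length = lf$pos[j] - rt$pos[i], n_right = rt$n_reads[i],
            n_left = lf$n_reads[j],
            samples = paste(sort(sup), collapse = ","),
            stringsAsFactors = FALSE)
    }
    if (!length(calls)) return(empty)
    out <- do.call(rbind, calls)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write deletion calls as TSV
#'
#' @param calls output of [pairBreakpoints].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDeletionCalls <- function(calls, path) {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
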