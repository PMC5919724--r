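# Genotype-calling thresholds applied to simulated read counts: a call
# requires depth >= 4; hom-alt needs alt fraction >= 0.9, het 0.25-0.75,
# hom-ref <= 0.1; fractions in the indeterminate bands give a missing call.
.CALL_MIN_DEPTH <- 4L
.HOM_FRAC <- 0.9
.HET_BAND <- c(0.25, 0.75)
.REF_FRAC <- 0.1

#' Configure a simulated inbred ENU screen
#'
#' Defaults describe the desk-scale study conditions: a 5 x 30 Mb genome
#' (chromosomes several times the default 10 Mb mapping window, so sliding
#' windows localize within a chromosome as they do at genome scale), an
#' expected founder load of 3000 heterozygous ENU variants (Poisson), a
#' mouse-like genetic map of 0.5 cM/Mb, a recessive causal variant on chr1
#' at 15 Mb, three affected embryos sequenced at 20x with 0.5% base error,
#' and background contamination injected per exclusion category.
#'
#' @param genome `Seqinfo` (default `genomeBuild(chr1..chr5, 30 Mb)`).
#' @param enuLoad expected founder heterozygous ENU variants (default 3000).
#' @param cmPerMb genetic map density (default 0.5 cM/Mb; Haldane,
#'   no interference).
#' @param causalChrom,causalPos recessive causal locus (default chr1:5e6).
#' @param deletion optional planted deletion: `list(chrom, start, end)`,
#'   half-open `[start, end)` so `length = end - start`.
#' @param modifier optional planted dominant modifier:
#'   `list(chrom, pos)`.
#' @param nAffected affected embryos to collect (default 3).
#' @param meanDepth mean sequencing depth (default 20).
#' @param errorRate per-read base error rate (default 0.005).
#' @param contamRates expected counts of injected non-ENU variant sites per
#'   exclusion category; the `artifact` category injects low-evidence noise
#'   sites removed by the quality filter rather than by exclusion lists.
#' @param seed RNG seed; identical config + seed reproduces the screen
#'   byte-identically.
#' @return a [SimConfig].
#' @export
simConfig <- function(genome = genomeBuild(paste0("chr", 1:5), rep(3e7, 5)),
                      enuLoad = 3000, cmPerMb = 0.5,
                      causalChrom = "chr1", causalPos = 1.5e7,
                      deletion = list(), modifier = list(),
                      nAffected = 3, meanDepth = 20, errorRate = 0.005,
                      contamRates = c(dbsnp = 200, strain = 150,
                                      pedigree = 100, repeats = 150,
                                      artifact = 100),
                      seed = 1) {
    new("SimConfig", genome = genome, enuLoad = enuLoad, cmPerMb = cmPerMb,
        causalChrom = causalChrom, causalPos = as.integer(causalPos),
        deletion = deletion, modifier = modifier,
        nAffected = as.integer(nAffected), meanDepth = meanDepth,
        errorRate = errorRate, contamRates = contamRates,
        seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")

.randomAlleles <- function(n) {
    ref <- sample(.BASES, n, replace = TRUE)
    shift <- sample(1:3, n, replace = TRUE)
    alt <- .BASES[(match(ref, .BASES) - 1L + shift) %% 4L + 1L]
    list(ref = ref, alt = alt)
}

#' Simulate the founder (G1) ENU variant set
#'
#' Draws `Poisson(enuLoad)` heterozygous variants placed uniformly, with
#' chromosomes weighted by length; the configured causal variant (and
#' modifier, if any) is forced into the set. The caller controls the RNG
#' state ([simulateScreen] seeds it from the config).
#'
#' @param cfg a [SimConfig].
#' @return sorted `GRanges` with `id`, `ref`, `alt` metadata columns; the
#'   causal variant has id `"causal"`, the modifier `"modifier"`.
#' @export
simulateFounder <- function(cfg) {
    sl <- seqlengths(cfg@genome)
    n <- rpois(1, cfg@enuLoad)
    chrom <- sample(names(sl), n, replace = TRUE, prob = sl / sum(sl))
    pos <- floor(runif(n, 0, sl[chrom])) + 1
    ids <- sprintf("enu%04d", seq_len(n))
    chrom <- c(chrom, cfg@causalChrom)
    pos <- c(pos, cfg@causalPos)
    ids <- c(ids, "causal")
    if (length(cfg@modifier)) {
        chrom <- c(chrom, cfg@modifier$chrom)
        pos <- c(pos, cfg@modifier$pos)
        ids <- c(ids, "modifier")
    }
    dup <- duplicated(paste(chrom, pos))
    # keep the forced variants over colliding background draws
    dup[ids %in% c("causal", "modifier")] <- FALSE
    drop <- duplicated(paste(chrom, pos), fromLast = TRUE) &
        !(ids %in% c("causal", "modifier"))
    keep <- !dup & !drop
    chrom <- chrom[keep]; pos <- pos[keep]; ids <- ids[keep]
    al <- .randomAlleles(length(ids))
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                  seqinfo = cfg@genome)
    mcols(gr) <- DataFrame(id = ids, ref = al$ref, alt = al$alt)
    gr <- sort(gr, ignore.strand = TRUE)
    names(gr) <- mcols(gr)$id
    gr
}

.mapPrep <- function(founder, cfg) {
    chrom <- as.character(seqnames(founder))
    list(idx = split(seq_along(founder), chrom),
         pos = start(founder), lens = seqlengths(cfg@genome),
         morgans = seqlengths(cfg@genome) / 1e6 * cfg@cmPerMb / 100)
}

# One meiotic product: TRUE where the gamete carries haplotype 1 (the
# mutant haplotype when applied to the G1), under Haldane's no-interference
# model (crossovers Poisson per chromosome, positions uniform).
.gameteCarry <- function(prep) {
    out <- logical(length(prep$pos))
    for (chr in names(prep$idx)) {
        i <- prep$idx[[chr]]
        k <- rpois(1, prep$morgans[[chr]])
        startHap <- runif(1) < 0.5
        if (k == 0) { out[i] <- startHap; next }
        cx <- sort(runif(k, 0, prep$lens[[chr]]))
        nBelow <- findInterval(prep$pos[i], cx)
        out[i] <- xor(startHap, nBelow %% 2L == 1L)
    }
    out
}

#' Simulate G2-backcross embryos
#'
#' Each embryo unites a gamete drawn directly from the G1 male with a
#' gamete from a carrier G2 daughter (her paternal haplotype is itself a
#' G1 meiotic product conditioned to carry the causal allele, standing in
#' for progeny testing). An embryo is affected iff homozygous for the
#' causal variant.
#'
#' @param founder founder `GRanges` from [simulateFounder].
#' @param cfg a [SimConfig].
#' @param nEmbryos embryos to simulate.
#' @return list: `dosage` (variants x embryos alt-dosage matrix),
#'   `affected` (logical vector).
#' @export
breedBackcross <- function(founder, cfg, nEmbryos) {
    prep <- .mapPrep(founder, cfg)
    ci <- match("causal", mcols(founder)$id)
    dosage <- matrix(0L, length(founder), nEmbryos,
                     dimnames = list(names(founder), NULL))
    for (e in seq_len(nEmbryos)) {
        repeat {  # carrier G2 daughter: paternal gamete has the causal allele
            pg <- .gameteCarry(prep)
            if (pg[ci]) break
        }
        g2 <- .gameteCarry(prep) & pg   # her gamete: mosaic of paternal/WT
        g1 <- .gameteCarry(prep)        # fresh G1 gamete
        dosage[, e] <- as.integer(g2) + as.integer(g1)
    }
    list(dosage = dosage, affected = dosage[ci, ] == 2L)
}

.callGeno <- function(depth, alt) {
    frac <- ifelse(depth > 0, alt / depth, NA_real_)
    geno <- matrix(NA_integer_, nrow(depth), ncol(depth),
                   dimnames = dimnames(depth))
    ok <- depth >= .CALL_MIN_DEPTH & !is.na(frac)
    geno[ok & frac >= .HOM_FRAC] <- 2L
    geno[ok & frac >= .HET_BAND[1] & frac <= .HET_BAND[2]] <- 1L
    geno[ok & frac <= .REF_FRAC] <- 0L
    geno
}

#' Sample reads and call genotypes over simulated embryos
#'
#' Per site and sample: depth ~ Poisson(`meanDepth`); alt reads ~
#' Binomial(depth, mu) with mu = errorRate, 0.5 or 1 - errorRate for
#' dosages 0/1/2. Genotypes are called from the alt fraction (see package
#' constants), and site QUAL is synthesized as `3 x pooled alt reads`
#' (capped at 500), so evidence-poor sites fall below the quality floor.
#'
#' @param dosage variants x samples integer matrix of true alt dosages.
#' @param cfg a [SimConfig].
#' @return list of matrices `depth`, `alt`, `geno` and vector `qual`.
#' @export
simulateReadsAndCalls <- function(dosage, cfg) {
    n <- length(dosage)
    depth <- matrix(rpois(n, cfg@meanDepth), nrow(dosage),
                    dimnames = dimnames(dosage))
    mu <- matrix(cfg@errorRate, nrow(dosage), ncol(dosage))
    mu[dosage == 1L] <- 0.5
    mu[dosage == 2L] <- 1 - cfg@errorRate
    alt <- matrix(rbinom(n, as.vector(depth), as.vector(mu)), nrow(dosage),
                  dimnames = dimnames(dosage))
    list(depth = depth, alt = alt, geno = .callGeno(depth, alt),
         qual = pmin(500, round(3 * rowSums(alt), 1)))
}

.simContamination <- function(cfg, sampleNames) {
    sl <- seqlengths(cfg@genome)
    sites <- list(); intervals <- list(); rows <- list()
    for (cat in names(cfg@contamRates)) {
        k <- rpois(1, cfg@contamRates[[cat]])
        if (k == 0) next
        chrom <- sample(names(sl), k, replace = TRUE, prob = sl / sum(sl))
        pos <- as.integer(floor(runif(k, 0, sl[chrom])) + 1)
        al <- .randomAlleles(k)
        if (cat == "artifact") {
            # alignment-noise sites: all samples truly hom-ref, but reads
            # show a noisy 5-15% alt fraction
            dos <- matrix(0L, k, length(sampleNames),
                          dimnames = list(NULL, sampleNames))
            depth <- matrix(rpois(k * ncol(dos), cfg@meanDepth), k)
            f <- matrix(runif(k * ncol(dos), 0.05, 0.15), k)
            altm <- matrix(rbinom(length(depth), as.vector(depth),
                                  as.vector(f)), k)
            dimnames(depth) <- dimnames(altm) <- dimnames(dos)
            rows[[cat]] <- list(chrom = chrom, pos = pos, ref = al$ref,
                                alt = al$alt, depth = depth, altm = altm,
                                geno = .callGeno(depth, altm),
                                qual = pmin(500, round(3 * rowSums(altm), 1)))
            next
        }
        # inherited strain/dbSNP-like polymorphisms segregating in the cross
        dos <- matrix(rbinom(k * length(sampleNames), 2L, 0.5), k,
                      dimnames = list(NULL, sampleNames))
        rc <- simulateReadsAndCalls(dos, cfg)
        rows[[cat]] <- list(chrom = chrom, pos = pos, ref = al$ref,
                            alt = al$alt, depth = rc$depth, altm = rc$alt,
                            geno = rc$geno, qual = rc$qual)
        if (cat == "repeats") {
            intervals[[cat]] <- reduce(GRanges(
                chrom, IRanges(pmax(1L, pos - 100L),
                               pmin(sl[chrom], pos + 100L)),
                seqinfo = cfg@genome))
        } else {
            g <- GRanges(chrom, IRanges(pos, width = 1L),
                         seqinfo = cfg@genome)
            mcols(g)$alt <- al$alt
            sites[[cat]] <- g
        }
    }
    list(sites = sites, intervals = intervals, rows = rows)
}

.toyGeneModel <- function(cfg) {
    sl <- seqlengths(cfg@genome)
    # one gene whose CDS covers the causal position, plus background genes
    cstart <- cfg@causalPos - 500L; cend <- cfg@causalPos + 500L
    exons <- GRanges(cfg@causalChrom,
                     IRanges(c(cstart - 3000L, cstart),
                             c(cstart - 2000L, cend)),
                     gene = "GeneC", transcript = "GeneC.t1")
    cds <- GRanges(cfg@causalChrom, IRanges(cstart, cend), gene = "GeneC",
                   transcript = "GeneC.t1")
    bgChr <- rep(names(sl), each = 4L)
    bgStart <- unlist(lapply(names(sl), function(chr)
        as.integer(seq(1e6, sl[[chr]] - 1e6, length.out = 4))))
    bgName <- paste0("Gene_", bgChr, "_", rep(1:4, length(sl)))
    bg <- GRanges(bgChr, IRanges(bgStart, bgStart + 2000L),
                  gene = bgName, transcript = paste0(bgName, ".t1"),
                  seqinfo = cfg@genome)
    exons <- GRanges(seqnames(exons), ranges(exons), seqinfo = cfg@genome,
                     gene = mcols(exons)$gene,
                     transcript = mcols(exons)$transcript)
    cds <- GRanges(seqnames(cds), ranges(cds), seqinfo = cfg@genome,
                   gene = mcols(cds)$gene,
                   transcript = mcols(cds)$transcript)
    GeneModel(exons = c(exons, bg), cds = c(cds, bg))
}

.deletionAlignments <- function(cfg, samples, readLen = 100L) {
    d <- cfg@deletion
    rows <- list()
    rate <- cfg@meanDepth / readLen
    for (s in samples) {
        # left-flank reads crossing the left breakpoint: aligned prefix then
        # soft-clipped tail that re-maps at the deletion end
        for (st in seq(d$start - readLen + 10L, d$start - 10L)) {
            if (runif(1) > rate) next
            m <- d$start - st
            rows[[length(rows) + 1L]] <- data.frame(
                sample = s, chrom = d$chrom, pos = st,
                cigar = sprintf("%dM%dS", m, readLen - m),
                remap = d$end, stringsAsFactors = FALSE)
        }
        # mirrored reads anchored right of the deletion
        for (st in seq_len(readLen - 19L)) {
            if (runif(1) > rate) next
            m <- readLen - st - 9L
            rows[[length(rows) + 1L]] <- data.frame(
                sample = s, chrom = d$chrom, pos = d$end,
                cigar = sprintf("%dS%dM", readLen - m, m),
                remap = d$start, stringsAsFactors = FALSE)
        }
        # fully aligned flank reads
        for (st in seq(d$start - 600L, d$start - readLen - 10L, by = 25L))
            rows[[length(rows) + 1L]] <- data.frame(
                sample = s, chrom = d$chrom, pos = st, cigar = "100M",
                remap = NA_integer_, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Forward-simulate a complete screen
#'
#' Seeds the RNG from `cfg@seed`, simulates the founder, breeds embryos
#' until the required cohort is collected, samples reads and genotype
#' calls, injects contamination, and assembles the emitted [VariantTable]
#' (sites with essentially no alternate-allele evidence are not emitted,
#' as a joint variant caller would not report them), exclusion sets, a toy
#' gene model placing the causal variant in coding sequence, soft-clipped
#' alignments over any planted deletion, and the ground truth.
#'
#' @param cfg a [SimConfig].
#' @param samplePrefix prefix for generated sample ids.
#' @param forcedRecomb optional `list(sample = i, halfWidth = w)`: after
#'   breeding, embryo `i`'s homozygosity on the causal chromosome is
#'   limited to `causalPos +/- w` (recombination tight around the causal
#'   locus, the situation that defeats coarse windows).
#' @param classes optional named integer vector splitting the affected
#'   cohort into phenotype classes by modifier carriage, e.g.
#'   `c(cleft_palate = 5, exencephaly = 3)`: the first class collects
#'   affected modifier carriers, the second affected non-carriers
#'   (requires a configured modifier).
#' @return a [SimScreen].
#' @export
simulateScreen <- function(cfg, samplePrefix = "mut", forcedRecomb = NULL,
                           classes = NULL) {
    set.seed(cfg@seed)
    founder <- simulateFounder(cfg)
    prep <- .mapPrep(founder, cfg)
    ci <- match("causal", mcols(founder)$id)
    mi <- match("modifier", mcols(founder)$id)
    if (!is.null(classes) && (length(cfg@modifier) == 0L || is.na(mi)))
        stop("class split by modifier carriage needs a configured modifier")

    needTotal <- if (is.null(classes)) cfg@nAffected else sum(classes)
    cols <- list(); labels <- character()
    quota <- if (is.null(classes)) c(affected = needTotal) else classes
    got <- setNames(integer(length(quota)), names(quota))
    guard <- 0L
    while (sum(got) < needTotal) {
        guard <- guard + 1L
        if (guard > 10000L) stop("breeding failed to fill the cohort quota")
        emb <- breedBackcross(founder, cfg, 1L)
        if (!emb$affected[1]) next
        lab <- if (is.null(classes)) "affected" else {
            carrier <- emb$dosage[mi, 1] >= 1L
            if (carrier) names(quota)[1] else names(quota)[2]
        }
        if (got[lab] >= quota[lab]) next
        got[lab] <- got[lab] + 1L
        cols[[length(cols) + 1L]] <- emb$dosage[, 1]
        labels <- c(labels, lab)
    }
    dosage <- do.call(cbind, cols)
    ord <- order(match(labels, names(quota)))
    dosage <- dosage[, ord, drop = FALSE]; labels <- labels[ord]
    colnames(dosage) <- paste0(samplePrefix, seq_len(ncol(dosage)))
    rownames(dosage) <- names(founder)

    if (!is.null(forcedRecomb)) {
        i <- forcedRecomb$sample
        onChrom <- as.character(seqnames(founder)) == cfg@causalChrom
        far <- abs(start(founder) - cfg@causalPos) > forcedRecomb$halfWidth
        hit <- onChrom & far & dosage[, i] == 2L
        dosage[hit, i] <- 1L
    }

    rc <- simulateReadsAndCalls(dosage, cfg)
    contam <- .simContamination(cfg, colnames(dosage))

    # emission: a joint caller only reports sites with alt evidence
    emitted <- rowSums(rc$alt) >= 2L |
        rowSums(rc$geno >= 1L, na.rm = TRUE) > 0L
    gr <- founder[emitted]
    geno <- rc$geno[emitted, , drop = FALSE]
    depth <- rc$depth[emitted, , drop = FALSE]
    altm <- rc$alt[emitted, , drop = FALSE]
    qual <- rc$qual[emitted]
    ids <- mcols(gr)$id; ref <- mcols(gr)$ref; alt <- mcols(gr)$alt
    chrom <- as.character(seqnames(gr)); pos <- start(gr)
    for (cat in names(contam$rows)) {
        r <- contam$rows[[cat]]
        keep <- rowSums(r$altm) >= 2L
        chrom <- c(chrom, r$chrom[keep]); pos <- c(pos, r$pos[keep])
        ref <- c(ref, r$ref[keep]); alt <- c(alt, r$alt[keep])
        ids <- c(ids, paste0(cat, seq_len(sum(keep))))
        geno <- rbind(geno, r$geno[keep, , drop = FALSE])
        depth <- rbind(depth, r$depth[keep, , drop = FALSE])
        altm <- rbind(altm, r$altm[keep, , drop = FALSE])
        qual <- c(qual, r$qual[keep])
    }
    vgr <- GRanges(chrom, IRanges(pos, width = 1L), seqinfo = cfg@genome)
    mcols(vgr) <- DataFrame(ref = ref, alt = alt, qual = as.numeric(qual),
                            indel = rep(FALSE, length(ids)), id = ids)
    ord2 <- order(as.integer(match(chrom, seqlevels(vgr))), pos)
    vgr <- vgr[ord2]
    geno <- geno[ord2, , drop = FALSE]; depth <- depth[ord2, , drop = FALSE]
    altm <- altm[ord2, , drop = FALSE]

    manifest <- data.frame(sample = colnames(dosage), class = labels,
                           pedigree = samplePrefix,
                           stringsAsFactors = FALSE)
    vt <- VariantTable(vgr, geno, depth, altm, manifest)
    excl <- ExclusionSet(intervals = contam$intervals,
                         sites = contam$sites)
    aln <- if (length(cfg@deletion)) {
        aff <- colnames(dosage)[if (is.null(classes)) labels == "affected"
                                else rep(TRUE, length(labels))]
        .deletionAlignments(cfg, aff)
    } else data.frame()
    truth <- list(causal_id = "causal", causal_chrom = cfg@causalChrom,
                  causal_pos = cfg@causalPos,
                  affected_samples = colnames(dosage),
                  deletion = if (length(cfg@deletion))
                      c(cfg@deletion,
                        length = cfg@deletion$end - cfg@deletion$start)
                      else NULL,
                  modifier_id = if (length(cfg@modifier)) "modifier"
                      else NULL,
                  classes = if (!is.null(classes)) as.list(quota) else NULL)
    new("SimScreen", variants = vt, founder = founder, dosage = dosage,
        exclusions = excl, alignments = aln, genes = .toyGeneModel(cfg),
        truth = truth, config = cfg)
}

#' Merge two simulated screens into one joint cohort
#'
#' Emulates joint variant calling over samples from two pedigrees: the row
#' union of both tables, with samples of the other pedigree filled in as
#' confident hom-ref (depth = mean depth, no alt reads) at sites private to
#' one screen.
#'
#' @param a,b `SimScreen` objects over the same genome, with disjoint
#'   sample ids.
#' @return a [VariantTable]; the per-screen truths are kept in
#'   `metadata()$truths`.
#' @export
mergeScreens <- function(a, b) {
    va <- a@variants; vb <- b@variants
    if (length(intersect(colnames(va), colnames(vb))))
        stop("screens must have disjoint sample ids")
    keyA <- paste(seqnames(rowRanges(va)), start(rowRanges(va)),
                  mcols(rowRanges(va))$alt)
    keyB <- paste(seqnames(rowRanges(vb)), start(rowRanges(vb)),
                  mcols(rowRanges(vb))$alt)
    onlyB <- !(keyB %in% keyA)
    gr <- c(granges(rowRanges(va), use.mcols = TRUE),
            granges(rowRanges(vb)[onlyB], use.mcols = TRUE))
    .pad <- function(m, rows, cols, fill) {
        out <- matrix(fill, rows, length(cols), dimnames = list(NULL, cols))
        out
    }
    fillDepth <- as.integer(round(a@config@meanDepth))
    nA <- nrow(va); nB <- sum(onlyB)
    sA <- colnames(va); sB <- colnames(vb)
    geno <- rbind(cbind(genotypes(va), .pad(NULL, nA, sB, 0L)),
                  cbind(.pad(NULL, nB, sA, 0L),
                        genotypes(vb)[onlyB, , drop = FALSE]))
    depth <- rbind(cbind(depths(va), .pad(NULL, nA, sB, fillDepth)),
                   cbind(.pad(NULL, nB, sA, fillDepth),
                         depths(vb)[onlyB, , drop = FALSE]))
    altm <- rbind(cbind(altReads(va), .pad(NULL, nA, sB, 0L)),
                  cbind(.pad(NULL, nB, sA, 0L),
                        altReads(vb)[onlyB, , drop = FALSE]))
    # shared sites keep screen A's record; genotypes of B's samples there
    shared <- match(keyA, keyB)
    hasB <- !is.na(shared)
    if (any(hasB)) {
        geno[which(hasB), sB] <- genotypes(vb)[shared[hasB], , drop = FALSE]
        depth[which(hasB), sB] <- depths(vb)[shared[hasB], , drop = FALSE]
        altm[which(hasB), sB] <- altReads(vb)[shared[hasB], , drop = FALSE]
    }
    manifest <- rbind(
        data.frame(sample = sA, class = colData(va)$class,
                   pedigree = colData(va)$pedigree),
        data.frame(sample = sB, class = colData(vb)$class,
                   pedigree = colData(vb)$pedigree))
    ord <- order(as.integer(match(as.character(seqnames(gr)),
                                  seqlevels(gr))), start(gr))
    vt <- VariantTable(gr[ord], geno[ord, , drop = FALSE],
                       depth[ord, , drop = FALSE], altm[ord, , drop = FALSE],
                       manifest)
    metadata(vt)$truths <- list(a = a@truth, b = b@truth)
    vt
}
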