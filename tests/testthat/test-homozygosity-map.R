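test_that("window tiling matches the published parameterizations", {
    g <- genomeBuild("chrA", 2e7)
    w <- makeWindows(g, 1e7, 1e6, tail = "drop")
    expect_equal(length(w), 11L)                       # floor((20-10)/1)+1
    expect_equal(start(w), seq(1, 1e7 + 1, by = 1e6))
    expect_equal(unique(width(w)), 1e7)

    w1 <- makeWindows(genomeBuild("chrA", 1e7), 1e7, 1e6)
    expect_equal(length(w1), 1L)

    wt <- makeWindows(genomeBuild("chrA", 95e3), 5e4, 5e4, tail = "truncate")
    expect_equal(as.data.frame(wt)[, c("start", "end")],
                 data.frame(start = c(1, 50001), end = c(50000, 95000)))

    expect_error(makeWindows(g, 1e7, 0), "positive")
    expect_error(makeWindows(g, 1e6, 2e6), "exceed")
})

test_that("window statistics reproduce the hand-computed toy example", {
    # 5 SNVs, 2 samples: 3 hom in both; pooled per-SNV alt fractions
    # 1, 1, 1, 0.5, 0.4 -> hom_count 3, hom_pct 60, avg_naf 0.78
    geno <- cbind(s1 = c(2L, 2L, 2L, 1L, 1L), s2 = c(2L, 2L, 2L, 1L, 1L))
    depth <- matrix(10L, 5, 2, dimnames = list(NULL, c("s1", "s2")))
    alt <- cbind(s1 = c(10L, 10L, 10L, 5L, 4L),
                 s2 = c(10L, 10L, 10L, 5L, 4L))
    x <- tableAt("chr1", c(10, 20, 30, 40, 50) * 1e3, geno, depth, alt)
    w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5))
    st <- windowStats(x, w)
    expect_equal(st$n_snps, 5L)
    expect_equal(st$hom_count, 3L)
    expect_equal(st$hom_pct, 60)
    expect_equal(st$avg_naf, 0.78)
    expect_false(st$empty)
})

test_that("empty windows carry zero statistics and the empty flag", {
    x <- toyTable(n = 10, seed = 2)
    w <- GenomicRanges::GRanges("chr2", IRanges::IRanges(9.9e6, 1e7))
    st <- windowStats(x[seqnames(rowRanges(x)) == "chr1"], w)
    if (st$n_snps == 0) {
        expect_equal(st$hom_count, 0L)
        expect_equal(st$hom_pct, 0)
        expect_equal(st$avg_naf, 0)
        expect_true(st$empty)
    }
    # guaranteed-empty: no chr2 variants at all
    x1 <- tableAt("chr1", 100,
                  geno = matrix(2L, 1, 1, dimnames = list(NULL, "s1")),
                  depth = matrix(10L, 1, 1), alt = matrix(10L, 1, 1))
    st1 <- windowStats(x1, w)
    expect_true(st1$empty)
    expect_equal(st1$hom_pct, 0)
})

test_that("interval-indexed statistics equal a naive per-SNP double loop", {
    x <- toyTable(n = 1000, seed = 13)
    w <- makeWindows(genomeBuild(c("chr1", "chr2"), c(1e7, 1e7)), 2e6, 5e5)
    st <- windowStats(x, w)
    gr <- rowRanges(x); g <- genotypes(x); dp <- depths(x); ar <- altReads(x)
    for (i in sample(seq_along(w), 25)) {
        inW <- as.character(seqnames(gr)) ==
            as.character(seqnames(w))[i] &
            start(gr) >= start(w)[i] & start(gr) <= end(w)[i]
        carrier <- apply(!is.na(g) & g >= 1L, 1, any)
        idx <- which(inW & carrier)
        hom <- vapply(idx, function(k) all(!is.na(g[k, ]) & g[k, ] == 2L),
                      logical(1))
        expect_equal(st$n_snps[i], length(idx))
        expect_equal(st$hom_count[i], sum(hom))
        if (length(idx)) {
            expect_equal(st$hom_pct[i], 100 * sum(hom) / length(idx))
            expect_equal(st$avg_naf[i],
                         mean(rowSums(ar[idx, , drop = FALSE]) /
                              rowSums(dp[idx, , drop = FALSE])))
        }
    }
})

test_that("non-overlapping tilings conserve the SNP count", {
    x <- toyTable(n = 500, seed = 21)
    w <- makeWindows(genomeBuild(c("chr1", "chr2"), c(1e7, 1e7)), 1e6, 1e6)
    st <- windowStats(x, w)
    carrier <- apply(!is.na(genotypes(x)) & genotypes(x) >= 1L, 1, any)
    expect_equal(sum(st$n_snps), sum(carrier))
})

test_that("region calling merges overlapping qualifying windows and ranks", {
    mk <- function(starts, hc, pct, naf, chrom = "chrA") {
        g <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(starts, starts + 9.99e6))
        S4Vectors::mcols(g) <- S4Vectors::DataFrame(
            n_snps = 100L, hom_count = hc, hom_pct = pct, avg_naf = naf,
            empty = FALSE)
        g
    }
    # all-zero stats: no regions
    z <- mk(c(1, 1e6), c(0L, 0L), c(0, 0), c(0, 0))
    expect_equal(length(callRegions(z, minHomCount = 5)), 0L)

    # two windows sharing 9 Mb: one merged region, peak = stronger window
    two <- mk(c(1, 1e6), c(90L, 95L), c(90, 95), c(0.9, 0.95))
    rg <- callRegions(two, minHomCount = 5)
    expect_equal(length(rg), 1L)
    expect_equal(rg$peak_hom_count, 95L)
    expect_equal(rg$n_windows, 2L)

    # ranking: count first, then pct, then naf, then coordinate
    s <- c(mk(1, 50L, 90, 0.9), mk(2e7, 50L, 95, 0.9),
           mk(6e7, 60L, 80, 0.85))
    rg2 <- callRegions(s, minHomCount = 5, minHomPct = 80, minAvgNaf = 0.8)
    expect_equal(rg2$peak_hom_count, c(60L, 50L, 50L))
    expect_equal(rg2$peak_hom_pct[2], 95)
})

test_that("homogeneous cohorts form a single resolved group", {
    fx <- cachedFixture("fosse_like")
    scrA <- fx$screens$a
    x <- filterEnuSnps(screenVariants(scrA), screenExclusions(scrA))
    w <- makeWindows(GenomeInfoDb::seqinfo(rowRanges(x)))
    pt <- partitionSamples(x, w, samples = colnames(x)[1:4])
    expect_equal(length(pt), 1L)
    expect_true(pt[[1]]$resolved)
    expect_setequal(pt[[1]]$samples, colnames(x)[1:4])
})

test_that("a mixed 6+2 cohort is split into its pedigrees", {
    fx <- cachedFixture("fosse_like")
    x <- filterEnuSnps(fx$variants, fx$exclusions)
    w <- makeWindows(GenomeInfoDb::seqinfo(rowRanges(x)))
    pt <- partitionSamples(x, w)
    grps <- lapply(pt, function(g) sort(g$samples))
    expect_equal(grps[[1]], paste0("mutA", 1:6))
    expect_equal(grps[[2]], paste0("mutB", 1:2))
    # each group maps to its own causal locus
    tr <- fx$truth$groups
    for (k in 1:2) {
        ref <- GenomicRanges::GRanges(
            tr[[k]]$causal_chrom,
            IRanges::IRanges(tr[[k]]$causal_pos, width = 1))
        expect_true(IRanges::overlapsAny(pt[[k]]$regions[1], ref))
    }
})

test_that("greedy partition agrees with exhaustive 2-block search", {
    fx <- cachedFixture("fosse_like")
    x <- filterEnuSnps(fx$variants, fx$exclusions)
    w <- makeWindows(GenomeInfoDb::seqinfo(rowRanges(x)))
    smp <- colnames(x)
    # brute force: a 2-block partition is valid when both blocks (size >= 2)
    # jointly map to at least one qualifying region
    valid <- list()
    for (mask in 1:(2^(length(smp) - 1) - 1)) {
        b1 <- smp[c(TRUE, as.logical(intToBits(mask)[1:7]))]
        b2 <- setdiff(smp, b1)
        if (length(b1) < 2 || length(b2) < 2) next
        ok <- all(vapply(list(b1, b2), function(b)
            length(callRegions(windowStats(x, w, b))) > 0, logical(1)))
        if (ok) valid[[length(valid) + 1]] <- list(sort(b1), sort(b2))
    }
    expect_equal(length(valid), 1L)
    expect_setequal(valid[[1]],
                    list(sort(paste0("mutA", 1:6)), sort(paste0("mutB", 1:2))))
})

test_that("refinement re-tiles a region and conserves counts", {
    x <- toyTable(n = 400, seed = 31)
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e6 + 1, 4e6))
    fine <- refineRegion(x, region, windowSize = 5e4, step = 5e4)
    expect_true(all(start(fine) >= 2e6 + 1 & end(fine) <= 4e6))
    expect_equal(unique(as.character(seqnames(fine))), "chr1")
    gr <- rowRanges(x); g <- genotypes(x)
    carrier <- apply(!is.na(g) & g >= 1L, 1, any)
    inR <- as.character(seqnames(gr)) == "chr1" & start(gr) > 2e6 &
        start(gr) <= 4e6 & carrier
    expect_equal(sum(fine$n_snps), sum(inR))

    # refinement of a region with no variants: all-empty windows
    bare <- tableAt("chr2", 1,
                    geno = matrix(2L, 1, 1, dimnames = list(NULL, "s1")),
                    depth = matrix(10L, 1, 1), alt = matrix(10L, 1, 1))
    fe <- refineRegion(bare, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(1, 2e5)))
    expect_true(all(fe$empty))
})

test_that("a recombinant interval below window size appears on refinement", {
    fx <- cachedFixture("timon_like")
    x <- filterEnuSnps(fx$variants, fx$exclusions)
    w <- makeWindows(GenomeInfoDb::seqinfo(rowRanges(x)))
    coarse <- callRegions(windowStats(x, w))
    expect_equal(length(coarse), 0L)    # invisible at 10 Mb thresholds
    sr <- fx$truth$search_region
    region <- GenomicRanges::GRanges(sr$chrom,
                                     IRanges::IRanges(sr$start + 1, sr$end))
    fine <- refineRegion(x, region)     # 50 kb / 50 kb
    rg <- callRegions(fine, minHomCount = 2)
    expect_gt(length(rg), 0L)
    hi <- fx$truth$hom_interval
    expect_true(IRanges::overlapsAny(
        rg[1], GenomicRanges::GRanges(hi$chrom,
                                      IRanges::IRanges(hi$start, hi$end))))
})
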