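# A founder built by hand puts markers at exact genetic distances.
handFounder <- function(cfg, pos, chrom = "chr1") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                 seqinfo = cfg@genome)
    ids <- c("causal", paste0("m", seq_len(length(pos) - 1)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        id = ids, ref = rep("A", length(pos)), alt = rep("G", length(pos)))
    names(gr) <- ids
    gr
}

test_that("founder simulation honours the Poisson load and placement", {
    cfg <- simConfig(enuLoad = 0, seed = 1)
    set.seed(1)
    f0 <- simulateFounder(cfg)
    expect_equal(names(f0), "causal")

    # Poisson mean over replicates
    cfg2 <- simConfig(enuLoad = 3000)
    set.seed(2)
    counts <- replicate(200, length(simulateFounder(cfg2)))
    se <- sqrt(3000 / 200)
    expect_lt(abs(mean(counts) - 3000), 3 * se + 1)

    # placement proportional to chromosome length
    cfgL <- simConfig(genome = genomeBuild(c("cA", "cB"), c(2e7, 1e7)),
                      causalChrom = "cA", causalPos = 1e6, enuLoad = 6000)
    set.seed(3)
    fL <- simulateFounder(cfgL)
    pA <- mean(as.character(seqnames(fL)) == "cA")
    expect_lt(abs(pA - 2 / 3), 3 * sqrt(2 / 9 / 6000))
})

test_that("carrier-cross embryos segregate 1/4 affected", {
    cfg <- simConfig(enuLoad = 20, seed = 5)
    set.seed(5)
    f <- simulateFounder(cfg)
    emb <- breedBackcross(f, cfg, 800)
    phat <- mean(emb$affected)
    expect_lt(abs(phat - 0.25), 3 * sqrt(0.25 * 0.75 / 800))
    # only dosages 0/1/2 occur
    expect_true(all(emb$dosage %in% 0:2))
    # at the causal site, affected embryos are exactly the hom-alt ones
    ci <- which(rownames(emb$dosage) == "causal")
    expect_equal(emb$dosage[ci, ] == 2L, emb$affected)
})

test_that("segregation at the causal locus is 1/4 - 1/2 - 1/4", {
    cfg <- simConfig(enuLoad = 5, seed = 6)
    set.seed(6)
    f <- simulateFounder(cfg)
    emb <- breedBackcross(f, cfg, 900)
    ci <- which(rownames(emb$dosage) == "causal")
    tab <- tabulate(emb$dosage[ci, ] + 1L, 3) / 900
    expect_lt(abs(tab[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 900))
    expect_lt(abs(tab[2] - 0.50), 3 * sqrt(0.5 * 0.5 / 900))
    expect_lt(abs(tab[3] - 0.25), 3 * sqrt(0.25 * 0.75 / 900))
})

test_that("linked-marker homozygosity follows the Haldane map function", {
    # inflate the map so the effect is measurable at test scale:
    # marker 1 Mb from the causal locus at 50 cM/Mb -> d = 0.5 Morgan,
    # r = (1 - exp(-1))/2; P(hom at marker | affected) = (1 - r)^3
    cfg <- simConfig(cmPerMb = 50, enuLoad = 0, seed = 7)
    set.seed(7)
    f <- handFounder(cfg, pos = c(1.5e7, 1.6e7))
    emb <- breedBackcross(f, cfg, 2400)
    aff <- emb$affected
    r <- (1 - exp(-2 * 0.5)) / 2
    want <- (1 - r)^3
    got <- mean(emb$dosage["m1", aff] == 2L)
    expect_lt(abs(got - want), 3 * sqrt(want * (1 - want) / sum(aff)))

    # an unlinked marker is hom in 1/4 of affected embryos when the G2
    # carries it; unconditionally in 1/8
    cfg2 <- simConfig(cmPerMb = 0.5, enuLoad = 0, seed = 8)
    set.seed(8)
    f2 <- GenomicRanges::GRanges(c("chr1", "chr3"),
                                 IRanges::IRanges(c(1.5e7, 1.5e7), width = 1),
                                 seqinfo = cfg2@genome)
    S4Vectors::mcols(f2) <- S4Vectors::DataFrame(id = c("causal", "m1"),
                                                 ref = "A", alt = "G")
    names(f2) <- c("causal", "m1")
    emb2 <- breedBackcross(f2, cfg2, 2400)
    aff2 <- emb2$affected
    got2 <- mean(emb2$dosage["m1", aff2] == 2L)
    expect_lt(abs(got2 - 1 / 8), 3 * sqrt(1 / 8 * 7 / 8 / sum(aff2)))
})

test_that("average homozygosity decays with distance from the causal locus", {
    cfg <- simConfig(cmPerMb = 5, enuLoad = 0, seed = 9)
    set.seed(9)
    f <- handFounder(cfg, pos = 1.5e7 + c(0, 2e6, 6e6, 12e6))
    emb <- breedBackcross(f, cfg, 1500)
    aff <- emb$affected
    homFrac <- rowMeans(emb$dosage[, aff] == 2L)
    expect_true(all(diff(homFrac) < 0))
})

test_that("read sampling and genotype calling behave at the thresholds", {
    cfg <- simConfig(errorRate = 0, seed = 10)
    dos <- matrix(c(2L, 1L, 0L), 3, 1, dimnames = list(
        c("a", "b", "c"), "s1"))
    set.seed(10)
    rc <- simulateReadsAndCalls(dos, cfg)
    expect_equal(unname(rc$alt[1, 1] / rc$depth[1, 1]), 1)
    expect_equal(unname(rc$geno[1, 1]), 2L)
    expect_equal(unname(rc$geno[3, 1]), 0L)
    expect_equal(rc$qual, pmin(500, round(3 * rowSums(rc$alt), 1)),
                 ignore_attr = TRUE)
    # depth below the call floor gives a missing genotype
    cfg2 <- simConfig(meanDepth = 0.5, seed = 11)
    set.seed(11)
    rc2 <- simulateReadsAndCalls(matrix(2L, 50, 1,
                                        dimnames = list(NULL, "s1")), cfg2)
    expect_true(anyNA(rc2$geno))
    expect_true(all(is.na(rc2$geno[rc2$depth < 4])))
})

test_that("identical config and seed regenerate identical bundles", {
    d1 <- tempfile(); d2 <- tempfile()
    fx1 <- makeFixture("modifier_like", dir = d1, seed = 3)
    fx2 <- makeFixture("modifier_like", dir = d2, seed = 3)
    files <- setdiff(list.files(d1), character(0))
    expect_setequal(files, list.files(d2))
    for (f in files)
        expect_equal(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("fixture truth matches its configuration and VCF round-trips", {
    d <- tempfile()
    fx <- makeFixture("timon_like", dir = d, seed = 4)
    tr <- jsonlite::read_json(file.path(d, "truth.json"))
    scr <- fx$screens[[1]]
    expect_equal(tr$causal_chrom, scr@config@causalChrom)
    expect_equal(tr$causal_pos, scr@config@causalPos)
    expect_equal(tr$deletion$length,
                 scr@config@deletion$end - scr@config@deletion$start)

    mf <- readSampleManifest(file.path(d, "manifest.tsv"))
    back <- readVariants(file.path(d, "variants.vcf"), mf)
    expect_equal(dim(back), dim(fx$variants))
    expect_equal(genotypes(back), genotypes(fx$variants),
                 ignore_attr = TRUE)
    expect_equal(depths(back), depths(fx$variants), ignore_attr = TRUE)
    expect_equal(altReads(back), altReads(fx$variants), ignore_attr = TRUE)
})

test_that("affected embryos are homozygous at the causal variant", {
    fx <- cachedFixture("modifier_like")
    scr <- fx$screens[[1]]
    expect_true(validObject(scr))
    i <- match("causal", rownames(scr@dosage))
    expect_true(all(scr@dosage[i, ] == 2L))
})

test_that("the emitted table passes filtering with exclusions removing contamination", {
    fx <- cachedFixture("modifier_like")
    x <- fx$variants
    ids <- S4Vectors::mcols(rowRanges(x))$id
    flt <- filterEnuSnps(x, fx$exclusions)
    keptIds <- S4Vectors::mcols(rowRanges(flt))$id
    # planted contamination never survives its own exclusion category
    expect_false(any(grepl("^dbsnp|^strain|^pedigree|^repeats", keptIds)))
    # the causal variant does survive
    expect_true("causal" %in% keptIds)
})
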