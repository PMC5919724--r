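# 8-sample table: 5 cases, 3 contrasts; explicit genotype patterns.
modifierToy <- function(n = 500, seed = 6) {
    set.seed(seed)
    samples <- c(paste0("cp", 1:5), paste0("ex", 1:3))
    geno <- matrix(sample(c(0L, 1L, 2L, NA), n * 8, replace = TRUE,
                          prob = c(.5, .25, .2, .05)),
                   n, dimnames = list(NULL, samples))
    # plant a dominant modifier: het in every case, absent in contrasts
    geno[1, ] <- c(rep(1L, 5), rep(0L, 3))
    depth <- matrix(rpois(n * 8, 20), n, dimnames = list(NULL, samples))
    depth[depth < 1] <- 1L
    alt <- matrix(0L, n, 8, dimnames = list(NULL, samples))
    alt[!is.na(geno) & geno == 1L] <- 7L
    alt[!is.na(geno) & geno == 2L] <- 15L
    alt <- pmin(alt, depth)
    pos <- sort(sample.int(2e7, n))
    chrom <- ifelse(pos <= 1e7, "chr1", "chr2")
    pos2 <- ifelse(pos <= 1e7, pos, pos - 1e7)
    tableAt(chrom, pos2, geno, depth, alt,
            classes = rep(c("cleft_palate", "exencephaly"), c(5, 3)))
}

test_that("shared dominant candidates require carriage in every case", {
    samples <- c(paste0("cp", 1:5), paste0("ex", 1:3))
    geno <- matrix(c(rep(1L, 5), 0L, 0L, 0L,    # het all cases, clean: kept
                     rep(1L, 4), 0L, 0L, 0L, 0L, # het in 4/5: dropped
                     rep(1L, 5), 1L, 0L, 0L,    # contrast carrier: dropped
                     rep(2L, 5), 0L, 0L, 0L),   # hom all cases: kept
                   4, 8, byrow = TRUE, dimnames = list(NULL, samples))
    x <- tableAt("chr1", c(100, 200, 300, 400), geno,
                 depth = matrix(10L, 4, 8), alt = pmin(geno * 5L, 10L),
                 classes = rep(c("cleft_palate", "exencephaly"), c(5, 3)))
    got <- sharedDominantCandidates(x, paste0("cp", 1:5), paste0("ex", 1:3))
    expect_equal(start(rowRanges(got)), c(100, 400))

    # a hom-alt contrast carrier is tolerated under het_only
    got2 <- sharedDominantCandidates(
        x, paste0("cp", 1:5), paste0("ex", 1:3), contrastMode = "het_only")
    geno[3, "ex1"] <- 2L
    x2 <- tableAt("chr1", c(100, 200, 300, 400), geno,
                  depth = matrix(10L, 4, 8), alt = pmin(geno * 5L, 10L),
                  classes = rep(c("cleft_palate", "exencephaly"), c(5, 3)))
    got3 <- sharedDominantCandidates(
        x2, paste0("cp", 1:5), paste0("ex", 1:3), contrastMode = "het_only")
    expect_true(300 %in% start(rowRanges(got3)))
    expect_false(300 %in% start(rowRanges(
        sharedDominantCandidates(x2, paste0("cp", 1:5), paste0("ex", 1:3)))))

    expect_error(sharedDominantCandidates(x, character()), "at least one")
})

test_that("a depth-deficient case sample drops a variant", {
    samples <- c(paste0("cp", 1:5), paste0("ex", 1:3))
    geno <- matrix(1L, 1, 8, dimnames = list(NULL, samples))
    geno[1, 6:8] <- 0L
    depth <- matrix(10L, 1, 8, dimnames = list(NULL, samples))
    depth[1, "cp3"] <- 4L
    x <- tableAt("chr1", 100, geno, depth, alt = pmin(geno * 3L, depth),
                 classes = rep(c("cleft_palate", "exencephaly"), c(5, 3)))
    expect_equal(nrow(sharedDominantCandidates(
        x, paste0("cp", 1:5), paste0("ex", 1:3), minDepth = 5)), 0L)
    expect_equal(nrow(sharedDominantCandidates(
        x, paste0("cp", 1:5), paste0("ex", 1:3), minDepth = 4)), 1L)
})

test_that("candidate set equals brute force and contains the plant", {
    x <- modifierToy()
    cases <- paste0("cp", 1:5); contrasts <- paste0("ex", 1:3)
    got <- sharedDominantCandidates(x, cases, contrasts)
    g <- genotypes(x); dp <- depths(x)
    keep <- logical(nrow(x))
    for (i in seq_len(nrow(x))) {
        cg <- g[i, cases]; xg <- g[i, contrasts]
        keep[i] <- all(!is.na(cg) & cg >= 1L) &&
            all(dp[i, cases] >= 5L) &&
            !any(!is.na(xg) & xg >= 1L)
    }
    expect_equal(nrow(got), sum(keep))
    expect_true(keep[1])   # the planted modifier passes the brute force too
    key <- paste(as.character(seqnames(rowRanges(x))), start(rowRanges(x)))
    expect_setequal(paste(as.character(seqnames(rowRanges(got))),
                          start(rowRanges(got))), key[keep])
})

test_that("adding a contrast sample never enlarges the candidate set", {
    x <- modifierToy(seed = 16)
    cases <- paste0("cp", 1:5)
    ex <- paste0("ex", 1:3)
    prev <- NULL
    for (k in 0:3) {
        got <- sharedDominantCandidates(x, cases, ex[seq_len(k)])
        if (!is.null(prev))
            expect_true(all(start(rowRanges(got)) %in% prev))
        prev <- start(rowRanges(got))
    }
})

test_that("class-specific window counts subtract shared variants", {
    samples <- c("a1", "a2", "b1")
    # identical carriage across classes -> all-zero tracks
    geno <- matrix(1L, 6, 3, dimnames = list(NULL, samples))
    x <- tableAt("chr1", seq(1e5, 6e5, by = 1e5), geno,
                 depth = matrix(10L, 6, 3), alt = matrix(5L, 6, 3),
                 classes = c("A", "A", "B"))
    w <- makeWindows(genomeBuild(c("chr1", "chr2"), c(1e7, 1e7)), 1e6, 1e6)
    ct <- classSpecificWindowCounts(x, w)
    expect_true(all(ct$A == 0L) && all(ct$B == 0L))

    # class-private clusters peak in their windows
    geno2 <- rbind(matrix(c(1L, 1L, 0L), 4, 3, byrow = TRUE),
                   matrix(c(0L, 0L, 2L), 3, 3, byrow = TRUE))
    colnames(geno2) <- samples
    pos <- c(seq(2e6 + 1e4, 2e6 + 4e4, by = 1e4), seq(5e6 + 1e4, 5e6 + 3e4,
                                                      by = 1e4))
    x2 <- tableAt("chr1", pos, geno2, depth = matrix(10L, 7, 3),
                  alt = pmin(geno2 * 5L, 10L), classes = c("A", "A", "B"))
    ct2 <- classSpecificWindowCounts(x2, w)
    expect_equal(max(ct2$A), 4L)
    expect_equal(as.character(seqnames(ct2))[which.max(ct2$A)], "chr1")
    expect_equal(start(ct2)[which.max(ct2$A)], 2e6 + 1)
    expect_equal(max(ct2$B), 3L)
    expect_equal(start(ct2)[which.max(ct2$B)], 5e6 + 1)
    # conservation over the non-overlapping tiling
    expect_equal(sum(ct2$A), 4L)
    expect_equal(sum(ct2$B), 3L)
})

test_that("class-specific sets are pairwise disjoint", {
    x <- modifierToy(seed = 26)
    w <- makeWindows(genomeBuild(c("chr1", "chr2"), c(1e7, 1e7)), 1e6, 1e6)
    ct <- classSpecificWindowCounts(x, w)
    g <- genotypes(x)
    presA <- rowSums(!is.na(g[, 1:5]) & g[, 1:5] >= 1L) > 0
    presB <- rowSums(!is.na(g[, 6:8]) & g[, 6:8] >= 1L) > 0
    qual <- siteQual(x) >= 30
    specA <- qual & presA & !presB & rowSums(depths(x)[, 1:5]) >= 5
    specB <- qual & presB & !presA & rowSums(depths(x)[, 6:8]) >= 5
    expect_equal(sum(ct$cleft_palate), sum(specA))
    expect_equal(sum(ct$exencephaly), sum(specB))
    expect_equal(sum(specA & specB), 0L)
    expect_error(classSpecificWindowCounts(
        x, w, classes = list(A = paste0("cp", 1:5))), "two")
})

test_that("validation genotypes reject non-co-segregating candidates", {
    x <- modifierToy()
    cand <- sharedDominantCandidates(x, paste0("cp", 1:5), paste0("ex", 1:3))
    key <- paste(as.character(seqnames(rowRanges(cand))),
                 start(rowRanges(cand)),
                 S4Vectors::mcols(rowRanges(cand))$alt, sep = ":")
    co <- data.frame(variant = key[1], sample = paste0("v", 1:4),
                     phenotype = c(TRUE, TRUE, FALSE, FALSE),
                     geno = c(1L, 2L, 0L, 0L))
    expect_equal(modifierValidation(cand[1, ], co)$verdict, "compatible")
    bad <- co; bad$geno[3] <- 1L   # a without-phenotype carrier
    expect_equal(modifierValidation(cand[1, ], bad)$verdict, "rejected")
    bad2 <- co; bad2$geno[1] <- 0L # a with-phenotype non-carrier
    expect_equal(modifierValidation(cand[1, ], bad2)$verdict, "rejected")

    # randomized fixture vs brute force
    set.seed(12)
    val <- data.frame(variant = sample(key, 60, TRUE),
                      sample = paste0("w", 1:60),
                      phenotype = sample(c(TRUE, FALSE), 60, TRUE),
                      geno = sample(c(0:2, NA), 60, TRUE))
    res <- modifierValidation(cand, val)
    for (i in seq_along(key)) {
        rows <- val[val$variant == key[i], ]
        carries <- !is.na(rows$geno) & rows$geno >= 1
        want <- if (any(rows$phenotype & !carries) ||
                    any(!rows$phenotype & carries)) "rejected" else "compatible"
        expect_equal(res$verdict[i], want)
    }
})

test_that("the planted modifier survives the simulated two-class screen", {
    fx <- cachedFixture("modifier_like")
    x <- filterEnuSnps(fx$variants, fx$exclusions)
    cp <- samplesOf(x, "cleft_palate"); ex <- samplesOf(x, "exencephaly")
    expect_equal(length(cp), 5L)
    expect_equal(length(ex), 3L)
    cand <- sharedDominantCandidates(x, cp, ex)
    expect_true("modifier" %in% S4Vectors::mcols(rowRanges(cand))$id)
    # combined-reads track peaks on the modifier chromosome
    w <- makeWindows(GenomeInfoDb::seqinfo(rowRanges(x)))
    ct <- classSpecificWindowCounts(x, w)
    peak <- which.max(ct$cleft_palate)
    expect_equal(as.character(seqnames(ct))[peak],
                 fx$screens[[1]]@config@modifier$chrom)
})
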