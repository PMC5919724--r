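#' @importFrom stats pchisq fisher.test rbinom rpois runif
#' @importFrom utils combn
NULL

#' Penetrance of a phenotypic feature among mutants
#'
#' @param a mutants showing the feature.
#' @param b mutants without the feature.
#' @return percentage `100 * a / (a + b)` (full precision; round for
#'   display).
#' @examples
#' penetrance(11, 51)  # 17.74194
#' @export
penetrance <- function(a, b) {
    stopifnot(a >= 0, b >= 0)
    if (a + b == 0) stop("penetrance undefined for an empty cohort")
    100 * a / (a + b)
}

#' Contingency of a feature on the mutant genotype
#'
#' Tests whether the absence of a feature among unaffected (wild-type-
#' looking) littermates deviates from the rate observed in the mutant
#' cohort. The default is a goodness-of-fit chi-squared (1 df) of the
#' observed littermate split against the expectation `n_wt * a / (a + b)`;
#' Fisher's exact test on the 2x2 table is available as an alternative.
#'
#' @param a,b feature-positive / feature-negative counts among mutants.
#' @param nWt unaffected littermates genotyped/scored.
#' @param oWt littermates observed with the feature.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return list with `expected` (unrounded expected littermates with the
#'   feature), `statistic` (NA for Fisher), `p.value`, `method`.
#' @examples
#' contingentPhenotypeTest(16, 46, 155, 0)$expected  # 40
#' @export
contingentPhenotypeTest <- function(a, b, nWt, oWt,
                                    method = c("chisq", "fisher")) {
    method <- match.arg(method)
    stopifnot(nWt > 0, oWt >= 0, oWt <= nWt)
    expected <- nWt * a / (a + b)
    if (method == "chisq") {
        if (expected == 0)
            stop("degenerate test: expected feature count is zero")
        obs <- c(nWt - oWt, oWt)
        exp <- c(nWt - expected, expected)
        stat <- sum((obs - exp)^2 / exp)
        list(expected = expected, statistic = stat,
             p.value = pchisq(stat, df = 1, lower.tail = FALSE),
             method = "chisq")
    } else {
        ft <- fisher.test(matrix(c(a, b, oWt, nWt - oWt), nrow = 2))
        list(expected = expected, statistic = NA_real_,
             p.value = ft$p.value, method = "fisher")
    }
}

#' Mapping success rate when subsampling the cohort
#'
#' In-silico estimate of how many sequenced mutants a screen needs: draws
#' subsets of `k` samples, maps each subset with [windowStats] +
#' [callRegions], and reports the fraction whose top-ranked region overlaps
#' the reference region. All `choose(n, k)` subsets are enumerated when
#' there are at most `enumerateLimit` of them; otherwise `nDraws` random
#' subsets are drawn without replacement under `seed`.
#'
#' @param x ENU-filtered [VariantTable].
#' @param windows `GRanges` from [makeWindows].
#' @param samples pool of sample ids.
#' @param k subset size (`1 <= k <= length(samples)`).
#' @param reference `GRanges` the top region must overlap (ground truth or
#'   the full-cohort region).
#' @param nDraws random draws when not enumerating (default 50).
#' @param seed RNG seed for the random draws (default 1).
#' @param enumerateLimit enumerate exhaustively up to this many subsets
#'   (default 200).
#' @param ... thresholds passed to [callRegions].
#' @return success fraction in `[0, 1]`, with the number of subsets tried
#'   as attribute `n_subsets`.
#' @export
subsampleMappingPower <- function(x, windows, samples, k, reference,
                                  nDraws = 50, seed = 1,
                                  enumerateLimit = 200, ...) {
    n <- length(samples)
    if (k > n) stop("k exceeds the number of available samples")
    if (k < 1) stop("k must be at least 1")
    subsets <- if (choose(n, k) <= enumerateLimit) {
        asplit(combn(samples, k), 2L)
    } else {
        rng <- .seededRng(seed)
        replicate(nDraws, rng$sample(samples, k), simplify = FALSE)
    }
    hits <- vapply(subsets, function(s) {
        st <- windowStats(x, windows, samples = s)
        rg <- callRegions(st, ...)
        length(rg) > 0L && overlapsAny(rg[1], reference,
                                       ignore.strand = TRUE)
    }, logical(1))
    structure(mean(hits), n_subsets = length(subsets))
}

# Local RNG stream that leaves the caller's .Random.seed untouched.
.seededRng <- function(seed) {
    env <- new.env()
    env$state <- local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                            globalenv())
        set.seed(seed)
        s <- get(".Random.seed", globalenv())
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        s
    })
    run <- function(fn) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                            globalenv())
        assign(".Random.seed", env$state, globalenv())
        on.exit({
            env$state <- get(".Random.seed", globalenv())
            if (!is.null(old)) assign(".Random.seed", old, globalenv())
        })
        fn()
    }
    list(sample = function(v, k) run(function() sample(v, k)))
}
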