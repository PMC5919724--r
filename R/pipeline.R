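#' Run the filter -> map -> candidates pipeline
#'
#' Chains the core analysis on files: read variants and exclusions, filter
#' putative ENU SNVs, compute window statistics, call regions, and extract
#' coding/splice-proximal candidates. All outputs plus a machine-readable
#' run manifest (inputs, thresholds, output hashes) are written under
#' `outDir`.
#'
#' @param config named list:
#'   \describe{
#'     \item{`vcf`, `manifest`}{input paths (required).}
#'     \item{`exclusions`}{named list of BED/VCF paths (optional).}
#'     \item{`gff`}{gene models for candidate extraction (optional).}
#'     \item{`genome`}{`list(chroms, lengths)`; defaults to the VCF
#'       contigs.}
#'     \item{`samples`}{analyzed samples (default: all).}
#'     \item{`minQual`, `minDepth`, `depthMode`}{filter settings
#'       (defaults 30, 5, per_sample_min).}
#'     \item{`windowSize`, `step`}{window spec (defaults 1e7, 1e6).}
#'     \item{`minHomCount`, `minHomPct`, `minAvgNaf`}{region thresholds.}
#'   }
#'   Unknown keys are rejected.
#' @param outDir output directory.
#' @return invisibly, a list with the filtered table, window stats,
#'   regions, candidates and the manifest path.
#' @export
runPipeline <- function(config, outDir) {
    known <- c("vcf", "manifest", "exclusions", "gff", "genome", "samples",
               "minQual", "minDepth", "depthMode", "windowSize", "step",
               "minHomCount", "minHomPct", "minAvgNaf")
    bad <- setdiff(names(config), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    if (is.null(config$vcf) || is.null(config$manifest))
        stop("config needs 'vcf' and 'manifest'")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    mf <- readSampleManifest(config$manifest)
    x <- readVariants(config$vcf, mf)
    excl <- if (!is.null(config$exclusions))
        readExclusions(config$exclusions) else NULL
    samples <- config$samples %||% colnames(x)
    params <- filterParams(minSiteQual = config$minQual %||% 30,
                           minDepth = config$minDepth %||% 5)
    flt <- filterEnuSnps(x, excl, params,
                         depthMode = config$depthMode %||% "per_sample_min",
                         samples = samples)
    genome <- if (!is.null(config$genome))
        genomeBuild(config$genome$chroms, config$genome$lengths)
        else GenomeInfoDb::seqinfo(rowRanges(x))
    if (any(is.na(seqlengths(genome))))
        stop("genome lengths unavailable; provide config$genome or VCF ",
             "contig headers with lengths")
    w <- makeWindows(genome, config$windowSize %||% 1e7,
                     config$step %||% 1e6)
    st <- windowStats(flt, w, samples = samples)
    rg <- callRegions(st, minHomCount = config$minHomCount,
                      minHomPct = config$minHomPct %||% 80,
                      minAvgNaf = config$minAvgNaf %||% 0.8)
    paths <- list(windows = file.path(outDir, "windows.tsv"),
                  regions = file.path(outDir, "regions.tsv"),
                  audit = file.path(outDir, "filter_audit.tsv"))
    writeWindowStats(st, paths$windows)
    write.table(as.data.frame(rg), paths$regions, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(auditFilter(flt), paths$audit, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cands <- NULL
    if (!is.null(config$gff)) {
        genes <- readGeneModels(config$gff)
        cands <- candidatesInRegions(flt, rg, genes, samples = samples)
        paths$candidates <- file.path(outDir, "candidates.tsv")
        write.table(as.data.frame(cands), paths$candidates, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
        config = config[setdiff(names(config), "exclusions")],
        exclusions = config$exclusions,
        thresholds = list(
            minQual = params$minSiteQual, minDepth = params$minDepth,
            windowSize = config$windowSize %||% 1e7,
            step = config$step %||% 1e6,
            minHomCount = config$minHomCount %||%
                .defaultMinHomCount(st),
            minHomPct = config$minHomPct %||% 80,
            minAvgNaf = config$minAvgNaf %||% 0.8),
        n_input = nrow(x), n_filtered = nrow(flt),
        n_regions = length(rg),
        outputs = lapply(paths, function(p)
            unname(tools::md5sum(p))))
    mpath <- file.path(outDir, "run_manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(list(filtered = flt, stats = st, regions = rg,
                   candidates = cands, manifest = mpath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
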