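# enuscan

Homozygosity mapping and variant prioritization for ENU mutagenesis
screens run on an **inbred** mouse background.

## The problem

Classical forward-genetic mapping outcrosses a mutant line to a second
strain and follows strain-polymorphic markers. An inbred screen has no
such markers — but N-ethyl-N-nitrosourea (ENU) itself induces roughly
3000 heterozygous point mutations in the mutagenized founder's genome,
and those lesions can serve as the mapping markers. In a G2 backcross
(G2 daughters crossed back to the G1 founder male), affected embryos are
homozygous for the chromosomal segment carrying the recessive causal
lesion, together with every linked ENU variant on it.

`enuscan` implements the desk side of such a screen for whole-genome
sequencing of affected embryos:

* **ENU SNV filtering** — remove known variation (dbSNP-like catalogs,
  strain variants, in-house pedigrees, repeat regions) and low-evidence
  calls (site quality < 30, depth < 5).
* **Homozygosity mapping** — per sliding window (10 Mb, 1 Mb step by
  default), three statistics over the analyzed samples:
  * `hom_count` — number of SNVs homozygous-alt in *every* sample,
  * `hom_pct` — `100 * hom_count / n_snps`,
  * `avg_naf` — mean novel allele frequency: per SNV, reads are pooled
    across samples and the alt-read fraction taken, then averaged over
    the window.
  The causal region shows high values of all three; regions are called,
  merged and ranked.
* **Cohort partitioning** — when one apparent phenotype is really two
  mutations, samples are grouped by similarity of their single-sample
  maps, with every merge verified by joint re-mapping.
* **Candidate extraction** — homozygous variants in coding sequence or
  within 10 bp of an exon, plus concordance scoring of follow-up
  genotyping.
* **Dominant-modifier screening** — shared heterozygous variants private
  to a phenotype class, and class-specific sliding-window SNV counts.
* **Split-read deletion detection** — soft-clipped reads clustered by
  exact trimmed location (> 5 reads), right/left clip clusters paired
  into deletion calls with `length = end - start` (half-open).
* **Screen statistics** — penetrance, the chi-squared test for
  phenotype contingency, and in-silico subsampling to ask how many
  sequenced mutants a screen needs.
* **A forward simulator** — founder mutation load, Haldane
  recombination through the backcross, read sampling, genotype calling,
  exclusion-list contamination and planted deletions/modifiers, so the
  whole pipeline is testable with known ground truth.

## Worked example

Simulate a three-embryo screen at the package's test scale (5 x 30 Mb
genome, 3000 founder variants, 20x depth), filter, map and extract
candidates:

```r
library(enuscan)

cfg <- simConfig(nAffected = 3, seed = 42)
scr <- simulateScreen(cfg)
x   <- filterEnuSnps(screenVariants(scr), screenExclusions(scr))
auditFilter(x)
#>     reason    n
#> 1    dbsnp  189
#> 2   strain  151
#> 3 pedigree  106
#> 4  repeats  135
#> 5  quality  379
#> 6    depth    0
#> 7 retained 2211

w  <- makeWindows(GenomeInfoDb::seqinfo(SummarizedExperiment::rowRanges(x)))
st <- windowStats(x, w)          # n_snps / hom_count / hom_pct / avg_naf
rg <- callRegions(st)
as.data.frame(rg)[1, c(1:3, 6:9)]
#>   seqnames   start      end peak_hom_count peak_hom_pct peak_avg_naf n_windows
#> 1     chr1 6000001 30000000            217     98.19005    0.9894671        15

candidatesInRegions(x, rg, screenGenes(scr))
#>   seqnames    start  gene effect region_rank
#> 1     chr1 15000000 GeneC coding           1
```

The top-ranked region covers chr1:6–30 Mb with 98% of its 221 window
SNVs homozygous in all three embryos at a pooled novel allele frequency
of 0.99; the single coding candidate inside it is the planted causal
variant (chr1:15,000,000). Deletion scanning works the same way from
alignments:

```r
fx    <- makeFixture("timon_like", seed = 3)
calls <- pairBreakpoints(clusterClips(collectClipped(fx$alignments)))
calls[, 1:4]
#>   chrom    start      end length
#> 1 chr18 58012626 58014322   1696
```

A thin command-line front end wraps the same functions:
`Rscript $(Rscript -e 'cat(system.file("cli","enuscan.R",package="enuscan"))') --help`
(subcommands `simulate`, `run`, `svscan`, `stats`, `power`).

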