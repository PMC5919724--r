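---
title: "Mapping recessive lesions in inbred ENU screens: methods and design"
author: "enuscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive lesions in inbred ENU screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping model

An inbred ENU screen removes the usual source of mapping markers (strain
polymorphism) and substitutes the mutagen's own lesions. The G1 founder
male carries on the order of 3000 heterozygous ENU-induced point
mutations. His daughters (G2) inherit a random half of them; backcrossing
G2 daughters to the G1 makes any given founder variant homozygous in 1/4
of embryos from carrier crosses. An embryo selected for a recessive
phenotype is therefore homozygous not only for the causal lesion but for
the whole co-inherited segment around it, in *every* affected embryo —
while at unlinked sites the probability that all of `n` embryos are
homozygous decays geometrically (1/8 per embryo unconditionally, 1/4
conditional on the G2 carrying the variant; with three embryos the
genome-wide background is below 1%).

Three statistics summarize a window of filtered putative ENU SNVs over
the analyzed samples:

* `hom_count` — SNVs homozygous-alt in every sample (a missing genotype
  never counts as homozygous);
* `hom_pct` — `100 * hom_count / n_snps`;
* `avg_naf` — the novel allele frequency: per SNV, alt reads and total
  reads are pooled across samples and their ratio taken; the per-SNV
  fractions are averaged unweighted over the window. Pooling before the
  ratio is robust at low per-sample depth; per-sample averaging is
  available via `nafMode = "per_sample"`.

The causal region is where all three are high; `callRegions()` merges
qualifying windows and ranks regions by peak `hom_count`, with
`hom_pct`, `avg_naf` and coordinate as deterministic tie-breaks.

### Which SNVs enter a window's denominator

By default `n_snps` counts only SNVs *segregating in the analyzed
subset* (at least one analyzed sample carries the alternate allele).
Joint cohort VCFs contain sites private to other pedigrees, at which the
analyzed samples are uniformly homozygous reference; counting them would
roughly halve `hom_pct` for mixed cohorts without adding information.
`segregatingOnly = FALSE` restores the literal all-sites denominator.

### Window geometry

"10 Mb windows with a 1 Mb overlap" is implemented as window 10 Mb,
step 1 Mb — consecutive windows share 9 Mb. This reading is forced by
the refinement case, where "window and overlap size 50 kb" only makes
sense as a 50 kb step (a non-overlapping tiling). Both parameters are
free (`makeWindows(genome, windowSize, step)`), so the alternative
reading (step = window − overlap) is one argument away.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minSiteQual` | 30 (phred) | VCF site QUAL floor ("quality score" is read as site QUAL — the only site-level quality a generic VCF carries) |
| `minDepth` | 5 reads | depth floor; `per_sample_min` for per-individual workflows, `pooled_total` for combined-reads workflows |
| `windowSize`, `step` | 10 Mb, 1 Mb | mapping windows; 50 kb / 50 kb for refinement |
| `minHomPct` | 80 | windows qualify at ≥ 80% homozygous SNVs |
| `minAvgNaf` | 0.8 | and pooled novel allele frequency ≥ 0.8 |
| `minHomCount` | `max(5, 0.5 × mean)` | scan-relative count floor, so sparse scans do not qualify on two or three SNVs |
| `spliceMargin` | 10 bp | splice-proximal margin; distance 1 is the base adjacent to the exon edge, boundaries inclusive, strand ignored |
| `minReads` (clips) | 6 | "more than five reads with the same trimmed location" |

When a region is re-tiled at 50 kb the marker supply per window drops by
two orders of magnitude, so the count floor must scale with it: region
calling on refined windows should pass an explicit small `minHomCount`
(the acceptance analyses use 2). The percentage and allele-frequency
thresholds are scale-free and stay put.

## Exclusion screening

Site catalogs (dbSNP-like, strain variants, in-house pedigrees) match on
chromosome, position and alternate allele; positional masks (repeats)
match on position alone. Whether pedigree exclusion should be
allele-aware is not determinable from first principles, so it is a
per-category switch (`alleleAware=`), defaulting to allele-aware like the
other catalogs. Multiallelic VCF rows are split per alternate allele
before any matching; indels are flagged and retained. Removal-reason
audits attribute each removed record to its first failing category in a
fixed order (dbsnp, strain, pedigree, repeats, quality, depth), so audit
tables are deterministic.

## Partitioning mixed cohorts

Two near-identical phenotypes arising from different genes can enter one
cohort. Each sample is first mapped alone and its set of qualifying
windows recorded; samples are grouped by greedy average-linkage
agglomeration on the Jaccard similarity of those sets. Window sets alone
are not decisive: a single embryo contributes only three informative
meioses, so chance chromosome-scale homozygous runs are common, inflate
the union, and can even coincide with the other pedigree's locus.
Every proposed merge is therefore verified by re-mapping the merged
group jointly — two pedigrees are homozygous for *different variants*
even where their windows coincide, so a wrong merge has no joint
qualifying region and is rejected. The similarity cutoff (default 0.05)
is only a shortlist heuristic; verification decides every merge. This
makes the iterative try-sample-combinations strategy explicit and
deterministic. Groups below `minGroup` (default 2) or with no joint
region are reported unresolved — which genuinely happens when an embryo
recombined tightly around the causal locus; window refinement, not
partitioning, is the tool for that case.

## Split-read deletion calling

Soft clips are taken from CIGAR strings (SAM/BAM via Rsamtools, or a
plain TSV dialect `sample chrom pos cigar [remap]`). A trailing clip
records a right-clip at the 1-based boundary after the last aligned
base; a leading clip records a left-clip at the alignment start.
Clusters require identical (chromosome, position, side) by default —
"the same trimmed location" — with an optional ±N bp tolerance for
noisier aligners. Right-clip clusters pair with the nearest downstream
left-clip cluster; the deleted segment is the half-open interval
`[start, end)`, so `length = end − start` (the published chr18
coordinates 58,012,626–58,014,322 give 1696 bp under this convention;
an inclusive-inclusive reading would give 1697). Whether read support
is pooled across samples (default) or required per sample is a flag
(`requireSamples`).

## Screen-level statistics

`penetrance(a, b)` is `100·a/(a+b)`, full precision (display rounding is
the caller's). The contingency test compares unaffected littermates
against the mutant-cohort feature rate: expected = `n_wt·a/(a+b)`,
goodness-of-fit chi-squared with 1 df on (with feature, without), with
Fisher's exact 2×2 as an alternative. For the printed exencephaly
counts (16/46 mutants, 155 littermates, 0 observed) this gives an
expectation of 40 and a chi-squared of 40²/40 + 40²/115 ≈ 53.9, i.e. p
far below 10⁻⁶. The package reports its own computed statistic; it does
not attempt to match any particular printed p-value, since the exact
test construction behind such values is generally not recoverable.
Expected counts are reported unrounded (27.5 stays 27.5).

`subsampleMappingPower()` asks the screen-design question directly:
draw k-sample subsets, map each, and report the fraction whose
top-ranked region overlaps the reference. All `choose(n,k)` subsets are
enumerated when there are ≤ 200; otherwise seeded draws. On simulated
six-embryo screens power is ~1 at k = 3 and visibly lower at k = 1,
where chance homozygous runs in a single embryo can outrank the causal
chromosome — the quantitative form of "three samples suffice".

## The simulator: what it emulates, and what it does not

`simulateScreen()` draws the founder load as Poisson(3000) with
positions uniform per chromosome (length-weighted); crossovers follow
Haldane's model (Poisson count per chromosome at the genetic length, no
interference, uniform positions). Each embryo unites a fresh G1 gamete
with a gamete from a carrier G2 daughter whose paternal haplotype is
itself a G1 meiotic product conditioned to carry the causal allele —
conditioning stands in for progeny testing. Embryos accumulate until the
configured cohort is reached; affected ⇔ homozygous at the causal locus.

Reads per site and sample are Poisson(20) with Binomial alt counts at
error-perturbed allele fractions (0.5% base error); genotypes are called
from the alt fraction (hom ≥ 0.9, het 0.25–0.75, hom-ref ≤ 0.1, depth
≥ 4, otherwise missing), and site QUAL is synthesized as 3× pooled alt
reads capped at 500, so evidence-poor sites genuinely fail the quality
floor. Sites with essentially no alternate evidence are not emitted,
as a joint caller would not report them. Contamination is injected per
exclusion category — segregating polymorphism-like sites carried in the
matching dbSNP/strain/pedigree catalogs or repeat BED, plus an
`artifact` category of noisy low-fraction sites that the quality filter,
not the exclusion lists, must remove.

The default test scale is a 5 × 30 Mb genome at the real map density of
0.5 cM/Mb, chromosomes several times the 10 Mb window so sliding windows
localize within a chromosome exactly as they do at genome scale; the
causal variant sits mid-chromosome inside a toy gene's CDS. Named
profiles provide the structured cases: `fosse_like` (two pedigrees
sequenced as one 6 + 2 cohort, distinct loci), `timon_like` (a
recombination tight around the causal locus on a 60 Mb chromosome plus
a planted 1696 bp deletion with soft-clip read support), and
`modifier_like` (5 + 3 phenotype classes split by carriage of a planted
dominant modifier).

What the simulator does **not** model: nucleotide-context bias of ENU,
crossover interference, sex chromosomes, mosaicism, alignment artifacts
beyond the soft-clip geometry, shared founder pedigrees (approximated
only by the pedigree contamination knob), or FASTQ-level read
simulation. Passing tests therefore demonstrate the statistical
machinery under the breeding design's genetics — not robustness to
aligner- or caller-specific failure modes of real WGS data.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive for variants (VCF convention) and
  converted at I/O boundaries; BED input/output is 0-based half-open;
  windows are reported as 1-based closed `GRanges` and written to TSV
  as half-open.
* Empty windows carry `hom_pct = 0`, `avg_naf = 0` and an `empty` flag
  rather than NaN; empty tables filter to empty tables; a cohort with
  no qualifying window yields an empty, typed region set.
* Region ranking, audit attribution, cluster ordering and pairing are
  all given fixed tie-break orders, so every output is reproducible
  byte-for-byte under a seed.
* Missing genotypes never count as homozygous, never as carriers, and
  never enter denominators.
* In embryo genotype matrices the backcross design admits dosages 0/1/2
  only; the simulator's calling stage is the only source of NA.

## Problem sizes

The test suite and acceptance script run at the desk scale the package
was designed around: 3000-variant founders, 3–8 embryos, 20× depth,
5 × 30 Mb genomes (60 Mb chromosome for the deletion profile), 50
replicate screens for the recovery rate, and exhaustive subset
enumeration for k ≤ 3 of 6. A mouse-scale configuration is a
`simConfig(genome = ...)` call away, but the statistical behavior of
every component is already exercised at these sizes.
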