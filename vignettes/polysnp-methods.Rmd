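---
title: "Methods: polyploid-aware SNP discovery and marker genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyploid-aware SNP discovery and marker genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysnp)
```

## The problem

Transcriptome (EST) sequencing is an attractive route to SNP discovery
in species without a reference genome, but in polyploids it has a
characteristic failure mode. Hexaploid oat (*Avena sativa*, AACCDD,
2n = 6x = 42) carries three related subgenomes; homoeologous gene
copies are similar enough that a de novo assembler frequently collapses
them into a single contig. Reads from the distinct copies then disagree
with the contig consensus at every site where the copies differ, and a
naive variant caller reports those sites as SNPs. These *pseudo-SNPs*
are not allelic variation — every genotype shows them — and assays
designed on them fail or produce uninterpretable multi-locus signals.
The same applies to paralogous duplicates within a subgenome.

`polysnp` implements a discovery pipeline built around a simple, strong
observation: a *true* allelic difference between a (largely inbred)
genotype and the reference assembly should be carried by **all** of
that genotype's reads at the site, while a collapsed-copy artifact is
carried by only the fraction of reads contributed by the deviating
copy. Requiring 100% within-genotype frequency is therefore the
decisive polyploidy screen; indel/ambiguity removal and a depth floor
guard its inputs.

## Pipeline model

Candidate variants enter as mapper-style records: contig, 1-based
start/end, reference and variant allele, frequency (percent of reads at
the site carrying the variant), read depth, genotype. One genotype is
the *reference-assembly genotype*: its contigs are the coordinate frame
and its own re-mapped records drive the self-screen.

1. **Reference self-screen** (`screen_reference`): contigs with
   indel/multi-base self-variants are removed first, then contigs with
   ambiguous (`N`) consensus bases or `N` self-calls. Both percentages
   are reported against the initial contig count, and a contig failing
   both rules is counted once, under the indel stage.
2. **Filter cascade** (`filter_candidates`): records on screened-out
   contigs are dropped silently; the cascade then removes, in reported
   order, (i) indel/multi-base/`N` records, (ii) records with depth
   ≤ 4, (iii) records with frequency < 100%. Stage percentages share
   the cascade's entering count as denominator, matching how such
   attrition is conventionally narrated. Passing the conservation rule
   requires exact equality to 100 within 1e-9 on the percent scale:
   anything less is evidence of a second locus, not an allele.
3. **Sharing classification** (`classify_candidates`): surviving
   records are grouped by (contig, position, variant allele); the
   number of genotypes in a group is its sharing class (1, 2, 3 for a
   four-genotype survey). Sharing requires an *identical* variant
   allele at an identical coordinate. This is the conservative choice —
   a laxer position-only rule would merge genuinely distinct alleles
   into one candidate; both interpretations are recoverable from the
   catalog since distinct alleles at one position remain separate rows.
4. **Assay-target selection** (`select_assay_targets`): a contig with
   two candidate positions strictly closer than 100 bp is excluded from
   the assay set (its candidates stay in the catalog). Melt-curve
   genotyping interrogates the whole amplicon, so a second polymorphism
   inside the product window corrupts the assay. We read "within a
   100 bp region" as a strict inequality and document the boundary
   (candidates exactly 100 bp apart are retained).
5. **Masking** (`mask_snp_fasta`): each eligible candidate is exported
   as a dbSNP-style FASTA window — up to 50 bp flank per side, the SNP
   base replaced by the two-base IUPAC code (A/G→R, C/T→Y, A/C→M,
   G/T→K, A/T→W, C/G→S) — annotated with the 90 ± 30 bp product-size
   constraint passed to primer-design software. Windows truncated by a
   contig end are flagged, not rejected; primer design decides their
   fate.

### Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `depth_min` | 5 | reads | below 5 reads, a 100%-frequency observation is too easily a sampling accident |
| `freq_required` | 100 | % | the polyploidy screen itself; exact equality, tolerance 1e-9 |
| `window_bp` | 100 | bp | amplicon-scale exclusion zone for secondary targets |
| `flank_bp` | 50 | bp | flank handed to primer design; with the SNP centred this accommodates the product-size optimum |
| `product_size`/`product_tol` | 90 / 30 | bp | short amplicons maximize melt sensitivity to a single-base change |

### Reporting conventions

Attrition lines render as `N (P%) removed`, thousands-separated, with
percentages rounded to the nearest integer — except below 2%, where one
decimal is kept so small classes do not print as `0%`. A single
consistent rounding rule cannot reproduce every hand-rounded figure
seen in published narratives of this kind (nearest-rounding a 1.85%
class gives `1.9%`, where truncation would give `1.8%` but would also
turn a 0.17% class into `0.1%`); we chose nearest rounding throughout
and treat the one-decimal band as a readability device, not a promise
of any particular historical table.

The cross-genotype cascade's denominator is labelled *candidate
records* (the records entering the filter), the only reading under
which the published-scale stage percentages (14%, 13%, 55%, 18%
retained) are mutually consistent.

## The built-in caller

`align_reads`/`call_variants` provide a deterministic stand-in for the
proprietary mapper that produced the original header reports, so the
pipeline can be exercised from reads. Placement is best-scoring banded
edit-distance alignment (band 10% of read length) of each read against
each contig; a small gap-opening surcharge (0.5 on top of unit gap
cost) breaks mismatch-versus-indel ties toward the mismatch, so a
substitution near a read end is never reported as an indel. Ties
between placements resolve to the lexicographically smaller contig id,
then the smaller offset. Calling emits one record per column per
observed non-reference allele with frequency `100 × allele reads /
depth` rounded to one decimal; read deletions carry `-` as the variant
allele and insertions `-` as the reference allele, anchored at the
preceding reference position. How the original mapper aggregated
multi-base events into single rows is not documented; we emit
per-column records and note the divergence. `N` counts toward depth as
its own allele class; uncovered columns never emit records.

## The synthetic data generator

`simulate_transcriptomes` emulates the genome features that create the
filtering problem: gene families with 1–3 subgenome copies diverged at
a configurable per-base rate; a configurable fraction of families
collapsing to a single reference contig (those inter-copy differences
are the ground-truth pseudo-SNPs, visible in every genotype at a read
fraction set by the expression ratio); true allelic SNPs planted in
non-reference genotypes, fixed within carriers across all copies of
the family so an error-free caller sees them at 100%. The sharing-class
mix of planted SNPs defaults to 0.89/0.10/0.01, the heavy
single-genotype skew such surveys report.

Defaults are chosen once to describe a four-genotype hexaploid-like
survey: 580 bp genes (mean EST contig length near 577 bp), mean
coverage 4× (reported transcript coverage 3.1–4.1×), 350 bp reads
(FLX-Titanium era), two copies per family at 2% divergence, equal
homoeolog expression, base-miscall rate 0.005 and homopolymer-run
indel rate 0.005 (the technology's characteristic error mode: per
homopolymer run of length ≥ 3, one base inserted or deleted).

`simulate_reads` draws Poisson read counts per transcript with uniform
start positions — adequate for desk-scale tests, though real 454
coverage is neither uniform along transcripts nor independent of
composition. `simulate_variant_tables` is a record-level shortcut that
skips alignment: depths are Poisson, pseudo-SNP allele counts binomial
in the expression share, planted-SNP counts binomial in
`1 − base_error`. Both modes emit the same record schema, and all
randomness in either mode flows from the single integer seed (each
entry point re-seeds deterministically, so transcriptomes, reads and
tables are individually reproducible).

What passing on synthetic data does **not** show: robustness to
chimeric contigs, misassembly beyond clean copy-collapse, strand
biases, quality-correlated errors, or paralog families larger than
three copies. The generator makes the filter's *logic* testable, not
the upstream assembler's behaviour.

## Marker genetics

* `score_segregation` counts parental calls per marker in a RIL table,
  reports the segregation ratio SR = n_A/n_B (parent-A allele first;
  `NA`, not an error, when n_B = 0) and tests 1:1 with a 1-df
  chi-square without continuity correction on the homozygous counts.
  The distortion flag (default α = 0.05) is an extension beyond the
  plain ratio and is labelled as such. Markers with ≥ 40% heterozygous
  calls are flagged separately: in an F6 RIL population that pattern
  indicates a two-locus mixture, not a marker. Simulating 1,000
  markers over 136 lines under a true 1:1 puts the flag's type-I rate
  at the nominal 5% (the acceptance suite checks 0.05 ± 0.02).
* `code_binary` expands a diversity-mode call table into marker-state
  indicator columns. `Null` scores 0 everywhere for its marker
  (absence of amplification is the absence of every allele); missing
  scores `NA` and is handled pairwise-complete downstream. Het coding
  is configurable because melt analysis genuinely resolves the
  heterozygote as its own curve class: the default keeps `Het` as a
  state column; `expand` mode scores both constituent alleles when the
  marker has exactly two single-base states. Whether historical
  analyses coded Het one way or the other is not documented; both are
  provided and the default follows the instrument's phenomenology.
* `dice_similarity` implements S = 2a/(2a + b + c) over
  pairwise-complete columns, defined as 0 for empty profiles.
* `upgma` is written out rather than delegated so its tie-break is
  specified: equal-distance merges resolve to the lexicographically
  smallest pair of minimum member labels, making dendrograms
  reproducible across platforms (generic average-linkage
  implementations leave tie order to floating-point accidents; on
  tie-free inputs ours matches `hclust(method = "average")`
  cophenetics exactly, and the tests enforce this). Merge height is
  half the merged distance; the output is ultrametric by construction
  and serializes to Newick with branch lengths.
* `allele_summary` counts distinct observed states per marker and
  partitions them by prefix into SNP alleles versus supplementary
  insertion/deletion, heterozygote and null states. `Null` counts as
  an allele here (a reproducible no-amplification class is
  informative), which is deliberately different from its all-zero
  treatment in the binary coding.

## Numerical and degenerate-input choices

* Frequencies are compared at 1e-9 on the percent scale; one-decimal
  printing in the TSV dialect is exact for frequencies derived from
  read counts up to depth 1000.
* Per-genotype contig-length SDs use the population formula (divide by
  n), matching how assembler summary tables are produced; the overall
  mean contig length is the contig-count-weighted mean of per-genotype
  means.
* Zero-depth columns, empty variant tables, header-only files, and
  empty candidate sets all produce empty-but-valid outputs, never
  errors; malformed rows fail loudly with line numbers.
* A candidate within one flank of a contig end yields a truncated,
  flagged masking window.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which every stochastic check is statistically
comfortable: the filter oracle uses 10,000 random records; Dice is
verified against all 4,096 length-6 vector pairs; UPGMA against an
exhaustive definitional oracle on 3–5 taxa; the recovery experiment
simulates 50 two-copy families of 600 bp at 50× depth (≈ 600 pseudo-SNP
sites and ≈ 150 planted records), at which scale the conservation stage
removes ≥ 99% of pseudo-SNP sites (the probability that a balanced
binomial at depth ~50 hits 100% is ~2^-50) and every planted fixed SNP
with depth ≥ 5 survives; calibration uses 1,000 markers × 136 lines.

## Known limitations

* The aligner is a test-scale stand-in: all-vs-all alignment is
  quadratic and unsuitable for survey-scale read sets; real deployments
  should feed externally produced variant tables (or SAM-derived
  pileups) into `filter_candidates` directly.
* Indel candidates are filtered out by design, as in the original
  protocol; real low-frequency indel alleles (and 454 homopolymer
  artifacts that mimic them) are discarded rather than adjudicated.
* The conservation rule assumes near-homozygous germplasm; residual
  heterozygosity in an outbreeding species would fail genuine alleles.
* Sharing classification requires identical alternate alleles; a
  tri-allelic site shared across genotypes appears as multiple
  lower-class candidates.
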