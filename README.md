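# polysnp

SNP discovery from transcriptome (EST) contig assemblies in polyploid
species, with the downstream marker genetics needed to validate and
use the resulting assays.

## The problem

In a polyploid such as cultivated oat (*Avena sativa*, AACCDD), de novo
transcriptome assembly frequently collapses homoeologous gene copies
from different subgenomes into a single contig. Every position at which
the collapsed copies differ then looks like a SNP in *every* genotype's
reads — a **pseudo-SNP** that wastes assay development effort and
corrupts genetic maps. `polysnp` implements the filter cascade that
separates true allelic variation from this subgenome noise:

1. **Reference self-screen** — contigs whose own reads re-map with
   indel polymorphism or ambiguous (`N`) calls are removed.
2. **Filter cascade** over candidate records from the other genotypes:
   indel/multi-base/`N` calls out; read depth ≤ 4 out; and decisively,
   any variant carried by **less than 100% of a genotype's reads** at
   its site out. A true allele in inbred germplasm is fixed within the
   genotype; a collapsed homoeolog shows up at the expression share of
   the deviating copy (≈ 50% for a balanced pair), so the conservation
   rule is the polyploidy screen.
3. **Sharing classification** — surviving candidates grouped by
   identical allele and coordinate, classed by how many genotypes share
   them versus the reference assembly.
4. **Assay design prep** — contigs with two candidates < 100 bp apart
   are excluded from the assay set, and each remaining target is
   exported as a dbSNP-style FASTA window with the SNP masked by its
   IUPAC ambiguity code (A/G → R, C/T → Y, ...), annotated with a
   90 ± 30 bp product-size constraint for primer design.

Companion tools score marker segregation in recombinant inbred lines
(segregation ratio and a 1:1 chi-square), code multi-allelic
melt-curve (HRM) calls — SNP alleles, insertions, deletions,
heterozygotes, nulls — into a binary matrix, compute Dice similarity,
and build deterministic UPGMA dendrograms with Newick output. A
synthetic polyploid transcriptome generator with ground-truth labels
(`allelic_snp` / `homoeolog_pseudo_snp` / `error`) makes every stage
testable without any external data.

## Worked example

Simulate a four-genotype survey in which 40% of two-copy gene families
collapse into single reference contigs, then run the pipeline:

```r
library(polysnp)

cfg <- sim_config(n_gene_families = 40, collapse_prob = 0.4,
                  depth_lambda = 12, snp_rate = 0.004,
                  base_error = 0, homopolymer_indel_rate = 0, seed = 20)
sim <- simulate_variant_tables(cfg)
table(sim$truth$label)
#>          allelic_snp homoeolog_pseudo_snp
#>                  132                  335

res <- run_pipeline(pipeline_config(sim$reference, sim$tables, "REF",
                                    out_dir = "demo_out"))
res$report
#> self_indel: 0 (0.0%) removed, 54 remaining
#> self_ambiguous_N: 0 (0.0%) removed, 54 remaining
#> indel_or_ambiguous: 0 (0.0%) removed, 1,157 remaining
#> low_depth: 15 (1.3%) removed, 1,142 remaining
#> not_conserved: 988 (85%) removed, 154 remaining
res$class_counts
#> [1] 115  18   1
```

The 335 planted pseudo-SNP sites generate most of the 1,157 candidate
records (each is seen by all four genotypes at ≈ 50% frequency), and
the conservation stage removes them wholesale — the 85% attrition line
is the polyploidy screen doing its work. The 154 surviving records
collapse into 134 candidate SNPs, of which 115 distinguish a single
genotype from the reference and 1 is shared by all three non-reference
genotypes. `demo_out/` then contains the candidate catalog
(`candidates.tsv`), the attrition report (`attrition.txt`/`.tsv`), a
VCF, and the masked assay targets:

```text
>c0001_281 alleles=C/T pos=51 product=90+/-30
TGACGAAAGCCCGATACCTTTGCTAATATTTTTAACATGTAAGGTTTCACYGACAGTACACTGCAGTCATGTGCGCCAAG
```

Downstream, with an assay panel scored on a diversity panel:

```r
panel <- synthetic_diversity_panel()      # 36 markers x 34 lines
allele_summary(panel)[c("total_alleles", "mean_alleles",
                        "n_snp_alleles", "n_supplementary")]
#> $total_alleles [1] 140   $mean_alleles [1] 3.89
#> $n_snp_alleles [1] 73    $n_supplementary [1] 67

tree <- upgma(dice_similarity(code_binary(panel)))
write_newick(tree, "panel.nwk")
```

A thin CLI wraps the same functions:
`polysnp simulate|run|segregate|diversity|report` (see `exec/polysnp`).

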