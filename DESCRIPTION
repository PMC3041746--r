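Package: polysnp
Title: Polyploid-Aware SNP Discovery and Marker Genetics from
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: SNP discovery for polyploid species from expressed sequence
    tag (EST) contig assemblies, modelled on high-throughput 454
    transcriptome surveys of hexaploid oat. Candidate variants called
    against a reference contig assembly are passed through a filter
    cascade that eliminates pseudo-SNPs caused by collapsed homoeologous
    or paralogous gene copies (indel/multi-base and ambiguous calls,
    insufficient read depth, lack of 100% within-genotype conservation),
    classified by genotype sharing, screened for crowded assay targets,
    and exported as IUPAC-masked primer-design templates. Downstream
    marker genetics include segregation scoring in recombinant inbred
    populations, multi-allelic diversity coding from high-resolution
    melting calls, Dice similarity, and UPGMA dendrograms. A built-in
    synthetic polyploid transcriptome generator provides ground-truthed
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
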