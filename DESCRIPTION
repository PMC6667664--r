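Package: bsaseq
Title: Mapping-by-Sequencing of Dominant Loci in EMS Mutant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bulked-segregant mapping-by-sequencing of a dominant
    locus segregating in an EMS-mutagenized (TILLING) population, as used in
    tetraploid wheat forward screens. Implements the per-site allele-depth
    (AO/DP) ratio and its bulk difference (the Delta statistic) with
    moving-average smoothing and threshold-based enriched-region calling; an
    EMS SNP filter cascade (quality, depth, zygosity, transition spectrum,
    varietal-SNP subtraction, SNP-density masking, gene-proximity extraction
    and codon-level effect classification); flank-based SNP coordinate
    lifting and gene-anchored placement of draft-assembly scaffolds onto a
    reference; recombinant-based interval fine-mapping under a dominant
    single-locus model; and a synthetic data generator that emulates the
    full experiment (EMS mutagenesis, selfing pedigrees, F2 segregation,
    equal-DNA bulks with binomial read sampling, varietal background,
    scaffold fragmentation and flow-sort contamination) with complete truth
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
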