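---
title: "Mapping a dominant locus by sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant locus by sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaseq)
```

# The problem

A forward screen of an EMS-mutagenized (TILLING) tetraploid wheat population
can surface dominant mutations: a single mutant allele suffices for the
phenotype, so the F2 of a mutant x wild-type cross segregates 3:1
mutant:wild type. `bsaseq` implements the computational side of localizing
such a locus by bulked-segregant analysis (BSA) with sequencing, refining the
candidate region with novel SNPs from a flow-sorted chromosome called against
both a reference genome and a cultivar-specific draft assembly, and
fine-mapping with recombinant genotypes.

# The Delta statistic

At every SNP site, each phenotypic bulk yields an alternate-allele
observation count AO and a depth DP; AO/DP estimates the mutant-allele
frequency among the pooled plants. For a fully dominant locus:

* the mutant-phenotype ("yellow") bulk is a 1:2 mixture of homozygous mutant
  and heterozygous plants, so its expected allele fraction at the causal SNP
  is $\tfrac{1}{3} \cdot 1 + \tfrac{2}{3} \cdot \tfrac{1}{2} = \tfrac{2}{3} \approx 0.66$
  (`expected_allele_fraction(1/3, 2/3, 0)`),
* the wild-type ("green") bulk contains only homozygous wild-type plants and
  is expected at 0.

Their difference $\Delta = \mathrm{AO/DP}_{yellow} - \mathrm{AO/DP}_{green}$
therefore approaches 0.66 over the causal locus and 0 at unlinked sites.
The track is smoothed with a trailing moving average of 4 SNPs and regions
are called as maximal runs of at least `min_snps = 3` consecutive SNPs with
smoothed $\Delta \ge 0.5$.

Numerical policies, chosen where the procedure is silent:

* **Zero-depth sites** yield a missing ratio and are *skipped* by the
  smoother rather than imputed; imputing zeros would dilute the peak. A
  record claiming AO > 0 at DP = 0 is still treated as missing (depth is the
  stronger signal that the site is uninformative), while AO > DP at positive
  depth is a data-integrity error.
* **Trailing window**: an even window has no center, so the moving average
  at SNP *i* covers the last four non-missing values at or before *i*, in
  SNP-index order. The alignment is configurable in effect via `window`.
* **Threshold on the smoothed track** (the raw-delta alternative is
  available with `use_smoothed = FALSE`); `min_snps = 3` suppresses
  single-SNP artifacts in place of the original visual curation.
* $\Delta$ is computed per site shared by both bulks; one-sided sites are
  dropped and counted (`merge_bulk_counts()` reports them).

# The SNP filter cascade

Variant records pass, in fixed order: parent-SNP intersection (when a parent
list and a coordinate lifter are supplied), EMS spectrum, quality, varietal
subtraction, density masking, and gene proximity. Each record is attributed
to exactly one outcome, so the `FilterReport` always balances.

* **EMS spectrum**: EMS produces G>A and C>T transitions. Only records with
  *reference* G and alternate A, or reference C and alternate T, are
  EMS-like; the reverse pairs (A>G, T>C) are rejected, reading the spectrum
  relative to the reference the mutant was aligned to.
* **Quality**: QUAL $\ge$ 20 (inclusive), DP > 10 (strict), homozygous calls
  only — boundary conventions follow the printed thresholds exactly.
* **Varietal subtraction** matches on position only, not allele: any
  cultivar polymorphism at a site makes a mutant call there untrustworthy.
* **Density masking** replaces manual curation of repeat-driven call
  pile-ups: 10 kb windows are masked when they hold at least 5 SNPs *and*
  the Poisson upper tail at the expected TILLING density (23/Mb, so
  $\lambda = 0.23$ per window) is below $10^{-4}$. All four parameters are
  arguments. A spurious cluster straddling a window boundary can leave a
  couple of sub-threshold calls unmasked; the truth-table tests therefore
  assert $\ge 99\%$ classification agreement rather than exactness.
* **Gene proximity**: within 1 kb of a gene, with all qualifying genes
  annotated (a SNP between two close gene models counts for both).
* **Effect classes** are strand-aware; "promoter" is defined numerically as
  the 1 kb upstream of the transcription start, mirroring the proximity
  window, since no other definition is given. Coding changes are classified
  by translating the reference and mutated codon with the standard nuclear
  code.

# Coordinate lifting and scaffold anchoring

Parent SNPs recorded on a different assembly are lifted by exact matching of
a 201 bp flank window in both orientations (`lift_by_flank()`): a unique
forward hit lifts in place, a unique reverse-complement hit lifts with
complemented alleles, multiple hits are ambiguous, and flanks truncated
below 20 bp by a contig end are not lifted.

Draft-assembly scaffolds are placed through their genes
(`find_gene_anchors()`): fixed 31 bp exact seeds at up to 8 evenly spaced
positions per orientation nominate candidate offsets, each candidate is
scored by ungapped full-length comparison, and at most one anchor — the
best-scoring — is kept per (gene, scaffold) pair, with thresholds of 200 bp
matched length and 95% identity. Gene-anchored lifting (rather than
whole-scaffold alignment) avoids repeat-driven misplacement at the cost of
an "extrapolated" confidence flag for variants outside the anchored match.
Ungapped extension is sufficient because the simulated divergence model is
substitution-only; with real indel-rich divergence a gapped aligner should
replace this step.

# Fine-mapping

Under full dominance a yellow plant is inconsistent with a marker iff its
call there is WT; a green plant iff its call is HET or MUT; missing calls
are never inconsistent. A marker is excluded from the interval only when at
least two independent plants are inconsistent with it — a single plant,
possibly a genotyping error, never defines a boundary. The rule is applied
per marker (`min_independent` is configurable), and the physical interval
spans the first to the last retained marker.

Disjoint qualifying runs signal a genotyping problem or a second locus and
are an error by default. The pipeline runner instead keeps the largest run
(`multiple_runs = "largest"`) and logs the satellites: with markers at the
density of the simulated SNPs, sampling noise in the inconsistency counts
near the exclusion boundary can detach one or two qualifying markers, and
aborting an otherwise sound run on those satellites would be wrong for an
automated pipeline. Plants inconsistent at a single isolated marker but
consistent at both neighbours are flagged as possible genotyping errors;
they still count toward the rule.

# What the generator simulates

`sim_config()` fixes the study conditions: 23 EMS mutations/Mb sampled
uniformly over G/C bases with the forced G>A / C>T alternate; an M2
heterozygous at every induced locus; two rounds of selfing to the M4;
a cross to wild type whose single F1 is redrawn until it carries the causal
allele (the real F1 was phenotypically mutant; other loci are left
unconditioned); an F2 of 214 plants (the scale of the scored field
populations); fully penetrant dominant phenotyping (penetrance is a dial for
environments where the phenotype vanishes); equal-DNA bulks of 75 yellow and
16 green plants; and site-level sequencing with DP ~ Poisson(depth) and
AO ~ Binomial(DP, f(1-e) + (1-f)e). Flow-sorted chromosome samples emit
target-chromosome records at 80% of the depth and contaminant-chromosome
records at 20%, with QUAL = min(60, 4 AO) as a documented monotone stand-in
for a caller's quality and a zygosity call of "hom" at AO/DP >= 0.8.

Values the experiment does not pin down were chosen once, for realism at
desk scale:

* **Chromosomes: two of 8 Mb** (one carrying the causal locus mid-arm, one
  unlinked). At the default 0.02 Morgans/Mb each spans 0.16 M — the genetic
  scale over which the real Delta signal decays (a ~33 Mb interval on a
  wheat chromosome of roughly 0.003 M/Mb is ~0.1 M). Simulating a 750 Mb
  chromosome would add nothing but runtime: the analysis is local in
  genetic, not physical, distance.
* **Mean depth 200**: the order of magnitude implied by two HiSeq2500 lanes
  over four exome libraries (~30 Gb per bulk on an ~84 Mb capture space).
* **Sequencing error 0.005** per base, a typical post-filter Illumina rate.
* **Varietal SNP density 2500/Mb**, from ~970k homozygous cultivar SNPs over
  the ~380 Mb scanned chromosome arm region.
* **Scaffold mean length 100 kb**, the scale of a short-read draft assembly.
* **Crossovers**: Poisson count at 0.02 M/Mb with uniform positions and no
  interference. Real wheat recombination is strongly distally biased; a
  uniform map is the simplest defensible default and is configurable.

What it deliberately does not model: read-level data (FASTQ/BAM; alignment
and calling are consumed, not simulated), base-quality models, capture
probe bias, and homoeologous cross-mapping beyond optional clusters of
spurious EMS-like calls used to exercise density masking. Tetraploidy is
reduced to a single diploid subgenome for the scanned chromosome, since the
analysis operates per chromosome after alignment. Passing tests on this
generator therefore validate the statistics and bookkeeping of the
analysis, not robustness to alignment artifacts in real polyploid data.

# Problem sizes and tolerances in the test suite

The suite exercises: analytic allele-fraction expectations exactly;
simulated Delta at the causal SNP over 60-100 replicates of an F2 of 10,000
with 500-plant bulks at depth 200 (agreement within Monte-Carlo error of
2/3); 3:1 segregation at an F2 of 100,000; the ~50% transmission loss of
M4-heterozygous mutations over ~10,000 simulated loci (measured away from
the causal chromosome, where F1 conditioning would inflate transmission);
the realized 23/Mb density on a 100 Mb chromosome; ten seeded
simulate-and-scan runs at the default conditions (modal called-region count
of one, causal SNP contained); and oracle-equivalence property suites
(brute-force smoothing and run enumeration on ~1,250 random tracks,
exhaustive fine-mapping rule evaluation on ~300 random matrices, lift
round-trips, cascade conservation, and >= 99% truth-table classification).
Stochastic assertions use 3-sigma bands around the analytic expectation.

# Known limitations

* The smoothed-threshold region caller can split one broad peak when the
  expected Delta hovers near 0.5 across many consecutive SNPs; at the
  default geometry this is rare, but on long chromosomes with dense markers
  the region count is better read as "regions overlapping one locus".
* `lift_by_flank()` is exact-match only: it will not lift across indels or
  high-divergence flanks, and reports such SNPs as not found rather than
  guessing.
* The graphical-genotype wildcard merge is greedy in discovery order; plants
  missing many calls can be absorbed into an earlier class that a different
  order would have split.
* Quality scores in simulated records are a stand-in; filter thresholds on
  real data should be calibrated to the caller that produced them.
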