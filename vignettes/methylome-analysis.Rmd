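---
title: "Models and methods behind bdellometh"
author: "bdellometh authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bdellometh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdellometh)
```

## Scope

bdellometh implements the analysis chain used to characterize
N4-methylcytosine (4mC) and N6-methyladenine (6mA) as feature-targeted DNA
marks in a eukaryotic genome of the kind found in bdelloid rotifers:
single-base modification calling from single-molecule polymerase kinetics,
per-site methylation-fraction estimation, DIP-seq/ChIP-seq coverage
normalization and enrichment peak calling, feature-association statistics,
and sequence-context statistics. A synthetic annotated-genome and
methylome generator makes the whole chain testable against planted ground
truth; the same functions accept externally produced files in the standard
formats (FASTA, GFF3, BED, bedGraph, TSV).

## The synthetic data generator

`sim_config()` fixes the study conditions; `simulate_genome()`,
`plant_methylome()`, `simulate_kinetics()`, `simulate_dipseq()`,
`simulate_chipseq()` and `simulate_rnaseq()` generate data under them.
Identical configurations (including the seed) produce bit-identical
outputs; each stage, and each mark within the methylome stage, draws from
its own seeded stream, so changing one stage's parameters never perturbs
another's draws.

**Genome.** A default 200-kb, four-contig genome with i.i.d. sequence at
32% GC carries non-overlapping gene models (5'UTR, CDS exons, introns,
3'UTR, with promoters defined as the 2 kb upstream of the TSS),
transposable-element (TE) copies from configurable families, and
tandem-repeat (TR) arrays. TE copies carry the 5' portion of a per-family
consensus sequence and are partitioned by the fraction of the consensus
they span: full (>= 0.9), medium (0.5-0.9), short (< 0.5, the published
boundary). A configurable fraction of full/medium copies contains an
internal TE-derived gene, flagged in the annotation; TE-derived genes are
identified by this flag rather than by homology search, which is out of
scope. Feature placement partitions each contig's free space with random
gaps, so any configuration whose features fit is placed without rejection
sampling; oversized configurations raise a sizing error. The desk-scale
genome is deliberately TE-dense (about a quarter of the sequence) so that
every downstream statistic has enough signal at 200 kb; the real genome's
much smaller TE fraction changes the magnitudes of density ratios but not
the directions the tests assert.

**Methylome.** 4mC is planted on cytosines (either strand) of full and
medium TE copies and of TRs, with dinucleotide context weights favouring
CpG and CpA (defaults chosen so that CpG+CpA make up about three quarters
of modified doublets, matching the published composition) and an
exponential positional bias toward TE 5' ends (decay 800 bp over a floor
of 0.4; the 5' enrichment is shown but not parameterized in the source
data, so the scale is a package choice). Only a subset of TE copies
(`copy_prob`) is targeted, mirroring the observation that a subset of
transposons concentrates the mark. 6mA is planted genome-wide at
GA-context adenines with a bonus for AGG/GAA triplets. Methylation is
asymmetric: when both cytosines of one CpG happen to be drawn, the
minus-strand record is dropped, and an explicit complementary-strand
partner (offset +1 within the doublet) is added for a small configured
fraction of sites (default 0.1). True fractions follow a point mass at
1.0 (58% by default) mixed with a Beta for 4mC, and a Beta with mean 0.74
for 6mA — the published fraction structure.

**Kinetics.** Per-pass inter-pulse durations (IPDs) are log-normal with
sigma 0.4; at a site with true fraction f each pass is modified with
probability f, and modified passes have their median IPD multiplied by 3.
The noise law is a package choice (the detection statistic used downstream
only relies on ratios); the multiplier is of the order seen at strong
4mC/6mA kinetic signatures. Pass counts are truncated-normal around the
configured mean (25 per strand) with cv 0.1 — a narrow dispersion chosen
so that a 25x design actually delivers ≥ 20x at nearly all sites. A
matched control sample of unmodified passes is drawn per site; the
analytic unmodified mean is carried as an in-silico control.

**Read sets.** DIP fragments are uniform with lengths 200-400 bp;
antibody capture weight is background + capture_odds x (summed fraction of
matching marks covered), so capture odds grow with the number of methyl
marks on the fragment, a background rate retains unmethylated fragments
(residual IgG binding), and `capture_odds = 0` is the exact null. Reads
are 50-bp 5' prefixes (single-end; paired-end simulation is omitted). ChIP reads (75 bp) mix a uniform
background fraction (default 0.7 — most ChIP material is unenriched) with
signal placed bimodally around the TSS of expressed genes (H3K4me3) or
uniformly over TE bodies and heterochromatic TR arrays plus a 500-bp
spread (H3K9me3/H3K27me3). RNA-seq counts are multinomial with per-gene
rates = log-normal baseline x 0.05 for silent genes x 0.25 for TE genes
carrying 4mC within ±500 bp x 2 for genes with 6mA within ±500 bp; the
source data fix only the directions of these effects, so the effect sizes
are package defaults, all configurable. Reads are emitted as alignment
intervals (BED-like) rather than sequences: alignment is out of scope and
intervals are sufficient for all downstream statistics. Library sizes are
met exactly.

What the generator does *not* emulate: sequencing error and base
qualities, mappability structure, diploid/allelic variation, PCR bias
beyond duplicate draws, local composition biases, and bacterial
contamination. Passing tests therefore demonstrate that the analysis
chain is correct and calibrated under its stated statistical model, not
that it is robust to every artifact of real libraries.

## Modification calling

`compute_ipd_ratio()` is mean(native IPD)/mean(control IPD).
`score_site()` is a Phred-scaled one-sided Welch test on log-IPDs (native
greater than control): score = -10 log10 p, capped, with exact tie
handling at zero variance. This reimplements the modification quality
("mQv") semantics — mQv >= 22 corresponds to p <= 10^-2.2 — since the
vendor's scoring algorithm is not public. `call_modifications()` applies
the published decision rule: sites under 10x coverage are removed; the
mark is assigned from the reference base on the tested strand (C -> 4mC,
A -> 6mA, others discarded); primary calls require 20x coverage and
mQv >= 22. The filter additionally requires an IPD ratio of at least 1.5
for primary calls (and > 1 for retained sites): a per-site p-value
threshold alone admits a 10^-2.2 false-positive rate per null site, which
at genome scale would swamp a desk-scale methylome, whereas genuine
4mC/6mA kinetic signatures sit at ratios well above 2. Both thresholds
(10x and 20x) are exposed because analyses differ in which they need.

`estimate_fraction()` classifies each pass to the nearer log-IPD component
(unmodified vs modified; equal spreads, so the boundary is the component
midpoint) and reports the modified proportion — deterministic,
order-invariant, bounded in [0,1]. An EM-style mixture fit would reduce
the small attenuation bias at high fractions but is left as an extension
point. `classify_fraction()` uses the published level bins: low
[0.1, 0.5), moderate [0.5, 0.8), high [0.8, 1]; values below 0.1 fall
outside the three classes. Note one structural consequence used in the
validation experiments: a site planted exactly at fraction 0.5 sits on a
bin boundary, so an unbiased estimator classifies only about half of such
sites "moderate"; across the planted levels {0.25, 0.5, 0.75, 1.0} the
expected class agreement is about 0.86.

Calls on the two strands of one position are independent records — no
symmetric merging, since the modelled methylation is mostly asymmetric.

## Enrichment tracks and peaks

`bin_coverage()` extends each read to the configured fragment length from
its 5' end (50 bp for DIP, 75 bp for ChIP by default) and counts
overlapping base pairs per 10-bp bin (grid anchored at position 0, last
partial bin kept). `normalize_rpgc()` scales to 1x genome coverage;
`log2_ratio()` forms per-bin log2((IP + 1)/(input + 1)) on the RPGC
scale. `call_peaks()` tests each bin's count against the genome-wide mean
with a one-sided Poisson upper tail — a deliberate "no model, no local
lambda" design — at p < 1e-5, merges significant bins within 300 bp
(about one fragment), drops peaks under 150 bp, and places the summit at
the midpoint of the leftmost maximal bin. No duplicate removal,
mappability correction, or broad-peak mode.

## Association statistics

* `occupancy_profile()` / `metaprofile()`: per-bin item counts around
  anchors (5' end, TSS, TTS, summit) divided by the number of features
  ("IP occupancy"), with strand-flipped axes; metaprofiles rescale
  feature bodies to a fixed number of bins (0-100% length) between
  absolute-bp flanks. `fraction_profile()` averages call fractions per
  bin under a coverage mask.
* `normalized_density()`: (sites in class / number of annotations) /
  genome fraction of the class — the published density measure.
* `window_intersect()`: association within ±500 bp by default; the rule
  is closest-base distance <= window, identical to overlap against
  window-expanded features. Union semantics per item.
* `jaccard_bp()` and `permutation_spatial_test()`: base-pair
  intersection-over-union after self-merge, or mean nearest distance,
  with a null built by relocating query intervals uniformly within their
  contigs (lengths and contig assignment preserved) and the add-one
  p-value floor 1/(n_perm+1). The permutation loop uses event-sweep
  internals that are property-tested to agree exactly with the reference
  implementations.
* `classify_te_integrity()` / `density_by_integrity()`: the short class
  follows the published "< half of consensus" rule; the full/medium
  boundary at 0.9 is a package decision (configurable in the generator).
* `colocalization_fractions()`, `summit_signal_profile()`: peak-class
  overlap percentages (combined classes use unions) and mean log2-ratio
  tracks around DIP summits.
* `strand_symmetry()`: complementary calls pair at offset +1 within the
  doublet (CpG-style for 4mC, ApT-style for 6mA) or at identical
  coordinates otherwise; reports the fraction of modified positions with
  both strands called.
* `cpg_obs_exp()`: (N_CpG x L)/(N_C x N_G) per window — the standard
  formula, since only the ratio is named in the source; CG cannot overlap
  itself, so naive counting equals a non-overlapping scan. The i.i.d.
  generator sits near 1, the signature of a genome without historical
  5mC deamination.
* `rpkm()` and `expression_group_tests()`: RPKM per its definition;
  two-group mark contrasts use a two-tailed Welch t-test on
  log2(RPKM + 0.1) (the pseudocount guards zero counts), multi-level
  histone-class groupings use one-way ANOVA with Tukey's post hoc.
  Tukey handles that family; the two planned t-tests are reported
  unadjusted. Groups under 2 members are skipped with a flag.

## Sequence-context statistics

`extract_context()` returns ±flank windows read on the modified strand
(reverse-complemented for minus-strand sites), dropping and counting
edge-truncated windows and centre-base mismatches.
`doublet_triplet_stats()` tabulates the (centre, centre+1) doublet — the
nucleotide adjacent to the methylated base — and both triplet framings.
`kmer_enrichment()` replaces position-specific motif discovery with an
exhaustive, deterministic test: for every k-mer (k = 2-6) observed in
either set, a one-sided Fisher's exact test on window
presence/absence, foreground vs a 5x-larger background of random
same-centre-base positions, with Benjamini-Hochberg adjustment across all
tested k-mers. Presence/absence over a window dilutes a centre-doublet
signal as windows grow, so ±5 bp (one of the standard window choices) is
used where the centre context is the question.

## Validation experiments and problem sizes

The `benchmark_*` functions are the package's validation experiments,
shared by the test suite and by `scripts/acceptance.R`; the sizes below
are the package's chosen study conditions.

* Null calibration: 12,000 unmodified sites; the mQv >= 22 rate must stay
  within 10^-2.2 + 3 binomial SE (the margin-free Welch score sits at the
  level; the ratio floor then removes most of those false calls).
* Caller recovery: the default 200-kb genome with all fractions planted
  at 1.0, multiplier 3, sigma 0.4, 25x; recall >= 0.9 and
  precision >= 0.95 against truth.
* Fraction recovery: 2,000 sites per level {0.25, 0.5, 0.75, 1.0} at
  50x; MAE <= 0.1 per level and class agreement >= 0.85 (see the
  boundary note above).
* Peak recovery: 60 compact (250-bp) fully methylated clusters on 300 kb,
  10x capture, 500k reads; cluster recall, summit-to-centre distance,
  and a matched no-enrichment null for the false-positive bin count.
* Interval oracles: binned coverage, Jaccard, windowed intersection and
  occupancy profiles are compared exactly against brute-force per-bp /
  all-pairs implementations on 100 random instances.
* Spatial correlation: planted 4mC vs its TE targets (999 permutations),
  and 50 uniform-query runs (199 permutations) for the level.
* Directions: TE density above gene density; full > medium > short ~ 0
  integrity stratification; positive H3K9me3/H3K27me3 and near-zero
  H3K4me3 log2-ratios at 4mC DIP summits; lower log2 RPKM for 4mC-marked
  TE genes and higher for 6mA-marked genes (a ~2.2-Mb genome with ~1180
  gene models keeps both contrast groups above 200 genes); CG/CA as top
  doublets with CG significantly enriched.
* Determinism: the full pipeline, run twice with one seed on a compact
  configuration, must produce byte-identical artifacts and reports.

## Known limitations

The caller assumes log-normal pass kinetics with a site-independent
baseline; real polymerase kinetics have sequence-context-dependent
baselines that the in-silico control of the vendor pipeline models
explicitly. The fraction estimator is mildly biased toward the centre at
the extremes (about -0.08 at fraction 1.0 under default noise). The peak
caller has no local background, by design, and will over-call in genomes
with strong large-scale coverage trends. Interval statistics are exact
but quadratic oracles bound the tested instance sizes, not the
implementations. The generator's i.i.d. sequence lacks CpG-island-like
structure, so observed/expected CpG is a calibration check here, not a
discovery tool.
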