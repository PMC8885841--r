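# bdellometh

Analysis of N4-methylcytosine (4mC) and N6-methyladenine (6mA) DNA
methylomes of the kind found in bdelloid rotifers — genomes where a
horizontally acquired bacterial methyltransferase deposits 4mC at active
transposable elements (TEs) and certain tandem repeats (TRs), in
partnership with repressive chromatin. The package is aimed at
researchers who need a tested, reproducible implementation of the full
analysis chain for such atypical methylomes, from raw per-site polymerase
kinetics to feature-association statistics, together with a synthetic
genome/methylome generator that makes every stage verifiable against
planted ground truth.

## What it computes

* **Kinetic modification calling.** Single-molecule sequencing detects
  modified bases through polymerase kinetics, quantified as the
  inter-pulse duration (IPD) ratio, mean(native IPD)/mean(control IPD).
  Sites are scored with a Phred-scaled one-sided Welch test on log-IPDs
  (mQv = -10 log10 p); the published filters are applied: sites < 10x
  coverage removed, primary calls at >= 20x coverage and mQv >= 22, mark
  assigned by the reference base on the tested strand (C -> 4mC,
  A -> 6mA). Per-site methylation fraction — the methylated proportion of
  passes, 1 meaning full methylation — is estimated by nearest-component
  classification of each pass, and classified into the standard bins:
  low [0.1, 0.5), moderate [0.5, 0.8), high [0.8, 1].
* **Enrichment analysis.** Read extension and 10-bp binned coverage, RPGC
  (1x genome) normalization, log2(IP/input) tracks, and a global-Poisson
  peak caller (no local lambda) at p < 1e-5 with summit calling.
* **Feature association.** Occupancy profiles and length-normalized
  metaprofiles, normalized densities ((sites/annotations)/genome
  fraction), ±500-bp windowed intersections, base-pair Jaccard spatial
  correlation with permutation nulls, TE-integrity stratification
  (full/medium/short), chromatin co-localization, strand symmetry, CpG
  observed/expected, and RPKM expression grouping with t-tests/ANOVA.
* **Sequence context.** Strand-aware context windows, doublet/triplet
  composition, and exhaustive k-mer enrichment by one-sided Fisher's
  exact test with Benjamini-Hochberg correction.
* **Synthetic data.** `sim_config()` + the `simulate_*()` functions
  generate an annotated genome, a planted methylome (asymmetric 4mC at
  CpG/CpA in TEs/TRs with a point mass of fully methylated sites; 6mA at
  GA contexts with a Beta fraction distribution), per-site kinetics, and
  DIP-seq/ChIP-seq/RNA-seq read sets, deterministically from a seed.

## Worked example

```r
library(bdellometh)

cfg    <- sim_config(seed = 42)          # 200-kb annotated genome
genome <- simulate_genome(cfg)
truth  <- plant_methylome(genome, cfg)   # 1707 4mC, 424 6mA planted
kin    <- simulate_kinetics(genome, truth, cfg)

calls   <- call_modifications(kin, genome, call_filter())
primary <- subset(calls, primary)
print(calls)
#> mod_calls: 101082 retained sites ( 2015 primary; 32797 4mC / 68285 6mA )

gl    <- sum(genome$contig_len)
genes <- subset(genome$genes, !te_gene)
rbind(
  normalized_density(primary, genes, interval_bp(genes) / gl, "genes"),
  normalized_density(primary, genome$te_copies,
                     interval_bp(genome$te_copies) / gl, "TE"),
  normalized_density(primary, genome$tandem_repeats,
                     interval_bp(genome$tandem_repeats) / gl, "TR"))
#>   class n_sites n_annotations genome_fraction normalized_density defined
#> 1 genes     184            60          0.4081               7.51    TRUE
#> 2    TE    1384            46          0.2506             120.04    TRUE
#> 3    TR     321             6          0.0145            3689.66    TRUE

strand_symmetry(primary, genome)$symmetric_fraction
#> [1] 0.025
```

Reading the output: of the 2015 primary calls, recall against the planted
truth is 0.92 and precision 0.97 at the default filters; the normalized
density ranks TR > TE > genes — tandem repeats carry an extra-high
modification density and TEs far exceed genic background, the hallmark
feature-targeting of this methylation system — and only ~2.5% of modified
positions are methylated on both strands, i.e. the marks are almost
entirely asymmetric.

`run_pipeline(cfg, "outdir")` chains all stages (simulate, call, peaks,
associate, motifs), writes FASTA/GFF3/BED/bedGraph/TSV artifacts plus a
JSON run report with checksums, and is byte-deterministic for a fixed
seed. `validate_inputs()` checks externally supplied files before
analysis.

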