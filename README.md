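# axiomsnp

Design, quality control, and population genetics for Axiom-style fixed SNP
genotyping arrays — aimed at species, such as conifers, whose large and
repetitive genomes make array design and genotype clustering hard, and whose
raw array intensities are often proprietary.

The package re-implements, as an open and testable pipeline, the workflow of
a large transcriptome-based conifer SNP array project:

1. **Array design** — filter candidate SNPs carried on 71-nt probe contexts
   (the target SNP at position 36, two 35-nt flanks), drop probesets whose
   flank carries a high-confidence non-target variant or whose vendor
   recommendation is unusable, remove A/T and C/G SNPs (they need two
   probesets each) unless already validated on an Infinium platform, rank
   transcripts (reference-hit category, assembly confidence, SNP count) and
   probesets within transcripts (Infinium success, flanking rank,
   perfect-allele count, pConvert, target-SNP evidence), then select
   probesets by a deterministic coverage-maximizing round robin.
2. **Genotype calling** — a transparent stand-in for the proprietary Axiom
   caller: per probeset, 1–3-component Gaussian mixtures on the contrast
   coordinate `log2(A/B)` with BIC model selection, genotype labels from
   component means, and per-call confidence `1 − max posterior` (lower is
   better, so the conventional 0.15 / 0.10 thresholds apply verbatim).
3. **QC and classification** — Dish-QC / sample-call-rate / plate filters;
   the seven-category SNP classification (*PolyHighResolution*,
   *NoMinorHom*, *MonoHighResolution*, *CallRateBelowThreshold*, *OTV*,
   *Other*, *Rescued*); the two-phase rescue protocols that readmit
   *Other* / *CallRateBelowThreshold* SNPs at a lowered call-rate cutoff
   (90/80/70/60%) under a tightened confidence threshold; and
   duplicate-sample genotype/allele accuracy.
4. **Population genetics** — per SNP and population: call rate, MAF,
   HET_obs = n_AB / n, HET_exp = 2pq, PIC = 1 − (p² + q²) − 2p²q²
   (biallelic Botstein form), and a Hardy-Weinberg χ² goodness-of-fit test
   (df = 1, no continuity correction); cross-population medians over
   polymorphic SNPs in HWE (P ≥ 0.01) and MAF histograms.
5. **Success prediction** — feature engineering from standard 12-column
   BLAST tabular output (best/second-best percent identity with an
   80-floor, binned hit counts at PID > 90), likelihood-ratio χ² (G²),
   Welch *t* and Monte-Carlo Wilcoxon tests, stepwise logistic regression
   with cross-validated ROC/AUC, and the detection sample-size calculator:
   the smallest *n* with (1 − MAF)^n ≤ 1 − power.
6. **Synthetic data** — a seeded generator emulating the statistical
   structure of a two-population array experiment (HWE genotypes with a
   configurable MAF spectrum, latent SNP quality classes, log-normal
   two-channel intensities, plate/Dish-QC structure, duplicate trees), so
   every stage runs and is testable without the undeposited real data.

## Worked example

```r
library(axiomsnp)

cfg   <- sim_config(n_snps = 400, n_samples_per_pop = 150, n_pops = 2, seed = 42)
truth <- gen_genotype_truth(cfg)
ints  <- gen_intensity_data(truth, cfg)
calls <- call_genotypes(transform_intensities(ints$signal_a, ints$signal_b))
prot  <- run_protocol(calls, truth$samples, "rescue70")
prot$summaries$C1$counts
#>     PolyHighResolution             NoMinorHom     MonoHighResolution
#>                    110                     62                     65
#> CallRateBelowThreshold                    OTV                  Other
#>                      0                      2                    132
#>                Rescued
#>                     29
```

Population C1 classifies 110 of 400 probesets as *PolyHighResolution*
(three clean genotype clusters, call rate ≥ 97%) and rescues another 29
from Phase 1's *Other*/*CallRateBelowThreshold* at the 70% cutoff, so
139 SNPs count as successful (reliably genotyped **and** polymorphic).
Across both populations:

```r
acc <- duplicate_accuracy(apply_confidence_threshold(calls, 0.15), truth$samples)
sprintf("genotype accuracy %.3f, allele accuracy %.3f, missing %.3f",
        acc$genotype_accuracy, acc$allele_accuracy, acc$missing_fraction)
#> "genotype accuracy 0.998, allele accuracy 0.999, missing 0.016"
```

Duplicate samples of the same tree agree at 99.8% of compared genotype
pairs (allele-wise 99.9%); allele accuracy can never fall below genotype
accuracy. Per-SNP statistics for the successful SNPs of C1:

```r
passing <- prot$qc$C1$passing
stats <- call_matrix_stats(apply_confidence_threshold(calls, 0.15)[passing, ], "C1")
population_summary(stats[prot$per_population$C1$successful], hwe_alpha = 0.01)$averaged
#>    cr       maf   het_obs   het_exp       pic
#>     1 0.2570423 0.3815789 0.3819431 0.3090028
```

Medians are taken over polymorphic SNPs in HWE (P ≥ 0.01), the filter used
for array summaries. And the planning calculator:

```r
detection_sample_size(maf = 0.05, success_rate = 0.95)  # 59 trees
detection_sample_size(maf = 0.05, success_rate = 0.99)  # 90 trees
```

## Command line

```sh
Rscript -e 'axiomsnp::cli_main()' run-all --out out/ --seed 3 \
    --n-snps 400 --n-samples 150 --protocol rescue70
```

Subcommands `simulate`, `design`, `call`, `qc`, `popgen`, `predict`,
`export` run the stages separately on TSV/FASTA/VCF files; every run
writes a `manifest.json` with inputs, thresholds, and seed.

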