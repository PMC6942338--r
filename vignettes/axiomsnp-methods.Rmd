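---
title: "Methods: models, thresholds, and design choices in axiomsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds, and design choices in axiomsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axiomsnp)
```

`axiomsnp` packages the analysis chain behind a transcriptome-based fixed
SNP genotyping array: probe design on 71-nt SNP contexts, a mixture-model
genotype caller, multi-protocol quality control with SNP rescue,
per-population SNP statistics, and logistic prediction of assay success.
This vignette explains each model, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the decisions taken where the design was genuinely open.

## 1. Array design

Candidates carry a 71-nt context with the target SNP at 1-based position
36, i.e. two 35-nt flanks. A probe direction is *buildable* when its flank
(positions 1–35 forward, 37–71 reverse) contains no high-confidence
non-target variant; lower-confidence variants only demote the probeset's
*flanking rank* (1 = no variants at any tier, 2 = only low-tier, 3 =
low/medium but no high). Filtering removes probesets with no reference
match, unbuildable flanks, or a `not_recommended`/`not_possible` vendor
recommendation; A/T and C/G SNPs are removed because they occupy two
probesets. Infinium-validated SNPs are exempt from the recommendation and
A/T–C/G rules (prior empirical success outweighs predicted failure) as
long as one buildable probeset remains.

Transcripts are ranked on three keys — reference-hit category (exactly one
65-nt hit best, then more than one, then zero), discovery confidence score
(ascending; absent for the secondary discovery set, which is compared on
the other keys), SNP count (descending) — and probesets within a
transcript on five (Infinium success, flanking rank, perfect-allele count
in order 1, 2, 0, pConvert descending, target-SNP evidence). **Design
choice:** the combined rank is realized as plain lexicographic ordering of
these keys with an id tiebreak. A numeric combined score could weight the
keys differently, but no weighting is defined anywhere in the workflow we
emulate, and a lexicographic order is the minimal total order consistent
with "ranked using these variables". Selection is a round robin over
ranked transcripts — each pass takes the best unselected probeset of an
uncovered SNP per transcript, so coverage strictly dominates depth — and
A/T–C/G probesets cost two capacity units. **Open point:** the trigger for
adding a second, opposite-strand probeset of an already covered SNP is not
quantified in the source workflow; here any later pass may add it once the
transcript's SNPs are all covered, and the behaviour can be disabled
(`second_probeset_per_snp = FALSE`).

## 2. Genotype calling

The vendor's caller is proprietary, so calling is a documented stand-in,
not a re-implementation. Channels are transformed to Axiom-convention
coordinates: contrast = log2(A/B), size = (log2 A + log2 B)/2;
non-positive signals become missing rather than errors (zeroed signals are
how corrupted assays present). Per probeset we fit 1-, 2-, and
3-component Gaussian mixtures to contrast by EM and select the component
count by BIC. Numerical choices:

* **Initialization** is deterministic — component means equally spaced
  over the observed range. No random restarts, so a fixed input always
  gives the same fit, and channel swap mirrors the fit exactly. Quantile
  initialization was rejected: for a low-MAF SNP with 95% of samples in
  one homozygote cluster all quantiles fall in that cluster and EM locks
  onto a spurious split.
* **Variance ridge:** component variances are floored at `var_floor`
  (1e-4) so a single-sample cluster cannot collapse the likelihood.
* **Labels** come from component means: above `het_band` (+0.75, half the
  nominal homozygote contrast of 1.5) = AA, below −0.75 = BB, else AB.
* **Confidence** is 1 − max posterior, lower = better, so the
  conventional thresholds 0.15 (default) and 0.10 (rescue phase 2) apply
  on their original scale. Calls above threshold become NoCall.
* **Resolution:** a probeset is resolved when every component SD is at
  most `max_cluster_sd` (0.5 log2 units), no two components share a label,
  and multi-component fits reach a minimum pairwise separation
  |Δμ|/pooled SD of `separation_min` (3.6). The separation of a
  1-component fit is reported as 0 — a fused blob separates nothing — and
  such fits are judged on the SD cap alone, which keeps tight monomorphic
  clusters resolved. These geometry thresholds have no published
  reference values (the vendor's cluster-QC metrics are different and
  undocumented); they are stated defaults, deliberately not tuned to
  claim equivalence with vendor output.

Off-target variants (OTV) are probe/target mismatches that produce an
extra low-intensity cluster. Detection is size-based: a sample is flagged
when its size falls more than `size_offset` (2 log2 units) below the
per-probeset median; a probeset is classified OTV when the flagged
fraction reaches `otv_min_fraction` (0.1).

## 3. QC protocols, classification, rescue

Thresholds follow the standard diploid defaults: Dish-QC ≥ 0.82, sample
call rate ≥ 97%, plate percent-passing ≥ 95%, plate call rate ≥ 98.5%
(average over *passing* samples only, per the metric's definition), SNP
call-rate cutoff 97%, confidence 0.15. The `modified` protocol relaxes
sample/plate gates (0.50 / 80% / 80% / 90%) with a 95% SNP cutoff and a
phase-2 step at call rate 80% / confidence 0.10.

Classification order per probeset: OTV, else Other (unresolved geometry),
else CallRateBelowThreshold, else MonoHighResolution (one called class),
else NoMinorHom (minor homozygote never called), else PolyHighResolution.
Rescue (protocols `rescue90`…`rescue60`) re-thresholds only the
*Other*/*CallRateBelowThreshold* probesets at confidence 0.10 — stricter,
so the call rate can only drop while accuracy improves — and reclassifies
as *Rescued* those whose recomputed call rate reaches the lowered cutoff
**and** that remain polymorphic. **Design choice:** whether a rescue
candidate that is monomorphic after re-thresholding may be labelled
*Rescued* is ambiguous in the source workflow; since "successful" is
defined as polymorphic and reliably called, such SNPs are excluded by
default and can be recorded separately (`allow_monomorphic_rescue`), where
they are never counted successful. Converted = Poly + NoMinorHom + Mono +
Rescued; successful = Poly + Rescued. With two populations the package
reports per-population counts, their mean, and the "sum" (SNPs successful
in at least one population — each population has successful SNPs
monomorphic in the other). Call rates are fractions internally and
percentages at one decimal in reports.

Duplicate-sample accuracy compares all within-tree sample pairs at
probesets where both calls are present: genotype accuracy is the
concordant fraction; allele accuracy counts shared alleles out of two
(identical = 2, homozygote vs heterozygote = 1, opposite homozygotes = 0),
so allele accuracy ≥ genotype accuracy always; pairs with a NoCall count
toward the missing fraction.

## 4. Population statistics

With p estimated from called genotypes, MAF = min(p, 1−p), HET_obs =
n_AB/n, HET_exp = 2pq, PIC = 1 − (p² + q²) − 2p²q². **Design choice:**
HET_exp uses the plain 2pq product estimator; the source workflow names
the statistic but not the estimator, and the small-sample (2n/(2n−1))
correction is a negligible 0.1% at the sample sizes involved. The HWE test
is a Pearson χ² of observed versus np², 2npq, nq² with df = 1 and no
continuity correction (the workflow specifies a chi-square goodness-of-fit
test; an exact test would change tail behaviour at low MAF and is out of
scope). Monomorphic SNPs return χ² = 0, p = 1 by convention and are
excluded from summaries, which consider polymorphic SNPs in HWE
(p ≥ 0.01). Summaries report per-population medians of CR, MAF, HET_obs,
HET_exp, PIC and their arithmetic mean across populations, plus MAF
histograms in 0.05 bins for all polymorphic versus HWE-filtered SNPs.

## 5. Success prediction

BLAST feature engineering follows the two reference passes of the
workflow: the design-time pass counts hits of ≥ 65 aligned nt per 71-mer
and perfect alleles (PID 100 over 71 nt, per allele sequence); the
post-hoc pass extracts best/second-best percent identity per query with an
80 floor for missing hits, the three-way category of the top two hits, and
per-target hit counts at PID > 90 binned 1 / >1 / 0. Univariate tests are
the likelihood-ratio χ² (G² = 2 Σ O ln(O/E), zero cells contributing 0),
Welch's t with Satterthwaite df, and a Wilcoxon rank-sum with Monte-Carlo
p = (exceedances + 1)/(permutations + 1), default 10,000 seeded
permutations.

Stepwise logistic regression uses forward entry by best likelihood-ratio
χ² with backward removal. **Design choices:** entry/stay levels are not
stated in the source workflow; 0.05/0.05 — the SAS stepwise convention —
are the defaults and both are exposed. The score test SAS uses at entry is
replaced by the likelihood-ratio test (asymptotically equivalent,
one-deviance-difference simple, and the entry χ² it reports is the
model-improvement statistic of interest). Cross-validation is 10-fold,
stratified, seeded — the fold count is likewise unstated. Out-of-fold
probabilities are pooled into one ROC (trapezoidal AUC); quasi-separation
is flagged when any coefficient exceeds 15.

The detection sample-size calculator returns the smallest n with
(1 − MAF)^n ≤ 1 − power. This one-informative-allele-per-tree geometric
model is the only simple model that reproduces both published planning
values (59 trees at 95% power and 90 at 99%, MAF 0.05); its biological
reading — each tree contributes one informative allele draw — is stated
here because the source workflow never articulates it.

## 6. What the synthetic generator emulates — and what it does not

The generator fabricates the full experiment with one master seed and one
RNG stream per entity class (SNPs, samples, genotypes, intensities,
features), so enlarging the SNP set does not perturb sample draws and a
fixed seed gives bit-identical output (intensities are deterministic
doubles; any cross-platform differences would be at most one ulp of
`rnorm`).

Latent SNP classes default to `poly_resolved` 0.31, `unresolvable` 0.31,
`monomorphic` 0.16, `no_minor_hom` 0.13, `low_cr` 0.08, `otv` 0.01 —
loosely calibrated to the default-protocol category percentages of a
large conifer array (Poly 31, Other 30, Mono 16, NoMinorHom 13,
CallRateBelowThreshold 8, OTV 1); they are proportions of *latent* class
membership, so realized categories shift (a low-MAF `poly_resolved` SNP
legitimately classifies NoMinorHom when no minor homozygote is sampled).
True MAF is uniform on [0.01, 0.5] — array SNPs are pre-selected for
common variation, and the published MAF spectrum is nearly flat.
Genotypes follow HWE (conditioned on "no minor homozygote" for that
class; all major-homozygote for `monomorphic`), and duplicated trees copy
genotypes exactly, so duplicate discordance arises only in the calling
noise. Dish-QC is Beta(28, 2) (≈ 2% below the 0.82 gate); plates fill
sequentially at 96.

Intensities are log-normal with genotype contrast means +1.5/0/−1.5 and
SD 0.15 for well-behaved SNPs, size ~ N(10, 0.3). `low_cr` SNPs zero a
per-SNP fraction of signal pairs drawn as 0.03 + 0.37·Beta(1, 5) — most
call rates just under 97% with a thin tail toward 60%, the shape that
makes the graded rescue cutoffs informative. `otv` SNPs move 30% of
samples 3 log2 units down in size. **The key modelling decision:**
`unresolvable` SNPs compress the genotype means to ±0.375 and inflate the
SD to 0.75, fusing the clusters into one broad blob. A seemingly more
literal alternative — clusters separated just below the resolution
threshold — was rejected because a symmetric-Gaussian SNP sitting just
under separation 3.6 unavoidably posts ~10–25% ambiguous (NoCall) calls,
and 31% such SNPs would push every sample below the 97% sample-call-rate
gate and every plate below 98.5%, a world in which the default protocol
ends with zero passing samples. Real arrays show the opposite: `Other`
SNPs fail on cluster *geometry* while their calls remain confident. The
blob model reproduces exactly that (confident calls, unresolved geometry)
at the cost that blob SNPs are usually monomorphic after calling and so
are rarely rescued; rescued SNPs therefore come mostly from
`CallRateBelowThreshold`, whereas the published workflow also rescued from
`Other`. The rescue logic itself is category-agnostic and is unit-tested
on hand-built `Other` probesets.

Not emulated: pedigree/kinship structure (duplicates are the only
relatedness; the published related trees enter only performance
counting), batch/plate effects on intensity, the vendor's Dish-QC
computation, pConvert/Repetitive/target-SNP-probability computation (all
consumed as inputs and fabricated from simple distributions), and any
linkage between SNPs. A green test on synthetic data therefore
establishes that the pipeline's logic is correct under its stated
statistical model — not that the caller matches vendor output on real
intensities, nor that published headline counts (which depend on
undeposited raw data) are reproduced.

## 7. Known limitations

* The caller is a 1-D mixture on contrast; it ignores size except for OTV
  detection, has no SNP-specific priors, and its resolution thresholds
  are stand-ins.
* Stepwise selection inherits the usual caveats (greedy, p-values
  post-selection are optimistic); the cross-validated ROC mitigates the
  optimism for prediction but not for inference on entry statistics.
* The Phase-2 rescue only re-thresholds confidences; it does not re-fit
  clusters, so a call can be removed but never changed.
* VCF export places unmapped SNPs on their transcript at position 36; two
  SNPs of one transcript share coordinates, which consumers must treat as
  nominal.
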