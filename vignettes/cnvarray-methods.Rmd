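---
title: "Copy-number discovery from two-channel SNP arrays: models and methods"
author: "cnvarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number discovery from two-channel SNP arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Some genotyping platforms ship only raw per-probe two-channel intensities
(X for the A allele, Y for the B allele) and genotype calls — no
vendor-normalized copy-number signals.  Calling copy-number variants (CNVs)
on such data, and testing them for case-control association, requires the
whole chain to be rebuilt: a normalization that turns raw X/Y into the two
standard summaries — B allele frequency (BAF, the allelic ratio) and log R
ratio (LRR, total intensity relative to a diploid expectation) — a
segmentation model over ordered probes, sample-level quality control, and
an association procedure robust to the very large multiplicity of CNV
calls.  `cnvarray` implements that chain, together with a synthetic cohort
generator that makes every stage testable without access to controlled
genotype data.

A particular difficulty motivates several design choices: when the assay
chemistry runs PCR to saturation, total-intensity differences between
copy-number states are compressed, so the intensity channel alone is a weak
copy-number signal.  The allelic channel is not: a duplicated heterozygous
site carries three alleles (AAB or ABB), and its BAF falls in bands near
1/3 and 2/3 instead of 1/2.  The emission model and the evidence-review
statistics therefore lean on genotype-band structure as much as on
intensity.

# Signal model

**Polar transform.**  Raw intensities are floored at 1 and log10-reduced;
we define `theta = (2/pi) * atan2(log10 Y, log10 X)` in [0, 1] and
`R = log10 X + log10 Y`.  The platform never publishes a polar convention,
so these are declared conventions of the package, validated by the
qualitative BAF/LRR signatures they reproduce (duplication bands at
1/3 and 2/3, LRR elevation in gains).  `R` is the *sum* of log
intensities — an "A + B" total on the log scale — not a Euclidean norm.

**Canonical clusters.**  Per SNP, the AA/AB/BB cluster centers in
(theta, R) are 10%-trimmed means over samples whose external (or fallback)
genotype call has confidence at or below 0.1; trimming resists outliers,
including undetected CNV carriers sitting inside a diploid cluster.  A
missing heterozygote cluster is imputed at the homozygote midpoint with
`R = max(R_AA, R_BB)`; a missing homozygote is imputed by reflecting the
observed spacing (flagged, and dropped if the reflection leaves [0, 1]).
SNPs with fewer than two observed clusters, or disordered centers, are
unusable and masked throughout.

**BAF and LRR.**  BAF is the piecewise-linear interpolation of theta
through the three centers (0, 0.5, 1 at the AA, AB, BB centers, clamped
outside).  The expected intensity at an observed theta interpolates the
(theta, R) anchor points; `LRR = log2(R_obs / R_exp)` (base 2, the
platform convention for "log R ratio").  A contrasting quantile-normalized
`Log2Ratio` — per-sample totals quantile-normalized to the common profile,
then log2 against the per-SNP median — is provided for comparison; it
needs no genotype clusters but carries no allelic information.

**Population B allele frequency (PFB)** is the per-SNP mean BAF over
QC-passing samples, clipped to [0.01, 0.99]; it weights the genotype-band
mixtures in the HMM emissions.

**Fallback genotype caller.**  When no external calls exist, a per-SNP
three-component 1-D Gaussian mixture on theta is fit by EM (means started
at 0.15/0.5/0.85 and kept ordered, 200-iteration cap); the call is the
maximum-posterior component, confidence `1 - max posterior`, no-call above
0.1.

# The copy-number HMM

Six states: CN0, CN1, CN2, CN2-LOH, CN3, CN4.  The copy-neutral
loss-of-heterozygosity state exists so that long runs of homozygosity —
common by chance and capable of masking duplication bands — are explained
without a false deletion call.

**Emissions** treat LRR and BAF as conditionally independent given the
state.  The LRR term is Gaussian with per-state mean and SD; defaults
`(-3.5, -0.66, 0, 0, 0.40, 0.68)` follow the compressed-intensity
expectation `gamma * log2((cn + 0.1) / 2.1)` at saturation exponent
`gamma = 0.7` with a 5% background term (against the uncompressed
brute-force expectation `log2(cn/2)` these are deflated by roughly the
exponent).  The BAF term is a genotype-band mixture weighted by PFB p:
diploid bands {0, 1/2, 1} with Hardy-Weinberg weights; CN1 and CN2-LOH
bands {0, 1} with weights {1-p, p}; CN3 bands {0, 1/3, 2/3, 1} with
binomial(3, p) weights; CN4 bands {0, 1/4, 1/2, 3/4, 1} with
binomial(4, p) weights; CN0 uniform.  Boundary bands at 0 and 1 are
half-Gaussians (carrying the reflected mass), interior bands Gaussians
with SD 0.04.  Every emission is mixed with a 1% uniform outlier
component; without it a single-probe intensity spike of a few SD would
out-vote the transition penalty and produce one-probe calls.  Probes with
a masked BAF contribute LRR-only evidence; fully masked probes are
uninformative.

**Transitions** depend on inter-probe distance d:
`f(d) = 1 - 0.9 * exp(-d / D)` with `D = 100 kb` scales all off-diagonal
entries of a base matrix, the diagonal restoring row sums.  The two limits
are interpretable: adjacent probes (small d) strongly favour extending the
current state, and the base matrix is recovered as d grows.  Default base
rates: leaving CN2 at ~3x10^-4 per (distant) probe, returning from any CNV
state at 10^-2.

**Decoding and confidence.**  Per sample and chromosome, the Viterbi path
(C++ inner loop) is cut into maximal non-diploid runs; each becomes a call
with 1-based inclusive boundaries at the run's first/last probe.  The
confidence is the log10 likelihood ratio of the decoded path against the
same path with the segment forced diploid — the concept behind the usual
segment confidence score, without claiming bit-compatibility with any
particular legacy implementation.

**Training.**  Baum-Welch in three successive batches of 30 samples —
first the lowest-noise samples (smallest LRR SD), then random draws
without replacement — each warm-starting from the previous estimate.
Re-estimated: LRR SDs (all states), LRR means of non-diploid states
(diploid means stay pinned at 0; ordering enforced by projection), and the
base transition matrix.  Because transitions are distance-modulated, the
exact M-step has no closed form; expected transition counts are
inverse-weighted by f(d) to recover base rates, an approximation monitored
by the batch likelihood (a decrease beyond tolerance aborts).  The BAF
band SD is deliberately not re-estimated: with few CNV probes per batch it
is poorly identified and drifting it degrades the band structure the
caller depends on.

# Quality control

All thresholds are strict (boundary values fail), matching the
inequality conventions of the filters: call rate > 0.98; LRR noise
< 0.25; GC wave factor inside (-0.02, 0.02) after correction; CNV count
< 100; duplicates (PI_HAT >= 0.9) reduced to the better-called member;
ancestry outliers beyond 6 SD on any of the top 10 genotype principal
components removed over up to 5 re-computation rounds (standard
Eigenstrat-style defaults).

The LRR noise statistic is the derivative log-ratio spread,
`sd(diff(LRR)) / sqrt(2)` — equal in expectation to the plain SD under
serially independent noise, but robust to genuine copy-number segments.
This matters only because the simulated region is short: a 646 kb
duplication is ~21% of a 3 Mb fixture and would push a true carrier's
plain SD over threshold, whereas on a whole genome it is negligible.  The
statistic, not the threshold, absorbs that scale artifact.

The GC wave factor is `slope x sd(GC)` from a least-squares regression of
LRR on centered local GC — a dimensionless signed waviness; correction
subtracts the fitted component and is idempotent.  PI_HAT uses the
standard method-of-moments IBD construction from IBS counts given allele
frequencies, on an evenly thinned SNP subset (synthetic SNPs are unlinked,
so thinning costs only precision).  At 2,000 probes the estimator's
sampling SD for unrelated pairs is ~0.03 with a long right tail — far
below the 0.9 duplicate threshold, but worth knowing when reading the
pairwise matrix.

# Association

Calls below 10 SNPs or 100 kb are discarded (inclusive thresholds).  Per
SNP, a sample is a carrier of a duplication (cn > 2) or deletion (cn < 2)
if any retained call of that type spans the position; overlapping calls
count once.  The one-sided Fisher exact tail (toward case enrichment;
a `direction` switch reverses it) is computed in log space.  SNPs with
p < 0.05 merge into a region while consecutive significant SNPs are
within 1 Mb; the region's peak is its statistical local minimum (ties:
leftmost).  Exclusivity — zero control carriers at the peak — is the
default reporting condition, because recurrent-but-shared regions are
dominated by common polymorphic CNVs.

Four exclusion flags mark likely artifacts: arm-terminal or acen/gvar
cytobands; a boundary within 50 kb of the same-side boundary of a >1%
frequency common CNV (the "peninsula" produced by boundary-truncation
variability — the concept is standard, the 50 kb window is this package's
operationalization); mean probe GC outside [0.30, 0.60]; and samples
contributing to multiple reported regions.

Permutation significance permutes case/control labels; the statistic is
the pseudo-case carrier count at the observed region, zeroed whenever any
carrier lands in pseudo-controls (the exclusivity requirement), with the
+1-corrected empirical p.  For a single locus this converges to the
hypergeometric closed form, which the test suite checks at 3 Monte-Carlo
SE.  A prevalence-based contamination estimate
(`round(prevalence x n_unscreened)`) quantifies expected undiagnosed
cases among unscreened control supplements.

Duplications and deletions are tested separately by default (plus a
pooled track): their artifact profiles differ, and a locus where cases
gain and controls lose is not one signal.

# The synthetic cohort generator

The generator works backwards from the polar representation.  Per probe,
the target theta interpolates the configured AA/AB/BB centers (defaults
0.1/0.5/0.9) at the allelic fraction b/(a+b); carriers inside an embedded
CNV draw their extra allele Bernoulli(p) (two draws for CN4) or lose one
uniformly (CN1), the simplest population-consistent choice.  The target
polar R is `(R_dip * (a + b + 0.1) / 2.1)^gamma` with
`R_dip = 2 log10(intensity_scale)`: a 5% background per channel keeps
homozygote theta finite, and the exponent `gamma = 0.7` models PCR
saturation on the summed log scale — the strength is a fixture knob, not
a platform claim, since no quantitative saturation model is published.
At `gamma = 1` the CN3 LRR shift is `log2(3.1/2.1) = 0.56`; at 0.7 it is
0.39, which is what the default HMM emission means assume.

Channel noise is *correlated* lognormal noise (default SD 0.26 per
channel, correlation 0.9): shared hybridization/PCR efficiency moves both
channels together, so the total (hence LRR, per-sample SD ~0.2) is much
noisier than the allelic ratio (BAF band SD ~0.03) — the regime real
arrays live in, and the regime the paper-condition fixture must reproduce.
Uncorrelated noise at the same LRR SD would smear BAF bands three-fold
wider than the emission model's 0.04 and make the band structure
unrealistically uninformative.  A per-sample GC wave coefficient
~N(0, 0.05) multiplies centered GC on the log10 total scale.  Duplicate
pairs copy genotypes (independent noise); parent-offspring pairs transmit
one allele per probe; two-subpopulation stratification uses
Balding-Nichols Beta draws around the base frequency.  The generator's
own genotype labels come from an equal-weight three-Gaussian posterior on
theta (no-call when the winning posterior drops below 0.9) — a stand-in
for an external caller, which is why carrier probes inside duplications
still receive forced diploid labels, as a real caller would produce.

**The default fixture** is the study condition: 1,693 cases and 4,506
controls over ~2,000 probes spanning 3 Mb of a chromosome-5-like region,
with one 646,850 bp CN=3 segment carried by 5 cases and no controls.
What the generator does *not* emulate: real probe spacing and LD (probes
are unlinked and uniform), batch/plate effects, mosaic fractional states,
sex chromosomes, and the platform's true chemistry.  Passing tests
therefore demonstrate the pipeline's internal correctness and its
behaviour under realistic noise magnitudes — not performance on any real
array.

# Numerical choices and degenerate inputs

Raw intensities are floored at 1 before logs; non-finite raw values mask
the probe rather than erroring.  Unusable SNPs are masked through BAF/LRR
and skipped by PFB.  Emission densities never hit zero (outlier mixture),
so Viterbi and forward-backward stay finite; forward-backward is scaled,
with a per-probe shift making masked probes exactly uninformative.
Zero-variance GC yields wave factor 0 by convention.  Fisher tails use
`lchoose` sums with a max-shift, exact to enumeration at 1e-12 relative
tolerance.  The empirical permutation p uses the +1 correction and is
never zero.  Region peaks break p-value ties leftmost; dedupe breaks
call-rate ties by sample-id order.  Chromosomes with fewer than two
usable probes produce no calls.

# Problem sizes

The validation suite runs the full study-scale reconstruction (6,199
samples x 2,000 probes) once end-to-end; unit and property tests use
cohorts of 60-400 samples over 60-2,000 probes, 100-replicate breakpoint
panels, and 10,000-permutation comparisons — sizes chosen so each
statistical check has the power its tolerance needs.  Training batches
follow the 3 x 30 schedule on 500-probe tracks, where parameter recovery
is already within the +/-0.05 tolerance.

# Known limitations

Boundary placement inherits probe resolution: a breakpoint between probes
cannot be localized better than the flanking probes.  The confidence
score is comparable within a run of this package, not across
implementations.  The PI_HAT method-of-moments estimator is noisy at
thousands of SNPs (fine for duplicate detection at 0.9, coarse for
distinguishing, say, half-siblings from cousins).  Genomic-control
inflation factors, LD pruning, family-based joint calling and
cross-platform replication are out of scope.
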