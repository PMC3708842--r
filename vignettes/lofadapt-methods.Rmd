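---
title: "Models and methods behind lofadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lofadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofadapt)
```

`lofadapt` analyses how loss-of-function (null) mutations change bacterial
fitness: significance calling for transposon-footprint selections,
clustering of fitness profiles, class-level meta-analysis of beneficial and
deleterious calls, flux balance analysis of metabolic rewiring, expression
false-discovery estimation, and doubling-time inference. This vignette
records the models, the parameter choices that matter, and the points where
the design was genuinely open.

## Transposon footprint statistics

The data are per-gene ratios of transposon signal to genomic DNA signal, on
arrays hybridized before selection (five technical "reference" arrays of
the same library) and after selection (two or three biological replicates
per condition).

**Normalization.** Each array is scaled so its ratio total equals the mean
array total, then log2-transformed so increases and decreases have similar
magnitudes; each array's log2 values are regressed on the per-gene mean of
the log2 reference arrays by loess (span 0.3, locally linear, tricube
weights, no robustness iterations, prediction by interpolation) and the
fitted value subtracted. The order — sum-normalize on the ratio scale, then
log, then loess — is a convention; the alternatives differ only at second
order. Sum normalization targets the *mean* array total; a fixed total
would change all arrays by a common constant that the loess stage removes
anyway. At least two reference arrays are required: with one, the regressor
is a single noisy array and the regression has no averaging to stand on. If
the regressor is degenerate (zero spread, as in an already-flattened
dataset) the stage falls back to column centring, which keeps normalization
idempotent on flat data.

**Summary statistic.** For each gene and condition the statistic is the
replicate value closest to zero when all replicates strictly share a sign,
and zero otherwise; a replicate exactly at zero has no sign and so breaks
concordance. This is deliberately conservative — a single discordant
replicate vetoes the gene, and the magnitude is bounded by the weakest
replicate.

**Null model.** Significance comes from a simulated null of pseudo-genes
(500,000 by default; the tests and the acceptance script use 50,000, which
leaves the quantile of interest with ample resolution at the problem sizes
they run). Each pseudo-gene receives r draws (r = the condition's replicate
count) from a t-distribution with 4 degrees of freedom, rescaled so the
*distribution's standard deviation* — not its raw scale parameter — equals
the replicate standard deviation of a randomly chosen real gene, and
shifted by the median normalized reference residual of an independently
chosen ("possibly different") gene. The t draw is divided by
sqrt(df/(df−2)); df ≤ 2 is rejected because the variance would be infinite.
Gene-for-sd and gene-for-mean are sampled independently with replacement
from one seeded generator.

**p-values and FDR.** p is the fraction of pseudo-genes whose summary
strictly exceeds the observed magnitude, floored at 1/n_pseudo; ties count
as not exceeding (the choice matters only at machine precision). Per
condition, the significance cutoff is the largest threshold α whose plug-in
estimate α·n/#{p ≤ α} stays at or below the target FDR (5% by default).
Essential genes are excluded before testing from a user-supplied list; the
package ships no organism data.

**Calibration, honestly stated.** The summary statistic has an atom at
zero (under the null only ~2^(1−r) of genes are sign-concordant), so the
p-value distribution is uniform on (0, q] with a point mass at
q = P(summary ≠ 0); calibration is therefore assessed on the continuous
part — p-values of sign-concordant genes divided by q. Even there, the null
construction is not exactly calibrated: its scale is the *sample* standard
deviation of three replicates of a random gene, which is the true per-gene
sd distribution broadened by an independent chi-type factor. The observed
statistic carries no such factor, so the null is slightly over-dispersed;
the discrepancy concentrates conservatively at small p-values, which is why
realized FDR control holds comfortably (the acceptance run measures
realized FDR well under the nominal 5%) while a Kolmogorov–Smirnov test at
desk scale can still detect the mid-distribution curvature. The package
keeps the construction faithful rather than re-deriving a different null.

## Synthetic footprint data

The generator writes, on the log2 scale, per-gene baseline (Normal,
sd 1.5) + per-array smooth bias + spiked effect (selected arrays only) +
scaled t-noise, then exponentiates and floors at 1e-6 to keep logs finite.
Choices worth recording:

* The smooth bias is a sine in the scaled baseline with per-array random
  amplitude (≤ 0.5 log2 units) and phase — slowly varying in reference
  intensity, so the loess stage has real work to do.
* Heavy-tailed draws are rescaled so the distribution's sd equals the
  drawn per-gene sd, mirroring the same decision in the null model.
* Selected arrays draw per-gene sds from a lognormal around 0.3 log2
  units (biological spread between independent selections). Reference
  arrays get their own smaller technical scale, 0.1 by default: they are
  re-hybridizations of one pre-selection library, and giving them
  biological-scale noise would both misstate the assay and leak
  reference-mean estimation error into every normalized value.
* The magnitude distribution of true fitness effects in a real library is
  unknown; the default spike magnitude (|log2| = 4) is a convention chosen
  to represent a strong, clearly selectable fitness effect, and is a
  parameter, not an inference.

What the generator does **not** emulate: probe-level structure, spatial
array artifacts, abundance-dependent noise coupling, or correlated
selection between genes. Passing tests on this data demonstrates that the
statistics do what they claim under the stated noise model — not that real
arrays satisfy that model.

## Fitness-profile clustering

The cluster matrix holds each significant gene's normalized replicate
values plus per-condition averages; average columns get ten times the
weight of replicate columns. A column weight w enters the squared Euclidean
distance linearly, implemented by scaling the column by sqrt(w) — the
standard weighted-distance reading. k defaults to 9 and is configurable;
initialization is seeded k-means++ with 50 restarts, keeping the best run
by within-cluster sum of squares (neither k nor the initialization is
canonical; both are conventions). Labels are canonicalized by descending
cluster mean so runs are comparable. Values are clipped to [−3, 3] only for
display. Cluster×category enrichment is a plain upper-tail hypergeometric
test with Benjamini–Hochberg across pairs — deliberately simple plumbing,
not a reimplementation of mutual-information-based pathway analysis.

## Meta-analysis of call tables

Datasets distributed as z-scores with a standard-normal null are called by
one pooled cutoff: the smallest c with 2(1−Φ(c))·N/#{|z| ≥ c} at or below
the target FDR, applied over all experiments collectively. The
class-enrichment test simulates, per class and condition, a Binomial with
the class's tested-member count and the condition's average per-gene call
probability, sums across conditions, and takes the fraction of simulated
sums at or above the observed total (floored at 1/(n_draws+1), 10,000
draws by default; 2,000 in the time-boxed acceptance run). Beneficial and
deleterious directions are tested as separate Benjamini–Hochberg families
at FDR 0.01 — whether the original analysis pooled both directions into one
family is not stated; separate families match the two-panel presentation
of the results and are the choice here. Essential genes are expected to be
removed upstream, and per-study curation (dose selection, verified-gene
substitutions for single-replicate studies) is treated as configuration:
the package ingests ready-made call lists and records provenance, it does
not re-impose other studies' criteria.

The spontaneous null-allele rate multiplies a per-nucleotide mutation rate,
an ORF length, the fraction of the ORF where a premature stop is assumed to
abolish function, and the probability that a random single-base change in a
random sense codon creates a stop — computed by exhaustive enumeration over
all 61×3×3 substitution outcomes (23/549 ≈ 0.042 under uniform codon
usage). With the conventional inputs (1e-10 per nt, 1 kb, first half) this
gives ≈ 2.1e-9 per gene per division. The function reports the computed
value and its assumptions; the commonly quoted order-of-magnitude figure of
1e-8 is not reproducible from these assumptions by enumeration, and the
package does not assert it.

## Flux balance and variability analysis

The model container holds metabolites, stoichiometry, flux bounds
(mmol·gDW⁻¹·h⁻¹), boolean gene-protein-reaction rules (AND for complexes,
OR for isozymes; an empty rule survives any deletion, the usual
reconstruction semantics), and a single biomass objective. Uptake is a
negative exchange flux. Minimal media are configured by closing every
exchange's uptake bound except a whitelist and opening the named carbon
exchange at the given rate (10 by default).

FBA maximizes the biomass flux subject to steady-state mass balance and
bounds. The LPs are solved by the package's own dense two-phase primal
simplex with Bland's anti-cycling rule; infinite bounds are boxed at 1e5.
A bespoke solver is warranted here because the objective-fixed LPs of flux
variability analysis are maximally degenerate, and the tests verify the
solver against an independent oracle — exhaustive enumeration of basic
feasible points — on every toy model, to 1e-6.

Numerical conventions: a gene is essential *for maximum growth* when
deleting it lowers the optimum by more than 1e-6 relative (LP noise); FVA
pins the objective at its optimum exactly (opt_tol = 0) since the question
is about maximum growth, not a fraction of it; a reaction is
"zero-required" when its whole FVA range lies within 1e-6 of zero — fluxes
are not required to be exactly zero, and the threshold is configurable. The
must-be-off report collects genes appearing in any zero-required reaction's
rule (membership suffices, even if the gene also catalyzes active
reactions) and removes genes that are themselves essential for maximum
growth.

The four toy models are built to make the interesting phenomena provable by
hand: the futile cycle burns energy without net product (growth =
(10 − cycle flux)/2, optimum 5 with the cycle off), the costly bypass
spends extra energy per unit product (optimum 20/3 with the bypass off),
and the parallel-path model shows flux variability without forced zeros.
Each carries its closed-form optimum as an attribute.

Model I/O covers a tabular dialect (one reaction per row: id, equation,
bounds, rule, objective flag) and SBML Level 3 with fbc-style bounds,
nested and/or gene associations and a maximization objective. The SBML
reader handles the writer's output and generic fbc constructs; it is not a
full SBML validator.

## Expression-change FDR

Differential expression is called on the average of two biological
replicates at a fold threshold (default 2, i.e. |log2| ≥ 1, with the
boundary counted as called — a documented convention). The null sample is
the replicate half-difference (r1 − r2)/2, which has zero mean and exactly
the same noise distribution as the replicate average (both sd σ/√2 under
iid replicate noise with sd σ — the identity the tests verify). Nulls are
pooled across all supplied contrasts by default, mirroring a single null
for a batch of related samples; per-contrast nulls are a flag. Expected
false positives use a strict comparison (null values strictly beyond the
threshold), matching the stated counting rule; calls use ≥. The difference
matters only for values exactly at the threshold. FDR is expected false
positives over calls, capped at 1, undefined (NA) when nothing is called.
Overlap significance between differentially expressed sets is an
upper-tail hypergeometric probability with a Bonferroni factor for the
number of comparisons.

## Growth kinetics

Doubling times come from a least-squares line on
log2(background-corrected absorbance × cumulative dilution) versus time;
with log base 2 the reciprocal slope is the doubling time directly. The
fitting window is selected on background-corrected absorbance before
dilution multiplication — the plate-reader convention uses 0.015625–0.0625
with r² ≥ 0.99, while serial-dilution flask fits conventionally accept
r² ≥ 0.95. Hand-identified exponential regions are supported as explicit
index windows recorded in the output; the package requires explicit
windows rather than guessing intent, since manual region identification is
not an algorithm. Non-positive corrected values inside a window are an
error with a count, not silently dropped.

Strain-vs-parent comparisons use the one-sided Mann–Whitney test (mutant
doubling times stochastically smaller), exact for small untied samples and
normally approximated above, with Benjamini–Hochberg applied across the
whole set of strain/media combinations — one FDR budget for the entire
screen. Fully tied data yields p = 1 with a warning.

The parameter-recovery conditions in the tests use the serial-dilution
regime: doubling time 240 min, 16 samples spanning about 15 generations,
15-fold dilutions whenever corrected absorbance approaches 0.15, blank
0.04, reader noise 0.005 absorbance units, fitting window 0.012–0.2. Under
those conditions the median doubling-time error is well under 2%. The
short plate-reader window (two doublings at 8-minute sampling) cannot
reach that accuracy at the same noise level — at absorbance 0.016, 0.005
absorbance units is almost half a log2 unit — which is precisely why
long-span dilution-corrected fits are the regime of record for slow media.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. The test-suite and acceptance problem sizes — 50 spiked
footprint datasets of 2,000 genes with 50,000 pseudo-genes per null, 100
seeds for class enrichment at 2,000 resampling draws, 100 growth curves —
were chosen so the whole suite exercises every end-to-end property in
about a minute on one core while keeping Monte-Carlo error comfortably
below the margins being asserted.

## Known limitations

* The footprint null's sample-sd scale mixture makes strict p-value
  uniformity unattainable (see above); FDR control is the guaranteed
  property, calibration of the continuous part is approximate.
* The LP solver is dense and sized for compact models; a genome-scale
  reconstruction (thousands of reactions) wants a sparse solver with
  bounded-variable pivoting and would make FVA on such models far faster.
* The SBML reader targets fbc-style documents; exotic SBML (kinetic laws,
  initial assignments, groups) is ignored.
* The class-enrichment permutation type-I rate sits near its nominal
  bound when strong spikes are present and labels are permuted, because
  the binomial null's rate is estimated from the same data; the effect is
  small (fractions of a percent) but visible at tight thresholds.
* Growth fitting assumes clean exponential phase inside the window; lag
  and stationary phases are out of scope by design.
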