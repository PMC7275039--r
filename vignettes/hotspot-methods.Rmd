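---
title: "Detecting somatic mutation hotspots with a patient-specific background model"
author: "somaticHotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mutation hotspots with a patient-specific background model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Recurrent somatic mutations concentrated in a short genomic window — a
*hotspot* — are a signal of positive selection and hence of candidate
driver events, in coding and non-coding DNA alike. The difficulty is that
the somatic background mutation rate is anything but uniform: it varies by
orders of magnitude with local sequence context, chromatin state,
replication timing, regional effects that no annotated covariate explains,
and, across patients, with each tumor's total mutation burden. A recurrence
test that ignores this heterogeneity floods the caller with passenger
windows in late-replicating, mutation-prone sequence.

somaticHotspots addresses this in two stages: (i) estimate, for every
patient and every analyzable genomic position, the probability that this
patient carries a somatic mutation at this position under neutrality; and
(ii) test each 21-bp window for carrying more *distinct mutated patients*
than that background predicts.

## The background model

For a (patient $i$, position $j$) pair the model is plain logistic
regression,

$$\Pr(Y_{ij}=1) = \mathrm{logit}^{-1}\!\big(\alpha + \beta^\top x_j + \gamma^\top z_i\big),$$

where $x_j$ collects positional covariates and $z_i$ patient-level
covariates. Separate models are fitted for SNVs and for indels, which arise
from different mutational processes.

Positional covariates available out of the box:

* **Sequence context** (SNV models): the mutated base class (A/T vs C/G),
  and one-hot encodings of the trinucleotide, pentanucleotide and 1-bp /
  2-bp flanks centered at the position. Contexts are reported on the
  pyrimidine strand of the center base (purine-centered windows are
  reverse-complemented), the standard mutational-signature convention, so a
  site and its reverse complement get identical encodings. The
  lexicographically first level of each one-hot group is dropped as the
  reference to keep the design full-rank. The default `context =
  "standard"` set uses center class, trinucleotide and 1-bp flanks;
  `"full"` adds the pentanucleotide and 2-bp flanks (3-mer information is
  then represented redundantly, which LASSO selection resolves).
* **Homopolymer context** (indel models): a binary flag for a
  mononucleotide run longer than 5 bp overlapping the indel's reference
  span — long runs are a known source of indel-calling artifacts.
* **Epigenomic overlays**: any user-supplied BED (binary membership) or
  bedGraph (continuous profile) track — DNase hypersensitivity, histone
  marks, TF binding, replication timing, predicted editing-site overlays,
  and so on. Continuous tracks are z-scored over the training sites so the
  LASSO penalty treats all features comparably; binary tracks stay 0/1.
* **Local mutation rate**: the cohort's empirical rate in 100-kb
  non-overlapping bins (count / (bin width × cohort size)), absorbing
  regional variation the annotated covariates miss. The queried position
  takes its containing bin's value. Note one acknowledged imperfection: the
  bin rate includes the tested windows' own mutations, a mild circularity
  that slightly *reduces* power at true hotspots and is therefore
  conservative.

Patient-level covariates: log1p of the patient's mutation count of the
modelled class, centered (multiplicative burden effect on the odds), plus
any user-supplied per-sample columns (mutational-signature proportions,
subtype indicators). Signature proportions are accepted as inputs, never
computed here.

## Training-site sampling and the case-control correction

Fitting on every (patient, position) pair is unnecessary; the model is fit
on up to one million mutated sites (all of them in smaller cohorts) and an
equal number of non-mutated (position, patient) pairs drawn uniformly over
the analyzable mask, each control pair verified not to be mutated in the
catalog. Controls are *pairs*, not bare positions, so patient covariates
are defined for both classes. A site mutated in several patients
contributes one case row per patient — the model's unit is the
(patient, position) Bernoulli trial.

Balanced case-control sampling inflates the fitted intercept by
$\log(f_1/f_0)$, where $f_1$ and $f_0$ are the case and control sampling
fractions; with genome-scale denominators this inflation is on the order
of ten log-odds units. All prediction functions therefore subtract
$\log(f_1/f_0)$ from the fitted intercept (the classical prior-correction
for case-control logistic regression). Without this step the recurrence
test's per-window success probabilities would be wrong by orders of
magnitude, so the correction is applied unconditionally whenever
$f_1 \neq f_0$.

## Feature selection

Candidate positional features are screened by LASSO logistic regression
(via glmnet) under bootstrap stability selection:

1. 100 subsamples of 50% of the training rows, drawn without replacement
   (the m-out-of-n scheme standard in stability selection).
2. Per subsample, 10-fold cross-validation (folds stratified by label) over
   a log-spaced penalty grid descending four decades from the data-derived
   maximum; the chosen penalty is the largest whose mean CV deviance is
   within one standard error of the minimum (the 1-SE rule, matching
   `cv.glmnet`'s `lambda.1se`).
3. A feature is *selected* when the fraction of subsamples in which any of
   its design columns is nonzero strictly exceeds its category's
   recurrence threshold: 0.90 for sequence-context features, 0.75 for
   everything else. Both thresholds are user-adjustable; raising a
   threshold can only shrink the selected set.

Patient-level covariates bypass selection and always enter the final
model: they parameterize who the patient is rather than competing
positional biology, and the final unpenalized fit estimates their effects
freely. Selection frequencies are reported per feature *group* (a
trinucleotide's 31 dummies count as one feature).

The final model is an unpenalized maximum-likelihood logistic fit on the
selected features; coefficients, standard errors from the observed
information matrix, and Z-values ($\hat\beta/\mathrm{SE}$) are reported.
Degenerate designs are handled explicitly: constant or aliased columns are
dropped with a warning naming them, and quasi-separation triggers a
ridge-stabilized fallback fit (again with a warning). McFadden's pseudo
$R^2 = 1 - LL_{model}/LL_{null}$ summarizes fit quality; it saturates
around $2\times10^5$ training rows on cohorts of this kind, which is why a
warning is emitted below that size.

## The recurrence test

A hotspot candidate is an $l$-bp window (default $l = 21$, chosen because
most TF-binding motifs are shorter than 20 bp, so motif-gain/loss events
cluster within 20 bp) centered on an analyzable nucleotide whose window
holds mutations from at least $n$ distinct patients (default $n = 2$; for
a 1000-tumor cohort one would raise $n$ to, say, 20 to demand 2%
recurrence — this also shrinks the evaluated set and the compute time).

For each candidate the per-patient window success probability is

$$q_i = 1 - \prod_{j \in \text{window}} (1 - p_{ij}),$$

the probability of at least one mutation in the window under independence
across positions. Masked or context-less positions are simply skipped in
the product. The observed statistic is $k_{obs}$, the number of *distinct*
mutated patients (two hits in one tumor are one patient), and the p-value
is the exact Poisson-binomial tail $\Pr(K \ge k_{obs})$ computed by
dynamic-programming convolution of the pmf — $O(N^2)$, numerically exact
to $\sim10^{-13}$ against brute-force enumeration, with the result clipped
into $(10^{-300}, 1]$.

Every analyzable nucleotide is a hypothesis: centers never evaluated
(fewer than $n$ mutated patients nearby) implicitly carry $P = 1$.
Benjamini-Hochberg therefore runs over $m_{total}$ = the number of
analyzable nucleotides (genome mode) or of masked nucleotides inside the
regions of interest (region mode), implemented without materializing the
padding: the step-up running minimum is capped at 1, which is exactly what
explicit padding would do (property-tested against `p.adjust` on the
padded vector). In region mode the same window gets the same p-value as in
genome mode; only the q-value changes through $m_{total}$.

Overlapping significant windows sharing at least one mutated position are
merged into a single reported hotspot (union span; the minimum-p window is
the representative). The merge rule is a reporting decision — per-center
q-values are available in the unmerged window table.

## Analyzable mask

The scan excludes poorly mappable regions and any user blacklist
(immunoglobulin loci and similar artifact-prone regions), both supplied as
BED; runs of N in the reference are always excluded, and coding regions
can be excluded for a non-coding scan. The per-contig identity
|analyzable| + |excluded| = contig length is enforced by tests. Sites
within 2 bp of a contig edge or an N cannot carry a full 5-mer context;
they are excluded from training and skipped inside window products, but
remain counted in $m_{total}$, which is conservative.

## Baseline models

For method comparison the package re-runs the identical scan under four
simpler backgrounds: (1) one binomial rate for everybody (cohort average);
(2) per-patient genome-wide rates (burden / mask size); (3) additionally
modulated by a replication-timing profile, quantile-binned into five bins
with per-bin relative rates estimated from the catalog; (4) additionally
modulated by the 100-kb local rate. Information added monotonically
removes false candidates, so call counts are expected to be non-increasing
from (1) to (4) — a property the tests check on rate-heterogeneous
simulations.

## The synthetic-data generator

`simulateGenome` / `simulateTracks` / `simulateCatalog` generate an i.i.d.
random genome at a configurable GC content, binary overlays (unions of
1-kb intervals placed until a target coverage fraction is met, accurate to
well under 5%), smooth continuous profiles (piecewise-constant sinusoid
plus Gaussian bin noise, standing in for replication timing), and a cohort
catalog drawn *from the same logistic model family the fit assumes*: one
Bernoulli trial per (patient, position), with per-patient log-odds shifts
for burden heterogeneity and optional spiked windows where each patient
acquires a mutation with a configured success probability. Matching the
generative family to the fitted family is deliberate: parameter recovery
and FDR calibration then test the estimation machinery itself, not model
misspecification.

Defaults describe a realistic desk-scale cohort: 1-Mb genome, 30 tumors,
5 mutations per megabase per tumor (mid-range for adult solid cancers),
log-normal burden variation (SD 0.4 on the log-odds scale), one binary
overlay covering 20% of the genome with coefficient 0.7, one continuous
profile with coefficient 0.3. What the generator does *not* emulate:
mutational-signature-driven context biases beyond the configured
coefficients, clustered artifact processes, copy-number or purity effects,
and mappability structure. Green tests on this generator demonstrate
correct estimation and calibration under the stated model family, not
robustness to everything real tumors do.

## Numerical and design choices

* Penalty grid: 100 log-spaced values over four decades;
  cross-validation deviance computed by hand around `glmnet()` path fits
  (one path per fold against a shared grid), which matches `cv.glmnet`
  while being substantially faster at these scales.
* Poisson-binomial probabilities are clipped to $[0, 1-10^{-16}]$ before
  the convolution; p-values clipped at $10^{-300}$; q-values to $[0,1]$.
* Ties in the hotspot table are broken by (contig, start) after p-value,
  making outputs byte-stable; reruns with the same seed and any thread
  count are byte-identical (threads partition candidate windows by contig
  and results are reassembled in fixed order).
* All RNG consumption is seeded; stage seeds are derived from one master
  seed recorded in the run manifest.
* One-hot levels are fixed a priori from the collapsed alphabet (never
  data-dependent), so training and prediction encodings always align.
* Coordinates are 1-based closed inside the package (the GRanges
  convention); BED/bedGraph 0-based half-open conversion happens only in
  the readers/writers, and the hotspot TSV reports 0-based starts.

## Desk-scale test conditions

The shipped statistical checks run at deliberately desk-scale problem
sizes — small enough to re-run routinely during development, large enough
that every assertion is statistically meaningful. These are the package's
own study conditions:

* Support recovery: 600-kb genome over 2 contigs, 30 tumors, background
  rate $3.3\times10^{-4}$ (roughly 10,000 mutated training sites), 20
  candidate binary overlays of which 3 carry effects
  ($\beta = 1.0, -0.9, 0.8$), 100 bootstraps, 10 replicate runs: the
  selected set must equal the planted support in at least 9/10 runs and
  fitted coefficients must sit within ±0.15 of truth. Larger training
  sets only make this easier; the default 1M-site cap applies to real
  cohorts.
* Null calibration: 20 replicate cohorts at the generator defaults, no
  spikes; at least 15/20 runs must yield zero calls at FDR < 0.05 and the
  mean false-discovery proportion must not exceed 0.05.
* Spike-in power: 10 disjoint 21-bp windows at per-patient success
  probability 0.15 in the default 30-tumor cohort; the median number of
  recovered spikes over 21 replicates must be at least 9/10. This sits
  deliberately at the design's own detection boundary: with these
  parameters a spike needs 3 mutated patients to clear genome-wide
  correction, which happens with probability ≈0.85 per spike, so the
  run-level median is exactly at the required value.
* Calibration: decile-binned predicted vs observed mutation counts over
  all (patient, position) pairs of one default cohort must agree within 3
  Monte-Carlo SDs in every decile.

## Known limitations

* The local-rate covariate is not leave-one-out; strong hotspots slightly
  inflate their own background (conservative).
* The exact Poisson-binomial DP is $O(N^2)$ in cohort size; beyond a few
  thousand tumors a refined-normal or DFT approximation would be the next
  step.
* Indel support is functional (separate model, homopolymer covariate) but
  the simulator's indel process is deliberately simple.
* bigWig tracks are not parsed; convert to bedGraph first. bedGraph is the
  reference path because it is text and fully testable.
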