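---
title: "Leukocyte CNV burden models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leukocyte CNV burden models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsrcnv)
```

## The problem and the statistic

Germline copy-number variation (CNV) in circulating leukocytes carries a
burden signal associated with the clinical course of prostate cancer after
radical prostatectomy. Gene-by-gene association of leukocyte CNV with
recurrence is weak, but the *size distribution* of a patient's CNV fragments
is informative: recurrent patients carry a markedly heavier large-fragment
tail (arm-level mean sizes differ by about 3-fold).

The core statistic is the **large size ratio**. For a patient whose retained
CNV fragments have sizes $s_1, \dots, s_n$ (bp) and a large-size threshold
$\delta$,

$$\mathrm{LSR}(\delta) \;=\; \frac{\#\{i : s_i \ge \delta\}}{n}.$$

`computeLSR()` implements this; membership is inclusive ($s_i \ge \delta$).
An empty profile raises an error rather than returning 0: a genome with no
retained fragments has an *undefined* burden ratio, and silently scoring it
as "all small" would bias any downstream model. The statistic is
scale-equivariant and non-increasing in $\delta$, properties the test suite
asserts over randomly generated profiles.

Segments enter the statistic only after the standard SNP-array reliability
filter (`filterSegments()`): size $\ge$ 2 kb (inclusive), marker support
$\ge$ 10 (inclusive), and call p-value $< 0.001$ (strict). The boundary
conventions follow the filter's usual wording exactly, and the defaults can
be overridden. Whether gains and losses should be pooled in the per-sample
fragment multiset is not prescribed anywhere we know of; the package pools
both states (the burden hypothesis is state-agnostic), and callers wanting a
single state can subset the segment `GRanges` on its `state` column before
`buildProfiles()`.

Coordinates are stored internally in Bioconductor's 1-based closed
convention (so `width()` is the fragment size in bp) and written to disk in
the 0-based half-open dialect; a 1-based fully-closed "partek" input dialect
is also accepted. Declaring the dialect explicitly keeps size arithmetic
unambiguous, which matters because every statistic in the package is a
function of fragment size.

## Threshold and cutoff tuning

$\delta$ is tuned on training data by maximizing the AUC of LSR against the
outcome over a log10 grid (`optimizeDelta()`), default $10^{3.3}$ to
$10^{6.5}$ in steps of $0.1$ — a decade range comfortably bracketing the two
documented optima ($10^{4.5}$ and $10^{5.7}$), both of which lie on a 0.1
grid. Ties go to the smallest threshold, for determinism. The decision
cutoff on any model score is chosen by maximizing the Youden index
$J = \text{sensitivity} + \text{specificity} - 1$ under the rule
score $\ge$ cutoff $\Rightarrow$ positive (`fitCutoff()`); candidate cutoffs
are the observed values plus midpoints between adjacent distinct values, so
perfect separation yields the midpoint between the classes, and ties again
go to the smallest candidate.

Whether $\delta$ should be re-tuned inside every cross-validation training
half or fixed once globally is ambiguous in the protocol this package
follows; we re-tune per training half, which is the honest (nested) choice —
tuning outside the split would leak test information into $\delta$.

## Covariates and model combination

Three clinical modalities accompany the CNV burden (L): the binary
high-grade Gleason flag (G: score $> 7$), the MSKCC-style nomogram 7-year
progression-free probability (N), and the binary fusion-transcript status
(F: any of the eight assayed transcripts detected). The nomogram probability
is consumed as an externally computed number; internally the feature is
$1 - p$ so that *every* feature is oriented higher = more likely recurrent.

Multi-modality models combine features with Fisher's linear discriminant:
$w = S^{-1}(\mu_+ - \mu_-)$ with $S$ the pooled within-class covariance
(`fitLDA()`). Binary covariates on small training halves readily produce a
singular $S$, so a ridge $\varepsilon I$ with
$\varepsilon = 10^{-6}\,\mathrm{tr}(S)/d$ is added when the solve fails;
the tests check that a duplicated feature column leaves the sample ranking
unchanged. Single-modality models use the raw oriented feature directly —
a one-dimensional discriminant is monotone in the feature anyway.

## Cross-validation protocol

`runSplit()` performs one repeat of two-fold cross-validation: the contrast
samples are randomly and *equally* split; $\delta$, the discriminant and the
cutoff are fitted on one half and evaluated on both; roles are then swapped;
the two train-role and two test-role evaluations are averaged (p-values by
geometric mean). Splits that leave a one-class half are redrawn (at most
100 times, logged). `trimmedCV()` repeats this 14 times, ranks repeats by
train + test AUC, discards the top 2 and bottom 2 (guarding against
accidentally extreme assignments), and averages the remaining 10 per metric.
The representative repeat — used for representative ROC/KM displays — is the
retained repeat whose metric vector is closest (Euclidean over the six
non-p metrics of both roles) to the trimmed average.

The protocol's "accuracy" is not pinned down in the source material (its
printed values sit between sensitivity and specificity); we therefore emit
both the raw overall accuracy and the balanced accuracy
$(\text{sens}+\text{spec})/2$ and let the reader choose.

Three nested outcome contrasts are supported (`contrastLabels()`):
recurrence (vs non-recurrent with $\ge 90$ months follow-up), fast
recurrence (PSADT $\le 4$ months vs non-recurrent-or-PSADT $\ge 15$;
intermediate doubling times are excluded), and lethal disease (recurrence
within 12 months with PSADT $\le 4$, vs long-term non-recurrent).

## Survival layer

Predicted risk groups come from one merged two-fold cross-fit
(`mergedCvGroups()`): each patient is scored by the model trained on the
half not containing them, so everyone is predicted exactly once. The
Gleason-only model is the exception — its global $> 7$ threshold involves no
tuning, so it is applied to all samples directly. Groups are compared with
Kaplan-Meier curves truncated at 90 months (`kmEstimate()`: any observation
beyond the horizon is censored there) and the two-group log-rank test
(`logrankTest()`), both delegated to the survival package behind the module
interface. Horizon survival is reported both as the KM estimate and the raw
event-free fraction, since either reading of a "percent surviving" figure is
defensible.

To ask whether model A separates survival *better* than model B, the U test
(`uTest()`) refers $U = |\chi^2_A - \chi^2_B|$ to a Monte-Carlo null of the
absolute difference of two independent $\chi^2_1$ variables ($10^7$ draws by
default). The p-value uses the add-one estimator $(k+1)/(n+1)$, which cannot
produce an exact zero — no finite simulation can honestly report $p = 0$.
The independence assumption between the two statistics is inherited from the
protocol, not endorsed: two models evaluated on the same patients are
positively dependent, which makes the test conservative for close
comparisons.

## The synthetic cohort generator

`generateCohort()` exists so that every pipeline stage is exercised on data
with known structure. Its defaults *are* the study conditions the package
targets: 35 / 55 / 53 non-recurrent / fast-recurrent / slow-recurrent
patients, a mean of 152 retained CNV fragments per genome
(negative-binomial, dispersion 20 — overdispersion is an assumption; no
variance is reported anywhere), log-normal fragment sizes truncated below
the 2 kb retention bound — so the count model is a model of *retained*
fragments (log10 location 4.11, SD 0.5; with the mixture tail this gives a
non-recurrent arm mean size near 55 kb and a design-mix cohort-wide mean
near 147 kb), and a recurrent-arm large-size mixture
component whose location is solved in closed form so the recurrent /
non-recurrent arm mean-size ratio equals exactly 3.2
(`expectedMeanSizes()` exposes the closed form; a law-of-large-numbers test
checks the generator against it).

Two generator choices deserve emphasis:

* **Per-patient burden heterogeneity.** Each patient draws a personal
  large-fragment mixture weight from a Beta distribution (mean 0.05
  non-recurrent, 0.25 recurrent; concentration 4). Without this, ~150
  fragments per genome would make per-class LSR distributions nearly
  point masses and every model trivially perfect. The chosen concentration
  puts single-modality discrimination in the realistic 0.7–0.85 AUC range.
  Covariate effects (Gleason shift, nomogram depression, fusion-gate odds)
  are similarly scaled so that each single modality discriminates weakly.
* **Decoy fragments.** A controlled fraction (15%) of extra fragments each
  violate exactly one retention rule, so `filterSegments()` always has real
  work to do; size-passing decoys draw from the sample's own size mixture so
  filtering does not distort the calibrated fold change.

Event times are truncated-exponential within the follow-up horizon (median
10 months fast, 30 months slow — chosen so a lethal subset with recurrence
$\le 12$ months exists), non-recurrent follow-up is uniform on [90, 120]
months, and PSADT is uniform within each class's defining band. All
randomness flows from one master seed through per-sample sub-streams, so
cohorts are byte-reproducible and partially regenerable.

What the generator does **not** emulate: chromosomal placement biases,
marker-level intensities, linkage between fragment count and size, family
structure, or any real-world miscalibration of the nomogram. Passing tests
on synthetic cohorts therefore demonstrate correctness of the machinery and
recoverability of planted signal — not clinical performance on real data.

## Numerical and testing choices

* AUC is computed from midranks (Mann-Whitney with tie splitting), making it
  invariant under monotone transforms; the test suite checks it against
  exhaustive pair counting. The one-sided ROC p-value uses the normal
  approximation with tie and continuity corrections; an exact route
  (closed-form Wilcoxon null when tie-free, full enumeration otherwise) is
  available and agrees within 0.02 down to five samples per class.
* The U-test calibration check places null U values at the quantiles of the
  $|\chi^2_1 - \chi^2_1|$ distribution (obtained by Bessel-function
  quadrature: $X - Y \overset{d}{=} 2Z_1Z_2$, whose density is
  $K_0(|w|)/\pi$) rather than drawing them at random. This stratification
  removes replicate-sampling noise — with 1000 i.i.d. replicates the
  *expected* Kolmogorov-Smirnov distance of even perfectly uniform p-values
  is ≈ 0.027 — so the measured KS distance isolates estimator bias.
* Scale: tests run cohorts of 100–500 patients, cross-validation at 14
  repeats, and Monte-Carlo checks at $10^4$–$10^5$ draws; these sizes give
  each statistical assertion comfortable margins while keeping the whole
  suite quick. The planted-signal recovery check uses a coarse 0.4-step
  grid with a deliberately single-peaked AUC profile (fold 1.8,
  concentration 10), because "recovered within one grid step" is only a
  meaningful claim when the population optimum is a peak, not a plateau.

## Known limitations

* The LSR treats fragments exchangeably; no positional or gene-aware
  weighting is attempted (deliberately — gene-level association is weak in
  this setting, and the package's gene-level Fisher/KS layer exists to let
  users verify that on their own data).
* The nomogram and fusion covariates are consumed, never computed; garbage
  in, garbage out.
* The U test inherits the independence assumption discussed above.
* Totals from `mapSegmentsToGenes()` depend entirely on the supplied BED;
  no gene annotation ships with the package.
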