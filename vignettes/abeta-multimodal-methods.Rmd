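---
title: "Predicting the CSF amyloid-beta 42/40 ratio from multimodal EEG and MRI features: models and methods"
author: "AbetaMM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal prediction of the CSF amyloid ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(AbetaMM)
```

# The problem

The concentration ratio of amyloid-beta 1-42 to amyloid-beta 1-40 in
cerebrospinal fluid (CSF) is a gold-standard biochemical marker of amyloid
deposition: values at or below a clinical threshold (0.1 here) indicate the
amyloid-positive, Alzheimer-like state. Measuring it requires lumbar
puncture. AbetaMM implements a noninvasive surrogate: it extracts a
multimodal feature set — resting-state EEG descriptors, linear ventricular
atrophy indices and visual atrophy grades from structural MRI, and cognitive
scale scores — and regresses the ratio on those features with a random
forest, evaluated by leakage-free cross-validation.

Clinical cohorts of this kind are not publicly deposited, so the package
ships a seeded synthetic-cohort generator that plants the qualitative effect
structure such cohorts show. Every downstream stage is therefore testable
end to end, and all quantitative claims in the test suite refer to synthetic
data whose ground truth is known.

# Feature extraction

## Preprocessing

Recordings are band-pass filtered to 0.5–100 Hz with a zero-phase
Butterworth cascade (an order-2 high-pass and an order-2 low-pass section,
run forward and backward; cascading two low-order sections is numerically
stable at a 0.5 Hz corner on a 1000 Hz recording, where a single order-4
polynomial is not). Segments of 2000 samples in which any channel exceeds
`rejectSd` (default 7) times that channel's standard deviation are rejected;
this amplitude screen stands in for the manual/ICA artifact cleaning used on
clinical recordings, and externally cleaned data can be passed through with
`rejectSd = Inf`. Finally every retained sample is re-referenced to the
instantaneous whole-head mean, so the across-channel mean is zero at each
time point.

## Segment-averaged spectrum and band energies

The spectrum is the average over 20 consecutive non-overlapping segments of
2000 samples of the squared-magnitude FFT (rectangular window by default, a
Hann taper is available), giving 0.5 Hz resolution at 1000 Hz. Power is
one-sided and normalized so that the sum over bins equals the time-domain
mean square (Parseval), which the tests assert exactly on pure tones and
filtered noise.

Band energies sum the bins whose centre falls in delta 0.5–3, theta 3–8,
alpha 8–12, beta 12–20 or gamma 20–40 Hz. Edges are half-open
`[low, high)` — 3 Hz belongs to theta, 8 Hz to alpha, 12 Hz to beta, 20 Hz
to gamma — so the five bands tile 0.5–40 Hz and their energies sum to the
total exactly. Whether reported energies are per-channel means or whole-head
sums is a reporting convention; AbetaMM uses the per-channel mean and
records that in the output metadata. The dominant alpha frequency is the
most powerful alpha bin of the channel-mean spectrum, ties resolved toward
the lower frequency.

## Lempel–Ziv complexity

Each channel is quantized into `l` symbols (default `l = 2`, median split;
the alphabet size is configurable and quantile thresholds keep symbol
frequencies balanced). The LZ76 phrase count `c` comes from exhaustive
sequential parsing: the next phrase starting at position *i* is the shortest
continuation `s[i..j]` that does not occur as a substring of the whole
preceding sequence `s[1..j-1]`, and the trailing — possibly reproducible —
phrase is counted. This variant matters: parsing conventions differ by
plus/minus one phrase, so the package states it explicitly and the tests pin
it against an independent brute-force parser over all short binary and
quaternary strings. The normalized complexity is the standard
length-comparable form

$$C = \frac{c \, \log_l n}{n},$$

which is invariant under relabeling of the symbols. The implementation uses
an online suffix automaton, so parsing is linear in the record length.

## Histogram mutual information

Dependence between channels is the plug-in mutual information of the joint
histogram,

$$I(X, Y) = \sum_{x,y} p(x,y) \log \frac{p(x,y)}{p(x)\,p(y)},$$

with 16 bins per marginal by default and natural-log units (configurable to
bits; the log base is a units convention only). The plug-in bias is of order
$(B-1)^2 / 2n$, about 0.003 nats at the default record length. Equal-width
bins span the mean plus/minus 2.5 standard deviations with outliers clipped
into the edge bins: spending bins on extreme tails wastes resolution where
the probability mass is, and the trimmed design keeps the 16-bin
discretization loss on strongly dependent Gaussian signals below 0.05 nats
(the tests check this against the analytic value $-\tfrac12\log(1-\rho^2)$).
Equal-count (quantile) binning is available via `method = "quantile"`.
Deliberately, no bias-corrected or nearest-neighbour estimators are used:
the histogram estimator is the method under study. MI is computed on the
preprocessed broadband signals.

The region-level matrix averages the pairwise MI over all channel pairs
spanning two regions (frontal F, parietal P, left/right temporal L-T/R-T,
occipital O); within-region diagonals average distinct pairs and are
reported as missing for single-channel regions, never as zero.

## Microstates (windowed-SD variant)

EEG is short-time stationary on a 50–120 ms scale, so the recording is cut
into 100 ms windows and each channel's standard deviation within the window
is taken as its activity intensity, giving one topography per window. Note
this is deliberately *not* the classical GFP-peak, polarity-invariant
microstate analysis: the windowed-SD variant is the method implemented here.
Topographies are L2-normalized (so shape, not amplitude, drives clustering;
raw-SD clustering is available) and pooled across all subjects before
k-means. Pooling is essential: only cohort-level states make per-subject
occurrence frequencies comparable, which the correlation analysis against
the CSF marker requires. The clusterer is Lloyd's algorithm with k-means++
seeding, at least 10 restarts keeping the lowest within-cluster sum of
squares, deterministic given a seed, with nearest-centre ties resolved
toward the lowest state index; `scanMicrostates()` sweeps k over 5–20 and
reports the marker correlation per k rather than selecting k automatically
(k = 7 is the bundled default). Occurrence frequencies are proportions of
windows assigned to each state (not counts), so they sum to one per subject
regardless of how many windows survived artifact rejection.

## MRI indices and atrophy grades

Eleven caliper distances (mm) enter as plain numbers: maximal transversal
(A) and longitudinal (B) intracranial width, maximal frontal horn width (E),
minimal inter-caudate distance (F), choroid plexuses distance (J), maximal
third-ventricle width (H), temporal horn width (O), suprasellar cistern
width (P), and the corpus callosum genu/body/splenium (a, b, c). Derived
indices live in an editable formula table
(`extdata/index_formulas.csv`) whose defaults follow standard radiology
conventions — Evans ratio E/A, bicaudate ratio F/A, Huckman number E+F,
Huckman ratio (E+F)/A, third ventricular ratio H/A, ventricle index J/F,
temporal horn ratio O/A, suprasellar cistern ratio P/A — so alternative
definitions can be dropped in without code changes. The corpus callosum
distances are carried as raw features; no default index consumes them.
Visual atrophy grades (0 none, 1 sulcal dilatation, 2 gyral volume loss,
3 knife-blade atrophy) are human ratings per lobe, validated but never
computed from images. For the grade-versus-marker analysis both the signed
correlation r and its square are reported, since squaring discards the
(expected negative) direction.

# Group statistics

Group comparisons use the classical two-sample t test (pooled variance by
default; Welch selectable) at a per-comparison alpha of 0.05 with no
multiple-testing correction by default — Benjamini–Hochberg adjustment is
one argument away (`adjust = TRUE`) and recommended for exploratory scans.
The comparison between the two groups' energy-distribution curves is a
paired t test across frequency bins of the group-mean spectra: pairing by
bin is the only pairing structure available between groups of unequal size.
A constant non-zero bin-wise difference has zero variance and is reported as
an exact difference (p = 0) flagged degenerate rather than tested. Band
comparisons are channel-averaged, matching the mean-energy convention above.

# Prediction

Features are ranked by the absolute Pearson correlation with the marker and
the top K kept (default 500, capped at the number of available features —
synthetic cohorts produce fewer features than a full clinical feature
inventory; the assembled count is recorded in the export metadata). The
regressor is a random forest of 100 bootstrap-aggregated trees with at least
5 observations per leaf and default per-split feature subsampling; the
error-versus-trees sweep (`maeVsTrees()`) reproduces the flattening curve
that motivates the 100-tree default.

Cross-validation is sevenfold, stratified on the positivity label, with
seeded fold assignment. Published descriptions of such pipelines are
ambiguous about whether feature ranking happens once globally or inside each
fold; a global ranking leaks target information from the test folds, so
AbetaMM re-ranks inside every training fold by default and exposes the
optimistic variant only behind an explicit `leakyRanking = TRUE` flag for
comparison. Reported fold counts also vary between cohort descriptions
(seven folds on the EEG-complete cohort, eight on a smaller joint subset);
the fold count is fully configurable with seven as the default. Subjects
with incomplete modalities are retained for modality-specific statistics but
excluded from joint prediction, mirroring a cohort whose EEG-complete and
joint-complete subsets differ.

Metrics: MAE; the normalized error MAE / (max − min of the true values);
accuracy defined as 1 − normalized error (this definition is printed in the
output metadata, since "accuracy" is otherwise ambiguous for a regression);
and the ROC/AUC of classifying amyloid positivity from the predicted values,
sweeping a cut over predictions and integrating by the trapezoid rule.
A mean-of-training-targets baseline is always carried along: a model is only
interesting if it beats it.

# The synthetic cohort generator

`generateCohort()` draws a cohort that emulates the statistical structure
the pipeline is designed to detect; `effectConfig()` holds the knobs.

* **Marker distribution.** A two-component log-normal mixture straddling
  the 0.1 threshold (positive component around 0.04, negative around 0.15,
  positive weight 47/82), truncated to `ratioRange` (2e-5–0.25). The
  defaults keep both groups populated at the clinical threshold, which every
  group analysis requires, with the positive-to-negative imbalance typical
  of memory-clinic cohorts.
* **Disease weight.** Effects enter through
  `w(ratio) = plogis((log 0.1 − log ratio)/0.5)`, ~1 deep in the positive
  range and ~0 deep in the negative range. A continuous weight (rather than
  a binary group effect) makes the marker learnable by regression while
  still producing group contrasts.
* **EEG.** Each channel is a sum of band-limited noise (alpha-dominant
  resting profile: delta/theta/alpha/beta/gamma RMS 4/3/6/2.5/1.5 uV, a 1 uV
  broadband floor, 8% per-subject band jitter and 5% per-channel gain
  jitter), synthesized in the frequency domain. A filtered-noise-plus-
  templates model was chosen over neural-mass models: only the statistical
  structure the features measure needs to be emulated. Beta and gamma
  amplitudes shrink by up to `betaGammaEnergyDeficit` (default 20% in
  energy) as w rises. Frontal/parietal channels re-route up to
  `complexityDeficit` (20%) of their broadband power into narrowband alpha —
  an energy-preserving swap that lowers Lempel–Ziv complexity without
  changing total energy. Latent broadband sources shared between
  frontal/left-temporal and occipital/right-temporal channels carry the
  between-region coupling; their amplitude shrinks with w
  (`miDeficit`, 30%), and the channel's own power is reduced accordingly so
  coupling changes are not confounded with energy changes. A weak global
  source gives every region pair a nonzero baseline MI.
* **Microstates.** Seven smooth channel-gain templates switch every
  ~100 ms, jittered ±20 ms so extraction windows and planted states are not
  artificially aligned; the first template's occurrence probability falls
  with the marker (`microstateCoupling`). The modulation depth (0.9) is set
  so that between-template separation comfortably exceeds the sampling noise
  of a within-window SD estimate (~7% at 100 samples), i.e. the planted
  states are recoverable by design.
* **MRI and scales.** Grades per lobe are cut from a latent normal coupled
  to the negated log marker; the latent correlation is inflated analytically
  for the discretization loss (from the fixed cut points) and empirically
  for the log-to-raw nonlinearity, so the realized grade-marker squared
  correlation matches `atrophyR2` (default 0.2) in expectation. Linear
  measurements are drawn in physiologic millimetre ranges with mild
  ventricular-enlargement coupling, scale scores (MMSE/MoCA-like) decline
  with w; both couplings have their own multipliers (`mriEffect`,
  `scaleEffect`) so a fully null cohort is one configuration away. A
  configurable number of subjects (5 of 82) lack MRI and scales, so the
  joint-modality subset is smaller than the EEG cohort, as in real data.
* **Duration.** 52 s at 1000 Hz: twenty 2000-sample spectrum segments plus
  a six-segment margin so amplitude-based rejection of a few segments never
  starves the spectrum stage (clinical protocols record several minutes for
  the same reason).

Determinism: everything is driven by one master seed through fixed derived
streams (one per modality, one per subject's EEG), so cohorts are
reproducible bit for bit, including the written EDF files.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real artifact morphology (only amplitude outliers
are screened), volume-conduction field spread and electrode geometry
(regions are label sets, not positions), non-Gaussian EEG microstructure,
1/f spectral slopes beyond the five-band profile, absolute energy scales in
microvolts squared (amplifier-dependent; only directions and detectability
are planted), demographic covariates, and any longitudinal structure.
Results on synthetic cohorts demonstrate that the pipeline recovers planted
effects of realistic size, not that such effects exist in any particular
clinical population.

# Numerical and testing choices

* EDF export quantizes to 16 bits against an 8-character ASCII physical
  range; the codec scales with the range as written, so write/read
  round-trips are exact up to one quantization step and byte-identical
  across runs.
* MI terms are accumulated in sorted order, making the estimator exactly
  symmetric in its arguments rather than symmetric up to floating-point
  summation order.
* k-means empty clusters are re-seeded at the point farthest from its
  centre; convergence is declared when assignments stop changing or the
  centre shift falls below 1e-10.
* Fold assignment continues a single counter across strata so no fold is
  ever empty when subjects outnumber folds.
* Degenerate inputs are flagged, not guessed at: constant features rank
  last with a warning, constant grades or occurrences yield NA correlations,
  constant truth makes normalized error undefined.
* Test problem sizes: the heavy cohort-level checks run on the standard
  19-channel clinical montage (`extdata/montage19.csv`) — the 64-channel
  montage is the pipeline default — with 82-subject cohorts for the
  end-to-end prediction checks (20 seeds), 200-subject cohorts (8
  replicates) for the power study of the planted beta/gamma-energy and
  frontal/parietal-complexity deficits, 200 replicate cohorts for the
  atrophy-correlation recovery, and 10,000 simulated nulls for test
  calibration. Subject counts of 82 (EEG-complete), 77 (joint subset) and
  63 (an alternative joint inventory) appear in cohort descriptions of this
  kind; the package treats all such counts as data-dependent, never as
  constants.

# Known limitations

* The amplitude screen is no substitute for ICA-based artifact removal on
  real recordings; an extension hook (`rejectSd = Inf`) accepts externally
  cleaned data instead.
* The plug-in MI estimator is biased upward under independence by
  ~$(B-1)^2/2n$; at the default record length this is negligible, but short
  records with many bins will show inflated coupling.
* Classical polarity-invariant microstate analysis is out of scope; results
  are not comparable to GFP-peak microstate literatures.
* No covariate adjustment or mixed models: group tests are plain two-sample
  comparisons at a per-test alpha.
* With ~85 synthetic features the top-K cap (500) is never active; on real
  feature inventories (thousands of per-channel features) ranking matters
  much more, and the leakage-free default is then essential.
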