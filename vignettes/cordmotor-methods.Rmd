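---
title: "Methods: spared-cord imaging markers and scES motor outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spared-cord imaging markers and scES motor outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmotor)
```

`cordmotor` studies whether the amount and location of spared spinal-cord
tissue relates to how much volitional leg movement a person with
motor-complete spinal cord injury regains under epidural stimulation (scES).
This vignette records the models, parameters and design decisions behind
each stage, and what the synthetic-data tests do and do not establish.

## Lesion quantification

Subjects are represented by binary cord and lesion masks on a common
template-space voxel grid (the cord mask includes the lesion; PAM50-like
0.5 mm isotropic voxels by default). The lesion is collapsed along the
superior–inferior axis by **logical union** into a single composite axial
image: a pixel is lesioned if the lesion occupies that axial position on any
slice. A fractional-occupancy projection (mean along the axis) was the main
design alternative; the union was chosen because the downstream statistic is
defined on one composite lesion image, and the union makes the monotonicity
property exact — adding a lesion voxel can never increase any spared
percentage.

Percent spared tissue of a region with per-pixel weights $w_r$ is

$$\mathrm{spared}_r \;=\; 100\,
  \frac{\sum_p w_r(p)\,\mathbf{1}[p \notin L]}{\sum_p w_r(p)},$$

with $L$ the projected lesion. Five values are reported: whole cord
("total", the full axial cord mask including grey matter — the published
figures colour the entire cross-section, and a union-of-regions variant
remains available via `spared_profile(..., total = "regions")`), plus
anterior, posterior, left-lateral and right-lateral sectors. Whether the
original analysis weighted pixels by atlas probability or binarized the
tract maps is not stated in the source material; both are supported
(`weighting = "binary"` or probabilistic weights read from NIfTI), and the
oracle-equivalence tests cover both.

The packaged sector atlas divides the cord ellipse into four 90° wedges
centred on the anatomical axes, with half-open angular intervals so binary
weights partition the cord exactly. A consequence worth knowing: pixels
lying exactly on a 45° diagonal belong wholly to one sector, so a
geometrically perfect half-cord lesion splits the two adjacent sectors into
"close to half" rather than exactly half (the tests document this).

`slicewise_align` is a deliberately simple per-slice rigid alignment
(centroid translation plus isotropic area-matching scale,
$s=\sqrt{A_\mathrm{template}/A_\mathrm{subject}}$, nearest-neighbour
resampling). It exists so phantom studies can exercise a
subject-to-template step; real nonlinear registration of clinical images is
out of scope and delegated to dedicated tooling. Analysis inputs are assumed
already in template space.

## EMG activation

Signals are acquired at 2 kHz and band-pass filtered 30–1000 Hz. The filter
is a 4th-order Butterworth applied forward–backward (zero phase); the design
is a package choice, as the original hardware filter is unspecified beyond
its band. At 2 kHz sampling the nominal 1000 Hz edge coincides with Nyquist,
where no digital band edge can sit, so edges at or above Nyquist are clipped
to 0.999 × Nyquist with a warning.

Volitional activation of a muscle in one attempt is
$\Delta\mathrm{RMS} = \mathrm{RMS}_\text{attempt} -
\mathrm{RMS}_\text{background}$, computed over the whole attempt window and
a fixed-duration resting window immediately before it (default 1 s;
only "prior to the attempt" is specified by the protocol). Negative values
are meaningful — volitional *suppression* of ongoing activity is a reported
phenomenon — and are never clamped.

Normalization divides ΔRMS by the muscle's largest evoked-potential
peak-to-peak amplitude from a recruitment curve: stimuli at 2 Hz, five per
intensity, peak-to-peak responses averaged within intensity, maximum taken
across intensities. The evoked-response window is 5–95 ms post-stimulus
(configurable); the protocol's exact window is unstated, and this default
fits inside the 500 ms inter-stimulus interval. Channels whose maximal
evoked response falls below 1e-6 mV cannot be normalized; they are flagged
and excluded, never silently zeroed. Because ΔRMS and the evoked maximum
scale identically with channel gain, normalized activation is invariant to
amplifier gain — a property the tests assert.

## Co-contraction (JPD quadrants)

For an agonist/antagonist pair (iliopsoas vs. medial hamstrings in flexion;
tibialis anterior vs. soleus in dorsiflexion) each time point contributes a
point to the joint distribution of the two amplitude envelopes. Ten percent
of the largest amplitude detected during the attempt defines the activity
threshold; the four regions (isolated A, isolated B, co-contraction high,
co-contraction low) are reported as percentages of time points, summing
to 100.

Two interpretive decisions, both flagged in the interface: the threshold is
**per muscle** (10% of that muscle's own maximum) because rectangular
quadrant regions require per-axis thresholds; a single joint-maximum
threshold is retained behind `per_muscle = FALSE`. Samples exactly at
threshold count as inactive (strict `>`), which makes the degenerate rule
fall out naturally: when neither muscle shows any activation (both maxima
below a 1e-9 floor), the attempt is 100% co-contraction at low activation —
the one worked rule stated by the protocol, and acceptance target `t1`.

The envelope estimator (moving RMS of the filtered signal, 50 ms window,
edge windows shrunk to the available samples) is a declared stand-in; the
original analysis cites prior methods without parameters.

## Association statistics

The cohort table holds 5 MRI percent variables and up to 39 motor outcomes
tagged `count`, `binary` or `continuous`. The ledger is:

1. **Zero-variance exclusion** — uninformative columns dropped and logged.
2. **Screening** — Spearman rank correlation (average ranks, two-sided
   asymptotic p) for every (MRI, motor) pair; a pair is "correlated" when
   $|\rho| \ge 0.4$ and $p < 0.05$ (the "not weakly correlated" cutoff is
   unstated in the source; both knobs are configurable and recorded in
   provenance). In parallel, Boruta importance: in each of 100 iterations
   every MRI variable is duplicated as a permuted shadow, a 500-tree random
   forest (ranger, permutation importance, single-threaded for
   reproducibility) is fitted, and a variable scores a hit when its
   importance exceeds the largest shadow importance; hits are judged by a
   two-sided binomial test against Binomial(100, ½) at α = 0.01.
3. **Retention** — an MRI variable is kept iff correlated-or-important for
   at least one motor outcome; a motor outcome is kept iff at least one MRI
   variable is correlated or important for it.
4. **Family-dispatched GLMs** — Poisson for counts, logistic for binaries,
   linear otherwise; univariable fits select significant predictors at
   α = 0.05 (the source reports p = 0.014–0.017 as significant without
   stating α; 0.05 is the conventional reading and configurable).
5. **Multivariable + bagging** — significant predictors are combined into
   one model per motor outcome and refitted on B = 1000 bootstrap copies of
   the rows; the ensemble mean is the adjusted estimate, the ensemble SD its
   SE, and a two-sided p-value comes from the normal approximation on
   mean/SD (how the original bagged p-values were derived is unstated).
   The outcome's family is kept under bagging; the alternative reading
   (bagging linear models regardless of family) is noted as ambiguous in
   the source description. Degenerate resamples — rank-deficient designs or
   a predictor collapsing to one value — are redrawn and counted, with an
   abort beyond 10 × B redraws. Rank deficiency and logistic separation in
   direct fits are flagged on the result, not fatal. No multiple-testing
   correction is applied, mirroring the source analysis; a
   Benjamini–Hochberg step could be added by the user on the report table.

With 13 subjects, missing values are handled by listwise deletion per fit.

### Small-sample behaviour of the Boruta shadow test

A property discovered and characterized while validating this module, and
worth stating plainly: the binomial reference of the hit test assumes the
per-iteration hits are independent coin flips, but only the shadows are
re-randomized across iterations — the dataset itself is fixed. Each
variable's hit probability therefore concentrates on a dataset-specific
value. With only five candidate predictors, the max-of-five-shadows bar is
weak (shadows the forest never uses get near-zero permutation importance),
so in a **null** dataset the variable with the strongest chance association
can clear the bar persistently and end up confirmed. Empirically, at the
study scale (n = 13, five predictors) roughly a third of null datasets
yield at least one spurious confirmation; the effect fades by n ≈ 200. It is
not an artifact of this implementation — Z-scaled importance behaves
identically, impurity importance is worse on both error types, and a fixed
permuted decoy column behaves exactly like a real one, so fixedness rather
than realness drives it. The corresponding acceptance check of null-data
quietness is left failing rather than weakened; practically, Boruta
confirmations at this cohort size should be read as "worth a look", not as
error-controlled inferences, and the GLM stage downstream — whose null
calibration *is* verified — carries the inferential weight.

### Null calibration of the report

The type-I property test runs the report with screening in pass-through
configuration (`alpha_screen = 1`, `rho_min = 0`, Boruta off) so that every
pair reaches the GLM stage: only then does "per-pair significant rate
≈ α" have a defined meaning, since any upstream screen at the same α
necessarily deflates the end-to-end rate below α. Calibration uses
continuous outcomes (exact t-based p-values under normality); Poisson and
logistic Wald p-values at n = 13 are approximate by construction. Over 200
null cohorts (5 MRI × 10 motor variables), the observed rate must lie
within α/2 of α = 0.05 — wide enough for the residual deflation from
pairing the univariable selection with the bagged adjusted test, tight
enough to catch broken or anti-conservative behaviour.

## Synthetic data: what it emulates, and what it does not

- **Phantoms**: elliptical cord cross-sections with box/ellipse lesion
  primitives whose projected footprints have exact pixel enumerations —
  the independent oracle computes spared fractions from the primitives
  alone, never via the mask pipeline. Phantoms emulate lesion *geometry*
  only: no MR intensities, no T2 hyperintensity, no registration error.
- **EMG**: Gaussian background + rectangular-envelope 150 Hz sine burst in
  the attempt window + biphasic evoked pulses (half-sine lobes of 2 ms at
  +0.6/−0.4 of the sigmoid amplitude, so peak-to-peak equals the sigmoid
  value; 10 ms onset latency) with amplitude following a logistic
  recruitment curve. The 2 ms lobe width is a deliberate choice: the
  band-pass transmits such a pulse with ~0.2% peak-to-peak loss, so the
  noiseless chain-recovery bound of 1% is meaningful. Real EMG
  nonstationarity, motion artifact, and stimulation artifact are not
  modelled — passing tests certify the computational chain, not robustness
  to those nuisances.
- **Cohorts**: MRI variables uniform on 0–100%; motor outcomes generated
  from identity/log/logit-link models with planted coefficients. The default
  study conditions are 13 subjects and three planted linear effects at the
  reported magnitudes (−0.02, 0.65, −0.987 per percent spared) with noise
  calibrated so the coefficient SEs land at the reported scale
  (σ = SE·sd(x)·√n gives 1.0, 23 and 35), plus a null Poisson task count at
  intercept log 2.7 and a null binary outcome. The weakest effect sits near
  its detection limit at n = 13 by construction — as in any real
  13-subject cohort.

Reproducibility: every generator and every stochastic analysis stage takes
one integer seed; sub-streams per subject/channel/motor-variable are derived
deterministically, so adding a variable does not perturb the others, and a
`run_config` seed reproduces an entire simulate-plus-run bit for bit.

## Problem sizes used by the test suite

Oracle equivalence runs 50 seeded phantoms on 48×48×12 grids; monotonicity
grows 20 phantom lesions voxel by voxel; the EMG chain checks three
noiseless sessions; JPD equivalence uses 100 random envelope pairs; bagged
recovery uses 50 cohorts of 13 subjects at B = 1000; null calibration uses
200 cohorts; the Boruta checks use the n = 200 recovery construction and 100
null datasets at the study scale. These sizes were chosen to give stable
Monte-Carlo verdicts at interactive runtimes.

## Known limitations

- Registration is out of scope; `slicewise_align` is a phantom-grade
  stand-in and must not be used on clinical images.
- The JPD threshold interpretation (per-muscle vs. joint maximum) is
  ambiguous in the source; both are implemented, per-muscle is default.
- Boruta at n = 13 with five predictors over-confirms on null data (see
  above); treat its output as screening, not inference.
- Poisson/logistic Wald p-values at n = 13 are approximate; the bagged
  normal-approximation p-values inherit that approximation.
- Synthetic cohorts draw MRI variables independently; real spared-tissue
  measures are correlated across regions, which screening and multivariable
  adjustment would feel as collinearity.
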