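# cordmotor

Quantitative pipeline linking spared spinal-cord tissue, measured from
template-space lesion masks, to the recovery of volitional leg movement
enabled by spinal cord epidural stimulation (scES) in motor-complete spinal
cord injury.

After severe spinal cord injury, some individuals regain volitional leg
movement when lumbosacral epidural stimulation is applied, and the extent of
recovery varies widely. One candidate explanation is the amount and location
of spared tissue at the lesion. `cordmotor` implements the full analysis
chain needed to test that hypothesis:

1. **Lesion quantification** (`spared_profile`): the 3-D lesion mask is
   projected onto the axial plane by logical union along the
   superior–inferior axis, giving one composite lesion image. Percent spared
   tissue is scored against an axial region atlas for the whole cord and for
   the anterior, posterior, left-lateral and right-lateral white-matter
   sectors:

   `spared_r = 100 × Σ_p w_r(p) · [p not lesioned] / Σ_p w_r(p)`

   where `w_r` are per-pixel region weights (binary or probabilistic).
2. **EMG activation** (`session_activation`): signals are band-pass filtered
   (30–1000 Hz zero-phase Butterworth); volitional activation is
   ΔRMS = RMS(attempt) − RMS(resting background), normalized by the largest
   evoked-potential peak-to-peak amplitude from a stimulation
   recruitment curve (5 stimuli per intensity, averaged per intensity).
3. **Co-contraction** (`jpd_quadrants`): the joint probability density of two
   muscles' amplitude envelopes is split into four regions by per-muscle
   thresholds at 10% of each muscle's attempt maximum — isolated activation
   of either muscle, co-contraction at high or at low activation — and the
   percentage of time points in each region is reported. An attempt with no
   detected activation in either muscle is, by definition, 100%
   co-contraction at low activation.
4. **Association statistics** (`build_report`): zero-variance variables are
   dropped; (MRI, motor) pairs are screened by Spearman correlation and by a
   Boruta shadow-feature importance test (random-forest permutation
   importance vs. permuted copies, binomial hit test); retained motor
   outcomes are fitted with family-dispatched GLMs (Poisson for task counts,
   logistic for binary outcomes, linear otherwise); individually significant
   MRI predictors are combined into a multivariable model whose coefficients
   are **bagged** over 1,000 bootstrap copies — the ensemble mean is the
   adjusted estimate and the ensemble SD its SE.

Because no clinical MRI or EMG data are distributed, the package ships a
first-class synthetic-data module (`make_cord_phantom`, `make_emg_session`,
`make_cohort`) whose outputs carry analytically known ground truth, so every
stage is verifiable end to end.

## Worked example

Simulate a 13-subject study (phantom lesions, EMG sessions, and a cohort
with three planted linear effects of −0.02, 0.65 and −0.987 per percent
spared — the magnitudes reported for anterior/right/total cord associations
with soleus activation and flexion coordination) and run the full pipeline:

```r
library(cordmotor)
cfg <- run_config(seed = 11, out_dir = "demo")
cm_simulate(cfg)
report <- cm_run(cfg)
print(report)
#> <association_report> n = 13, alpha = 0.05, B = 1000, seed = 41978709
#>   retained: 2 MRI x 3 motor variables
#>   significant associations (adjusted):
#>                motor       mri adj_estimate adj_se  adj_p
#> 1 motor_jpd_coco_low mri_total       -0.851  0.347 0.0142
#> 2     motor_jpd_r_mh mri_right        0.625  0.268 0.0200
```

At this seed the screening-and-regression ledger recovers two of the three
planted effects: low-level co-contraction decreases by 0.851 percentage
points per percent of total cord spared (planted −0.987), and isolated
hamstrings activation increases by 0.625 per percent of right-lateral cord
spared (planted 0.65); the weakest planted effect (−0.02, near its
detection limit at n = 13 by design) is missed here. Stage artifacts land in
`demo/derived/`: per-subject spared-tissue profiles (which match the
generator's ground truth exactly), normalized activations, JPD quadrant
percentages, and the report CSVs with a provenance block.

The same verbs are available from a shell:

```sh
Rscript inst/cli/cordmotor.R simulate --seed 11 --out demo
Rscript inst/cli/cordmotor.R run      --seed 11 --out demo
```

## Scope notes

Inputs to lesion quantification are assumed to be in template space;
nonlinear registration of clinical images belongs to external tooling (e.g.
the Spinal Cord Toolbox), and `slicewise_align` is a deliberately simple
centroid-and-scale per-slice stand-in used for phantom work. The methods
vignette (`vignettes/cordmotor-methods.Rmd`) documents the model choices,
defaults, and known limitations, including the small-sample behaviour of the
Boruta shadow test.
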