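# lumbarstretch

Trunk flexion and rotation are established physical risk factors for
occupational low back pain, but optical motion capture — the reference method
for measuring lumbar angles — only works inside a camera volume. A practical
alternative mounts four thin capacitive sheet stretch sensors on the lower
back (two vertical at the L5 level, two oblique at 45°) and converts their
length displacements into tri-axial lumbar angles. `lumbarstretch` implements
that estimation chain, the marker-based reference kinematics it is validated
against, the agreement statistics, and a trial-structured simulator so the
whole pipeline can be exercised end-to-end without any recorded data.

## The estimator

With channel displacements Δl₁, Δl₂ (vertical right/left) and Δl₃, Δl₄
(oblique right/left), each offset to trial start, the crosstalk-adjusted
oblique channels are Δl′₃ = Δl₃ − Δl₁ and Δl′₄ = Δl₄ − Δl₂ (the verticals
carry the flexion and side-bending loading that the obliques share, so the
subtraction isolates rotation). The three angle estimates are fixed linear
features scaled by per-direction calibration coefficients:

    Δθ̂_FX = α₁ · (Δl₁ + Δl₂) / 2
    Δθ̂_SB = α₂ · (Δl₁ − Δl₂)
    Δθ̂_RT = α₃ · (Δl′₃ − Δl′₄)

α₁, α₂, α₃ (deg/mm) are least-squares slopes (through the origin by default)
of the reference angles on the features over the first 10 s of each trial.
The reference angles come from ten anatomical markers: pelvis and trunk
frames are built from the ASIS/L5/coccyx and acromion/C7/L1 landmarks, and
the relative rotation is decomposed with a Cardan X–Y–Z
(flexion – lateral bending – rotation) sequence. Both streams are offset to
trial start and low-pass filtered with a zero-phase 4th-order Butterworth
filter at 10 Hz.

Agreement is quantified per trial and axis by range of motion (ROM), RMS
error, Pearson correlation, the error ratio (RMS as % of ROM, restricted to
trials with ROM above two-thirds of the subject's maximum), and Bland–Altman
limits of agreement on paired ROM measurements.

## Worked example

```r
library(lumbarstretch)

cfg   <- sim_config(seed = 42)                  # default study conditions
trial <- simulate_study(cfg, n_subjects = 1)[[1]]  # flexion trial
res   <- run_pipeline(trial$markers, trial$sensors)
res$calibration
#> Stretch-sensor calibration model
#>   window: [0, 10) s  (1000 samples)
#>   alpha1 (flexion-extension): 1.1128 deg/mm
#>   alpha2 (side-bending):      0.1959 deg/mm
#>   alpha3 (rotation):          0.2442 deg/mm

evaluate_trial(res$reference, res$estimated, subject = 1, trial = 1,
               condition = trial$condition)[, c(4:8)]
#>     axis rom_actual_deg rom_est_deg rms_error_deg pearson_r
#> 1 fx_deg         44.829      46.541         1.078    0.9994
#> 2 sb_deg          0.550       0.483         0.152    0.0335
#> 3 rt_deg          0.504       0.690         0.180    0.0176
```

The fitted α₁ ≈ 1.113 deg/mm inverts the simulator's 0.9 mm/deg vertical
flexion gain; the flexion estimate tracks the 44.8° ROM reference with ~1°
RMS error and r ≈ 0.999, while the inactive axes show only noise-scale
residuals (and correspondingly meaningless correlations — the same pattern
the agreement tables show for small-ROM movements).

A full synthetic study (6 subjects × 7 movement conditions) and its summary:

```r
report <- run_study(cfg, n_subjects = 6)
report$overall[, c("axis", "rms_error_deg_mean", "pearson_r_mean")]
#>     axis rms_error_deg_mean pearson_r_mean
#> 1 fx_deg               0.68          0.574
#> 2 sb_deg               0.56          0.569
#> 3 rt_deg               0.49          0.418
```

Overall per-axis RMS errors sit well below the 3° accuracy bound that makes
the sensor clinically useful, and the Bland–Altman biases on per-trial ROM
are under 1° with at most a couple of the 42 pairs outside the limits of
agreement.

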