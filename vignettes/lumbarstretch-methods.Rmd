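---
title: "Estimating tri-axial lumbar angles from sheet stretch sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tri-axial lumbar angles from sheet stretch sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbarstretch)
```

## The measurement problem

Lumbar flexion-extension, side-bending and axial rotation are the movement
directions most implicated in occupational low back pain, and monitoring
them outside a motion-capture volume requires a wearable measurement. Four
thin capacitive stretch sensors on the lower back — two mounted vertically
100 mm left and right of the midline at the L5 level, two obliquely at 45°
from L5 toward the mid-back, all with a 70 mm mounted length — stretch with
the skin, and their length displacement is, to a good approximation, linear
in the underlying joint angles. That linearity is the entire premise of the
estimator; everything in this package either exploits it, calibrates it, or
quantifies how far real(istic) signals depart from it.

## The estimation model

Let $\Delta l_1,\Delta l_2$ be the vertical channels (right, left) and
$\Delta l_3,\Delta l_4$ the obliques, all offset to trial start. The skin
over the obliques is stretched by flexion and side-bending too, so the
obliques are first crosstalk-adjusted by subtracting the ipsilateral
vertical channel:

$$\Delta l'_3 = \Delta l_3 - \Delta l_1,\qquad
  \Delta l'_4 = \Delta l_4 - \Delta l_2 .$$

The three estimated angular displacements are single-coefficient linear
maps of fixed channel combinations:

$$\hat\theta_{FX} = \alpha_1\,\frac{\Delta l_1+\Delta l_2}{2},\qquad
  \hat\theta_{SB} = \alpha_2\,(\Delta l_1-\Delta l_2),\qquad
  \hat\theta_{RT} = \alpha_3\,(\Delta l'_3-\Delta l'_4).$$

The symmetry logic: flexion stretches both verticals equally (mean),
side-bending stretches one and shortens the other (difference), rotation
moves the obliques antisymmetrically once their shared loading is removed.
The coefficients $\alpha_1,\alpha_2,\alpha_3$ (deg/mm) are least-squares
slopes of the reference angle on the corresponding feature over the first
10 s of each trial (1000 samples at 100 Hz, half-open window $[0,10)$ s).
The default regression is through the origin: the estimator has no
intercept term and both streams are displacement-zeroed at trial start. An
ordinary-least-squares option (`include_intercept = TRUE`) is provided
because a practitioner may prefer it when the zeroing frame is noisy.

Two estimator choices were genuinely open and are configurable:

* **Oblique pairing.** Which vertical is subtracted from which oblique is
  not dictated by the model; ipsilateral pairing (right from right) is the
  geometric default, with `contralateral` and `mean` alternatives
  (`adjust_oblique(pairing = ...)`).
* **Calibration scope.** Calibration is per trial — each trial's first 10 s
  — which matches a short re-zeroing routine before each recording bout.
  Cross-trial calibration can be emulated by passing one trial's
  `calibration_model` to `estimate_angles()` on another recording.

## Reference kinematics

The optical reference uses ten markers: C7, both acromions, an L1-level
triad, both ASIS, L5 and the coccyx. Per frame:

* pelvis frame: $\hat x$ from left to right ASIS; provisional $\hat y$ from
  the L5/coccyx midpoint to the ASIS midpoint; $\hat z=\hat x\times\hat
  y_0$, $\hat y=\hat z\times\hat x$;
* trunk frame: $\hat x$ from left to right acromion; provisional $\hat z$
  from L1 up to C7; $\hat y=\hat z_0\times\hat x$, $\hat z=\hat
  x\times\hat y$;
* relative rotation $R = P^\top T$, decomposed with the Cardan X–Y–Z
  sequence $R = R_x(\theta_{FX})R_y(\theta_{SB})R_z(\theta_{RT})$, i.e.
  $\theta_{SB}=\arcsin R_{13}$, $\theta_{FX}=\operatorname{atan2}(-R_{23},
  R_{33})$, $\theta_{RT}=\operatorname{atan2}(-R_{12},R_{11})$.

The frame constructions use only the listed landmarks, reduce exactly to
the identity in the neutral template pose, and are validated by a
compose-then-decompose round trip and by invariance to a common rigid
rotation of all markers. Angles are reported as displacements (zeroed at
frame 0) to match the sensor convention. A decomposition with
$|R_{13}|>1-10^{-6}$ (side-bending within ~0.08° of 90°) raises a
gimbal-lock error rather than clamping — that regime is far outside lumbar
range and indicates corrupted input. The L1-triad lateral markers and the
remaining landmarks are validated for presence but not used by the math;
they stay in the data model for format fidelity with the marker set.

## Preprocessing

Both marker-derived and sensor streams are offset by the first frame and
low-pass filtered with a 4th-order Butterworth design at 10 Hz (design via
`signal::butter`), applied forward and backward for zero phase lag — phase
lag would bias the regression between the streams. `order = 4` refers to
the one-pass design; the two-pass magnitude response is its square. Edges
use odd-reflection padding of $3\times\text{order}$ samples with
step-steady-state initial conditions, which makes the filter exactly
DC-transparent (a constant series is returned bit-for-bit to $10^{-9}$)
and keeps edge transients of passband signals below $10^{-3}$ of
amplitude. At the movement frequency of the protocol (0.125 Hz, i.e.
$f/f_c=0.0125$) the magnitude response is 1 to machine precision, so
filtering is effectively an identity on the signal and a variance reducer
on the noise.

One ordering subtlety matters numerically. The pipeline's default filters
the marker-**derived** angle series (then re-zeroes at frame 0) rather
than the marker coordinates. Filtering coordinates first is nearly
equivalent — the two routes differ by under $2\times10^{-4}$ degrees,
edge-localized — but the residual it leaves is *not* shared with the
sensor stream (the angle computation is nonlinear), and the frame-0
re-zeroing propagates a constant of that size along the whole trial. With
the default, reference and sensor streams pass through the identical
linear operator, which is exactly the premise of the linear calibration:
in the noise-free limit the pipeline then recovers the true angles to
$\sim10^{-14}$ degrees. `run_pipeline(marker_filter = "coordinates")`
selects the other reading. Similarly, the sensor channels are offset
before filtering (displacement convention) and re-zeroed after it, since
zero-phase filtering re-introduces a tiny nonzero first frame.

## The synthetic study

`simulate_study()` generates the full validation protocol: 6 subjects × 7
movement conditions, 30 s trials at 100 Hz, metronome-paced movement at
0.125 Hz. Three conditions are uniaxial (flexion, side-bending, rotation),
three drive two axes in phase, and the circumduction condition drives
flexion and side-bending in quadrature (a circle in the FX–SB plane). Each
active axis follows $A\sin(2\pi f t+\varphi)$ — the simplest periodic
model consistent with a metronome-paced smooth movement — with half-ROM
amplitudes defaulting to half the protocol's mean per-condition ROM values
(e.g. 16.91° for the flexion trial, so the peak-to-peak ROM is 33.82°).
Inactive axes are identically zero; real movements leak into off-target
axes, which is one reason measured small-ROM correlations are low, and the
simulator reproduces that effect through sensor crosstalk and noise rather
than through the trajectory itself.

Markers are generated by rigidly rotating the trunk landmarks of a neutral
template about the lumbar joint center by
$R_x(\theta_{FX})R_y(\theta_{SB})R_z(\theta_{RT})$, pelvis landmarks held
static, plus optional i.i.d. Gaussian coordinate noise. The template is
bilaterally symmetric, sized for a ~1.67 m adult, and built so both
anatomical frames are exactly the identity in neutral pose — this makes
the simulator round trip (angles → markers → angles) an exact oracle.
Global axes: X to the subject's right, Y anterior, Z cranial; positive
angles are forward flexion, right bend, right rotation. The sign
convention is absorbed by calibration and has no effect on agreement
statistics.

Sensor channels follow the linear forward model
$\Delta l(t) = G\,\theta(t) + d\,t + \varepsilon(t)$ with gain matrix $G$
(mm/deg), drift rate $d$ and i.i.d. Gaussian noise $\varepsilon$. The
default $G$ encodes the mounting geometry: vertical flexion gain
0.9 mm/deg (equal signs), vertical side-bending gain ±0.35 mm/deg,
oblique rotation gain ±0.5 mm/deg, a rotation crosstalk on the verticals
of 0.15 × their flexion gain, and oblique rows equal to the ipsilateral
vertical row plus the rotation term — so the crosstalk adjustment cancels
the shared loading exactly. These magnitudes are invented but stated,
overridable, and chosen so protocol-scale angles stay within the 100%
dynamic range of a 70 mm sensor. Drift (default −0.05 mm/s, i.e. −1.5 mm
over a trial) emulates the slow loss of mounting pre-strain, the error
mechanism that makes the sensor underestimate large flexion; its magnitude
is a free parameter because no measured value exists. Sensor noise SD
defaults to 0.5 mm — a third of the sensor's reported worst-case length
error — and marker noise to 0.5 mm, typical for optical capture.
Between-subject ROM spread is emulated by multiplying each subject's
active-axis amplitudes by lognormal jitter (sdlog 0.2, median 1); this
reproduces the scale of between-subject SDs without claiming a generative
model for them. The capacitance map $C = c_0 (l/l_0)^2$ (areal-strain
linearity at constant width) is provided as an explicit, invertible step;
the pipeline itself works in length displacement.

All randomness flows from `config$seed`: jitter and per-trial noise seeds
are drawn once from the master stream, so identical configurations produce
bit-identical studies.

**What passing on synthetic data does and does not show.** The simulator
satisfies the estimator's linearity premise by construction (plus noise,
drift and crosstalk), so end-to-end accuracy here demonstrates internal
consistency of the chain — calibration, filtering, decomposition, and
statistics — not field accuracy on skin. Real skin stretch is
history-dependent and nonlinearly coupled across directions; those effects
are deliberately out of the forward model's scope.

## Validation statistics

Per trial and axis: ROM (max − min), RMS of the residual between estimated
and reference series, and Pearson r with a two-sided p from the
t-transform on $n-2$ degrees of freedom, with $n$ the number of samples.
Within-trial samples are heavily autocorrelated, so these p-values are
anti-conservative; they are reported for comparability and flagged in the
printed report. Axes with numerically zero variance (inactive axes of a
noise-free trial; variance below $10^{-16}$) get `NA` correlations rather
than noise-driven values.

Study-level aggregation follows the protocol's table conventions:
per-condition means and SDs across subjects, plus an overall row computed
both ways the source tables could have been built — pooled across all
subject-trials (primary) and as the mean of condition means. The error
ratio (100 × RMS / ROM) is aggregated only over trials whose ROM exceeds
two-thirds of that subject-and-axis's maximum across the seven trials (the
movement range associated with elevated low-back-pain risk); the reference
for "max ROM" is configurable to a fixed literature value. Bland–Altman
agreement of per-trial ROM pairs uses differences estimated − actual
(direction stated in the output), bias ± 1.96 × sample SD for the limits
of agreement.

## Numerical choices and problem sizes

* Calibration window $[0,10)$ s, endpoint exclusive: first 1000 samples at
  100 Hz.
* Through-origin slope $\alpha=\sum fr/\sum f^2$; a window with
  $\sum f^2=0$ raises a calibration failure unless the reference is also
  flat (RMS below $10^{-6}$°), in which case $\alpha=0$ — the inactive-axis
  case.
* Filter minimum length: odd-reflection padding plus the MA warm-up needs
  $3\,\text{order} + \text{order} + 2$ samples (17 at order 4).
* Stream alignment tolerates a one-sample count mismatch (truncation);
  anything larger, or a sampling-rate mismatch, is an error — the
  acquisition model is co-triggered hardware, so resampling is refused.
* Test and validation problem sizes: the full default study (6 × 7 trials,
  30 s, 100 Hz) runs in about a second; the noise-monotonicity property
  uses 1 subject × 7 conditions × 20 replicates at noise SDs
  {0.1, 0.5, 1.0} mm with common random numbers across levels, isolating
  sensor noise as the only varying error source.

## Known limitations

* The forward model is linear by design: no skin continuum mechanics, no
  hysteresis, no temperature dependence.
* Only whole-lumbar angles relative to the pelvis are modeled — no
  intersegmental (vertebra-level) kinematics.
* The trunk-frame construction is one defensible reading of "the trunk
  segment" (acromion/C7/L1-based); an L1-triad-based distal segment would
  be an alternative and could be added behind the same interface.
* CSV (and read-only TRC) are the interchange formats; C3D is out of
  scope.
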