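---
title: "Simulating subtle blood-brain-barrier leakage measurement with dceDRO"
author: "dceDRO authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating subtle blood-brain-barrier leakage measurement with dceDRO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Dynamic contrast-enhanced MRI (DCE-MRI) quantifies blood-brain-barrier
(BBB) leakage by fitting a pharmacokinetic model to the signal changes that
follow intravenous injection of a gadolinium-based contrast agent. In
cerebral small vessel disease and dementia the leakage is *subtle*: the
permeability-surface area product `PS` is of order 1e-4 per minute and the
induced signal change is a few percent. At that level, effects that are
negligible in high-permeability applications — finite k-space sampling
(Gibbs ringing and partial volume), gross head motion, within-frame motion
artefacts, and the much stronger enhancement of extra-cerebral tissues —
can rival or exceed the biological signal.

`dceDRO` implements a four-dimensional computational model of this
measurement. It builds a digital reference object (DRO) with *known*
`PS` and plasma volume fraction `vP` per tissue, simulates the acquisition
including those spatio-temporal effects, runs the same analysis pipeline a
study would run, and reports the error of the recovered parameters. Because
the ground truth is known exactly, every deviation is attributable to the
measurement process.

## Signal model

Brain-tissue concentration follows the Patlak model, appropriate for
irreversible slow leakage at low temporal resolution:

$$C_t(t) = v_P\, c_p(t) + PS \int_0^t c_p(\tau)\, d\tau,$$

where $c_p$ is the arterial input function (AIF, plasma concentration in
mM), `vP` is dimensionless and `PS` is in min^-1. Using the same linear
model in synthesis and fitting is deliberate: recovered-parameter errors
are then caused by the measurement process alone, not by model mismatch.

Concentration modulates relaxation linearly,
$1/T_i(t) = 1/T_{i0} + r_i C_t(t)$ for $i \in \{1, 2^*\}$, and the signal
follows the spoiled gradient echo (SPGR) steady state:

$$S = S_0\,\frac{(1 - e^{-TR/T_1})\sin\theta}{1 - e^{-TR/T_1}\cos\theta}\,
      e^{-TE/T_2^*}.$$

Tissues without a BBB (muscle, skin, marrow, meninges, eyes) enhance far
more strongly and are modelled directly on the signal with exponential
saturation or power-law multipliers; vessels use $C_t = (1-\mathrm{Hct})
c_p$ with `PS = 0` and Hct = 0.45.

### Parameters and defaults

* Protocol (shipped fixture): TR 8.24 ms, TE 3.1 ms, flip 12 deg, FOV
  24 x 24 x 18.4 cm acquired at 0.9375 x 1.25 x 4 mm (matrix
  256 x 192 x 46), 73 s temporal resolution, 1 pre- + 20 post-contrast
  frames. The slice (partition) voxel dimension is by far the coarsest,
  which is where ringing is most visible.
* Ground-truth tissue values (shipped fixture, per tissue): equilibrium
  signal S0, T10 (s), `PS` (1e-4/min scale) and `vP` (1e-2 scale) for
  normal-appearing white matter, white matter hyperintensities, cortical
  and subcortical grey matter and a recent stroke lesion.
* AIF: a parametric biexponential bolus-decay (Weinmann-type population
  parameters, dose 0.1 mmol/kg), arriving at the start of the second frame.
  The same AIF object is used for synthesis and fitting, so AIF error is
  out of scope by construction.
* Relaxivities: r1 = 3.9, r2* = 4.5 per mM per s (representative gadoterate
  values at 1.5 T), configurable. T2*0 per tissue is not part of the
  ground-truth table's provenance and is shipped as documented assumptions
  (50-100 ms in brain, shorter in bone and fat).
* Extra-cerebral curve parameters are configurable templates whose peak
  enhancement is several-fold larger than brain enhancement — the property
  that drives the sinc-artefact mechanism; their exact shapes are
  assumptions, not measurements.

## The synthetic phantom

`buildSyntheticHead()` generates a nested-ellipsoid head: skin and adipose
shells, a three-layer skull, muscle with an inferior neck block and bone
column, meninges, subarachnoid CSF, a cortical grey-matter ribbon, white
matter with lateral ventricles, periventricular WMH caps, one basal-ganglia
stroke lesion, thalamus-like subcortical grey blobs, thin vessels crossing
the cortical surface, and eyes — 16 classes in total. Geometry is
parameterised in millimetres, so the same head can be sampled at any grid
spacing; internal structure centres carry a seeded jitter.

What it emulates: enhancing extra-cerebral tissue adjacent to the brain,
tissue interfaces at many orientations, small lesions, and vessels crossing
the brain surface — the features that matter for artefact phenomenology.
What it does not emulate: realistic cortical folding, vascular trees,
lesion-probability maps, or any specific anatomy. Tests passing on this
phantom therefore demonstrate the *mechanisms* (ringing, motion mixing,
partial volume) and the correctness of the pipeline, not quantitative
equivalence with any in-vivo cohort; headline in-vivo bias numbers depend
on real anatomy and real patient motion trajectories and are out of scope.
An external labelled atlas in NIfTI form can be substituted through
`readLabelVolume()`.

## Acquisition simulation

Per frame, five steps:

1. **Starting position** — one rigid-body transform, each degree of freedom
   uniform over +/-5 deg and +/-2.5 mm, shared by all frames.
2. **Gross motion** — a per-frame rigid transform from a seeded random-walk
   trajectory. Severity classes are defined by the mean frame-to-frame
   displacement of brain voxels: low < 0.5 mm, moderate 0.5-1.5 mm,
   high > 1.5 mm (configurable thresholds; the per-step scales are chosen
   to land in these bands). Transforms are applied by resampling the
   high-resolution object, so rotation and interpolation effects are real.
3. **k-space sampling** — 3D Cartesian: unitary FFT of the high-resolution
   frame, suppression of signal outside the acquired FOV along the
   frequency- and slice-encode axes (band filter and slab excitation; the
   phase-encode axis is left free to alias), and central block extraction
   at the acquired matrix with DC at the floor(N/2) centre index.
4. **Motion artefacts** — a composite k-space per frame: a random
   proportion of the successive phase-encode lines (bottom-to-top along
   the slowest, partition-encode axis by default) from the head at its
   current position, the rest at the next frame's position.
5. **Noise and reconstruction** — white complex Gaussian noise on both
   channels, 3D inverse FFT, voxelwise magnitude; background voxels are
   then Rayleigh, low-signal voxels Rician. The noise level is calibrated
   as (mean pre-contrast NAWM signal) / SNR with SNR = 91.5.

## Analysis pipeline

Frames are realigned rigidly to the pre-contrast frame (intensity-based
registration, or an oracle mode that inverts the known simulation
transforms — useful to separate registration error from interpolation and
sampling error). Enhancement relative to the pre-contrast mean is converted
to concentration by inverting the SPGR equation with the nominal flip
angle and a regional T10 map; `(vP, PS)` come from ordinary least squares
of $C_t$ on $\{c_p, \int c_p\}$ without intercept, omitting the first
three post-contrast frames as in-vivo analyses do. The segmentation is
propagated to acquired space by registering the high-resolution
pre-contrast image to the acquired one, resampling each class mask with
cubic interpolation and taking the per-voxel argmax (background where all
probabilities < 0.5). Summary estimators: mean/median over the parameter
map, and Patlak fitting of the mean/median ROI signal curve, optionally
after spherical mask erosion (radius 1 voxel), optionally after a Bessel
k-space low-pass.

## Numerical and design choices

* **FFT convention.** Unitary in both directions, so an image-domain noise
  sigma passes through unchanged and SNR calibration is unambiguous.
* **Grid alignment.** Plain spectrum cropping yields samples aligned with
  the *first* source sample; a half-voxel-difference phase ramp re-centres
  the acquired samples on the package's centred-grid affine convention.
  Without it, every cross-resolution operation inherits a systematic
  (spacing_acq - spacing_src)/2 offset.
* **Quadrature.** The Patlak integral uses the cumulative trapezoidal rule
  on the frame times, and the regression uses the *same* implementation, so
  fitting noise-free forward-model output is exact to machine precision.
  The quadrature itself is verified against the closed-form integral of the
  biexponential AIF on a 0.1 s grid. At 73 s resolution the discrete
  integral near the bolus differs from the continuous one by construction;
  this cancels between synthesis and fitting.
* **T2\* in the inverse.** The forward model retains the $e^{-TE/T_2^*}$
  factor; the default conversion neglects it (standard practice), which
  biases the recovered parameters slightly low — by under 1% for brain
  tissue and roughly 1-2% for the high-concentration vessel `vP` under the
  shipped protocol. An
  optional two-pass correction using the nominal r2* removes the bias; the
  ideal-condition recovery experiment uses it because that experiment is
  defined as a forward-inverse identity. Both paths are exported.
* **Registration.** Normalised cross-correlation, two resolution levels,
  BFGS descent with a Nelder-Mead polish at each level. Two refinements
  proved necessary: the cost uses cubic (Catmull-Rom) rather than trilinear
  interpolation, whose fractional-offset smoothing biases the optimum by
  ~0.3 voxel; and both images are pre-smoothed by a 0.6-voxel Gaussian,
  because on contrast-enhancing frames an un-smoothed cost rewards any
  transform whose resampling blurs the moving image, manifesting as
  spurious ~1.5 deg rotations on motion-free series. With both, known
  simulated transforms are recovered to 0.03-0.06 voxel. Segmentation
  propagation uses the same rigid engine; the simulator only ever applies
  rigid transforms, so the rigid subgroup suffices.
* **Bessel low-pass.** The reference analysis names the filter but not its
  parameters; the default is a 4th-order magnitude response with -3 dB
  cutoff at 0.7 of Nyquist, applied separably per axis. Any monotone
  unit-DC low-pass exercises the documented effect; order and cutoff are
  arguments.
* **Rotation centre** is the brain-mask centroid; Euler order is Z-Y-X;
  trajectories serialize to CSV with these conventions stated, so they are
  portable.
* **Seeds.** One master seed spawns per-run child seeds deterministically
  (`childSeeds()`); every random draw in a run (start position, trajectory,
  k-space split fractions, noise) derives from its child seed, making the
  201-run-style design reproducible and parallelisable.

## Desk-scale experiment sizes

The packaged experiments are scaled down from the full protocol so a
complete run fits on one CPU in minutes: the demo head is 96 mm FOV at
1 mm (or 64^3 at 1.5 mm in the test suite), acquired matrices are
proportionally scaled (e.g. 48 x 40 x 16, keeping the coarse-slice
anisotropy), and the Monte-Carlo demo uses 25 runs instead of 201. The
full-scale reference geometry remains available through `readProtocol()`.

Two desk-scale consequences are worth stating explicitly. First, the
miniature head makes each tissue only a few acquired voxels thick, so
sampling artefacts within eroded masks are proportionally larger than at
in-vivo scale — the directional conclusions (motion dominates error;
erosion and realignment help; ringing follows edge-to-grid phase) carry
over, the absolute biases do not. Second, the spatial-SNR calibration
check is evaluated on an acquired grid matched to the source grid: at a
truncating desk-scale matrix the within-mask standard deviation measures
miniature-phantom ringing rather than the injected noise, which is the
quantity the calibration controls; at in-vivo scale white matter is
hundreds of voxels across and the distinction vanishes.

A related sampling subtlety: the visibility of Gibbs overshoot in
*sampled* values depends on the phase of the edge relative to the acquired
grid — a grid-aligned edge places the samples on the ringing nodes. The
test suite's Gibbs oracle therefore evaluates the truncation at the
acquired sample positions, and the phantom experiments randomise the
starting position exactly because artefact expression depends on it.

## Known limitations

* No parallel imaging, partial Fourier, coil sensitivities, B0/B1 effects
  or scanner drift; motion is piecewise-static per frame (continuous
  intra-frame motion would be more realistic at much higher cost).
* The AIF is a population parametric form; dispersion, delay and
  patient-specific AIFs are out of scope.
* Water exchange and more complex pharmacokinetic models are deliberately
  excluded so measurement error is isolated from model error.
* The phantom's anatomy is schematic; in-vivo-conditioned bias magnitudes
  require a real atlas and real motion trajectories.

## A minimal session

```{r example}
library(dceDRO)

vol   <- buildSyntheticHead(phantomSpec(), seed = 1)
fix   <- loadFixtures()
aif   <- defaultAIF(onsetS = 73)
proto <- demoProtocol()

acq <- simulateAcquisition(vol, fix$table, aif, proto,
                           severity = "moderate", seed = 42)
ana <- realignFrames(acq, mode = "registration")
seg <- propagateSegmentation(vol, acq, table = fix$table, aif = aif,
                             proto = proto, mode = "registration")
pm  <- fitParameterMaps(ana, buildT10Map(seg, fix$table), aif, proto)
summarizeROI(map = pm, labelMap = seg, estimator = "median_parameter",
             table = fix$table, erodeRadius = 1)
```
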