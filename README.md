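# dceDRO

Digital reference objects (DROs) for simulating DCE-MRI measurement of
subtle blood–brain-barrier leakage.

## The problem

DCE-MRI estimates blood–brain-barrier (BBB) leakage by fitting a
pharmacokinetic model to the signal change after contrast injection. In
small vessel disease and dementia the leakage rate *PS* is of order
10⁻⁴ min⁻¹ and the signal change is a few percent — small enough that
k-space truncation (Gibbs ringing, partial volume), gross head motion,
within-frame motion artefacts and the much larger enhancement of
extra-cerebral tissue can rival or exceed the biological effect. Because
no convenient in-vivo reference method exists, these errors are hard to
quantify from patient data.

`dceDRO` addresses this with a four-dimensional computational model of the
whole measurement. It is aimed at researchers developing or validating
subtle-leakage protocols and analysis pipelines: every simulation starts
from a labelled head phantom with *known* parameters, so the error of every
processing choice can be measured exactly.

## The model

Brain tissue concentration follows the Patlak model for irreversible slow
leakage,

```
C_t(t) = v_P · c_p(t) + PS · ∫₀ᵗ c_p(τ) dτ ,
```

with `c_p` the arterial input function, `v_P` the plasma volume fraction
and `PS` the permeability–surface area product (min⁻¹). Relaxation rates
vary linearly with concentration, `1/T_i(t) = 1/T_i0 + r_i·C_t(t)` for
i ∈ {1, 2\*}, and the signal is spoiled-gradient-echo:

```
S = S0 · (1 − e^(−TR/T1)) sinθ / (1 − e^(−TR/T1) cosθ) · e^(−TE/T2*).
```

The acquisition simulator adds, per frame: a random starting head position
(±5°, ±2.5 mm uniform), gross rigid motion from a severity-classed
random-walk trajectory, 3D Cartesian k-space truncation to the acquired
matrix with FOV suppression, composite-k-space motion artefacts (a random
proportion of phase-encode lines from each of two head positions), and
complex Gaussian noise calibrated to a white-matter SNR of 91.5, followed
by magnitude reconstruction (Rician noise). The analysis pipeline mirrors a
clinical study: rigid realignment, segmentation propagation, regional T10
map, SPGR inversion to concentration, voxelwise Patlak regression (first
three post-contrast frames omitted), and ROI summaries by four estimators
with optional mask erosion and Bessel k-space low-pass filtering. A
Monte-Carlo harness repeats the whole chain across seeds, severities and
post-processing conditions.

## Worked example

```r
library(dceDRO)

vol   <- buildSyntheticHead(phantomSpec(dim = c(64, 64, 64),
                                        spacingMM = c(1.5, 1.5, 1.5)), seed = 2)
fix   <- loadFixtures()           # reference protocol + tissue ground truth
aif   <- defaultAIF(onsetS = 73)

## ideal condition: acquired grid = source grid, no motion, no noise
protoI <- demoProtocol(fovMM = c(96, 96, 96), acqMatrix = c(64, 64, 64))
ideal  <- simulateAcquisition(vol, fix$table, aif, protoI, seed = 1,
            flags = list(startPosition = FALSE, grossMotion = FALSE,
                         motionArtefacts = FALSE, noise = FALSE))
segI <- propagateSegmentation(vol, ideal, mode = "oracle")
pmI  <- fitParameterMaps(ideal, buildT10Map(segI, fix$table), aif, protoI,
                         t2starCorrection = TRUE)
summarizeROI(map = pmI, labelMap = segI, estimator = "median_parameter",
             table = fix$table)
```

```
           name   PS_est rel_err_PS_pct vP_est rel_err_vP_pct
           nawm 0.000275      -1.35e-05 0.0057      -1.31e-05
            wmh 0.000391      -6.93e-06 0.0072      -6.52e-06
         stroke 0.000725      -6.35e-06 0.0105      -5.45e-06
    cortical_gm 0.000385      -4.73e-06 0.0120      -4.72e-06
 subcortical_gm 0.000385      -4.73e-06 0.0120      -4.72e-06
```

Recovery is exact to ~10⁻⁵ %: with no degradation, the analysis inverts the
forward model. Switching the degradations on changes the picture entirely —
the same white matter, acquired at 3 × 3 × 6 mm with moderate motion,
motion artefacts and noise, then realigned and fitted:

```r
proto <- demoProtocol(fovMM = c(96, 96, 96), acqMatrix = c(32, 32, 16))
acq <- simulateAcquisition(vol, fix$table, aif, proto,
                           severity = "moderate", seed = 42)
ana <- realignFrames(acq, mode = "oracle")
seg <- propagateSegmentation(vol, acq, mode = "oracle")
pm  <- fitParameterMaps(ana, buildT10Map(seg, fix$table), aif, proto)
summarizeROI(map = pm, labelMap = seg, estimator = "median_parameter",
             table = fix$table, erodeRadius = 0, classes = 2)  # NAWM
```

```
NAWM, erosion 0: PS_est 0.000128 (err -53.4%), vP_est 0.00688 (err +20.7%), n=644
NAWM, erosion 1: PS_est 0.000168 (err -38.9%), vP_est 0.00424 (err -25.6%), n=216
```

A true `PS` of 2.75 × 10⁻⁴ min⁻¹ is recovered 53% too low purely because of
sampling and motion; eroding the mask by one voxel removes the most
contaminated rim and reduces the bias. `runMonteCarlo()` repeats such
experiments over many seeded runs and reports per-tissue medians and
interquartile ranges per estimator and post-processing condition.

A command-line front end is included at `inst/cli/bbbsim.R`
(`bbbsim simulate|fit|summarize|montecarlo --config run.yaml --seed N --out DIR`).

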