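---
title: "Methods: quantitative endpoints for tMCAO stroke and EV studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative endpoints for tMCAO stroke and EV studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokequant)
```

strokequant implements the quantitative analysis chain of a preclinical
stroke study: a mouse receives a transient middle cerebral artery occlusion
(tMCAO), the exposed skull is imaged continuously with combined laser
speckle contrast imaging (perfusion) and multispectral reflectance imaging
(oxy-/deoxyhemoglobin), and treatment — here plasma extracellular vesicles
(EVs) — is injected during occlusion. The package covers the image-derived
endpoints (core/penumbra segmentation, core tracking, region traces),
stereological infarct volumes, immunohistochemistry (IHC) ratios, EV homing
fluorescence, behavioral scores, and the bookkeeping rules of the EV arm.
Every stage can be validated on synthetic phantoms that carry their own
ground truth.

## Hemodynamic analysis

### Model and procedure

The imaging device records one frame per second; analysis runs at one frame
per minute. `downsample_to_minutes()` averages all frames of each whole
minute pixelwise (a trailing partial minute is dropped). Averaging, rather
than decimation, was chosen because it suppresses frame noise by roughly
`sqrt(60)` while matching the reporting rate; event frame indices (EV
injection, reperfusion) are remapped to the minute that contains them.

Large cortical vessels ride on top of the parenchymal signal and do not
carry the tissue-perfusion information of interest. `detect_vessels()`
masks them by thresholding the *reference map* — the pixelwise mean of all
frames strictly before reperfusion — at a percentile of the non-background
intensities. The default is the 95th percentile: in a field where vessels
cover a few percent of the pixels at several times the parenchymal
intensity, this lands between the parenchymal and vessel modes. The
percentile is configurable and the realized threshold is recorded in the
mask object so a run is auditable. Vessel pixels are excluded from *every*
downstream statistic — baseline, masks, core counts and traces — so
arbitrarily bright values under the mask cannot move any result (this is
asserted as a test invariant).

The perfusion baseline `B` (`compute_baseline()`) is the mean over
healthy-hemisphere non-vessel pixels across all downsampled frames strictly
before reperfusion. The injection frame is recorded but does not split the
baseline window: the injection happens during occlusion and does not change
healthy-hemisphere perfusion, so there is no reason to discard the frames
before it.

`build_region_masks()` segments the ischemic-hemisphere parenchyma from the
reference map relative to `B`: ischemic core below 33% of baseline,
penumbra from 33% to 70%, normally perfused tissue above 70%. The
boundaries are assigned core-strict / penumbra-closed / normal-strict, so
the three half-open intervals tile the real line exactly and the three
masks partition the parenchyma with no gaps or overlaps — an invariant the
test suite asserts on every run. `theta_core` and `theta_normal` are
plain arguments (fractions of `B`, defaults 0.33 and 0.70) because other
laboratories use other cutoffs.

Two distinct uses of the 33% threshold coexist and both are implemented:

* **static masks** from the pre-reperfusion reference map, which define the
  regions whose traces are followed through reperfusion
  (`build_region_masks()`), and
* **dynamic per-frame classification** for tracking the ischemic core over
  time (`track_core()`), which counts, in every frame, the parenchyma
  pixels currently below `0.33 * B` and reports them as a fraction of the
  ischemic-hemisphere non-vessel pixel count (i.e. "% of hemisphere").

`extract_region_traces()` computes, per region and signal, the per-frame
mean over the mask pixels and divides the trace by its own first value, so
every trace starts at exactly 1; the time axis is shifted so reperfusion is
minute 0. For the hemoglobin signals the same multiplicative scaling is
applied: the instrument's concentration signals are consumed as given, and
scaling each region's trace by its own initial value yields a unit-free
relative trace exactly as for flow. A region whose initial mean is 0 cannot
be scaled and is rejected with an error rather than silently producing
infinities; an empty region mask drops the trace with a warning.

### Conventions

All pixel and frame indices are 1-based (R convention), row-major
`[row, col]`. Hemisphere geometry is supplied as a label map (0 background,
1 healthy, 2 ischemic) — drawn by the experimenter or taken from phantom
ground truth; no automatic midline detection is attempted, since head
placement varies and the midline is trivially visible to the operator.

## Stereology

Infarct areas on serial sections are estimated with the classical isotropic
2D nucleator: with intercept lengths `l_i` from an interior point to the
profile boundary along isotropic directions, `area = pi * mean(l_i^2)`.
This is exact for a circle measured from its center and unbiased for
profiles that are star-shaped about the point. The multi-intercept signed
nucleator for non-star-shaped profiles is deliberately not implemented:
infarct profiles are treated as star-shaped about a well-chosen interior
point, and `intercept_lengths_polygon(..., require_star_shaped = TRUE)`
rejects profiles that violate the assumption instead of returning a biased
number. Ray designs: `nucleator_directions()` offers the systematic design
(n equally spaced rays with one random rotation; lower variance) as the
default and fully random isotropic rays as an alternative.

Volumes follow the Cavalieri estimator `V = d * sum(a_i)` with `d` the
section spacing (`cavalieri_volume()`); the study design this mirrors
collects sections every 600 µm. Units are mm internally. The section-series
phantom (`generate_section_series()`) defaults to midpoint-offset
systematic planes, which makes the cylinder worked example exact; the
uniform-random-start design (the classically unbiased one) is available via
`random_start = TRUE` and its unbiasedness is verified by simulation in the
test suite.

## IHC quantification

Blood-brain-barrier damage is read out as IgG extravasation relative to
vessel density: per region (infarct, penumbra, healthy), the IgG-positive
area divided by the CD31-positive area. "Analyzed with the same settings"
is operationalized as one fixed global threshold per channel per batch
(`threshold_channel()`), stored with the results. Aggregation order
follows the bench protocol: ROI counts, then ROI mean per region within a
section, then section mean per animal, then normalization of infarct and
penumbra to the healthy-region ratio (healthy maps to exactly 1). Regions
with zero CD31 area are flagged and excluded rather than propagating
division by zero. ROI placement is always explicit coordinates
(`roi_set()`); the package never auto-places ROIs because the original
measurements are operator-placed.

EV homing uses equal-area (1 mm²) ROIs placed pairwise in the middle
cerebral artery territory of both hemispheres. The homing ratio is the
mean of the ischemic-ROI means over the mean of the healthy-ROI means
(`normalize_hemispheres()`), which cancels any global intensity factor —
the point of the normalization, since differently labeled EV preparations
can differ in labeling efficiency. Scale invariance is asserted as a test
property.

## Behavioral endpoints

* `hargreaves_latency()`: of five withdrawal latencies, remove exactly one
  instance of the maximum and one of the minimum and average the remaining
  three — i.e. the mean of the 2nd–4th order statistics. With ties, exactly
  one tied value is removed at each end; the result is order-invariant.
* `corner_right_frequency()`: right turns out of exactly ten trials.
* `validate_tmcao_induction()`: a day-1 neuroscore of 1–4 counts as a
  successful occlusion; 0 means no deficit (exclusion).

Missing sessions (e.g. animals that died) are represented as absent rows
and never imputed.

## EV sample bookkeeping

* `hemolysis_filter()`: plasma with A414 above 0.2 is discarded
  (hemolysis); exactly 0.2 is kept, reading "exceeded" strictly. A subject
  is retained only if all timepoints pass, because the within-subject
  design needs the complete series; missing A414 counts as failing.
* `equalize_dose()`: per subject, every timepoint is diluted to the
  minimum concentration across that subject's timepoints (factors >= 1,
  exactly 1 at the minimum), so each subject contributes the same particle
  number at every timepoint. Concentrating samples is not modeled.
* `pool_samples()`: donors of one group and timepoint are pooled. The
  protocol states only that samples were pooled; the default takes equal
  particle contributions per donor (the largest count every donor can
  supply), with full-volume pooling as the configurable alternative.
  Particle conservation holds for both and is asserted.
* `normalize_to_pre()`: assay readouts are divided by the subject's
  pre-intervention value before between-group comparison; pre maps to
  exactly 1 and the ratios are invariant to the readout's units.

Group-level hypothesis testing (mixed models, ANOVA, multiple-comparison
corrections) is intentionally left to standard statistical tools; the
package produces the normalized, tidy per-animal/per-subject quantities
those tools consume.

## The phantoms: what they emulate, and what they do not

`phantom_spec()` describes a two-hemisphere cortical field: background
margin, healthy and ischemic hemispheres split at a midline column, a few
bright vessel strips (baseline × multiplier, regardless of the region they
cross — so vessel masking is consequential), an elliptical ischemic core
and a penumbral annulus at programmed fractions of baseline, and
single-exponential recovery toward a per-region plateau after reperfusion.
Noise is additive Gaussian, truncated at zero for perfusion. The defaults
are the conditions under which the pipeline's recovery claims are made: a
64×96 px field at 0.1 mm/pixel, baseline 100 with noise SD 2 (2% of
baseline), core at 20% and penumbra at 50% of baseline, two vessels at 3×
baseline covering ~4% of the field, 1 frame/s for 900 s with reperfusion at
frame 481. The 900 s recording is a deliberately compressed stand-in for
the hours-long acquisitions of a real experiment — the pipeline is
agnostic to duration, and examples and tests use sizes that keep a full
suite run around a minute. Tests that need a converged post-reperfusion
plateau use a 1500 s phantom (~8.5 recovery time constants past
reperfusion).

The hemoglobin phantom shares the geometry and programs per-region step +
recovery dynamics as fractions of a resting hemoglobin level; by default
deoxyhemoglobin mirrors oxyhemoglobin about rest, giving the
anti-correlated traces typical of ischemia-reperfusion.

What the phantoms deliberately do **not** emulate: speckle statistics and
any optical forward model (the pipeline consumes perfusion and hemoglobin
maps as instrument output), motion and registration errors, curved or
irregular core geometries, spatially correlated noise, and vascular trees
(vessels are straight strips). Passing the phantom suite therefore
demonstrates the correctness of the *analysis logic* — thresholds, masks,
scaling, bookkeeping — under known ground truth, not robustness to every
artifact of real recordings.

## Numerical choices and degenerate inputs

* Boundary ties at 33%/70% of baseline go to the penumbra (closed
  interval), making the partition exact.
* A constant reference map yields an empty vessel mask with a warning (a
  percentile threshold is meaningless there).
* Baseline requires at least one pre-reperfusion frame; `B <= 0` and
  non-flow signals are rejected for mask building.
* Trace scaling requires a nonzero first value; division is exact
  (`x/x == 1` in floating point), so the starts-at-1 contract is bit-exact.
* Dose equalization sets the effective concentration to the subject
  minimum directly — mathematically identical to dividing by the factor,
  but exact in floating point.
* TIFF float samples are stored in [0, 1]; stacks are affinely rescaled
  with the range recorded in the YAML sidecar and restored on read
  (round-trip exact to 32-bit float precision).

## Worked example

```{r example, eval = FALSE}
sp <- phantom_spec(seed = 1)
ph <- generate_perfusion_phantom(sp)
res <- analyze_hemodynamics(ph$stack, ph$geometry)
res$baseline                      # ~100, the programmed healthy intensity
res$masks                         # core/penumbra/normal pixel counts
head(res$core_track)              # % of hemisphere below 33% of baseline
subset(res$traces, region == "core" & time_min >= 0)  # recovery to ~3x
```

## Known limitations

* Hemisphere geometry must be supplied; there is no midline detection.
* The nucleator covers star-shaped profiles only (by design, validated).
* The IHC threshold is a user choice per batch; the package records it but
  cannot recover the operator's original ImageJ settings.
* Phantom realism limits are listed above; claims about real recordings
  should be validated against annotated in vivo data.
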