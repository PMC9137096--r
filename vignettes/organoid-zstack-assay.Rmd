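---
title: "Simulating and quantifying z-stack organoid imaging assays"
author: "OrganoidStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying z-stack organoid imaging assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrganoidStack)
```

## The problem

Organoids grown in a Matrigel dome are distributed through roughly a
millimetre of gel. A single focal plane therefore images only a thin slab:
objects near the plane are sharp, objects a few tens of micrometres away are
blurred, and objects farther than that are effectively invisible. A z-stack
scan — several focal planes spread over the gel depth, merged into one
all-in-focus composite by extended-depth-of-field (EDF) fusion — recovers
essentially every object at its maximal cross-section, which is what
plate-level readouts (object count, total cross-sectional area, live/dead
labeling) should be computed from.

OrganoidStack implements the full desk-scale counterpart of such an assay:
a synthetic scene and microscope simulator with known ground truth, the scan
planner, the EDF fusion engine, the segmentation/measurement stage, and the
assay analytics (survival as % of day 0, chemosensitivity calls, group
comparisons). Because every stage runs against simulated data with known
truth, each claim about the pipeline is testable without a microscope.

## The simulator and its assumptions

A `Scene` is a set of spheres in a gel volume, each with a centre, a
live-core diameter, a live fraction, a label state and an optional dead-cell
shell. `generateScene()` places objects uniformly; z spans the full gel depth
(z = 0 at the gel bottom), and lateral positions keep each footprint inside
the field. All lengths are micrometres.

The optical model (`opticalModel()`) has five parameters:

* `pixelSize` (2 um/px default) — lateral sampling. Capture-efficiency runs
  and pipeline wells render 512–1508 px fields at this sampling.
* `dofHalfDepth` h (80 um) — the detectability half-depth: a sphere of
  radius r is visible in a plane when its centre is within r + h of it, and
  renders sharp while within h. This single knob carries the axial physics:
  with h = 80 um the 7-layer/180 um reference scan captures essentially all
  20 um spheres, matching the design anchor of the assay. No optical
  parameters (NA, wavelength) are modelled that would pin h from first
  principles; it is a calibrated, configurable abstraction.
* `blurCoeff` (0.05 um sigma per um of defocus) — Gaussian blur growth
  beyond the depth-of-field band. We deliberately let blur start at the band
  edge (sigma = blurCoeff * max(0, |dz| - h)) rather than at the plane
  itself: this makes h an actual optical property, so the capture cliff of
  the rendered pipeline coincides with the closed-form
  min(1, 2(r + h)/step) rule instead of adding a second, diameter-dependent
  attenuation cliff. Within the band an object is drawn at its equatorial
  cross-section — the same convention under which EDF fusion reports an
  object's maximal section.
* `noiseSd` (0.01) and `backgroundBase` B0 (0.02) on the [0, 1] intensity
  scale; rendered stacks are clamped to [0, 1] (detector saturation) and
  quantised to the 16-bit camera grid, which also makes TIFF round trips
  bit-identical.

Staining follows a saturating dose-by-time law: a live object is labeled
with probability p = min(1, c·t/K). K defaults to 120 uM·min so that the
standard staining condition — 2 uM Calcein-AM for 60 min — sits exactly at
saturation (100% labeling). The nonspecific green gel background grows
linearly with staining time, B(t) = B0 + beta·t·max(0, 1 − [Cu2+]/0.1 mM),
vanishing at the 0.1 mM working concentration of the copper quencher. Both
laws are the simplest monotone forms consistent with the assay's observed
behaviour (labeling rises with dose and time; background rises with time and
is suppressed by Cu2+); how dye actually penetrates a 3D structure over time
is not modelled, and the saturating form is a stand-in, not a mechanistic
claim.

Treatment (`treatmentEffect()`) kills an independent `killFraction` of
objects outright (live fraction 0, body red-stained, green label lost);
survivors keep a live core shrunk by `shrinkFactor` inside a
`deadShellWidth` annulus of loose dead cells. This reproduces the
post-treatment morphology that motivates fluorescence-based delineation: the
live (green) footprint of a survivor is a strict subset of its brightfield
footprint, so brightfield areas overestimate surviving tissue.

What the simulator does **not** emulate: organoid lumen/crypt morphology
(objects are spheres; interiors are flat, so EDF index maps are only
informative near edges and wherever real texture exists), photobleaching,
stage drift, uneven illumination, and sub-organoid (cell-level) structure.
Tests passing on this simulator therefore validate the pipeline's geometry,
statistics and bookkeeping — not its robustness to the full mess of real
micrographs.

## Scan planning and capture efficiency

`planZStack(zRange, nLayers)` spaces planes from the gel bottom with step
zRange/(nLayers − 1), rounded to the nearest 10 um — the granularity a stage
controller is driven at. Over the 1100 um reference gel, 7 layers give the
180 um step (1100/6 = 183.3 → 180); the planes then span 0–1080 um, a few
micrometres short of the nominal range, which is immaterial because the top
plane's detectability band covers the remainder.

Capture efficiency has three routes, deliberately kept independent:

1. **Closed form**: each plane captures a band of 2(r + h), so a uniformly
   placed sphere is captured with probability min(1, 2(r + h)/step)
   (referred to the full range for a single-plane scan).
2. **Geometric Monte Carlo** (`captureCurve(mode = "empirical")`): sample z
   uniformly, test the nearest actual (rounded) plane against r + h. This
   differs from the closed form only through plane anchoring and edge
   effects, by design under 1 percentage point everywhere on the
   10–100 um × 2–14 layer grid.
3. **Full pipeline** (`captureEfficiencyEmpirical()`): render, fuse, detect,
   count. The scene is rendered in 512 px tiles with a guard margin, and
   only detections whose centroid falls in a tile's core are counted, so
   border objects are counted exactly once. Losses beyond the geometric
   prediction come from projected overlap (two objects sharing an xy
   footprint merge into one detection) — a real effect the overlap-rate
   readout quantifies, about 1–3% at the densities used (up to ~20
   objects/uL).

The minimum-area filter inside `captureEfficiencyEmpirical()` defaults to
half the nominal section area of the smallest planted diameter rather than
the global 314 um2 default: an experiment measuring capture of a known size
class must not discard that class. Everywhere else the 314 um2 default (a
20 um circle, the smallest object treated as real) applies.

## EDF fusion

The focus measure is the local variance of the 3x3 Laplacian within a
(2·window + 1) px box (window 4 px default). Per pixel, the layer maximising
the focus measure on the reference channel (brightfield by default — it
exists before staining) wins; ties go to the lowest layer index, so fusion
is deterministic. The raw index map is median-filtered (radius 2 px) to
suppress isolated layer switches, and every channel is composited from the
same smoothed map, which keeps channels co-registered by construction.
A flat-interior object leaves the index map uninformative inside its
footprint; the composite is still correct there because all layers agree up
to blur and noise. The fusion's fitness is asserted by a dominance property
— per-object sharpness of the composite is at least that of the best single
layer, minus a small smoothing tolerance — rather than by equivalence to any
particular reference implementation.

## Segmentation and measurement

Objects are round and brighter than background, so the classical chain is
used: Otsu threshold, hole filling, distance-transform watershed (local-max
suppression 2 px) to split touching footprints, minimum-area filtering.
Per object we record area, centroid, the **short diameter** — the minimum
Feret diameter of the footprint, computed by rotating calipers on the convex
hull — and mean green/red intensities; an object is called live when its
mean green exceeds the threshold B0 + 3·noiseSd (0.05 by default), three
noise standard deviations above the baseline background, so an unstained
well scores 0% and any labeled object clears it comfortably.

The gel background readout mirrors the bench procedure of reading a few
diffused points in cell-free gel: nine points, spread by a minimum-distance
rule (a seeded stand-in for the unstated manual placement), each averaged
over a 5x5 px patch.

Overlap rate is reported two ways because the assay only fixes its axis, not
its definition: the primary, ground-truth definition is the fraction of
objects whose projected footprint disk intersects another's (computed with a
sweep over x-sorted objects and verified exactly against an O(n^2) brute
force); the fallback, available for real data, is the detected-count deficit
1 − n_detected/n_true.

## Assay analytics

* `survivalRate()`: 100 × dN count / d0 count; errors on an empty d0 rather
  than returning anything. Counts at day N use green-channel (live)
  segmentation, because dead shells inflate brightfield footprints.
* `sizeChangeRatio()`: 100 × dN total area / d0 total area. The convention
  "ratio" (100 = unchanged) was chosen over "percent change" (0 =
  unchanged); the latter is available behind `asChange = TRUE` because the
  assay description admits either reading.
* `classifyChemosensitivity()`: ratio < cutoff → sensitive, with the
  boundary assigned to resistant. The 36.42% default is a configured
  constant of the assay (derived once, elsewhere, from patient outcomes via
  Youden's index); this package does not re-derive it. Which side of the
  cutoff means "sensitive" is not stated by the assay itself; below-cutoff →
  sensitive (treatment suppressed growth) is adopted and configurable.
* `compareGroups()`: per-group mean ± SD (or SEM), unadjusted two-tailed
  t tests against control with the conventional star thresholds. No
  multiplicity correction is applied — a documented limitation, matching how
  a handful of planned treated-vs-control contrasts are usually reported.

## Numerical choices and degenerate inputs

* Rasterisation uses a 1 px linear edge ramp (area-accurate anti-aliasing);
  a disk's measured area is within ~3% of pi r^2 at 1 um/px.
* Blur below 0.3 px sigma is skipped (indistinguishable from none).
* Intensities saturate at 1 when footprints overlap, as a detector would.
* Empty scenes, blank images and empty wells are legal inputs with defined
  outputs (empty tables, zero histograms) — except rates that are genuinely
  undefined (labeling and survival on empty wells), which raise errors.
* All randomness is seeded per call; a call never perturbs the caller's RNG
  state, and identical seeds give bit-identical scenes, stacks and CSVs.

## Problem sizes used in the checks

The shipped checks run the capture experiment at 2000 spheres of 20 um in a
10.2 x 10.2 mm, 1100 um-deep volume (about 17 objects/uL, inside the 2–20/uL
density range the assay was optimised over), rendered in 512 px tiles at
2 um/px; the staining grid at 200 organoids per condition; and the recovery
experiment at 4 wells x 50 organoids per kill fraction — 50 per 10 uL dome
being the assay's standard planting density, at which projected overlap
stays in the low percent. These sizes were chosen as the smallest at which
binomial noise is comfortably below the effects being measured.

## Known limitations

* The optical abstraction (hard detectability cliff at r + h, blur onset at
  the band edge) is calibrated to reproduce the assay's capture behaviour,
  not derived from microscope physics.
* Spheres only: no lumen, no crypts, no shape irregularity, so short
  diameter ≈ diameter by construction; on real organoids the short diameter
  is the more conservative of the two axes, which is why it is the size
  statistic of choice.
* The detected-mode overlap rate conflates merging with every other
  detection loss; it is a fallback, not a substitute for ground truth.
* Survival and size-change readouts assume d0 and dN image the same well
  geometry; no registration between time points is attempted.
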