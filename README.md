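# OrganoidStack

Z-stack focus stacking and live/dead quantification for 3D organoid imaging
assays — with a full synthetic-microscopy simulator so every stage of the
pipeline can be validated against known ground truth.

## The problem

Organoids and microspheres embedded in a Matrigel dome sit throughout a
~1100 µm-deep gel. A single focal plane captures only the objects near it;
everything else is blurred or invisible, so plate-level readouts (counts,
cross-sectional areas, live/dead labeling) taken from one plane are badly
biased. The remedy is a **z-stack**: *n* focal planes spread over the gel,
merged into one all-in-focus composite by **extended-depth-of-field (EDF)
fusion**, from which every object is measured at its sharpest section.

The package implements, for users designing or running such assays:

- a **simulator**: spheres of known position/size/viability in a virtual gel,
  rendered into multi-channel z-stacks with depth-of-field, defocus blur,
  Calcein-AM staining kinetics p = min(1, c·t/K), gel autofluorescence
  B(t) = B₀ + β·t·max(0, 1 − [Cu²⁺]/0.1 mM), and drug-treatment morphology
  (shrunken live core inside a dead-cell shell);
- the **scan planner**: step = z-range/(n − 1) rounded to the stage
  granularity, and capture efficiency both in closed form,
  min(1, 2(r + h)/step) for detectability half-depth *h*, and empirically
  through the full render → fuse → detect path;
- **EDF fusion** via a variance-of-Laplacian focus measure with a median-
  smoothed per-pixel layer index map shared across channels;
- **quantification**: Otsu + watershed segmentation, per-object area, short
  diameter (minimum Feret), channel intensities, labeling rate, overlap
  rate, gel background from nine diffused points;
- **assay analytics**: survival rate as % of day 0, size-change ratio,
  chemosensitivity calls against a configurable 36.42 % cutoff, staining
  optimisation grids, and two-tailed t-test group comparisons.

## Worked example

Fifty organoids (40–100 µm) in a 10 µL, 1100 µm-deep dome, scanned with 7
layers, stained at the saturating condition, then treated with an agent that
kills half of them:

```r
library(OrganoidStack)

plan <- planZStack(1100, 7)
plan
#> AcquisitionPlan: 7 layer(s) over 1100 um, step 180 um
#>   planes (um): 0, 180, 360, 540, 720, 900, 1080

stain <- stainingModel(concentration = 2, time = 60, cuConcentration = 0.1)
d0scene <- generateScene(50, diameter = function(n) runif(n, 40, 100),
                         gelDepth = 1100, xyExtent = 3015, seed = 1)
d0 <- quantifyWell(applyStaining(d0scene, stain, seed = 2),
                   plan, opticalModel(), stain, channel = "green", seed = 3)
d0
#> WellSummary: 50 object(s), total area 208208 um2
#>   labeling 100%, overlap 4%, background 0.02038042

trt <- applyTreatment(d0scene, treatmentEffect(killFraction = 0.5,
                                               shrinkFactor = 0.6,
                                               deadShellWidth = 10), seed = 4)
dN <- quantifyWell(applyStaining(trt, stain, seed = 5), plan, opticalModel(),
                   stain, channel = "green", minArea = 113, seed = 6)
pair <- timepointPair(d0, dN, day = 10)
survivalRate(pair)
#> [1] 62
classifyChemosensitivity(sizeChangeRatio(pair))
#> ChemoCall: size change 22.66% vs cutoff 36.42% -> sensitive
```

Reading the numbers: all 50 planted organoids were detected at day 0 (the
7-layer scan captures every object of this size class) and 100 % carried the
live label — 2 µM × 60 min sits exactly at the saturation point c·t = K of
the staining kinetics. After a treatment that kills each organoid with
probability 0.5, 31 green (live) objects remain (62 % of day 0 — the
binomial draw at n = 50 landed above its 50 % expectation), and the live
cross-sectional area fell to 22.7 % of day 0 — below the 36.42 % cutoff, so
the line is called treatment-sensitive.

`runPipeline(defaultRunConfig())` drives the same chain for a multi-well,
multi-group plate from a YAML-serialisable configuration, writing per-well
CSVs, group comparisons and a resolved config next to a run log. A thin CLI
over these functions is in `inst/scripts/organoidstack.R`
(`simulate | plan | fuse | quantify | assay | capture-curve | run`).

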