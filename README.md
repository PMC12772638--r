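# vsreport

Automated imaging-biomarker measurement and reporting for vestibular
schwannoma (VS) surveillance.

VS is a benign tumour of the vestibulocochlear nerve sheath. Small tumours
are typically managed by watchful waiting with serial MRI; treatment
decisions at the multidisciplinary team meeting (MDTM) hinge on whether the
tumour has grown. Standardized reporting distinguishes the **intrameatal**
portion (inside the internal auditory canal) from the **extrameatal**
portion (beyond the porus acusticus), and growth assessment needs both
linear and volumetric measurements extracted consistently across years of
scans — a tedious, variability-prone manual task.

`vsreport` takes longitudinal intra-/extrameatal segmentation masks (NIfTI
label volumes: 1 = intrameatal, 2 = extrameatal) plus a timeline manifest,
and produces the standardized measurements, growth classification and
rendered reports that support MDTM decision-making. A fully synthetic
two-compartment phantom generator with analytic ground truth makes the
entire pipeline testable without any clinical data.

## What it computes

Per session, from the canonicalized label volume:

- **D<sub>WT</sub>**, **D<sub>EM</sub>** — maximum in-plane diameters of the
  whole tumour and of the extrameatal portion, measured per axial slice by
  convex hull + rotating calipers over pixel-centre coordinates;
- **V<sub>intra</sub>, V<sub>extra</sub>, V<sub>whole</sub>** — compartment
  volumes (cm³) by voxel counting, with V<sub>whole</sub> =
  V<sub>intra</sub> + V<sub>extra</sub> exactly;
- **d(intra,∥), d(extra,∥), d(extra,⊥)** — compartment extents parallel and
  perpendicular to the meatal axis, estimated as the principal direction of
  the intra/extrameatal interface voxels.

One diameter is displayed per session. Operated (postoperative / post-SRS)
cases display D<sub>WT</sub>; entirely intrameatal tumours display
D<sub>WT</sub>; otherwise:

```
IF   d(intra,∥) >= d(extra,∥)  ->  use DWT
ELSE IF d(extra,⊥) > 2 mm      ->  use DEM
ELSE                           ->  use DWT
```

Growth between two sessions follows the EAONO significant-growth criteria
(all strict): **>2 mm** increase in the displayed diameter, **>1.2 cm³**
whole-tumour volume change, or **>20%** volume change. Changes beyond a
configurable fraction (default 0.5) of a threshold, but not past it, are
reported as *equivocal*. A surveillance timeline yields all consecutive-pair
assessments plus the two headline comparisons (index vs most recent, second
most recent vs most recent).

The report layer renders a deterministic, byte-stable HTML summary report —
per-session axial snapshots with the mask and diameter endpoints, stacked
intra-/extrameatal volume bars, a diameter-vs-months line chart with colour
coding (growth red, equivocal orange, no growth green) and decision icons —
and an extended report with the full measurement table, orthographic
silhouettes and an STL surface mesh per session.

## Worked example

Entirely synthetic: build a phantom, measure it, and assess a growing
three-session timeline.

```r
library(vsreport)

ph <- makePhantom(phantomParams())     # 0.5 mm voxels, two compartments
m  <- measureSession(cleanMask(ph$volume))
m
#> SessionMeasurements
#>   DWT: 18.97 mm, DEM: 11.93 mm
#>   d(intra,par): 5.91 mm, d(extra,par): 11.66 mm, d(extra,perp): 8.82 mm
#>   volumes (intra/extra/whole): 0.275 / 0.562 / 0.837 cm^3
#>   axial slices with tumour: 19

selectDisplayDiameter(m, "preoperative")
#> DiameterChoice: DEM = 11.93 mm (branch: extra_perp_gt2)
```

The extrameatal portion dominates along the porus trace (11.66 mm vs
5.91 mm) and extends 8.82 mm past the porus, so the extrameatal diameter is
the one a radiologist would report.

```r
res <- makePhantomTimeline(phantomParams(), scales = c(1.0, 1.08, 1.20),
                           dates = c("2020-01-15", "2021-01-15", "2022-01-15"),
                           decisions = c("surveillance", "surveillance", "SRS"),
                           dir = "phantom_series")
tl   <- readTimelineManifest(res$manifest)[[1]]
meas <- lapply(sessionTable(tl)$mask_path,
               function(p) measureSession(cleanMask(readLabeledVolume(p))))
ass  <- assessTimeline(tl, meas)
ass$indexVsLatest
#> GrowthAssessment [index_vs_latest]: growth
#>   deltaD = +2.39 mm, deltaV = +0.630 cm^3 (+75.2%)
#>   triggered by: diameter, volume_pct
```

A 20% linear size increase over two years trips both the diameter and
percentage-volume criteria (0.63 cm³ stays under the 1.2 cm³ absolute
criterion for a tumour this small). Rendering the reports:

```r
cmdReport(res$manifest, "reports", runConfig())
```

writes `PHANTOM01_summary.html`, `PHANTOM01_extended.html`, per-session STL
meshes and `measurements.csv`. The same pipeline is scriptable from a
shell via the installed entry point:

```sh
vsreport phantom --out-dir phantom_series --seed 1
vsreport report --manifest phantom_series/manifest.csv --out-dir reports
vsreport measure --manifest phantom_series/manifest.csv --out measurements.csv --diameter-mm 3
```

## Scope

Segmentation itself is out of scope: masks are inputs, produced upstream by
whatever segmentation process is in use. There is no DICOM/PACS
connectivity and no inter-session registration; each session is measured
independently. See `vignettes/vsreport-methods.Rmd` for the measurement
conventions, parameter choices and known limitations.
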