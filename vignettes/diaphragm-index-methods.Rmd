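---
title: "Measuring diaphragm configuration from chest CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diaphragm configuration from chest CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaphragmCT)
```

## The problem

Severe COPD traps air in the lung (hyperinflation) and pushes the diaphragm
into a flattened, mechanically disadvantaged configuration. The diaphragm
itself is hard to segment on CT — its density is close to that of the liver
and other abdominal organs — but the *lung--diaphragm intersection*, the
caudal surface of the lung segmentation resting on the diaphragm dome, is a
usable proxy. diaphragmCT extracts that surface from a lung or lobe
segmentation and summarises its shape as the **diaphragm index**:

$$\mathrm{DI} \;=\; \frac{\text{surface area of the diaphragm sheet}}
                        {\text{area of its axial projection}}$$

A perfectly flat diaphragm has DI = 1; a hemispherical dome has DI = 2. A
spherical cap of base radius $a$ and height $h$ has lateral area
$\pi(a^2+h^2)$ over base area $\pi a^2$, so its index is exactly
$1+(h/a)^2$ — the closed form that anchors all validation in this package.

## The extraction procedure

Processing assumes the canonical frame x = left→right,
y = posterior→anterior, z = caudal→cranial; volumes read from disk are
reoriented using header information. Each lung is processed independently:

1. **Resample** the label volume to an isotropic grid (default 1 mm) with
   nearest-neighbour assignment — a segmentation must never be interpolated.
   Output shape is `ceiling(extent / target)` per axis so no anatomy is
   cropped.
2. **Merge lobes into lungs** via a configurable label map (default:
   labels 1--2 left, 3--5 right).
3. **Lower third**: keep the caudal `round(extent/3)` slices of the lung's
   occupied z-range (at least one slice). The diaphragm dome lives here.
4. Per **coronal slice** (an (x, z) plane at fixed y):
   a. keep the largest 8-connected component;
   b. form the **outline** — dilation by a 3×3 box minus the region — a
      one-layer ring around the segmentation;
   c. **cut at the costophrenic recesses**: within the first and last 25%
      of the outline's x-extent, remove the most caudal voxel (outermost x
      on ties). If this splits the ring into exactly two components the
      smaller one — the caudal arc hugging the diaphragm — is retained;
   d. otherwise a **fallback trace** walks the ring outward from the most
      caudal voxel at the x-midpoint; each side's edge is its most caudal
      voxel if the ring ascends over the next 5 voxels beyond it, else the
      outermost voxel;
   e. **filters**: an arc is dropped if its path midpoint lies caudal to
      both endpoints (a valley — not a dome), or if its midpoint lies
      closer to its caudal extreme than 25% of the arc's x-extent (an
      inward-curving hook). Such slices, typically anterior/posterior of
      the dome, do not contain the lung--diaphragm intersection.
5. **Stitching**: each kept arc is overlaid with the previously kept arc,
   endpoints are joined pairwise (nearest pairing) by digital straight
   segments, and the enclosed region is filled. This guarantees that
   consecutive slice regions are 26-connected in 3D.
6. **3D cleanup**: only the largest 26-connected component of the stitched
   sheet is kept, which removes any fragments that slipped past the
   filters across slice gaps. Gaps are not bridged; the previous *kept*
   arc is used for stitching even across a gap.

## From voxel sheet to index

The (possibly multi-voxel-thick) sheet is collapsed to a **height map**:
per (x, y) column, the mean z of its surface voxels, in mm. The mean is
robust to the fill thickness left by stitching; heights are stored
relative to the sheet's own most caudal voxel, which makes every area
bit-for-bit independent of where the patient sat in the scanner.

Surface area is computed by triangulating every *complete* unit cell
(all four corner columns occupied) into four triangles meeting at the cell
centroid, and summing 3D triangle areas. Projected area is the number of
complete cells times the cell area — the same cell grid, so a flat sheet
has index exactly 1, and since no triangle is smaller than its axial
projection, DI ≥ 1 always. For two lungs the combined index pools areas:
$(SA_L+SA_R)/(PA_L+PA_R)$, the natural whole-diaphragm reading (per-side
indices are also reported).

The centroid fan (rather than a fixed diagonal split) was chosen because
it is exactly symmetric under left--right mirroring: per cell the corner
heights are canonicalised over the mirror symmetry before any float
arithmetic, and per-cell areas are summed in sorted order, so a mirrored
or translated input yields a bit-identical index. A fixed diagonal cannot
achieve this — its two triangles genuinely differ on non-planar cells.

## Connectivity conventions

Foreground uses 8-connectivity in 2D and 26-connectivity in 3D, so thin
diagonal curves count as connected; hole filling floods 4-connected
background, which an 8-connected closed curve seals.

One convention deserves emphasis. The box-dilation outline is thick at
staircase corners: under 8-connectivity those corners carry diagonal
shortcuts, and removing the two costophrenic voxels essentially never
separates the ring (verified on digital circles and dome cross-sections).
The same ring *is* a simple 4-connected cycle, and one removal per band
then splits it into exactly two arcs, which is the behaviour the method
is built on — the fallback trace is reserved for genuinely degenerate
slices. The post-cut component analysis therefore uses 4-connectivity;
the retained arc is still an 8-connected set, and all other steps keep
the conventions above.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `target_spacing` | 1 mm | isotropic processing resolution |
| `band_fraction` | 0.25 | width of each costophrenic search band |
| `ascent_check_length` | 5 voxels | ascent check past a candidate edge in the fallback trace |
| `filter2_min_distance_fraction` | 0.25 | minimum midpoint-to-caudal-extreme distance, as a fraction of arc x-extent |
| `lower_fraction` | 1/3 | caudal fraction of the lung retained |
| emphysema threshold | −950 HU | densitometry cutoff (%LAA-950) |

The ascent length and the filter-2 fraction are judgement calls — "a few
pixels" and "too short" are inherently soft notions — and are exposed in
`extraction_params()` rather than hard-coded. Two tie-breaks matter in
degenerate geometry: equal-size 2D components resolve to the first in
(z, x) scan order, and when an arc's most caudal voxel is tied (a
perfectly flat arc) filter 2 uses the tied voxel *farthest* from the
midpoint — the nearest would discard every flat arc, i.e. exactly the
severe-hyperinflation diaphragms the index exists to measure.

## The cap phantom: what it validates, and what it does not

`make_cap_phantom()` builds a cylindrical lung body whose caudal boundary
is a spherical cap: lung voxels satisfy $\rho \le a$ and
$\mathrm{dome}(\rho) \le z \le z_\mathrm{top}$ with
$\mathrm{dome}(\rho) = z_\mathrm{base} + \sqrt{R^2-\rho^2} - (R-h)$,
$R = (a^2+h^2)/(2h)$. Lobe labels are split by height so the lobe merge
is exercised. The lung height defaults to $\max(3.5h, 40)$ mm, keeping
the dome strictly inside the lower third (as in real anatomy, where the
dome is small relative to lung height) so mid-lung cross-sections stay
simply connected. Generation is deterministic; optional surface
roughening sits behind an explicit seed.

```{r phantom}
spec <- cap_phantom_spec(a = 30, h = 15, lung_height = 55)
res <- measure_diaphragm(make_cap_phantom(spec))
res$index
analytic_cap_index(30, 15)
```

The test suite checks recovery of $1+(h/a)^2$ across a dome-height ladder
($a = 60$ mm, $h = 12 \ldots 60$ mm at 1 mm voxels, phantoms of roughly
$127 \times 127 \times 220$ voxels — a scale each of which extracts in a
few seconds), the flat limit, strict monotonicity in $h$, per-column
surface fidelity against the analytic dome, and bit-identical behaviour
under translation, mirroring and reruns. Near the hemisphere limit the
rim of the cap is nearly vertical, so the height-map triangulation loses
part of the steep rim annulus to discretisation; the measured index there
sits a few percent below the closed form, and validation tolerances are
wider at $h = a$ for that reason.

What the phantom does *not* emulate: real lobe segmentations have rough,
noisy boundaries, partially collapsed regions, a zone of apposition
against the rib cage, a cardiac notch, and occasional segmentation
defects. Passing the phantom suite shows the geometry pipeline is
correct, not that segmentation-quality failure modes are handled; the
cohort QC tools (IQR outlier flagging, defect-label tabulation) exist
precisely because visual inspection remains necessary on real data.

## Cohort QC

`flag_outliers()` implements the 1.5×IQR rule per group (e.g. GOLD
stage): values outside $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 +
1.5\,\mathrm{IQR}]$ are flagged for inspection. Quartiles use linear
interpolation between order statistics (the `quantile()` type-7 default);
groups of fewer than 4 records are skipped with a warning, as quartiles
of so few points are not meaningful. `summarize_groups()` reports
n / mean / sample SD / range per group. Statistical inference between
groups is deliberately out of scope — the CSV outputs drop into any
statistics environment.

## Known limitations

- The method measures the lung--diaphragm intersection, not the muscle:
  no thickness, no zone of apposition, no motion.
- Slices whose arcs the filters reject leave gaps that are resolved by
  the largest-component step, not bridged; a diaphragm split into two
  similar-size sheets by a long run of rejected slices would lose one.
- Oblique acquisitions are supported only insofar as the header carries
  an axis-aligned orientation; truly oblique direction matrices are
  rejected rather than silently mis-frame the anatomy.
- Very coarse voxels (≫ 1 mm after resampling) bias the index upward on
  shallow domes via staircase area; keep the default 1 mm target.
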