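---
title: "Quantifying TNT-like protrusions and organelle transfer in fluorescence micrographs"
author: "tntquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TNT-like protrusions and organelle transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntquant)
```

## The measurement problem

Tunneling nanotubes (TNTs) are long, thin, actin-rich membrane channels
through which cells — macrophages prominently among them — pass organelles
such as lysosomes and mitochondria to neighbouring cells.  Two readouts
dominate wide-field co-culture experiments:

1. **Protrusion frequency** — what fraction of fluorescently labeled
   macrophages carry at least one thin, elongated membrane protrusion, and
2. **Transfer frequency** — what fraction of labeled recipient cells
   (typically DsRed⁺ fibroblasts) contain at least one donor-tagged punctum
   (e.g. a cystinosin–eGFP lysosome) delivered from the other population.

Both are percent-positive readouts over hundreds of cells per stitched
field, which makes manual scoring slow and biased.  `tntquant` implements
both workflows as deterministic, configurable pipelines, together with a
seeded synthetic scene generator that provides exact ground truth for every
stage, so the pipelines can be validated end to end without any microscope
data.

## Protrusion detection by opening residue

The cell channel is thresholded (Otsu's method on the image itself by
default), internal holes are filled, and connected components of at least
100 µm² are taken as cells.  For each cell mask $A$ the pipeline computes a
morphological opening

$$\gamma(A) = (A \ominus B^{(n)}) \oplus B^{(n)},$$

i.e. $n$ erosion passes followed by $n$ dilation passes with structuring
element $B$ (default: 3×3 square, $n = 7$).  The opening removes every
structure thinner than the accumulated element extent and restores the
central cell body; the **residue** $A \setminus \gamma(A)$ is therefore
exactly the thin peripheral material — the candidate protrusion set.  The
residue's connected components are filtered with four shape criteria
(defaults in parentheses, every comparison inclusive):

* area ≥ 20 µm²,
* maximum Feret diameter ≥ 10 µm,
* circularity ≤ 0.6, where circularity is the region area divided by the
  area of a circle whose diameter equals the region's maximum Feret
  diameter (1.0 for a disk, → 0 for a line),
* bounding-box-area / region-area ≥ 1.9, which selects elongated or bent
  shapes.

A cell is **protrusion-positive** when at least one filtered component
overlaps or touches (8-neighbourhood) the opened body.  The per-field
summary is $100 \times n_\text{positive} / n_\text{cells}$, with cells
whose body vanished entirely under erosion ("degenerate") excluded from
both counts and reported separately — a fully eroded cell would otherwise
be all residue and count positive by construction.

```{r protrusions}
scene <- generate_scene(scene_spec(seed = 7, field_size = 768,
                                   n_macrophages = 12, n_fibroblasts = 0,
                                   protrusion_prevalence = 0.4))
pa <- analyze_protrusions(scene$cell)
percent_positive(pa)
```

### Parameters that matter

* **`pixel_size` (µm/px, mandatory).**  Every µm-stated threshold is
  converted through it; it is never read silently from image metadata
  (TIFF resolution tags, when present and conflicting by more than 1%,
  produce a warning).  The synthetic fixtures use 0.5 µm/px, a typical
  wide-field 40× sampling.
* **`passes` (default 7).**  A pixel-space parameter: the opening captures
  structures up to roughly `2 * passes` px across (3×3 element).
  `captured_width_um()` reports this in µm so the parameter can be rescaled
  at other calibrations — at 0.5 µm/px the default captures widths up to
  ≈ 7 µm, comfortably above the 1–3 µm of typical TNTs and below cell-body
  diameters.
* **Structuring element.**  The 2×2 square element has no central pixel;
  `tntquant` implements it with a fixed anchor convention (offset set
  {(0,0),(0,1),(1,0),(1,1)}, reflected for dilation) under which the
  composite is a true anti-extensive opening.  The centred 3×3 element with
  the same pass count is the default because its behaviour is
  anchor-free and reproducible across implementations; both are tested
  pixel-exactly against a set-definition oracle.
* **Shape filters.**  The four TNT filters sit near the geometry of real
  protrusions (a 2 µm × 30 µm ribbon passes all four; a 15 µm² blob and a
  disk fail).  The box-area criterion is interpreted as the dimensionless
  bounding-box/area ratio — a pure number ≥ 1 that is large for elongated
  or bent shapes; it can be disabled by setting its minimum to 0.

## Shape descriptors

`measure_region()` computes area, maximum Feret diameter ("length"),
circularity, equivalent-ellipse aspect ratio (major/minor axis of the
ellipse with the region's second central moments; each pixel contributes
1/12 to the diagonal moments so 1-px-wide shapes stay finite), and the
bounding-box ratio.

Two geometric conventions are worth stating precisely:

* **Feret diameter is computed over pixel corner points** (each pixel
  contributes the four corners of its unit square; the exact maximum is
  taken over convex-hull vertices, with no orientation sampling).  Under
  this convention a $w \times h$ axis-aligned rectangle measures exactly
  $\sqrt{w^2+h^2}$ px and a digital disk of radius $r$ measures $2r + 1$ px,
  giving disk circularity ≈ 0.98.  Pixel-*center* distances were considered
  and rejected: they understate a square's diagonal by $\sqrt2$ px, which
  breaks the closed-form rectangle identity that the corner convention
  satisfies exactly.  Centroids and moments use pixel centers.
* **Circularity can exceed 1 slightly** for near-disks by rasterization;
  the raw value is used for filtering, and a display copy is capped at
  [0, 1.05] for transparency rather than silent clipping.

"Length" of a protrusion is its maximum Feret diameter.  TNTs can curve;
for strongly bent structures a traced/geodesic length would read longer
than the caliper, so the generator bounds ribbon curvature such that the
caliper stays ≥ 0.9 of the arc length, keeping the two definitions within
10% on all fixtures.  `apply_cut_lines()` supports the complementary manual
workflow — cutting a protrusion off the body along a drawn polyline and
measuring the separated piece.

## Transfer quantification

Recipient cells are segmented from the recipient channel (minimum 100 µm²)
and each becomes a region of interest applied to the donor channel.  The
donor background threshold comes from **donor-free control images**
(default: type-1 percentile 99.9 of pooled control pixels, which bounds the
supra-threshold fraction on the controls at 0.1%).  Donor components are
labeled on the full channel and triaged per ROI with a fixed, auditable
precedence:

1. components smaller than `punctum_min_area` (default 1 µm²) are
   suppressed as detector noise — a single supra-threshold noise pixel is
   not an object and must not consume a boundary or size verdict;
2. components touching a `boundary_width`-px inner margin of the ROI (or
   extending beyond it) are excluded (`excluded_boundary`) — edge signal
   typically reflects an overlapping donor cell rather than transfer;
3. remaining fully-interior components larger than `punctum_max_area`
   (default 25 µm²) are excluded (`excluded_oversize`);
4. the rest are accepted puncta.

A recipient is donor-positive iff it holds ≥ 1 accepted punctum; the
summary unit is one percent-positive value per field, matching how
stitched-image experiments are reported and averaged.

```{r transfer}
tr_scene <- generate_scene(scene_spec(seed = 11, field_size = 1024,
                                      n_macrophages = 0, n_fibroblasts = 10,
                                      n_interior_puncta = 25,
                                      n_edge_puncta = 5,
                                      n_oversize_blobs = 3,
                                      recipient_positive_fraction = 0.8))
ctrl <- generate_control(scene_spec(seed = 99, field_size = 1024))
cfg <- transfer_config(background = estimate_background(ctrl, "percentile",
                                                        99.9))
ta <- classify_recipients(recipient_rois(tr_scene$recipient, cfg),
                          tr_scene$donor, cfg)
ta$summary
colSums(ta$recipients[, c("n_puncta", "excluded_boundary",
                          "excluded_oversize")])
```

Because components are defined before ROI clipping, one physical punctum
spanning two touching recipients is boundary-excluded from both rather than
double-counted.  Whether the size cap should apply before or after ROI
clipping is ambiguous for boundary-spanning objects; clipping-first with
boundary exclusion taking precedence makes the question moot for accepted
puncta (they are always fully interior).

## The synthetic scene generator

`generate_scene()` draws, deterministically from a mandatory seed:

* macrophage bodies — rasterized ellipses of 150–600 µm² (aspect 1–1.8,
  random orientation), matching spread macrophage footprints;
* TNT-like ribbons on a Bernoulli fraction of macrophages
  (`protrusion_prevalence`, default 0.4) — quadratic-Bézier strokes of
  width 2 µm and length 45 ± 15 µm truncated at ≥ 15 µm, attached radially
  to the body.  These dimensions sit at the scale reported for macrophage
  TNT populations, and deliberately place fixture objects near the filter
  thresholds where tests are most informative.  The default bend (control
  point offset 0.15 × length) keeps the caliper ≥ 0.9 × arc length and
  lifts the bounding-box ratio of every orientation well above the 1.9
  filter, so classification does not hinge on the measure-zero axis-aligned
  case;
* fibroblast bodies of 400–1500 µm² — cultured fibroblasts spread larger
  than macrophages, and recipient ROIs must be deep enough to hold several
  well-separated interior puncta;
* donor puncta — disks of 2–20 µm² placed fully interior (with ≥ ~5 px
  clearance from the ROI margin so noise cannot bridge a punctum to the
  boundary band), centered on the boundary (straddling), or as 40 µm²
  oversize blobs; placements are spaced ≥ 5 px apart so thresholded
  components never merge;
* images — object intensity 1000 plus Gaussian background N(100, 10) on a
  16-bit scale (optional Poisson photon noise), a 10:1 contrast typical of
  a clean fluorescent-protein channel.

The ground truth records every placement, so recall, precision, exact
counts and percent-positive values can all be scored.  What the generator
does **not** emulate: point-spread-function blur, illumination gradients,
stitching seams, out-of-focus debris, touching/overlapping cells within one
channel, and 3-D structure.  Passing tests therefore demonstrate the
correctness of the *algorithms* under controlled imaging conditions, not
robustness to every real-world artifact; on real data the background model
and filters are the knobs that absorb those effects.

## Numerical choices and degenerate inputs

* Thresholding is strict (`pixels > threshold`); area bounds are inclusive
  ("100 µm² or larger" means ≥).
* Default connectivity is 8, so 1-px diagonal protrusion necks stay
  attached to their cell body; 4-connectivity is available and both are
  tested against a flood-fill oracle.
* Holes inside cell masks are filled before morphology, so internal holes
  cannot surface as spurious residue.
* Erosion treats pixels beyond the image border as background; each cell is
  processed in a crop padded by `passes + 2` px so cells never interact.
* An image with no supra-threshold pixels yields an empty region set, not
  an error; a group with zero valid cells reports a missing percentage
  (`NA`), never 0%.
* Single-pixel regions have defined area but undefined length/circularity;
  they are flagged and excluded from summaries.
* Scene generation saves and restores the caller's RNG state.
* The percentile background uses type-1 (inverse-ECDF) quantiles so its
  supra-threshold guarantee on the controls is exact; the `mean_plus_k_sd`
  threshold is the literal formula and may exceed the observed maximum of
  a finite control sample — intentionally, since it models the tail of the
  noise distribution rather than the sample extremum.

## Problem sizes used in the test-suite

The validation suite runs the classification-recovery benchmark on one
2048² px field with 100 macrophages at 40% prevalence (accuracy ≥ 0.95
against ground truth), exact transfer counting on a 1024² field with 10
recipients and 25/5/3 interior/edge/oversize puncta, a 20-field donor-free
false-positive control at 512², and pixel-exact morphology checks on 200
random 32² and 64² masks for both structuring elements.  These sizes give
stable statistics while keeping a full run in tens of seconds on one CPU;
all of them scale linearly if larger benchmarks are wanted.

## Known limitations

* Touching cells are not split (no watershed); real workflows exclude
  overlap signal, and the boundary-exclusion rule implements exactly that
  for transfer scoring.
* The protrusion detector reports residue components, which rarely capture
  a protrusion's full extent back to the membrane; absolute protrusion
  areas are therefore conservative, which is why the cut-line workflow
  exists for morphometry-grade measurements.
* Circularity uses the Feret-based definition throughout; it is not the
  ISO "form factor" $4\pi A / P^2$, and values from other software using
  perimeter-based definitions are not directly comparable.
* The 2×2 element's anchor convention is this package's own; other tools
  with unstated anchors may shift results by one pixel per pass.
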