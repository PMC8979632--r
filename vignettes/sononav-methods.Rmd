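---
title: "Ultrasound-only resection planning: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound-only resection planning: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Non-anatomical (atypical) liver resection removes only the tumor plus a
safety margin, sparing parenchyma. Without anatomical landmarks the surgeon
must mentally fuse the 2D intra-operative ultrasound with the 3D scene,
which makes negative (R0) margins hard to achieve. sononav implements the
computational core of a navigation approach that builds the entire surgical
plan from *tracked intra-operative ultrasound alone* — no pre-operative
CT/MRI registration — so the model is acquired after the large deformations
(mobilisation) have already happened:

1. **Surface scan.** The tracked probe glides over the liver; frames with
   full capsule contact each contribute one 3D surface point; a streaming
   outlier filter cleans the stream; the point cloud becomes a surface mesh.
2. **Tumor segmentation.** On one frozen frame showing the largest tumor
   cross-section, a seeded graph cut extracts the lesion from a single
   centre click plus an approximate diameter, with click-based corrections.
3. **Planning.** The tumor is modelled as a sphere; a cone is fitted so its
   boundary keeps the chosen safety margin from the tumor everywhere; its
   intersection with the surface mesh is the resection line.
4. **Margin analysis.** After resection (here: simulated), the 3D distance
   between the tumor mesh and the specimen's cut surface yields the margin
   and the R0/R1 call (R0 iff margin strictly exceeds 1 mm).

Everything runs on synthetic phantoms with full ground truth, so each stage
is validated against analytic or brute-force oracles.

## Coordinate chain and conventions

All 3D quantities are millimetres in a right-handed camera frame. A pixel
`(px, py)` of frame *i* maps to 3D as

```
p = C_T_MS(i) · MS_T_US · T_scale · (px, py, 0, 1)'
```

with `T_scale = diag(sx, sy, 1, 1)` from the pixel spacing and `MS_T_US`
the fixed probe calibration (an *input*, estimated externally on the real
system). The image convention is pixel (0,0) top-left, +x lateral,
+y axial/depth, image plane z = 0. Rigidity is enforced at 1e-9
(orthonormal rotation, det +1), and `compose()` is a plain matrix product,
so the chain mirrors the navigation system's transform algebra literally.

## Contact classification

Only frames with full capsule contact may contribute surface points.
Contact manifests in the near field, so five statistics of the upper third
of the image (min, max, mean, sd, excess kurtosis) feed an RBF-kernel SVM
on standardised features. Choices worth noting:

* *Excess kurtosis* (normal → 0); a zero-variance patch maps to 0 with a
  warning, so train and predict cannot silently disagree on degenerate
  frames.
* "Upper third" is the top `floor(H/3)` rows — the shallow band at the
  transducer face where the contact artefact lives.
* The real device applies automatic gain; the phantom instead renders
  contact frames at a fixed mean brightness, which stands in for that
  normalisation.

The SVM's kernel and training size are not constrained by any reported
number, so classifier quality is asserted only on phantom data: held-out
accuracy at n = 400 must reach 0.95, and in practice is ~1.0 because the
dark no-contact near field is trivially separable from tissue speckle.

## Surface scanning and the LOF filter

Candidate surface points (by default the top-row midpoint pixel — the
transducer-face centre on the capsule) stream through a FIFO buffer of the
last `W = 10` points. Once the buffer holds more than `k = 9` points, a
candidate joins the cloud only if its local outlier factor against the
buffer is at most `tau`. A no-contact frame clears the buffer, so a probe
lift-off can never bridge stale geometry into a new sweep segment.

The LOF inlier rule needs care: by construction LOF ≈ 1 for points exactly
as dense as their neighbourhood and *fluctuates around* 1 for genuine
inliers, so a hard threshold of exactly 1 would reject about half of them.
The default is therefore `LOF <= 1.5`; the stricter printed variants are
preserved as auditable presets (`"prose"`: accept `LOF < 1`;
`"pseudocode"`: accept `LOF > 1`). The implementation follows the classical
definition (k-distance with ties, reachability distance, local reachability
density) in the "novelty" convention — neighbourhoods are taken within the
buffer only — and is checked against an independent brute-force
implementation to 1e-9 on random instances.

## Surface reconstruction

The scanned patches are open, graph-like surfaces, so reconstruction is a
tangent-plane signed-distance zero-set in Hoppe's spirit, specialised to
that geometry: the cloud's PCA base plane parameterises the patch; around
each node of a regular grid (default 2 mm) a weighted linear tangent plane
is fitted to the `k = 12` nearest points (Gaussian weights, bandwidth = the
neighbourhood's median radius); the plane's value at the node is the
zero-crossing of the local signed distance along the base normal. Nodes
with no point within 6 mm, or whose support is one-sided (neighbourhood
centroid farther than 1.75 × grid from the node), are dropped rather than
extrapolated — trimming the footprint beats bending tangent planes past the
data. Grid cells with all four corners alive become two triangles.

Contracts: a noiseless plane reconstructs to |z| ≤ 1e-6 mm; a 60 mm sphere
cap sampled at σ = 0.2 mm noise stays within 1 mm symmetric Hausdorff; a
500-frame phantom sweep at 0.2 mm / 0.2° pose noise stays within 1 mm of
the analytic heightfield over the scanned area.

## Graph-cut segmentation

The energy is the standard seeded min-cut objective

```
E(l) = sum_p  -log P_{l(p)}(I_p)  +  lambda * sum_{(p,q)} exp(-dI_pq^2 / 2 sigma^2) / dist(p,q) * [l(p) != l(q)]
```

with per-region 32-bin histograms (Laplace-smoothed) as intensity models,
8-connectivity, and `sigma^2 = mean(dI^2)` over neighbour pairs. The seed
disk (the selected diameter) is hard foreground; the 20 mm annulus is free
("probably foreground"); outside the annulus is hard background by default
— with soft background a zero-contrast image would have no unique minimiser,
whereas hard background makes the seed disk the strict minimum there
(`bg_mode = "soft"` remains available). Data terms are computed on a
1.5-pixel Gaussian-smoothed image to tame speckle; the contrast term stays
on the raw image. `lambda = 8` by default.

Numerical choice: capacities are quantised to 2^-26 before the max-flow
solve. Integral capacities let the solver take a much faster path, and the
perturbation (~1.5e-8 per edge) is orders of magnitude below any data-term
difference; the exhaustive-enumeration oracle bounds the residual energy
gap at 1e-4 on 16-pixel instances.

A correction click re-seeds a 3 mm neighbourhood — hard background if the
click is inside the current mask, definite foreground if outside; that
membership test *is* the add/remove decision. The returned mask is the
connected component containing the seed (configurable off), and the sphere
tumor model takes the mask centroid (through the frame pose) as centre and
the equal-area circle diameter as diameter. The single-slice sphere
approximation is deliberate and inherited from the system being modelled;
irregular tumors would need multi-slice segmentation, which is out of
scope.

## Cone planning

The plan's axis runs from the tumor centre to the exact closest point on
the surface mesh (point-to-triangle over all faces; ties broken by lowest
face index). With tumor radius r, margin m and half-angle α, a point on the
axis at distance d below the centre has lateral-wall clearance d·sin α, so
the apex sits at

```
d_apex = max( (r + m) / sin(alpha),  r + m + clearance )
```

making the lateral wall exactly tangent to the margin sphere (first term)
while keeping a depth clearance below it (default 2 mm). The half-angle is
the one free shape parameter (default 45°; the in-silico trials use 30° to
keep the resection line inside a practical scan footprint). The fitted plan
is audited internally: minimum cone-boundary-to-tumor distance ≥ m − 1e-6.

The resection line is extracted by finding every mesh edge that crosses the
cone's implicit function (bisection along the edge), ordering crossings by
azimuth about the axis, and refining chords longer than 1 mm with points
projected back onto both surfaces. Overlay projection intersects each plan
structure with a frame's plane analytically (sphere → circle, cone → conic
arc sampled along generators, line vertices within a 1 mm band → marks) and
maps to pixels through the inverse calibration chain; every structure is
independently toggleable.

## Margin analysis

The tumor mesh is densified until no edge exceeds 0.5 mm; every vertex gets
its exact distance to the specimen. The *minimum* drives the R0/R1 call —
it is the oncologically meaningful margin, and the rule is strict:
R0 iff min > 1 mm, so exactly 1 mm is R1. The full distribution is kept for
reporting and PLY heat-map export. Cohort summaries use type-7
(linear-interpolation) quantiles.

Where the distance is measured matters for shallow tumors: the clinical
resection margin is the distance to the *cut* surface, not to the capsule
side of the specimen (a tumor 15 mm deep can be 8 mm from the capsule yet
10 mm from every cut). `measure_margin()` therefore takes an optional cut
surface; plain mesh pairs use the whole specimen boundary, and simulated
resections pass the cut wall explicitly. A tumor vertex outside the closed
specimen marks protrusion: margin 0, R1.

## The synthetic phantom

The generator emulates the ex-vivo conditions the approach was evaluated
under:

| parameter | default | basis |
|---|---|---|
| tumor diameter | N(12.1, 2.5) mm, truncated > 4 mm | reported mimic sizes |
| tumor centre depth | uniform 10–20 mm below surface | reported placement |
| lesion appearance | hyperechoic, contrast ratio 2.0 | reported appearance |
| surface | smooth random cosine heightfield, 4 mm amplitude, ~45 mm correlation | a plausible liver-lobe surface |
| imaging | 60 × 50 mm field, 0.2 mm/px | arbitrary, documented (device unspecified) |
| speckle | multiplicative Rayleigh, mean 70 | 8-bit headroom so a 2–2.5× lesion does not clip |
| pose noise | 0.2 mm / 0.2° | optical-tracker scale |

B-mode rendering is appearance-level — speckle, lesion contrast, mild depth
attenuation, a dark noisy near field on lift-off — not wave propagation:
the pipeline consumes intensity statistics and contours only, so passing
tests demonstrate geometric and statistical correctness, *not* robustness
to real acoustic artefacts (shadowing, reverberation, anisotropic speckle,
deformation). Tumors are spheres to match the pipeline's own single-slice
model (so planning error is attributable); execution noise displaces the
simulated cut wall along its normal by a Gaussian-filtered random field
(coherent surgical deviation, not vertex jitter), blended to zero at the
apex, and the rim is re-projected onto the liver surface.

## Validation sizes and determinism

Every generator is deterministic given its seed (the RNG state is saved and
restored around each). The test-suite / acceptance problem sizes: 200
random LOF instances (n ≤ 20, k = 5); one 500-frame sweep plus 100 seeded
60-frame outlier sweeps; 100 exhaustive graph-cut instances (≤ 16 free
pixels) plus 20 seeded lesions at contrast 1.5 (128–160 px frames at
0.4–0.5 mm/px); sphere-pair margin oracles at 80 × 40 resolution; 20
end-to-end in-silico resections at a 10 mm margin plus a
{0, 1, 3, 5} mm execution-noise sweep over 12 of them (margin sampling
1 mm there; halving it moves the minimum by < 0.05 mm). In-silico margins
land within ±1 mm of plan; the R0 rate is 100% at zero noise and decreases
with execution noise — ties between adjacent noise levels are expected
where both rates saturate at 100%.

## Known limitations

* No tissue deformation, shadowing or probe-pressure artefacts in the
  phantom; real-data performance is not claimed.
* The tumor model is a single sphere from one slice; strongly irregular
  lesions violate it (inherited, deliberate).
* Calibration is consumed, never estimated; no tracker/US latency model.
* The cone is a full cone with a configurable half-angle; the original
  device's aperture rule is unknown and not claimed.
* Reconstruction assumes graph-like patches; strongly overhanging anatomy
  would need a full volumetric zero-set extraction.
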