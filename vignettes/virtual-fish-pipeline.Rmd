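---
title: "Methods: simulating, rendering and annotating virtual RAS fish imagery"
author: "finsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, rendering and annotating virtual RAS fish imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finsim)
```

`finsim` generates synthetic training data for in-tank fish detection in
recirculating aquaculture systems (RAS). This vignette is the package's own
account of the models it implements, the parameters that matter, the
numerical choices behind them, and what the test suite does and does not
demonstrate about real data.

## 1. The schooling model

Fish are Boids particles: point agents with position and velocity that steer
by three local rules evaluated over the neighbours within a perception
radius $\rho$:

* **separation** — for each neighbour closer than the personal-space
  distance $d_{\min}$, a repulsion along the separating direction weighted
  by $1 - d/d_{\min}$;
* **alignment** — the difference between the mean neighbour velocity and the
  fish's own velocity;
* **cohesion** — the vector from the fish to the neighbour centroid.

Each term is scaled by its weight and clamped to the acceleration limit
$a_{\max}$, as is the sum. This is the canonical Boids rule set; the system
this package emulates names the particle model but not its internal rules,
so the classic definition is the defensible choice.

Three environmental force fields complete the model:

* **Vortex forcing.** Tank flow makes RAS fish swim in circles. Each vortex
  contributes a horizontal acceleration tangent to the circle through the
  fish about the tank axis, with magnitude
  $s \exp(-|z - z_0|/\lambda)$ for source plane $z_0$, strength $s$ and
  axial decay length $\lambda$. The default configuration pairs a dominant
  counter-clockwise vortex at the floor with a weaker clockwise one at the
  lid. A top/bottom pair of opposing vortices does not by itself define a
  net rotation direction, so the package makes the bottom vortex dominant —
  a deliberate reading, exposed through configuration rather than asserted
  as the only one.
* **Boundary avoidance.** Smooth quadratic repulsion from the wall, floor
  and lid starting an influence distance before the hard boundary
  ($a = a_w (1 - d/L)^2$), so fish turn before they hit anything.
* **Barrier.** A cuboid ramp placed upstream of the camera repels fish
  within a range of its faces along the outward face normal. This keeps the
  school from swimming into the lens, which otherwise floods frames with
  out-of-focus foreground bodies.

### Integration and containment

The state advances by explicit Euler: $v \leftarrow v + \Delta t\, a$ with
the speed clamped to $[v_{\min}, v_{\max}]$ (fish neither stall nor dart),
then $p \leftarrow p + \Delta t\, v$. Containment is enforced exactly after
each step by reflecting positions and velocities at the allowed cylinder
radius, the floor, the lid and the barrier faces. Residual fish–fish
overlaps (pairs closer than $d_{\min}$) are resolved by a soft push-apart
that splits the correction equally between the pair; push-apart and
containment alternate for up to four rounds because a reflection near the
wall can re-compress a freshly separated pair. Collision handling is thus
soft steering plus positional projection, not rigid-body dynamics — the
usual choice in flocking simulators, where contacts should be avoided
rather than resolved with impulse physics.

First-order integration is cheap and adequate here because the test suite
pins a convergence guardrail: halving $\Delta t$ must change a single-fish
trajectory endpoint by a decreasing, $O(\Delta t)$-sized amount.

### Defaults and units

Everything is metres and seconds. The default tank is a 150 m³ growout
cylinder (radius 3.45 m, water depth 4.0 m) with a 0.15 m wall margin. The
default school is 200 fish — commercial densities are quoted in kg·m⁻³
rather than counts, and 200 market-size trout (~1 kg) in 150 m³ is a
deliberately light stocking that keeps frames readable. Behavioural
defaults (cruise speeds 0.3–1.2 m s⁻¹, i.e. roughly 1–3 body lengths per
second; perception 0.6 m; separation/alignment/cohesion weights
2.0/0.5/0.15; $\Delta t$ = 50 ms) are not published quantities: they were
chosen once so that the simulated school satisfies the properties the
package promises — exact containment, a minimum pairwise distance of at
least half the personal-space radius over long runs, a coherent rotation
that follows the vortex sign, and a vertically spread (rather than
surface-clumped) school. Strong cohesion values produce a single wandering
ball of fish, which is visually striking but ruins the uniform spatial
coverage a training set needs; the default weights keep cohesion weak.

Initial positions are uniform in the allowed cylinder (excluding the
barrier), with tangentially biased headings, since the emulated system does
not describe its initialisation. Same seed, same trajectory, bitwise.

## 2. The renderer

Each school state is rasterized through a rectilinear pinhole camera. The
default sensor spec matches the wide-angle in-tank camera whose imagery this
pipeline is meant to complement: 1920 × 1080 px with a 140° horizontal field
of view, giving $f_x = (W/2)/\tan(\text{hfov}/2)$ with square pixels and the
principal point at the image centre. A true 140° lens would show barrel
distortion; the package deliberately renders undistorted rectilinear frames
and documents the simplification — the annotation geometry stays exact, at
the cost of a wider-than-physical rectilinear footprint.

Fish geometry is a procedural stand-in for a licensed trout model: an
ellipsoidal body (35 × 10 × 5 cm) plus a flattened caudal-fin fan, about a
hundred triangles. The mesh is an injectable `fish_mesh` object, so users
with their own scanned or artist-built model can substitute it.

Rasterization is a classic z-buffer: triangles are projected, screen-space
barycentric coordinates with perspective-correct inverse-depth interpolation
decide coverage at pixel centres, and the nearest surface wins each pixel.
Depth ties keep the earlier triangle in a fixed fish-then-triangle order, so
rendering is deterministic. The output is a `layered_frame` with three
co-registered rasters — RGB, Euclidean ray depth (infinite for background)
and the 1-based fish instance id — the exact analogue of a multi-channel
layered render (R, G, B, Z, ID). Shading is flat: one overhead diffuse
light over a 0.35 ambient floor, reflecting the shadowless uniform lighting
of indoor RAS halls. On small scenes the rasterizer is verified to agree
*exactly* with a brute-force per-pixel point-in-triangle oracle.

Triangles touching the near plane are dropped rather than clipped; at the
default near distance (5 cm) this only affects fish already inside the
barrier's keep-out zone.

### Turbidity

Water turbidity is modelled as Beer–Lambert attenuation plus scattering
blur. Per pixel, transmittance $T = e^{-\beta d}$ blends the surface colour
toward the background water colour ($T\,c + (1-T)\,c_{bg}$; background
pixels get exactly $c_{bg}$); pixels beyond a start distance are then
Gaussian-blurred with $\sigma = k (d - d_0)$ pixels, applied in six equal
depth bins so far fish blur more than near ones. Binning trades smooth
depth-of-field for speed and can seam at bin boundaries; for training-data
purposes the seams are invisible at realistic $k$.

Two shipped presets bracket RAS visibility: low turbidity
($\beta = 0.25\,\mathrm{m^{-1}}$, $k = 0.5$ px/m) and high turbidity
($\beta = 0.85\,\mathrm{m^{-1}}$, $k = 2.0$ px/m). The emulated rendering
system exposes scatter/absorption distances whose values are unpublished,
so these coefficients are qualitative stand-ins calibrated to one testable
ordering: on identical scenes, the number of fish whose contrast against
the water colour exceeds a fixed threshold is never larger under the high
preset than under the low one. Contrast itself is monotonically
non-increasing in both $\beta$ and distance, which the suite also checks.

Frames serialise to a lossless R-native container holding the three named
layers (round-trips are bit-identical, including the infinite-depth
sentinel), with PNG export for visual inspection.

## 3. Automatic annotation

Because the renderer writes the instance id into every covered pixel,
ground-truth labels are a deterministic function of the layers:

1. **Extract** one instance per distinct id. The id defines the instance —
   no connected-component analysis — so a fish split into disjoint pixel
   groups by an occluder stays one instance. Its representative depth is
   the median of its pixels' depths; the median resists the boundary pixels
   that straddle the silhouette.
2. **Filter** by pixel count first ($\ge$ `min_pixels`), then by depth
   ($\le$ `max_depth`). Tiny slivers carry no learnable signal, and far
   fish are blurred into the background; annotating either teaches a
   detector to box noise. Exclusion reasons are logged in rule order. The
   defaults (100 px, 3.0 m) are repo choices, not measured constants, and
   production configs should set both explicitly.
3. **Record** the tight axis-aligned box over the surviving pixels in COCO
   convention — $(x_{\min}, y_{\min}, w, h)$, 0-based pixel coordinates,
   origin top-left — with the 2-D mask centroid as the centre. A 3-D
   body-centre projection would differ by at most a few pixels for these
   poses; the mask centroid is the choice here because it is exactly
   consistent with the emitted box. Partial fish at frame edges are
   annotated like any others whenever they pass the filters.

Datasets are written as standard COCO JSON (single category `fish`,
sequential annotation ids, float boxes, `iscrowd = 0`) and validated
structurally on read. The whole flow is checked against an independent
brute-force single-pass pixel scan on randomized frames — agreement is
exact, not approximate.

## 4. Dataset design

The mixing design reproduces a ten-model benchmark: a fixed training budget
(700 images) with the virtual share swept through
100:0, 99:1, 98:2, 96:4, 94:6, 92:8, 90:10, 75:25, 50:50 and 0:100.
`mix_counts()` computes `round(total · pct/100)` and conserves the total;
in strict mode, non-integral mixes are refused — every benchmark row is
exactly integral, e.g. 90:10 of 700 is 630 virtual + 70 real. (The
benchmark's published table lists the all-real model with 500 images while
its text describes 700 for every model; the builder takes counts from
explicit configuration and hard-codes neither.)

Splits are 70:20:10 train/validation/test with **validation and test drawn
exclusively from real images** — the constraint that makes the evaluation a
genuine sim-to-real test. Sizes use largest-remainder rounding so they
always sum to the pool; a shortfall of real images is an explicit
infeasibility error stating the deficit, and assignment is a seeded shuffle.

Augmentation is photometric only (2X: each image yields two variants,
appended alongside the original, since the convention's retention behaviour
is unstated — the multiplier and retention are configurable): exposure gain
±25 %, brightness shift ±25 % of full scale, saturation ±25 % about Rec.601
luma, and Gaussian blur whose "±5 %" has no published unit — here
interpreted as a sigma of up to 5 % of (diagonal/100) pixels, about 1.1 px
at 1080p. Because every transform is photometric, bounding boxes carry over
verbatim. Geometric augmentations (flips, rotations) are deliberately out of
scope.

## 5. Evaluation metrics

Single-class detector scoring at an IoU threshold of 0.5:

* **IoU** with continuous box areas $w\cdot h$;
* **matching** by the standard greedy protocol — detections in decreasing
  confidence (ties keep input order), each claiming the unmatched
  ground-truth box of highest IoU above threshold (gt-index ties go low),
  one match per ground truth;
* **AP** as the all-points integral of the precision envelope over recall —
  the modern convention of the evaluation tools this mirrors, rather than
  the older 11-point sample (documented so users comparing against 11-point
  numbers know the difference);
* **F1** as $2pr/(p+r)$. Because reported F1 values in the wild rarely
  state their confidence threshold, `evaluate_detections()` returns the
  full F1-vs-threshold sweep and its maximum, making the operating point
  explicit.

AP and matching are verified against exhaustive small-case enumeration
oracles, including the pixel-counting identity
$\mathrm{IoU}\big((0,0,2,2),(1,0,2,2)\big) = 2/6 = 1/3$.

## 6. What the tests show — and what they do not

The suite (and `scripts/acceptance.R`, which recomputes the same quantities
from scratch) establishes: exact dataset arithmetic for every benchmark
mix; exact oracle equivalence for the rasterizer and annotator; simulator
invariants over ten 2000-step runs (containment, barrier exclusion,
pairwise distance ≥ half the personal-space radius, seeded determinism,
rotation following the vortex sign, vertical spread); the turbidity
visibility ordering on identical scenes; and an end-to-end run in which a
perfect detector echoing the generated ground truth scores AP = 1 and
F1 = 1 (problem sizes: 50 fish, 500 steps, twenty 320 × 180 frames in both
presets — small enough to re-run routinely, large enough to exercise every
path).

None of this demonstrates detector transfer to real imagery. The renders
are flat-shaded, texture-free, undistorted and noise-free; real RAS frames
have body texture, per-fish colour variation, lens distortion, suspended
particles and sensor noise. The virtual frames are training *inputs*, and
the package's mixing machinery exists precisely because virtual-only
training is known to transfer poorly while small real fractions recover
most of the gap. Measuring that transfer requires training an actual
detector on the emitted datasets, which is out of scope here.

Other known limitations: no hydrodynamics or body undulation (fish are
rigid posed meshes); no water-surface refraction or caustics; the vortex
pair is a minimal phenomenological flow model; and the turbidity presets
are qualitative, not radiometrically calibrated.
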