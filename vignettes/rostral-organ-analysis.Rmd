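---
title: "Modelling the coelacanth rostral organ: morphometry and the balanced-sensitivity zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the coelacanth rostral organ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rostralorgan)
```

## The problem

The rostral organ of the living coelacanth is an electrosensory array
reduced to its minimum: a single gel-filled sac in the ethmoid snout,
connected to the surrounding water by three bilateral pairs of tubules
that open via pores on the dorsal snout. An ampullary canal of this
Lorenzinian type measures the voltage drop between its pore and the
common internal reference, so its sensitivity follows the cosine of the
angle between the ambient electric field and the canal axis. Three
pairs cannot triangulate a source the way arrays of hundreds of canals
can; the hypothesis this package operationalises is that the array is
not an imaging device at all but a *trigger*: a coarse detector whose
three directional lobes only agree — with balanced gain — in a small
region of space directly in front of the mouth, the place from which
prey is inhaled during the suction feeding strike.

The analysis chain is: (1) a labelled 3D volume of the six tubules and
the sac; (2) smoothing of each label by truncated spherical-wave
decomposition (SWD); (3) per-tubule morphometry from the second-moment
tensor; (4) a dipole-antenna model of each left/right pair whose
iso-gain surfaces are tori, intersected to locate the balanced zone.
Because no volumetric data accompany the published specimen
measurements, stage (1) is served by a synthetic-anatomy generator with
exact ground truth, and the whole chain is validated by parameter
recovery.

## Anatomical frame and angle conventions

All coordinates use a fixed frame: x along the head–tail axis
(positive anterior), y left–right (positive specimen-left), z
dorsoventral (positive dorsal). A tubule axis is described by its
inclination from the head–tail axis, `alpha_v` in [0°, 180°], and a
rotation `alpha_h` in (−180°, 180°] within the orthogonal (coronal)
plane. The source tables state no sign convention, and their left/right
`alpha_h` signs are conspicuously *not* mirror-symmetric, so a
convention had to be fixed here. We measure `alpha_h` from the dorsal
direction, positive rotating toward specimen-left:

```
v = (cos alpha_v,  sin alpha_v * sin alpha_h,  sin alpha_v * cos alpha_h)
```

This choice was calibrated against the published orientation table: it
renders five of the six tubules anatomically consistent with their
names (both posterior-superior tubules point posterior-dorsal, the
posterior-inferior left tubule points ventral, both anterior tubules
point anterior), which no azimuth-from-lateral alternative achieves.
One row (posterior-inferior right, pointing dorsally) remains
inconsistent under every convention we examined — either a genuine
asymmetry of the preserved specimen or an artefact of the unreported
sign rules. The package uses the table values verbatim as phantom
ground truth and does not attempt to "correct" them.

Two documented discrepancies in the published summary figures are
deliberately left unresolved: recomputing max − min of the printed
`alpha_v` column gives 92.7°, not the stated 91.3°; and the printed
253° spread of `alpha_h` matches the *linear* range (253.51°), while
the circular smallest-covering-arc range is 217.43° (the widest empty
arc lies in the interior, not across the ±180° wrap). `angle_range()`
therefore defaults to the linear definition, with the circular one
available by flag; neither 91.3° nor any corrected value is asserted
anywhere.

## The head phantom

Each tubule is modelled as a capsule — a cylinder with hemispherical
caps — because the tables report only a volume and a length per
tubule. Given the published (volume, length) pair, the radius is solved
so that the end-to-end extent *and* the analytic volume match
simultaneously (`capsule_radius_for()`); the resulting radii are
3.5–4.3 mm. The sac is an ellipsoid with 10:7:6 semi-axes scaled to the
published 1810 mm³ medial-cavity volume. Tubule origins sit on the sac
surface, steered by small per-tubule lateral nudges chosen once so that
the six capsules radiate outward without intersecting (rasterisation
treats any label overlap as an error). Origins, landmarks and the
100–130 mm grid are phantom design choices: the source reports no
coordinates, only lengths, volumes and angles, and those are exactly
the quantities the recovery tests check.

The default voxel size is 1 mm. The nominal scan resolution behind the
published measurements was stated as "290 mm³ voxel resolution", which
is dimensionally inconsistent with its 150 × 150 × 128 mm field of
view; we read it as 0.29 mm isotropic but build phantoms at 1 mm so the
full test suite runs in seconds — the analysis itself is
resolution-independent, and the convergence tests run selected stages
at 0.5 and 0.25 mm.

Segmentation noise is emulated by seeded boundary jitter: each label's
surface voxels may be eroded, and adjacent background voxels dilated,
independently with probability 0.5, displacing the boundary by at most
one voxel. This models rater indecision at the tissue boundary; it does
not model grey-scale partial-volume effects, intensity inhomogeneity,
or spatially correlated rater bias, so recovery under jitter bounds
only the discretisation-plus-boundary-noise error, not every failure
mode of manual segmentation. Phantoms are bit-reproducible under a
fixed seed.

## SWD smoothing

Each label indicator is expanded about its centroid, inside its
bounding sphere of radius R, in real orthonormal spherical harmonics
times spherical Bessel radial functions `j_l(z_ln r / R)`, where `z_ln`
is the n-th positive zero of `j_l` — a Dirichlet basis vanishing on the
sphere, the simplest self-adjoint radial boundary choice. Truncation at
`L = N` of 5 or 7 (both exposed, neither privileged; 7 is the package
default) yields the band-limited smoothed field used for the inertia
tensor. Real harmonics are used rather than complex ones because the
field is real; the coefficient container is indexed by (l, m, n) either
way.

Coefficients are computed by least squares on the voxel grid (a Gram
matrix solve) rather than by naive quadrature projection. This has two
consequences worth stating: the discrete operator is an *exact*
projection, so decompose–reconstruct–decompose reproduces the
coefficients to solver precision (the idempotence tests use 1e−6
relative); and no resampling to spherical quadrature grids is needed.
An indicator function is not band-limited, so its truncated expansion
necessarily rings; the smoothed field is clamped at zero before moments
are formed so the weights stay non-negative. The justification for
smoothing at all is checked, not assumed: on noiseless capsules the
principal axis of the smoothed field agrees with the raw-mask axis to
within 1°.

## Morphometry

The inertia tensor is implemented as the intensity-weighted
second-moment matrix about the centroid,
`M_jk = Σ w(x)(x_j − c_j)(x_k − c_k) / Σ w`, and the elongation axis is
its largest-eigenvalue eigenvector. (The classical rotational inertia
tensor `tr(M) I − M` has the same eigenvectors in reverse eigenvalue
order; the tests verify both readings give the identical axis, and that
eigen- and singular-value decompositions of the symmetric tensor
agree.) A relative spectral gap below 1e−9 between the two leading
eigenvalues raises an error advising that the label is not tubular — a
grid-centred rasterised ball is exactly degenerate by symmetry.

The eigenvector sign is fixed anatomically: the axis is oriented from
the end nearest the sac centroid (proximal) toward the pore end
(distal). Tubule length is the extent of the voxel-centre projections
onto the axis plus one voxel (the two boundary half-voxels); this
definition reproduces capsule extents to within one voxel and the
published lengths to within 5% on Table-parameterised phantoms.
Left/right pair summaries use the n−1 sample SD, which for a pair is
`|L − R|/√2` — this convention reproduces every published mean ± SD
cell to printed precision, which is how it was identified.

## The antenna model

Each pair of tubules is treated as one "rabbit ears" dipole receiver.
Two axis strategies are implemented. The *bisector* (normalised sum of
the two oriented tubule axes) follows the intuition that the pair
points where its arms point; it is the `pair_dipole()` default. The
*baseline* (unit vector between the two distal pore ends) is the
physical effective dipole moment of a two-arm V receiver: the response
of oppositely-fed arms is governed by the vector *difference* of the
arm vectors, i.e. the tip-to-tip line. For near-parallel arms like the
anterior pair the two strategies are nearly orthogonal (≈73° apart on
the default phantom), so the choice matters. The pipeline defaults to
the baseline: it is the physically grounded reading, and it is the one
that reproduces the published geometric picture — three tori encircling
the dorsal and lateral snout whose mutual overlap sits in front of the
mouth. Both strategies remain available for comparison.

The gain pattern is the canonical short-dipole power pattern
`g = sin²θ / r²`: maximal broadside, zero along the axis, rotationally
symmetric, consistent with cosine canal sensitivity. Its superlevel
sets are exactly horn tori (hole radius 0, tube radius `1/(2√c)`), and
the torus-fitting cross-check recovers precisely that from extracted
iso-surface points. The published construction, however, is geometric:
one *ring* torus per pair with shared hole radius `a` and tube radius
`b`, representing a thickened iso-gain shell (the band of space within
an accepted gain tolerance of the target level). The geometric
construction is primary here too; the analytic pattern serves as a
cross-check and for topology oracles.

Neither `a`, `b`, nor the plotted gain level was published. The only
quantitative anchor is behavioural: feeding strikes begin with prey
10–20 cm in front of the snout. The defaults `a = 110 mm`, `b = 26 mm`
were calibrated once against that constraint on the default phantom:
they produce a single compact overlap whose centroid lies ~106 mm in
front of the snout tip, inside the strike band. Its off-midline
position (~60 mm right, slightly ventral) is inherited directly from
the non-mirrored published angles, not imposed.

Two modelling details deserve emphasis:

* **Exterior clipping.** The pure intersection of three ring tori also
  contains a second, antipodal lobe located behind the array — inside
  the animal's own head, where there is no water to sense. The
  pipeline therefore clips the balanced region to the half-space
  anterior of the forwardmost antenna centre. `overlap_region()`
  itself defaults to the pure unclipped intersection (and all
  order-invariance and monotonicity properties are tested on it); the
  clip is an explicit, optional argument.
* **Gain sweep by nested tori.** Raising the accepted gain band with a
  fixed antenna geometry corresponds to fattening the shell around the
  same core ring: `b → s·b` with the major radius `R = a + b` held
  fixed. Tori of larger scale then *contain* those of smaller scale,
  so the overlap volume is non-decreasing by genuine set inclusion,
  and the zone grows in place (observed centroid drift ≲ 12% of the
  equivalent-sphere radius across a 0.5–2× sweep). Scaling `a` and `b`
  jointly instead would translate the hole outward and is *not*
  monotone — a superficially natural parameterisation that breaks the
  very property the sweep is meant to demonstrate.

## Numerical choices

* Overlap and torus voxelisations use point-in-solid tests on voxel
  centres (default 2 mm grid over the tori's joint bounding box,
  processed in slabs); voxelised torus volumes converge to `2π²Rb²`
  (≤0.1% at 1 mm for the test torus).
* Iso-surface points are located on grid edges and polished by
  bisection, so every returned point satisfies `|g − c|` to near
  machine precision; torus cross-sections are fitted by the algebraic
  (Kasa) circle fit in cylindrical coordinates.
* Topology is checked via the exact Euler characteristic of the
  cubical cell complex (solid) and of the boundary quad mesh (surface:
  `V − E + F`, equal to twice the solid's characteristic for
  handlebodies); a solid torus gives 0, a ball 1. Mesh extraction and
  PLY export use the boundary-quad representation throughout.
* Near the dipole centre the point-dipole pattern is unphysical and
  its horn-torus pinch is unresolvable on any grid, so iso-surface
  extraction and topology checks exclude a near-field ball of radius
  `2√(h·b)` (h the grid spacing) — large enough to keep the central
  channel open, small relative to the torus.
* Problem sizes in the shipped tests: 1 mm phantoms on ~130³ grids,
  SWD at L = N ≤ 7 on ~30³ crops, 10⁶-point membership oracles, 20
  jitter realisations per tubule; the full suite runs in about half a
  minute, the acceptance script in ~15 s.

## What passing tests do and do not show

The phantom validates the *computational* chain: rasterisation →
smoothing → tensor → angles recovers known ground truth within 2°
(noiseless) and 4° (one-voxel boundary jitter), volumes and lengths
within 5%. It does not validate the segmentation of real MRI data
(no grey-scale model, no rater model), and the published
specimen-derived numbers are used only as generator inputs — they are
not independently recomputable without the original scan. The antenna
model is a geometric abstraction: no conductivity, no body boundary
effects, no near-field electrostatics, no neural integration. Its
claims — toroidal iso-gain geometry, a single balanced region in front
of the mouth, growth-in-place under gain widening, strike-range
consistency — are exactly the ones the acceptance tests measure.
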