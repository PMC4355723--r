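# rostralorgan

Morphometry and dipole-antenna modelling of paired electrosensory canal
arrays, built around the rostral organ of the extant coelacanth
*Latimeria chalumnae*.

Most electrosensitive fishes carry hundreds of ampullary canals spread
over the head, enough to encode the direction and polarity of a nearby
bioelectric source. The coelacanth's rostral organ is the extreme
opposite: a single gel-filled sac in the snout connected to the water by
just three pairs of tubules. With so few sensors the array cannot image
its surroundings — so what is it for? This package implements, as tested
and reusable code, an analysis chain that answers that question
geometrically:

1. **Synthetic anatomy** — labelled 3D head phantoms (NIfTI label maps)
   whose six tubule capsules carry known volumes, lengths and
   orientation angles, so every downstream stage can be validated by
   parameter recovery. The default phantom is parameterised by the
   published specimen measurements (volumes 1370/1337, 1405/1331,
   1629/1650 mm³; medial cavity 1810 mm³; the published inclination and
   rotation angles).
2. **Spherical-wave-decomposition smoothing** — each label is expanded
   in real spherical harmonics × spherical Bessel radial functions
   `j_l(z_ln r / R)` and truncated at `L = N` (5 or 7), yielding a
   band-limited smoothed field.
3. **Morphometry** — volumes by voxel counting; the second-moment
   (inertia) tensor `M_jk = Σ w(x)(x_j − c_j)(x_k − c_k)`; the principal
   axis as its leading eigenvector, oriented from the sac toward the
   pore; inclination `α^v = arccos(v_x)` and rotation
   `α^h = atan2(v_y, v_z)`; paired left/right summaries
   (mean, n−1 SD = |L−R|/√2).
4. **Antenna model** — each left/right pair acts as one "rabbit ears"
   dipole with the short-dipole gain pattern `g = sin²θ / r²`, whose
   iso-gain surfaces are tori about the dipole axis. One equal ring
   torus per pair is intersected to find the region where all three
   detectors respond with balanced gain — the predicted detection zone —
   together with its volume, centroid, equivalent-sphere radius and
   distance to the mouth/snout landmarks, plus a gain-band sweep and a
   behavioural strike-range check (feeding strikes start 10–20 cm in
   front of the snout).

## Worked example

```r
library(rostralorgan)

res <- run_pipeline(pipeline_config())
print(res)
#> pipeline_result
#>   6 tubule records, 3 antennas
#> overlap_region: 9688 mm^3 (1211 voxels at 2 mm), centroid (169.2, -6.3, -6.3) mm
#>   equivalent sphere radius 13.2 mm, 102.9 mm from the mouth landmark

res$strike$distance      # 105.7 mm in front of the snout -> within the
res$strike$in_range      # TRUE: 100-200 mm behavioural strike band

res$sweep[, c("scale", "volume", "centroid_drift")]
#>   scale volume centroid_drift
#> 1   0.5      0             NA
#> 2   1.0   9688             NA
#> 3   1.5 156912       4.161485
#> 4   2.0 552768       3.911485
```

Reading the output: the six tubule records recover the phantom's ground
truth (angles within ~1.2°, volumes within ~0.8%); the three ring tori
intersect in a single compact region centred ~170 mm anterior of the
snout tip, i.e. directly in the space in front of the mouth where
feeding strikes are launched; and widening the accepted gain band grows
that region monotonically (volume column) while its centroid barely
moves (drift of ~4 mm against an equivalent-sphere radius of 34–51 mm).

A command-line wrapper with the same defaults lives at
`inst/scripts/run_pipeline.R` and writes the report tables
(`dimensions.csv`, `orientations.csv`), the overlap summary
(`overlap.json`, `sweep.csv`), PLY meshes of the tori and overlap
region, and a full parameter log.

## Package layout

- `R/` — phantom generator, NIfTI I/O, SWD smoothing, morphometry,
  antenna/torus model, pipeline.
- `tests/testthat/` — unit, property and end-to-end acceptance tests
  (all fixtures are generated in code).
- `vignettes/rostral-organ-analysis.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical tolerances and limitations.
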