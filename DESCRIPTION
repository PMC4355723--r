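Package: rostralorgan
Title: Morphometry and Dipole-Antenna Modelling of Paired Electrosensory
    Canal Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing labelled 3D volumes of tubular
    electrosensory canal arrays such as the coelacanth rostral organ.
    Generates synthetic labelled head phantoms with known ground truth,
    smooths label fields by truncated spherical-wave decomposition
    (spherical harmonics times spherical Bessel radial functions),
    extracts per-tubule morphometry (volume, length, inertia-tensor
    principal axis, inclination and rotation angles), and models each
    left/right tubule pair as a short-dipole "rabbit ears" antenna whose
    iso-gain surfaces are ring tori.  The intersection of the three tori
    localises the region of balanced electrosensitivity in front of the
    mouth, and a gain sweep characterises how that region grows with
    detection threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
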