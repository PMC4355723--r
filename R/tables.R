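#' Published rostral-organ reference dimensions
#'
#' Structure volumes and lengths reported for the rostral organ of a
#' preserved 950 mm adult \emph{Latimeria chalumnae} (specimen SIO 75-347),
#' measured from segmented MRI data. These printed values are the inputs
#' that parameterise the default head phantom: the specimen itself is not
#' recomputable, so they serve as ground truth for the synthetic generator,
#' not as measurement targets.
#'
#' @return `data.frame` with columns `structure`, `side` (`"L"`, `"R"` or
#'   `NA`), `volume` (mm^3) and `length` (mm; `NA` for the medial cavity).
#' @seealso [reference_orientations()], [latimeria_phantom_spec()]
#' @export
reference_dimensions <- function() {
  data.frame(
    structure = rep(c("anterior", "posterior_inferior",
                      "posterior_superior"), each = 2L),
    side   = rep(c("L", "R"), 3L),
    volume = c(1370, 1337, 1405, 1331, 1629, 1650),
    length = c(34.38, 35.94, 39.15, 37.43, 31.24, 33.13))
}

#' Published medial-cavity (rostral sac) volume, mm^3
#' @return Scalar volume in mm^3.
#' @export
reference_sac_volume <- function() 1810

#' Published rostral-organ tubule orientations
#'
#' Inclination (`alpha_v`) and rotation (`alpha_h`) angles of the six
#' tubule principal axes for the same specimen as
#' [reference_dimensions()]. Interpreted under the package axis convention
#' (see [axis_convention()]); the source does not state its sign
#' convention and the left/right sign pattern is not mirror-symmetric, so
#' these are used verbatim as phantom ground truth.
#'
#' @return `data.frame` with columns `structure`, `side`, `alpha_v`,
#'   `alpha_h` (degrees).
#' @export
reference_orientations <- function() {
  data.frame(
    structure = rep(c("anterior", "posterior_inferior",
                      "posterior_superior"), each = 2L),
    side    = rep(c("L", "R"), 3L),
    alpha_v = c(40.05, 41.42, 113.77, 125.81, 111.88, 132.75),
    alpha_h = c(-100.68, -100.29, 152.83, -55.88, 10.26, -2.63))
}
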