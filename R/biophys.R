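#' Infinite-cylinder vessel model
#'
#' Describes a single blood vessel as an infinitely long cylinder of radius
#' `radius` whose axis makes an angle `theta` with the main magnetic field
#' B0, with a bulk susceptibility difference `delta_chi` between the blood
#' it carries and the surrounding tissue. This is the standard static
#' dephasing model for the extravascular field around a vein.
#'
#' @param radius Vessel radius in micrometres. Must be positive.
#' @param delta_chi Blood--tissue susceptibility difference in ppm
#'   (non-negative).
#' @param theta Angle between the vessel axis and B0, in degrees, in
#'   \[0, 90\]. 90 degrees (perpendicular) maximises the extravascular field.
#' @param b0 Main field strength in Tesla (positive). The field offset is
#'   expressed in ppm of B0, so `b0` does not enter the ppm-scale result;
#'   it is retained so absolute offsets (in Tesla or Hz) can be derived.
#'
#' @return An object of class `vessel_model`.
#' @examples
#' vessel_model(radius = 32.5, delta_chi = 1.0, theta = 90)
#' @export
vessel_model <- function(radius, delta_chi, theta = 90, b0 = 7) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(delta_chi), length(delta_chi) == 1L, is.finite(delta_chi),
            is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(b0), length(b0) == 1L, is.finite(b0))
  if (radius <= 0) stop("'radius' must be > 0 (micrometres)")
  if (delta_chi < 0) stop("'delta_chi' must be >= 0 (ppm)")
  if (theta < 0 || theta > 90) stop("'theta' must be in [0, 90] degrees")
  if (b0 <= 0) stop("'b0' must be > 0 (Tesla)")
  structure(list(radius = radius, delta_chi = delta_chi,
                 theta = theta, b0 = b0),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  cat(sprintf(
    "Infinite-cylinder vessel: R = %g um, delta-chi = %g ppm, theta = %g deg, B0 = %g T\n",
    x$radius, x$delta_chi, x$theta, x$b0))
  invisible(x)
}

#' Blood magnetic properties
#'
#' Holds the haematocrit and oxygen saturation of venous blood together
#' with the susceptibility difference between fully deoxygenated and fully
#' oxygenated red cells, from which the whole-blood-to-tissue
#' susceptibility difference is derived (see
#' [blood_tissue_susceptibility()]).
#'
#' @param hct Haematocrit, volume fraction of red cells in \[0, 1\].
#' @param y Venous oxygen saturation in \[0, 1\].
#' @param delta_chi_do Susceptibility difference between fully
#'   deoxygenated and fully oxygenated blood, in ppm. The commonly used
#'   cgs-convention value is 0.264 ppm.
#' @param convention Unit convention for the susceptibility value, either
#'   `"cgs"` or `"rationalised-SI"`. SI susceptibilities are 4*pi times the
#'   cgs values, and the conversion is applied by
#'   [blood_tissue_susceptibility()] when the SI convention is requested.
#'
#' @return An object of class `blood_properties`.
#' @examples
#' blood_properties(hct = 0.4, y = 0.6)
#' @export
blood_properties <- function(hct, y, delta_chi_do = 0.264,
                             convention = c("cgs", "rationalised-SI")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(hct), length(hct) == 1L,
            is.numeric(y), length(y) == 1L,
            is.numeric(delta_chi_do), length(delta_chi_do) == 1L)
  if (hct < 0 || hct > 1) stop("'hct' must be a fraction in [0, 1]")
  if (y < 0 || y > 1) stop("'y' must be a fraction in [0, 1]")
  if (delta_chi_do <= 0) stop("'delta_chi_do' must be > 0 (ppm)")
  structure(list(hct = hct, y = y, delta_chi_do = delta_chi_do,
                 convention = convention),
            class = "blood_properties")
}

#' Whole-blood to tissue susceptibility difference
#'
#' Computes `Hct * (1 - Y) * delta_chi_do`, the susceptibility difference
#' between partially deoxygenated whole blood and surrounding tissue,
#' assuming the tissue matches fully oxygenated blood. Under the
#' rationalised-SI convention the cgs-scale `delta_chi_do` is multiplied
#' by 4*pi.
#'
#' @param blood A [blood_properties()] object.
#' @return Susceptibility difference in ppm (scalar).
#' @examples
#' # fully deoxygenated pure red cells, cgs scale
#' blood_tissue_susceptibility(blood_properties(1, 0, 0.264))
#' @export
blood_tissue_susceptibility <- function(blood) {
  stopifnot(inherits(blood, "blood_properties"))
  scale <- if (blood$convention == "rationalised-SI") 4 * pi else 1
  blood$hct * (1 - blood$y) * blood$delta_chi_do * scale
}

#' Extravascular field offset of a cylindrical vessel
#'
#' Field perturbation, in ppm of B0, at radial distance `r` from the
#' vessel axis and azimuth `phi` (measured in the plane perpendicular to
#' the vessel, from the projection of B0). Outside the vessel
#' (`r >= radius`) the offset is
#' `delta_chi/2 * (R/r)^2 * cos(2*phi) * sin(theta)^2`; inside it is the
#' uniform `delta_chi/6 * (3*cos(theta)^2 - 1)`.
#'
#' @param vessel A [vessel_model()].
#' @param r Radial distance(s) from the vessel axis, micrometres
#'   (non-negative; vectorised).
#' @param phi Azimuthal angle in degrees (scalar or same length as `r`).
#'   `phi = 0` maximises the outside field.
#' @return Field offset(s) in ppm.
#' @examples
#' v <- vessel_model(32.5, 1.0, 90)
#' field_offset(v, r = c(32.5, 65), phi = 0)
#' @export
field_offset <- function(vessel, r, phi = 0) {
  stopifnot(inherits(vessel, "vessel_model"), is.numeric(r), is.numeric(phi))
  if (any(r < 0)) stop("radial distance 'r' must be >= 0")
  theta <- vessel$theta * pi / 180
  phi_r <- phi * pi / 180
  outside <- vessel$delta_chi / 2 * (vessel$radius / r)^2 *
    cos(2 * phi_r) * sin(theta)^2
  inside <- vessel$delta_chi / 6 * (3 * cos(theta)^2 - 1)
  ifelse(r >= vessel$radius, outside, inside)
}

#' Distance at which the extravascular field falls to a threshold
#'
#' Inverts the outside-field expression along the azimuth that maximises
#' it (`phi = 0`) to find the radius `r*` where the field magnitude first
#' equals `threshold`:
#' `r* = R * sqrt(delta_chi * sin(theta)^2 / (2 * threshold))`.
#' The returned distance is measured from the vessel *wall* and reported
#' in mm. If the field never exceeds the threshold (wall value at or below
#' it) the distance is 0 and `exceeded` is `FALSE`.
#'
#' @param vessel A [vessel_model()].
#' @param threshold Field magnitude in ppm (> 0) regarded as negligible.
#' @param digits Decimals of mm used for the rounded report (default 2).
#' @return A list of class `threshold_distance` with elements
#'   `distance_mm` (rounded), `distance_mm_exact`, `radius_um` (`r*`),
#'   `exceeded`, `threshold` and the vessel.
#' @examples
#' threshold_distance(vessel_model(32.5, 1.0, 90), threshold = 0.02)
#' @export
threshold_distance <- function(vessel, threshold, digits = 2L) {
  stopifnot(inherits(vessel, "vessel_model"),
            is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0) stop("'threshold' must be > 0 (ppm)")
  theta <- vessel$theta * pi / 180
  wall <- vessel$delta_chi / 2 * sin(theta)^2   # |offset| at r = R, phi = 0
  if (wall <= threshold) {
    out <- list(distance_mm = 0, distance_mm_exact = 0,
                radius_um = vessel$radius, exceeded = FALSE,
                threshold = threshold, vessel = vessel)
    class(out) <- "threshold_distance"
    return(out)
  }
  r_star <- vessel$radius * sqrt(vessel$delta_chi * sin(theta)^2 / (2 * threshold))
  d_mm <- (r_star - vessel$radius) / 1000
  out <- list(distance_mm = round(d_mm, digits), distance_mm_exact = d_mm,
              radius_um = r_star, exceeded = TRUE,
              threshold = threshold, vessel = vessel)
  class(out) <- "threshold_distance"
  out
}

#' @export
print.threshold_distance <- function(x, ...) {
  if (x$exceeded) {
    cat(sprintf("Field falls to %g ppm at %s mm from the vessel wall (exact %.4f mm)\n",
                x$threshold, format(x$distance_mm), x$distance_mm_exact))
  } else {
    cat(sprintf("Field never exceeds %g ppm; distance reported as 0 mm\n",
                x$threshold))
  }
  invisible(x)
}

#' Radial field profiles for a set of vessels
#'
#' Evaluates the extravascular field along the perpendicular from the
#' vessel wall at the maximising azimuth (`phi = 0`), on a distance grid
#' starting at the wall (distance 0 = wall).
#'
#' @param vessels A list of [vessel_model()] objects (an empty list yields
#'   an empty result).
#' @param max_distance Maximum distance from the wall, mm (> 0, or 0 for
#'   the degenerate single-point grid at the wall).
#' @param step Grid step in mm (> 0).
#' @param phi Azimuth in degrees at which profiles are evaluated.
#' @return A list of `field_profile` objects, each a list with
#'   `distances` (mm from wall), `offsets` (ppm), `phi` and `vessel`.
#' @examples
#' sweep_profiles(list(vessel_model(32.5, 0.5), vessel_model(32.5, 1.0)),
#'                max_distance = 0.5, step = 0.01)
#' @export
sweep_profiles <- function(vessels, max_distance = 0.5, step = 0.005, phi = 0) {
  stopifnot(is.list(vessels))
  if (length(vessels) == 0L) return(list())
  if (max_distance < 0) stop("'max_distance' must be >= 0 (mm)")
  if (step <= 0) stop("'step' must be > 0 (mm)")
  lapply(vessels, function(v) {
    stopifnot(inherits(v, "vessel_model"))
    d <- seq(0, max_distance, by = step)
    if (length(d) == 0L) d <- 0
    r <- v$radius + d * 1000
    structure(list(distances = d,
                   offsets = field_offset(v, r, phi = phi),
                   phi = phi, vessel = v),
              class = "field_profile")
  })
}
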