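#' Photon sources
#'
#' Four source geometries are supported. External sources (launch point on
#' the tissue surface, z = 0) are subject to specular reflection at the
#' air/tissue interface: under discrete or continuous absorption weighting
#' the photon starts with weight `1 - R_F` (Fresnel reflectance at the
#' launch angle) and the specular fraction is accounted separately; under
#' analog weighting a Bernoulli split terminates the photon as specular with
#' probability `R_F` so analog photons always carry weight exactly 1.
#' Internal sources (z > 0) launch with weight 1 and no specular loss.
#'
#' * `source_directional_point()`: pencil beam from a point.
#' * `source_isotropic_point()`: interstitial point source emitting
#'   uniformly over the full sphere.
#' * `source_directional_circular()`: surface beam over an annulus
#'   (`Flat` profile uniform over area, `Gaussian` profile with 1/e^2
#'   radius `beam_radius`, truncated to the annulus by rejection), optionally
#'   converging: the launch direction tilts linearly toward the beam axis
#'   from 0 on-axis to `convergence_angle` at the rim.
#' * `source_custom_point()`: point source emitting uniformly in solid angle
#'   within given polar/azimuthal ranges about a principal direction.
#'
#' @param position Length-3 launch point (mm); surface sources must sit at
#'   z = 0.
#' @param direction Length-3 direction (normalized internally).
#' @param initial_region Optional region index the photon starts in;
#'   computed from `position` when omitted.
#' @return An object of class `mc_source`.
#' @name sources
NULL

new_source <- function(type, fields) {
  structure(c(list(type = type), fields), class = "mc_source")
}

unitize <- function(v, what = "direction") {
  v <- as.numeric(v)
  if (length(v) != 3L || anyNA(v)) abort(sprintf("`%s` must be length 3", what))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) abort(sprintf("`%s` must be non-zero", what))
  v / nrm
}

#' @rdname sources
#' @export
source_directional_point <- function(position = c(0, 0, 0),
                                     direction = c(0, 0, 1),
                                     initial_region = NULL) {
  position <- as.numeric(position)
  direction <- unitize(direction)
  if (position[3] < 0) abort("launch point must not be above the surface")
  if (position[3] == 0 && direction[3] <= 0) {
    abort("an external launch must point into the tissue (uz > 0)")
  }
  new_source("DirectionalPoint", list(
    position = position, direction = direction,
    initial_region = initial_region
  ))
}

#' @rdname sources
#' @export
source_isotropic_point <- function(position, initial_region = NULL) {
  position <- as.numeric(position)
  if (position[3] <= 0) {
    abort("IsotropicPoint is internal-only: the location must be inside the tissue (z > 0)")
  }
  new_source("IsotropicPoint", list(
    position = position, initial_region = initial_region
  ))
}

#' @rdname sources
#' @param outer_radius,inner_radius Annulus radii (mm),
#'   `inner_radius < outer_radius`.
#' @param profile `"Flat"` or `"Gaussian"`.
#' @param beam_radius 1/e^2 intensity radius of the Gaussian profile (mm).
#' @param convergence_angle Convergence half-angle at the rim (radians,
#'   in \[0, pi/2); 0 = collimated).
#' @export
source_directional_circular <- function(position = c(0, 0, 0),
                                        outer_radius,
                                        inner_radius = 0,
                                        profile = c("Flat", "Gaussian"),
                                        beam_radius = NULL,
                                        convergence_angle = 0,
                                        initial_region = NULL) {
  profile <- match.arg(profile)
  position <- as.numeric(position)
  if (position[3] != 0) abort("DirectionalCircular launches from the surface (z = 0)")
  if (!is.numeric(outer_radius) || outer_radius <= 0) {
    abort("`outer_radius` must be positive")
  }
  if (inner_radius < 0 || inner_radius >= outer_radius) {
    abort("need 0 <= inner_radius < outer_radius")
  }
  if (convergence_angle < 0 || convergence_angle >= pi / 2) {
    abort("`convergence_angle` must be in [0, pi/2)")
  }
  if (profile == "Gaussian" && is.null(beam_radius)) {
    abort("a Gaussian profile needs `beam_radius` (1/e^2 radius)")
  }
  new_source("DirectionalCircular", list(
    position = position,
    outer_radius = outer_radius, inner_radius = inner_radius,
    profile = profile, beam_radius = beam_radius %||% outer_radius,
    convergence_angle = convergence_angle,
    initial_region = initial_region
  ))
}

#' @rdname sources
#' @param polar_range,azimuthal_range Emission angle intervals (radians),
#'   within \[0, pi\] and \[0, 2 pi\] respectively, about `direction`.
#' @export
source_custom_point <- function(position = c(0, 0, 0),
                                direction = c(0, 0, 1),
                                polar_range = c(0, pi / 2),
                                azimuthal_range = c(0, 2 * pi),
                                initial_region = NULL) {
  position <- as.numeric(position)
  direction <- unitize(direction)
  polar_range <- as.numeric(polar_range)
  azimuthal_range <- as.numeric(azimuthal_range)
  if (position[3] < 0) abort("launch point must not be above the surface")
  if (length(polar_range) != 2L || any(polar_range < 0) ||
      any(polar_range > pi) || diff(polar_range) < 0) {
    abort("`polar_range` must be an increasing interval within [0, pi]")
  }
  if (length(azimuthal_range) != 2L || any(azimuthal_range < 0) ||
      any(azimuthal_range > 2 * pi) || diff(azimuthal_range) < 0) {
    abort("`azimuthal_range` must be an increasing interval within [0, 2*pi]")
  }
  new_source("CustomPoint", list(
    position = position, direction = direction,
    polar_range = polar_range, azimuthal_range = azimuthal_range,
    initial_region = initial_region
  ))
}

#' @export
print.mc_source <- function(x, ...) {
  cat(sprintf("<source: %s> at (%g, %g, %g)\n", x$type,
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

#' Sample photon launches
#'
#' Draws initial photon states from a source placed on a tissue, including
#' the specular bookkeeping applied at external launches. Mostly useful for
#' inspecting or testing a source definition; [run_simulation()] launches
#' photons internally.
#'
#' @param source An `mc_source`.
#' @param tissue An `mc_tissue`.
#' @param n Number of launches to draw.
#' @param seed RNG seed for the draw.
#' @param absorption_weighting Weighting scheme, affects the specular rule
#'   (`"Analog"` uses the Bernoulli split).
#' @return A tibble with position, direction, `weight`, `specular` (weight
#'   fraction lost to specular reflection), `region` and `dead` (analog
#'   photon terminated as specular at launch).
#' @examples
#' tis <- tissue_model(data.frame(thickness = 5, mua = 0.1, mus = 10,
#'                                g = 0.9, n = 1.4))
#' sample_launch(source_directional_point(), tis, n = 3)
#' @export
sample_launch <- function(source, tissue, n = 1, seed = 1,
                          absorption_weighting = c("Discrete", "Continuous",
                                                   "Analog")) {
  stopifnot(inherits(source, "mc_source"), inherits(tissue, "mc_tissue"))
  absorption_weighting <- match.arg(absorption_weighting)
  mode <- match(absorption_weighting, c("Analog", "Discrete", "Continuous")) - 1L
  m <- sample_launch_cpp(source_cfg(source), tissue_cfg(tissue),
                         as.integer(n), as.integer(seed), mode)
  out <- as_tibble(as.data.frame(m))
  out$region <- as.integer(out$region)
  out$dead <- out$dead > 0
  out
}

source_cfg <- function(source) {
  unclass(source)
}
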