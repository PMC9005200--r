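#' Transport kernels
#'
#' The elementary sampling and boundary-physics rules used by the random
#' walk, exposed for inspection and testing. [run_simulation()] executes
#' the same kernels inside the compiled engine loop.
#'
#' @name kernels
NULL

#' Sample an intercollision step length
#'
#' Step lengths follow `mut * exp(-mut * s)` under analog and discrete
#' absorption weighting and `mus * exp(-mus * s)` under continuous
#' weighting, i.e. `s = -log(u) / coefficient`. A zero coefficient yields an
#' infinite step (the photon travels ballistically to the next boundary).
#'
#' @param properties An [optical_properties()] object.
#' @param absorption_weighting Weighting scheme (decides the coefficient).
#' @param u Uniform(0,1) draws; defaults to fresh random numbers.
#' @return Step lengths in mm, one per element of `u`.
#' @examples
#' sample_step(optical_properties(1, 1, 0, 1), "Discrete", u = exp(-1))
#' @export
sample_step <- function(properties,
                        absorption_weighting = c("Discrete", "Continuous",
                                                 "Analog"),
                        u = runif(1)) {
  absorption_weighting <- match.arg(absorption_weighting)
  stopifnot(inherits(properties, "mc_ops"))
  coeff <- if (absorption_weighting == "Continuous") {
    properties$mus
  } else {
    properties$mua + properties$mus
  }
  if (any(u <= 0 | u >= 1)) abort("`u` must lie strictly in (0, 1)")
  if (coeff <= 0) return(rep(Inf, length(u)))
  -log(u) / coeff
}

#' Sample Henyey-Greenstein scattering angles
#'
#' Inverts the Henyey-Greenstein CDF for the polar deflection cosine;
#' azimuth is uniform on (0, 2*pi). `E[cos(theta)] = g`.
#'
#' @param g Anisotropy, in (-1, 1).
#' @param n Number of draws.
#' @param u,u_phi Uniform draws for polar and azimuthal sampling.
#' @return A tibble with `cos_theta` and `phi`.
#' @export
scatter_hg <- function(g, n = 1, u = runif(n), u_phi = runif(n)) {
  if (abs(g) >= 1) abort("`g` must lie in (-1, 1) for Henyey-Greenstein")
  tibble(cos_theta = hg_cos_cpp(g, u), phi = 2 * pi * u_phi)
}

#' Bidirectional scattering for 1D slab problems
#'
#' The photon continues forward with probability `(1+g)/2` and reverses with
#' probability `(1-g)/2`.
#'
#' @param g Anisotropy in \[-1, 1\].
#' @param uz Current axial direction, +1 or -1 per element.
#' @param u Uniform draws.
#' @return New axial directions.
#' @export
scatter_bidirectional <- function(g, uz, u = runif(length(uz))) {
  if (!all(uz %in% c(-1, 1))) {
    abort("bidirectional scattering requires axial travel (uz = +/-1)")
  }
  ifelse(u < (1 - g) / 2, -uz, uz)
}

#' Rotate a direction by scattering angles
#'
#' Local-frame rotation of a unit vector by polar angle `acos(cos_theta)`
#' and azimuth `phi`, with the standard degenerate-pole branch when the
#' direction is within 1e-12 of +/-z.
#'
#' @param direction Length-3 unit vector.
#' @param cos_theta Cosine of the deflection angle.
#' @param phi Azimuthal angle (radians).
#' @return The rotated unit direction.
#' @export
update_direction <- function(direction, cos_theta, phi) {
  direction <- as.numeric(direction)
  if (abs(sum(direction^2) - 1) > 1e-9) {
    abort("`direction` must be a unit vector")
  }
  rotate_direction_cpp(direction, cos_theta, phi)
}

#' Unpolarized Fresnel reflection probability
#'
#' Average of the s- and p-polarized Fresnel reflectances with Snell
#' refraction; returns 1 under total internal reflection. At normal
#' incidence this is `((n1 - n2) / (n1 + n2))^2`.
#'
#' @param n1,n2 Refractive indices on the incident and far side.
#' @param cos_incident Cosine of the incidence angle, in (0, 1].
#' @return Reflection probability in \[0, 1\].
#' @examples
#' fresnel(1.0, 1.3, 1)  # normal incidence onto skin-like tissue
#' @export
fresnel <- function(n1, n2, cos_incident) {
  if (any(cos_incident <= 0) || any(cos_incident > 1)) {
    abort("`cos_incident` must lie in (0, 1]")
  }
  vapply(cos_incident, function(ci) fresnel_cpp(n1, n2, ci), numeric(1))
}

#' Russian roulette
#'
#' Once a photon's weight falls below `threshold` it survives with
#' probability `p_survive` (weight amplified by `1/p_survive`) or is killed.
#' The game is a fair one: the expected weight is unchanged, so the
#' estimator stays unbiased. A zero threshold disables the game.
#'
#' @param weight Photon weights.
#' @param threshold Weight threshold invoking the roulette.
#' @param p_survive Survival probability P.
#' @param u Uniform draws.
#' @return A tibble with the updated `weight` and a logical `killed`.
#' @export
russian_roulette <- function(weight, threshold, p_survive = 0.1,
                             u = runif(length(weight))) {
  if (p_survive <= 0 || p_survive >= 1) abort("`p_survive` must be in (0, 1)")
  play <- threshold > 0 & weight < threshold
  survive <- !play | u < p_survive
  tibble(
    weight = ifelse(play & survive, weight / p_survive,
                    ifelse(play, 0, weight)),
    killed = play & !survive
  )
}

#' Advance the photon clock
#'
#' Time of flight over a path of length `length` mm in a medium of
#' refractive index `n`: `dt = length * n / c`, with
#' c = 299.792458 mm/ns.
#'
#' @param time Elapsed time (ns).
#' @param length Path length (mm), >= 0.
#' @param n Refractive index of the traversed medium.
#' @return Updated time (ns).
#' @export
advance_time <- function(time, length, n) {
  if (any(length < 0)) abort("`length` must be >= 0")
  time + length * n / .c_mm_ns
}

#' Two-flux closed form for the bidirectional 1D slab
#'
#' Analytic diffuse reflectance and transmittance of a refractive-index
#' matched slab under bidirectional scattering: with backscattering rate
#' `sigma_b = mus * (1 - g) / 2`, `alpha = mua + sigma_b` and
#' `kappa = sqrt(mua * (mua + 2 * sigma_b))`,
#' \deqn{R = \sigma_b \sinh(\kappa d) / (\kappa \cosh(\kappa d) +
#'       \alpha \sinh(\kappa d))}
#' \deqn{T = \kappa / (\kappa \cosh(\kappa d) + \alpha \sinh(\kappa d))}
#' and the absorbed fraction is `A = 1 - R - T`. This closed form is the
#' independent oracle against which the Monte Carlo estimators are
#' validated.
#'
#' @param mua,mus,g Optical properties of the slab (1/mm, 1/mm, unitless).
#' @param thickness Slab thickness d (mm).
#' @return A tibble with `reflectance`, `absorption`, `transmittance`.
#' @examples
#' slab_two_flux(mua = 0.01, mus = 5, g = 0.8, thickness = 5)
#' @export
slab_two_flux <- function(mua, mus, g, thickness) {
  sigma_b <- mus * (1 - g) / 2
  d <- thickness
  if (mua == 0) {
    R <- sigma_b * d / (1 + sigma_b * d)
    Tt <- 1 / (1 + sigma_b * d)
  } else {
    alpha <- mua + sigma_b
    kappa <- sqrt(mua * (mua + 2 * sigma_b))
    den <- kappa * cosh(kappa * d) + alpha * sinh(kappa * d)
    R <- sigma_b * sinh(kappa * d) / den
    Tt <- kappa / den
  }
  tibble(reflectance = R, absorption = 1 - R - Tt, transmittance = Tt)
}
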