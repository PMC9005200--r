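#' Linear bin grid
#'
#' A uniform grid of `count` half-open bins `[a, b)` spanning
#' `[start, stop)`. Values beyond the last bin (or below the first) are
#' accumulated into the nearest edge bin, the overflow convention that makes
#' the conservation identities of the tallies exact.
#'
#' @param start,stop Grid limits.
#' @param count Number of bins (>= 1).
#' @return An object of class `mc_grid` with `edges` and bin `centers`.
#' @export
grid_spec <- function(start, stop, count) {
  if (!is.numeric(count) || count < 1 || count != round(count)) {
    abort("`count` must be a positive integer number of bins")
  }
  if (stop <= start) abort("`stop` must exceed `start`")
  count <- as.integer(count)
  delta <- (stop - start) / count
  edges <- start + delta * (0:count)
  structure(
    list(start = start, stop = stop, count = count, delta = delta,
         edges = edges, centers = (edges[-1] + edges[-(count + 1)]) / 2),
    class = "mc_grid"
  )
}

#' @export
print.mc_grid <- function(x, ...) {
  cat(sprintf("<grid> %d bins over [%g, %g), width %g\n",
              x$count, x$start, x$stop, x$delta))
  invisible(x)
}

as_grid <- function(x, what) {
  if (inherits(x, "mc_grid")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(grid_spec(x[1], x[2], x[3]))
  abort(sprintf("`%s` must be a grid_spec() or c(start, stop, count)", what))
}

# detector type catalogue
.exit_types <- c("RDiffuse", "ROfRho", "ROfRhoAndTime", "ROfXAndY", "ROfFx",
                 "ROfRhoAndOmega", "TDiffuse")
.absorption_types <- c("ATotal", "AOfRhoAndZ", "FluenceOfRhoAndZ")
.pmc_types <- c("pMCROfRho", "pMCROfFx")
.dmc_types <- c("dMCdROfRhoDMua", "dMCdROfRhoDMus")
.detector_types <- c(.exit_types, .absorption_types, .pmc_types, .dmc_types)

new_detector <- function(type, name, second_moment, fields = list()) {
  if (!nzchar(name)) abort("detector `name` must be non-empty")
  structure(
    c(list(type = type, name = name, second_moment = isTRUE(second_moment)),
      fields),
    class = "mc_detector"
  )
}

#' Detector specifications
#'
#' Tallies the simulation can score. Exit detectors bin the photon's state
#' as it leaves the tissue; history detectors accumulate absorbed weight at
#' interaction sites. Spatially resolved means are reported per unit area
#' (annulus `pi*(rho2^2 - rho1^2)` for rho bins, `dx*dy` for Cartesian,
#' additionally per ns for time bins and per mm depth for z bins); total
#' tallies are per-photon fractions. Frequency-domain detectors accumulate
#' complex weights `w * exp(-1i*2*pi*fx*x)` (spatial frequency, 1/mm) and
#' `w * exp(-1i*2*pi*omega*t)` (temporal frequency, GHz, t in ns) so one
#' simulation yields all listed frequencies.
#'
#' With `second_moment = TRUE` the per-photon contributions squared are
#' accumulated too, from which [tidy()] reports the standard error of each
#' bin mean, `sqrt((m2 - m^2)/N)` on the unnormalized scale.
#'
#' The pMC variants re-weight a stored photon database for perturbed optical
#' properties (see [perturbation()]); the dMC variants tally the analytic
#' derivative of reflectance with respect to `mua` or `mus` of one region.
#'
#' @param name Unique detector name (defaults to the type).
#' @param second_moment Accumulate second moments for error bars.
#' @param rho,z,x,y,time [grid_spec()] bin grids (mm; ns for `time`).
#' @param fx Spatial frequencies (1/mm).
#' @param omega Temporal frequencies (GHz).
#' @param perturbation A [perturbation()] for pMC detectors.
#' @param region Tissue region the dMC derivative refers to.
#' @return An object of class `mc_detector`.
#' @name detectors
NULL

#' @rdname detectors
#' @export
detector_r_diffuse <- function(name = "RDiffuse", second_moment = TRUE) {
  new_detector("RDiffuse", name, second_moment)
}

#' @rdname detectors
#' @export
detector_t_diffuse <- function(name = "TDiffuse", second_moment = TRUE) {
  new_detector("TDiffuse", name, second_moment)
}

#' @rdname detectors
#' @export
detector_r_of_rho <- function(rho, name = "ROfRho", second_moment = TRUE) {
  new_detector("ROfRho", name, second_moment, list(rho = as_grid(rho, "rho")))
}

#' @rdname detectors
#' @export
detector_r_of_rho_and_time <- function(rho, time, name = "ROfRhoAndTime",
                                       second_moment = TRUE) {
  new_detector("ROfRhoAndTime", name, second_moment,
               list(rho = as_grid(rho, "rho"), time = as_grid(time, "time")))
}

#' @rdname detectors
#' @export
detector_r_of_x_and_y <- function(x, y, name = "ROfXAndY",
                                  second_moment = TRUE) {
  new_detector("ROfXAndY", name, second_moment,
               list(x = as_grid(x, "x"), y = as_grid(y, "y")))
}

#' @rdname detectors
#' @export
detector_r_of_fx <- function(fx, name = "ROfFx", second_moment = TRUE) {
  if (!is.numeric(fx) || !length(fx)) abort("`fx` must be a non-empty numeric vector (1/mm)")
  new_detector("ROfFx", name, second_moment, list(fx = as.numeric(fx)))
}

#' @rdname detectors
#' @export
detector_r_of_rho_and_omega <- function(rho, omega,
                                        name = "ROfRhoAndOmega",
                                        second_moment = TRUE) {
  if (!is.numeric(omega) || !length(omega)) {
    abort("`omega` must be a non-empty numeric vector (GHz)")
  }
  new_detector("ROfRhoAndOmega", name, second_moment,
               list(rho = as_grid(rho, "rho"), omega = as.numeric(omega)))
}

#' @rdname detectors
#' @export
detector_a_total <- function(name = "ATotal", second_moment = TRUE) {
  new_detector("ATotal", name, second_moment)
}

#' @rdname detectors
#' @export
detector_a_of_rho_and_z <- function(rho, z, name = "AOfRhoAndZ",
                                    second_moment = TRUE) {
  new_detector("AOfRhoAndZ", name, second_moment,
               list(rho = as_grid(rho, "rho"), z = as_grid(z, "z")))
}

#' @rdname detectors
#' @export
detector_fluence_of_rho_and_z <- function(rho, z, name = "FluenceOfRhoAndZ",
                                          second_moment = TRUE) {
  new_detector("FluenceOfRhoAndZ", name, second_moment,
               list(rho = as_grid(rho, "rho"), z = as_grid(z, "z")))
}

#' @rdname detectors
#' @export
detector_pmc_r_of_rho <- function(rho, perturbation, name = "pMCROfRho",
                                  second_moment = TRUE) {
  stopifnot(inherits(perturbation, "mc_perturbation"))
  new_detector("pMCROfRho", name, second_moment,
               list(rho = as_grid(rho, "rho"), perturbation = perturbation))
}

#' @rdname detectors
#' @export
detector_pmc_r_of_fx <- function(fx, perturbation, name = "pMCROfFx",
                                 second_moment = TRUE) {
  stopifnot(inherits(perturbation, "mc_perturbation"))
  if (!is.numeric(fx) || !length(fx)) abort("`fx` must be a non-empty numeric vector (1/mm)")
  new_detector("pMCROfFx", name, second_moment,
               list(fx = as.numeric(fx), perturbation = perturbation))
}

#' @rdname detectors
#' @export
detector_dmc_d_r_of_rho_d_mua <- function(rho, region = 1,
                                          perturbation = NULL,
                                          name = "dMCdROfRhoDMua",
                                          second_moment = TRUE) {
  new_detector("dMCdROfRhoDMua", name, second_moment,
               list(rho = as_grid(rho, "rho"), region = as.integer(region),
                    perturbation = perturbation))
}

#' @rdname detectors
#' @export
detector_dmc_d_r_of_rho_d_mus <- function(rho, region = 1,
                                          perturbation = NULL,
                                          name = "dMCdROfRhoDMus",
                                          second_moment = TRUE) {
  new_detector("dMCdROfRhoDMus", name, second_moment,
               list(rho = as_grid(rho, "rho"), region = as.integer(region),
                    perturbation = perturbation))
}

#' @export
print.mc_detector <- function(x, ...) {
  cat(sprintf("<detector %s> type %s\n", x$name, x$type))
  invisible(x)
}

detector_units <- function(type) {
  switch(type,
    RDiffuse = , TDiffuse = , ATotal = , ROfFx = , pMCROfFx = "fraction",
    ROfRho = , ROfXAndY = , ROfRhoAndOmega = , pMCROfRho = ,
    FluenceOfRhoAndZ = "1/mm^2",
    ROfRhoAndTime = "1/(mm^2 ns)",
    AOfRhoAndZ = "1/mm^3",
    dMCdROfRhoDMua = , dMCdROfRhoDMus = "1/mm^2 per 1/mm",
    ""
  )
}
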