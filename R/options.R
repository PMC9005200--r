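#' Simulation options
#'
#' Run-level settings of the transport engine.
#'
#' @param seed Integer >= 0 for a reproducible random stream; -1 draws a
#'   seed from the system entropy (the drawn seed is recorded in the run
#'   output so published results stay reproducible).
#' @param absorption_weighting `"Analog"`, `"Discrete"` (per-collision
#'   deweighting by `mus/mut`) or `"Continuous"` (Beer's-law weight decay
#'   along every path segment).
#' @param phase_function `"HenyeyGreenstein"`, or `"Bidirectional"` for
#'   one-dimensional slab problems (photons travel along +/-z only; forward
#'   scattering probability `(1+g)/2`).
#' @param databases Character subset of
#'   `c("DiffuseReflectance", "pMCDiffuseReflectance")`. The pMC database
#'   additionally stores per-region path lengths and collision counts and
#'   requires discrete or continuous absorption weighting.
#' @param track_statistics Write a `statistics.txt` photon-accounting file
#'   with the outputs.
#' @param rr_threshold Russian roulette weight threshold (0 disables RR;
#'   positive values require discrete or continuous weighting).
#' @param rr_survival Survival probability P of the roulette fair game; a
#'   surviving photon's weight is amplified by 1/P.
#' @param simulation_index Integer tag identifying this run when several
#'   run side by side (parameter sweeps).
#' @param rng_type Only `"MersenneTwister"` is available.
#' @return An object of class `mc_options`.
#' @export
sim_options <- function(seed = 0,
                        absorption_weighting = c("Discrete", "Continuous",
                                                 "Analog"),
                        phase_function = c("HenyeyGreenstein",
                                           "Bidirectional"),
                        databases = character(),
                        track_statistics = FALSE,
                        rr_threshold = 0,
                        rr_survival = 0.1,
                        simulation_index = 0,
                        rng_type = "MersenneTwister") {
  absorption_weighting <- match.arg(absorption_weighting)
  phase_function <- match.arg(phase_function)
  rng_type <- match.arg(rng_type)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed) ||
      seed < -1) {
    abort("`seed` must be an integer >= 0, or -1 for a random stream")
  }
  bad_db <- setdiff(databases,
                    c("DiffuseReflectance", "pMCDiffuseReflectance"))
  if (length(bad_db)) {
    abort(sprintf("unknown database type '%s'", bad_db[1]))
  }
  if ("pMCDiffuseReflectance" %in% databases &&
      absorption_weighting == "Analog") {
    abort(paste("the pMCDiffuseReflectance database requires",
                "absorption_weighting 'Discrete' or 'Continuous'"))
  }
  if (!is.numeric(rr_threshold) || rr_threshold < 0) {
    abort("`rr_threshold` must be >= 0 (0 disables Russian roulette)")
  }
  if (rr_threshold > 0 && absorption_weighting == "Analog") {
    abort(paste("Russian roulette requires absorption_weighting",
                "'Discrete' or 'Continuous'"))
  }
  if (rr_survival <= 0 || rr_survival >= 1) {
    abort("`rr_survival` must be in (0, 1)")
  }
  if (simulation_index < 0 || simulation_index != round(simulation_index)) {
    abort("`simulation_index` must be a non-negative integer")
  }
  structure(
    list(
      seed = as.integer(seed),
      rng_type = rng_type,
      absorption_weighting = absorption_weighting,
      phase_function = phase_function,
      databases = unique(databases),
      track_statistics = isTRUE(track_statistics),
      rr_threshold = rr_threshold,
      rr_survival = rr_survival,
      simulation_index = as.integer(simulation_index)
    ),
    class = "mc_options"
  )
}

#' @export
print.mc_options <- function(x, ...) {
  cat(sprintf(
    "<options> seed %d | %s | %s | RR threshold %g | databases: %s\n",
    x$seed, x$absorption_weighting, x$phase_function, x$rr_threshold,
    if (length(x$databases)) paste(x$databases, collapse = ", ") else "none"
  ))
  invisible(x)
}

mode_code <- function(absorption_weighting) {
  match(absorption_weighting, c("Analog", "Discrete", "Continuous")) - 1L
}

phase_code <- function(phase_function) {
  match(phase_function, c("HenyeyGreenstein", "Bidirectional")) - 1L
}
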