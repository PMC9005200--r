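#' Assemble a simulation
#'
#' Bundles everything one run needs: photon count, options, source, tissue
#' and detectors, with all cross-field rules checked up front (before any
#' photon is launched).
#'
#' @param output_name Folder name the outputs are written under.
#' @param n_photons Number of photons N to launch (>= 1).
#' @param options An [sim_options()] object.
#' @param source An `mc_source`.
#' @param tissue An `mc_tissue`.
#' @param detectors A list of `mc_detector` specifications (unique names).
#' @return An object of class `mc_input`.
#' @export
simulation_input <- function(output_name = "results", n_photons,
                             options = sim_options(), source, tissue,
                             detectors = list()) {
  if (!is.character(output_name) || !nzchar(output_name)) {
    abort("`output_name` must be a non-empty string")
  }
  if (!is.numeric(n_photons) || n_photons < 1 ||
      n_photons != round(n_photons)) {
    abort("`n_photons` must be a positive integer")
  }
  stopifnot(inherits(options, "mc_options"), inherits(source, "mc_source"),
            inherits(tissue, "mc_tissue"))
  if (inherits(detectors, "mc_detector")) detectors <- list(detectors)
  ok <- vapply(detectors, inherits, logical(1), what = "mc_detector")
  if (!all(ok)) abort("`detectors` must be a list of detector specifications")
  nms <- vapply(detectors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate detector name '%s'", nms[duplicated(nms)][1]))
  }
  names(detectors) <- nms
  input <- structure(
    list(output_name = output_name, n_photons = as.double(n_photons),
         options = options, source = source, tissue = tissue,
         detectors = detectors),
    class = "mc_input"
  )
  validate_input(input)
  input
}

#' @export
print.mc_input <- function(x, ...) {
  cat(sprintf(
    "<simulation input '%s'> N = %g, %s / %s, %d detector(s)\n",
    x$output_name, x$n_photons, x$options$absorption_weighting,
    x$options$phase_function, length(x$detectors)
  ))
  invisible(x)
}

validate_input <- function(input) {
  opt <- input$options
  types <- vapply(input$detectors, `[[`, character(1), "type")
  needs_pmc <- any(types %in% c(.pmc_types, .dmc_types))
  if (needs_pmc && opt$absorption_weighting == "Analog") {
    abort("pMC/dMC detectors require discrete or continuous absorption weighting")
  }
  if (opt$phase_function == "Bidirectional") {
    # restricted to 1D slab problems: axial point source, matched-index
    # layered slab, no inclusion
    if (input$source$type != "DirectionalPoint" ||
        any(abs(input$source$direction[1:2]) > 0)) {
      abort("bidirectional scattering requires a DirectionalPoint source along +/-z")
    }
    tis <- input$tissue
    ns <- c(tis$n_above, tis$layers$n, tis$n_below)
    if (length(unique(ns)) != 1L) {
      abort("bidirectional scattering requires refractive-index matched media")
    }
    if (!is.null(tis$ellipsoid)) {
      abort("bidirectional scattering supports layered slabs only")
    }
  }
  # absorption grid detectors must share one (rho, z) grid
  agrids <- input$detectors[types %in% c("AOfRhoAndZ", "FluenceOfRhoAndZ")]
  if (length(agrids) > 1) {
    g1 <- agrids[[1]]
    same <- vapply(agrids[-1], function(d) {
      identical(d$rho[c("start", "stop", "count")],
                g1$rho[c("start", "stop", "count")]) &&
        identical(d$z[c("start", "stop", "count")],
                  g1$z[c("start", "stop", "count")])
    }, logical(1))
    if (!all(same)) {
      abort("AOfRhoAndZ and FluenceOfRhoAndZ detectors must share one (rho, z) grid")
    }
  }
  # pMC perturbations must refer to existing regions and leave g, n alone
  for (d in input$detectors[types %in% c(.pmc_types, .dmc_types)]) {
    if (!is.null(d$perturbation)) {
      check_perturbation(d$perturbation, input$tissue)
    }
    if (!is.null(d$region)) {
      tr <- tissue_regions(input$tissue)
      if (!all(d$region %in% tr$region[tr$kind != "air_above" &
                                       tr$kind != "air_below"])) {
        abort("dMC `region` must be a tissue region index")
      }
    }
  }
  invisible(input)
}

#' Run a Monte Carlo simulation
#'
#' Launches N photon random walks through the tissue, scores every
#' requested detector (with second moments where enabled), tracks the
#' photon accounting statistics, and assembles any requested trajectory
#' database. A fixed non-negative seed makes the run fully deterministic.
#'
#' `cpucount > 1` emulates a multi-process run by executing `cpucount`
#' sequential sub-simulations on streams seeded `seed, seed + 1, ...` and
#' pooling tallies and second moments; independence of the sub-streams
#' rests on the distinct Mersenne Twister seeds.
#'
#' @param input An [simulation_input()] object (or an infile path parsed
#'   with [parse_infile()]).
#' @param cpucount Number of pooled sub-simulations.
#' @return An `mc_output` with elements `tallies` (named list of tallies),
#'   `statistics`, `database` (when requested), `seed` (the seed actually
#'   used) and `runtime` (seconds).
#' @examples
#' tis <- tissue_model(data.frame(thickness = 5, mua = 0.01, mus = 5,
#'                                g = 0.8, n = 1))
#' inp <- simulation_input(
#'   n_photons = 500, source = source_directional_point(), tissue = tis,
#'   options = sim_options(seed = 3, absorption_weighting = "Continuous"),
#'   detectors = list(detector_r_diffuse(), detector_a_total())
#' )
#' out <- run_simulation(inp)
#' tidy(out)
#' @export
run_simulation <- function(input, cpucount = 1) {
  stopifnot(inherits(input, "mc_input"))
  if (cpucount < 1 || cpucount != round(cpucount)) {
    abort("`cpucount` must be a positive integer")
  }
  opt <- input$options
  seed <- opt$seed
  if (seed < 0) {
    # -1: draw entropy from the system, but record what was drawn
    seed <- sample.int(.Machine$integer.max, 1)
  }
  types <- vapply(input$detectors, `[[`, character(1), "type")
  want_coll <- any(types %in% c(.pmc_types, .dmc_types)) ||
    "pMCDiffuseReflectance" %in% opt$databases
  arz_det <- input$detectors[types %in% c("AOfRhoAndZ", "FluenceOfRhoAndZ")]
  arz <- if (length(arz_det)) {
    d <- arz_det[[1]]
    list(rho_start = d$rho$start, rho_stop = d$rho$stop,
         rho_count = d$rho$count, z_start = d$z$start, z_stop = d$z$stop,
         z_count = d$z$count)
  } else {
    NULL
  }

  t0 <- proc.time()[["elapsed"]]
  n_each <- chunk_sizes(input$n_photons, cpucount)
  runs <- vector("list", cpucount)
  for (k in seq_len(cpucount)) {
    cfg <- list(
      n_photons = as.integer(n_each[k]),
      seed = as.double(seed + k - 1),
      mode = mode_code(opt$absorption_weighting),
      phase = phase_code(opt$phase_function),
      rr_threshold = opt$rr_threshold,
      rr_survival = opt$rr_survival,
      max_collisions = 1000000L,
      collect_collision = want_coll,
      collect_per_photon = FALSE,
      tissue = tissue_cfg(input$tissue),
      source = source_cfg(input$source),
      arz = arz
    )
    runs[[k]] <- run_engine_cpp(cfg)
  }
  eng <- pool_runs(runs)
  runtime <- proc.time()[["elapsed"]] - t0

  records <- as_tibble(as.data.frame(eng$exits))
  db <- new_database(
    exits = records,
    L = eng$collision_L, J = eng$collision_J,
    n_photons = input$n_photons, tissue = input$tissue,
    absorption_weighting = opt$absorption_weighting, seed = seed
  )

  tallies <- list()
  for (d in input$detectors) {
    tallies[[d$name]] <- compute_tally(d, eng, db, input)
  }

  stats <- tibble(
    n_photons = input$n_photons,
    n_out_top = eng$n_out_top,
    n_out_bottom = eng$n_out_bottom,
    n_specular = eng$n_specular,
    n_absorbed = eng$n_absorbed,
    n_killed_rr = eng$n_killed_rr,
    n_capped = eng$n_capped,
    specular_weight = eng$specular_weight
  )

  keep_db <- length(opt$databases) > 0
  structure(
    list(
      input = input,
      tallies = tallies,
      statistics = stats,
      database = if (keep_db) db else NULL,
      seed = seed,
      runtime = runtime
    ),
    class = "mc_output"
  )
}

# per-photon accounting (specular, deposited, exit weight, status) for
# conservation checks; statuses: 1 specular, 2 exited top, 3 exited bottom,
# 4 absorbed, 5 killed by RR, 6 collision cap
run_simulation_debug <- function(input) {
  stopifnot(inherits(input, "mc_input"))
  opt <- input$options
  cfg <- list(
    n_photons = as.integer(input$n_photons),
    seed = as.double(max(opt$seed, 0)),
    mode = mode_code(opt$absorption_weighting),
    phase = phase_code(opt$phase_function),
    rr_threshold = opt$rr_threshold,
    rr_survival = opt$rr_survival,
    max_collisions = 1000000L,
    collect_collision = TRUE,
    collect_per_photon = TRUE,
    tissue = tissue_cfg(input$tissue),
    source = source_cfg(input$source),
    arz = NULL
  )
  run_engine_cpp(cfg)
}

chunk_sizes <- function(n, k) {
  base <- floor(n / k)
  sizes <- rep(base, k)
  sizes[seq_len(n - base * k)] <- base + 1
  sizes
}

pool_runs <- function(runs) {
  if (length(runs) == 1L) return(runs[[1]])
  out <- runs[[1]]
  out$exits <- do.call(rbind, lapply(runs, `[[`, "exits"))
  for (f in c("n_photons", "n_out_top", "n_out_bottom", "n_specular",
              "n_absorbed", "n_killed_rr", "n_capped", "specular_weight",
              "a_total", "a_total_m2")) {
    out[[f]] <- sum(vapply(runs, `[[`, numeric(1), f))
  }
  if (!is.null(out$collision_L)) {
    out$collision_L <- do.call(rbind, lapply(runs, `[[`, "collision_L"))
    out$collision_J <- do.call(rbind, lapply(runs, `[[`, "collision_J"))
  }
  if (!is.null(out$arz)) {
    out$arz <- Reduce(`+`, lapply(runs, `[[`, "arz"))
    out$arz_m2 <- Reduce(`+`, lapply(runs, `[[`, "arz_m2"))
  }
  out
}

compute_tally <- function(det, eng, db, input) {
  N <- input$n_photons
  if (det$type %in% .exit_types) {
    r <- tally_exit_raw(db$exits, det)
    return(new_tally(det, r$raw, r$m2, N))
  }
  if (det$type == "ATotal") {
    return(new_tally(det, eng$a_total, eng$a_total_m2, N))
  }
  if (det$type %in% c("AOfRhoAndZ", "FluenceOfRhoAndZ")) {
    tal <- new_tally(det, eng$arz, eng$arz_m2, N)
    if (det$type == "FluenceOfRhoAndZ") {
      tal <- absorbed_to_fluence(tal, det, input$tissue)
    }
    return(tal)
  }
  # pMC / dMC detectors re-tally the in-memory collision database
  retally_one(db, det)
}

# fluence = absorbed energy density / mua of the bin's region; bins that
# straddle an interface use the region at the bin center (rho_c, 0, z_c)
absorbed_to_fluence <- function(tally, det, tissue) {
  pts <- cbind(
    rep(det$rho$centers, times = det$z$count),
    0,
    rep(det$z$centers, each = det$rho$count)
  )
  reg <- region_index_at(tissue, pts)
  tr <- tissue_regions(tissue)
  mua <- tr$mua[match(reg, tr$region)]
  mua_arr <- array(mua, dim = dim(tally$mean))
  tally$mean <- tally$mean / mua_arr
  if (!is.null(tally$std_error)) tally$std_error <- tally$std_error / mua_arr
  tally$measure <- tally$measure * mua_arr
  tally
}

#' @export
print.mc_output <- function(x, ...) {
  cat(sprintf("<simulation output '%s'> N = %g photons, seed %d, %.2f s\n",
              x$input$output_name, x$input$n_photons, x$seed, x$runtime))
  for (t in x$tallies) print(t)
  invisible(x)
}
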