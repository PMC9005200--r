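# Shared fixtures: benchmark tissues, input builders and a per-session run
# cache so expensive simulations are shared across test files.

slab_1d <- function(n = 1) {
  tissue_model(data.frame(thickness = 5, mua = 0.01, mus = 5, g = 0.8,
                          n = n))
}

two_layer_tissue <- function() {
  tissue_model(data.frame(
    thickness = c(0.1, Inf),
    mua = c(2, 1), mus = c(20, 20), g = c(0.7, 0.9), n = c(1.3, 1.4)
  ))
}

# matched-index bidirectional slab benchmark (totals detectors)
bidir_input <- function(n_photons, seed = 1,
                        absorption_weighting = "Continuous") {
  simulation_input(
    output_name = "bidir",
    n_photons = n_photons,
    options = sim_options(seed = seed,
                          absorption_weighting = absorption_weighting,
                          phase_function = "Bidirectional",
                          track_statistics = TRUE),
    source = source_directional_point(),
    tissue = slab_1d(),
    detectors = list(detector_r_diffuse(), detector_a_total(),
                     detector_t_diffuse())
  )
}

# two-layer skin-like benchmark (collimated beam, DAW)
two_layer_input <- function(n_photons, seed = 1, rr_threshold = 1e-4) {
  simulation_input(
    output_name = "two_layer",
    n_photons = n_photons,
    options = sim_options(seed = seed, absorption_weighting = "Discrete",
                          rr_threshold = rr_threshold,
                          track_statistics = TRUE),
    source = source_directional_point(),
    tissue = two_layer_tissue(),
    detectors = list(detector_r_diffuse(), detector_a_total(),
                     detector_t_diffuse())
  )
}

# 3D Henyey-Greenstein slab with a pMC database and an R(rho) detector
pmc_slab_input <- function(n_photons, seed, mua = 0.01, mus = 5,
                           rho = grid_spec(0, 4, 16), thickness = 5) {
  simulation_input(
    output_name = "pmc_slab",
    n_photons = n_photons,
    options = sim_options(seed = seed, absorption_weighting = "Continuous",
                          databases = "pMCDiffuseReflectance"),
    source = source_directional_point(),
    tissue = tissue_model(data.frame(thickness = thickness, mua = mua,
                                     mus = mus, g = 0.8, n = 1)),
    detectors = list(detector_r_of_rho(rho))
  )
}

# isotropic-scattering phantom for the optical-property recovery
# experiment: with g = 0 detected photons carry few collisions, keeping the
# pMC likelihood-ratio variance small across +/-30% scattering changes
inverse_phantom_input <- function(n_photons, seed, mua = 0.012, musp = 1.2,
                                  rho = grid_spec(0, 6, 20)) {
  simulation_input(
    output_name = "phantom",
    n_photons = n_photons,
    options = sim_options(seed = seed, absorption_weighting = "Continuous",
                          databases = "pMCDiffuseReflectance"),
    source = source_directional_point(),
    tissue = tissue_model(data.frame(thickness = 10, mua = mua, mus = musp,
                                     g = 0, n = 1)),
    detectors = list(detector_r_of_rho(rho))
  )
}

scalar_mean <- function(out, name) as.numeric(Re(out$tallies[[name]]$mean))
scalar_se <- function(out, name) as.numeric(Re(out$tallies[[name]]$std_error))

.run_cache <- new.env(parent = emptyenv())

run_cached <- function(key, input) {
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_simulation(input)
  }
  .run_cache[[key]]
}

# fabricate an exit-record database for detector unit tests
fake_database <- function(x, y, weight, side = 0, time = 0,
                          n_photons = length(x), with_collision = FALSE,
                          L = NULL, J = NULL, tissue = slab_1d()) {
  n <- length(x)
  exits <- tibble::tibble(
    x = x, y = y, ux = 0, uy = 0, uz = rep_len(ifelse(side == 0, -1, 1), n),
    weight = weight, time = rep_len(time, n), side = rep_len(side, n)
  )
  photonmc:::new_database(
    exits = exits,
    L = if (with_collision) L else NULL,
    J = if (with_collision) J else NULL,
    n_photons = n_photons, tissue = tissue,
    absorption_weighting = "Continuous", seed = 0L
  )
}
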