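ops_d <- optical_properties(mua = 1, mus = 1, g = 0, n = 1)    # mut = 2
ops_c <- optical_properties(mua = 0.01, mus = 5, g = 0.8, n = 1)

test_that("step sampling inverts the exponential intercollision law", {
  expect_equal(sample_step(ops_d, "Discrete", u = exp(-1)), 0.5)
  expect_equal(sample_step(ops_c, "Continuous", u = exp(-1)), 0.2)
  expect_equal(sample_step(ops_d, "Analog", u = exp(-2)), 1)
  # u -> 1- gives vanishing but never negative steps
  expect_gt(sample_step(ops_d, "Discrete", u = 1 - 1e-12), 0)
  expect_lt(sample_step(ops_d, "Discrete", u = 1 - 1e-12), 1e-9)
  # a non-scattering region is ballistic under CAW
  clear <- optical_properties(0.1, 0, 0, 1)
  expect_identical(sample_step(clear, "Continuous", u = 0.5), Inf)
})

test_that("Henyey-Greenstein sampling matches its inverse CDF and mean", {
  expect_equal(scatter_hg(0, u = 0.25)$cos_theta, -0.5)
  # closed-form inverse CDF at g = 0.8, u = 0.5
  g <- 0.8; u <- 0.5
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  expect_equal(scatter_hg(g, u = u)$cos_theta, (1 + g^2 - tmp^2) / (2 * g))
  expect_equal(round(scatter_hg(g, u = u)$cos_theta, 4), 0.9440)
  set.seed(11)
  draws <- scatter_hg(0.8, n = 1e5)
  # E[cos] = g; var of the HG cosine bounded by 1
  expect_lt(abs(mean(draws$cos_theta) - 0.8), 3 * stats::sd(draws$cos_theta) / sqrt(1e5))
  expect_true(all(draws$cos_theta >= -1 & draws$cos_theta <= 1))
})

test_that("bidirectional scattering reverses with probability (1-g)/2", {
  expect_equal(scatter_bidirectional(1, rep(1, 100), u = runif(100)),
               rep(1, 100))
  set.seed(12)
  uz <- rep(1, 1e5)
  rev_frac <- mean(scatter_bidirectional(0.8, uz) == -1)
  expect_lt(abs(rev_frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  rev_frac0 <- mean(scatter_bidirectional(0, uz) == -1)
  expect_lt(abs(rev_frac0 - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("direction rotation is exact in the degenerate pole frame", {
  expect_equal(update_direction(c(0, 0, 1), 1, 2.3), c(0, 0, 1))
  expect_equal(update_direction(c(0, 0, 1), 0, 0), c(1, 0, 0))
  set.seed(13)
  for (i in 1:100) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    ct <- runif(1, -1, 1); ph <- runif(1, 0, 2 * pi)
    nd <- update_direction(d, ct, ph)
    expect_lt(abs(sum(nd^2) - 1), 1e-12)
    expect_lt(abs(sum(nd * d) - ct), 1e-9)  # deflection angle preserved
  }
})

test_that("Fresnel reflectance covers normal incidence and TIR", {
  expect_equal(fresnel(1.0, 1.3, 1), ((1 - 1.3) / (1 + 1.3))^2)
  expect_equal(round(fresnel(1.0, 1.3, 1), 6), 0.017013)
  expect_equal(fresnel(1.4, 1.4, 0.5), 0)
  # 60 deg from n=1.4 into 1.0 is beyond the 45.6 deg critical angle
  expect_equal(fresnel(1.4, 1.0, cos(pi / 3)), 1)
  expect_error(fresnel(1, 1.3, 0), "cos_incident")
})

test_that("time advances as path length times n over c", {
  expect_equal(advance_time(0, 3, 1.4), 3 * 1.4 / 299.792458)
  expect_equal(round(advance_time(0, 3, 1.4), 6), 0.014010)
  expect_equal(advance_time(1.5, 0, 1.4), 1.5)
  expect_equal(advance_time(0, 299.792458 / 1.4, 1.4), 1)
})

test_that("Russian roulette is a fair game", {
  out <- russian_roulette(5e-5, threshold = 1e-4, p_survive = 0.1, u = 0.05)
  expect_equal(out$weight, 5e-4)
  out <- russian_roulette(1e-3, threshold = 1e-4, u = 0.99)
  expect_equal(out$weight, 1e-3)
  expect_false(out$killed)
  set.seed(14)
  w <- rep(5e-5, 1e5)
  res <- russian_roulette(w, threshold = 1e-4, p_survive = 0.1)
  # unbiasedness: E[weight after] = weight before
  se <- stats::sd(res$weight) / sqrt(1e5)
  expect_lt(abs(mean(res$weight) - 5e-5), 3 * se)
})

test_that("a non-interacting slab is ballistic", {
  inp <- simulation_input(
    n_photons = 10,
    options = sim_options(seed = 0, absorption_weighting = "Continuous"),
    source = source_directional_point(),
    tissue = tissue_model(data.frame(thickness = 5, mua = 0, mus = 0,
                                     g = 0, n = 1)),
    detectors = list(detector_t_diffuse(), detector_r_diffuse())
  )
  out <- run_simulation(inp)
  expect_equal(scalar_mean(out, "TDiffuse"), 1)
  expect_equal(scalar_mean(out, "RDiffuse"), 0)
  db <- photonmc:::run_simulation_debug(inp)
  expect_equal(as.vector(db$exits[, "weight"]), rep(1, 10))
  expect_equal(as.vector(db$exits[, "time"]), rep(5 / 299.792458, 10))
})

test_that("per-photon weight is conserved under DAW and CAW without RR", {
  for (aw in c("Discrete", "Continuous")) {
    inp <- simulation_input(
      n_photons = 300,
      options = sim_options(seed = 21, absorption_weighting = aw),
      source = source_directional_point(),
      tissue = tissue_model(data.frame(thickness = 2, mua = 0.5, mus = 10,
                                       g = 0.7, n = 1.4)),
      detectors = list(detector_r_diffuse())
    )
    eng <- photonmc:::run_simulation_debug(inp)
    pp <- eng$per_photon
    total <- pp[, "specular"] + pp[, "deposited"] + pp[, "exit_weight"]
    expect_lt(max(abs(total - 1)), 1e-12)
  }
})

test_that("analog photons contribute exactly 1 to exactly one fate", {
  inp <- bidir_input(2000, seed = 5, absorption_weighting = "Analog")
  out <- run_simulation(inp)
  st <- out$statistics
  expect_equal(st$n_out_top + st$n_out_bottom + st$n_specular +
                 st$n_absorbed, 2000)
  expect_equal(scalar_mean(out, "RDiffuse") + scalar_mean(out, "ATotal") +
                 scalar_mean(out, "TDiffuse"), 1)
  eng <- photonmc:::run_simulation_debug(inp)
  w <- eng$exits[, "weight"]
  expect_true(all(w == 1))
})

test_that("bidirectional slab totals agree with the two-flux closed form", {
  an <- slab_two_flux(0.01, 5, 0.8, 5)
  out <- run_cached("bidir_caw_3e4", bidir_input(3e4, seed = 31))
  for (pair in list(c("RDiffuse", "reflectance"),
                    c("ATotal", "absorption"),
                    c("TDiffuse", "transmittance"))) {
    expect_lt(abs(scalar_mean(out, pair[1]) - an[[pair[2]]]),
              4 * scalar_se(out, pair[1]))
  }
})

test_that("analog, discrete and continuous estimators agree", {
  a <- run_cached("bidir_analog_3e4",
                  bidir_input(3e4, seed = 41, "Analog"))
  d <- run_cached("bidir_daw_3e4",
                  bidir_input(3e4, seed = 42, "Discrete"))
  c <- run_cached("bidir_caw_3e4b",
                  bidir_input(3e4, seed = 43, "Continuous"))
  pairs <- utils::combn(list(a, d, c), 2, simplify = FALSE)
  for (p in pairs) {
    dz <- abs(scalar_mean(p[[1]], "RDiffuse") -
                scalar_mean(p[[2]], "RDiffuse"))
    sig <- sqrt(scalar_se(p[[1]], "RDiffuse")^2 +
                  scalar_se(p[[2]], "RDiffuse")^2)
    expect_lt(dz, 3 * sig)
  }
})

test_that("fixed seeds reproduce runs exactly", {
  inp <- two_layer_input(100, seed = 0)
  o1 <- run_simulation(inp)
  o2 <- run_simulation(inp)
  expect_identical(o1$tallies$RDiffuse$mean, o2$tallies$RDiffuse$mean)
  expect_identical(o1$statistics, o2$statistics)
  o3 <- run_simulation(two_layer_input(100, seed = 1))
  expect_false(identical(o1$tallies$RDiffuse$mean, o3$tallies$RDiffuse$mean))
})

test_that("boundary physics conserves weight in mismatched layered media", {
  inp <- two_layer_input(2000, seed = 51, rr_threshold = 0)
  eng <- photonmc:::run_simulation_debug(inp)
  pp <- eng$per_photon
  total <- pp[, "specular"] + pp[, "deposited"] + pp[, "exit_weight"]
  expect_lt(max(abs(total - 1)), 1e-11)
})

test_that("photons traverse an ellipsoid inclusion consistently", {
  tis <- tissue_model(
    data.frame(thickness = 10, mua = 0.01, mus = 5, g = 0.8, n = 1.4),
    ellipsoid = ellipsoid_region(c(0, 0, 3), c(1, 1, 1),
                                 optical_properties(0.2, 8, 0.9, 1.4))
  )
  inp <- simulation_input(
    n_photons = 1000,
    options = sim_options(seed = 61, absorption_weighting = "Discrete"),
    source = source_directional_point(), tissue = tis,
    detectors = list(detector_r_diffuse(), detector_a_total(),
                     detector_t_diffuse())
  )
  eng <- photonmc:::run_simulation_debug(inp)
  pp <- eng$per_photon
  expect_lt(max(abs(pp[, "specular"] + pp[, "deposited"] +
                      pp[, "exit_weight"] - 1)), 1e-11)
  # some photons do collide inside the inclusion (region 3 of this stack)
  expect_gt(sum(eng$collision_J[, 4]), 0)
})
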