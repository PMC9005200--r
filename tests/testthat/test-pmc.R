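# two-region collision fixture: one photon with 3 collisions over 2 mm in
# layer 1 and nothing in any other region
one_photon_db <- function() {
  tis <- tissue_model(data.frame(thickness = c(5, 5),
                                 mua = c(0.01, 0.02), mus = c(5, 4),
                                 g = c(0.8, 0.8), n = c(1, 1)))
  L <- matrix(0, 1, 4); J <- matrix(0, 1, 4)
  L[1, 2] <- 2; J[1, 2] <- 3  # region 1 occupies column 2
  fake_database(x = 0.5, y = 0, weight = 1, n_photons = 1,
                with_collision = TRUE, L = L, J = J, tissue = tis)
}

test_that("the pMC likelihood ratio matches its closed form", {
  db <- one_photon_db()
  # zero perturbation: multiplier is exactly 1
  expect_identical(pmc_weight_factor(db, perturbation(1, mua = 0.01)), 1)
  expect_identical(pmc_weight_factor(db, perturbation(1, mus = 5)), 1)
  # mus 5 -> 6 with j = 3, L = 2: (6/5)^3 * exp(-(6.01 - 5.01) * 2)
  f <- pmc_weight_factor(db, perturbation(1, mus = 6))
  expect_equal(f, (6 / 5)^3 * exp(-2))
  expect_equal(round(f, 5), 0.23386)
  # CAW mua-only perturbation is Beer's law: mua 0.01 -> 0.02 over L = 10
  db2 <- one_photon_db()
  db2$L[1, 2] <- 10
  expect_equal(pmc_weight_factor(db2, perturbation(1, mua = 0.02)),
               exp(-0.1))
  expect_equal(round(pmc_weight_factor(db2, perturbation(1, mua = 0.02)), 6),
               0.904837)
  # untouched regions contribute nothing
  expect_identical(pmc_weight_factor(db, perturbation(2, mua = 0.5)), 1)
})

test_that("zero-perturbation pMC re-tally equals the baseline bit-for-bit", {
  out <- run_cached("db_slab_1e4", pmc_slab_input(1e4, seed = 81))
  rho <- grid_spec(0, 4, 16)
  base <- out$tallies$ROfRho
  pmc0 <- retally(out$database,
                  detector_pmc_r_of_rho(rho, perturbation(1, mua = 0.01)))[[1]]
  expect_identical(base$mean, pmc0$mean)
  expect_identical(base$second_moment, pmc0$second_moment)
})

test_that("pMC at perturbed properties agrees with an independent run", {
  rho <- grid_spec(0, 4, 16)
  out <- run_cached("db_slab_3e4", pmc_slab_input(3e4, seed = 82))
  pmc <- retally(out$database,
                 detector_pmc_r_of_rho(rho, perturbation(1, mua = 0.012)))[[1]]
  ind <- run_cached("slab_mua12_3e4",
                    pmc_slab_input(3e4, seed = 99, mua = 0.012))
  z <- (pmc$mean - ind$tallies$ROfRho$mean) /
    sqrt(pmc$std_error^2 + ind$tallies$ROfRho$std_error^2)
  expect_lt(max(abs(z)), 3.6)
  # the perturbed estimate actually moved
  expect_false(isTRUE(all.equal(pmc$mean, out$tallies$ROfRho$mean)))
})

test_that("pMC second moments stay finite under a large mus perturbation", {
  out <- run_cached("db_slab_1e4", pmc_slab_input(1e4, seed = 81))
  rho <- grid_spec(0, 4, 8)
  tal <- retally(out$database,
                 detector_pmc_r_of_rho(rho, perturbation(1, mus = 10)))[[1]]
  expect_true(all(is.finite(tal$second_moment)))
  expect_true(all(tal$second_moment >= 0))
})

test_that("dMC derivatives are the analytic slope of the pMC multiplier", {
  out <- run_cached("db_slab_3e4", pmc_slab_input(3e4, seed = 82))
  db <- out$database
  rho <- grid_spec(0, 4, 16)
  dmua <- retally(db, detector_dmc_d_r_of_rho_d_mua(rho, region = 1))[[1]]
  # more absorption can only reduce reflectance
  expect_true(all(dmua$mean <= 0))
  # central finite differences of pMC at +/-1% mua
  h <- 0.01 * 0.01
  up <- retally(db, detector_pmc_r_of_rho(rho, perturbation(1, mua = 0.01 + h)))[[1]]
  dn <- retally(db, detector_pmc_r_of_rho(rho, perturbation(1, mua = 0.01 - h)))[[1]]
  fd <- (up$mean - dn$mean) / (2 * h)
  expect_equal(as.vector(dmua$mean), as.vector(fd), tolerance = 1e-4)

  dmus <- retally(db, detector_dmc_d_r_of_rho_d_mus(rho, region = 1))[[1]]
  hs <- 0.01 * 5
  ups <- retally(db, detector_pmc_r_of_rho(rho, perturbation(1, mus = 5 + hs)))[[1]]
  dns <- retally(db, detector_pmc_r_of_rho(rho, perturbation(1, mus = 5 - hs)))[[1]]
  fds <- (ups$mean - dns$mean) / (2 * hs)
  expect_equal(as.vector(dmus$mean), as.vector(fds), tolerance = 5e-3)
})

test_that("photons that never visit a region score zero derivatives there", {
  db <- one_photon_db()
  rho <- grid_spec(0, 1, 2)
  d2a <- retally(db, detector_dmc_d_r_of_rho_d_mua(rho, region = 2))[[1]]
  d2s <- retally(db, detector_dmc_d_r_of_rho_d_mus(rho, region = 2))[[1]]
  expect_equal(sum(abs(d2a$raw)), 0)
  expect_equal(sum(abs(d2s$raw)), 0)
})

test_that("perturbations of g or n and unknown regions are rejected", {
  out <- run_cached("db_slab_1e4", pmc_slab_input(1e4, seed = 81))
  expect_error(perturbation(1), "at least one")
  expect_error(
    retally(out$database,
            detector_pmc_r_of_rho(grid_spec(0, 1, 2),
                                  perturbation(7, mua = 0.02))),
    "regions"
  )
})
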