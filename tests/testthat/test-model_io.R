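test_that("infiles round-trip through write and parse", {
  inp <- simulation_input(
    output_name = "roundtrip",
    n_photons = 100,
    options = sim_options(seed = 0, absorption_weighting = "Discrete",
                          rr_threshold = 1e-4, track_statistics = TRUE),
    source = source_directional_point(),
    tissue = two_layer_tissue(),
    detectors = list(detector_r_of_rho(grid_spec(0, 10, 100)))
  )
  path <- withr::local_tempfile(fileext = ".txt")
  write_infile(inp, path)
  back <- parse_infile(path)
  expect_equal(back$output_name, "roundtrip")
  expect_equal(back$n_photons, 100)
  expect_equal(back$options, inp$options)
  expect_equal(back$tissue$layers, inp$tissue$layers)
  expect_equal(back$source$direction, inp$source$direction)
  expect_equal(back$detectors$ROfRho$rho$edges, inp$detectors$ROfRho$rho$edges)
  # Russian roulette threshold survives as stated
  expect_identical(back$options$rr_threshold, 1e-4)
})

test_that("cross-field option rules are enforced before launch", {
  expect_error(
    sim_options(databases = "pMCDiffuseReflectance",
                absorption_weighting = "Analog"),
    "Discrete' or 'Continuous"
  )
  expect_error(
    sim_options(rr_threshold = 1e-4, absorption_weighting = "Analog"),
    "Discrete' or 'Continuous"
  )
  expect_error(
    simulation_input(
      n_photons = 10,
      options = sim_options(absorption_weighting = "Analog"),
      source = source_directional_point(), tissue = slab_1d(),
      detectors = list(detector_dmc_d_r_of_rho_d_mua(grid_spec(0, 1, 2)))
    ),
    "pMC/dMC"
  )
  expect_error(
    simulation_input(
      n_photons = 10, options = sim_options(),
      source = source_directional_point(), tissue = slab_1d(),
      detectors = list(detector_r_diffuse(), detector_r_diffuse())
    ),
    "duplicate"
  )
})

test_that("unknown and malformed infile keys are rejected with their path", {
  inp <- simulation_input(
    n_photons = 10, options = sim_options(),
    source = source_directional_point(), tissue = slab_1d(n = 1),
    detectors = list(detector_r_diffuse())
  )
  path <- withr::local_tempfile(fileext = ".txt")
  write_infile(inp, path)
  txt <- paste(readLines(path), collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)

  doc$Options$Typo <- 1
  expect_error(parse_infile(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "Options\\$Typo")
  doc$Options$Typo <- NULL
  doc$TissueInput$Regions[[2]]$OP$Mua <- "fast"
  expect_error(parse_infile(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "Mua")
})

test_that("example infiles cover every detector and re-parse cleanly", {
  dir <- withr::local_tempdir()
  paths <- generate_example_infiles(dir)
  expect_true(file.path(dir, "infile_one_all_detectors.txt") %in% paths)
  for (p in paths) {
    inp <- parse_infile(p)
    expect_s3_class(inp, "mc_input")
  }
  all_txt <- paste(readLines(file.path(dir, "infile_one_all_detectors.txt")),
                   collapse = "\n")
  for (type in photonmc:::.detector_types) {
    expect_match(all_txt, type, fixed = TRUE)
  }
  # idempotent overwrite
  sizes1 <- file.size(paths)
  paths2 <- generate_example_infiles(dir)
  expect_identical(sort(paths), sort(paths2))
  expect_identical(file.size(paths2), sizes1)
})

test_that("outputs are written per detector with statistics and round-trip", {
  inp <- simulation_input(
    output_name = "outtest", n_photons = 400,
    options = sim_options(seed = 2, absorption_weighting = "Discrete",
                          track_statistics = TRUE),
    source = source_directional_point(), tissue = slab_1d(n = 1),
    detectors = list(detector_r_of_rho(grid_spec(0, 5, 20)),
                     detector_r_diffuse())
  )
  out <- run_simulation(inp)
  dir <- withr::local_tempdir()
  manifest <- write_outputs(out, dir)
  folder <- file.path(dir, "outtest")
  expect_true(file.exists(file.path(folder, "ROfRho.raw")))
  expect_true(file.exists(file.path(folder, "ROfRho.json")))
  expect_true(file.exists(file.path(folder, "RDiffuse.raw")))
  expect_true(file.exists(file.path(folder, "statistics.txt")))
  expect_identical(nrow(manifest), 5L)

  st <- readLines(file.path(folder, "statistics.txt"))
  expect_match(st[1], "out top")
  expect_match(st[2], "out bottom")
  expect_match(st[3], "specular")
  expect_match(st[4], "Russian Roulette")
  counts <- as.integer(sub(".*: ", "", st))
  expect_identical(counts[1], as.integer(out$statistics$n_out_top))

  # bit-for-bit read-back of the binary detector file
  back <- read_detector_output(folder, "ROfRho")
  expect_identical(back$mean, as.vector(out$tallies$ROfRho$mean))
  expect_identical(back$second_moment,
                   as.vector(out$tallies$ROfRho$second_moment))

  expect_error(write_outputs(out, dir), "overwrite")
  expect_silent(write_outputs(out, dir, overwrite = TRUE))
})

test_that("a random seed request records the seed actually used", {
  inp <- simulation_input(
    n_photons = 50, options = sim_options(seed = -1),
    source = source_directional_point(), tissue = slab_1d(n = 1),
    detectors = list(detector_r_diffuse())
  )
  set.seed(99)
  out <- run_simulation(inp)
  expect_gte(out$seed, 0)
  # replaying with the recorded seed reproduces the run
  inp2 <- inp
  inp2$options$seed <- out$seed
  out2 <- run_simulation(inp2)
  expect_identical(out$tallies$RDiffuse$mean, out2$tallies$RDiffuse$mean)
})
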