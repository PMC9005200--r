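# JSON simulation-input files. Key names mirror the established input
# dialect ("OutputName", "N", "Options", "Seed", "AbsorptionWeightingType",
# ...) so published examples read naturally. Unknown keys are rejected with
# their path; cross-field rules are checked before any photon is launched.

inf_to_json <- function(x) if (is.finite(x)) x else if (x > 0) "Infinity" else "-Infinity"

num_from_json <- function(x, path) {
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("Infinity", "Inf")) return(Inf)
    if (x %in% c("-Infinity", "-Inf")) return(-Inf)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("'%s' must be a number", path))
  }
  as.numeric(x)
}

chk_keys <- function(obj, allowed, required, path) {
  if (!is.list(obj)) abort(sprintf("'%s' must be an object", path))
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown key '%s$%s'", path, unknown[1]))
  }
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    abort(sprintf("missing key '%s$%s'", path, missing[1]))
  }
  invisible(obj)
}

op_to_json <- function(mua, mus, g, n) {
  list(Mua = mua, Mus = mus, G = g, N = n)
}

op_from_json <- function(x, path) {
  chk_keys(x, c("Mua", "Mus", "G", "N"), c("Mua", "Mus", "G", "N"), path)
  lapply(stats::setNames(c("Mua", "Mus", "G", "N"),
                         c("mua", "mus", "g", "n")),
         function(k) num_from_json(x[[k]], paste0(path, "$", k)))
}

xyz_to_json <- function(v) list(X = v[1], Y = v[2], Z = v[3])
xyz_from_json <- function(x, path) {
  chk_keys(x, c("X", "Y", "Z"), c("X", "Y", "Z"), path)
  c(num_from_json(x$X, paste0(path, "$X")),
    num_from_json(x$Y, paste0(path, "$Y")),
    num_from_json(x$Z, paste0(path, "$Z")))
}

range_to_json <- function(v) list(Start = v[1], Stop = v[2])
range_from_json <- function(x, path) {
  chk_keys(x, c("Start", "Stop"), c("Start", "Stop"), path)
  c(num_from_json(x$Start, paste0(path, "$Start")),
    num_from_json(x$Stop, paste0(path, "$Stop")))
}

grid_to_json <- function(g) list(Start = g$start, Stop = g$stop,
                                 Count = g$count)
grid_from_json <- function(x, path) {
  chk_keys(x, c("Start", "Stop", "Count"), c("Start", "Stop", "Count"), path)
  grid_spec(num_from_json(x$Start, paste0(path, "$Start")),
            num_from_json(x$Stop, paste0(path, "$Stop")),
            num_from_json(x$Count, paste0(path, "$Count")))
}

# ---- tissue ----------------------------------------------------------------

tissue_to_list <- function(tissue) {
  lay <- tissue$layers
  regions <- list(list(
    RegionType = "Air",
    ZRange = list(Start = "-Infinity", Stop = 0),
    OP = op_to_json(0, 0, 0, tissue$n_above)
  ))
  for (i in seq_len(nrow(lay))) {
    regions[[i + 1]] <- list(
      RegionType = "Layer",
      ZRange = list(Start = lay$zmin[i], Stop = inf_to_json(lay$zmax[i])),
      OP = op_to_json(lay$mua[i], lay$mus[i], lay$g[i], lay$n[i])
    )
  }
  if (is.finite(lay$zmax[nrow(lay)])) {
    regions[[length(regions) + 1]] <- list(
      RegionType = "Air",
      ZRange = list(Start = lay$zmax[nrow(lay)], Stop = "Infinity"),
      OP = op_to_json(0, 0, 0, tissue$n_below)
    )
  }
  out <- list(
    TissueType = if (is.null(tissue$ellipsoid)) "MultiLayer"
                 else "SingleEllipsoid",
    Regions = regions
  )
  if (!is.null(tissue$ellipsoid)) {
    e <- tissue$ellipsoid
    p <- e$properties
    out$EllipsoidRegion <- list(
      Center = xyz_to_json(e$center),
      Axes = list(A = e$axes[1], B = e$axes[2], C = e$axes[3]),
      OP = op_to_json(p$mua, p$mus, p$g, p$n)
    )
  }
  out
}

tissue_from_list <- function(x, path = "TissueInput") {
  chk_keys(x, c("TissueType", "Regions", "EllipsoidRegion"),
           c("TissueType", "Regions"), path)
  type <- x$TissueType
  if (!type %in% c("MultiLayer", "SingleEllipsoid")) {
    abort(sprintf("'%s$TissueType' must be 'MultiLayer' or 'SingleEllipsoid'",
                  path))
  }
  if (type == "MultiLayer" && !is.null(x$EllipsoidRegion)) {
    abort(sprintf("'%s$EllipsoidRegion' requires TissueType 'SingleEllipsoid'",
                  path))
  }
  if (type == "SingleEllipsoid" && is.null(x$EllipsoidRegion)) {
    abort(sprintf("missing key '%s$EllipsoidRegion'", path))
  }
  regions <- x$Regions
  lays <- list()
  n_above <- 1
  n_below <- 1
  for (i in seq_along(regions)) {
    rp <- sprintf("%s$Regions[[%d]]", path, i)
    r <- regions[[i]]
    chk_keys(r, c("RegionType", "ZRange", "OP"),
             c("RegionType", "ZRange", "OP"), rp)
    zr <- range_from_json(r$ZRange, paste0(rp, "$ZRange"))
    op <- op_from_json(r$OP, paste0(rp, "$OP"))
    if (identical(r$RegionType, "Air")) {
      if (zr[2] <= 0) n_above <- op$n else n_below <- op$n
    } else if (identical(r$RegionType, "Layer")) {
      lays[[length(lays) + 1]] <- tibble(
        zmin = zr[1], zmax = zr[2],
        mua = op$mua, mus = op$mus, g = op$g, n = op$n
      )
    } else {
      abort(sprintf("'%s$RegionType' must be 'Air' or 'Layer'", rp))
    }
  }
  if (!length(lays)) abort(sprintf("'%s' defines no tissue layers", path))
  ell <- NULL
  if (!is.null(x$EllipsoidRegion)) {
    ep <- paste0(path, "$EllipsoidRegion")
    e <- x$EllipsoidRegion
    chk_keys(e, c("Center", "Axes", "OP"), c("Center", "Axes", "OP"), ep)
    chk_keys(e$Axes, c("A", "B", "C"), c("A", "B", "C"), paste0(ep, "$Axes"))
    op <- op_from_json(e$OP, paste0(ep, "$OP"))
    ell <- ellipsoid_region(
      center = xyz_from_json(e$Center, paste0(ep, "$Center")),
      axes = c(num_from_json(e$Axes$A, paste0(ep, "$Axes$A")),
               num_from_json(e$Axes$B, paste0(ep, "$Axes$B")),
               num_from_json(e$Axes$C, paste0(ep, "$Axes$C"))),
      properties = optical_properties(op$mua, op$mus, op$g, op$n)
    )
  }
  tissue_model(dplyr::bind_rows(lays), n_above = n_above, n_below = n_below,
               ellipsoid = ell)
}

# ---- source ----------------------------------------------------------------

source_to_list <- function(src) {
  out <- list(SourceType = src$type,
              TranslationFromOrigin = xyz_to_json(src$position))
  if (src$type == "DirectionalPoint") {
    out$Direction <- list(Ux = src$direction[1], Uy = src$direction[2],
                          Uz = src$direction[3])
  } else if (src$type == "DirectionalCircular") {
    out$Direction <- list(Ux = 0, Uy = 0, Uz = 1)
    out$OuterRadius <- src$outer_radius
    out$InnerRadius <- src$inner_radius
    out$SourceProfile <- if (src$profile == "Gaussian") {
      list(ProfileType = "Gaussian", BeamRadius = src$beam_radius)
    } else {
      list(ProfileType = "Flat")
    }
    out$ThetaConvOrDiv <- src$convergence_angle
  } else if (src$type == "CustomPoint") {
    out$Direction <- list(Ux = src$direction[1], Uy = src$direction[2],
                          Uz = src$direction[3])
    out$PolarAngleEmissionRange <- range_to_json(src$polar_range)
    out$AzimuthalAngleEmissionRange <- range_to_json(src$azimuthal_range)
  }
  out$InitialTissueRegionIndex <- src$initial_region %||% 0L
  out
}

dir_from_json <- function(x, path) {
  chk_keys(x, c("Ux", "Uy", "Uz"), c("Ux", "Uy", "Uz"), path)
  c(num_from_json(x$Ux, paste0(path, "$Ux")),
    num_from_json(x$Uy, paste0(path, "$Uy")),
    num_from_json(x$Uz, paste0(path, "$Uz")))
}

source_from_list <- function(x, path = "Source") {
  if (!is.list(x) || is.null(x$SourceType)) {
    abort(sprintf("'%s$SourceType' is required", path))
  }
  type <- x$SourceType
  common <- c("SourceType", "TranslationFromOrigin",
              "InitialTissueRegionIndex")
  pos_path <- paste0(path, "$TranslationFromOrigin")
  reg <- if (!is.null(x$InitialTissueRegionIndex)) {
    as.integer(x$InitialTissueRegionIndex)
  } else {
    NULL
  }
  if (type == "DirectionalPoint") {
    chk_keys(x, c(common, "Direction"),
             c("SourceType", "TranslationFromOrigin", "Direction"), path)
    source_directional_point(
      position = xyz_from_json(x$TranslationFromOrigin, pos_path),
      direction = dir_from_json(x$Direction, paste0(path, "$Direction")),
      initial_region = reg
    )
  } else if (type == "IsotropicPoint") {
    chk_keys(x, common, c("SourceType", "TranslationFromOrigin"), path)
    source_isotropic_point(
      position = xyz_from_json(x$TranslationFromOrigin, pos_path),
      initial_region = reg
    )
  } else if (type == "DirectionalCircular") {
    chk_keys(x, c(common, "Direction", "OuterRadius", "InnerRadius",
                  "SourceProfile", "ThetaConvOrDiv"),
             c("SourceType", "TranslationFromOrigin", "OuterRadius"), path)
    if (!is.null(x$Direction)) {
      d <- dir_from_json(x$Direction, paste0(path, "$Direction"))
      if (any(abs(d - c(0, 0, 1)) > 1e-12)) {
        abort(sprintf("'%s': DirectionalCircular supports the +z principal axis only",
                      path))
      }
    }
    prof <- x$SourceProfile %||% list(ProfileType = "Flat")
    chk_keys(prof, c("ProfileType", "BeamRadius"), "ProfileType",
             paste0(path, "$SourceProfile"))
    source_directional_circular(
      position = xyz_from_json(x$TranslationFromOrigin, pos_path),
      outer_radius = num_from_json(x$OuterRadius, paste0(path, "$OuterRadius")),
      inner_radius = if (is.null(x$InnerRadius)) 0
                     else num_from_json(x$InnerRadius, paste0(path, "$InnerRadius")),
      profile = prof$ProfileType,
      beam_radius = if (is.null(prof$BeamRadius)) NULL
                    else num_from_json(prof$BeamRadius,
                                       paste0(path, "$SourceProfile$BeamRadius")),
      convergence_angle = if (is.null(x$ThetaConvOrDiv)) 0
                          else num_from_json(x$ThetaConvOrDiv,
                                             paste0(path, "$ThetaConvOrDiv")),
      initial_region = reg
    )
  } else if (type == "CustomPoint") {
    chk_keys(x, c(common, "Direction", "PolarAngleEmissionRange",
                  "AzimuthalAngleEmissionRange"),
             c("SourceType", "TranslationFromOrigin"), path)
    source_custom_point(
      position = xyz_from_json(x$TranslationFromOrigin, pos_path),
      direction = if (is.null(x$Direction)) c(0, 0, 1)
                  else dir_from_json(x$Direction, paste0(path, "$Direction")),
      polar_range = if (is.null(x$PolarAngleEmissionRange)) c(0, pi / 2)
                    else range_from_json(x$PolarAngleEmissionRange,
                                         paste0(path, "$PolarAngleEmissionRange")),
      azimuthal_range = if (is.null(x$AzimuthalAngleEmissionRange)) c(0, 2 * pi)
                        else range_from_json(x$AzimuthalAngleEmissionRange,
                                             paste0(path, "$AzimuthalAngleEmissionRange")),
      initial_region = reg
    )
  } else {
    abort(sprintf("'%s$SourceType' '%s' is not supported", path, type))
  }
}

# ---- detectors -------------------------------------------------------------

detector_to_list <- function(det, tissue) {
  out <- list(TallyType = det$type, Name = det$name)
  for (nm in c("rho", "z", "x", "y", "time")) {
    if (!is.null(det[[nm]])) {
      key <- c(rho = "Rho", z = "Z", x = "X", y = "Y", time = "Time")[[nm]]
      out[[key]] <- grid_to_json(det[[nm]])
    }
  }
  if (!is.null(det$fx)) out$Fx <- det$fx
  if (!is.null(det$omega)) out$Omega <- det$omega
  if (det$type %in% c(.pmc_types, .dmc_types)) {
    tr <- tissue_regions(tissue)
    regs <- if (!is.null(det$perturbation)) det$perturbation$regions
            else det$region
    i <- match(regs, tr$region)
    mua <- tr$mua[i]
    mus <- tr$mus[i]
    if (!is.null(det$perturbation)) {
      if (!is.null(det$perturbation$mua)) mua <- det$perturbation$mua
      if (!is.null(det$perturbation$mus)) mus <- det$perturbation$mus
    }
    out$PerturbedRegionsIndices <- as.list(regs)
    out$PerturbedOps <- purrr::map(seq_along(regs), function(k) {
      op_to_json(mua[k], mus[k], tr$g[i[k]], tr$n[i[k]])
    })
  }
  out$TallySecondMoment <- det$second_moment
  out
}

detector_from_list <- function(x, tissue, path) {
  if (!is.list(x) || is.null(x$TallyType)) {
    abort(sprintf("'%s$TallyType' is required", path))
  }
  type <- x$TallyType
  if (!type %in% .detector_types) {
    abort(sprintf("'%s$TallyType' '%s' is not supported", path, type))
  }
  axes_of <- list(
    RDiffuse = character(), TDiffuse = character(), ATotal = character(),
    ROfRho = "Rho", ROfRhoAndTime = c("Rho", "Time"),
    ROfXAndY = c("X", "Y"), ROfFx = "Fx", ROfRhoAndOmega = c("Rho", "Omega"),
    AOfRhoAndZ = c("Rho", "Z"), FluenceOfRhoAndZ = c("Rho", "Z"),
    pMCROfRho = "Rho", pMCROfFx = "Fx",
    dMCdROfRhoDMua = "Rho", dMCdROfRhoDMus = "Rho"
  )[[type]]
  pmc_keys <- if (type %in% c(.pmc_types, .dmc_types)) {
    c("PerturbedRegionsIndices", "PerturbedOps")
  } else {
    character()
  }
  chk_keys(x, c("TallyType", "Name", "TallySecondMoment", axes_of, pmc_keys),
           c("TallyType", axes_of, pmc_keys), path)
  name <- x$Name %||% type
  sm <- isTRUE(x$TallySecondMoment %||% TRUE)
  gx <- function(key) grid_from_json(x[[key]], paste0(path, "$", key))
  vx <- function(key) {
    v <- unlist(x[[key]])
    if (!is.numeric(v) || !length(v)) {
      abort(sprintf("'%s$%s' must be a non-empty numeric array", path, key))
    }
    as.numeric(v)
  }
  pert <- NULL
  region <- NULL
  if (type %in% c(.pmc_types, .dmc_types)) {
    regs <- as.integer(unlist(x$PerturbedRegionsIndices))
    ops <- purrr::map(seq_along(x$PerturbedOps), function(k) {
      op_from_json(x$PerturbedOps[[k]],
                   sprintf("%s$PerturbedOps[[%d]]", path, k))
    })
    if (length(ops) != length(regs)) {
      abort(sprintf("'%s': PerturbedOps and PerturbedRegionsIndices lengths differ",
                    path))
    }
    tr <- tissue_regions(tissue)
    i <- match(regs, tr$region)
    if (anyNA(i)) abort(sprintf("'%s': unknown perturbed region index", path))
    mua <- vapply(ops, `[[`, numeric(1), "mua")
    mus <- vapply(ops, `[[`, numeric(1), "mus")
    gg <- vapply(ops, `[[`, numeric(1), "g")
    nn <- vapply(ops, `[[`, numeric(1), "n")
    if (any(gg != tr$g[i]) || any(nn != tr$n[i])) {
      abort(sprintf("'%s': perturbing g or n is not supported", path))
    }
    changed <- any(mua != tr$mua[i]) || any(mus != tr$mus[i])
    if (changed) pert <- perturbation(regs, mua = mua, mus = mus)
    region <- regs
    if (type %in% .pmc_types && is.null(pert)) {
      # zero perturbation: identity re-weighting
      pert <- perturbation(regs, mua = mua)
    }
  }
  switch(type,
    RDiffuse = detector_r_diffuse(name, sm),
    TDiffuse = detector_t_diffuse(name, sm),
    ATotal = detector_a_total(name, sm),
    ROfRho = detector_r_of_rho(gx("Rho"), name, sm),
    ROfRhoAndTime = detector_r_of_rho_and_time(gx("Rho"), gx("Time"), name, sm),
    ROfXAndY = detector_r_of_x_and_y(gx("X"), gx("Y"), name, sm),
    ROfFx = detector_r_of_fx(vx("Fx"), name, sm),
    ROfRhoAndOmega = detector_r_of_rho_and_omega(gx("Rho"), vx("Omega"),
                                                 name, sm),
    AOfRhoAndZ = detector_a_of_rho_and_z(gx("Rho"), gx("Z"), name, sm),
    FluenceOfRhoAndZ = detector_fluence_of_rho_and_z(gx("Rho"), gx("Z"),
                                                     name, sm),
    pMCROfRho = detector_pmc_r_of_rho(gx("Rho"), pert, name, sm),
    pMCROfFx = detector_pmc_r_of_fx(vx("Fx"), pert, name, sm),
    dMCdROfRhoDMua = detector_dmc_d_r_of_rho_d_mua(gx("Rho"), region, pert,
                                                   name, sm),
    dMCdROfRhoDMus = detector_dmc_d_r_of_rho_d_mus(gx("Rho"), region, pert,
                                                   name, sm)
  )
}

# ---- options ---------------------------------------------------------------

options_to_list <- function(opt) {
  list(
    Seed = opt$seed,
    RandomNumberGeneratorType = opt$rng_type,
    AbsorptionWeightingType = opt$absorption_weighting,
    PhaseFunctionType = opt$phase_function,
    Databases = as.list(opt$databases),
    TrackStatistics = opt$track_statistics,
    RussianRouletteWeightThreshold = opt$rr_threshold,
    SimulationIndex = opt$simulation_index
  )
}

options_from_list <- function(x, path = "Options") {
  chk_keys(x, c("Seed", "RandomNumberGeneratorType",
                "AbsorptionWeightingType", "PhaseFunctionType", "Databases",
                "TrackStatistics", "RussianRouletteWeightThreshold",
                "SimulationIndex"),
           character(), path)
  aw <- x$AbsorptionWeightingType %||% "Discrete"
  if (!aw %in% c("Analog", "Discrete", "Continuous")) {
    abort(sprintf("'%s$AbsorptionWeightingType' must be Analog, Discrete or Continuous",
                  path))
  }
  pf <- x$PhaseFunctionType %||% "HenyeyGreenstein"
  if (!pf %in% c("HenyeyGreenstein", "Bidirectional")) {
    abort(sprintf("'%s$PhaseFunctionType' must be HenyeyGreenstein or Bidirectional",
                  path))
  }
  sim_options(
    seed = x$Seed %||% 0,
    absorption_weighting = aw,
    phase_function = pf,
    databases = as.character(unlist(x$Databases)),
    track_statistics = isTRUE(x$TrackStatistics),
    rr_threshold = if (is.null(x$RussianRouletteWeightThreshold)) 0
                   else num_from_json(x$RussianRouletteWeightThreshold,
                                      paste0(path, "$RussianRouletteWeightThreshold")),
    simulation_index = x$SimulationIndex %||% 0,
    rng_type = x$RandomNumberGeneratorType %||% "MersenneTwister"
  )
}

# ---- top level -------------------------------------------------------------

#' Parse a JSON simulation-input file
#'
#' Reads and fully validates an infile. Unknown keys are rejected with
#' their path; cross-field constraints (for instance that the pMC database
#' or Russian roulette require discrete or continuous absorption weighting)
#' raise distinct errors before any photon is launched.
#'
#' @param text Path to an infile, or a JSON string.
#' @return A validated [simulation_input()] object.
#' @export
parse_infile <- function(text) {
  json <- if (length(text) == 1L && !grepl("[{\n]", text)) {
    if (!file.exists(text)) abort(sprintf("infile '%s' not found", text))
    paste(readLines(text, warn = FALSE), collapse = "\n")
  } else {
    paste(text, collapse = "\n")
  }
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  chk_keys(x, c("OutputName", "N", "Options", "Source", "TissueInput",
                "DetectorInputs"),
           c("OutputName", "N", "Source", "TissueInput"), "infile")
  tissue <- tissue_from_list(x$TissueInput)
  dets <- purrr::map(seq_along(x$DetectorInputs), function(i) {
    detector_from_list(x$DetectorInputs[[i]], tissue,
                       sprintf("DetectorInputs[[%d]]", i))
  })
  simulation_input(
    output_name = x$OutputName,
    n_photons = num_from_json(x$N, "infile$N"),
    options = options_from_list(x$Options %||% list()),
    source = source_from_list(x$Source),
    tissue = tissue,
    detectors = dets
  )
}

#' Write a simulation input as a JSON infile
#'
#' @param input An [simulation_input()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_infile <- function(input, path) {
  stopifnot(inherits(input, "mc_input"))
  x <- list(
    OutputName = input$output_name,
    N = input$n_photons,
    Options = options_to_list(input$options),
    Source = source_to_list(input$source),
    TissueInput = tissue_to_list(input$tissue),
    DetectorInputs = purrr::map(input$detectors, detector_to_list,
                                tissue = input$tissue)
  )
  x$DetectorInputs <- unname(x$DetectorInputs)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Generate example input files
#'
#' Writes ready-to-run example infiles into `target_dir`, including
#' `infile_one_all_detectors.txt` which exercises every supported detector
#' type. Each written file re-parses without error; calling twice
#' overwrites idempotently.
#'
#' @param target_dir Directory to write into (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
generate_example_infiles <- function(target_dir = ".") {
  dir.create(target_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(target_dir, mode = 2L) != 0L) {
    abort(sprintf("'%s' is not writable", target_dir))
  }
  paths <- character()

  slab <- tissue_model(
    data.frame(thickness = 5, mua = 0.01, mus = 5, g = 0.8, n = 1.4),
    n_above = 1, n_below = 1
  )
  rho <- grid_spec(0, 10, 50)
  zg <- grid_spec(0, 5, 25)
  all_det <- simulation_input(
    output_name = "one_all_detectors",
    n_photons = 10000,
    options = sim_options(seed = 0, absorption_weighting = "Discrete",
                          databases = "pMCDiffuseReflectance",
                          track_statistics = TRUE),
    source = source_directional_point(),
    tissue = slab,
    detectors = list(
      detector_r_diffuse(),
      detector_t_diffuse(),
      detector_r_of_rho(rho),
      detector_r_of_rho_and_time(rho, grid_spec(0, 1, 50)),
      detector_r_of_x_and_y(grid_spec(-5, 5, 20), grid_spec(-5, 5, 20)),
      detector_r_of_fx(seq(0, 0.5, by = 0.05)),
      detector_r_of_rho_and_omega(rho, c(0, 0.5, 1)),
      detector_a_total(),
      detector_a_of_rho_and_z(rho, zg),
      detector_fluence_of_rho_and_z(rho, zg),
      detector_pmc_r_of_rho(rho, perturbation(1, mua = 0.012)),
      detector_pmc_r_of_fx(seq(0, 0.5, by = 0.05),
                           perturbation(1, mua = 0.012)),
      detector_dmc_d_r_of_rho_d_mua(rho, region = 1),
      detector_dmc_d_r_of_rho_d_mus(rho, region = 1)
    )
  )
  p <- file.path(target_dir, "infile_one_all_detectors.txt")
  write_infile(all_det, p)
  paths <- c(paths, p)

  bidir <- simulation_input(
    output_name = "bidirectional_slab",
    n_photons = 10000,
    options = sim_options(seed = 0, absorption_weighting = "Continuous",
                          phase_function = "Bidirectional",
                          track_statistics = TRUE),
    source = source_directional_point(),
    tissue = tissue_model(
      data.frame(thickness = 5, mua = 0.01, mus = 5, g = 0.8, n = 1)
    ),
    detectors = list(detector_r_diffuse(), detector_a_total(),
                     detector_t_diffuse())
  )
  p <- file.path(target_dir, "infile_bidirectional_slab.txt")
  write_infile(bidir, p)
  paths <- c(paths, p)

  two_layer <- simulation_input(
    output_name = "two_layer",
    n_photons = 10000,
    options = sim_options(seed = 0, absorption_weighting = "Discrete",
                          rr_threshold = 1e-4, track_statistics = TRUE),
    source = source_directional_point(),
    tissue = tissue_model(
      data.frame(
        thickness = c(0.1, Inf),
        mua = c(2, 1), mus = c(20, 20), g = c(0.7, 0.9), n = c(1.3, 1.4)
      )
    ),
    detectors = list(detector_r_diffuse(), detector_a_total(),
                     detector_t_diffuse(), detector_r_of_rho(grid_spec(0, 2, 40)))
  )
  p <- file.path(target_dir, "infile_two_layer.txt")
  write_infile(two_layer, p)
  paths <- c(paths, p)

  ellips <- simulation_input(
    output_name = "ellipsoid",
    n_photons = 10000,
    options = sim_options(seed = 0, absorption_weighting = "Continuous"),
    source = source_directional_circular(outer_radius = 0.1,
                                         convergence_angle = pi / 6),
    tissue = tissue_model(
      data.frame(thickness = 10, mua = 0.01, mus = 5, g = 0.8, n = 1.4),
      ellipsoid = ellipsoid_region(
        center = c(0, 0, 3), axes = c(1, 1, 1),
        properties = optical_properties(0.05, 5, 0.8, 1.4)
      )
    ),
    detectors = list(detector_r_diffuse(), detector_r_of_rho(grid_spec(0, 5, 25)))
  )
  p <- file.path(target_dir, "infile_ellipsoid.txt")
  write_infile(ellips, p)
  paths <- c(paths, p)

  invisible(paths)
}
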