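# Photon trajectory databases: exit records (position, direction, weight,
# time of flight) and, for pMC, per-region path lengths and collision
# counts, one-to-one with the exit records. The header records N launched -
# photons that never exit still count in every normalization.

new_database <- function(exits, L, J, n_photons, tissue,
                         absorption_weighting, seed) {
  structure(
    list(
      exits = exits,
      L = L, J = J,
      n_photons = n_photons,
      n_regions = nrow(tissue_regions(tissue)),
      tissue = tissue,
      absorption_weighting = absorption_weighting,
      seed = seed
    ),
    class = "mc_database"
  )
}

#' @export
print.mc_database <- function(x, ...) {
  cat(sprintf(
    "<photon database> %d exit record(s) of N = %g launched, %s weighting%s\n",
    nrow(x$exits), x$n_photons, x$absorption_weighting,
    if (is.null(x$L)) "" else ", with collision info"
  ))
  invisible(x)
}

#' Write / read a photon database
#'
#' The on-disk layout is documented and deliberately simple: little-endian
#' float64 records (`exit.bin`: x, y, ux, uy, uz, weight, time, side per
#' photon; `collision.bin`: per-region path lengths then collision counts),
#' plus a JSON header carrying N launched, the region count, the weighting
#' mode, the seed and the tissue definition.
#'
#' @param db An `mc_database` (from [run_simulation()] with a database
#'   option enabled).
#' @param path Directory to hold `header.json`, `exit.bin` and (for pMC
#'   databases) `collision.bin`.
#' @return `write_photon_database()` returns `path` invisibly;
#'   `read_photon_database()` returns the reconstructed `mc_database`.
#' @export
write_photon_database <- function(db, path) {
  stopifnot(inherits(db, "mc_database"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n_exit <- nrow(db$exits)
  header <- list(
    format = "photonmc-database-1",
    layout = "little-endian float64",
    n_photons = db$n_photons,
    n_exit = n_exit,
    n_regions = db$n_regions,
    has_collision = !is.null(db$L),
    absorption_weighting = db$absorption_weighting,
    seed = db$seed,
    tissue = tissue_to_list(db$tissue)
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "exit.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t(as.matrix(db$exits))), con, size = 8,
           endian = "little")
  if (!is.null(db$L)) {
    con2 <- file(file.path(path, "collision.bin"), "wb")
    on.exit(close(con2), add = TRUE)
    writeBin(as.vector(t(cbind(db$L, db$J))), con2, size = 8,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_photon_database
#' @export
read_photon_database <- function(path) {
  hfile <- file.path(path, "header.json")
  if (!file.exists(hfile)) abort(sprintf("no database header at '%s'", path))
  header <- jsonlite::read_json(hfile, simplifyVector = FALSE)
  n_exit <- as.integer(header$n_exit)
  nreg <- as.integer(header$n_regions)
  efile <- file.path(path, "exit.bin")
  expected <- n_exit * 8L
  vals <- readBin(efile, "double", n = expected + 1L, size = 8,
                  endian = "little")
  if (length(vals) != expected) {
    abort(sprintf("truncated exit database: %d values, expected %d",
                  length(vals), expected))
  }
  m <- matrix(vals, ncol = 8, byrow = TRUE,
              dimnames = list(NULL, c("x", "y", "ux", "uy", "uz", "weight",
                                      "time", "side")))
  exits <- as_tibble(as.data.frame(m))
  L <- J <- NULL
  if (isTRUE(header$has_collision)) {
    cfile <- file.path(path, "collision.bin")
    expc <- n_exit * 2L * nreg
    cv <- readBin(cfile, "double", n = expc + 1L, size = 8,
                  endian = "little")
    if (length(cv) != expc) {
      abort(sprintf("truncated collision database: %d values, expected %d",
                    length(cv), expc))
    }
    cm <- matrix(cv, ncol = 2L * nreg, byrow = TRUE)
    L <- cm[, seq_len(nreg), drop = FALSE]
    J <- cm[, nreg + seq_len(nreg), drop = FALSE]
  }
  new_database(
    exits = exits, L = L, J = J,
    n_photons = as.numeric(header$n_photons),
    tissue = tissue_from_list(header$tissue),
    absorption_weighting = header$absorption_weighting,
    seed = as.integer(header$seed)
  )
}

#' Re-tally detectors from a photon database
#'
#' Recomputes any exit-based (reflectance/transmittance family) detector,
#' and the pMC/dMC variants when collision info is stored, from a saved
#' database: the re-tally is bit-identical to the tally the engine would
#' have produced live in the same run. History detectors (absorbed energy,
#' fluence) need full trajectories and cannot be post-processed.
#'
#' @param db An `mc_database`.
#' @param detectors A detector specification or list of them.
#' @return A named list of tallies.
#' @export
retally <- function(db, detectors) {
  stopifnot(inherits(db, "mc_database"))
  if (inherits(detectors, "mc_detector")) detectors <- list(detectors)
  out <- list()
  for (det in detectors) {
    out[[det$name]] <- retally_one(db, det)
  }
  out
}

retally_one <- function(db, det) {
  if (det$type %in% .exit_types) {
    r <- tally_exit_raw(db$exits, det)
    return(new_tally(det, r$raw, r$m2, db$n_photons))
  }
  if (det$type %in% c(.pmc_types, .dmc_types)) {
    if (is.null(db$L)) {
      abort("pMC/dMC re-tally needs a database with collision info (pMCDiffuseReflectance)")
    }
    w <- if (det$type %in% .pmc_types) {
      db$exits$weight * pmc_weight_factor(db, det$perturbation)
    } else {
      base <- if (is.null(det$perturbation)) 1
              else pmc_weight_factor(db, det$perturbation)
      db$exits$weight * base *
        dmc_score(db, det$type, det$region, det$perturbation)
    }
    r <- tally_exit_raw(db$exits, det, weights = w)
    return(new_tally(det, r$raw, r$m2, db$n_photons))
  }
  abort(sprintf(
    "detector '%s' is history-based and cannot be re-tallied from an exit database",
    det$type
  ))
}
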