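# Detector output files: per detector a little-endian float64 binary
# (mean array in column-major order, then the second-moment array when
# tallied; complex arrays store the real part then the imaginary part)
# plus a JSON sidecar recording grids, units, N and layout.

#' Write simulation outputs
#'
#' Writes one data file and one JSON sidecar per detector into
#' `out_dir/<OutputName>/`, plus `statistics.txt` (photon accounting) when
#' `track_statistics` was enabled.
#'
#' @param output An `mc_output` from [run_simulation()].
#' @param out_dir Parent directory for the result folder.
#' @param overwrite Overwrite an existing result folder.
#' @return A tibble manifest of written files, invisibly.
#' @export
write_outputs <- function(output, out_dir = ".", overwrite = FALSE) {
  stopifnot(inherits(output, "mc_output"))
  folder <- file.path(out_dir, output$input$output_name)
  if (file.exists(file.path(folder, "manifest.json")) && !overwrite) {
    abort(sprintf("'%s' already holds results; use overwrite = TRUE", folder))
  }
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (tal in output$tallies) {
    files <- c(files, write_detector_file(tal, folder))
  }
  if (output$input$options$track_statistics) {
    st <- output$statistics
    lines <- c(
      sprintf("Number of photons out top: %d", as.integer(st$n_out_top)),
      sprintf("Number of photons out bottom: %d",
              as.integer(st$n_out_bottom)),
      sprintf("Number of photons specularly reflected: %d",
              as.integer(st$n_specular)),
      sprintf("Number of photons killed by Russian Roulette: %d",
              as.integer(st$n_killed_rr))
    )
    writeLines(lines, file.path(folder, "statistics.txt"))
    files <- c(files, file.path(folder, "statistics.txt"))
  }
  manifest <- tibble(file = files)
  jsonlite::write_json(list(output_name = output$input$output_name,
                            n_photons = output$input$n_photons,
                            seed = output$seed,
                            files = basename(files)),
                       file.path(folder, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

flatten_numeric <- function(x) {
  if (is.complex(x)) c(as.vector(Re(x)), as.vector(Im(x))) else as.vector(x)
}

write_detector_file <- function(tal, folder) {
  raw_path <- file.path(folder, paste0(tal$name, ".raw"))
  con <- file(raw_path, "wb")
  on.exit(close(con))
  vals <- flatten_numeric(tal$mean)
  if (!is.null(tal$second_moment)) {
    vals <- c(vals, flatten_numeric(tal$second_moment))
  }
  writeBin(vals, con, size = 8, endian = "little")
  axes <- purrr::map(tal$axes, function(a) {
    if (inherits(a, "mc_grid")) grid_to_json(a) else a
  })
  sidecar <- list(
    name = tal$name,
    type = tal$type,
    n_photons = tal$n_photons,
    units = tal$units,
    dim = dim(tal$mean) %||% length(tal$mean),
    complex = is.complex(tal$mean),
    has_second_moment = !is.null(tal$second_moment),
    layout = "little-endian float64, column-major; mean then second moment; complex as Re block then Im block",
    axes = axes
  )
  jsonlite::write_json(sidecar, file.path(folder, paste0(tal$name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(raw_path, file.path(folder, paste0(tal$name, ".json")))
}

#' Read back a written detector file
#'
#' Reconstructs the mean (and second-moment) arrays of a detector from its
#' binary file and JSON sidecar, bit-for-bit.
#'
#' @param folder Result folder written by [write_outputs()].
#' @param name Detector name.
#' @return A list with `mean`, `second_moment` (or `NULL`) and `meta`.
#' @export
read_detector_output <- function(folder, name) {
  meta <- jsonlite::read_json(file.path(folder, paste0(name, ".json")),
                              simplifyVector = TRUE)
  dims <- meta$dim
  n <- prod(dims)
  per_array <- if (isTRUE(meta$complex)) 2L * n else n
  total <- per_array * (1L + as.integer(isTRUE(meta$has_second_moment)))
  vals <- readBin(file.path(folder, paste0(name, ".raw")), "double",
                  n = total + 1L, size = 8, endian = "little")
  if (length(vals) != total) {
    abort(sprintf("truncated detector file '%s'", name))
  }
  unflatten <- function(v) {
    x <- if (isTRUE(meta$complex)) {
      complex(real = v[seq_len(n)], imaginary = v[n + seq_len(n)])
    } else {
      v
    }
    if (length(dims) > 1) dim(x) <- dims
    x
  }
  mean <- unflatten(vals[seq_len(per_array)])
  sm <- if (isTRUE(meta$has_second_moment)) {
    unflatten(vals[per_array + seq_len(per_array)])
  } else {
    NULL
  }
  list(mean = mean, second_moment = sm, meta = meta)
}
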