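# broom-style tidiers: every result type flattens to a tibble.

#' Tidy a detector tally
#'
#' One row per bin with the axis coordinates (bin centers for grids, the
#' listed values for frequency axes), the normalized `mean`, and - when
#' second moments were tallied - the `std_error` of the bin mean.
#' Frequency-domain tallies are complex; their tibble carries `mean` as a
#' complex column plus a real `magnitude`.
#'
#' @param x An `mc_tally`.
#' @param ... Unused.
#' @method tidy mc_tally
#' @export
tidy.mc_tally <- function(x, ...) {
  ax <- x$axes
  coords <- purrr::map(ax, function(a) {
    if (inherits(a, "mc_grid")) a$centers else a
  })
  grid <- if (length(coords)) {
    # expand.grid varies the first factor fastest, matching column-major
    # array flattening
    do.call(expand.grid, c(coords, KEEP.OUT.ATTRS = FALSE))
  } else {
    data.frame(row.names = 1)
  }
  out <- as_tibble(grid)
  out$mean <- as.vector(x$mean)
  if (is.complex(x$mean)) out$magnitude <- Mod(as.vector(x$mean))
  if (!is.null(x$std_error)) {
    out$std_error <- if (is.complex(x$std_error)) {
      sqrt(Re(as.vector(x$std_error))^2 + Im(as.vector(x$std_error))^2)
    } else {
      as.vector(x$std_error)
    }
  }
  out$detector <- x$name
  out
}

#' Tidy a simulation output
#'
#' Stacks the scalar (single-bin) tallies of a run - diffuse reflectance,
#' total absorption, diffuse transmittance and friends - into one tibble.
#' Use `tidy()` on an individual element of `x$tallies` for binned
#' detectors.
#'
#' @param x An `mc_output`.
#' @param ... Unused.
#' @method tidy mc_output
#' @export
tidy.mc_output <- function(x, ...) {
  scalars <- purrr::keep(x$tallies, ~ length(.x$mean) == 1)
  rows <- purrr::map(scalars, function(t) {
    tibble(
      detector = t$name,
      mean = as.numeric(Re(t$mean)),
      std_error = if (is.null(t$std_error)) NA_real_
                  else as.numeric(Re(t$std_error))
    )
  })
  bind_rows(rows)
}

#' Photon accounting summary of a run
#'
#' @param x An `mc_output`.
#' @param ... Unused.
#' @return A one-row tibble: photon counts by fate, the specular weight
#'   fraction, the seed used and the runtime in seconds.
#' @method glance mc_output
#' @export
glance.mc_output <- function(x, ...) {
  st <- x$statistics
  mutate(st,
         specular = st$specular_weight / st$n_photons,
         seed = x$seed,
         runtime = x$runtime)
}

#' Tidy an inverse fit
#'
#' One row per fitted parameter with `estimate` and the starting value;
#' when the truth is known the relative error is included.
#'
#' @param x An `mc_fit`.
#' @param ... Unused.
#' @method tidy mc_fit
#' @export
tidy.mc_fit <- function(x, ...) {
  out <- tibble(
    term = names(x$par),
    estimate = as.numeric(x$par),
    init = as.numeric(x$init)
  )
  if (!is.null(x$truth)) {
    out$truth <- as.numeric(x$truth[out$term])
    out$rel_error <- abs(out$estimate - out$truth) / out$truth
  }
  out
}

#' One-row fit summary
#'
#' @param x An `mc_fit`.
#' @param ... Unused.
#' @method glance mc_fit
#' @export
glance.mc_fit <- function(x, ...) {
  tibble(
    chi2_init = x$chi2_init,
    chi2 = x$chi2,
    iterations = x$iterations,
    converged = x$converged
  )
}
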