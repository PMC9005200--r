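# Tally accumulation and normalization. Exit-side detectors are computed
# from photon exit records by this one code path, whether the records come
# straight from the engine (live run) or from a stored database, so a
# post-processed re-tally is bit-identical to the live tally.

bin_index <- function(values, grid) {
  i <- floor((values - grid$start) / grid$delta) + 1
  pmin(pmax(i, 1), grid$count)
}

bin_sum <- function(values, idx, nbins) {
  out <- numeric(nbins)
  if (length(idx)) {
    s <- rowsum(values, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

bin_sum_complex <- function(values, idx, nbins) {
  bin_sum(Re(values), idx, nbins) + 1i * bin_sum(Im(values), idx, nbins)
}

annulus_area <- function(grid) {
  pi * diff(grid$edges^2)
}

# raw (unnormalized) weight sums and squared-contribution sums for one
# exit detector; `weights` may be pre-multiplied (pMC / dMC reweighting).
tally_exit_raw <- function(records, det, weights = records$weight) {
  type <- sub("^pMC", "", det$type)
  top <- records$side == 0
  w <- weights
  switch(type,
    RDiffuse = {
      list(raw = sum(w[top]), m2 = sum(w[top]^2), dim = 1L)
    },
    TDiffuse = {
      bot <- !top
      list(raw = sum(w[bot]), m2 = sum(w[bot]^2), dim = 1L)
    },
    ROfRho = ,
    dMCdROfRhoDMua = ,
    dMCdROfRhoDMus = {
      rho <- sqrt(records$x[top]^2 + records$y[top]^2)
      idx <- bin_index(rho, det$rho)
      list(raw = bin_sum(w[top], idx, det$rho$count),
           m2 = bin_sum(w[top]^2, idx, det$rho$count),
           dim = det$rho$count)
    },
    ROfRhoAndTime = {
      rho <- sqrt(records$x[top]^2 + records$y[top]^2)
      ir <- bin_index(rho, det$rho)
      it <- bin_index(records$time[top], det$time)
      idx <- (it - 1L) * det$rho$count + ir
      nb <- det$rho$count * det$time$count
      list(raw = array(bin_sum(w[top], idx, nb),
                       dim = c(det$rho$count, det$time$count)),
           m2 = array(bin_sum(w[top]^2, idx, nb),
                      dim = c(det$rho$count, det$time$count)),
           dim = c(det$rho$count, det$time$count))
    },
    ROfXAndY = {
      ix <- bin_index(records$x[top], det$x)
      iy <- bin_index(records$y[top], det$y)
      idx <- (iy - 1L) * det$x$count + ix
      nb <- det$x$count * det$y$count
      list(raw = array(bin_sum(w[top], idx, nb),
                       dim = c(det$x$count, det$y$count)),
           m2 = array(bin_sum(w[top]^2, idx, nb),
                      dim = c(det$x$count, det$y$count)),
           dim = c(det$x$count, det$y$count))
    },
    ROfFx = {
      xt <- records$x[top]
      wt <- w[top]
      raw <- vapply(det$fx, function(f) {
        c0 <- wt * exp(-1i * 2 * pi * f * xt)
        sum(c0)
      }, complex(1))
      m2 <- vapply(det$fx, function(f) {
        c0 <- wt * exp(-1i * 2 * pi * f * xt)
        complex(real = sum(Re(c0)^2), imaginary = sum(Im(c0)^2))
      }, complex(1))
      list(raw = raw, m2 = m2, dim = length(det$fx))
    },
    ROfRhoAndOmega = {
      rho <- sqrt(records$x[top]^2 + records$y[top]^2)
      ir <- bin_index(rho, det$rho)
      tt <- records$time[top]
      wt <- w[top]
      nr <- det$rho$count
      raw <- matrix(0i, nr, length(det$omega))
      m2 <- matrix(0i, nr, length(det$omega))
      for (k in seq_along(det$omega)) {
        c0 <- wt * exp(-1i * 2 * pi * det$omega[k] * tt)
        raw[, k] <- bin_sum_complex(c0, ir, nr)
        m2[, k] <- bin_sum(Re(c0)^2, ir, nr) + 1i * bin_sum(Im(c0)^2, ir, nr)
      }
      list(raw = raw, m2 = m2, dim = c(nr, length(det$omega)))
    },
    abort(sprintf("'%s' is not an exit-based detector", det$type))
  )
}

# per-bin normalization measure
tally_measure <- function(det) {
  switch(det$type,
    RDiffuse = , TDiffuse = , ATotal = , ROfFx = , pMCROfFx = 1,
    ROfRho = , pMCROfRho = , dMCdROfRhoDMua = , dMCdROfRhoDMus =
      annulus_area(det$rho),
    ROfRhoAndTime = outer(annulus_area(det$rho),
                          rep(det$time$delta, det$time$count)),
    ROfXAndY = matrix(det$x$delta * det$y$delta, det$x$count, det$y$count),
    ROfRhoAndOmega = matrix(annulus_area(det$rho), det$rho$count,
                            length(det$omega)),
    AOfRhoAndZ = , FluenceOfRhoAndZ =
      outer(annulus_area(det$rho), rep(det$z$delta, det$z$count)),
    1
  )
}

detector_axes <- function(det) {
  ax <- list()
  for (nm in c("rho", "x", "y", "z", "time")) {
    if (!is.null(det[[nm]])) ax[[nm]] <- det[[nm]]
  }
  for (nm in c("fx", "omega")) {
    if (!is.null(det[[nm]])) ax[[nm]] <- det[[nm]]
  }
  ax
}

new_tally <- function(det, raw, m2, n_photons) {
  measure <- tally_measure(det)
  mean <- raw / n_photons / measure
  second_moment <- if (det$second_moment) m2 / n_photons else NULL
  std_error <- if (det$second_moment) {
    mean_raw <- raw / n_photons
    if (is.complex(raw)) {
      se_re <- sqrt(pmax(Re(second_moment) - Re(mean_raw)^2, 0) / n_photons)
      se_im <- sqrt(pmax(Im(second_moment) - Im(mean_raw)^2, 0) / n_photons)
      (se_re + 1i * se_im) / measure
    } else {
      sqrt(pmax(second_moment - mean_raw^2, 0) / n_photons) / measure
    }
  } else {
    NULL
  }
  structure(
    list(
      name = det$name,
      type = det$type,
      mean = mean,
      second_moment = second_moment,
      std_error = std_error,
      raw = raw,
      raw_m2 = m2,
      n_photons = n_photons,
      axes = detector_axes(det),
      units = detector_units(det$type),
      measure = measure
    ),
    class = "mc_tally"
  )
}

#' @export
print.mc_tally <- function(x, ...) {
  cat(sprintf("<tally %s> type %s, N = %g photons, units: %s\n",
              x$name, x$type, x$n_photons, x$units))
  if (length(x$mean) == 1) {
    cat(sprintf("  mean %.6g", as.numeric(Re(x$mean))))
    if (!is.null(x$std_error)) cat(sprintf(" +/- %.3g", Re(x$std_error)))
    cat("\n")
  } else {
    cat(sprintf("  %s bins\n", paste(dim(x$mean) %||% length(x$mean),
                                     collapse = " x ")))
  }
  invisible(x)
}

#' Normalize tally moments
#'
#' Turns raw accumulator sums into the reported mean, second moment and
#' standard error: `mean = raw / (N * measure)`,
#' `second_moment = raw_m2 / N` (per-photon contributions squared, on the
#' unnormalized scale), and
#' `std_error = sqrt((second_moment - (raw/N)^2) / N) / measure`.
#'
#' @param raw Sum of per-photon contributions.
#' @param raw_m2 Sum of squared per-photon contributions.
#' @param n_photons Number of photons launched (not detected).
#' @param measure Bin measure (area, area x time, ...) dividing the mean.
#' @return A tibble with `mean`, `second_moment` and `std_error`.
#' @examples
#' # four photons contributing {1, 0, 0, 1}
#' finalize_tally(raw = 2, raw_m2 = 2, n_photons = 4)
#' @export
finalize_tally <- function(raw, raw_m2, n_photons, measure = 1) {
  mean_raw <- raw / n_photons
  m2 <- raw_m2 / n_photons
  tibble(
    mean = as.vector(mean_raw / measure),
    second_moment = as.vector(m2),
    std_error = as.vector(sqrt(pmax(m2 - mean_raw^2, 0) / n_photons) / measure)
  )
}

#' Relative error and computational efficiency
#'
#' The relative error of a tally is `R = sigma / mean` and the figure of
#' merit comparing estimators is the efficiency `Eff = 1 / (R^2 * T)` where
#' `T` is the run time in seconds: halving the error at fixed cost
#' quadruples the efficiency.
#'
#' @param tally A scalar `mc_tally` (or one with a single bin).
#' @param runtime Run time T in seconds.
#' @return A tibble with `relative_error`, `runtime` and `efficiency`
#'   (`NA` when the mean is zero).
#' @export
efficiency <- function(tally, runtime) {
  stopifnot(inherits(tally, "mc_tally"))
  if (is.null(tally$std_error)) {
    abort("efficiency needs a tally with second moments enabled")
  }
  mean_raw <- Re(tally$raw[1]) / tally$n_photons
  se_raw <- Re(tally$std_error[1]) * tally$measure[1]
  if (mean_raw == 0) {
    return(tibble(relative_error = NA_real_, runtime = runtime,
                  efficiency = NA_real_))
  }
  R <- se_raw / mean_raw
  tibble(relative_error = R, runtime = runtime,
         efficiency = 1 / (R^2 * runtime))
}
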