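#' Optical properties of a tissue region
#'
#' Bundles the absorption coefficient `mua` (1/mm), scattering coefficient
#' `mus` (1/mm), scattering anisotropy `g` (mean cosine of the deflection
#' angle, dimensionless) and refractive index `n` of a homogeneous region.
#' The total attenuation coefficient `mut = mua + mus` and the reduced
#' scattering coefficient `musp = mus * (1 - g)` are derived.
#'
#' @param mua Absorption coefficient, 1/mm, >= 0.
#' @param mus Scattering coefficient, 1/mm, >= 0.
#' @param g Anisotropy, in \[-1, 1\].
#' @param n Refractive index, >= 1.
#' @return An object of class `mc_ops`.
#' @examples
#' optical_properties(mua = 0.01, mus = 5, g = 0.8, n = 1.4)
#' @export
optical_properties <- function(mua, mus, g, n) {
  if (!is.numeric(mua) || length(mua) != 1L || is.na(mua) || mua < 0) {
    abort("`mua` must be a single non-negative number (1/mm)")
  }
  if (!is.numeric(mus) || length(mus) != 1L || is.na(mus) || mus < 0) {
    abort("`mus` must be a single non-negative number (1/mm)")
  }
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < -1 || g > 1) {
    abort("`g` must be a single number in [-1, 1]")
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a single number >= 1")
  }
  structure(
    list(mua = mua, mus = mus, g = g, n = n),
    class = "mc_ops"
  )
}

#' @export
print.mc_ops <- function(x, ...) {
  cat(sprintf(
    "<optical properties> mua = %g /mm, mus = %g /mm, g = %g, n = %g (mut = %g, musp = %g)\n",
    x$mua, x$mus, x$g, x$n, x$mua + x$mus, x$mus * (1 - x$g)
  ))
  invisible(x)
}

#' @method as_tibble mc_ops
#' @export
as_tibble.mc_ops <- function(x, ...) {
  tibble(
    mua = x$mua, mus = x$mus, g = x$g, n = x$n,
    mut = x$mua + x$mus, musp = x$mus * (1 - x$g)
  )
}
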