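#' Optical-property perturbation
#'
#' Describes perturbed absorption and/or scattering coefficients for a set
#' of tissue regions, relative to the baseline the database was generated
#' with. Anisotropy and refractive index cannot be perturbed.
#'
#' @param regions Integer region indices (1..L layers, L+2 inclusion).
#' @param mua,mus Perturbed coefficients (1/mm), recycled to
#'   `length(regions)`; `NULL` leaves the baseline value.
#' @return An object of class `mc_perturbation`.
#' @examples
#' perturbation(regions = 1, mua = 0.012)  # +20% absorption in layer 1
#' @export
perturbation <- function(regions, mua = NULL, mus = NULL) {
  regions <- as.integer(regions)
  if (!length(regions) || anyNA(regions)) {
    abort("`regions` must name at least one tissue region")
  }
  if (is.null(mua) && is.null(mus)) {
    abort("give at least one of `mua`, `mus`")
  }
  if (!is.null(mua)) {
    mua <- rep_len(as.numeric(mua), length(regions))
    if (any(mua < 0)) abort("perturbed `mua` must be >= 0")
  }
  if (!is.null(mus)) {
    mus <- rep_len(as.numeric(mus), length(regions))
    if (any(mus < 0)) abort("perturbed `mus` must be >= 0")
  }
  structure(list(regions = regions, mua = mua, mus = mus),
            class = "mc_perturbation")
}

check_perturbation <- function(pert, tissue) {
  stopifnot(inherits(pert, "mc_perturbation"))
  tr <- tissue_regions(tissue)
  valid <- tr$region[!tr$kind %in% c("air_above", "air_below")]
  if (!all(pert$regions %in% valid)) {
    abort("perturbed regions must be tissue regions of the baseline tissue")
  }
  invisible(pert)
}

# baseline/perturbed coefficient table for the listed regions
pert_table <- function(db, pert) {
  check_perturbation(pert, db$tissue)
  tr <- tissue_regions(db$tissue)
  i <- match(pert$regions, tr$region)
  tibble(
    region = pert$regions,
    col = i,  # column in the collision matrices (region index + 1)
    mua0 = tr$mua[i], mus0 = tr$mus[i],
    mua1 = pert$mua %||% tr$mua[i],
    mus1 = pert$mus %||% tr$mus[i]
  )
}

#' Perturbation Monte Carlo weight factor
#'
#' The likelihood ratio (Radon-Nikodym derivative) that re-weights each
#' stored photon history for perturbed optical properties:
#' \deqn{\prod_r (\mu_s^*/\mu_s)^{j_r} \exp(-(\mu_t^* - \mu_t) L_r)}
#' over the perturbed regions, with `j_r` collisions and path length `L_r`
#' in region r. For a continuous-weighting database with a mua-only change
#' this reduces to the Beer's-law factor `exp(-dmua * L_r)`.
#'
#' @param db An `mc_database` with collision info.
#' @param pert A [perturbation()].
#' @return One multiplier per stored photon.
#' @export
pmc_weight_factor <- function(db, pert) {
  stopifnot(inherits(db, "mc_database"))
  if (is.null(db$L)) abort("the database carries no collision info")
  pt <- pert_table(db, pert)
  f <- rep(1, nrow(db$exits))
  for (i in seq_len(nrow(pt))) {
    L <- db$L[, pt$col[i]]
    J <- db$J[, pt$col[i]]
    dmut <- (pt$mua1[i] + pt$mus1[i]) - (pt$mua0[i] + pt$mus0[i])
    if (pt$mus1[i] != pt$mus0[i]) {
      if (pt$mus0[i] == 0 && any(J > 0)) {
        abort("cannot perturb mus in a region with baseline mus = 0 and recorded collisions")
      }
      f <- f * (pt$mus1[i] / pt$mus0[i])^J * exp(-dmut * L)
    } else {
      f <- f * exp(-dmut * L)
    }
  }
  f
}

# per-photon derivative score of the pMC multiplier:
# d/dmua_r -> -L_r ; d/dmus_r -> j_r/mus_r - L_r (evaluated at the
# perturbed coefficients when a perturbation is supplied)
dmc_score <- function(db, type, region, pert = NULL) {
  tr <- tissue_regions(db$tissue)
  s <- rep(0, nrow(db$exits))
  for (r in region) {
    col <- match(r, tr$region)
    if (is.na(col)) abort("unknown dMC region index")
    L <- db$L[, col]
    J <- db$J[, col]
    if (type == "dMCdROfRhoDMua") {
      s <- s - L
    } else {
      mus_at <- tr$mus[col]
      if (!is.null(pert) && r %in% pert$regions && !is.null(pert$mus)) {
        mus_at <- pert$mus[match(r, pert$regions)]
      }
      if (mus_at == 0) abort("dMC mus derivative undefined at mus = 0")
      s <- s + (J / mus_at - L)
    }
  }
  s
}
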