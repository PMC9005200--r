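#' Layered tissue model with optional ellipsoidal inclusion
#'
#' A tissue is an ordered stack of plane-parallel layers bounded in depth z
#' (z = 0 is the tissue surface, z grows into the tissue), with
#' non-scattering air above and below, and optionally a single ellipsoidal
#' inclusion strictly interior to one layer. Region indices follow the
#' convention: 0 = air above, 1..L = layers top-down, L+1 = air below,
#' L+2 = inclusion (when present).
#'
#' @param layers A data frame with one row per layer and columns `mua`,
#'   `mus`, `g`, `n` plus either `thickness` (mm; `Inf` allowed for the last,
#'   semi-infinite layer) or explicit `zmin`/`zmax` bounds.
#' @param n_above,n_below Refractive index of the air half-spaces.
#' @param ellipsoid Optional inclusion created by [ellipsoid_region()].
#' @return An object of class `mc_tissue`.
#' @examples
#' two_layer <- tissue_model(data.frame(
#'   thickness = c(0.1, Inf),
#'   mua = c(2, 1), mus = c(20, 20), g = c(0.7, 0.9), n = c(1.3, 1.4)
#' ))
#' @export
tissue_model <- function(layers, n_above = 1, n_below = 1, ellipsoid = NULL) {
  layers <- as_tibble(layers)
  need <- c("mua", "mus", "g", "n")
  if (!all(need %in% names(layers))) {
    abort("`layers` needs columns mua, mus, g, n")
  }
  if (!all(c("zmin", "zmax") %in% names(layers))) {
    if (!"thickness" %in% names(layers)) {
      abort("`layers` needs either `thickness` or `zmin`/`zmax` columns")
    }
    th <- layers$thickness
    if (any(th <= 0)) abort("layer thicknesses must be positive")
    if (any(!is.finite(th[-length(th)]))) {
      abort("only the last layer may be semi-infinite")
    }
    zmax <- cumsum(th)
    layers$zmin <- c(0, zmax[-length(zmax)])
    layers$zmax <- zmax
  }
  if (layers$zmin[1] != 0) abort("the first layer must start at z = 0")
  if (nrow(layers) > 1 &&
      any(abs(layers$zmin[-1] - layers$zmax[-nrow(layers)]) > 1e-12)) {
    abort("layers must tile depth with no gaps or overlaps")
  }
  if (any(layers$zmin >= layers$zmax)) abort("each layer needs zmin < zmax")
  if (any(layers$mua < 0) || any(layers$mus < 0)) {
    abort("mua and mus must be non-negative")
  }
  if (!is.null(ellipsoid)) {
    if (!inherits(ellipsoid, "mc_ellipsoid")) {
      abort("`ellipsoid` must be created by ellipsoid_region()")
    }
    zc <- ellipsoid$center[3]
    c_ax <- ellipsoid$axes[3]
    host <- which(layers$zmin < zc - c_ax & zc + c_ax < layers$zmax)
    if (length(host) != 1L) {
      abort("the ellipsoid must lie strictly inside a single layer")
    }
  }
  structure(
    list(
      layers = layers[, c("zmin", "zmax", "mua", "mus", "g", "n")],
      n_above = n_above,
      n_below = n_below,
      ellipsoid = ellipsoid
    ),
    class = "mc_tissue"
  )
}

#' Ellipsoidal inclusion
#'
#' Defines an ellipsoidal heterogeneity by its center, semi-axes and optical
#' properties. Membership is the quadratic test
#' `sum(((p - center) / axes)^2) < 1`; ray-surface distances use the exact
#' quadratic roots, so curved surfaces carry no voxelization error.
#'
#' @param center Numeric length-3 center (x, y, z) in mm.
#' @param axes Numeric length-3 semi-axes (a, b, c) in mm, all > 0.
#' @param properties An [optical_properties()] object.
#' @export
ellipsoid_region <- function(center, axes, properties) {
  center <- as.numeric(center)
  axes <- as.numeric(axes)
  if (length(center) != 3L || anyNA(center)) abort("`center` must be (x, y, z)")
  if (length(axes) != 3L || any(axes <= 0)) {
    abort("`axes` must be three positive semi-axes (a, b, c)")
  }
  if (!inherits(properties, "mc_ops")) {
    abort("`properties` must be created by optical_properties()")
  }
  structure(
    list(center = center, axes = axes, properties = properties),
    class = "mc_ellipsoid"
  )
}

#' @export
print.mc_tissue <- function(x, ...) {
  cat(sprintf(
    "<tissue model> %d layer(s), air n = %g above / %g below%s\n",
    nrow(x$layers), x$n_above, x$n_below,
    if (is.null(x$ellipsoid)) "" else ", 1 ellipsoidal inclusion"
  ))
  print(x$layers)
  invisible(x)
}

#' Region table of a tissue model
#'
#' One row per region in index order (0 = air above, 1..L layers, L+1 air
#' below, then the inclusion if present).
#'
#' @param tissue An `mc_tissue`.
#' @return A tibble with columns `region`, `kind`, `mua`, `mus`, `g`, `n`.
#' @export
tissue_regions <- function(tissue) {
  stopifnot(inherits(tissue, "mc_tissue"))
  L <- nrow(tissue$layers)
  out <- tibble(
    region = c(0L, seq_len(L), L + 1L),
    kind = c("air_above", rep("layer", L), "air_below"),
    mua = c(0, tissue$layers$mua, 0),
    mus = c(0, tissue$layers$mus, 0),
    g = c(0, tissue$layers$g, 0),
    n = c(tissue$n_above, tissue$layers$n, tissue$n_below)
  )
  if (!is.null(tissue$ellipsoid)) {
    e <- tissue$ellipsoid$properties
    out <- bind_rows(out, tibble(
      region = L + 2L, kind = "inclusion",
      mua = e$mua, mus = e$mus, g = e$g, n = e$n
    ))
  }
  out
}

# engine-facing representation
tissue_cfg <- function(tissue) {
  lay <- tissue$layers
  cfg <- list(
    layers = cbind(lay$zmin, lay$zmax, lay$mua, lay$mus, lay$g, lay$n),
    n_above = tissue$n_above,
    n_below = tissue$n_below,
    ellipsoid = NULL
  )
  if (!is.null(tissue$ellipsoid)) {
    e <- tissue$ellipsoid
    p <- e$properties
    cfg$ellipsoid <- c(e$center, e$axes, p$mua, p$mus, p$g, p$n)
  }
  cfg
}

#' Region index at a point
#'
#' Looks up which region contains each point. The inclusion test evaluates
#' the quadratic `Q(p) = sum(((p - c) / axes)^2) < 1`. Points lying exactly
#' on a boundary plane resolve to the region below it (half-open layers);
#' transport code passes positions nudged off surfaces, so boundary points
#' never arise there.
#'
#' @param tissue An `mc_tissue`.
#' @param points A length-3 vector or an n-by-3 matrix / data frame of
#'   (x, y, z) positions in mm.
#' @return An integer vector of region indices (0-based, see [tissue_model]).
#' @export
region_index_at <- function(tissue, points) {
  stopifnot(inherits(tissue, "mc_tissue"))
  pts <- rbind_points(points)
  region_index_cpp(pts, tissue_cfg(tissue))
}

#' Distance to the nearest boundary along a ray
#'
#' Smallest positive travel distance from `position` along unit vector
#' `direction` to any bounding surface of the containing region (layer
#' planes, and the ellipsoid surface via the exact quadratic roots). `Inf`
#' means no surface lies ahead (only possible heading down in a
#' semi-infinite bottom layer).
#'
#' @param tissue An `mc_tissue`.
#' @param position Length-3 position (mm).
#' @param direction Length-3 unit direction.
#' @param region Optional region index; computed from `position` if omitted.
#' @return A tibble with `distance` (mm), `far_region` (index beyond the
#'   surface) and `surface` (`"plane_up"`, `"plane_down"` or `"ellipsoid"`).
#' @export
distance_to_boundary <- function(tissue, position, direction, region = NULL) {
  stopifnot(inherits(tissue, "mc_tissue"))
  position <- as.numeric(position)
  direction <- as.numeric(direction)
  if (abs(sum(direction^2) - 1) > 1e-9) {
    abort("`direction` must be a unit vector")
  }
  if (is.null(region)) region <- region_index_at(tissue, position)
  L <- nrow(tissue$layers)
  if (region == 0L || region == L + 1L) {
    abort("photon must not be in air")
  }
  h <- distance_to_boundary_cpp(position, direction, region,
                                tissue_cfg(tissue))
  tibble(
    distance = h$distance,
    far_region = if (h$far_region < 0) NA_integer_
                 else as.integer(h$far_region),
    surface = if (h$surface < 0) NA_character_
              else c("plane_up", "plane_down", "ellipsoid")[h$surface + 1L]
  )
}

rbind_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) abort("points must have 3 columns (x, y, z)")
  points
}

# optical properties of a region by index
region_ops <- function(tissue, region) {
  tr <- tissue_regions(tissue)
  row <- tr[match(region, tr$region), ]
  if (anyNA(row$region)) abort("unknown region index")
  row
}
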