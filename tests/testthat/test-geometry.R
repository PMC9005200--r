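test_that("region lookup follows the air/layer/inclusion convention", {
  t5 <- two_layer_tissue()
  expect_identical(region_index_at(t5, c(0, 0, -0.1)), 0L)
  expect_identical(region_index_at(t5, c(0, 0, 0.05)), 1L)
  expect_identical(region_index_at(t5, c(0, 0, 0.2)), 2L)

  sph <- tissue_model(
    data.frame(thickness = 10, mua = 0.01, mus = 5, g = 0.8, n = 1.4),
    ellipsoid = ellipsoid_region(c(0, 0, 3), c(1, 1, 1),
                                 optical_properties(0.05, 5, 0.8, 1.4))
  )
  # Q((0,0,3)) = 0 < 1 -> inclusion (index L+2 = 3); Q((0,0,4.5)) = 2.25 > 1
  expect_identical(region_index_at(sph, c(0, 0, 3)), 3L)
  expect_identical(region_index_at(sph, c(0, 0, 4.5)), 1L)
  expect_identical(region_index_at(sph, rbind(c(0, 0, 3), c(0, 0, 4.5),
                                              c(0, 0, 11))),
                   c(3L, 1L, 2L))
})

test_that("ray-boundary distances match slab planes and quadratic roots", {
  slab <- slab_1d(n = 1.4)
  h <- distance_to_boundary(slab, c(0, 0, 1e-9), c(0, 0, 1))
  expect_equal(h$distance, 5, tolerance = 1e-8)
  expect_identical(h$far_region, 2L)  # air below
  expect_identical(h$surface, "plane_down")

  sph <- tissue_model(
    data.frame(thickness = 10, mua = 0.01, mus = 5, g = 0.8, n = 1.4),
    ellipsoid = ellipsoid_region(c(0, 0, 3), c(1, 1, 1),
                                 optical_properties(0.05, 5, 0.8, 1.4))
  )
  # entering the unit sphere centered 3 mm deep from just under the surface
  entry <- distance_to_boundary(sph, c(0, 0, 1e-12), c(0, 0, 1))
  expect_equal(entry$distance, 2, tolerance = 1e-9)
  expect_identical(entry$far_region, 3L)
  expect_identical(entry$surface, "ellipsoid")
  # leaving it from the center: one radius
  exit <- distance_to_boundary(sph, c(0, 0, 3), c(0, 0, 1))
  expect_equal(exit$distance, 1, tolerance = 1e-12)
  expect_identical(exit$far_region, 1L)

  expect_error(distance_to_boundary(slab, c(0, 0, 1), c(0, 0, 2)), "unit")
  expect_error(distance_to_boundary(slab, c(0, 0, -1), c(0, 0, 1)), "air")
})

test_that("semi-infinite bottom layer heading down has no surface ahead", {
  t5 <- two_layer_tissue()
  h <- distance_to_boundary(t5, c(0, 0, 5), c(0, 0, 1))
  expect_identical(h$distance, Inf)
})

test_that("stepping past a crossing lands in the descriptor's far region", {
  sph <- tissue_model(
    data.frame(thickness = c(2, 8), mua = c(0.01, 0.02), mus = c(5, 5),
               g = c(0.8, 0.8), n = c(1.4, 1.4)),
    ellipsoid = ellipsoid_region(c(0.2, -0.3, 5), c(1, 0.7, 1.5),
                                 optical_properties(0.05, 5, 0.8, 1.4))
  )
  set.seed(101)
  checked <- 0
  for (i in 1:200) {
    p <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, 1e-3, 9.99))
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2))
    reg <- region_index_at(sph, p)
    if (reg %in% c(0L, 3L)) next  # skip air (regions 0 and 3 of this stack)
    h <- distance_to_boundary(sph, p, d, region = reg)
    if (!is.finite(h$distance)) next
    landed <- region_index_at(sph, p + d * (h$distance + 1e-9))
    expect_identical(landed, h$far_region)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("ray-ellipsoid distances agree with a dense ray-marching oracle", {
  ell <- list(center = c(0.1, -0.2, 4), axes = c(1.2, 0.8, 1.5))
  tis <- tissue_model(
    data.frame(thickness = 10, mua = 0.01, mus = 5, g = 0.8, n = 1.4),
    ellipsoid = ellipsoid_region(ell$center, ell$axes,
                                 optical_properties(0.05, 5, 0.8, 1.4))
  )
  qfun <- function(p) sum(((p - ell$center) / ell$axes)^2)
  set.seed(7)
  tested <- 0
  for (i in 1:100) {
    p <- c(runif(1, -3, 3), runif(1, -3, 3), runif(1, 0.5, 9.5))
    # aim at a random interior point so most rays strike the surface
    target <- ell$center + runif(3, -0.5, 0.5) * ell$axes
    d <- target - p
    d <- d / sqrt(sum(d^2))
    reg <- region_index_at(tis, p)
    h <- distance_to_boundary(tis, p, d, region = reg)
    if (!is.finite(h$distance) || h$surface != "ellipsoid") next
    # march in 1e-4 steps until the inside/outside state flips
    ts <- seq(0, h$distance + 5e-3, by = 1e-4)
    inside0 <- qfun(p) < 1
    qs <- vapply(ts, function(t) qfun(p + t * d) < 1, logical(1))
    flip <- which(qs != inside0)[1]
    expect_false(is.na(flip))
    expect_lt(abs(ts[flip] - h$distance), 1e-3)
    tested <- tested + 1
  }
  expect_gt(tested, 20)
})

test_that("degenerate tissue definitions are rejected", {
  expect_error(tissue_model(data.frame(thickness = c(Inf, 1), mua = 0.1,
                                       mus = 1, g = 0, n = 1)),
               "semi-infinite")
  expect_error(
    tissue_model(
      data.frame(thickness = 2, mua = 0.1, mus = 1, g = 0, n = 1),
      ellipsoid = ellipsoid_region(c(0, 0, 1), c(1, 1, 1.5),
                                   optical_properties(0.1, 1, 0, 1))
    ),
    "strictly inside"
  )
})
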