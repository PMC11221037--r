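test_that("water tank construction follows the rounding rule and uniform fill", {
  g <- make_water_tank(c(300, 300, 300), c(5, 5, 5))
  expect_identical(g$dims, c(60L, 60L, 60L))
  expect_true(all(g$density == 1.0))
  expect_identical(make_water_tank(c(10, 10, 10), 1)$dims, c(10L, 10L, 10L))
  expect_identical(make_water_tank(c(10, 10, 10), 3)$dims, c(3L, 3L, 3L))
  expect_error(make_water_tank(c(-1, 10, 10), 1), "positive")
  expect_error(make_water_tank(c(10, 10, 10), 0), "positive")
})

test_that("slab phantom places layers on snapped voxel planes", {
  layers <- data.frame(thickness = c(50, 80, 170), density = c(1, 0.26, 1),
                       material = c("water", "lung", "water"))
  g <- make_slab_phantom(c(300, 300, 300), 5, layers)
  prof <- g$density[1, 1, ]
  expect_equal(prof, c(rep(1, 10), rep(0.26, 16), rep(1, 34)))

  # single water layer degenerates to the water tank
  g1 <- make_slab_phantom(c(100, 100, 100), 5,
                          data.frame(thickness = 100, density = 1,
                                     material = "water"))
  expect_equal(g1$density, make_water_tank(c(100, 100, 100), 5)$density)

  # zero-thickness layers are dropped without error
  g2 <- make_slab_phantom(c(100, 100, 100), 5,
                          data.frame(thickness = c(50, 0, 50),
                                     density = c(1, 0.5, 1),
                                     material = c("water", "lung", "water")))
  expect_true(all(g2$density == 1))

  expect_error(make_slab_phantom(c(100, 100, 100), 5,
                                 data.frame(thickness = 60, density = 1,
                                            material = "water")),
               "sum to the axial extent")
})

test_that("slab phantom conserves mass to one voxel-snapping quantum", {
  layers <- data.frame(thickness = c(48, 77, 175), density = c(1, 0.26, 1.85),
                       material = c("water", "lung", "bone"))
  g <- make_slab_phantom(c(100, 100, 300), 4, layers)
  vox_vol <- prod(g$spacing) / 1000            # cm^3
  mass <- sum(g$density) * vox_vol             # g
  analytic <- sum(layers$thickness / 10 * layers$density) * 100  # g (per cm^2 * area)
  quantum <- max(layers$density) * 0.4 * 100   # one 4 mm plane of the column
  expect_lt(abs(mass - analytic), quantum)
})

test_that("radiological path matches closed forms and a supersampling oracle", {
  g <- make_water_tank(c(300, 300, 300), 5)
  expect_equal(radiological_path(g, c(0, 0, 10), c(0, 0, 110)), 100,
               tolerance = 1e-9)
  expect_equal(radiological_path(g, c(0, 0, 50), c(0, 0, 50)), 0)
  # fully outside
  expect_equal(radiological_path(g, c(500, 500, 0), c(500, 500, 100)), 0)

  # 20 + 0.26 * 80 through a lung slab
  sl <- make_slab_phantom(c(300, 300, 300), 5,
                          data.frame(thickness = c(20, 80, 200),
                                     density = c(1, 0.26, 1),
                                     material = c("water", "lung", "water")))
  expect_equal(radiological_path(sl, c(0, 0, 0), c(0, 0, 100)),
               20 + 0.26 * 80, tolerance = 1e-9)

  # random segments vs dense supersampling
  set.seed(11)
  dens <- array(runif(8 * 8 * 8, 0.1, 2), c(8, 8, 8))
  gr <- voxel_grid(dens, origin = c(0, 0, 0), spacing = c(7, 9, 11))
  lo <- gr$origin - gr$spacing / 2
  hi <- gr$origin + (gr$dims - 0.5) * gr$spacing
  supersample <- function(p0, p1, n = 1e4) {
    t <- (seq_len(n) - 0.5) / n
    pts <- outer(t, p1 - p0) + rep(p0, each = n)
    idx <- sapply(1:3, function(a)
      pmin(pmax(floor((pts[, a] - lo[a]) / gr$spacing[a]) + 1, 1), gr$dims[a]))
    inside <- pts[, 1] >= lo[1] & pts[, 1] < hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] < hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] < hi[3]
    rho <- dens[idx] * inside
    sum(rho) * sqrt(sum((p1 - p0)^2)) / n
  }
  for (i in 1:50) {
    p0 <- runif(3, -30, 110)
    p1 <- runif(3, -30, 110)
    a <- radiological_path(gr, p0, p1)
    b <- supersample(p0, p1)
    expect_lt(abs(a - b), 0.005 * max(b, 1))
  }
})

test_that("radiological path is additive over splits and symmetric", {
  set.seed(12)
  sl <- make_slab_phantom(c(200, 200, 200), 5,
                          data.frame(thickness = c(60, 60, 80),
                                     density = c(1, 0.3, 1.8),
                                     material = c("water", "lung", "bone")))
  for (i in 1:20) {
    p0 <- runif(3, -50, 250); p1 <- runif(3, -50, 250)
    lam <- runif(1)
    pm <- p0 + lam * (p1 - p0)
    full <- radiological_path(sl, p0, p1)
    expect_equal(radiological_path(sl, p0, pm) + radiological_path(sl, pm, p1),
                 full, tolerance = 1e-8)
    expect_equal(radiological_path(sl, p1, p0), full, tolerance = 1e-10)
  }
})

test_that("voxel grid and mask validation catches bad inputs", {
  expect_error(voxel_grid(array(-1, c(2, 2, 2)), origin = c(0, 0, 0),
                          spacing = c(1, 1, 1)), "non-negative")
  expect_error(voxel_grid(array(1, c(2, 2, 2)), origin = c(0, 0, 0),
                          spacing = c(0, 1, 1)), "positive")
  expect_error(voxel_grid(array(1, c(2, 2, 2)),
                          material = array(9L, c(2, 2, 2)),
                          origin = c(0, 0, 0), spacing = c(1, 1, 1)),
               "catalog")
  g <- make_water_tank(c(20, 20, 20), 5)
  expect_error(structure_mask(g, array(TRUE, c(2, 2, 2))), "match")
  m <- sphere_mask(g, c(0, 0, 10), 6)
  expect_true(sum(m$mask) > 0)
})

test_that("voxel grids round-trip through MetaImage + sidecar", {
  sl <- make_slab_phantom(c(40, 40, 40), 5,
                          data.frame(thickness = c(20, 20),
                                     density = c(1, 0.26),
                                     material = c("water", "lung")))
  stem <- file.path(tempdir(), "ph")
  write_voxel_grid(sl, stem)
  back <- read_voxel_grid(stem)
  expect_equal(back$density, sl$density)
  expect_identical(as.integer(back$material), as.integer(sl$material))
  expect_equal(back$origin, sl$origin)
  expect_equal(back$spacing, sl$spacing)
})
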