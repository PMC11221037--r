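test_that("free-path sampling in uniform water follows the exponential law", {
  g <- make_water_tank(c(20, 20, 2000), c(5, 5, 5))
  fp <- sample_free_path(g, c(0, 0, 1), c(0, 0, 1), E = 1.0, n = 1e5,
                         seed = 31)
  expect_lt(mean(fp$exited), 1e-3)
  mu <- mu_components("water", 1.0, 1.0)$mu_total / 10  # 1/mm
  ks <- suppressWarnings(
    stats::ks.test(fp$distance[!fp$exited], "pexp", rate = mu))
  expect_gt(ks$p.value, 0.01)
})

test_that("free paths through a two-slab phantom follow the piecewise exponential law", {
  sl <- make_slab_phantom(c(50, 50, 1500), 5,
                          data.frame(thickness = c(100, 1400),
                                     density = c(1, 0.26),
                                     material = c("water", "lung")))
  n <- 1e5
  fp <- sample_free_path(sl, c(0, 0, 0.5), c(0, 0, 1), E = 1.0, n = n,
                         seed = 32)
  mu1 <- mu_components("water", 1.0, 1.0)$mu_total / 10
  mu2 <- mu_components("lung", 1.0, 0.26)$mu_total / 10
  depth <- fp$distance[!fp$exited] + 0.5  # interaction depth below surface
  cdf <- function(z) ifelse(z <= 100, 1 - exp(-mu1 * (z - 0.5)),
                            1 - exp(-mu1 * 99.5 - mu2 * (z - 100)))
  edges <- c(0.5, seq(25, 100, 25), seq(300, 1300, 200))
  p <- diff(cdf(edges))
  cnt <- as.numeric(table(cut(depth, edges)))
  for (k in seq_along(p)) {
    se <- sqrt(n * p[k] * (1 - p[k]))
    expect_lt(abs(cnt[k] - n * p[k]), 3 * se + 3)
  }
  # exit fraction matches the survival beyond the phantom
  p_exit <- 1 - cdf(1500)
  expect_lt(abs(mean(fp$exited) - p_exit),
            3 * sqrt(p_exit * (1 - p_exit) / n) + 1e-4)
})

test_that("the Woodcock majorant bounds every voxel attenuation", {
  sl <- make_slab_phantom(c(50, 50, 100), 5,
                          data.frame(thickness = c(40, 30, 30),
                                     density = c(1, 0.26, 1.85),
                                     material = c("water", "lung", "bone")))
  E <- 1.3
  mats <- sl$materials$name
  mu_vox <- numeric(length(sl$density))
  for (m in seq_along(mats)) {
    sel <- as.integer(sl$material) == m
    if (any(sel))
      mu_vox[sel] <- mu_components(mats[m], E, 1.0)$mu_total *
        as.numeric(sl$density)[sel]
  }
  mu_max <- max(vapply(seq_along(mats), function(m) {
    sel <- as.integer(sl$material) == m
    if (!any(sel)) return(0)
    mu_components(mats[m], E, 1.0)$mu_total * max(sl$density[sel])
  }, 0.0))
  expect_true(all(mu_vox <= mu_max + 1e-12))
})

test_that("Klein-Nishina samples satisfy kinematics exactly and match quadrature", {
  E <- 1.0
  s <- sample_compton(E, 1e6, seed = 33)
  alpha <- E / 0.5109989
  pred <- E / (1 + alpha * (1 - s$cos_theta))
  expect_lt(max(abs(s$energy_out - pred) / E), 1e-12)

  # mean scattered fraction vs numerical quadrature of the Klein-Nishina pdf
  x0 <- 1 / (1 + 2 * alpha)
  f <- function(x) {
    cth <- 1 - (1 - x) / (alpha * x)
    (1 / x + x - (1 - cth^2))
  }
  norm <- integrate(f, x0, 1, rel.tol = 1e-10)$value
  mean_x <- integrate(function(x) x * f(x), x0, 1, rel.tol = 1e-10)$value / norm
  expect_lt(abs(mean(s$energy_out) / E - mean_x) / mean_x, 0.005)
})

test_that("the low-energy Compton limit reproduces the Thomson law", {
  s <- sample_compton(0.001, 1e6, seed = 34)
  # symmetric distribution: mean cos ~ 0 within 3 sigma
  se_mean <- sd(s$cos_theta) / sqrt(1e6)
  expect_lt(abs(mean(s$cos_theta)), 3 * se_mean + 2e-3)
  # E[|cos|] under (3/8)(1 + cos^2) is 9/16
  se_abs <- sd(abs(s$cos_theta)) / sqrt(1e6)
  expect_lt(abs(mean(abs(s$cos_theta)) - 9 / 16), 3 * se_abs + 2e-3)
})

test_that("electron deposition conserves energy and scales with density", {
  g <- make_water_tank(c(100, 100, 100), 5)
  r <- deposit_electron(c(0, 0, 30), c(0, 0, 1), E_kinetic = 2, grid = g,
                        seed = 35)
  expect_equal(r$deposited + r$escaped, 2, tolerance = 1e-9)
  expect_equal(r$escaped, 0)

  # 99% of the deposited energy lies within the CSDA range of the origin
  range_mm <- csda_range("water", 2, 1.0)
  cz <- 2.5 + (0:19) * 5
  ez <- apply(r$energy, 3, sum)
  inside <- sum(ez[cz <= 30 + range_mm + 2.5])
  expect_gt(inside / sum(ez), 0.99)

  # low-density medium stretches the longitudinal extent by ~1/rho
  lung <- voxel_grid(array(0.26, c(20, 20, 80)),
                     array(2L, c(20, 20, 80)),
                     origin = c(-47.5, -47.5, 2.5), spacing = c(5, 5, 5))
  rl <- deposit_electron(c(0, 0, 10), c(0, 0, 1), E_kinetic = 2, grid = lung,
                         seed = 35)
  extent <- function(res, start) {
    ez <- apply(res$energy, 3, sum)
    zc <- res_z <- (seq_along(ez) - 0.5) * 5
    max(zc[ez > 0]) - start
  }
  ew <- extent(r, 30)
  el <- extent(rl, 10)
  expect_lt(abs(el / ew - 1 / 0.26), 0.1 * (1 / 0.26) + 2 * 5 / ew * 4)
})

test_that("MU scaling is exactly linear and zero-MU plans give zero dose", {
  ps <- fixture_ps60()
  tank <- make_water_tank(c(100, 100, 60), 5)
  mkplan <- function(mu) beam_plan(
    data.frame(iso_x = 0, iso_y = 0, iso_z = 15, dir_x = 0, dir_y = 0,
               dir_z = 1, collimator = 60, mu = mu))
  cfg <- sim_config(histories = 4e4, batches = 2, seed = 36)
  d0 <- run_mc(tank, mkplan(0), list("60" = ps), cfg)
  expect_true(all(d0$dose == 0))
  d1 <- run_mc(tank, mkplan(1), list("60" = ps), cfg)
  d2 <- run_mc(tank, mkplan(2), list("60" = ps), cfg)
  expect_equal(d2$dose, 2 * d1$dose, tolerance = 1e-12)
  expect_error(run_mc(tank, mkplan(1), list("15" = ps), cfg),
               "no phase space")
})

test_that("identical seeds reproduce doses bitwise; energy bookkeeping balances", {
  ps <- fixture_ps60()
  tank <- make_water_tank(c(100, 100, 60), 5)
  plan <- beam_plan(data.frame(iso_x = 0, iso_y = 0, iso_z = 15, dir_x = 0,
                               dir_y = 0, dir_z = 1, collimator = 60, mu = 1))
  cfg <- sim_config(histories = 4e4, batches = 4, seed = 37)
  a <- run_mc(tank, plan, list("60" = ps), cfg)
  b <- run_mc(tank, plan, list("60" = ps), cfg)
  expect_identical(a$dose, b$dose)
  bk <- a$manifest$energy[[1]]
  expect_lt(abs(bk[["launched"]] - bk[["deposited"]] - bk[["escaped"]]),
            1e-6 * bk[["launched"]])
})

test_that("narrow-beam primary transmission follows Beer-Lambert", {
  g <- make_water_tank(c(20, 20, 100), c(5, 5, 5))
  n <- 2e5
  fp <- sample_free_path(g, c(0, 0, 0.001), c(0, 0, 1), E = 1.0, n = n,
                         seed = 38)
  mu <- mu_components("water", 1.0, 1.0)$mu_total
  p <- exp(-mu * 10)  # 10 cm of water
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(fp$exited) - p), 3 * se)
})

test_that("batch uncertainty follows the closed form and shrinks with histories", {
  expect_error(estimate_uncertainty(matrix(1, 5, 1)), "2 batches")
  m <- matrix(c(9, 11), nrow = 1)
  u <- estimate_uncertainty(m)
  expect_equal(u$rel_per_voxel, 0.1)
  ident <- matrix(5, nrow = 3, ncol = 4)
  expect_true(all(estimate_uncertainty(ident)$rel_per_voxel == 0))

  ps <- fixture_ps60()
  tank <- make_water_tank(c(100, 100, 60), 5)
  plan <- beam_plan(data.frame(iso_x = 0, iso_y = 0, iso_z = 15, dir_x = 0,
                               dir_y = 0, dir_z = 1, collimator = 60, mu = 1))
  u1 <- run_mc(tank, plan, list("60" = ps),
               sim_config(histories = 5e4, batches = 10, seed = 39))
  u4 <- run_mc(tank, plan, list("60" = ps),
               sim_config(histories = 2e5, batches = 10, seed = 40))
  r <- u1$manifest$average_rel_uncertainty /
    u4$manifest$average_rel_uncertainty
  expect_lt(abs(r - 2), 0.4)
})

test_that("the target-uncertainty stopping rule adds batch rounds until it is met", {
  ps <- fixture_ps60()
  tank <- make_water_tank(c(100, 100, 60), 5)
  plan <- beam_plan(data.frame(iso_x = 0, iso_y = 0, iso_z = 15, dir_x = 0,
                               dir_y = 0, dir_z = 1, collimator = 60, mu = 1))
  base <- run_mc(tank, plan, list("60" = ps),
                 sim_config(histories = 5e4, batches = 5, seed = 45))
  target <- base$manifest$average_rel_uncertainty / 1.8
  dg <- run_mc(tank, plan, list("60" = ps),
               sim_config(histories = 5e4, batches = 5, seed = 45,
                          target_rel_unc = target))
  expect_lte(dg$manifest$average_rel_uncertainty, target)
  expect_gt(dg$histories, base$histories)
  expect_identical(ncol(dg$batch_doses) %% 5L, 0L)
})

test_that("calibration factors from different history counts are statistically consistent", {
  ps <- fixture_ps60()
  c1 <- fixture_cal()                            # 4e6 histories
  c2 <- calibrate(ps, sim_config(histories = 1.6e7, batches = 10, seed = 46))
  se <- sqrt(c1$rel_se^2 + c2$rel_se^2)
  expect_lt(abs(c1$factor / c2$factor - 1), 3 * se)
  expect_gt(c1$factor, 0)
})

test_that("a run equals the sum of partitioned sub-runs within statistics", {
  ps <- fixture_ps60()
  tank <- make_water_tank(c(100, 100, 60), 5)
  plan <- beam_plan(data.frame(iso_x = 0, iso_y = 0, iso_z = 15, dir_x = 0,
                               dir_y = 0, dir_z = 1, collimator = 60, mu = 1))
  full <- run_mc(tank, plan, list("60" = ps),
                 sim_config(histories = 2e5, batches = 10, seed = 41))
  h1 <- run_mc(tank, plan, list("60" = ps),
               sim_config(histories = 1e5, batches = 5, seed = 42))
  h2 <- run_mc(tank, plan, list("60" = ps),
               sim_config(histories = 1e5, batches = 5, seed = 43))
  sel <- irisdose:::ref_region_voxels(tank, 15, 10)
  a <- mean(full$dose[sel])
  b <- mean((h1$dose[sel] + h2$dose[sel]) / 2)
  bm_full <- colSums(full$batch_doses[sel, ]) / length(sel)
  se <- sd(bm_full) / sqrt(10)
  expect_lt(abs(a - b), 4 * se)
})

test_that("dose grids round-trip through MetaImage with manifest", {
  ps <- fixture_ps60()
  tank <- make_water_tank(c(60, 60, 40), 5)
  plan <- beam_plan(data.frame(iso_x = 0, iso_y = 0, iso_z = 15, dir_x = 0,
                               dir_y = 0, dir_z = 1, collimator = 60, mu = 1))
  dg <- run_mc(tank, plan, list("60" = ps),
               sim_config(histories = 2e4, batches = 2, seed = 44))
  stem <- file.path(tempdir(), "dg")
  write_dose_grid(dg, stem)
  back <- read_dose_grid(stem)
  expect_equal(back$dose, dg$dose)
  expect_equal(back$rel_uncertainty, dg$rel_uncertainty)
  expect_equal(back$histories, dg$histories)
})
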