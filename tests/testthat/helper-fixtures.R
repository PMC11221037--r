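# Shared fixtures, built lazily and cached for the whole test session.
# Commissioning (calibration + beam data) is the expensive part; every test
# that needs it shares one commissioned system.

.fix <- new.env(parent = emptyenv())

fixture_ps60 <- function() {
  if (is.null(.fix$ps60)) .fix$ps60 <- generate_phase_space(n = 2e5, seed = 42)
  .fix$ps60
}

fixture_ps15 <- function() {
  if (is.null(.fix$ps15))
    .fix$ps15 <- collimate(fixture_ps60(),
                           aperture_factors(7.5, 1.5, 1.5, 0.4, 0.7))
  .fix$ps15
}

fixture_ps_map <- function() list("60" = fixture_ps60(), "15" = fixture_ps15())

fixture_cal <- function() {
  if (is.null(.fix$cal))
    .fix$cal <- calibrate(fixture_ps60(),
                          sim_config(histories = 4e6, batches = 10, seed = 7))
  .fix$cal
}

fixture_beam_data <- function() {
  if (is.null(.fix$bd))
    .fix$bd <- build_beam_data(fixture_ps_map(),
                               sim_config(histories = 3e6, batches = 2,
                                          seed = 21),
                               collimators = c("60", "15"),
                               ocr_depths = c(15, 100, 250),
                               pdd_depth_max = 280)
  .fix$bd
}

# small dose_grid wrapper for analytic gamma/DVH tests
make_dose <- function(a, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  dims <- dim(a)
  structure(list(origin = origin, spacing = spacing, dims = dims, dose = a,
                 rel_uncertainty = array(0, dims), histories = 0L,
                 batches = 0L, batch_doses = NULL, manifest = list()),
            class = "dose_grid")
}

# brute-force gamma oracle wrapper (dense scan kernel, no pruning)
gamma_oracle <- function(ref, ev, criteria, radius_factor = 3,
                         step_factor = 0.1) {
  mx <- max(ref$dose)
  irisdose:::.gamma_bruteforce_cpp(as.numeric(ref$dose), as.numeric(ev$dose),
                                   as.integer(ref$dims),
                                   as.numeric(ref$spacing),
                                   criteria$dose_tolerance / 100 * mx,
                                   criteria$dta,
                                   criteria$low_dose_threshold / 100 * mx,
                                   radius_factor, step_factor)
}

# analytic fluence-based OCR surrogate: annulus-summed projected weight at
# the 800 mm plane.  Shares the region definition with the real forward
# engine but involves no transport; used to unit-test fit logic cheaply.
fluence_forward_engine <- function() {
  function(ps) {
    rp <- projection_radius(ps, plane_z_to = 800)
    b <- floor(rp) + 1
    ok <- rp < 60
    w <- vapply(split(ps$particles$weight[ok], factor(b[ok], levels = 1:60)),
                sum, 0.0)
    area <- pi * ((1:60)^2 - (0:59)^2)
    v <- w / area
    data.frame(r = seq(0.5, 59.5, 1), value = v / v[1])
  }
}
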