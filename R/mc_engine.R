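#' Beam plan
#'
#' @param beams data.frame with one row per beam: `iso_x`, `iso_y`, `iso_z`
#'   (isocenter, mm), `dir_x`, `dir_y`, `dir_z` (unit beam direction),
#'   `collimator` (projection diameter, mm), `mu` (monitor units, >= 0).
#' @param sad source-axis distance, mm (the source sits `sad` mm upstream of
#'   each isocenter along the beam direction).
#' @param calibration_factor cGy per MU scaling (from [calibrate()]).
#' @export
beam_plan <- function(beams, sad = 800, calibration_factor = 1.0) {
  need <- c("iso_x", "iso_y", "iso_z", "dir_x", "dir_y", "dir_z",
            "collimator", "mu")
  stopifnot(all(need %in% names(beams)))
  nrm <- sqrt(beams$dir_x^2 + beams$dir_y^2 + beams$dir_z^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("beam directions must be unit length")
  if (any(beams$mu < 0)) stop("MU must be non-negative")
  structure(list(beams = beams, sad = sad,
                 calibration_factor = calibration_factor),
            class = "beam_plan")
}

# single-beam helper
beam_row <- function(iso, dir, collimator, mu) {
  dir <- dir / sqrt(sum(dir^2))
  data.frame(iso_x = iso[1], iso_y = iso[2], iso_z = iso[3],
             dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
             collimator = collimator, mu = mu)
}

#' Simulation configuration
#'
#' @param histories photon histories per beam (>= batches).
#' @param batches number of statistically independent batches (>= 2).
#' @param seed integer seed; batch `b` of beam `j` uses the independent
#'   stream `(j - 1) * batches + b` derived from it.
#' @param photon_cutoff MeV; photons below it deposit locally (default
#'   10 keV).
#' @param electron_steps condensed-history steps per electron track.
#' @param target_rel_unc optional stopping rule: after the configured
#'   batches, further rounds of `batches` batches are added (up to
#'   `max_rounds`) until the average relative uncertainty of the hot region
#'   falls at or below this value.
#' @param max_rounds cap on uncertainty-driven batch rounds.
#' @param keep_batches retain per-batch dose vectors on the result (needed
#'   for uncertainty estimation; default TRUE).
#' @export
sim_config <- function(histories = 2e5, batches = 10, seed = 1,
                       photon_cutoff = 0.01, electron_steps = 20,
                       target_rel_unc = NULL, max_rounds = 8,
                       keep_batches = TRUE) {
  if (batches < 2) stop("at least 2 batches are required")
  if (histories < batches) stop("histories must be >= batches")
  rng <- physics_tables()$energy_range
  if (photon_cutoff < rng[1] || photon_cutoff > rng[2])
    stop("photon cutoff outside physics table range")
  structure(list(histories = as.integer(histories),
                 batches = as.integer(batches), seed = as.integer(seed),
                 photon_cutoff = photon_cutoff,
                 electron_steps = as.integer(electron_steps),
                 target_rel_unc = target_rel_unc,
                 max_rounds = as.integer(max_rounds),
                 keep_batches = isTRUE(keep_batches)),
            class = "sim_config")
}

dose_grid <- function(grid, dose, rel_uncertainty, histories, batches,
                      batch_doses = NULL, manifest = list()) {
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dims = grid$dims, dose = dose,
                 rel_uncertainty = rel_uncertainty,
                 histories = histories, batches = batches,
                 batch_doses = batch_doses, manifest = manifest),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(x$dims, collapse = " x "), " voxels, max dose ",
      signif(max(x$dose), 5), " cGy, ", x$histories, " histories in ",
      x$batches, " batches\n", sep = "")
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(as.integer(a$dims), as.integer(b$dims)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Run the Monte Carlo dose engine
#'
#' Transports phase-space photons through the phantom with Woodcock (delta)
#' tracking; interactions are photoelectric absorption, Klein-Nishina
#' Compton scattering and Rayleigh scattering (Thomson-shaped, direction
#' change only). Secondary electrons deposit energy along condensed
#' straight-ahead tracks with Highland-style lateral blur. Scoring is
#' energy per unit mass per voxel (dose to medium), scaled by beam MU and
#' the plan's calibration factor. Zero-density voxels are transparent and
#' receive no dose.
#'
#' @param phantom a [voxel_grid()].
#' @param plan a [beam_plan()].
#' @param ps_map named list of `phase_space` objects keyed by collimator
#'   diameter (e.g. `list("60" = ps60)`).
#' @param config a [sim_config()].
#' @return A `dose_grid` with per-voxel dose (cGy per plan), relative
#'   uncertainty, and a run manifest (seeds, histories, energy bookkeeping).
#' @export
run_mc <- function(phantom, plan, ps_map, config = sim_config()) {
  geom <- grid_geom(phantom)
  dens <- as.numeric(phantom$density)
  mat <- as.integer(phantom$material) - 1L
  xs <- xs_for_grid(phantom)
  csda <- csda_for_cpp()
  nvox <- prod(phantom$dims)
  voxvol_cm3 <- prod(phantom$spacing) / 1000
  mass_g <- dens * voxvol_cm3

  nb <- config$batches
  nbeams <- nrow(plan$beams)
  bookkeeping <- list()

  # one round = `nb` batches of histories/nb each, for every beam; extra
  # rounds use fresh random streams so batches stay independent
  run_round <- function(round) {
    be <- matrix(0.0, nvox, nb)
    for (j in seq_len(nbeams)) {
      b <- plan$beams[j, ]
      if (b$mu == 0) next
      key <- as.character(b$collimator)
      ps <- ps_map[[key]]
      if (is.null(ps))
        stop("no phase space provided for collimator ", key, " mm")
      dir <- c(b$dir_x, b$dir_y, b$dir_z)
      src <- c(b$iso_x, b$iso_y, b$iso_z) - dir * plan$sad
      e1 <- if (abs(dir[3]) < 0.99) c(-dir[2], dir[1], 0) else c(0, -dir[3], dir[2])
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      pm <- as.matrix(ps$particles[, c("energy", "x", "y", "u", "v", "w",
                                       "weight")])
      # zero-weight particles (collimated out) contribute exactly nothing:
      # transport only the carrying subset and rescale by its count fraction,
      # so every history is informative without changing the expectation
      keep <- pm[, 7] > 0
      frac <- mean(keep)
      if (frac == 0) next
      pm <- pm[keep, , drop = FALSE]
      np <- nrow(pm)
      hb <- config$histories %/% nb
      launched <- deposited <- escaped <- 0
      for (bt in seq_len(nb)) {
        stream <- ((round - 1) * nbeams + (j - 1)) * nb + bt
        res <- .mc_batch_cpp(geom, dens, mat, xs, csda, pm, ps$plane_z,
                             src, e1, e2, dir, hb, ((bt - 1L) * hb) %% np,
                             config$photon_cutoff, config$electron_steps,
                             as.double(config$seed), as.double(stream))
        # energy (MeV*weight) -> dose (cGy) per MU: per-history mean, scaled
        # by MU and the absolute calibration
        d <- res$energy / pmax(mass_g, .Machine$double.eps) / hb * frac
        d[mass_g <= 0] <- 0
        be[, bt] <- be[, bt] + d * b$mu * plan$calibration_factor
        launched <- launched + res$launched * frac
        deposited <- deposited + res$deposited * frac
        escaped <- escaped + res$escaped * frac
      }
      if (launched > 0 &&
          abs(launched - deposited - escaped) > 1e-6 * launched)
        stop("energy bookkeeping violation in MC transport")
      bk <- c(launched = launched, deposited = deposited, escaped = escaped)
      bookkeeping[[j]] <<- if (round == 1) bk else bookkeeping[[j]] + bk
    }
    be
  }

  batch_energy <- run_round(1)
  rounds <- 1L
  if (!is.null(config$target_rel_unc)) {
    while (rounds < config$max_rounds &&
           estimate_uncertainty(batch_energy)$average >
             config$target_rel_unc) {
      rounds <- rounds + 1L
      batch_energy <- cbind(batch_energy, run_round(rounds))
    }
  }

  dose <- rowMeans(batch_energy)
  unc <- estimate_uncertainty(batch_energy)
  dose_grid(phantom,
            array(dose, dim = phantom$dims),
            array(unc$rel_per_voxel, dim = phantom$dims),
            histories = rounds * config$histories,
            batches = ncol(batch_energy),
            batch_doses = if (config$keep_batches) batch_energy else NULL,
            manifest = list(seed = config$seed,
                            histories = rounds * config$histories,
                            batches = ncol(batch_energy),
                            photon_cutoff = config$photon_cutoff,
                            energy = bookkeeping,
                            average_rel_uncertainty = unc$average))
}

#' Batch-based statistical uncertainty
#'
#' Per-voxel relative standard deviation of the batch mean (standard error
#' over batches divided by the mean), plus its scalar average over the
#' reporting region (voxels receiving more than 50% of the maximum dose).
#'
#' @param batch_doses matrix, voxels x batches (>= 2 batches).
#' @return list with `rel_per_voxel` and scalar `average`.
#' @export
estimate_uncertainty <- function(batch_doses) {
  if (is.null(dim(batch_doses)) || ncol(batch_doses) < 2)
    stop("at least 2 batches are required")
  m <- rowMeans(batch_doses)
  nb <- ncol(batch_doses)
  se <- sqrt(pmax(0, rowMeans(batch_doses^2) - m^2) * nb / (nb - 1)) / sqrt(nb)
  rel <- ifelse(m > 0, se / m, 0)
  hot <- m > 0.5 * max(m)
  list(rel_per_voxel = rel, average = mean(rel[hot]))
}

#' Absolute dose calibration
#'
#' Simulates the reference geometry -- a water phantom whose surface is
#' placed so that the scoring point at `ref_depth` lies `sad` mm from the
#' source, irradiated by the corrected 60 mm phase space -- and returns the
#' factor mapping 1 MU to 1 cGy at the reference point (dose averaged over a
#' disc of `ref_region_radius` in the reference depth slab). Errors if the
#' statistical uncertainty of the reference region exceeds 2%.
#'
#' @param ps60 corrected 60 mm `phase_space`.
#' @param config a [sim_config()].
#' @param ref_depth reference depth, mm.
#' @param sad source-axis distance, mm.
#' @param ref_dose_cgy_per_mu reference dose value, cGy per MU.
#' @param spacing,extent water tank voxel size and extent, mm.
#' @param ref_region_radius averaging disc radius, mm.
#' @return list with `factor` (cGy per MU per raw dose unit), `ref_dose_raw`,
#'   `rel_se`, and the geometry used.
#' @export
calibrate <- function(ps60, config = sim_config(), ref_depth = 15, sad = 800,
                      ref_dose_cgy_per_mu = 1.0,
                      spacing = c(2.5, 2.5, 2.5),
                      extent = c(150, 150, 60), ref_region_radius = 5) {
  tank <- make_water_tank(extent, spacing)
  plan <- beam_plan(beam_row(c(0, 0, ref_depth), c(0, 0, 1),
                             ps60$collimator, mu = 1),
                    sad = sad, calibration_factor = 1.0)
  # surface at z = 0 -> SSD = sad - ref_depth by construction
  dg <- run_mc(tank, plan, stats::setNames(list(ps60),
                                           as.character(ps60$collimator)),
               config)
  # averaging cylinder: disc of ref_region_radius over +-3 mm of slabs
  # around the reference depth (the dose plateau near d_max is flat there)
  sel <- ref_region_voxels(tank, ref_depth, ref_region_radius,
                           half_depth = 3)
  bm <- colSums(dg$batch_doses[sel, , drop = FALSE]) / length(sel)
  m <- mean(bm)
  se <- sd(bm) / sqrt(length(bm))
  rel_se <- se / m
  if (!is.finite(rel_se) || rel_se > 0.02)
    stop(sprintf("calibration-unstable: reference region uncertainty %.1f%% > 2%%",
                 100 * rel_se))
  list(factor = ref_dose_cgy_per_mu / m, ref_dose_raw = m, rel_se = rel_se,
       ref_depth = ref_depth, sad = sad, ssd = sad - ref_depth,
       ref_region_radius = ref_region_radius)
}

# voxel indices of the reference averaging cylinder (linear indices):
# transverse disc of `radius` over slabs within `half_depth` of `depth`
# (at least the nearest slab)
ref_region_voxels <- function(grid, depth, radius, half_depth = 0) {
  cx <- grid_axis(grid, 1); cy <- grid_axis(grid, 2); cz <- grid_axis(grid, 3)
  izs <- which(abs(cz - depth) <= half_depth)
  if (length(izs) == 0) izs <- which.min(abs(cz - depth))
  inplane <- which(outer(cx^2, cy^2, `+`) <= radius^2)
  nxy <- grid$dims[1] * grid$dims[2]
  as.vector(outer(inplane, (izs - 1L) * nxy, `+`))
}

#' Woodcock free-path sampling (diagnostic surface)
#'
#' Samples distances to the first real interaction from a fixed start point
#' and direction, using the same Woodcock tracking as the transport engine.
#'
#' @param grid a [voxel_grid()].
#' @param position,direction length-3 numerics (start may be outside the
#'   grid; the flight then begins at the grid entry).
#' @param E photon energy, MeV.
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with `distance` (mm; NA when the photon exits) and
#'   `exited`.
#' @export
sample_free_path <- function(grid, position, direction, E, n = 1, seed = 1) {
  d <- .sample_free_path_cpp(grid_geom(grid), as.numeric(grid$density),
                             as.integer(grid$material) - 1L, xs_for_grid(grid),
                             as.numeric(position), as.numeric(direction),
                             E, as.integer(n), as.double(seed))
  data.frame(distance = d, exited = is.na(d))
}

#' Klein-Nishina Compton sampling (diagnostic surface)
#'
#' @param E photon energy, MeV.
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with `energy_out` (MeV) and `cos_theta`; each pair
#'   satisfies the Compton kinematic identity by construction.
#' @export
sample_compton <- function(E, n, seed = 1) {
  m <- .sample_compton_cpp(E, as.integer(n), as.double(seed))
  data.frame(energy_out = m[, 1], cos_theta = m[, 2])
}

#' Condensed electron energy deposition (diagnostic surface)
#'
#' @param origin,direction start point and direction, mm / unit vector.
#' @param E_kinetic electron kinetic energy, MeV.
#' @param grid a [voxel_grid()].
#' @param weight statistical weight.
#' @param nsteps condensed-history steps.
#' @param seed integer seed (for the lateral scattering deviates).
#' @return list with the per-voxel deposited `energy` array (MeV), total
#'   `deposited` and `escaped` energy.
#' @export
deposit_electron <- function(origin, direction, E_kinetic, grid, weight = 1,
                             nsteps = 20, seed = 1) {
  r <- .deposit_electron_cpp(grid_geom(grid), as.numeric(grid$density),
                             as.integer(grid$material) - 1L, csda_for_cpp(),
                             as.numeric(origin), as.numeric(direction),
                             E_kinetic, weight, as.integer(nsteps),
                             as.double(seed))
  list(energy = array(r$energy, dim = grid$dims), deposited = r$deposited,
       escaped = r$escaped)
}
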