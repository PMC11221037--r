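# Commissioning fits for the phase-space source model: the per-region radial
# correction for the 60 mm collimator and the four-factor aperture correction
# for smaller collimators.  All forward simulations inside a fit reuse one
# fixed seed (common random numbers): particle trajectories do not depend on
# their weights under Woodcock tracking, so measured/simulated ratios are
# almost noise-free and fits converge deterministically.

#' Forward water-tank OCR engine
#'
#' Returns a function mapping a `phase_space` to its off-center-ratio curve
#' at `depth` in water with the measurement plane `sad` mm from the source
#' (surface at SSD = sad - depth), evaluated as annulus means on 1 mm radial
#' regions 0-60 mm scaled onto the measurement plane and normalized to the
#' axial region.
#'
#' @param depth measurement depth, mm.
#' @param sad source-to-detector distance, mm.
#' @param histories,batches,seed Monte Carlo settings (fixed seed: common
#'   random numbers across calls).
#' @param spacing voxel size, mm.
#' @param extent_xy transverse tank extent, mm.
#' @param slab_halfwidth half-width of the scoring slab around `depth`, mm.
#' @return function(ps) -> data.frame(r, value).
#' @export
ocr_forward_engine <- function(depth = 100, sad = 800, histories = 4e5,
                               batches = 2, seed = 760417,
                               spacing = c(1.25, 1.25, 2.5),
                               extent_xy = 150, slab_halfwidth = 10,
                               bin_edges = 0:60) {
  spacing <- rep_len(spacing, 3L)
  ssd <- sad - depth
  tank <- make_water_tank(c(extent_xy, extent_xy, depth + slab_halfwidth + 10),
                          spacing)
  cfg <- sim_config(histories = histories, batches = batches, seed = seed)
  function(ps) {
    plan <- beam_plan(beam_row(c(0, 0, sad - ssd), c(0, 0, 1),
                               ps$collimator, mu = 1))
    dg <- run_mc(tank, plan,
                 stats::setNames(list(ps), as.character(ps$collimator)), cfg)
    ocr_radial(dg, depth, ssd, sad, slab_halfwidth, bin_edges)
  }
}

# radial bins adapted to a collimator: 1 mm resolution across the penumbra,
# coarser in the flat interior and the low-dose tail, so every annulus holds
# enough voxels for stable statistics
ocr_bins_for_collimator <- function(collimator) {
  R <- collimator / 2
  fine_lo <- max(0, floor(0.6 * R)); fine_hi <- min(60, ceiling(1.4 * R) + 4)
  edges <- sort(unique(c(seq(0, fine_lo, by = 3), seq(fine_lo, fine_hi, by = 1),
                         seq(fine_hi, 60, by = 3), 60)))
  edges[edges <= 60]
}

#' Forward water-tank PDD engine
#'
#' Returns a function mapping a `phase_space` to its percent depth dose
#' curve in water at SSD = `ssd`.
#'
#' @param ssd source-skin distance, mm.
#' @param depth_max tank depth, mm.
#' @param histories,batches,seed Monte Carlo settings.
#' @param spacing voxel size, mm.
#' @param extent_xy transverse tank extent, mm.
#' @param axis_radius central-axis averaging disc radius, mm.
#' @return function(ps) -> data.frame(depth, value).
#' @export
pdd_forward_engine <- function(ssd = 800, depth_max = 310, histories = 4e5,
                               batches = 2, seed = 760417, spacing = 2.5,
                               extent_xy = 160, axis_radius = 5) {
  tank <- make_water_tank(c(extent_xy, extent_xy, depth_max), spacing)
  cfg <- sim_config(histories = histories, batches = batches, seed = seed)
  function(ps) {
    plan <- beam_plan(beam_row(c(0, 0, 800 - ssd), c(0, 0, 1),
                               ps$collimator, mu = 1))
    dg <- run_mc(tank, plan,
                 stats::setNames(list(ps), as.character(ps$collimator)), cfg)
    extract_pdd(dg, radius = axis_radius)
  }
}

smooth_triangular <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  y[2:(n - 1)] <- 0.25 * x[1:(n - 2)] + 0.5 * x[2:(n - 1)] + 0.25 * x[3:n]
  y
}

#' Fit the radial correction coefficients
#'
#' Fixed-point iteration per 1 mm radial region:
#' `c_{k+1}(r) = c_k(r) * (measured(r) / simulated_k(r))^damping`, starting
#' from all ones, where `simulated_k` is the forward OCR of the phase space
#' with the current coefficients applied. Stops when
#' `max_r |measured/simulated - 1| < tol` or after `max_iter` iterations.
#' Updates are damped (default 0.7), ratio-smoothed with a small triangular
#' kernel, and clipped to `[0.1, 10]` for robustness under Monte Carlo
#' noise. Regions where both curves are empty keep their coefficient;
#' a region with (near) zero simulated dose but nonzero measured dose is a
#' degenerate fit and raises an error naming the region.
#'
#' @param ps the uncorrected 60 mm `phase_space`.
#' @param measured_ocr data.frame(r, value) covering 0-60 mm off-axis.
#' @param forward_engine function(ps) -> data.frame(r, value) at 10 cm
#'   depth (see [ocr_forward_engine()]).
#' @param tol convergence tolerance on the max region ratio deviation.
#' @param max_iter maximum iterations.
#' @param damping exponent applied to the update ratio.
#' @param smooth smooth the update ratios radially (default TRUE).
#' @return A [radial_correction()] whose `trace` records per-iteration
#'   residuals and the convergence flag.
#' @export
fit_radial_correction <- function(ps, measured_ocr,
                                  forward_engine = ocr_forward_engine(),
                                  tol = 0.002, max_iter = 20, damping = 0.7,
                                  smooth = TRUE) {
  measured_ocr <- measured_ocr[is.finite(measured_ocr$value), , drop = FALSE]
  if (min(measured_ocr$r) > 1 || max(measured_ocr$r) < 59)
    stop("measured curve must cover 0-60 mm off-axis")
  centers <- seq(0.5, 59.5, by = 1)
  meas <- approx(measured_ocr$r, measured_ocr$value, xout = centers,
                 rule = 2)$y
  co <- rep(1.0, 60)
  residuals <- numeric(0)
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    sim <- forward_engine(apply_radial_correction(ps, radial_correction(co)))
    sim <- sim[is.finite(sim$value), , drop = FALSE]
    simv <- approx(sim$r, sim$value, xout = centers, rule = 2)$y
    empty <- !is.finite(simv) | simv <= 1e-3
    bad <- empty & meas > 0.05
    if (any(bad))
      stop("fit-degenerate: zero simulated dose with nonzero measured dose in region(s) ",
           paste(which(bad) - 1, collapse = ", "), " mm")
    ratio <- ifelse(empty, 1, meas / simv)
    resid <- max(abs(ratio[!empty] - 1))
    residuals <- c(residuals, resid)
    if (resid < tol) { converged <- TRUE; break }
    if (smooth) ratio <- smooth_triangular(ratio)
    co <- pmin(pmax(co * ratio^damping, 0.1), 10)
  }
  radial_correction(co, trace = list(residuals = residuals,
                                     iterations = length(residuals),
                                     converged = converged))
}

#' Fit the four aperture correction factors
#'
#' Coordinate-descent search over `(delta_R1, delta_R2, W1, W2)` minimizing
#' the RMS deviation between the simulated and measured OCR at 10 cm depth
#' (curves normalized to the axis value, so the objective is in units of
#' the axis value). Only improving steps are accepted, so the objective is
#' non-increasing; step sizes halve when a full sweep yields no improvement.
#' The band structure encodes the penumbra asymmetry: simulated-above-
#' measured inside the aperture pulls `W2` below 1, simulated-below-measured
#' outside pulls `W1` above 0.
#'
#' @param ps60 the radially corrected 60 mm `phase_space`.
#' @param R target collimator projection radius, mm (< 30).
#' @param measured_ocr data.frame(r, value) for the target collimator.
#' @param forward_engine function(ps) -> data.frame(r, value).
#' @param init starting [aperture_factors()] (default
#'   `aperture_factors(R, 1.5, 1.5, 0.5, 0.9)`).
#' @param steps initial step sizes for (mm bands, weights).
#' @param min_steps convergence thresholds for the step sizes.
#' @param max_rounds maximum coordinate sweeps.
#' @return list with `factors`, final `objective`, the accepted-step
#'   `trace`, and the number of forward `evaluations`.
#' @export
fit_aperture_factors <- function(ps60, R, measured_ocr,
                                 forward_engine = ocr_forward_engine(),
                                 init = NULL, steps = c(band = 1, weight = 0.2),
                                 min_steps = c(band = 0.1, weight = 0.02),
                                 max_rounds = 25) {
  if (is.null(init)) init <- aperture_factors(R, 1.5, 1.5, 0.5, 0.9)
  measured_ocr <- measured_ocr[is.finite(measured_ocr$value), , drop = FALSE]
  meas_fun <- function(r) approx(measured_ocr$r, measured_ocr$value,
                                 xout = r, rule = 2)$y
  nev <- 0L
  objective <- function(p) {
    f <- aperture_factors(R, p[1], p[2], p[3], p[4])
    sim <- forward_engine(collimate(ps60, f))
    sim <- sim[is.finite(sim$value), , drop = FALSE]
    nev <<- nev + 1L
    val <- sqrt(mean((sim$value - meas_fun(sim$r))^2))
    if (!is.finite(val)) stop("fit-degenerate: non-finite aperture objective")
    val
  }
  lower <- c(0, 0, 0, 0)
  upper <- c(8, min(R, 8), 1.5, 1.5)
  p <- pmin(pmax(c(init$delta_R1, init$delta_R2, init$W1, init$W2), lower),
            upper)
  st <- c(steps[["band"]], steps[["band"]], steps[["weight"]],
          steps[["weight"]])
  stmin <- c(min_steps[["band"]], min_steps[["band"]], min_steps[["weight"]],
             min_steps[["weight"]])
  best <- objective(p)
  trace <- best
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (i in 1:4) {
      for (sgn in c(1, -1)) {
        cand <- p
        cand[i] <- min(max(cand[i] + sgn * st[i], lower[i]), upper[i])
        if (cand[i] == p[i]) next
        val <- objective(cand)
        if (val < best) {
          p <- cand; best <- val; improved <- TRUE
          trace <- c(trace, best)
          break
        }
      }
    }
    if (!improved) {
      st <- st / 2
      if (all(st < stmin)) break
    }
  }
  list(factors = aperture_factors(R, p[1], p[2], p[3], p[4]),
       objective = best, trace = trace, evaluations = nev)
}

#' Synthetic commissioning measurements
#'
#' Stand-in for water-tank diode measurements: runs the forward engines on
#' a (optionally perturbed) phase space and exports smoothed curves with a
#' stated relative noise level. Deterministic given `seed`.
#'
#' @param engine_config list with `ps` (the phase space), `histories`,
#'   `spacing`, `ocr_depths` (default 100), `pdd` (logical, default TRUE)
#'   and optionally `seed` for the forward engines.
#' @param perturbation_spec list with optional `radial_fun` (function of
#'   projection radius multiplying the weights), `aperture` (an
#'   [aperture_factors()] applied via [collimate()]), `noise_sd` (relative
#'   Gaussian noise, default 0), `smooth` (logical, default TRUE).
#' @param seed integer seed for the measurement noise.
#' @return list with `pdd` (or NULL) and `ocr`, a named list of
#'   data.frame(r, value) by depth.
#' @export
make_synthetic_measurements <- function(engine_config, perturbation_spec =
                                          list(), seed = 1) {
  ps <- engine_config$ps
  if (!is.null(perturbation_spec$radial_fun)) {
    rp <- projection_radius(ps, plane_z_to = 800)
    ps$particles$weight <- ps$particles$weight *
      perturbation_spec$radial_fun(rp)
  }
  if (!is.null(perturbation_spec$aperture))
    ps <- collimate(ps, perturbation_spec$aperture)
  hist <- engine_config$histories %||% 4e5
  sp <- engine_config$spacing %||% c(1.25, 1.25, 2.5)
  fseed <- engine_config$seed %||% 760417
  depths <- engine_config$ocr_depths %||% 100
  noise <- perturbation_spec$noise_sd %||% 0
  # smoothing is part of the noise treatment: a noiseless export reproduces
  # the forward engine output exactly
  do_smooth <- perturbation_spec$smooth %||% (noise > 0)

  post <- function(v, i) {
    with_seed(seed + i, {
      if (noise > 0) v <- v * (1 + rnorm(length(v), 0, noise))
      if (do_smooth) v <- smooth_triangular(v)
      v
    })
  }
  pdd <- NULL
  if (engine_config$pdd %||% TRUE) {
    pdd <- pdd_forward_engine(histories = hist, spacing = sp, seed = fseed)(ps)
    pdd$value <- post(pdd$value, 0L)
    pdd$value <- 100 * pdd$value / max(pdd$value)
  }
  ocr <- lapply(seq_along(depths), function(i) {
    cur <- ocr_forward_engine(depth = depths[i], histories = hist,
                              spacing = sp, seed = fseed)(ps)
    cur$value <- post(cur$value, i)
    cur$value <- cur$value / cur$value[1]
    cur
  })
  names(ocr) <- as.character(depths)
  list(pdd = pdd, ocr = ocr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
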