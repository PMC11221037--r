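# Stored OCR curves are statistically conditioned: annulus values are
# smoothed with two triangular passes and renormalized so the count-weighted
# mean of the inner 5 mm equals 1 (the inner annuli hold few voxels, so the
# raw bin-1 normalization is the noisiest point of the whole curve).
# Commissioned PDD: depth-adaptive smoothing against per-bin counting noise
# (light in the high-curvature build-up region, heavier in the smooth
# exponential fall-off where the bias is negligible), renormalized to 100.
condition_pdd_curve <- function(pdd, buildup_end = 30) {
  light <- smooth_triangular(pdd$value)
  heavy <- pdd$value
  for (i in 1:4) heavy <- smooth_triangular(heavy)
  w <- pmin(pmax((pdd$depth - buildup_end) / 20, 0), 1)
  pdd$value <- (1 - w) * light + w * heavy
  pdd$value <- 100 * pdd$value / max(pdd$value)
  pdd
}

condition_ocr_curve <- function(cur, axis_radius = 5) {
  ok <- is.finite(cur$value)
  v <- cur$value
  v[ok] <- smooth_triangular(smooth_triangular(cur$value[ok]))
  inner <- ok & cur$r < axis_radius & cur$n > 0
  axis_val <- sum(v[inner] * cur$n[inner]) / sum(cur$n[inner])
  cur$value <- v / axis_val
  # the innermost annuli hold too few voxels to resolve sub-percent
  # structure: represent the in-field core by its mean
  cur$value[inner] <- 1
  cur
}

# Water beam data (PDD, OCR, output factors) commissioned from the Monte
# Carlo engine.  Commissioning the ray-tracing comparator from the MC
# engine's own water curves keeps the two engines self-consistent: in water
# they agree by construction, so differences in heterogeneous media isolate
# the effective-path-length approximation.

#' Commission water beam data from the Monte Carlo engine
#'
#' Per collimator: a PDD curve at SSD 800 mm, OCR profiles at the requested
#' depths (each measured with the plane at 800 mm from the source, i.e.
#' SSD = 800 - depth), and a relative output factor at the calibration
#' reference point (SAD 800 mm, 15 mm depth) against the 60 mm collimator.
#'
#' @param ps_map named list of corrected `phase_space` objects by collimator
#'   diameter; must contain "60" for output-factor normalization.
#' @param config a [sim_config()] (its seed/histories drive every
#'   commissioning run).
#' @param collimators collimators to commission (default: all in `ps_map`).
#' @param ocr_depths OCR measurement depths, mm.
#' @param pdd_depth_max PDD tank depth, mm.
#' @param spacing voxel size for the commissioning tanks, mm.
#' @param sad reference source-axis distance, mm.
#' @return A `beam_data` object.
#' @export
build_beam_data <- function(ps_map, config = sim_config(),
                            collimators = names(ps_map),
                            ocr_depths = c(15, 100, 300),
                            pdd_depth_max = 310, spacing = 2.5, sad = 800) {
  if (!"60" %in% names(ps_map))
    stop("ps_map must contain the 60 mm phase space")
  ref_raw <- function(ps, radius) {
    tank <- make_water_tank(c(120, 120, 40), spacing)
    plan <- beam_plan(beam_row(c(0, 0, 15), c(0, 0, 1), ps$collimator, 1),
                      sad = sad)
    # output factors multiply the whole rt dose, so this estimator gets the
    # same extra statistics as the PDD commissioning
    cfg <- sim_config(histories = 4 * config$histories,
                      batches = max(config$batches, 2), seed = config$seed)
    dg <- run_mc(tank, plan,
                 stats::setNames(list(ps), as.character(ps$collimator)),
                 cfg)
    sel <- ref_region_voxels(tank, 15, radius, half_depth = 3)
    mean(dg$dose[sel])
  }
  out <- lapply(collimators, function(key) {
    ps <- ps_map[[key]]
    # the central-axis disc estimator is the noisiest commissioning quantity
    # (clustered electron-track deposits): use extra histories for the PDD.
    # The same averaging radius is used for the PDD disc and the OCR axis
    # normalization so the two curve families share one axis definition.
    axis_rad <- min(8, ps$collimator / 4)
    pdd <- condition_pdd_curve(pdd_forward_engine(
      ssd = sad, depth_max = pdd_depth_max,
      histories = 4 * config$histories, seed = config$seed,
      spacing = spacing,
      extent_xy = 2 * (ps$collimator * 1.4 / 2 + 40),
      axis_radius = axis_rad)(ps))
    ocr <- lapply(ocr_depths, function(d) {
      # finer transverse voxels so every annulus holds voxel centers
      eng <- ocr_forward_engine(depth = d, sad = sad,
                                histories = config$histories,
                                seed = config$seed,
                                spacing = c(spacing / 2, spacing / 2, spacing),
                                extent_xy = 150,
                                slab_halfwidth = min(7.5, d / 2),
                                bin_edges = ocr_bins_for_collimator(
                                  ps$collimator))
      condition_ocr_curve(eng(ps), axis_radius = axis_rad)
    })
    names(ocr) <- as.character(ocr_depths)
    anchor <- rt_anchor(pdd, ocr, sad = sad)
    of <- if (key == "60") 1.0 else {
      # identical averaging region for both runs of the ratio
      rad <- min(5, ps$collimator / 4)
      ref_raw(ps, rad) / ref_raw(ps_map[["60"]], rad)
    }
    list(pdd = pdd, ocr = ocr, output_factor = of, anchor = anchor)
  })
  names(out) <- collimators
  structure(list(collimators = out, ocr_depths = ocr_depths,
                 ssd_pdd = sad, sad = sad, ref_depth = 15),
            class = "beam_data")
}

# Absolute anchor of the rt factorization: the curve product
# T(d_eff) * OCR * inverse-square evaluated over the exact voxel geometry of
# the calibration reference region (water tank at SSD = sad - 15, averaging
# cylinder r <= 5 mm, |z - 15| <= 3 mm).  Dividing the rt dose by this value
# makes the engine reproduce "1 MU = 1 cGy at the reference point" exactly by
# construction, curve noise and all, mirroring how the Monte Carlo engine is
# calibrated at the same region.
rt_anchor <- function(pdd, ocr, sad = 800, ref_depth = 15) {
  tank <- make_water_tank(c(150, 150, 60), 2.5)
  sel <- ref_region_voxels(tank, ref_depth, 5, half_depth = 3)
  idx <- arrayInd(sel, tank$dims)
  cx <- grid_axis(tank, 1)[idx[, 1]]
  cy <- grid_axis(tank, 2)[idx[, 2]]
  cz <- grid_axis(tank, 3)[idx[, 3]]
  ssd <- sad - ref_depth
  sfd <- sqrt(cx^2 + cy^2 + (ssd + cz)^2)
  tfac <- pdd$value / 100 * ((sad + pdd$depth) / sad)^2
  tv <- approx(pdd$depth, tfac, xout = cz, rule = 2)$y
  rmeas <- sqrt(cx^2 + cy^2) * sad / (ssd + cz)
  ov <- ocr_value_at(ocr, rmeas, cz)
  mean(tv * ov * (sad / sfd)^2)
}

# OCR value at (r, depth): linear interpolation over radius within each
# commissioned depth curve, then linear interpolation across depths (clamped
# at the commissioned ends)
ocr_value_at <- function(ocr, rmeas, depth) {
  depths <- as.numeric(names(ocr))
  n <- length(rmeas)
  vals <- vapply(ocr, function(cur) {
    cur <- cur[is.finite(cur$value), , drop = FALSE]
    approx(cur$r, cur$value, xout = rmeas, rule = 2)$y
  }, numeric(n))
  if (length(depths) == 1) return(vals[, 1])
  dcl <- pmin(pmax(depth, min(depths)), max(depths))
  k <- findInterval(dcl, depths, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(depths) - 1L)
  w <- (dcl - depths[k]) / (depths[k + 1L] - depths[k])
  vals <- matrix(vals, nrow = n)
  vals[cbind(seq_len(n), k)] * (1 - w) + vals[cbind(seq_len(n), k + 1L)] * w
}

#' @export
print.beam_data <- function(x, ...) {
  ofs <- vapply(x$collimators, function(c) c$output_factor, 0.0)
  cat("<beam_data> collimators:", paste(names(x$collimators), collapse = ", "),
      "mm\n  output factors:", paste(signif(ofs, 4), collapse = ", "),
      "\n  OCR depths:", paste(x$ocr_depths, collapse = ", "), "mm\n")
  invisible(x)
}

#' Effective-path-length ray-tracing dose
#'
#' The comparator dose algorithm. For each voxel and beam:
#' `D = MU * D_ref * OF(c) * T(d_eff) / T(15) * OCR(r, d_eff) * (SAD / SFD)^2`
#' where `d_eff` is the water-equivalent (radiological) depth from the beam
#' entry surface to the voxel along the source ray, `T(d)` is the
#' commissioned PDD with its measurement-geometry inverse square removed
#' (`T(d) = PDD(d)/100 * ((800 + d)/800)^2`), `r` is the off-axis distance
#' scaled onto the SAD plane, and `SFD` the geometric source-to-voxel
#' distance. Depth variation only enters through the effective path length:
#' heterogeneity changes attenuation but not the water-commissioned scatter
#' or penumbra, which is exactly the approximation whose failure in
#' low-density media this engine exists to exhibit.
#'
#' Effective depths beyond the commissioned PDD range are clamped (with a
#' warning); voxels upstream of the beam-entry surface (first voxel with
#' density above `surface_density` along the ray) receive zero dose.
#'
#' `D_ref` is the absolute reference dose (1 cGy per MU at SAD 800 mm and
#' 15 mm depth with the 60 mm collimator) -- the same anchor the Monte Carlo
#' engine is calibrated to, so the two engines share their absolute scale.
#'
#' @param phantom a [voxel_grid()].
#' @param plan a [beam_plan()].
#' @param beam_data a [build_beam_data()] result covering all plan
#'   collimators.
#' @param surface_density beam-entry surface threshold, g/cm^3.
#' @param ref_dose_cgy_per_mu absolute reference dose, cGy per MU.
#' @return A `dose_grid` (zero statistical uncertainty).
#' @export
rt_dose <- function(phantom, plan, beam_data, surface_density = 0.05,
                    ref_dose_cgy_per_mu = 1.0) {
  geom <- grid_geom(phantom)
  dens <- as.numeric(phantom$density)
  mat <- as.integer(phantom$material) - 1L
  nvox <- prod(phantom$dims)
  total <- numeric(nvox)
  sad <- plan$sad
  clamped <- FALSE

  for (j in seq_len(nrow(plan$beams))) {
    b <- plan$beams[j, ]
    if (b$mu == 0) next
    key <- as.character(b$collimator)
    bd <- beam_data$collimators[[key]]
    if (is.null(bd))
      stop("beam data does not cover collimator ", key, " mm")
    dir <- c(b$dir_x, b$dir_y, b$dir_z)
    src <- c(b$iso_x, b$iso_y, b$iso_z) - dir * sad
    g <- .rt_geometry_cpp(geom, dens, mat, src, dir, sad, surface_density)
    dgeom <- g[, 1]; deff <- g[, 2]; rmeas <- g[, 3]; sfd <- g[, 4]

    pdd <- bd$pdd
    tfac <- pdd$value / 100 * ((beam_data$ssd_pdd + pdd$depth) /
                                 beam_data$ssd_pdd)^2
    dmax <- max(pdd$depth)
    if (any(deff > dmax, na.rm = TRUE)) clamped <- TRUE
    dv <- pmin(pmax(deff, 0), dmax)
    tv <- approx(pdd$depth, tfac, xout = dv, rule = 2)$y
    ov <- ocr_value_at(bd$ocr, rmeas, dv)

    # bd$anchor is the same curve product evaluated over the calibration
    # reference region, so 1 MU gives exactly ref_dose at that region
    dose_b <- b$mu * ref_dose_cgy_per_mu * bd$output_factor *
      tv * ov * (sad / sfd)^2 / bd$anchor
    dose_b[is.na(dgeom) | dgeom < 0] <- 0
    total <- total + dose_b
  }
  if (clamped)
    warning("effective depths beyond the commissioned PDD range were clamped")
  dose_grid(phantom, array(total, dim = phantom$dims),
            array(0, dim = phantom$dims), histories = 0L, batches = 0L,
            manifest = list(engine = "raytrace",
                            surface_density = surface_density))
}
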