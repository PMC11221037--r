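#' Extract a percent depth dose curve
#'
#' Central-axis dose versus depth, averaged per depth slab over a small
#' transverse disc, normalized so the maximum is 100.
#'
#' @param dose a `dose_grid` from a water-tank run (beam along +z, surface
#'   at `surface_z`).
#' @param axis_xy beam axis position in the transverse plane, mm.
#' @param surface_z phantom surface plane, mm.
#' @param radius transverse averaging disc radius, mm (enlarged to the
#'   transverse voxel size if smaller).
#' @return data.frame with `depth` (mm) and `value` (max 100).
#' @export
extract_pdd <- function(dose, axis_xy = c(0, 0), surface_z = 0, radius = 3) {
  cx <- dose$origin[1] + (seq_len(dose$dims[1]) - 1) * dose$spacing[1]
  cy <- dose$origin[2] + (seq_len(dose$dims[2]) - 1) * dose$spacing[2]
  cz <- dose$origin[3] + (seq_len(dose$dims[3]) - 1) * dose$spacing[3]
  r <- max(radius, max(dose$spacing[1:2]) * 0.71)
  sel <- outer((cx - axis_xy[1])^2, (cy - axis_xy[2])^2, `+`) <= r^2
  if (!any(sel)) stop("beam axis outside grid")
  v <- apply(dose$dose, 3, function(s) mean(s[sel]))
  keep <- cz >= surface_z
  d <- data.frame(depth = cz[keep] - surface_z, value = v[keep])
  if (max(d$value) <= 0) stop("no dose on the central axis")
  d$value <- 100 * d$value / max(d$value)
  d
}

#' Extract an off-center ratio profile
#'
#' Transverse profile through the beam axis at a given depth, normalized to
#' the central-axis value.
#'
#' @param dose a `dose_grid` (beam along +z).
#' @param depth depth of the measurement plane below `surface_z`, mm.
#' @param axis_xy beam axis position, mm.
#' @param surface_z phantom surface plane, mm.
#' @return data.frame with `r` (signed off-axis position along x, mm) and
#'   `value` (axis value 1).
#' @export
extract_ocr <- function(dose, depth, axis_xy = c(0, 0), surface_z = 0) {
  cz <- dose$origin[3] + (seq_len(dose$dims[3]) - 1) * dose$spacing[3]
  zplane <- surface_z + depth
  if (zplane < cz[1] - dose$spacing[3] / 2 ||
      zplane > cz[length(cz)] + dose$spacing[3] / 2)
    stop("measurement plane outside grid")
  iz <- which.min(abs(cz - zplane))
  cy <- dose$origin[2] + (seq_len(dose$dims[2]) - 1) * dose$spacing[2]
  ys <- which(abs(cy - axis_xy[2]) <= dose$spacing[2] * 0.51)
  prof <- rowMeans(dose$dose[, ys, iz, drop = FALSE])
  cx <- dose$origin[1] + (seq_len(dose$dims[1]) - 1) * dose$spacing[1]
  ax <- prof[which.min(abs(cx - axis_xy[1]))]
  if (ax <= 0) stop("zero dose on the central axis at this depth")
  data.frame(r = cx - axis_xy[1], value = prof / ax)
}

# internal: radial (annulus-averaged) OCR at one depth, with each voxel's
# off-axis radius scaled by sad/(source-to-voxel axial distance) onto the
# measurement plane; this is the per-region curve the source-model fits use.
ocr_radial <- function(dose, depth, ssd, sad = 800, slab_halfwidth = 10,
                       bin_edges = 0:60) {
  cx <- dose$origin[1] + (seq_len(dose$dims[1]) - 1) * dose$spacing[1]
  cy <- dose$origin[2] + (seq_len(dose$dims[2]) - 1) * dose$spacing[2]
  cz <- dose$origin[3] + (seq_len(dose$dims[3]) - 1) * dose$spacing[3]
  zsel <- which(abs(cz - depth) <= slab_halfwidth)
  nb <- length(bin_edges) - 1L
  sums <- numeric(nb); cnts <- numeric(nb)
  for (iz in zsel) {
    scale <- sad / (ssd + cz[iz])
    rr <- sqrt(outer(cx^2, cy^2, `+`)) * scale
    bin <- findInterval(rr, bin_edges, rightmost.closed = FALSE)
    s <- as.numeric(dose$dose[, , iz])
    ok <- bin >= 1 & bin <= nb
    grp <- factor(bin[ok], levels = seq_len(nb))
    sums <- sums + vapply(split(s[ok], grp), sum, 0.0)
    cnts <- cnts + tabulate(bin[ok], nbins = nb)
  }
  val <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  if (!is.finite(val[1]) || val[1] <= 0)
    stop("zero dose in the axial region")
  data.frame(r = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
             value = val / val[1], n = cnts)
}

#' Gamma analysis criteria
#'
#' @param dose_tolerance percent of the global normalization (the reference
#'   maximum).
#' @param dta distance to agreement, mm.
#' @param low_dose_threshold percent of the reference maximum below which
#'   reference voxels are excluded (default 10).
#' @export
gamma_criteria <- function(dose_tolerance, dta, low_dose_threshold = 10) {
  if (dose_tolerance <= 0 || dta <= 0 || low_dose_threshold <= 0)
    stop("criteria must be strictly positive")
  structure(list(dose_tolerance = dose_tolerance, dta = dta,
                 low_dose_threshold = low_dose_threshold,
                 normalization = "global"),
            class = "gamma_criteria")
}

#' @export
format.gamma_criteria <- function(x, ...) {
  sprintf("%g%%/%g mm", x$dose_tolerance, x$dta)
}

#' 3D global gamma analysis
#'
#' For each reference voxel with dose at or above the low-dose threshold,
#' the gamma index is the minimum over a trilinearly interpolated
#' neighbourhood of the evaluated distribution (sampled every
#' `step_factor * dta` within `radius_factor * dta`) of
#' `sqrt((dD / (tol% * max_ref))^2 + (dr / dta)^2)`. Pass rate is the
#' percentage of evaluated voxels with gamma <= 1. Absolute dose
#' comparison, global normalization to the reference maximum.
#'
#' @param ref,eval `dose_grid` objects on identical geometry (reference
#'   first; pass rates are not symmetric).
#' @param criteria a [gamma_criteria()].
#' @param radius_factor,step_factor search radius and step in units of dta.
#' @return A `gamma_result` with per-voxel `gamma`, the evaluated-voxel
#'   `mask`, and `pass_rate` (percent).
#' @export
gamma_3d <- function(ref, eval, criteria, radius_factor = 3,
                     step_factor = 0.1) {
  if (!same_geometry(ref, eval)) stop("dose grids must share geometry")
  mx <- max(ref$dose)
  res <- .gamma_cpp(as.numeric(ref$dose), as.numeric(eval$dose),
                    as.integer(ref$dims), as.numeric(ref$spacing),
                    criteria$dose_tolerance / 100 * mx, criteria$dta,
                    criteria$low_dose_threshold / 100 * mx,
                    radius_factor, step_factor)
  structure(list(gamma = array(res$gamma, dim = ref$dims),
                 mask = array(res$mask, dim = ref$dims),
                 pass_rate = res$pass_rate,
                 n_evaluated = res$n_evaluated, criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat("<gamma_result> ", format(x$criteria), ": pass rate ",
      sprintf("%.2f%%", x$pass_rate), " over ", x$n_evaluated,
      " voxels\n", sep = "")
  invisible(x)
}

#' Voxel-wise dose difference
#'
#' `dD = D_g - D_c`, optionally restricted to a body mask (voxels outside
#' the mask are set to NA).
#'
#' @param Dg,Dc `dose_grid` objects on identical geometry.
#' @param body_mask optional [structure_mask()].
#' @return 3D array of dose differences.
#' @export
dose_difference <- function(Dg, Dc, body_mask = NULL) {
  if (!same_geometry(Dg, Dc)) stop("dose grids must share geometry")
  d <- Dg$dose - Dc$dose
  if (!is.null(body_mask)) {
    if (!same_geometry(Dg, body_mask)) stop("mask geometry mismatch")
    d[!body_mask$mask] <- NA_real_
  }
  d
}

#' DVH point metrics
#'
#' `D_mean` is the arithmetic mean over the structure; `D_i` is the minimum
#' dose received by the hottest i% of the structure volume, i.e. the
#' (100 - i)th percentile (from the bottom) of the within-structure dose
#' distribution, with linear interpolation of order statistics
#' (`stats::quantile` type 7).
#'
#' @param dose a `dose_grid`.
#' @param mask a non-empty [structure_mask()] on the same geometry.
#' @return list with `D_mean`, `D_2`, `D_95` (cGy).
#' @export
dvh_metrics <- function(dose, mask) {
  if (!same_geometry(dose, mask)) stop("mask geometry mismatch")
  v <- dose$dose[mask$mask]
  if (length(v) == 0) stop("empty structure mask")
  list(D_mean = mean(v),
       D_2 = unname(quantile(v, 0.98, type = 7)),
       D_95 = unname(quantile(v, 0.05, type = 7)))
}
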