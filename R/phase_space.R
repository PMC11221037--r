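#' Energy spectrum histogram
#'
#' @param edges increasing bin edges, MeV.
#' @param probs per-bin probabilities (non-negative; normalized to sum 1).
#' @export
energy_spectrum <- function(edges, probs) {
  if (length(edges) != length(probs) + 1L || any(diff(edges) <= 0))
    stop("edges must be increasing with length(probs) + 1")
  if (any(probs < 0) || sum(probs) <= 0) stop("invalid probabilities")
  structure(list(edges = as.numeric(edges),
                 probs = as.numeric(probs) / sum(probs)),
            class = "energy_spectrum")
}

#' Default beam spectrum
#'
#' A flattening-filter-free-like 6 MV bremsstrahlung histogram,
#' `p(E) ~ E * exp(-E / 0.75)` discretized on 24 log-spaced bins over
#' 0.05-7 MeV; mean energy about 1.5 MeV.
#'
#' @export
default_spectrum <- function() {
  edges <- exp(seq(log(0.05), log(7), length.out = 25))
  mid <- (edges[-1] + edges[-25]) / 2
  w <- mid * exp(-mid / 0.75) * diff(edges)
  energy_spectrum(edges, w)
}

sample_energies <- function(spectrum, n) {
  k <- sample.int(length(spectrum$probs), n, replace = TRUE,
                  prob = spectrum$probs)
  runif(n, spectrum$edges[k], spectrum$edges[k + 1L])
}

# evaluate/restore R's RNG around seeded generation
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Synthetic phase space for the 60 mm collimator
#'
#' Generates weighted particle records on a scoring plane `plane_z` mm
#' downstream of the source (beam-local frame, source at z = 0, axis +z).
#' The model is a Gaussian focal spot firing through a cone whose projection
#' at the source-axis distance (`sad`) is a disc of `cone_radius`; a small
#' `halo_fraction` of particles is aimed into a wider disc
#' (`halo_radius`) emulating collimator scatter and leakage so that the
#' whole 0-60 mm radial correction domain carries fluence. Energies are
#' drawn from `spectrum`; all weights start at 1. Deterministic given
#' `seed`.
#'
#' @param spectrum an [energy_spectrum()].
#' @param focal_spot_sigma Gaussian focal spot sigma, mm.
#' @param plane_z scoring plane distance from source, mm (> 0).
#' @param n number of particles (> 0).
#' @param seed integer seed.
#' @param cone_radius primary aperture projection radius at `sad`, mm.
#' @param halo_fraction fraction of particles aimed into the halo disc.
#' @param halo_radius halo projection radius at `sad`, mm.
#' @param sad source-axis distance defining the projection plane, mm.
#' @return A `phase_space` object.
#' @export
generate_phase_space <- function(spectrum = default_spectrum(),
                                 focal_spot_sigma = 1.0, plane_z = 400,
                                 n, seed, cone_radius = 30,
                                 halo_fraction = 0.05, halo_radius = 65,
                                 sad = 800) {
  if (n <= 0) stop("n must be positive")
  if (plane_z <= 0) stop("plane_z must be positive")
  with_seed(seed, {
    halo <- runif(n) < halo_fraction
    rad <- ifelse(halo, halo_radius, cone_radius) * sqrt(runif(n))
    phi <- runif(n, 0, 2 * pi)
    ax <- rad * cos(phi); ay <- rad * sin(phi)
    fx <- rnorm(n, 0, focal_spot_sigma); fy <- rnorm(n, 0, focal_spot_sigma)
    dx <- ax - fx; dy <- ay - fy; dz <- sad
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    u <- dx / nrm; v <- dy / nrm; w <- dz / nrm
    t <- plane_z / w
    particles <- data.frame(
      energy = sample_energies(spectrum, n),
      x = fx + t * u, y = fy + t * v,
      u = u, v = v, w = w, weight = rep(1.0, n))
    phase_space(particles, plane_z = plane_z, collimator = 60,
                provenance = list(seed = seed, n = n,
                                  focal_spot_sigma = focal_spot_sigma,
                                  cone_radius = cone_radius,
                                  halo_fraction = halo_fraction,
                                  halo_radius = halo_radius, sad = sad))
  })
}

#' Phase space container
#'
#' @param particles data.frame with columns `energy` (MeV), `x`, `y` (mm on
#'   the scoring plane), `u`, `v`, `w` (unit direction, `w > 0`), `weight`.
#' @param plane_z scoring plane distance from source, mm.
#' @param collimator projection diameter, mm (one of 5, 7.5, 10, 12.5, 15,
#'   20, 25, 30, 35, 40, 50, 60).
#' @param provenance free-form metadata list.
#' @export
phase_space <- function(particles, plane_z, collimator = 60,
                        provenance = list()) {
  stopifnot(all(c("energy", "x", "y", "u", "v", "w", "weight") %in%
                  names(particles)))
  if (plane_z <= 0) stop("plane_z must be positive")
  allowed <- c(5, 7.5, 10, 12.5, 15, 20, 25, 30, 35, 40, 50, 60)
  if (!collimator %in% allowed)
    stop("collimator_diameter must be one of: ",
         paste(allowed, collapse = ", "))
  nrm <- particles$u^2 + particles$v^2 + particles$w^2
  if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit vectors")
  if (any(particles$w <= 0)) stop("axial direction component must be > 0")
  if (any(!is.finite(particles$weight)) || any(particles$weight < 0))
    stop("weights must be finite and non-negative")
  structure(list(particles = particles, plane_z = plane_z,
                 collimator = collimator, provenance = provenance),
            class = "phase_space")
}

#' @export
print.phase_space <- function(x, ...) {
  cat("<phase_space> ", nrow(x$particles), " particles at plane_z = ",
      x$plane_z, " mm, collimator ", x$collimator, " mm, total weight ",
      signif(sum(x$particles$weight), 6), "\n", sep = "")
  invisible(x)
}

#' Straight-line projection radius
#'
#' Radial distance from the beam axis of each particle's straight-line
#' extension from its scoring plane to another plane.
#'
#' @param ps a `phase_space` (or its particle data.frame).
#' @param plane_z_from plane the positions refer to, mm from source.
#' @param plane_z_to target plane, mm from source.
#' @return numeric vector of radii, mm.
#' @export
projection_radius <- function(ps, plane_z_from = NULL, plane_z_to = 800) {
  p <- if (inherits(ps, "phase_space")) ps$particles else ps
  if (is.null(plane_z_from)) {
    if (!inherits(ps, "phase_space"))
      stop("plane_z_from required when passing a raw particle table")
    plane_z_from <- ps$plane_z
  }
  if (any(p$w <= 0)) stop("invalid particle: axial direction component <= 0")
  t <- (plane_z_to - plane_z_from) / p$w
  sqrt((p$x + t * p$u)^2 + (p$y + t * p$v)^2)
}

#' Radial correction coefficients
#'
#' 60 positive coefficients over half-open 1 mm radial bins `[k, k+1)` mm,
#' `k = 0..59`, on the projection plane.
#'
#' @param coefficients numeric vector of length 60, positive and finite.
#' @param trace optional fit convergence trace.
#' @export
radial_correction <- function(coefficients, trace = NULL) {
  if (length(coefficients) != 60L)
    stop("exactly 60 radial bins are required")
  if (any(!is.finite(coefficients)) || any(coefficients <= 0))
    stop("coefficients must be positive and finite")
  structure(list(bin_edges = 0:60, coefficients = as.numeric(coefficients),
                 trace = trace),
            class = "radial_correction")
}

#' Apply radial correction to a phase space
#'
#' Each particle's weight is multiplied by the coefficient of the 1 mm bin
#' containing its projection radius on the projection plane; radii of 60 mm
#' or more are outside the corrected disc and left unchanged.
#'
#' @param ps a `phase_space`.
#' @param corr a [radial_correction()].
#' @param projection_plane_z projection plane, mm from source (default 800,
#'   where the collimator projection diameter is defined).
#' @export
apply_radial_correction <- function(ps, corr, projection_plane_z = 800) {
  rp <- projection_radius(ps, plane_z_to = projection_plane_z)
  fac <- rep(1.0, length(rp))
  inb <- rp < 60
  fac[inb] <- corr$coefficients[floor(rp[inb]) + 1L]
  ps$particles$weight <- ps$particles$weight * fac
  ps
}

#' Aperture correction factors
#'
#' The four-factor correction used to derive a smaller collimator from the
#' corrected 60 mm phase space: a hard aperture of radius `R` (projection
#' radius beyond `R` is zeroed) plus penumbra reweighting bands for
#' near-axial particles (axial direction cosine above
#' `axial_cosine_threshold`): weight `W1` on `[R, R + delta_R1]`, `W2` on
#' `[R - delta_R2, R]`.
#'
#' @param R collimator projection radius, mm.
#' @param delta_R1,delta_R2 band widths, mm, >= 0 with `R - delta_R2 >= 0`.
#' @param W1,W2 replacement weights, >= 0.
#' @param axial_cosine_threshold default 0.99.
#' @export
aperture_factors <- function(R, delta_R1, delta_R2, W1, W2,
                             axial_cosine_threshold = 0.99) {
  if (delta_R1 < 0 || delta_R2 < 0 || R - delta_R2 < 0)
    stop("band widths must be >= 0 with R - delta_R2 >= 0")
  if (W1 < 0 || W2 < 0 || !all(is.finite(c(R, delta_R1, delta_R2, W1, W2))))
    stop("factors must be finite and non-negative")
  structure(list(R = R, delta_R1 = delta_R1, delta_R2 = delta_R2,
                 W1 = W1, W2 = W2,
                 axial_cosine_threshold = axial_cosine_threshold),
            class = "aperture_factors")
}

#' Collimate a phase space with aperture factors
#'
#' Rules applied in order: (1) weight set to 0 where the projection radius
#' exceeds `R`; (2) for near-axial particles (direction cosine along the
#' axis above the threshold) the weight is *replaced* by `W1` on
#' `[R, R + delta_R1]` and by `W2` on `[R - delta_R2, R]` (the inner band
#' wins at exactly `R`). All other particles are unchanged.
#'
#' @param ps a `phase_space` (the radially corrected 60 mm phase space).
#' @param factors an [aperture_factors()].
#' @param projection_plane_z projection plane, mm from source.
#' @export
collimate <- function(ps, factors, projection_plane_z = 800) {
  rp <- projection_radius(ps, plane_z_to = projection_plane_z)
  wt <- ps$particles$weight
  wt[rp > factors$R] <- 0
  axial <- ps$particles$w > factors$axial_cosine_threshold
  b1 <- axial & rp >= factors$R & rp <= factors$R + factors$delta_R1
  wt[b1] <- factors$W1
  b2 <- axial & rp >= factors$R - factors$delta_R2 & rp <= factors$R
  wt[b2] <- factors$W2
  ps$particles$weight <- wt
  ps$collimator <- 2 * factors$R
  ps$provenance$aperture <- unclass(factors)
  ps
}
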