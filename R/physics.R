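# Embedded photon cross sections and electron CSDA ranges.
# Tables ship as CSV under inst/extdata/physics (see the README there for the
# generating model); photon mass attenuation is interpolated log-log in
# energy, CSDA mass range linearly in log(energy).

.physics_env <- new.env(parent = emptyenv())

physics_tables <- function() {
  if (!is.null(.physics_env$tab)) return(.physics_env$tab)
  dir <- system.file("extdata", "physics", package = "irisdose")
  xs <- read.csv(file.path(dir, "photon_xs.csv"))
  csda <- read.csv(file.path(dir, "electron_csda_water.csv"))
  mats <- unique(xs$material)
  per <- lapply(mats, function(m) {
    t <- xs[xs$material == m, ]
    t <- t[order(t$energy_mev), ]
    list(energy = t$energy_mev,
         logE = log(t$energy_mev),
         log_pe = log(t$mu_pe),
         log_co = log(t$mu_compton),
         log_ra = log(t$mu_rayleigh),
         total = t$mu_total)
  })
  names(per) <- mats
  .physics_env$tab <- list(
    xs = per,
    csda = list(logE = log(csda$energy_mev), range = csda$csda_g_cm2),
    energy_range = range(xs$energy_mev))
  .physics_env$tab
}

check_energy_range <- function(E) {
  rng <- physics_tables()$energy_range
  if (any(E < rng[1] - 1e-12) || any(E > rng[2] + 1e-12))
    stop(sprintf("energy out of table range [%g, %g] MeV", rng[1], rng[2]))
}

loglog_interp <- function(logx, logy, E) {
  exp(approx(logx, logy, xout = log(E), rule = 1)$y)
}

#' Linear attenuation components
#'
#' Log-log interpolation of the embedded mass attenuation tables, scaled by
#' the mass density. Energies outside the table range raise an error (no
#' extrapolation).
#'
#' @param material catalog material name ("water", "lung", "bone", "air").
#' @param E photon energy, MeV (vectorized).
#' @param density mass density, g/cm^3.
#' @return data.frame with columns `mu_pe`, `mu_compton`, `mu_rayleigh`,
#'   `mu_total`, all in 1/cm.
#' @export
mu_components <- function(material, E, density) {
  tab <- physics_tables()$xs[[material]]
  if (is.null(tab)) stop("unknown material: ", material)
  check_energy_range(E)
  pe <- loglog_interp(tab$logE, tab$log_pe, E) * density
  co <- loglog_interp(tab$logE, tab$log_co, E) * density
  ra <- loglog_interp(tab$logE, tab$log_ra, E) * density
  data.frame(mu_pe = pe, mu_compton = co, mu_rayleigh = ra,
             mu_total = pe + co + ra)
}

#' Sample the photon interaction type
#'
#' Partitions `[0, 1)` by the relative attenuation components at energy `E`:
#' photoelectric for `u < mu_pe/mu_tot`, Compton for
#' `u < (mu_pe + mu_compton)/mu_tot`, otherwise Rayleigh.
#'
#' @param material catalog material name.
#' @param E photon energy, MeV.
#' @param u uniform deviates in `[0, 1)` (vectorized).
#' @return character vector: "photoelectric", "compton" or "rayleigh".
#' @export
sample_interaction <- function(material, E, u) {
  mu <- mu_components(material, E, 1.0)
  p1 <- mu$mu_pe / mu$mu_total
  p2 <- (mu$mu_pe + mu$mu_compton) / mu$mu_total
  ifelse(u < p1, "photoelectric", ifelse(u < p2, "compton", "rayleigh"))
}

#' Electron CSDA range
#'
#' Mass CSDA range interpolated linearly in log(E) from the embedded water
#' table, divided by the mass density and converted to mm. The same mass
#' range curve is used for every catalog material (low-Z media agree to a
#' few percent).
#'
#' @param material catalog material name (selects nothing but is kept for
#'   the table interface; see details).
#' @param E electron kinetic energy, MeV (vectorized).
#' @param density mass density, g/cm^3.
#' @return Range in mm.
#' @export
csda_range <- function(material, E, density) {
  tab <- physics_tables()$csda
  rng <- range(exp(tab$logE))
  if (any(E < rng[1] - 1e-12) || any(E > rng[2] + 1e-12))
    stop(sprintf("energy out of CSDA table range [%g, %g] MeV",
                 rng[1], rng[2]))
  r_mass <- approx(tab$logE, tab$range, xout = log(E), rule = 1)$y
  r_mass / density * 10  # g/cm2 / (g/cm3) = cm -> mm
}

# internal: per-material matrices (logE, log_pe, log_co, log_ra) in the order
# of a grid's material catalog, for the C++ kernels
xs_for_grid <- function(grid) {
  tabs <- physics_tables()$xs
  lapply(grid$materials$name, function(m) {
    t <- tabs[[m]]
    if (is.null(t)) stop("no cross-section table for material: ", m)
    cbind(t$logE, t$log_pe, t$log_co, t$log_ra)
  })
}

csda_for_cpp <- function() {
  t <- physics_tables()$csda
  cbind(t$logE, t$range)
}
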