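#' Electrochemical parameters of an alloy/solution pair
#'
#' Bundles the quantities that govern whether crevice corrosion can be
#' sustained: the passivation potential `e_pass` (below which the surface
#' dissolves actively), the passive current density `i_pass` feeding the
#' crevice's cumulative anodic current, the corrosion potential `e_corr`
#' (below which net anodic dissolution is negligible), and the potential
#' `e_out` applied or established on the metal outside the crevice. All
#' potentials are V vs Ag/AgCl; `i_pass` is given in mA/cm^2 (the usual
#' reporting unit) and also stored as mA/mm^2 for use with mm-based geometry.
#'
#' @param name Label for the alloy/solution pair.
#' @param e_pass Passivation potential, V vs Ag/AgCl.
#' @param i_pass Passive current density, mA/cm^2 (> 0).
#' @param e_corr Corrosion potential, V vs Ag/AgCl; must not exceed `e_pass`
#'   (the active domain is delimited by `e_corr` and `e_pass`).
#' @param e_out Applied/outer potential, V vs Ag/AgCl. A warning (not an
#'   error) is raised if `e_out <= e_pass`, since the outer surface is then
#'   not meaningfully passive.
#' @return An object of class `material_electrochem` with the fields above
#'   plus `i_pass_mm` (mA/mm^2).
#' @export
material_electrochem <- function(name, e_pass, i_pass, e_corr, e_out) {
  if (!is.numeric(i_pass) || i_pass <= 0)
    stop("i_pass must be positive (mA/cm^2)", call. = FALSE)
  if (e_corr > e_pass)
    stop("e_corr must not exceed e_pass (active domain is [e_corr, e_pass])",
         call. = FALSE)
  if (e_out <= e_pass)
    warning("e_out <= e_pass: the outer surface is not passive at e_out",
            call. = FALSE)
  structure(list(name = as.character(name), e_pass = e_pass, i_pass = i_pass,
                 i_pass_mm = i_pass * 0.01, e_corr = e_corr, e_out = e_out),
            class = "material_electrochem")
}

#' @export
print.material_electrochem <- function(x, ...) {
  cat(sprintf("material_electrochem: %s\n", x$name))
  cat(sprintf("  E_pass = %g V, i_pass = %g mA/cm^2, E_corr = %g V, E_out = %g V (Ag/AgCl)\n",
              x$e_pass, x$i_pass, x$e_corr, x$e_out))
  invisible(x)
}

#' Electrolyte conductivity / resistivity
#'
#' Either the conductivity (mS/cm, as conductivity meters report it) or the
#' resistivity (Ohm mm, as the resistance model consumes it) may be given;
#' the other is derived via `rho * kappa = 1e4` (Ohm mm x mS/cm). When both
#' are supplied they must be consistent to 1e-6 relative.
#'
#' @param conductivity Conductivity, mS/cm.
#' @param rho Resistivity, Ohm mm.
#' @param ph Solution pH (informational).
#' @return An object of class `electrolyte` with `conductivity`, `rho`, `ph`.
#' @export
electrolyte <- function(conductivity = NULL, rho = NULL, ph = NA_real_) {
  if (is.null(conductivity) && is.null(rho))
    stop("supply conductivity (mS/cm) or rho (Ohm mm)", call. = FALSE)
  if (is.null(rho)) rho <- resistivity_from_conductivity(conductivity)
  if (is.null(conductivity)) conductivity <- 1e4 / rho
  if (conductivity <= 0 || rho <= 0)
    stop("conductivity and rho must be positive", call. = FALSE)
  if (abs(rho * conductivity - 1e4) > 1e-6 * 1e4)
    stop("inconsistent conductivity and rho: rho * kappa must equal 1e4",
         call. = FALSE)
  structure(list(conductivity = conductivity, rho = rho, ph = ph),
            class = "electrolyte")
}

#' @export
print.electrolyte <- function(x, ...) {
  cat(sprintf("electrolyte: kappa = %g mS/cm (rho = %.4g Ohm mm), pH = %s\n",
              x$conductivity, x$rho, format(x$ph)))
  invisible(x)
}

#' Convert conductivity to resistivity
#'
#' `rho (Ohm mm) = 1e4 / kappa (mS/cm)`; e.g. 28.3 mS/cm gives 353.4 Ohm mm.
#'
#' @param kappa Conductivity, mS/cm (> 0).
#' @return Resistivity, Ohm mm.
#' @export
resistivity_from_conductivity <- function(kappa) {
  if (!is.numeric(kappa) || any(kappa <= 0))
    stop("kappa must be positive (mS/cm)", call. = FALSE)
  1e4 / kappa
}

#' Hydronium inventory of a crevice volume
#'
#' Moles of H3O+ initially available in the occluded solution: volume times
#' concentration.
#'
#' @param volume Crevice solution volume, cm^3.
#' @param concentration Hydronium concentration, mol/L.
#' @return Amount, mol.
#' @export
hydronium_inventory <- function(volume, concentration) {
  if (volume <= 0 || concentration <= 0)
    stop("volume and concentration must be positive", call. = FALSE)
  (volume / 1000) * concentration
}

#' Faraday's-law molar flux from a current density
#'
#' Converts an electrode current density to the molar flux of the reacting
#' species: `flux = i / (z * F)` with F = 96485 C/mol. For proton reduction
#' (H+ + e- -> 1/2 H2), z = 1.
#'
#' @param current_density Current density, mA/cm^2 (> 0).
#' @param electrons_per_ion Electrons transferred per ion, z (>= 1; default 1).
#' @return Molar flux, mol/(s cm^2).
#' @export
faraday_flux <- function(current_density, electrons_per_ion = 1L) {
  if (current_density <= 0)
    stop("current_density must be positive", call. = FALSE)
  if (electrons_per_ion < 1)
    stop("electrons_per_ion must be >= 1", call. = FALSE)
  (current_density / 1000) / (electrons_per_ion * 96485)
}

#' Time to deplete an ion inventory by electrode consumption
#'
#' Given the available amount, the area-specific molar consumption flux and
#' the reacting area, returns the total consumption rate and the time until
#' the inventory is exhausted (at constant rate).
#'
#' @param inventory Amount available, mol (>= 0).
#' @param flux Molar flux, mol/(s cm^2) (> 0).
#' @param area Reacting area, cm^2 (> 0).
#' @return List with `rate` (mol/s) and `time` (s).
#' @export
depletion_time <- function(inventory, flux, area) {
  if (inventory < 0) stop("inventory must be non-negative", call. = FALSE)
  if (flux <= 0 || area <= 0)
    stop("flux and area must be positive", call. = FALSE)
  rate <- flux * area
  list(rate = rate, time = inventory / rate)
}

#' Polarization curve container
#'
#' A potentiodynamic sweep: potentials (V vs Ag/AgCl, monotone) and the
#' corresponding signed current densities (mA/cm^2, anodic positive).
#'
#' @param potentials Numeric, monotone, length >= 10.
#' @param current_densities Numeric, same length, signed.
#' @return An object of class `polarization_curve`.
#' @export
polarization_curve <- function(potentials, current_densities) {
  if (length(potentials) < 10L)
    stop("a polarization curve needs at least 10 samples", call. = FALSE)
  if (length(potentials) != length(current_densities))
    stop("potentials and current_densities must have the same length",
         call. = FALSE)
  d <- diff(potentials)
  if (!(all(d > 0) || all(d < 0)))
    stop("potentials must be monotone", call. = FALSE)
  structure(list(potentials = as.numeric(potentials),
                 current_densities = as.numeric(current_densities)),
            class = "polarization_curve")
}

#' Read a polarization curve from a two-column text file
#'
#' Two numeric columns, E (V vs Ag/AgCl) and i (mA/cm^2, signed); comment
#' lines start with `#`.
#'
#' @param path File path.
#' @return A [polarization_curve()].
#' @export
read_polarization_file <- function(path) {
  dat <- read_two_columns(path)
  polarization_curve(dat[[1]], dat[[2]])
}

#' Tafel extrapolation of corrosion potential and current density
#'
#' Fits straight lines to `log10|i|` vs E inside user-chosen anodic and
#' cathodic potential windows (one on each side of the zero-current
#' crossing) and intersects them. The intersection potential estimates
#' E_corr and the current there estimates i_corr.
#'
#' @param curve A [polarization_curve()].
#' @param anodic_window Length-2 numeric, potential range (V) of the anodic
#'   Tafel region.
#' @param cathodic_window Length-2 numeric, potential range (V) of the
#'   cathodic Tafel region.
#' @param min_points Minimum samples with non-zero current required in each
#'   window (default 5).
#' @return List with `e_corr` (V), `i_corr` (mA/cm^2, > 0) and the two fitted
#'   slopes (`anodic_slope`, `cathodic_slope`, decades/V).
#' @export
tafel_extrapolate <- function(curve, anodic_window, cathodic_window,
                              min_points = 5L) {
  stopifnot(inherits(curve, "polarization_curve"))
  fit_branch <- function(window, label) {
    window <- sort(window)
    sel <- curve$potentials >= window[1] & curve$potentials <= window[2] &
      abs(curve$current_densities) > 0
    if (sum(sel) < min_points)
      stop(sprintf("%s window contains %d usable samples; >= %d required",
                   label, sum(sel), min_points), call. = FALSE)
    stats::lm(log10(abs(curve$current_densities[sel])) ~
                curve$potentials[sel])
  }
  fa <- fit_branch(anodic_window, "anodic")
  fc <- fit_branch(cathodic_window, "cathodic")
  sgn_a <- sign(mean(curve$current_densities[
    curve$potentials >= min(anodic_window) &
      curve$potentials <= max(anodic_window)]))
  sgn_c <- sign(mean(curve$current_densities[
    curve$potentials >= min(cathodic_window) &
      curve$potentials <= max(cathodic_window)]))
  if (sgn_a == sgn_c)
    warning("anodic and cathodic windows lie on the same side of the ",
            "zero-current crossing", call. = FALSE)
  ca <- stats::coef(fa); cc <- stats::coef(fc)
  dslope <- ca[2] - cc[2]
  if (!is.finite(dslope) || abs(dslope) < 1e-8)
    stop("degenerate Tafel fit: branch slopes are parallel or undefined",
         call. = FALSE)
  e_corr <- as.numeric((cc[1] - ca[1]) / dslope)
  i_corr <- as.numeric(10^(ca[1] + ca[2] * e_corr))
  list(e_corr = e_corr, i_corr = i_corr,
       anodic_slope = as.numeric(ca[2]), cathodic_slope = as.numeric(cc[2]))
}
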