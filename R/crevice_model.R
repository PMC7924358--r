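#' Electrolyte resistance of one crevice section
#'
#' The solution in the crevice occupies a thin annulus between the trunnion
#' (radius `r_int`) and the bore (radius `r_int + gap`). One axial section of
#' length `dx` has resistance
#' `R_i = rho * dx / (pi * ((r_int + gap)^2 - r_int^2))`.
#'
#' @param rho Electrolyte resistivity, Ohm mm.
#' @param dx Section length, mm.
#' @param r_int Inner (trunnion) radius, mm.
#' @param gap Local gap, mm (> 0; upstream clamping guarantees this).
#' @return Resistance, Ohm.
#' @export
segment_resistance <- function(rho, dx, r_int, gap) {
  if (rho <= 0 || dx <= 0 || r_int <= 0)
    stop("rho, dx and r_int must be positive", call. = FALSE)
  if (any(gap <= 0))
    stop("gap must be positive (clamp to the gap floor upstream)",
         call. = FALSE)
  rho * dx / (pi * ((r_int + gap)^2 - r_int^2))
}

#' Cumulative electrolyte resistance along the crevice
#'
#' Sums the per-section annulus resistances from the crevice mouth (x = 0,
#' where the circuit to the outer reference closes, so R(0) = 0) up to each
#' depth. The discrete sum uses the trapezoidal rule on the annulus
#' integrand, i.e. adjacent sections are averaged, which converges to the
#' continuous line-resistance integral as dx shrinks.
#'
#' @param geometry A [crevice_geometry()].
#' @param electrolyte An [electrolyte()].
#' @param gap A [build_gap_profile()] result, or a bare numeric gap trace
#'   (mm) on the geometry's grid.
#' @return Numeric vector R(x), Ohm: non-negative, non-decreasing, R(0) = 0.
#' @export
cumulative_resistance <- function(geometry, electrolyte, gap) {
  stopifnot(inherits(geometry, "crevice_geometry"),
            inherits(electrolyte, "electrolyte"))
  g <- if (inherits(gap, "gap_profile")) gap$gap else as.numeric(gap)
  if (any(g <= 0)) stop("gap trace must be positive", call. = FALSE)
  f <- electrolyte$rho /
    (pi * ((geometry$r_int + g)^2 - geometry$r_int^2))  # Ohm/mm
  dx <- geometry$dx
  c(0, cumsum(dx * (f[-length(f)] + f[-1]) / 2))
}

#' Closed-form resistance of a smooth (zero-roughness) conical crevice
#'
#' For a gap `g(x) = tan(alpha) * (L - x) + C` the line-resistance integral
#' has the antiderivative
#' `R(x) = rho / (2 pi r_int tan(alpha)) *
#'   ln( g(0) (2 r_int + g(x)) / ( g(x) (2 r_int + g(0)) ) )`.
#' Used as an independent analytic reference for the discrete summation.
#'
#' @param geometry A [crevice_geometry()].
#' @param electrolyte An [electrolyte()].
#' @param x Depths from the mouth, mm (must keep `g(x) > 0`).
#' @param c_max Constant gap offset C, mm (default 0).
#' @return Numeric vector R(x), Ohm.
#' @export
smooth_cone_resistance <- function(geometry, electrolyte, x, c_max = 0) {
  stopifnot(inherits(geometry, "crevice_geometry"),
            inherits(electrolyte, "electrolyte"))
  tana <- tan(geometry$alpha * pi / 180)
  r <- geometry$r_int
  g0 <- tana * geometry$length_L + c_max
  gx <- tana * (geometry$length_L - x) + c_max
  if (any(gx <= 0))
    stop("g(x) must stay positive for the closed form", call. = FALSE)
  electrolyte$rho / (2 * pi * r * tana) *
    log(g0 * (2 * r + gx) / (gx * (2 * r + g0)))
}

#' Cumulative passive (anodic) current at depth x
#'
#' Every element of trunnion surface between the mouth and depth x feeds its
#' passive current through the electrolyte path to the outer cathode, so the
#' current crossing the section at x is the passive current density times
#' the lateral cylinder area from the mouth to x:
#' `I_pass(x) = i_pass * 2 pi r_int * x`. The alternative convention
#' `"deep"` collects the current from the surface deeper than x instead
#' (`~ (L - x)`).
#'
#' @param i_pass Passive current density, mA/mm^2 (note: mm-based; divide a
#'   mA/cm^2 figure by 100, or use the `i_pass_mm` field of
#'   [material_electrochem()]).
#' @param r_int Trunnion radius, mm.
#' @param x Depths from the mouth, mm.
#' @param convention `"mouth"` (default, cumulative from the mouth) or
#'   `"deep"` (collected from beyond x); requires `length_L` for `"deep"`.
#' @param length_L Crevice length, mm (only used by `"deep"`).
#' @return Current, mA; I_pass(0) = 0 under the default convention.
#' @export
passive_current <- function(i_pass, r_int, x,
                            convention = c("mouth", "deep"),
                            length_L = NULL) {
  convention <- match.arg(convention)
  if (i_pass <= 0 || r_int <= 0)
    stop("i_pass and r_int must be positive", call. = FALSE)
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  if (convention == "mouth") {
    i_pass * 2 * pi * r_int * x
  } else {
    if (is.null(length_L))
      stop("length_L is required for the 'deep' convention", call. = FALSE)
    i_pass * 2 * pi * r_int * (length_L - x)
  }
}

#' IR-drop potential distribution inside the crevice
#'
#' The potential at depth x is the outer potential minus the ohmic drop of
#' the cumulative passive current across the cumulative electrolyte
#' resistance: `E(x) = E_out - I_pass(x) * R(x)`. With I in mA and R in Ohm
#' the product is in mV and is converted to V. The expression treats
#' I_pass as a net anodic current, which holds only while E(x) stays above
#' E_corr; deeper samples are still computed but flagged as outside the
#' model's validity.
#'
#' @param material A [material_electrochem()].
#' @param R_trace Cumulative resistance R(x), Ohm.
#' @param I_trace Cumulative current I_pass(x), mA (same grid).
#' @return List with `E` (V vs Ag/AgCl), `drop_mV` (`E_out - E(x)` in mV) and
#'   `valid` (logical, `E >= e_corr`).
#' @export
potential_profile <- function(material, R_trace, I_trace) {
  stopifnot(inherits(material, "material_electrochem"))
  if (length(R_trace) != length(I_trace))
    stop("R_trace and I_trace must share the grid", call. = FALSE)
  drop_mV <- I_trace * R_trace            # mA * Ohm = mV
  E <- material$e_out - drop_mV / 1000
  list(E = E, drop_mV = drop_mV, valid = E >= material$e_corr)
}

#' Classify crevice depths into corrosion zones
#'
#' Applies the sustainment criterion: a depth is `passive` while
#' `E > E_pass` (the film is maintained), `active` while
#' `E_corr < E <= E_pass` (the surface dissolves actively — crevice
#' corrosion is sustainable there), and `negligible` once `E <= E_corr`
#' (anodic kinetics shut down). Threshold crossing depths are located by
#' linear interpolation between adjacent grid samples.
#'
#' @param E_trace Potential E(x), V vs Ag/AgCl.
#' @param material A [material_electrochem()].
#' @param x Depths, mm (same grid as `E_trace`).
#' @return List with `zone` (character vector), `e_pass_crossing_mm`,
#'   `e_corr_crossing_mm` (NA when no crossing), and `verdict`
#'   (`"crevice corrosion sustainable"` iff any sample is active, else
#'   `"no crevice corrosion"`).
#' @export
classify_zones <- function(E_trace, material, x) {
  stopifnot(inherits(material, "material_electrochem"))
  if (length(E_trace) != length(x))
    stop("E_trace and x must share the grid", call. = FALSE)
  zone <- ifelse(E_trace > material$e_pass, "passive",
                 ifelse(E_trace > material$e_corr, "active", "negligible"))
  list(zone = zone,
       e_pass_crossing_mm = first_crossing(x, E_trace, material$e_pass),
       e_corr_crossing_mm = first_crossing(x, E_trace, material$e_corr),
       verdict = if (any(zone == "active")) "crevice corrosion sustainable"
                 else "no crevice corrosion")
}

# First depth where a decreasing E(x) reaches `level`, by linear
# interpolation between the straddling samples; NA if never reached.
first_crossing <- function(x, E, level) {
  below <- which(E <= level)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(x[1])
  x[i - 1L] + (E[i - 1L] - level) / (E[i - 1L] - E[i]) * (x[i] - x[i - 1L])
}

#' Solve the full crevice IR-drop model
#'
#' Chains the gap construction, resistance summation, passive-current
#' accumulation, potential distribution and zone classification into one
#' per-depth solution table.
#'
#' @param geometry A [crevice_geometry()].
#' @param profile A `surface_profile` (single period or full length).
#' @param electrolyte An [electrolyte()].
#' @param material A [material_electrochem()].
#' @param convention Passive-current convention, see [passive_current()].
#' @return An object of class `crevice_profile`: a `data.frame` with columns
#'   `x_mm`, `gap_mm`, `R_ohm`, `Ipass_mA`, `E_V`, `drop_mV`, `zone`,
#'   `valid`, and attributes `crossings` (list with `e_pass_crossing_mm`,
#'   `e_corr_crossing_mm`), `verdict`, `max_drop_mV`, `material`,
#'   `electrolyte`, `geometry`.
#' @export
solve_crevice <- function(geometry, profile, electrolyte, material,
                          convention = "mouth") {
  gp <- build_gap_profile(geometry, profile)
  R <- cumulative_resistance(geometry, electrolyte, gp)
  I <- passive_current(material$i_pass_mm, geometry$r_int, gp$x,
                       convention = convention, length_L = geometry$length_L)
  pot <- potential_profile(material, R, I)
  cls <- classify_zones(pot$E, material, gp$x)
  out <- data.frame(x_mm = gp$x, gap_mm = gp$gap, R_ohm = R, Ipass_mA = I,
                    E_V = pot$E, drop_mV = pot$drop_mV, zone = cls$zone,
                    valid = pot$valid)
  structure(out,
            crossings = cls[c("e_pass_crossing_mm", "e_corr_crossing_mm")],
            verdict = cls$verdict,
            max_drop_mV = max(pot$drop_mV),
            material = material, electrolyte = electrolyte,
            geometry = geometry,
            class = c("crevice_profile", "data.frame"))
}

#' Interpolate the ohmic drop at a given depth
#'
#' @param solution A [solve_crevice()] result.
#' @param x_mm Depth from the crevice mouth, mm.
#' @return Potential drop `E_out - E(x)` in mV.
#' @export
drop_at <- function(solution, x_mm) {
  stopifnot(inherits(solution, "crevice_profile"))
  stats::approx(solution$x_mm, solution$drop_mV, xout = x_mm)$y
}

#' @export
print.crevice_profile <- function(x, ...) {
  cr <- attr(x, "crossings")
  cat(sprintf("crevice_profile: %s\n", attr(x, "material")$name))
  cat(sprintf("  %d samples over %g mm; verdict: %s\n",
              nrow(x), max(x$x_mm), attr(x, "verdict")))
  cat(sprintf("  max IR drop %.4g mV; E_pass crossing %s mm; E_corr crossing %s mm\n",
              attr(x, "max_drop_mV"),
              format(cr$e_pass_crossing_mm, digits = 4),
              format(cr$e_corr_crossing_mm, digits = 4)))
  invisible(x)
}

#' Summarize a crevice solution
#'
#' @param object A [solve_crevice()] result.
#' @param ... Unused.
#' @return List with `verdict`, `e_pass_crossing_mm`, `e_corr_crossing_mm`
#'   and `max_drop_mV`, as serialized to the JSON summary.
#' @export
summary.crevice_profile <- function(object, ...) {
  cr <- attr(object, "crossings")
  list(verdict = attr(object, "verdict"),
       e_pass_crossing_mm = cr$e_pass_crossing_mm,
       e_corr_crossing_mm = cr$e_corr_crossing_mm,
       max_drop_mV = attr(object, "max_drop_mV"))
}

#' Write the per-depth solution table to CSV
#'
#' Columns `x_mm, gap_mm, R_ohm, Ipass_mA, E_V, zone` (deterministic bytes
#' for identical inputs).
#'
#' @param solution A [solve_crevice()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(solution, path) {
  stopifnot(inherits(solution, "crevice_profile"))
  utils::write.csv(
    solution[, c("x_mm", "gap_mm", "R_ohm", "Ipass_mA", "E_V", "zone")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the scenario summary to JSON
#'
#' @param solution A [solve_crevice()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(solution, path) {
  jsonlite::write_json(summary(solution), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
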