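#' Assemble a simulation scenario
#'
#' A scenario bundles everything one run needs: the crevice geometry, a
#' profile specification (a synthetic waveform or a measured trace file), the
#' electrolyte and the alloy parameters. Presets for the studied
#' alloy/solution pairs are available through [preset_scenario()].
#'
#' @param geometry A [crevice_geometry()].
#' @param profile_spec List describing the roughness trace: `kind`
#'   (`"triangle"`, `"sine"`, `"jitter"` or `"file"`), `period_mm`,
#'   `amplitude_um`, `seed`, and `path` (for `kind = "file"`).
#' @param electrolyte An [electrolyte()].
#' @param material A [material_electrochem()].
#' @param label Scenario label used in outputs and diagnostics.
#' @return An object of class `scenario`.
#' @export
scenario <- function(geometry, profile_spec, electrolyte, material,
                     label = material$name) {
  stopifnot(inherits(geometry, "crevice_geometry"),
            inherits(electrolyte, "electrolyte"),
            inherits(material, "material_electrochem"))
  profile_spec <- utils::modifyList(
    list(kind = "triangle", period_mm = 0.27, amplitude_um = 15,
         seed = 0L, path = NULL),
    as.list(profile_spec))
  if (!profile_spec$kind %in% c("triangle", "sine", "jitter", "file"))
    stop("unknown profile kind '", profile_spec$kind, "'", call. = FALSE)
  if (identical(profile_spec$kind, "file") && is.null(profile_spec$path))
    stop("profile kind 'file' requires a path", call. = FALSE)
  structure(list(geometry = geometry, profile_spec = profile_spec,
                 electrolyte = electrolyte, material = material,
                 label = as.character(label)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario: %s\n", x$label))
  cat(sprintf("  profile: %s (period %g mm, amplitude %g um)\n",
              x$profile_spec$kind, x$profile_spec$period_mm,
              x$profile_spec$amplitude_um))
  print(x$geometry); print(x$electrolyte); print(x$material)
  invisible(x)
}

# Materialize the profile a scenario describes.
scenario_profile <- function(scn) {
  ps <- scn$profile_spec
  if (identical(ps$kind, "file")) {
    normalize_profile(read_profile_file(ps$path, period = ps$period_mm))
  } else {
    generate_fixture_profile(ps$kind, period = ps$period_mm,
                             amplitude = ps$amplitude_um / 1000,
                             dx = scn$geometry$dx, seed = ps$seed)
  }
}

#' Run a scenario through the full crevice model
#'
#' Materializes the roughness profile, builds the gap, sums the electrolyte
#' resistance, accumulates the passive current, computes the IR-drop
#' potential distribution and classifies the corrosion zones. The pipeline
#' is deterministic: identical scenarios give identical outputs.
#'
#' @param scn A [scenario()] or the name of a preset (see [list_presets()]).
#' @param convention Passive-current convention, see [passive_current()].
#' @param quiet Suppress the per-stage log line.
#' @return A `crevice_profile` (see [solve_crevice()]); its `scenario`
#'   attribute records the scenario that produced it.
#' @export
run_scenario <- function(scn, convention = "mouth", quiet = TRUE) {
  if (is.character(scn)) scn <- preset_scenario(scn)
  stopifnot(inherits(scn, "scenario"))
  sol <- tryCatch(
    solve_crevice(scn$geometry, scenario_profile(scn), scn$electrolyte,
                  scn$material, convention = convention),
    error = function(e)
      stop("scenario '", scn$label, "': ", conditionMessage(e),
           call. = FALSE))
  attr(sol, "scenario") <- scn
  if (!quiet)
    message(sprintf("[%s] n = %d, max drop = %.4g mV, verdict: %s",
                    scn$label, nrow(sol), attr(sol, "max_drop_mV"),
                    attr(sol, "verdict")))
  sol
}

#' Build a scenario from an alloy/solution preset
#'
#' Combines a [material_preset()] with the reference taper geometry
#' (alpha = 0.02 deg, L = 13 mm, r_int = 6 mm) and the default triangular
#' roughness fixture (period 0.27 mm, amplitude 15 um).
#'
#' @param name Preset name, see [list_presets()].
#' @param geometry Override geometry.
#' @param profile_spec Override profile specification entries.
#' @param e_out Override applied outer potential, V (e.g. the documented
#'   alternative potential of a preset).
#' @param rho Override electrolyte resistivity, Ohm mm (e.g. the rounded
#'   350 Ohm mm reference value for the H2SO4 solution).
#' @return A [scenario()].
#' @export
preset_scenario <- function(name, geometry = crevice_geometry(),
                            profile_spec = list(), e_out = NULL,
                            rho = NULL) {
  p <- material_preset(name)
  mat <- p$material
  if (!is.null(e_out))
    mat <- material_electrochem(mat$name, mat$e_pass, mat$i_pass,
                                mat$e_corr, e_out)
  elec <- if (is.null(rho)) p$electrolyte
          else electrolyte(rho = rho, ph = p$electrolyte$ph)
  scenario(geometry, profile_spec, elec, mat, label = name)
}

#' Sweep the cone mismatch angle
#'
#' Re-runs a scenario at each mismatch angle with everything else fixed.
#' Narrower mismatch angles close the gap, raising the electrolyte
#' resistance and the IR drop at every depth.
#'
#' @param base A [scenario()].
#' @param angles Positive, distinct mismatch angles, degrees, in the order
#'   to report.
#' @return An object of class `sweep_result`: list with `parameter`,
#'   `values`, `summaries` (one row per value: `value`, `max_drop_mV`,
#'   `verdict`, `e_pass_crossing_mm`, `e_corr_crossing_mm`) and `profiles`
#'   (the full per-depth solutions, in input order).
#' @export
sweep_mismatch_angle <- function(base, angles) {
  stopifnot(inherits(base, "scenario"))
  if (any(angles <= 0)) stop("angles must be positive", call. = FALSE)
  if (anyDuplicated(angles)) stop("angles must be distinct", call. = FALSE)
  runs <- lapply(angles, function(a) {
    g <- base$geometry; g$alpha <- a
    run_scenario(scenario(g, base$profile_spec, base$electrolyte,
                          base$material,
                          label = sprintf("%s (alpha=%g)", base$label, a)))
  })
  sweep_result("mismatch_angle_deg", angles, runs)
}

#' Sweep the roughness height scale
#'
#' Multiplies the profile heights by each factor (then re-normalizes, with C
#' recomputed) and re-runs the scenario. Smoother surfaces (factors < 1)
#' leave less interstitial space, so the resistance and the potential drop
#' grow.
#'
#' @param base A [scenario()].
#' @param scales Positive multiplicative factors on the profile heights.
#' @return A `sweep_result`, see [sweep_mismatch_angle()].
#' @export
sweep_roughness_scale <- function(base, scales) {
  stopifnot(inherits(base, "scenario"))
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  base_profile <- scenario_profile(base)
  runs <- lapply(scales, function(s) {
    prof <- scale_profile(base_profile, s)
    sol <- solve_crevice(base$geometry, prof, base$electrolyte,
                         base$material)
    attr(sol, "scenario") <- base
    sol
  })
  sweep_result("roughness_scale", scales, runs)
}

sweep_result <- function(parameter, values, runs) {
  summaries <- do.call(rbind, lapply(seq_along(runs), function(i) {
    s <- summary(runs[[i]])
    data.frame(value = values[i], max_drop_mV = s$max_drop_mV,
               verdict = s$verdict,
               e_pass_crossing_mm = s$e_pass_crossing_mm %||% NA_real_,
               e_corr_crossing_mm = s$e_corr_crossing_mm %||% NA_real_)
  }))
  structure(list(parameter = parameter, values = values,
                 summaries = summaries, profiles = runs),
            class = "sweep_result")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result over %s (%d values)\n", x$parameter,
              length(x$values)))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Write a sweep summary table to JSON
#'
#' @param sweep A `sweep_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_json <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  jsonlite::write_json(
    list(parameter = sweep$parameter, summaries = sweep$summaries),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
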