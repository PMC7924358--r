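#' Read a scenario from a YAML configuration file
#'
#' The configuration is a key tree with blocks `geometry` (`alpha_deg`,
#' `length_mm`, `r_int_mm`, `dx_mm`, `gap_floor_mm`), `profile` (`kind`,
#' `period_mm`, `amplitude_um`, `seed`, `path`), `electrolyte`
#' (`conductivity_mS_cm` or `rho_ohm_mm`, `ph`), `material` (`name`,
#' `e_pass_V`, `i_pass_mA_cm2`, `e_corr_V`, `e_out_V`) and an optional
#' `label`. Alternatively a top-level `preset` key names a
#' [material_preset()]; any blocks present then override the preset's
#' components. Every preset is expressible as a plain config, so presets
#' are documentation, not magic.
#'
#' @param path YAML file path.
#' @return A [scenario()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  if (!is.null(cfg$preset)) {
    base <- material_preset(cfg$preset)
    mat_defaults <- list(name = base$material$name,
                         e_pass_V = base$material$e_pass,
                         i_pass_mA_cm2 = base$material$i_pass,
                         e_corr_V = base$material$e_corr,
                         e_out_V = base$material$e_out)
    elec_defaults <- list(conductivity_mS_cm = base$electrolyte$conductivity,
                          ph = base$electrolyte$ph)
    label <- cfg$label %||% cfg$preset
  } else {
    if (is.null(cfg$material) || is.null(cfg$electrolyte))
      stop("config needs 'material' and 'electrolyte' blocks (or a 'preset')",
           call. = FALSE)
    mat_defaults <- list(); elec_defaults <- list()
    label <- cfg$label %||% cfg$material$name %||% "scenario"
  }
  g <- utils::modifyList(
    list(alpha_deg = 0.02, length_mm = 13, r_int_mm = 6, dx_mm = 1e-3,
         gap_floor_mm = 1e-4),
    as.list(cfg$geometry))
  geometry <- crevice_geometry(alpha = g$alpha_deg, length_L = g$length_mm,
                               r_int = g$r_int_mm, dx = g$dx_mm,
                               gap_floor = g$gap_floor_mm)
  m <- utils::modifyList(mat_defaults, as.list(cfg$material))
  material <- material_electrochem(m$name %||% label, e_pass = m$e_pass_V,
                                   i_pass = m$i_pass_mA_cm2,
                                   e_corr = m$e_corr_V, e_out = m$e_out_V)
  e <- utils::modifyList(elec_defaults, as.list(cfg$electrolyte))
  elec <- electrolyte(conductivity = e$conductivity_mS_cm,
                      rho = e$rho_ohm_mm, ph = e$ph %||% NA_real_)
  scenario(geometry, cfg$profile %||% list(), elec, material, label = label)
}

#' Serialize a scenario to a YAML configuration file
#'
#' Writes the fully resolved parameter tree; reading it back with
#' [read_scenario_config()] reproduces the scenario losslessly.
#'
#' @param scn A [scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  g <- scn$geometry; m <- scn$material; e <- scn$electrolyte
  ps <- scn$profile_spec
  cfg <- list(
    label = scn$label,
    geometry = list(alpha_deg = g$alpha, length_mm = g$length_L,
                    r_int_mm = g$r_int, dx_mm = g$dx,
                    gap_floor_mm = g$gap_floor),
    profile = Filter(Negate(is.null),
                     list(kind = ps$kind, period_mm = ps$period_mm,
                          amplitude_um = ps$amplitude_um, seed = ps$seed,
                          path = ps$path)),
    electrolyte = list(conductivity_mS_cm = e$conductivity, ph = e$ph),
    material = list(name = m$name, e_pass_V = m$e_pass,
                    i_pass_mA_cm2 = m$i_pass, e_corr_V = m$e_corr,
                    e_out_V = m$e_out))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
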