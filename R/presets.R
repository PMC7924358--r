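#' Named alloy/solution presets
#'
#' Electrochemical presets for the alloy/solution pairs studied at conical
#' taper junctions: an FeCr (AISI 430-type) reference alloy in 0.05 M H2SO4,
#' and the biomedical alloys CoCrMo and Ti6Al4V in 0.9 wt.% NaCl at pH 2.3
#' and 5.6. Each preset bundles a [material_electrochem()] and an
#' [electrolyte()].
#'
#' FeCr parameters (E_pass = -0.37 V, i_pass = 1.8 mA/cm^2, E_corr = -0.5 V)
#' come from its measured potentiodynamic curve, which shows a clear
#' active-passive transition. Ti6Al4V and CoCrMo curves show no such
#' transition, so literature bounds are used: i_pass = 0.01 uA/cm^2 and
#' E_pass = -0.75 V for titanium (an upper limit on i_pass in dilute acid),
#' i_pass = 2 uA/cm^2 and E_pass = -0.9 V for CoCrMo (the pseudo-active peak
#' occasionally reported in PBS). Neither alloy has a measurable E_corr for
#' the active domain; the presets place e_corr nominally below e_pass, which
#' never affects predictions because the computed potential stays above
#' e_pass throughout. Applied outer potentials follow the experimental
#' choices: FeCr 0.5 V; CoCrMo 0.5 V at pH 2.3 (with -0.1 V as the
#' documented alternative, `e_out_alt`) and -0.1 V at pH 5.6; Ti6Al4V 0.3 V
#' at pH 2.3 and 0.5 V at pH 5.6. Electrolyte conductivities are the
#' measured solution values (H2SO4 28.3, NaCl pH 2.3 17.1, NaCl pH 5.6
#' 14.0 mS/cm).
#'
#' @param name One of `"FeCr_H2SO4"`, `"CoCrMo_NaCl_pH2.3"`,
#'   `"CoCrMo_NaCl_pH5.6"`, `"Ti6Al4V_NaCl_pH2.3"`, `"Ti6Al4V_NaCl_pH5.6"`.
#' @return A list with elements `label`, `material`
#'   ([material_electrochem()]), `electrolyte` ([electrolyte()]) and
#'   `e_out_alt` (alternative applied potential, V, or `NA`).
#' @export
#' @examples
#' material_preset("FeCr_H2SO4")
material_preset <- function(name) {
  if (!name %in% names(.preset_table))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.preset_table), collapse = ", "), call. = FALSE)
  p <- .preset_table[[name]]
  list(label = name,
       material = material_electrochem(p$material_name, e_pass = p$e_pass,
                                       i_pass = p$i_pass, e_corr = p$e_corr,
                                       e_out = p$e_out),
       electrolyte = electrolyte(conductivity = p$conductivity, ph = p$ph),
       e_out_alt = p$e_out_alt)
}

#' @rdname material_preset
#' @export
list_presets <- function() names(.preset_table)

.preset_table <- list(
  FeCr_H2SO4 = list(
    material_name = "FeCr 15% Cr (AISI 430) / 0.05 M H2SO4",
    e_pass = -0.37, i_pass = 1.8, e_corr = -0.5, e_out = 0.5,
    e_out_alt = NA_real_, conductivity = 28.3, ph = 1.5),
  CoCrMo_NaCl_pH2.3 = list(
    material_name = "CoCrMo / 0.9% NaCl pH 2.3",
    e_pass = -0.9, i_pass = 2e-3, e_corr = -1.0, e_out = 0.5,
    e_out_alt = -0.1, conductivity = 17.1, ph = 2.3),
  CoCrMo_NaCl_pH5.6 = list(
    material_name = "CoCrMo / 0.9% NaCl pH 5.6",
    e_pass = -0.9, i_pass = 2e-3, e_corr = -1.0, e_out = -0.1,
    e_out_alt = NA_real_, conductivity = 14.0, ph = 5.6),
  Ti6Al4V_NaCl_pH2.3 = list(
    material_name = "Ti6Al4V / 0.9% NaCl pH 2.3",
    e_pass = -0.75, i_pass = 1e-5, e_corr = -0.85, e_out = 0.3,
    e_out_alt = NA_real_, conductivity = 17.1, ph = 2.3),
  Ti6Al4V_NaCl_pH5.6 = list(
    material_name = "Ti6Al4V / 0.9% NaCl pH 5.6",
    e_pass = -0.75, i_pass = 1e-5, e_corr = -0.85, e_out = 0.5,
    e_out_alt = NA_real_, conductivity = 14.0, ph = 5.6)
)
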