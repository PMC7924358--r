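# Shared fixtures: the reference taper geometry, a smooth (flat) profile,
# and a synthetic Butler-Volmer polarization curve whose generator
# parameters serve as the oracle for Tafel extrapolation.

ref_geometry <- function(alpha = 0.02, dx = 1e-3) {
  crevice_geometry(alpha = alpha, length_L = 13, r_int = 6, dx = dx)
}

flat_profile <- function(length_L = 13, dx = 1e-3, period = 0.27) {
  surface_profile(seq(0, length_L, by = dx),
                  rep(0, length(seq(0, length_L, by = dx))),
                  period = period, normalized = TRUE)
}

# i = i0 * (10^((E - e0)/ba) - 10^(-(E - e0)/bc)), mA/cm^2
bv_curve <- function(i0 = 0.5, e0 = -0.5, ba = 0.06, bc = 0.12,
                     span = 0.4, n = 201) {
  E <- seq(e0 - span, e0 + span, length.out = n)
  polarization_curve(E, i0 * (10^((E - e0) / ba) - 10^(-(E - e0) / bc)))
}
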