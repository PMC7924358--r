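# Fully explicit scenario configuration (equivalent to `preset: FeCr_H2SO4`
# with the resistivity override used for the reference calculation).
label: FeCr_H2SO4_explicit
geometry:
  alpha_deg: 0.02       # cone mismatch angle
  length_mm: 13.0       # crevice length
  r_int_mm: 6.0         # trunnion radius
  dx_mm: 0.001          # axial discretization step
  gap_floor_mm: 0.0001  # residual asperity-scale gap
profile:
  kind: triangle        # triangle | sine | jitter | file
  period_mm: 0.27
  amplitude_um: 15.0    # half peak-to-valley
  seed: 0
electrolyte:
  rho_ohm_mm: 350.0     # 0.05 M H2SO4 (28.3 mS/cm, rounded to 350 Ohm mm)
  ph: 1.5
material:
  name: FeCr 15% Cr (AISI 430) / 0.05 M H2SO4
  e_pass_V: -0.37
  i_pass_mA_cm2: 1.8
  e_corr_V: -0.5
  e_out_V: 0.5
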