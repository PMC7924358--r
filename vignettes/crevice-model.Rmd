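---
title: "An IR-drop crevice-corrosion model for conical taper junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An IR-drop crevice-corrosion model for conical taper junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crevsim)
```

## The physical picture

At the taper junction of a modular hip implant, the male cone (trunnion) and
the female cone (bore) are machined to nominally equal angles, but a small
mismatch `alpha` (here 0.02°) remains. The junction therefore closes a
wedge-shaped, solution-filled crevice: widest at its mouth, vanishing at the
deep end, and modulated by the periodic thread-like roughness the machining
leaves on the trunnion.

The crevice-corrosion question for passive alloys is an *electrical* one
before it is a chemical one. The passive surface inside the crevice leaks a
small anodic current (the passive current density `i_pass`) that must flow
out through the electrolyte film to the cathodic outer surface. That film is
thin and long, so its ohmic resistance is large, and the cumulative IR drop
lowers the local electrode potential with depth. If at some depth the
potential falls below the passivation potential `E_pass` while still above
the corrosion potential `E_corr`, the film there cannot be maintained at the
passive current: the surface sits in its active dissolution window and
crevice corrosion is sustainable. If the potential never reaches `E_pass`,
the crevice stays passive no matter how long it is immersed.

`crevsim` resolves this balance in one dimension along the crevice axis.

## Model chain and assumptions

With `x` the depth from the mouth (mm; `x = 0` at the mouth, `x = L` at the
closed end — this coordinate convention makes the `(L - x)` wedge term give
the widest gap at the mouth, as a convergent crevice requires):

1. **Gap.** `y_g(x) = tan(alpha) (L - x) + C - y_p(x)`, where `y_p` is the
   centerline-normalized roughness trace and `C = max(y_p)`. Subtracting
   `y_p` from the bore envelope `... + C` presses the roughness peaks
   against the bore: the gap is exactly zero where a peak touches, by
   construction. Adding any constant to the raw trace changes nothing — the
   normalization removes it.
2. **Resistance.** The electrolyte occupies the annulus between the
   trunnion (radius `r_int`) and the bore (radius `r_int + y_g`). Summing
   axial sections from the mouth,
   `R(x) = sum rho dx / (pi (r_int + y_g)^2 - pi r_int^2)`, with `R(0) = 0`
   because the circuit to the outer reference closes at the mouth.
3. **Current.** Each surface element between the mouth and `x` contributes
   `i_pass` over its lateral cylinder area, so the current crossing the
   section at `x` is `I_pass(x) = i_pass 2 pi r_int x`, cumulative from the
   mouth. (The notational alternative — current collected from the surface
   *deeper* than `x`, proportional to `L - x` — is available via
   `passive_current(..., convention = "deep")`; the cumulative-from-mouth
   reading is the default because the current that loads the resistance
   between the mouth and `x` is the current that has entered through that
   span.)
4. **Potential.** `E(x) = E_out - I_pass(x) R(x)` (mA × Ohm = mV). Treating
   `I_pass` as a net anodic current is valid only while `E(x) >= E_corr`;
   deeper samples are still reported but flagged `valid = FALSE` rather
   than truncated, so the full curve remains inspectable.
5. **Zones.** `passive` for `E > E_pass`; `active` for
   `E_corr < E <= E_pass` (closed at `E_pass`, open at `E_corr` — the only
   tie-break the thresholds need); `negligible` for `E <= E_corr`. The
   verdict is "crevice corrosion sustainable" iff any sample is active.
   Crossing depths are located by linear interpolation between the two
   straddling grid samples, so reported depths do not snap to the grid.

Assumptions worth keeping in mind: the model is steady-state and purely
ohmic (no transient oxygen depletion, pH evolution, or cathodic kinetics
inside the crevice); `i_pass` is uniform wherever the surface is passive;
`r_int` is constant (the metal taper over 13 mm amounts to a few µm and is
neglected); and the crevice is axisymmetric, so a 1-D line model suffices.

## Parameters, units, defaults

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `alpha` | deg | 0.02 | machining mismatch of the reference taper |
| `length_L` | mm | 13 | engaged taper length |
| `r_int` | mm | 6 | trunnion radius |
| `dx` | mm | 0.001 | resolves the 270 µm roughness period with 270 samples |
| `gap_floor` | mm | 1e-4 | residual asperity-scale film where peaks touch the bore; prevents infinite section resistance |
| profile period | mm | 0.27 | peak-to-peak periodicity of the machined thread |
| profile amplitude | mm | 0.015 | mid-range plausible thread height (half peak-to-valley); a calibration parameter, see below |
| `i_pass` | mA/cm² | per preset | user-facing unit; stored internally as mA/mm² (×0.01) for mm-based geometry |
| potentials | V vs Ag/AgCl | per preset | the reference scale of the underlying measurements |
| `rho` | Ohm mm | from conductivity | `rho = 1e4 / kappa(mS/cm)` |

Internally every length is millimetres; profile files may be in µm with a
`# units: um` header (the default) and are converted on load.

### Presets

The five presets (`list_presets()`) bundle the studied alloy/solution
pairs. The FeCr parameters come from a measured active–passive transition
(`E_pass = -0.37` V, `i_pass = 1.8` mA/cm², `E_corr = -0.5` V). Ti6Al4V
and CoCrMo show no such transition experimentally, so literature bounds are
used: `i_pass = 0.01` µA/cm² and `E_pass = -0.75` V for titanium (an upper
limit from dilute-acid data — at the near-neutral pH of interest the true
value should be lower still, which only strengthens a "no corrosion"
verdict), and `i_pass = 2` µA/cm² with `E_pass = -0.9` V for CoCrMo (the
pseudo-active peak occasionally reported). Since neither alloy has a
measurable active-domain `E_corr`, the presets place `e_corr` nominally
below `e_pass` (−0.85 V for Ti, −1.0 V for CoCrMo); the choice is inert
because the computed potential never descends to `e_pass` for these alloys,
let alone below it.

Electrolytes use the measured conductivities (H₂SO₄ 28.3, NaCl pH 2.3
17.1, NaCl pH 5.6 14.0 mS/cm). For the FeCr reference calculation the
rounded `rho = 350` Ohm mm is conventionally used; `preset_scenario(...,
rho = 350)` applies that override while the preset itself keeps the
measured conductivity.

## The synthetic roughness generator

Real trunnion topography is only available as a measured line trace; the
package instead ships a deterministic generator
(`generate_fixture_profile()`) producing one period of a triangular wave
(thread-like, the default), a sinusoid, or a jittered triangle (seeded
uniform noise, for robustness tests). All waveforms start at their peak —
the same anchoring `average_periods()` applies to measured traces — and are
centerline-normalized. A measured two-column trace file can be substituted
anywhere a waveform is accepted (`kind = "file"`).

What the fixture emulates: the 270 µm periodicity, the peak-to-valley
scale, and the peaks-touch-the-bore contact geometry that dominates the
resistance integral (the section resistance is a harmonic-type average over
the gap oscillation, so the narrow passages near the peaks matter most).
What it does not emulate: the asymmetric tooth shape, period-to-period
variability and 2-D lay of a real machined surface. Passing tests therefore
show that the model chain is correct and that verdicts are robust over a
plausible roughness band — not that any particular implant's trace was
reproduced. Accordingly, the profile amplitude is treated as a calibration
parameter: the test suite spans 10–25 µm and checks that the FeCr active
window lands near the experimentally observed ~2 mm depth, without claiming
exact reproduction.

## Numerical choices

- **Discrete resistance sum.** `cumulative_resistance()` applies the
  trapezoidal rule to the annulus integrand (adjacent sections averaged).
  Against the closed-form antiderivative for a smooth cone
  (`smooth_cone_resistance()`, an independent analytic oracle) the
  summation agrees to well within 0.1 % at `dx` = 1 µm, and halving `dx`
  moves mid-crevice results by less than 0.1 % with the roughness fixture
  in place.
- **Gap floor.** Where roughness peaks meet the bore the nominal gap is
  zero and the section resistance would diverge. The 0.1 µm floor models an
  asperity-scale residual film; it caps, rather than drives, the resistance
  of the final fraction of each period near contact.
- **Crossings.** Threshold depths are linearly interpolated, so summary
  depths are grid-independent at the 1 µm resolution.
- **Determinism.** Only the jittered fixture consumes randomness, under an
  explicit seed (default 0); identical scenarios yield byte-identical CSV
  outputs.
- **Problem sizes.** All shipped scenarios run on the 13 001-point grid
  (13 mm at 1 µm); a full preset run completes in well under a second, and
  the whole test suite—including the amplitude span and both sensitivity
  sweeps—in a few seconds.

## Design choices that were genuinely open

- **Which current loads the resistance.** The cumulative-from-mouth reading
  of the passive current (step 3 above) was adopted as the default; the
  deep-end alternative is exposed behind an option flag so the two readings
  can be compared on any scenario.
- **Resistance summed to `x`, not `L`.** The cumulative resistance at depth
  `x` includes only the path between the mouth and `x` — the quantity the
  IR product at `x` physically traverses.
- **Reporting below `E_corr`.** Samples outside the net-anodic validity
  domain are flagged, not dropped, keeping the printed curve comparable to
  potential-vs-depth figures that show the full descent.
- **Mouth aperture rounding.** The nominal smooth-cone mouth aperture is
  `tan(0.02°) × 13 mm = 4.54` µm, commonly quoted rounded as 4.6 µm; the
  package computes the exact value and treats the 2 % difference as
  rounding, not error.
- **Tafel windows are user-supplied.** Automatic detection of linear Tafel
  regions is notoriously fragile; `tafel_extrapolate()` takes explicit
  anodic/cathodic potential windows and validates sample counts and branch
  sides instead.

## What the model predicts

The test suite and `scripts/acceptance.R` recompute, from scratch: the FeCr
reference case (active window with its `E_corr` crossing ~1.5 mm deep at
the default fixture amplitude, within the 1.5–2.5 mm band over the
calibration range — the model's explanation of the corrosion ring observed
~2 mm into the test crevice); the CoCrMo case (drop at the 10 mm electrode
position below the 100 mV scale, and quartered when `i_pass` drops to
0.5 µA/cm², by linearity); the Ti6Al4V case (sub-millivolt drop at 10 mm,
potential nowhere near `E_pass`: no crevice corrosion); and the two design
trends — decreasing the mismatch angle through 0.02°/0.01°/0.005° or
scaling roughness heights by 1/5 strictly increases the drop at every
depth, i.e. tighter and smoother junctions are *more* at risk.

## Known limitations

- Steady-state only: incubation, oxygen depletion, pH drift and
  repassivation kinetics are outside scope, so the model bounds *whether*
  corrosion is sustainable, not *when* it starts.
- One-dimensional: no 2-D/3-D Laplace solution, no azimuthal variation, no
  contact mechanics or assembly-force dependence of the gap.
- `i_pass` and `E_pass` for spontaneously passive alloys are literature
  bounds, not measurements; verdicts for CoCrMo in particular inherit that
  uncertainty (the preset's 2 µA/cm² versus 0.5 µA/cm² comparison in the
  tests shows the sensitivity directly).
- The potential below `E_corr` is extrapolated outside the model's own
  validity and must be read qualitatively.
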