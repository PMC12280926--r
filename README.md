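# hoverstab

Stability mechanics and energetics of hovering in near-neutrally buoyant
fishes.

## The problem

Hovering — holding position and orientation in the water column — looks
like it should be nearly free for a fish with a swim bladder: the water
carries its weight, so no lift is needed. It is not free. The center of
mass (COM) typically sits dorsal to the center of buoyancy (COB), so the
weight/buoyancy pair forms a destabilizing couple: at body angle θ it
produces a torque

    τ_COM-COB = m · g · d · sin θ

(m body mass, d the COM–COB separation) that amplifies any angular
displacement. A hovering fish is an inverted pendulum, stabilized only by
continuous corrective fin movements whose mechanical work shows up as
elevated metabolic rate. The torque balance

    τ_fin = τ_COM-COB − I·α − D

(I = m·r_g² the moment of inertia, α angular acceleration, D rotational
drag) says which morphological traits should predict that cost: COM–COB
separation (more destabilizing torque), fin position (lever arm of the
corrective force), mass and fineness ratios (inertia and damping).

`hoverstab` is for comparative biomechanists and ecophysiologists who
want to run that full argument quantitatively:

* **Stability simulation** — `simulate_hover()` integrates the torque
  balance (RK4, PD fin controller with force saturation, seeded
  ventilation + noise perturbations) and reports the stabilization work
  ∫|τ_fin·ω|dt; `sweep_and_fit()` maps morphology to mass-specific cost
  over a factorial grid and recovers the predicted coefficient signs
  (mass −, COM–COB separation −with the dorsal-origin sign convention,
  lever arm −, fineness +).
* **Respirometry** — `o2_slope()`, `mo2_from_trace()` implement
  MO₂ = slope × 60 × (V_chamber − V_fish) × M^−0.9
  (mg O₂ kg⁻¹ h⁻¹), `net_and_ratio()` and `energy_kj()` (3.25 cal per
  mg O₂) convert to net hovering cost, hover/rest ratio and kJ kg⁻¹ per
  bout.
* **Kinematics** — roll/pitch/body angle from 3D landmark series, Menger
  body curvature, cross-correlation pectoral phase lag folded into
  [0°, 180°], per-fin distance traveled (BL s⁻¹), fin-beat cycle
  extraction.
* **Morphometrics** — COM from least-squares intersection of suspension
  axes, COB from swim-bladder voxel-mask centroids, signed proportional
  COM–COB offsets (dorsal origin: negative = COB ventral of COM),
  fineness ratios.
* **Statistics** — `hover_lm()` multilinear regression (classed S3 fit
  with `coef`/`predict`/`summary` methods), drop and permutation variable
  importance, G1/G2 metabolic grouping, species ANOVA/Tukey/t-tests, and
  `abouheif()`, a topology-only (branch-length-free) permutation test of
  phylogenetic signal.
* **Synthetic data** — `synth_plan()` + generators for every input type
  with known ground truth (linear morphology→MO₂ structure from the
  packaged reference coefficients, oxygen declines, oscillating landmark
  series, trees with optional Brownian trait signal), so the whole
  pipeline is testable end to end without any downloads.

## Worked example

Generate 13 synthetic species from the packaged reference coefficient
vector with zero noise and refit — the regression stage returns the
generating coefficients exactly:

```r
library(hoverstab)
tab <- gen_species_table(synth_plan(seed = 1, noise_sd = 0, ratio_noise_sd = 0))
fit <- hover_lm(mo2_formula("mo2net"), tab)
print(fit)
#> Multilinear regression (mo2net ~ mass + fineness_depth + comcob_ap + ...)
#>    (Intercept)           mass fineness_depth      comcob_ap      comcob_dv
#>        1501.05        -440.24         201.28        -114.18        -116.80
#> fineness_width    pect_fin_ap    caud_fin_ap
#>         194.16       -1297.36       -1297.60
#> R2 = 1.0000 on 13 observations
```

The intercept 1501.05 is the net hovering cost (mg O₂ kg⁻¹ h⁻¹) at the
origin of the morphospace; the negative mass and fin-position
coefficients and positive fineness coefficients are the signature of
instability-driven cost. With the default calibrated noise
(`noise_sd = 170`) the same fit lands near R² ≈ 0.86 instead of 1.

Simulate stabilization of a 10 g fish with a 2 mm COM–COB separation,
ventilating at 2 Hz:

```r
b    <- rigid_body(mass = 0.01, d_comcob = 0.002, r_gyration = 0.004)
ctrl <- default_controller(b, lever_arm = 0.01)
pp   <- perturbation(ventilation_amp = 4e-5, ventilation_freq = 2,
                     noise_sd = 1e-5, seed = 1)
simulate_hover(b, ctrl, pp, duration = 10)
#> Hovering stabilization simulation: 10.0 s at dt = 0.001 s
#>   max |angle| 3.11 deg, fin work 0.000104 J (0.0104 J/kg)
```

The fish holds its posture within ~3 degrees — the dynamic stability real
hovering fishes display — at a nonzero mechanical cost. And the
respirometry round trip, here on noiseless synthetic traces of a fish
hovering at twice its resting rate:

```r
plan  <- synth_plan(seed = 1)
hover <- gen_o2_trace(240, mass = 0.008, chamber_vol = 0.615, plan = plan)
rest  <- gen_o2_trace(120, mass = 0.008, chamber_vol = 0.615, plan = plan)
respirometry(hover, rest)
#> Respirometry summary (mg O2 kg^-1 h^-1):
#>   MO2 hover 239.89, rest 119.89, net 120.00, ratio 2.00
#>   energy for 10 min: 0.272 kJ/kg
```

A net rate of 120 mg O₂ kg⁻¹ h⁻¹ costs 0.272 kJ kg⁻¹ per 10-minute
hovering bout.

The whole chain runs from one YAML config via `run_pipeline()`
(synthetic or file-based inputs; per-stage seeds fanned out from one
global seed; CSV bundle + report out).

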