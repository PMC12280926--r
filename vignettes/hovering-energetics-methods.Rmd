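---
title: "Methods: stability mechanics and energetics of hovering fishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability mechanics and energetics of hovering fishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoverstab)
```

## The scientific problem

A fish with a swim bladder is nearly neutrally buoyant: the water supports
its weight, so hovering — holding position and orientation at zero net
translation — requires no lift. It is nevertheless not free. The center of
mass (COM), set by the axial musculature and skeleton, usually sits dorsal
to the center of buoyancy (COB), set by the swim bladder and viscera. The
weight/buoyancy force pair then forms a couple: any small angular
displacement $\theta$ produces a torque

$$\tau_{\mathrm{COM-COB}} = m\,g\,d\,\sin\theta$$

(with $m$ body mass, $d$ the COM–COB separation) that *amplifies* the
displacement. The body is an inverted pendulum; posture survives only
through continuous corrective fin forces, and those forces cost energy.
This package implements the full chain used to quantify that cost: a
mechanistic simulator of the torque balance, respirometry of the metabolic
cost, kinematics of the corrective fin movements, morphometrics of the
COM/COB geometry, and the statistical layer linking morphology to
metabolic rate, plus a synthetic-data generator so every stage can be
validated against known ground truth.

## The stability model

`simulate_hover()` integrates the single-axis rigid-body balance

$$I\ddot\theta \;=\; \tau_{\mathrm{COM-COB}}(\theta)\;-\;D\,\omega\;+\;
\tau_{\mathrm{fin}}\;+\;\tau_{\mathrm{perturb}}(t),$$

with $I = m r_g^2$ the moment of inertia ($r_g$ the radius of gyration
about the rotation axis — proportional to body width for roll, body length
for pitch), $D$ a rotational drag coefficient linear in angular velocity
(low Reynolds rotational damping, proportional to wetted surface area),
and $\tau_{\mathrm{fin}}$ the corrective fin torque. Solved for
$\tau_{\mathrm{fin}}$, the same balance reads
$\tau_{\mathrm{fin}} = \tau_{\mathrm{COM-COB}} - I\alpha - D$: the fins
must supply whatever the destabilizing couple produces beyond what inertia
and drag absorb. We integrate the dynamics form because it also covers the
uncontrolled and capsizing regimes.

Design choices that were genuinely open:

* **Controller.** Fish postural control is not specified by the physics,
  so we use the simplest stabilizing law: proportional–derivative control
  with saturation. The fish is assumed to modulate fin *force*; the fin's
  lever arm $L$ (distance of force application from the COM) converts
  force to torque, $\tau_{\mathrm{fin}} = L\,\mathrm{clip}(-(k_p\theta +
  k_d\omega), \pm F_{\max})$. This encodes the leverage mechanism
  directly: distal fins achieve the same torque with smaller forces, so —
  with force gains held fixed — a longer lever arm stiffens the closed
  loop, shrinks excursions and lowers the stabilization cost. Storing
  torque gains instead would make the lever arm inert except through
  saturation and could not express that mechanism. Default gains
  (`default_controller()`) are sized from the plant: torque stiffness 5
  times the critical destabilizing stiffness $mg|d|$, torque damping
  critical for the resulting loop.
* **Cost functional.** Stabilization cost is the mechanical work of the
  fin torque, $\int |\tau_{\mathrm{fin}}\,\omega|\,dt$, counting positive
  and negative work equally: muscle performs metabolic work in both
  shortening and controlled lengthening and we assume no elastic storage.
  An efficiency divisor is exposed in `stabilization_cost()`.
* **Perturbations.** Internal perturbations are a sinusoidal ventilation
  torque plus white torque noise. The noise is generated on a fixed
  100 Hz grid from the mandatory seed and linearly interpolated, so the
  perturbation signal is independent of the integration step — this is
  what makes the solver-convergence property (halving `dt` changes the
  cost by far less than 0.1%) well-posed despite stochastic forcing.
* **Integration.** Fixed-step 4th-order Runge–Kutta, default
  `dt = 1e-3` s (well below 1/20 of the natural period for the default
  body). Excursions beyond 90 degrees flag the run as capsized and stop
  it rather than raising an error, so sweeps can count failures.

### The morphology sweep

`sweep_and_fit()` simulates a factorial grid over mass, dorsal–ventral
COM–COB offset, fineness ratio and fin lever arm, then regresses the
stabilization cost on the factors. Three modeling decisions matter here:

* The regression response is the **mass-specific** cost (J kg$^{-1}$),
  because the empirical quantities it parallels (oxygen consumption
  rates) are mass-specific. Absolute corrective work does not fall with
  body size, work per kilogram does — which is how the negative mass
  coefficient arises.
* Inside the sweep, the radius of gyration and drag surface scale
  isometrically with mass ($r_g \propto m^{1/3}$, surface
  $\propto m^{2/3}$), so "mass" means "a geometrically similar, larger
  fish". Fineness enters only through the drag/surface proxy (thinner
  bodies have less wetted area and less rotational damping at fixed
  length), and the metric COM–COB separation uses a fixed reference body
  depth, keeping the grid factors independent.
* The controller's force gains are held fixed across cells (stiffness
  sized on the worst-case destabilizing couple; damping sized critically
  for the smallest inertia in the grid so no cell's closed loop becomes
  numerically stiff).

Under these conditions the fitted signs reproduce the mechanistic
prediction: negative for mass, negative for the signed dorsal-origin
COM–COB offset (cost rises with separation), negative for lever arm,
positive for fineness.

```{r sweep, eval = FALSE}
sw <- sweep_and_fit(seed = 3, duration = 8)
sw$signs
#>      mass comcob_dv  fineness lever_arm
#>        -1        -1         1        -1
```

## Respirometry

Closed-chamber oxygen consumption is the OLS slope of the dissolved-O2
decline converted to a mass-specific hourly rate,

$$\dot M_{\mathrm{O_2}} = \mathrm{slope}\;[\mathrm{mg\,L^{-1}\,min^{-1}}]
\times 60 \times (V_{\mathrm{chamber}} - V_{\mathrm{fish}})
\times M^{-0.9},$$

in mg O2 kg$^{-1}$ h$^{-1}$; the exponent 0.9 corrects for the allometric
scaling of metabolic rate with mass. The factor 60 converts the per-minute
slope to the hourly units in which such rates are conventionally reported.
Net hovering cost is hovering minus resting rate; the hover/rest ratio
provides a size-, temperature- and salinity-robust relative measure; and
the energy for a 10-minute bout uses the oxy-calorific equivalent of
3.25 cal (thermochemical, 4.184 J) per mg O2. When the fish volume is not
measured it defaults to $M/1000$ L (near-neutral density). Window
selection defaults to the full trace, with an optional rolling window
maximizing fit $r^2$ for disturbed recordings. Background respiration and
solubility corrections are out of scope.

## Kinematics

Landmark series use x anterior–posterior, y lateral, z vertical. Roll is
the transverse-plane angle of the eye-to-bottom-of-eye segment from
vertical; pitch is the elevation of the snout–peduncle axis. Because the
printed definitions leave the zero reference open, excursions are measured
about the time-mean posture by default (the fish's own equilibrium), with
an absolute-reference option; the series is first de-rotated by its mean
heading so both angles are invariant to the yaw orientation of the
recording. Body curvature uses the Menger three-point discretization
($4 \times$ triangle area over the product of side lengths), chosen
because it is parameter-free and exact on circular arcs.

The left–right pectoral phase lag cross-correlates the mean-centered
abduction signals (signed lateral displacement of tip relative to base,
outward positive). The dominant period comes from the first
autocorrelation peak (unbiased estimator, ties toward the shorter period,
subsample refinement from interpolated zero-crossing spacings); the
best-correlation time shift is found on a window of $\pm 3/4$ period with
per-window Pearson normalization — so the periodic replicas of the true
peak stay outside the search — and refined parabolically, then converted
to degrees and folded into $[0^\circ, 180^\circ]$. Cycle extraction
delimits fin beats at upward zero crossings detected with a
quarter-amplitude hysteresis, which keeps measurement noise near the zeros
from creating or destroying cycles.

## Morphometrics

The COM of a suspended specimen is the least-squares intersection of the
suspension axes (the point minimizing summed squared perpendicular
distances; with more than two inconsistent axes this is well defined where
a pairwise-crossing average is not, and the RMS residual is reported as a
registration-quality diagnostic). The COB is the unweighted centroid of
the segmented swim-bladder voxel mask. Both are expressed as proportions:
anterior–posterior along the snout-to-peduncle axis, dorsal–ventral from
the dorsal-most point (dorsal = 0). The signed offsets are COM minus COB,
so a COB ventral of the COM gives a negative dorsal–ventral offset — the
convention under which the regression's negative coefficient means "more
separation, more cost". Fin positions are the anterior–posterior
proportions of the fin-base landmarks; whether base or insertion midpoint
is intended by the field's protocols is not settled, so the choice is an
explicit argument with base as default.

## The statistical layer

`hover_lm()` fits ordinary least squares on raw (uncentered) predictor
scales — the intercept stays interpretable — and refuses rank-deficient
designs by naming the collinear columns. Variable importance is measured
two ways (`importance()`): refitting without the predictor (exact nested
$\Delta R^2$) and shuffling its values (permutation $\Delta R^2$, mean
over seeded shuffles, default 999). Species grouping assigns G2 (high) to
species above the across-species mean on either the net cost or the
hover/rest ratio, with strict "above". Species comparisons use the
classical one-way ANOVA, Tukey HSD and Welch t-tests from base R.

Phylogenetic signal uses Abouheif's topology-only test: the proximity
between two tips is the inverse product of the direct-descendant counts of
the internal nodes on the path between them; the statistic is Moran's I of
the standardized trait under the row-normalized proximity (diagonal zero);
the p-value is a one-sided tip permutation test with the $+1$ correction,
seeded. On the 4-taxon tree `((A,B),(C,D))` with trait $(1,1,-1,-1)$ the
statistic is exactly $1/3$ and exhaustive enumeration of all $4!$
assignments gives $p = 1/3$; the permutation p-value converges to the
same value, and under an i.i.d. trait the test's type-I error at
$\alpha = 0.05$ is exact by construction with 199 permutations.

## The synthetic-data generator

The generator's defaults are the study conditions the package is built
around: 13 species; the packaged reference coefficient vectors
(`hover_reference_coefs()`) as the generative morphology-to-metabolism
structure; predictors uniform within ranges bracketing small
aquarium-sized near-neutrally buoyant teleosts (1–20 g, fineness 2.2–9,
dorsal–ventral COM–COB offsets mostly negative); 60-minute oxygen traces
sampled each minute in a 0.615 L chamber; 1000 fps landmark recordings
with 4 degree roll and 2 degree pitch amplitudes (the across-species
averages such recordings show) and a 3 Hz fin beat; trees with unit
branches and i.i.d. or Brownian traits.

Two calibrations deserve explanation:

* **Response noise.** The within-species variance of metabolic rates is
  a free parameter of the generator. The defaults
  (`noise_sd = 170` mg O2 kg$^{-1}$ h$^{-1}$, `ratio_noise_sd = 0.75`)
  were chosen once, a priori, so that the full-model fits on
  default-range designs sit near the explanatory power the regressions
  are known to achieve in data of this kind ($R^2 \approx 0.86$ for the
  net rate, $\approx 0.63$ for the ratio): with independent uniform
  predictors the linear signal variance implied by the reference
  coefficients and ranges is $\approx 427^2$ (net) and $\approx 0.98^2$
  (ratio), and solving $R^2 = \sigma^2_{\mathrm{signal}} /
  (\sigma^2_{\mathrm{signal}} + \sigma^2_\varepsilon)$ gives those noise
  levels.
* **Predictor covariance.** Predictors are drawn independently by
  default, which maximizes identifiability for recovery tests. Real
  morphologies are not independent — deep-bodied fishes tend to be wide —
  so a Gaussian-copula correlation knob (`fineness_cor`) couples the two
  fineness ratios when the collinear regime matters (e.g. showing that a
  reduced model without one fineness ratio retains most of its $R^2$).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: digitization error and landmark occlusion,
non-sinusoidal and amplitude-modulated fin strokes, drifting respirometry
baselines and background respiration, phylogenetically structured
predictor covariance, and hydrodynamic coupling between fins. Generator
round trips certify the estimators, not the biology.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is sharply decided: 13-species
designs for exact recovery (any full-rank design recovers a noiseless
linear response to machine precision); 3-second, 1000 fps signals for
phase extremes; 8–10 second simulations at `dt` of 0.5–1 ms for costs
(RK4 halving error below $10^{-3}$ relative); 200 replicates with 199
permutations for the null calibration of the Abouheif test (with the +1
correction, $P(p \le 0.05)$ is exactly 0.05 under exchangeability);
5-point grids for monotonicity sweeps. Tolerances in the tests mirror the
arithmetic: $10^{-9}$–$10^{-12}$ for exact identities, 5% for the
small-angle growth-rate comparison (the closed form is the $t \to \infty$
asymptote of a $\cosh$), binomial confidence bounds for Monte-Carlo
rates.

## Known limitations

The simulator is single-axis with linear drag and a PD controller; it is
a mechanistic rationale for which morphological variables belong in the
regression, not a hydrodynamic model — translational degrees of freedom,
fin-fin interaction, vortex shedding and the possibility that excessive
leverage is itself destabilizing are all outside it. The respirometry
module assumes a closed, well-mixed chamber with negligible background
respiration. The Abouheif test uses topology only by construction; it
will not detect signal expressed purely in branch lengths. Real-data
reproduction of species-level results requires the original measurement
deposit and is wired in as the pipeline's `paths` mode, exercised in the
tests only with synthetic stand-ins.
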