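---
title: "Methods: simulating epiretinal stimulation of retinal ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating epiretinal stimulation of retinal ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retistim)
```

retistim predicts per-electrode activation thresholds of an epiretinal
prosthesis from first principles: a volume-conductor solve of the
stimulating electric field, multi-compartment biophysics of retinal
ganglion cells (RGCs) placed under each electrode, and a bisection search
for the smallest pulse amplitude that makes at least one cell fire on
every pulse. A simulated-psychophysics harness provides the observational
side: an adaptive Weibull maximum-likelihood estimator of perceptual
threshold with catch-trial auditing, so model-versus-observed comparisons
can be exercised end to end without any patient data.

This vignette records the model, its assumptions, the tunable parameters,
and the numerical and design choices — including every place where the
package had to make a decision the underlying science leaves open.

## 1. The quasi-static field problem

Biological tissue is resistive and linear at stimulation frequencies
(tens of Hz), so the extracellular potential obeys the Poisson equation

$$\nabla \cdot (\sigma \nabla \varphi) = -I\,\delta(\mathbf{x}_0),$$

solved once per electrode for unit current, and time enters only as a
multiplicative waveform: $V_e(\mathbf{x}, t) = \varphi(\mathbf{x})\,I(t)$.
The active electrode is an equipotential terminal carrying the injected
current in total; inactive electrodes float (implemented as
high-conductivity metal voxels, $10^6 \times$ the largest tissue
conductivity, and verified in tests to carry ~zero net current); the
distant return is a grounded grid face behind the vitreous. A contact
impedance $z_c$ (Ω·m²) between retina and sclera models the thin
resistive retinal pigment epithelium as a potential jump proportional to
the normal current density.

**Discretization.** Cell-centered finite volumes on a regular voxel grid
with harmonic-mean face conductances — the robust choice for
piecewise-constant conductivity — and a matrix-free Jacobi-preconditioned
conjugate-gradient solve in C++. The terminal condition is solved at 1 V
and rescaled to the requested current (exact by linearity). Two analytic
oracles pin the accuracy: the point-source potential
$I/(4\pi\sigma r)$ (within 2% in the mid-field at 20 μm voxels) and the
disk access resistance $1/(4\sigma a)$ (within 5% at spacing $a/10$).
For oracle runs the outer boundary can be held at the analytic monopole
far field (`far_field = TRUE`); for a terminal source the far-field
amplitude depends on the still-unknown current, so the solve iterates
two to three times on the current estimate (convergence is geometric
because the boundary correction is small).

**Default conductivities** (S/m): vitreous 1.28, retina 0.10, sclera
0.50, fibrotic capsule 0.2715, RPE contact impedance 0.5 Ω·m². The
source study's conductivity table lives in supplementary material that is
not publicly printed, so these are literature-typical stand-ins, clearly
overridable via `tissue_conductivities()`. The fibrotic value is the
device-calibration midpoint; `calibrate_fibrotic_conductivity()` sweeps
the published encapsulation range 0.15–0.37 S/m to match a measured
impedance (impedance is monotone decreasing in capsule conductivity,
which the routine verifies).

## 2. Parametric patient geometry

The geometry module emulates what ocular imaging provides for a real
implantee, without any imaging input: eye-scale dimensions; a 6×10
electrode array (200 μm disks at 575 μm pitch — the device its letter
labels imply; all overridable) with tilt about both in-plane axes and a
standoff; a retinal surface described by smooth lattice-sampled thickness
and height fields; and a fibrotic capsule enveloping the array. The
scene is a layered slab, not a whole-eye mesh: the neural drive depends
on the local field near the array, and the distant return is absorbed
into the solver boundary.

`generate_synthetic_patient()` samples this space deterministically per
seed. Its default ranges are the stated world: retinal thickness
100–350 μm (degenerate retina), electrode–retina gaps 0–300 μm, tilt
±2°, capsule 0–100 μm. The pose is drawn so that *every* electrode gap
falls inside the requested range (tilt is shrunk when its induced gap
span exceeds the range width — the range is the contract). What the
generator does *not* emulate: real OCT segmentation noise, spatially
correlated degeneration, eccentricity-dependent RGC density, or the true
(unpublished) patient pose — so a green test establishes internal
correctness and stated-range coverage, not fidelity to any individual.

## 3. RGC cable model

Each neuron is the standard reduced block morphology used in epiretinal
modelling — soma (20/20 μm L/d), axon hillock (40/2), sodium-channel band
"SOCB" (40/1.5), narrow segment (90/0.5), distal axon (d = 1 μm, length
absorbing the remainder of the 3,000 μm total) — discretized at 1 μm
compartments and embedded in 3D: the cable starts at the 55 μm soma
depth, ascends vertically exactly 40 μm to the 15 μm nerve-fiber-layer
depth, takes the 90° bend, and then follows the retinal surface contour
along its Jansonius trajectory. The bend sits at the end of the ascent,
which is not a region boundary; the source literature does not say where
the bend falls, and this is the declared convention (the "soma depth" is
the depth of the proximal cable end).

**Membrane.** Five nonlinear channels of the amphibian
(Fohlmeister-lineage) RGC repertoire at 22 °C, no Q10 scaling: Na (m³h),
delayed-rectifier K (n⁴), A-type K (a³h_A), Ca-activated K (gated
algebraically by [Ca]ᵢ), and L-type Ca (c³) whose reversal is recomputed
every step from the instantaneous submembrane [Ca]ᵢ by the Nernst
relation. Rate functions live in one table-driven unit (`fcm_rates()`);
the C++ integrator carries a transcription that tests pin to the R table,
so the brute-force single-compartment oracle exercises exactly the same
kinetics through an independent integration path (classic RK4 versus the
production Rush–Larsen/θ-method cable solve; they agree within 0.1 mV on
a full action potential).

**Per-region maximal conductances.** The study this package re-implements
does not print its per-region table. The defaults
(`default_channel_table()`, mS/cm²) are a reconstruction: gNa 80 (soma),
150 (hillock), 2000 (SOCB), 100 (narrow), 40 (distal axon); gK 18,
gKA 54, gKCa 0.065, gCa 1.5, leak 0.05 everywhere. The
SOCB density was calibrated upward within the range used by band models
so that the package reproduces the published physiology it must predict:
near-threshold spike initiation in the SOCB for ≥90% of resolved neurons
across 50–300 μm electrode standoffs. With a weaker band (e.g. 700
mS/cm²) the passing distal axon wins for laterally displaced somas and
the initiation statistic drops to ~75–85%. Every value is configuration,
not code.

**Resting state.** The leak reversal defaults to `"auto"`: per
compartment, $E_L$ is chosen so the stated resting potential (−65 mV) is
an exact equilibrium of the full channel set. This makes resting
stability a property of the construction (drift < 10⁻⁴ mV over 300 ms)
rather than a tuning exercise.

**Integration.** θ-method on the cable tridiagonal system (backward Euler
by default, Crank–Nicolson for oracle-grade accuracy), Rush–Larsen gating
from precomputed $x_\infty$/$e^{-\Delta t/\tau}$ tables at 0.01 mV
resolution, Thomas solve, implicit Ca-pool decay
(τ = 10 ms, resting 10⁻⁴ mM, shell = compartment volume — the pool
barely matters at threshold timescales but is kept for completeness and
is configurable). Default dt 0.005 ms; halving dt changes responses
< 1%.

## 4. Population placement and axon routing

Somas are spread under each electrode by Lloyd's algorithm: a random
draw in the 500 μm sampling disk relaxed toward a centroidal Voronoi
configuration against a fixed sunflower lattice (deterministic per seed;
the nearest-neighbor-distance coefficient of variation drops relative to
the raw draw, the standard CVT uniformization check). The device-scale
default is 250 neurons per electrode.

Axons follow the published nerve-fiber power-law model: in optic-disc
polar coordinates, a bundle leaving the disc at angle $\phi_0$ follows
$\phi(r) = \phi_0 + b\,(r - r_0)^c$ with separate superior/inferior
fits, $r_0 = 4°$, and 0.286 mm/° retinal scaling. Orientation matters
and is easy to get wrong: $\phi = 0$ points **nasally**, and the
temporal ray $\phi = \pm180°$ through the fovea is the horizontal raphe,
which bundles approach asymptotically (the near-raphe/papillomacular
bundles are the nearly-straight ones, $b \to 0$). Routing a soma means
root-solving for its $\phi_0$; the nasal sliver the fits do not cover
falls back to the nearest admissible bundle rigidly offset in angle
(flagged), and all paths are clipped at the raphe so it is never
crossed. Raphe starts take the superior branch by declared tie-break.
Left eyes mirror the x axis, flipping slope signs exactly. Because the
published hemifield fits are not mirror images, exact superior/inferior
mirror symmetry holds only under the package's `symmetric = TRUE`
option, which is what the symmetry test uses.

## 5. Thresholds

Per neuron, bisection on the pulse amplitude down to a 0.25 μA bracket,
with the activation criterion "at least one detected spike attributed to
every pulse of the train" (attribution windows `[onset, next onset)`;
criterion switchable to any-pulse). Spike detection is an upward 0 mV
crossing with 1 ms refractory merging per compartment. The bracket
expands geometrically from 1,000 μA to a 10 mA cap before declaring a
neuron not excitable (a result, not an error). Monotonicity of the
criterion in amplitude is assumed, as in all such searches; the final
bracket endpoints are by construction one sub- and one supra-threshold
evaluation, and the near-threshold spike pattern is checked for
multi-spike anomalies.

The electrode threshold is the population minimum — single-cell *in
silico* activation as the perceptual proxy. Activation maps report the
active set, the minimum bounding radius of active somas (the
phosphene-extent proxy), and an inverse-distance-weighted threshold
contour (presentational only; natural-neighbor interpolation is not
available in the environment and the contour carries no numeric
contract).

Convergence studies: `axon_length_convergence()` truncates the distal
axon and reports the shortest total length whose threshold is within 1%
of the longest-length reference. At the 0.25 μA bisection quantum and
point-source fields 50–300 μm from the SOCB, thresholds converge already
at 1,000 μm — comfortably consistent with the 3,000 μm sufficiency the
framework adopts. `distance_threshold_table()` sweeps standoff and flags
any monotonicity violation.

## 6. Simulated psychophysics

The observer answers yes/no with probability
$p(I) = \gamma + (1 - \gamma - \lambda)\,(1 - e^{-(I/\alpha)^\beta})$,
anchored so $p = 0.5$ at the true threshold when guess rate γ and lapse
rate λ vanish. The adaptive "hybrid" estimator is a declared
reconstruction (its published description is procedural, not
algorithmic): a coarse multiplicative staircase to 3 reversals, then
maximum-likelihood Weibull fits proposing each next amplitude at the
running 50% point, randomized interleaving across the six-electrode
block, 32 stimulus-absent catch trials, stopping on estimate
stabilization (< 5% change over 10 trials) within a 400-trial session
budget. The fitted psychometric deliberately has *no* guess-rate term —
which is precisely why observer false positives drag estimates leftward,
the bias mechanism the framework needs to exhibit (sign test across
observers, p < 0.01 at γ = 0.25). Catch-trial auditing excludes a block
iff its false-positive rate strictly exceeds 25% (9/32 = 28.1% →
excluded; 8/32 = 25.0% → kept). Comparison statistics are Pearson
correlation with two-sided test, least-squares regression, an optional
observed-threshold floor filter, and one-way fixed-effects ANOVA across
blocks.

## 7. Orchestration and determinism

`run_pipeline()` chains geometry → grid → per-electrode solve →
placement → routing → thresholds → maps, writing plain-text artifacts
(CSV/JSON) plus an md5 manifest. Every stochastic stage draws its seed
deterministically from the master seed; solvers are deterministic; no
artifact carries a timestamp — so identical configurations reproduce
bit-identical output, which is itself an acceptance criterion.
Compartment centers on the distal axon leave the solved grid where the
potential is small; rather than a hard zero (which would inject an
artificial extracellular step at the domain edge), sampling continues
radially as ~1/r from the electrode center. Field solutions are
regenerated rather than persisted in binary (no HDF5 binding is
available in the target environment).

## 8. Numerical choices, degenerate inputs, limitations

* CG tolerance 10⁻⁶–10⁻⁷ relative residual; non-convergence is an error
  carrying the achieved residual. Discrete conservation (unit flux
  through nested boxes) holds to ~10⁻⁴.
* Voxelization snaps electrode metal to at least one voxel layer and
  errors out when the spacing exceeds the thinnest retinal layer or an
  electrode loses all its voxels.
* Degenerate sampler ranges (min = max) are honored exactly — collapsed
  ranges give flat geometry with every gap equal to the standoff, which
  tests rely on.
* Ties in initiation are broken toward the smaller compartment index;
  raphe starts to the superior branch; duplicate convergence lengths
  evaluate identically (pure functions of the scenario).
* Refractoriness: with these kinetics the absolute refractory period is
  1.5–2 ms — a second identical pulse 1.5 ms after a spike fails even 20%
  above threshold, but by 2 ms the threshold elevation has decayed below
  ~5%, so prompt re-excitation at 2 ms is possible. Mammalian or
  Q10-scaled kinetics (out of scope) would lengthen this.
* Limitations carried over from the modelled framework: isotropic
  conductivities, no retinal network (bipolar/amacrine) contribution, no
  RGC-density eccentricity gradient, amphibian kinetics without Q10
  correction, single-domain retina. The synthetic patient is a sampler
  over plausible ranges, not a reconstruction of any individual — the
  headline clinical numbers of the source study (its impedance and mean
  thresholds) depended on one patient's unpublished imaging and are
  treated as magnitude context only.
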