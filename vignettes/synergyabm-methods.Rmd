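---
title: "Methods: an agent-based model for two-drug synergy prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based model for two-drug synergy prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyabm)
```

# Overview

`synergyabm` simulates a population of cancer cells as autonomous agents
on a 3D cubic lattice, exposed to two decaying drugs, and uses the
simulator to (a) calibrate cell-death parameters against dose-inhibition
tables and (b) predict drug-combination synergy through the
Loewe-additivity combination index. This vignette documents the model,
every parameter with its units and default, the synthetic-data
generator, and the numerical and design decisions baked into the
implementation.

# The model

## Lattice and microenvironment

Space is a cubic lattice of `n_per_axis` sites per axis (default 100,
site spacing 5 µm), each site holding at most one cell. The drug field is
**spatially uniform**: every cell sees the same concentration at a given
time. Concentrations follow first-order pharmacokinetic decay, computed
in closed form each step so there is no accumulation of integration
error:

$$c(t) = c_0 \cdot \left(\tfrac{1}{2}\right)^{t/T},$$

where $T$ is the drug's half-life in hours. `decay_drug()` implements
this law; `plot_drug_decay()` draws it.

## Cell states and the per-step update

Time advances in discrete steps of `time_step_h` hours (default 0.72 h;
33⅓ steps per day), and a full cell cycle spans 24 steps. Each step,
cells are visited in a fresh uniform random order and pass through four
phases:

1. **Apoptosis decision.** Each cell combines a *natural* mortality
   hazard and a *drug-computed* mortality:
   $$M_n(t) = 1 - e^{-\lambda t} \;(t > 0;\ 0\ \text{otherwise}), \qquad
     M_c = \theta_0 + \theta_1 d_1 + \theta_2 d_2,$$
   with $t$ the cell's age in hours and $d_1, d_2$ the current (decayed)
   doses in µM. The cell enters apoptosis when
   $c_1 M_n + c_2 M_c > u$ for a fresh uniform draw $u$. An apoptotic
   cell stays on the lattice for `apoptosis_steps` more steps (default
   10) and is then removed, freeing its site.
2. **Proliferation decision.** A quiescent cell turns its cycle ON when
   a fresh uniform draw satisfies $u < P_{pro}$ (default 0.8). Cycling
   cells advance one step through a G0/G1–S–G2–M schedule.
3. **Division.** A cell that completes the 24-step cycle places a
   daughter on a free neighbouring site; if all neighbouring sites are
   occupied the cell becomes quiescent instead (contact inhibition).
4. **Migration.** Non-apoptotic, non-mitotic cells move to one free
   neighbouring site chosen by roulette-wheel selection over normalised
   ranks $R_l \propto P(r_l)\, V_l$, where
   $P(r) = \frac{1}{4\pi D \Delta t} e^{-r^2/(4\pi D \Delta t)}$ is a
   diffusion-like distance kernel ($D$ = 10 µm²/s by default) and $V_l$
   weights the candidate's crowding: 1 for 1–2 occupied neighbours, 1/4
   for 3–4, 1/8 for 5–6, and 1/16 for an isolated site, so cells prefer
   moderately populated sites. A cell with no free neighbour becomes
   quiescent.

`run_simulation()` returns a tidy per-step trajectory (counts, births,
removals, drug concentrations, running mortality) with the final cell
table and optional full snapshots as attributes; `autoplot()` draws it.

## Parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `lambda` | 1/h | 1 | natural-mortality hazard rate |
| `c1`, `c2` | – | 0.025, 0.06 | apoptosis mixing weights |
| `theta` | –, 1/µM, 1/µM | (0.1686, 0.0067, 0.0019) | dose–mortality coefficients |
| `p_pro` | probability | 0.8 | proliferation (cycle-ON) probability |
| `time_step_h` | h | 0.72 | step length |
| `n_per_axis` | sites | 100 | lattice edge |
| `n_cells` | cells | 100 | initial population |
| `apoptosis_steps` | steps | 10 | apoptosis duration |
| `motility_D` | µm²/s | 10 | migration kernel diffusivity |
| `half_life_h` | h | per drug | drug decay half-life |

Half-lives shipped with the default pairs reflect published human
pharmacokinetics: gefitinib 48 h, erlotinib 36 h, imatinib 18 h,
rosiglitazone 3.5 h, quinacrine ≈ 228 h.

# Calibration

Calibration is two-stage, mirroring how wet-lab dose-inhibition data
constrain the model.

**Local stage.** Triplicate absorbance-derived inhibition fractions are
stabilised per dose row by a bootstrap mean (`bootstrap_mean()`, B =
1000 resampled means by default), then the linear dose–mortality
coefficients θ are fitted by batch gradient descent on standardised
doses (`fit_local()`). The loss is the half mean squared error; the fit
agrees with closed-form least squares to numerical precision (this is
enforced by the test suite against `stats::lm()`) and reports the
overall regression F-test p-value. Fitting always sees the **raw**
linear model; clamping of $M_c$ into [0, 1] happens only inside the
simulator, where a probability is required.

**Global stage.** The remaining parameters $(c_1, c_2, \lambda)$ are
fitted by a particle-swarm optimiser (`pso_optimize()`) minimising a
weighted squared error between simulated endpoint mortality
$M_s = (N_0 - N_1)/N_0$ and the experimental values, with per-pair
weights $1/\max(M_e)^2$ so pairs with different mortality scales
contribute comparably. `make_endpoint_simulator()` evaluates the engine
with **common random numbers** (a fixed seed set per evaluation), which
makes the stochastic objective quasi-deterministic and lets the swarm
descend to the replicate-noise floor. Validation uses
`crossvalidate()` (train on one third, test on the rest, by default;
leave-one-out optional), `relative_error()`, and a paired Wilcoxon
signed-rank test (`significance_test()`), where p > 0.1 is read as "no
significant difference" between simulated and experimental series.

**PSO settings.** Constricted PSO with inertia w = 0.72 and cognitive =
social coefficient 1.49 (the standard constriction regime), velocities
clamped to 20% of the box range, absorbing boundaries (a velocity
component is zeroed when its position is clamped), zero initial
velocity, and an elitist restart that re-scatters all but the best
particle after 8 non-improving iterations. The restart guards against
premature swarm collapse, which matters because the objective landscape
has a strong $c_1$/$c_2$ trade-off ridge.

# Synergy prediction

`find_iso_dose()` inverts a single-agent dose–effect curve for the dose
producing X% effect (default 50%), by deterministic bisection, or, for
stochastic simulated curves, by isotonic-regression smoothing of a
12-point dose grid followed by linear interpolation. For a combination
at observed doses $(d_1, d_2)$ reaching the same effect, the
combination index is

$$CI = \frac{d_1}{D_{X,1}} + \frac{d_2}{D_{X,2}},$$

classified as antagonism (CI ≥ 1.1), additive (0.9 ≤ CI < 1.1),
synergism (0.3 ≤ CI < 0.9), or strong synergism (CI < 0.3).
`synergy_report()` evaluates fixed dose-ratio rays (e.g. "4:1"), flags
rays that cannot reach the target effect as `"unreachable"` rather than
extrapolating, and has an `autoplot()` method.

# Synthetic data generator

`generator_spec()` + `generate_table()` produce seeded triplicate
dose-inhibition tables with known ground truth for end-to-end testing.
The default design is 4 dose ratios (4:1, 3:2, 2:3, 1:4) × 6 total doses
(5–80 µM) plus 6 single-agent anchor rows — 30 rows spanning 0–100 µM,
the concentration range over which a linear dose–mortality model is a
defensible local approximation. Replicates are the clamped linear mean
plus truncated Gaussian noise (σ = 0.03 on the inhibition-fraction
scale, a typical triplicate assay spread). The spec's defaults for
$(c_1, c_2, \lambda)$ = (0.025, 0.06, 1) were chosen once so that, at
per-step application of the apoptosis rule, 48-h endpoint mortality
spans roughly 0.4–0.95 across the dose grid — i.e. the observable is
informative, neither saturated nor flat.
`generate_simulator_consistent_table()` replaces the linear mean with
actual engine endpoint mortality (under the spec's seed), so parameter
recovery can be tested without model misspecification.
`default_drug_pairs()` wires three reference pairs with the half-lives
above.

**Generator realism and limits.** The generator captures triplicate
noise, bounded fractions, dose-grid structure and (optionally) full
simulator consistency; it does not model plate effects, heteroscedastic
noise at high inhibition, or inter-batch drift.

# Design decisions and numerical choices

- **Decision-rule direction.** Apoptosis triggers when the combined
  hazard *exceeds* the uniform draw ($c_1 M_n + c_2 M_c > u$); over many
  draws the acceptance frequency equals the clamped hazard.
- **ON/OFF boundary.** $u$ exactly equal to $P_{pro}$ is OFF (strict
  `<`); a measure-zero choice, fixed for determinism.
- **Cell age, not global time,** drives the natural hazard $M_n$; ages
  are initialised uniformly up to one cycle (24 h), and by default the
  initial cycle position is derived from age
  (`init_cycle_from_age = TRUE`), which desynchronises division waves.
- **Phase schedule.** The 24-step cycle is split G0/G1 = 11, S = 8,
  G2 = 4, M = 1 steps (proportions of a canonical 24-h mammalian cell
  cycle); configurable via `cycle_schedule`.
- **Per-step hazard application.** The apoptosis rule is applied once
  per cell per step with $M_c$ from the current decayed doses; the
  calibrated $c_1, c_2$ absorb the per-step-versus-endpoint timescale.
- **Clamping.** $M_c$ is clamped into [0, 1] inside the simulator only,
  never in the fitting loss.
- **CI boundaries.** CI = 0.9 is classified additive, CI = 1.1
  antagonism, CI = 0.3 synergism (lower-closed intervals).
- **Problem sizes.** The 100-site lattice edge, 100 initial cells,
  0.72-h step, 48-h calibration endpoint (67 steps), and the 30-row
  generator grid are this package's own defaults, chosen to keep a full
  two-stage calibration within minutes on one CPU while leaving the
  lattice far from confluence; all are configurable.
- **Reproducibility.** All stochastic entry points take seeds; the C++
  engine draws from R's RNG stream, so `set.seed()` governs everything.

# Limitations

- The drug field is uniform — no diffusion gradients, vasculature or
  cell-level pharmacokinetic heterogeneity.
- Dose–mortality is linear in dose; sigmoidal saturation outside the
  calibrated 0–100 µM window is not represented.
- One cell per site and face-neighbour moves coarse-grain real motility;
  the lattice spacing (5 µm) is below typical cell diameters.
- The combination index inherits the usual Loewe caveats: it is
  effect-level-specific (X = 50% by default) and assumes monotone
  single-agent curves.
- Endpoint mortality is the only calibrated observable; dynamics between
  0 and 48 h are emergent, not fitted.
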