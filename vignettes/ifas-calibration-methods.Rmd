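---
title: "Automated calibration of a steady-state IFAS model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated calibration of a steady-state IFAS model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Integrated fixed-film activated sludge (IFAS) reactors combine suspended
biomass with biofilm grown on submerged media. Biokinetic models of such
systems are heavily over-parameterized: the bundled registry carries 68
kinetic and stoichiometric constants, while a typical calibration data set is
three composite effluent determinands (BOD, TN, TSS). `ifascal` implements
the systematic answer to that mismatch as a reusable pipeline:

1. **Screen** all parameters with Method-of-Morris elementary effects and
   keep the ten most influential per model output.
2. **Decompose** the output variance of the screened set with Sobol indices
   to separate genuinely influential parameters (total-order index >= 0.05)
   from those that only matter through interactions, and to detect
   collinearity.
3. **Estimate** the influential set jointly with a from-scratch Nelder-Mead
   simplex against observed effluent quality under a normal-error
   (weighted least squares) likelihood.
4. **Quantify** the output uncertainty contributed by the calibrated
   parameters with Monte-Carlo propagation and GUM-style expanded
   uncertainties (`U_e = 1.96 U_c` for 95% coverage).
5. **Validate** the calibrated model under alternative dissolved-oxygen
   regimes (0.5 and 4.5 mg/L besides the 2.5 mg/L calibration regime).

The pilot system behind the bundled fixtures is a 20 m3 aerated IFAS tank
fed at 1.8 m3/h (HRT 11.1 h), SRT 11 d, MLSS ~2000 mg/L, with a secondary
clarifier; influent/effluent characterizations for three DO regimes are
shipped as plain CSV.

# The reduced process model

Industrial IFAS simulators couple a comprehensive activated-sludge model
with a one-dimensional biofilm and a layered settler. Those components are
proprietary; `ifascal` ships a deliberately reduced stand-in whose every
equation lives in one auditable file (`R/gujer.R`). It is a two-step
nitrification/denitrification Monod model over 16 state variables:

* COD pools: readily/slowly biodegradable substrate, soluble and particulate
  inerts; nitrogen pools: ammonia, soluble/particulate organic N, nitrite,
  nitrate, dinitrogen; biomass: heterotrophs, ammonia oxidizers, nitrite
  oxidizers — each with a suspended and an attached (biofilm) pool.
* Processes: aerobic heterotrophic growth (yield `X52`), anoxic growth on
  nitrate and on nitrite (yield `X53`, the nitrite pathway scaled by the
  reduction factor `X12`, oxygen inhibition switch `K/(K+S_O)` with
  `K = X15`), death-regeneration decay (`X16`, inert fraction `X61`),
  two-step nitrification (`mu_NOB = X27` for the second step), hydrolysis,
  ammonification, and first-order attachment/detachment exchange with the
  media.
* Electron-accepting equivalents use exact fractions 40/14 = 2.86 gCOD/gNO3-N
  and 24/14 = 1.71 gCOD/gNO2-N, so each stoichiometric row conserves COD
  (oxygen negative) and nitrogen to machine precision
  (`continuity_check()`).

Deliberate simplifications, each a documented design choice:

* **Attached biomass** is a fully retained, capacity-capped pool sharing the
  bulk liquid: attachment saturates and attached growth stops as the
  inventory approaches `attached_capacity_gm3`. There is no 1-D diffusion
  model; instead the biofilm sees a reduced oxygen level
  (`biofilm_do_factor`, default 0.2), a crude but effective stand-in for
  oxygen penetration limits that lets simultaneous
  nitrification/denitrification happen at a 2.5 mg/L bulk setpoint, as
  observed in real IFAS systems.
* **DO is a fixed setpoint**, not solved from aeration: the study regimes are
  defined by setpoints (0.5/2.5/4.5 mg/L).
* **The clarifier is an ideal point-settler**: a non-settleable fraction
  `f_ns` (default 0.005) of mixed-liquor solids escapes with the effluent;
  solids are conserved exactly (`clarifier_split()`).
* **Influent fractionation** splits total COD 20/50/5/25% into
  S_S/X_S/S_I/X_I and organic N 40/60 into its soluble/particulate pools
  (configurable); TN - TKN enters as nitrate. These are typical municipal
  values; the split reconstructs COD and TKN exactly and reports the BOD/TSS
  it implies.
* Composite conversions: BOD = 0.66 x biodegradable effluent COD,
  COD:VSS = 1.48, VSS/TSS = 0.63 (from the influent characterization).
* Particulate inerts carry no nitrogen, so the influent TKN closure is exact
  and decay routes all biomass nitrogen to the particulate organic pool.
* No pH/alkalinity chemistry, no temperature correction, no dynamic
  simulation as a user feature (time integration exists as an independent
  test oracle only).

## Steady-state solver

The mass balances (dilution for solubles, SRT-controlled wastage for
suspended particulates, full retention for attached pools) are solved as an
algebraic system by damped Newton iteration with positivity projection.
Numerical choices:

* Convergence is componentwise `|F_i| < tol * max(1, |x_i|)` with
  `tol = 1e-10`: a pure absolute criterion below 1 mg/L, relaxed
  proportionally above it because residual entries at the 1e4 mg/L scale
  carry ~1e-11 of floating-point cancellation noise.
* Cold starts first run a linearized implicit-Euler pseudo-transient phase
  (dt capped at 2 d). The cap matters: with an unstable mode of rate lambda
  the step amplification is `1/(1 - lambda dt)`, which only tracks the
  physically growing mode while `lambda dt < 1`; uncapped steps behave like
  Newton and can land on unstable roots.
* These balances genuinely have multiple roots (washout states coexist with
  the operating state whenever growth exceeds dilution). After convergence
  the Jacobian's eigenvalues are checked; a root with a positive real part
  is rejected, washed-out pools are reseeded, and a small-step transient
  (dt <= 0.1 d) is followed into a stable basin. The solver therefore
  returns the *attracting* steady state — the one a plant would settle
  into — and genuine washout (e.g. nitrite oxidizers under oxygen stress)
  remains a valid stable answer.
* The iteration cap (500) counts Newton steps; continuation phases are
  bounded by fixed step counts. Non-convergence is reported, never hidden;
  the evaluator substitutes a penalty value and counts failures.

The independent oracle for all of this is brute-force time integration of
the same balances (`deSolve::lsoda`, tolerances 1e-12, integrated in 5000 d
chunks until the scaled derivative vanishes); solver and oracle agree to
better than 1e-6 relative on random parameter draws, and in practice to
~1e-8.

# Screening: Method of Morris

Trajectories use the standard construction: p = 4 grid levels, perturbation
`delta = p / (2(p-1)) = 2/3`, `r` trajectories of `k+1` points costing
`r(k+1)` runs. Elementary effects are computed in unit-hypercube
coordinates, so `mu*` is range-scaled and comparable across parameters with
different units. Ranges default to +/-50% of each default value, mirroring
the variance stage. Statistics per factor: mean `mu`, absolute mean `mu*`
(robust to sign cancellation in non-monotonic responses), standard
deviation `sigma` (sample form, divisor r-1 — the conventional reading of
the summary-statistic definitions), the ranking score
`B = sqrt(mu*^2 + sigma^2)`, and the polarity `sign(mu)`.

Scores are min-max normalized to [0, 1]; the influence threshold is an
inclusive 0.1 on normalized `mu*`, and the ten top-B factors per output are
forwarded to the variance stage (ties broken by `mu*`, then registry order,
for determinism). Trajectories containing non-finite model outputs are
dropped and counted; above 20% dropped the summary refuses to proceed.

# Variance decomposition: Sobol indices

Saltelli-type designs stack base matrices A and B with cross matrices AB_i
(and BA_i when second-order indices are requested): `n(k+2)` or `n(2k+2)`
rows. Estimators — recorded in the result metadata — are Saltelli-2010 for
first order, Jansen for total order, and the Saltelli-2002 cross-matrix
closed form for pairwise indices. Confidence intervals are percentile
bootstrap over resampled base rows (95%, 200 replicates by default).

Sampling uses a seeded Latin hypercube (`lhs`) over the +/-50% ranges. A
quasi-random Sobol' sequence would be the textbook choice for this step; no
installed R package provides one and direction-number tables are exactly
the kind of primitive one should not hand-roll, so the stratified LHS —
which keeps the variance-reduction benefit and exact seed determinism — is
used instead and noted in the design metadata.

Influence requires a total-order index >= 0.05; an interaction flag is
raised when `ST - S1 >= 0.05` or any pairwise index reaches 0.05. Small
negative index estimates are Monte-Carlo noise and are reported as-is
(flagged below -0.05, never clipped). The estimators reproduce the Ishigami
benchmark's closed-form indices within bootstrap error at n = 2^14 and the
analytic variance split of additive models.

# Parameter estimation: Nelder-Mead

The calibration objective is the negative log-likelihood of independent
normal observation errors, i.e. the weighted sum of squares
`sum(((y_j - t_j)/sigma_j)^2)` over BOD/TN/TSS. Scales `sigma_j` default to
the reported spread of each observed effluent determinand where the
characterization table prints one, else 5% of the target — the likelihood
needs a scale and printed spreads are the least arbitrary source.

The simplex implementation is from scratch: reflection 1, expansion 2,
contraction 0.5, shrink 0.5; box constraints by projecting proposed
vertices onto the bounds; initial simplex at the registry defaults plus 5%
of each range per axis (flipped inward at a bound, 0.00025 of the range if
squeezed). "No further significant change in parameters" is quantified as
relative vertex spread < 1e-8; a vanishing value-spread alone is not
accepted until the simplex is also geometrically small, because a simplex
straddling a symmetric minimum has zero value spread at finite size. The
iteration cap returns the best vertex flagged "not converged" rather than
failing.

## Identifiability: what three observations can and cannot pin down

Joint estimation of four parameters from three exact observations is
structurally underdetermined: the map from (X52, X53, X16, X12) to
(BOD, TN, TSS) cannot be injective, so the zero-noise objective has a
manifold of exact fits. On this model the degeneracy is aggravated by
classic chemostat algebra — the effluent substrate concentration is
yield-independent, so BOD and TSS respond almost collinearly to X52 and
X16, and X53/X12 trade off against each other inside TN. The simplex
reaches an (exact) zero of the objective, but *which* zero depends on the
start: synthetic-recovery experiments show X16/X12 landing ~20% away from
their true values at an objective of ~1e-13, and the nitrite-pathway factor
is particularly free. This is a property of the calibration design (three
composite targets), not of the optimizer; the package surfaces it instead
of hiding it. An identifiable subset behaves as theory predicts: the two
yields (X52, X53) are recovered exactly from noise-free synthetic
observations and to well under 1% of their ranges at 2% observation noise.
Practical consequences: treat the estimated values of near-collinear
parameters as one consistent calibration, not as individually identified
constants, and read the Sobol interaction report before trusting any of
them in isolation.

# Uncertainty analysis

Influential parameters receive uniform PDFs over their literature ranges
(bundled fixture: 0.63-0.69 for X52, 0.52-0.57 for X53, 0.23-0.70 d^-1 for
X16, 0.375-0.48 for X12 — the latter encoding half of the reported total
denitrification reduction range under an equal NO2/NO3 split). Uniform is
the conservative choice when only limits are known; normal and triangular
shapes are available with standard uncertainties `a/sqrt(3)`, sample sd,
and `a/sqrt(6)` respectively. Parameters in the calibrated subset without
literature values fall back to their +/-50% screening ranges, which is
conservative and stated in the spec of each run. Monte-Carlo propagation
(default n = 1e5 at full scale, 1e4 in the bundled reports) holds the
remaining parameters at their calibrated values, reports per-output mean
and combined standard uncertainty `U_c` (sample sd), the exact identity
`U_e = 1.96 U_c`, and 50-bin histogram data plus raw samples. Runs abort if
more than 1% of evaluations fail to converge.

# Synthetic observations

`generate_synthetic_observation()` evaluates the model at a known true
parameter point and adds independent normal noise per output (truncated at
zero), reproducing the structure of a pilot-plant effluent characterization:
three composite outputs with spreads. It emulates observation noise only —
not influent variability, not model-structure error, not autocorrelated
sampling campaigns. Green recovery tests on these observations therefore
demonstrate that the pipeline machinery is self-consistent, not that the
reduced model (or any model) matches a physical plant.

# Problem sizes

Full field-study scale is r = 100 Morris trajectories (6900 runs over the
68-parameter registry), Sobol base n = 10,000, Monte-Carlo n = 1e5. The
bundled model evaluates in milliseconds, so the package's own reports use
r = 100, Sobol n = 256 (5,632 runs per output with second-order blocks),
bootstrap 200, Monte-Carlo n = 1e4; the unit-test suite scales further down
(r = 6-30, n = 32-128). These sizes are the package's reporting choices;
all of them are settings of `pipeline_settings()`.

# Known limitations

* The reduced biokinetics are a stand-in: sensitivity *magnitudes* (which
  parameters clear the thresholds, exact index values) are properties of
  this model. Index values reported for proprietary plant simulators are
  not reproducible here and are not targeted.
* On this stand-in, influence is spread across more parameters than the
  four headline ones — nitrifier kinetics and the biomass nitrogen content
  also clear the 0.05 total-order threshold on TN — so the default
  calibrated subset is larger and even less individually identifiable;
  override `pipeline_settings(subset = ...)` to calibrate a chosen set.
* The attached-biomass treatment has no depth resolution; the biofilm DO
  factor is a single tunable standing in for diffusion physics.
* Validation against the low-DO regime is expected to be poor (the model
  keeps nitrifying/denitrifying at 0.5 mg/L more readily than a stressed
  plant), which mirrors the known difficulty of representing IFAS behaviour
  under severe oxygen stress.
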