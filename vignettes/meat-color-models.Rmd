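---
title: "Modelling oxidative browning of beef surfaces in cold storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxidative browning of beef surfaces in cold storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myocolor)
```

## The problem

Consumers buy bright-red beef and reject brown beef. The color is set by the
redox state of myoglobin at the cut surface: deoxymyoglobin (Mb, purplish),
oxymyoglobin (MbO2, bright red, formed during "blooming" when a vacuum-packed
cut first meets oxygen) and metmyoglobin (MMb, brown, the oxidized Fe3+
form). During refrigerated storage under a modified atmosphere the surface
slowly browns; the main drivers are storage temperature and headspace oxygen
content. `myocolor` implements two complementary models of this process,
calibrated and exercised entirely on data the package can generate itself.

## The reaction-diffusion model

The slab of meat is one-dimensional: depth `x` runs from the exposed surface
(`x = 0`) into the cut. Every species reacts under mass action,

$$\frac{dC_i}{dt} = \sum_{j=1}^{N} a_{ij}\, k_j \prod_{a_{ij}<0}
C_i^{-a_{ij}},$$

and dissolved oxygen additionally diffuses,

$$\frac{\partial O_2}{\partial t} = D_{O_2}\frac{\partial^2 O_2}
{\partial x^2} + \text{(reaction terms)},$$

with a Dirichlet condition at the surface (dissolved O2 fixed at solubility
times the headspace percentage) and zero flux at the tray contact. Rate
constants known at a 20 °C reference are moved to storage temperature with a
single activation energy through the relative Arrhenius form

$$k_j(T) = k_j(T_{ref})\,\exp\!\left(-\frac{E_a}{R}\Big(\frac1T -
\frac1{T_{ref}}\Big)\right),$$

which returns exactly $k_j(T_{ref})$ at the reference temperature (the
one-exponential absolute form does not, which is why the relative form is
used). One $E_a$ for every reaction keeps the parameter count identifiable
from small storage datasets.

Myoglobin forms are carried as dimensionless fractions summing to 1 at every
node; oxygen is in mol m$^{-3}$. Rate-constant units therefore differ by
reaction order and are documented inside the scheme file.

### The default scheme is a stand-in

The full published myoglobin oxidation scheme has 22 reactions whose
constants are not reproduced here, so the scheme is a *configuration input*
(`read_scheme()`, JSON or YAML, strictly parsed). The packaged default
(`default_scheme()`) is a deliberately small surrogate with four species and
five reactions:

* oxygenation `Mb + O2 -> MbO2` and deoxygenation `MbO2 -> Mb + O2`, fast
  relative to browning (the pool equilibrates within tens of minutes);
* autoxidation from **both** forms, `Mb -> MMb` (faster) and
  `MbO2 -> MMb` (slower);
* metmyoglobin reduction `MMb -> Mb`.

Two autoxidation channels rather than one is a deliberate design choice.
Under the Dirichlet boundary the surface chemistry is local, so the oxygen
dependence of surface browning comes entirely from how the rate of MMb
formation responds to the bloomed fraction. A single `MbO2 -> MMb` channel
saturates once the surface is bloomed, making browning almost independent of
headspace oxygen; a single `Mb -> MMb` channel over-protects, so a surface
under 100% oxygen essentially never browns. Splitting the flux between the
two -- with the deoxy form autoxidizing faster, as it does chemically --
reproduces the observed behaviour: raising headspace oxygen from 20% to
100% delays browning by a few days without abolishing it. The constants are
derived analytically in `tools/tune_default_scheme.R` (fast-equilibrium
algebra targeting a ~10-day surface color plateau at 2 °C / 20% O2) and are
*not* the published scheme; anyone with the full scheme can drop it in.

### From chemistry to color

There is no simple published map from myoglobin fractions to CIELAB
coordinates. The package uses the threshold rule on the surface ratio
$r = \mathrm{MbO_2}/(\mathrm{MMb}+\mathrm{Mb}) =
\mathrm{MbO_2}/(1-\mathrm{MbO_2})$: normalized redness $a^*/a^*_0 = 1$ while
$r \ge S$, and $r/S$ below. The $r/S$ branch (the ratio *normalized by its
value at the threshold*) makes the map continuous at $S$ and bounded in
$[0,1]$; the raw piecewise variant, which jumps at $S$ and can exceed 1, is
retained behind `rule = "literal"` for comparison only. A sharp threshold is
itself an idealization -- reality likely has a window of thresholds -- so a
smooth soft-threshold variant is available as an opt-in
(`smooth = TRUE`), default off.

### Numerics

Method of lines on a uniform grid with second-order central differences;
time integration by a banded-Jacobian implicit BDF solver
(`deSolve::ode.1D(method = "bdf")`), suited to rate constants spanning five
orders of magnitude. Defaults: `rtol = 1e-6`, `atol = 1e-12`. The tight
absolute tolerance matters: the oxygen front at the bloom boundary is steep,
and looser `atol` produces small negative undershoots; the solver enforces a
$-10^{-9}$ floor, clips anything less negative to zero on output, and checks
myoglobin-fraction conservation to $10^{-6}$ at every node and time.

Because the surface oxygen value is pinned by the boundary condition and
the myoglobin forms do not diffuse, the surface node's chemistry is local:
the surface color series is mathematically independent of the mesh. Mesh
refinement (`mesh_convergence()`, e.g. 100/200/400 nodes) therefore shows
differences at the integrator-tolerance floor (~1e-7 and below) rather than
a systematic decay -- the study is kept as a guard against discretization
artefacts, and interior profiles *do* depend on the mesh. Slab depth
defaults to 0.02 m (ribeye steaks are 2-3 cm thick), oxygen solubility to
0.017 mol m$^{-3}$ per percent headspace O2, diffusivity to
$10^{-10}$ m$^2$ s$^{-1}$; none of these is known precisely for this system
and all are configurable in the scheme file.

## The Gompertz phenomenological model

Measured $a^*(t)$ kinetics show three phases -- a lag plateau, an
exponential-like decay, and a final plateau -- captured by a modified
Gompertz curve

$$a^*(t) = a^*_0 + (a^*_f - a^*_0)\exp\!\left(-\exp\!\Big(
\frac{\mu_{max}\,e\,(lag - t)}{(a^*_f-a^*_0)\cdot s} + 1\Big)\right),$$

where $s$ is a denominator scale. With $s = 1$ this is the classical
Zwietering parameterization whose steepest tangent is exactly $\mu_{max}$;
the package default $s = \ln 10$ keeps the extra log-10 factor that the
surrounding regressions were built with, under which the realized steepest
slope is $\mu_{max}/\ln 10$. The factor's placement is typographically
ambiguous in the source material, so it is exposed as `denom_scale` and
fitted $\mu_{max}$ values are only comparable under one fixed choice.

The two shape parameters are regressed on the storage factors on a log-10
scale with fixed term sets:

* $\log_{10}(lag) = b_0 + b_1\,pO_2^2 + b_2\,pO_2\!\cdot\!Angle +
  b_3\,T\!\cdot\!pO_2 + b_4\,Angle^2 + b_5\,pO_2$
* $\log_{10}(-\mu_{max}) = c_0 + c_1\,pO_2 + c_2\,pO_2^2 + c_3\,Mat^2 +
  c_4\,pO_2\!\cdot\!Mat + c_5\,Mat\!\cdot\!Angle$

with factors in natural units and `Mat` the aging (maturation) time in days
(the source equations use two spellings for what can only be the same
factor; both are read as aging time). The coefficients were never published:
they are always *estimated from data* (`fit_factor_regression()`), never
hard-coded. Note the structural quirk that temperature enters the lag model
only through the $T \cdot pO_2$ interaction -- a strong temperature effect
at 20% O2 then implies a five-fold stronger one at 100% O2, which
constrains how the synthetic truth below can behave.

`fit_gompertz()` is bounded Levenberg-Marquardt over
$(a^*_0, a^*_f, \mu_{max}, lag)$ with $lag \in [0, t_{max}]$ and
$\mu_{max} \le 0$. Starting values use level-crossing heuristics (the times
at which the series passes 25% and 75% of its total drop) because raw
finite-difference slopes are hopeless at dense sampling under noise.
Constant series are returned as flagged degenerate fits rather than
optimizer failures.

## Calibration of S and Ea

`calibrate_rd()` identifies the two free parameters of the
reaction-diffusion color prediction by least squares against observed
$a^*/a^*_0$ kinetics, pooling squared residuals over all storage conditions
with equal weight (no per-condition weighting is defensible without error
models). Three stages mirror the original coarse-to-fine protocol:

1. direct scan over integer $S$ candidates {1,2,3,4} and an $E_a$ grid
   (25-40 kJ/mol, step 2.5) on a 100-node mesh -- one simulation per
   $(E_a,\,\text{condition})$, since the trajectory does not depend on $S$;
2. Levenberg-Marquardt refinement of $E_a$ at each shortlisted $S$ (the LM
   start is nudged strictly inside the box bounds; starting exactly on a
   bound degenerates the finite-difference Jacobian);
3. recomputation of the per-condition root-RSS table on the 400-node mesh
   at each refined pair; smallest mean wins, ties toward smaller $S$.

Model output is linearly interpolated to the observation times. A dataset
to which the model is insensitive (e.g. a frozen scheme) yields a flat
objective; the function warns and returns the minimal-RSS candidate instead
of fabricating precision. Whether the original protocol refined $E_a$
jointly across conditions or per condition is not stated; this
implementation pools (one $E_a$ for all conditions), which matches the
single-$E_a$ modelling assumption.

## The synthetic-data generator

No storage-experiment data are deposited anywhere, so the package generates
its own, emulating the experiment's structure: a four-factor, three-level
definitive screening design (13 runs: fold-over of an order-6 Paley
conference matrix plus a centre run, first four columns -- the standard
construction when studying four factors), levels T ∈ {2, 6, 10} °C, O2 ∈
{0, 20, 100}%, aging ∈ {0, 7, 14} d, angle ∈ {0, 45, 90}°, and $a^*/a^*_0$
sampled every 15 min for 15 days (1441 points) with additive Gaussian noise
(σ = 0.02 by default, there being no published measurement-error model) and
clipping to [0, 1.05].

The generating "truth" coefficients (`default_truth()`) are fabricated and
clearly labelled synthetic. They encode the qualitative storage effects
where the experiments demonstrate them: lag ≈ 10 d at 2 °C / 20% O2
shrinking to ≈ 6 d at 10 °C, oxygen enrichment extending the lag by a few
days at 2 °C, a short lag without oxygen, and lags within [1, 14] d over
the whole design (validated at generation time). Because temperature enters
the lag regression only via $T\cdot pO_2$, a temperature effect of that
size forces the 100% O2 lag at 10 °C down to ~1.3 d -- the term structure
cannot express an oxygen-protective effect at every temperature while
keeping lags in range, so the defaults prioritize the low-temperature
behaviour that matters for cold-chain practice.

A second generator route, `synth_from_rd()`, produces self-consistency data
from the reaction-diffusion model itself at known (S, Ea) -- the backbone of
the calibration recovery studies.

### What passing tests do and do not show

The synthetic data share the design, sampling, kinetic shape and noise
scale of the real measurements, but not their messiness: no spatial
heterogeneity of browning onset, no drift in illumination or camera
response, no microbial contribution, and an exactly Gompertz (or exactly
model-consistent) mean curve. Parameter-recovery results on these data
demonstrate that the estimation machinery is correct and well-conditioned
at realistic noise -- not that the models are adequate for any particular
real cut of meat.

## Problem sizes and reproducibility

The shipped studies use hourly sampling over 15 days (361 points per
condition) for calibration datasets, 100-node meshes for scans and
400-node meshes for verification, and 20 seeded replicates for the noisy
recovery studies; these are the package's own desk-scale choices and are
all arguments. Every stochastic routine takes an explicit seed and restores
the caller's RNG state, so identical seeds give byte-identical datasets.
`scripts/acceptance.R` reruns the full self-consistency calibration and the
oxygen-delay comparison from scratch and writes the recovered values as
JSON.

## Known limitations

* The default scheme is a tuned surrogate, not the published 22-reaction
  chemistry; absolute times are only as good as its constants.
* One-dimensional, single-compartment: no fat compartments, no
  mitochondrial reduction pathway, no microbial effects, no MbFe4+ species,
  no CO2 transport under modified atmospheres.
* The Dirichlet surface boundary ignores any external mass-transfer
  resistance; with it, surface color cannot depend on the mesh (see above).
* A single sharp threshold S and a single Ea for all reactions are
  deliberate simplifications inherited from the modelling approach.
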