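---
title: "Models and methods behind carrierkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind carrierkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierkin)
```

`carrierkin` analyses proteoliposome transport assays for solute carriers
of the mitochondrial (SLC25) family, together with the two biophysical
assays that routinely accompany them: thermal unfolding by nano
differential scanning fluorimetry (nanoDSF) and oligomeric-state
determination by size-exclusion chromatography (SEC). This vignette
explains the models, their assumptions, the tunable parameters, and the
design decisions taken where the underlying experimental literature leaves
the analysis under-specified.

## The transport experiment and its model

A reconstituted carrier is assayed by loading liposomes with unlabelled
substrate (the *internal* pool, concentrations of order 0.1–1 mM), removing
external substrate, and starting homo-exchange by adding radiolabelled
substrate outside (0.5–50 uM). Because the exchanged species are chemically
identical, there is no net chemistry: the carrier merely shuttles label
between two finite pools. Homo-exchange deliberately avoids the
complications of charge imbalance or proton coupling that attend
hetero-exchange.

### Two-pool tracer model

With the chemical concentrations at steady state, the unidirectional
exchange flux $J$ (nmol/min per well) is constant in time and the labelled
amount inside, $L_{in}$, obeys the linear ODE

$$\frac{dL_{in}}{dt} = J\left(\frac{L_{out}}{N_{out}} -
  \frac{L_{in}}{N_{in}}\right),$$

where $N_{in}, N_{out}$ are the total (labelled + unlabelled) substrate
amounts of the two pools and $L_{in}+L_{out}$ is conserved. The solution is
a single exponential,

$$L_{in}(t) = L_\infty\left(1 - e^{-\lambda (t-d)}\right),\qquad
\lambda = J\left(\tfrac{1}{N_{in}}+\tfrac{1}{N_{out}}\right),\quad
L_\infty = L_{tot}\frac{N_{in}}{N_{in}+N_{out}},$$

used in closed form by the simulator (no numerical integrator). As
$N_{out}/N_{in}\to\infty$ this reduces exactly to the exchange equation
fitted to experimental curves,

$$Q(t) = \beta\left(1 - e^{-\frac{k}{\beta}(t-d)}\right),$$

with $\beta = N_{in}/m_{prot}$ (nmol/mg) and $k$ equal to the specific
flux (nmol mg$^{-1}$ min$^{-1}$). Every simulated curve is therefore
exactly of the fitted functional form, and the infinite-pool consistency
is verified numerically in the test suite to below $10^{-8}$ relative
deviation.

Units follow the field's reporting conventions: time in seconds,
concentrations in uM, rates in nmol mg$^{-1}$ min$^{-1}$; the exponent is
evaluated as $k(t-d)/(60\beta)$ so that the reported $k$ is per minute.

### Rate laws

The generative rate laws are the classical bi-reactant forms. With $A$ the
external and $B$ the internal substrate concentration:

* ping-pong (double displacement):
  $v = V_{max} A B / (K_{m,int}A + K_{m,ext}B + AB)$;
* sequential (rapid-equilibrium ternary complex): the same with
  $K_{i,ext}K_{m,int}$ added to the denominator, so the ping-pong law is
  the nested $K_{i,ext}=0$ case.

Both give $v=0$ when $A=0$ or $B=0$ — a strict antiporter cannot turn over
without counter-substrate. At fixed $B$ both reduce to Michaelis–Menten
dependences on $A$ with apparent constants; the diagnostic difference is
that $K_m^{app}/V_{max}^{app}$ is exactly $K_{m,ext}/V_{max}$ for every
$B$ under ping-pong, but decreases with $B$ under the sequential law.
A random-order elaboration of the ternary-complex law is out of scope; the
single-$K_i$ rapid-equilibrium form already reproduces the qualitative
discrimination pattern.

## What the simulator emulates (and what it does not)

`sim_config()` defaults mirror a typical carrier experiment: internal
loads {100, 250, 500, 1000} uM plus substrate-free background liposomes,
an external series {0.5, 1, 1.5, 2.5, 5, 10, 15, 20} uM, sampling at
{0, 10, 20, 30, 40, 50, 60, 90, 120} s, and 3 technical x 2 biological
replicates. Background controls are simulated at a single external
concentration (2.5 uM), matching how such controls are typically recorded;
since the modelled background signal is an additive constant, its
replicate-mean trace is valid for subtraction from every condition.

The noise model has four components, all configurable via
`noise_model()`:

* multiplicative Gaussian error on each measured quantity
  (`counting_cv`, default 5 %), emulating scintillation counting;
* an additive nonspecific background (`background_offset`, default
  0.5 nmol/mg);
* an optional Poisson counting layer (`poisson_scale`, counts per
  nmol/mg; 0 disables);
* a lognormal between-batch multiplier on $V_{max}$ per biological
  replicate (`biological_cv`, default 10 %), emulating
  reconstitution-efficiency differences between preparations.

Two geometry parameters are not measurable from published protocols and
are explicit placeholders: the entrapped internal volume per mg protein
(default 200 uL/mg) and the protein per well (default 1 ug, with 200 uL
external volume and fully labelled external substrate). The defaults give
curve scales — plateaus of order 10²
nmol/mg, saturation within the 120-s window, initial rates of tens to
hundreds of nmol mg⁻¹ min⁻¹ — comparable to published carrier data.

The default filtration delay is 0 s. The instrument artefact it represents
is typically 0–5 s; the fitter recovers a nonzero delay when present
(exercised in the tests with $d = 2$ s). In the generator, quantities are
clamped to zero for $t < d$ (nothing can be filtered before the dead
time), whereas the fitted model is evaluated as written — the delay
parameter absorbs the artefact rather than modelling it mechanistically.

What simulated data do **not** contain: carrier inactivation over time,
substrate leak through the bilayer, saturation of the filter, pipetting
outliers, or correlated drift within a plate. Passing the validation suite
therefore demonstrates correctness of the estimators under the stated
stochastic model, not robustness to every artefact of real instrument
data.

## Fitting decisions

**Uptake fits.** Each replicate curve is fitted separately by
Levenberg–Marquardt with analytic derivatives; the condition's rate is the
replicate mean and its uncertainty the replicate SD (fit SE when only one
replicate exists). Pooled fitting of all replicates is available
(`pool_replicates = TRUE`), and the delay can be fixed (`fix_delay`).
Ordinary (unweighted) least squares is used per curve because per-point
counting errors are unknown in real exports. Starting values are
$\beta_0=\max Q$, $k_0$ from the first two rising points, $d_0=0$, with
box constraints $\beta \in (0, 10\max Q]$, $k>0$, $d\in[-10,30]$ s to keep
the optimiser away from degenerate exponentials. Flat curves return a
flagged `no_transport` result (infinite $k$ SE) rather than numbers;
non-convergence is likewise flagged, and failed fits propagate as missing
rows with a note, never interpolated.

**Michaelis–Menten fits.** Iterative nonlinear least squares with starting
values $V_{max}=1.1\max v$ and $K_m$ at the half-maximal concentration. A
fit whose $K_m$ exceeds ten times the largest tested concentration is
flagged `poorly_determined`. Two weighting schemes exist; the default is
**unweighted**, for a reason worth spelling out. With 3–6 replicates the
per-point SDs carry only ~5 degrees of freedom. Using them as
inverse-variance weights makes the weights themselves random, which adds
estimator variance that the nominal GLS covariance does not account for,
and each series' own residual variance is then estimated on 6 degrees of
freedom — both effects leave the standard errors that the downstream
homogeneity test divides by systematically too small, and the test
anticonservative. Unweighted fitting, combined with pooling the residual
variance across the (typically four) series of one experiment
(`pool_variance = TRUE` in `fit_mm_curves()`, ~24 degrees of freedom),
restores the test's nominal size; the acceptance suite measures both size
and power directly. Inverse-variance weighting remains available for
designs with many replicates.

**Double-reciprocal plots.** Lineweaver–Burk lines are always derived from
the nonlinear fit ($1/V_{max}$ intercept, $K_m/V_{max}$ slope), never from
least squares on the transformed points, whose error structure grossly
over-weights the least reliable low-concentration rates. Non-positive
rates are excluded from the display with a message; rates with CV above
50 % attach a warning.

## Mechanism discrimination

The experimental literature states the ping-pong criterion visually — the
$K_m/V_{max}$ ratio is "constant within experimental error" — without a
formal statistic. The package formalizes it twice:

1. **Ratio-constancy test.** Delta-method standard errors for
   $r_i=K_{m,i}/V_{max,i}$ (including the fit covariance), then the
   weighted homogeneity statistic
   $X^2=\sum_i (r_i-\bar r)^2/se_i^2$ against $\chi^2_{n-1}$, where
   $\bar r$ is the inverse-variance weighted mean. $p\ge\alpha$ supports
   ping-pong; $p<\alpha$ supports a sequential mechanism. Degenerate
   inputs (a single ratio, or zero SEs with discordant ratios) are
   errors, not silent results.
2. **Nested global fit.** Both rate laws fitted to the full $(A,B,v)$
   surface; extra-sum-of-squares F test with 1 and $n-4$ degrees of
   freedom. When both laws fit to numerical precision (noiseless nested
   truth) the statistic is defined as 0.

`classify_mechanism()` reports the combined verdict: concordant tests give
that call, discordant tests give `inconclusive` with both statistics. The
default $\alpha$ is 0.05. Both p-values are invariant to rescaling of all
rates or all concentrations.

The validation suite runs both tests over hundreds of simulated
experiments at the default design: size is checked against the nominal
level on ping-pong data, and power against sequential data generated with
$K_{i,ext}=10$ uM, which induces a 3.6-fold ratio spread over the internal
series — comfortably detectable, as the acceptance run confirms.

## Thermostability analysis

The apparent melting temperature is defined by the derivative-peak rule:
the temperature of the most prominent positive peak of $dR/dT$, where $R$
is the fluorescence ratio. The implementation:

* moving-average smoothing of the ratio over a temperature window
  (default 2 °C; the window shrinks symmetrically at the scan edges so
  linear baselines pass through unchanged);
* central-difference derivative, smoothed with the same window;
* peak candidates restricted to the interior region where the full
  smoothing window fits (nearer the edges the derivative is dominated by
  raw point noise); candidates must exceed a topographic prominence of
  5 % of the derivative range;
* sub-grid refinement by fitting a Gaussian peak plus constant offset
  over the top 80 % of the winning peak's prominence;
* peaks at or beyond the interior boundary are flagged
  `edge_unreliable`; monotone or flat traces raise a "no transition"
  error; multi-peak traces report every qualifying peak with the most
  prominent one as Tm.

Two caveats are intrinsic rather than implementation choices. First, for
the exact two-state van't Hoff model the derivative peak sits slightly
below the thermodynamic midpoint (about 0.05 °C at the default
$\Delta H = 400$ kJ/mol) because $d\theta/dT$ carries a $1/T^2$ factor —
one reason the quantity is called an *apparent* Tm. Second, vendor
instrument software uses unpublished smoothing; equivalence with it is not
claimed. The simulator's default enthalpy (400 kJ/mol, a 10–90 % width of
roughly 10 °C) and flat-ish baselines are typical of detergent-solubilised
carrier proteins.

`thermal_shift()` is a plain difference Tm(holo) − Tm(apo), sign
preserved, with reliability flags propagated.

## SEC oligomeric state

Calibration fits $\log_{10} MW$ linearly in the partition coefficient
$K_{av}=(V_e-V_0)/(V_t-V_0)$; larger species must elute earlier and the
slope must be negative. $V_0$ and $V_t$ default to 8 and 24 mL (a 10/300
column) and are required configuration in spirit: when unknown they can be
set to `NA`, in which case the line is fitted on raw elution volume.
Elution volumes outside the calibrated range are flagged as
extrapolations.

The oligomeric call subtracts the bound lipid/detergent micelle mass
(default 135 kDa, appropriate for carriers in lauryl maltose neopentyl
glycol with cardiolipin, and overridable per detergent system) from the
apparent mass, divides by the sequence-based protomer mass, and rounds to
the nearest integer $n\ge 1$. Calls whose corrected-to-protomer ratio lies
more than 0.3 from the nearest integer are flagged ambiguous. A known
reporting subtlety for dimeric carriers with large protomers is whether a
published apparent mass has already been micelle-corrected; the result
object therefore always reports both the raw apparent and corrected
masses.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` drives simulate-or-ingest → validate → background
subtraction → rates → Michaelis–Menten fits → mechanism verdict (plus
optional Tm and SEC stages) from one YAML/JSON config with a single
top-level seed. The verdict JSON embeds a provenance block (config hash,
seed, package version) and is byte-identical across reruns of the same
config; timestamps live only in the run log. Input validation fails before
any computation on schema errors; a missing background is a warning and
analysis proceeds without subtraction; fewer than two internal
concentrations aborts with an explicit degrees-of-freedom message.

The validation studies are sized to run comfortably on a single CPU:
500 simulated curves for uptake-rate recovery, 100 simulated experiment
grids for Michaelis–Menten recovery, 200 grids each for the size and power
of the mechanism tests, and 200 noisy melt curves for Tm recovery. With
the closed-form simulator and analytic-derivative fits the full suite
completes in a few minutes. `scripts/acceptance.R` recomputes all headline
quantities from a single command-line seed.

## Known limitations

* The tracer model assumes strict 1:1 exchange at chemical steady state;
  leak pathways, proton-coupled hetero-exchange, and electrogenic effects
  are out of scope.
* Initial rates are defined through the exponential-exchange parameter
  $k$; multi-exponential uptake (e.g. liposome subpopulations) is not
  modelled.
* The mechanism tests inherit the assumptions of their inputs: apparent
  Km/Vmax pairs that are unbiased and approximately Gaussian with
  believable covariances. Designs far from the default (very few external
  points, single replicates) weaken both tests before they weaken the
  point estimates.
* SEC-based state calls assume a single dominant species; overlapping
  peaks are not deconvolved, and SEC-MALS is the superior method when
  absolute masses matter.
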