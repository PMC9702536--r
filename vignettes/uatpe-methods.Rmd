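---
title: "Models and methods behind uatpe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uatpe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uatpe)
```

This vignette explains the models implemented in `uatpe`, the assumptions
they rest on, the numerical choices made where the design was genuinely
open, and what the synthetic-data machinery does and does not establish
about real extraction data.

## The system being modelled

Ultrasound-assisted aqueous two-phase extraction (ATPE) combines two
effects in one vessel: an ethanol–ammonium-sulfate aqueous two-phase
system that partitions phenolics into the alcohol-rich top phase (and
sugars into the salt-rich bottom phase), and sonication that accelerates
the release of phenolics from the plant particle interior. The package
models four aspects: where the two-phase region lies (phase equilibrium),
how solutes distribute once it forms (partitioning), how fast phenolics
leave the particles (diffusion kinetics), and an empirical surrogate of
yield as a function of the operating parameters (network model).

## Phase equilibrium

The binodal curve is modelled by the empirical alcohol–salt relation
$w_1 = \exp(a + b\sqrt{w_2} + c\,w_2 + d\,w_2^2)$, with both coordinates
as mass fractions in $[0,1]$. Compositions on or above the curve are
classified two-phase: the curve is the separating boundary, and for
screening purposes a composition exactly on it is treated as phase
forming. Mass fractions are stored as fractions throughout; percent
notation is converted at the boundary of the package.

Whether such a curve should be fitted in $w_1$ or in $\ln w_1$ is a real
choice: the model is linear in its coefficients after the log transform,
but the quality metrics users care about ($R^2$, AAD) are conventionally
computed on $w_1$ itself. `fit_binodal()` therefore solves the exact
log-linear least-squares problem first and, by default, refines it with
Levenberg–Marquardt on $w_1$ starting from that solution; both fitting
spaces are exposed, and on noiseless data they agree to numerical
precision.

A caution on interpreting fitted coefficients: the basis
$\{1, \sqrt{w_2}, w_2, w_2^2\}$ is strongly collinear on the salt range of
practical interest (0.02–0.35), so individual coefficients are poorly
identified under even 1% noise although the *curve* is recovered to well
under 1% average deviation. Tests of the noisy fit therefore assert
curve-level quality (AAD) and least-squares optimality against a
grid-search oracle, not coefficient-wise agreement; only noiseless data
identify the coefficients themselves.

## Partitioning statistics

Partition coefficient $K = C_T/C_B$, recoveries
$Y_T = 100\,C_T V_T/(C_T V_T + C_B V_B)$ and $Y_B = 100 - Y_T$ (exact by
construction), purity as phenolic mass over dried extract mass, and
percent-change comparisons are straightforward arithmetic. Two policies
matter:

* a zero bottom-phase concentration raises an error rather than returning
  an infinite $K$, keeping all numeric outputs finite and serialisable;
* all percentages are computed at full precision and only formatted at the
  reporting layer, because chaining statistics on pre-rounded values
  compounds error. (This is visible in published comparisons: a purity
  gain recomputed from rounded purities 6.98% and 2.48% gives 181.45%,
  slightly different from a value computed from unrounded inputs.)

`implied_volume_ratio()` inverts $Y_T = 100\,KR/(KR+1)$ for the
top-to-bottom volume ratio $R$; when a study reports $(K, Y_T)$ pairs but
not phase volumes, the implied ratios of different analytes measured in
the same vessel must agree, which is used as a consistency check.

## Diffusion model

Phenolic release is modelled as Fickian diffusion in a sphere,

$$\frac{\partial C_s}{\partial t} = D_e \frac{1}{x^2}
  \frac{\partial}{\partial x}\!\left(x^2 \frac{\partial C_s}{\partial x}\right),$$

with uniform initial loading $C_s(x,0) = C_{s0}$, an initially solute-free
well-stirred bath $C_L(0) = 0$, zero-gradient symmetry at the centre, and
the surface flux balance $-D_e A\,\partial C_s/\partial x|_{x=r} =
V\,dC_L/dt$. The underlying assumptions are the usual ones for this class
of model: spherical particles with uniformly distributed solute, no
degradation during extraction, and a spatially uniform solution phase.

Three modelling decisions deserve explanation.

**Closure of the boundary condition.** The flux balance alone does not
determine the surface concentration. The package closes the system with
interfacial equilibrium $C_s(r,t) = k\,C_L(t)$, default $k = 1$
(concentration continuity, i.e. no surface resistance, consistent with
the uniform-solution assumption); $k$ is exposed for sensitivity studies.

**Ensemble interpretation.** A single particle cannot account for grams of
solid in tens of millilitres, so the geometry is an ensemble of $N$
identical spheres: $N = m_{solid}/(\rho_p \frac{4}{3}\pi r^3)$, total area
$A = 3V_p/r$, bath volume $V$ shared by all particles. With the default
loading (2.5 g in 50 mL, $\rho_p$ = 1000 kg/m³) the bath-to-particle
capacity ratio is $\alpha = V/(kV_p) = 20$.

**The effective radius.** The model is identifiable only through
$D_e/r^2$: any radius choice rescales the fitted diffusivities without
changing the curves. Reported effective diffusivities for this system are
on the $10^{-10}$ m²/s scale, and the observed kinetics approach
equilibrium at about 60 min. Those two facts jointly fix the time scale,
and the default radius is therefore a *diffusion-effective* radius,
$r = 1.68$ mm, calibrated once (via the closed-form series solution) so
that the mid-grid condition ($D_e = 3.15\times10^{-10}$ m²/s) reaches 99%
of its equilibrium yield at 60 min. The measured volume-median particle
radius of the milled pomace (~336 µm) is 5× smaller; pairing it with
diffusivities on the $10^{-10}$ scale would equilibrate the bath within
two minutes, which the observed curves rule out. The effective radius
absorbs polydispersity and internal tissue resistance; users fitting
their own data should treat $r$ as part of the parameterisation, not as a
measured quantity, and remember that only $D_e/r^2$ is meaningful across
parameterisations.

`cs0` defaults to 18.9 kg/m³ so that the closed-system equilibrium yield
is 18 mg/g dry solid, matching the plateau of observed yield curves. Time
is SI seconds internally and minutes in tables (`time_min`), converted
exactly. Sonication duty cycling (5 s on / 5 s off) is ignored: the model
clock is elapsed time, which is how kinetics of this kind are normally
reported; fitted $D_e$ values are therefore duty-cycle-averaged.

### Numerical scheme

The radial coordinate is discretised with a conservative cell-centred
finite-volume scheme: `n_radial` equal-width spherical shells, fluxes
evaluated on shell faces, zero flux through the centre face (symmetry),
and the surface flux computed from the half-cell gradient to the pinned
surface value $k\,C_L$. Because every flux leaving one control volume
enters the next (or the bath), the semi-discrete system conserves total
solute mass *exactly*; the only conservation error comes from the time
integrator, and the solver reports it per output time (typically
$10^{-15}$ relative, against a contract of $10^{-6}$). A node-based
finite-difference scheme was rejected because it cannot make that
guarantee robustly. Time integration uses `deSolve::ode` (`lsoda`) with a
tridiagonal banded Jacobian, `rtol = 1e-9` and `atol = 1e-12·cs0`.

Accuracy was verified against the classical series solution for a sphere
in a well-stirred finite bath (`crank_fraction()`, with roots of
$\tan q = 3q/(3+\alpha q^2)$ bracketed in $(n\pi, n\pi + \pi/2)$ and the
$\tau = 0$ limit special-cased because the truncated series converges
slowly there). With the default 60 shells the extracted fraction agrees
with the series to ~$1.3\times10^{-3}$ relative at the hardest test point
(boundary layer, $\tau = 0.01$) and to $10^{-5}$ or better once
$\tau \ge 0.1$; halving the shell width reduces the worst error to
~$3\times10^{-4}$, the expected second-order behaviour. 60 shells is the
default as a speed/accuracy compromise for fitting; comparisons against
the analytical oracle in the tests use 120.

### Inverse problem

`fit_de()` minimises the RMSE between simulated and observed yields over
$D_e$ by Brent scalar minimisation on $\log_{10} D_e$ (default bounds
$10^{-12}$–$10^{-8}$ m²/s): the objective is smooth and unimodal in
practice and the log scale equalises sensitivity across orders of
magnitude. An optimum within 1% (log-span) of a bound triggers a warning
and is flagged in the report. All-zero yield curves are rejected as
degenerate (flat objective). Under the study conditions, recovery is
within ~$10^{-4}$ relative on noiseless curves and ~5% under 3%
multiplicative noise on nine time points.

## The D_e response surface

$D_e\times10^{10}$ is modelled as a full six-term quadratic in AED (W/L)
and temperature (°C), fitted by ordinary least squares. The design must
span at least two levels of each factor for rank; the factorial grids
used here (3–4 AED levels × 3 temperatures) identify all six terms.
Evaluation outside the calibration box (AED 41.1–111.2 W/L, 20–40 °C)
warns rather than fails: the quadratic extrapolates smoothly but without
empirical support, and it eventually goes negative far outside the box.

## Network yield surrogate

The surrogate is the classical single-hidden-layer feedforward network
$Y = \mathrm{purelin}(LW\,\mathrm{tansig}(IW\,x_n + b^{(1)}) + b^{(2)})$
with three inputs (AED, temperature, time) and one output (yield, mg/g).
Transfer functions are implemented from their definitions (`tansig` =
hyperbolic tangent; `logsig` available as an alternative). Inputs and
output are min–max scaled to $[-1,1]$ with ranges fitted on the training
split only; every model object carries its scaling metadata explicitly,
because a weight matrix without its scaling is not a model.

Training minimises mean squared error with BFGS using the analytic
backpropagation gradient, run in 25-iteration segments with early
stopping on validation RMSE (patience 50 iterations). The default split
is 70/15/15 train/validation/test by seeded shuffle. Given a seed,
training is fully deterministic. A constant-target dataset is handled
explicitly: the network learns the constant on the raw scale, the
degenerate $R^2$ is flagged as undefined, and a warning is raised.
`ann_select_hidden()` trains each candidate size under identical seeds
and splits and returns the validation-RMSE minimiser, ties going to the
smaller network.

The packaged reference weights (`reference_ann_model()`) are the printed
coefficients of a previously published 8-unit network for this system,
with the row layout (three input weights, one hidden bias, one layer
weight) inferred from dimensional necessity. The scaling used alongside
those published weights was never stated, so the fixture carries a
documented *convention* — min–max over the experimental ranges, identity
output — and its predictions are structural, not authoritative: they
demonstrate the machinery, and exact reproduction of the published
network's outputs is not possible from the published information. For
the same reason the published fit statistics ($R^2$ = 0.998) are not
acceptance targets; the surrogate's contract here is $R^2 \ge 0.99$ on
the noiseless synthetic factorial grid, which an 8-unit network reaches
comfortably (typically $R^2 \approx 0.9996$).

## Goodness of fit

All fitting stages report $R^2 = 1 - SSE/SST$,
$RMSE = \sqrt{SSE/n}$ (full $n$, no degrees-of-freedom correction), and
$AAD = 100\cdot\mathrm{mean}(|pred-obs|/obs)$ in percent. Zero observed
variance makes $R^2$ undefined and any zero observation makes AAD
undefined; both are returned as `NA` with explicit flags rather than
being silently dropped, and RMSE is always available.

## Synthetic data: what it emulates, and what passing tests show

The generators emulate the study design: binodal points scattered around
the reference curve on $w_2 \in [0.02, 0.35]$; a full-factorial kinetics
grid (AED {41.1, 63.5, 96.1, 111.2} W/L × {20, 30, 40} °C × times
{2.5, 5, 10, 15, 20, 30, 40, 50, 60} min) generated by mapping each
condition to $D_e$ through the reference response surface and running the
diffusion forward model; and partition samples with exactly specified
$K$ and volume ratio. Noise is multiplicative Gaussian truncated at zero,
because yields and concentrations are positive with roughly proportional
assay error; additive noise would misrepresent the small-signal early
time points. Default noise levels in the demonstration pipeline are 2%,
within the range of triplicate assay variability for these measurements.
Every generator is a pure function of (configuration, truth): identical
seeds give identical tables.

What passing tests establish: the estimators invert the generators —
binodal coefficients, $D_e$, surface coefficients and the network all
recover their generating truth at the stated tolerances, and the solver
agrees with an independent closed-form oracle. What they do not
establish: that real grape-pomace kinetics follow a single-$D_e$ Fickian
sphere model (real data include surface washing, polydispersity and
possibly time-varying $D_e$), that the reference coefficient sets are
correct for other raw materials or solvent systems, or that the network
extrapolates outside the factorial box. Published experimental values
that exist only as figures are deliberately not reproduced — they are
emulated, and the package's quantitative claims are confined to
printed, recomputable numbers and internal consistency.

## Problem sizes and runtime

The test and demonstration configurations are sized for interactive use:
20-point binodal tables, a 108-row factorial grid (12 conditions × 9
times), 60 radial shells for fitting and 120 for oracle comparisons, and
networks of 3–8 hidden units trained for at most a few thousand BFGS
iterations. The full demonstration pipeline (`run_demo_pipeline()`) runs
in well under a minute on one core; its `quick` mode fits $D_e$ on a
3 AED × 3 temperature subgrid, which still identifies the full quadratic
surface.

## Known limitations

* Tie-lines, phase-volume prediction from composition, and
  temperature-dependent binodals are out of scope; the binodal module
  describes the boundary, not the conjugate compositions.
* $K$ is measured, not predicted: there is no thermodynamic model linking
  composition to partitioning.
* The diffusion model excludes cavitation physics, particle breakage,
  swelling, multi-solute coupling and degradation; ultrasound enters only
  through the fitted $D_e$ and its response surface.
* Individual binodal coefficients are ill-conditioned under noise (see
  above); report and compare curves, not coefficients.
* The effective radius convention means fitted $D_e$ values are
  comparable within a parameterisation but not across different radius
  choices without rescaling by $r^2$.
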