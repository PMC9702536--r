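# uatpe

Modelling tools for **ultrasound-assisted aqueous two-phase extraction
(ATPE)** of phenolic compounds from grape pomace. The package is aimed at
extraction and bioprocess scientists who want to characterise an
ethanol–ammonium-sulfate two-phase system, quantify how solutes partition
between its phases, estimate intraparticle mass-transfer coefficients from
extraction kinetics, and build fast surrogate models of yield — all from
tabular data, with every stage testable on seeded synthetic datasets.

## What it computes

**Phase equilibrium.** The binodal curve of a small-alcohol/salt aqueous
two-phase system is fitted with the empirical relation

> w₁ = exp(a + b·w₂^0.5 + c·w₂ + d·w₂²)

where w₁ and w₂ are the ethanol and ammonium-sulfate mass fractions.
`fit_binodal()` solves the exact linear least-squares problem in ln w₁ and
refines it by Levenberg–Marquardt on w₁; `classify_region()` places
compositions in the one- or two-phase region.

**Partitioning.** `partition_stats()` computes the partition coefficient
K = C_T/C_B and the volume-weighted phase recoveries
Y_T = 100·C_T·V_T/(C_T·V_T + C_B·V_B) (with Y_T + Y_B = 100 exactly), plus
purity and percent-change statistics for comparing extraction methods.

**Diffusion kinetics.** `solve_diffusion()` integrates Fick's second law in
a sphere, ∂C_s/∂t = D_e·(1/x²)·∂/∂x(x²·∂C_s/∂x), for an ensemble of
uniformly loaded pomace particles coupled to a finite well-stirred bath
through the surface flux balance −D_e·A·∂C_s/∂x|_r = V·dC_L/dt, using a
conservative finite-volume scheme (mass balance closed to integrator
tolerance). `fit_de()` inverts it, adjusting D_e until the RMSE between
simulated and observed yields is minimal; `crank_fraction()` provides the
closed-form finite-bath series solution as an independent check.
`fit_de_surface()`/`eval_de_surface()` model D_e as a full quadratic in
acoustic energy density (AED, W/L) and temperature (°C).

**Yield surrogate.** `ann_train()` fits a single-hidden-layer feedforward
network, Y = purelin(LW·tansig(IW·xₙ + b⁽¹⁾) + b⁽²⁾), mapping
(AED, temperature, time) to phenolic yield, with min–max scaling, seeded
reproducible training, and `ann_select_hidden()` for hidden-layer sizing.

**Synthetic data.** `gen_binodal()`, `gen_kinetics_grid()` and
`gen_partition()` emulate the factorial study design (AED ∈ {41.1, 63.5,
96.1, 111.2} W/L × {20, 30, 40} °C × nine sampling times) with
multiplicative noise, so every fitting stage has a known ground truth.

## Worked example

```r
library(uatpe)

# Phase equilibrium: is 30% ethanol / 20% salt a two-phase composition?
co <- reference_binodal_coefficients()
eval_binodal(0.20, co)
#> [1] 0.1765856
classify_region(tibble::tibble(w2 = 0.20, w1 = 0.30), co)$region
#> [1] two-phase
```

The curve passes through w₁ = 0.177 at 20% salt, so a 30% ethanol mixture
lies well inside the two-phase region — the working system used for
extraction.

```r
# Forward-simulate extraction kinetics at 96.1 W/L and 30 °C,
# then re-estimate the diffusivity from the simulated curve
sys <- particle_system()
de  <- eval_de_surface(96.1, 30, reference_de_surface())
de
#> [1] 3.148512e-10
sol <- solve_diffusion(sys, de, times = c(2.5, 10, 30, 60) * 60)
sol$kinetics[, c("time_min", "yield_mg_per_g")]
#>   time_min yield_mg_per_g
#> 1      2.5           7.21
#> 2     10            12.4
#> 3     30            16.6
#> 4     60            17.8
glance(fit_de(sol$kinetics, sys))[, 1:3]
#>   de_m2_per_s r_squared        rmse
#> 1    3.15e-10     1.000 0.000000167
```

The response surface gives D_e = 3.15 × 10⁻¹⁰ m²/s at the mid-grid
condition; the simulated yields rise from 7.2 to 17.8 mg/g over an hour
(approaching the 18 mg/g closed-system equilibrium) and the inverse fit
recovers the generating diffusivity.

```r
# Partitioning: concentrations and volumes to K and recoveries
partition_stats(tibble::tibble(c_top = 24.46, c_bottom = 2,
                               v_top = 1.216, v_bottom = 1))[, c("k", "y_top")]
#>       k y_top
#> 1 12.23  93.7
percent_increase(6.98, 4.41)
#> [1] 58.27664
```

A phenolic partition coefficient of 12.23 with a 1.216 volume ratio puts
93.7% of the phenolics in the alcohol-rich top phase, and a purity of
6.98% versus 4.41% for crude ethanol extraction is a 58.3% gain.

`run_demo_pipeline(seed = 7)` chains all stages (synthetic generation,
binodal fit, per-condition D_e estimation, surface fit, network training,
partition statistics) into one deterministic report.

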