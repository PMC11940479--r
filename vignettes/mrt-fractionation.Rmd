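---
title: "Modelling combined temporal and spatial dose fractionation in microbeam radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling combined temporal and spatial dose fractionation in microbeam radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtfrac)
library(dplyr)
```

## The problem

Microbeam radiation therapy (MRT) delivers x-rays through a multi-slit
collimator as planar beams a few tens of micrometers wide, separated by
low-dose valleys. The resulting dose field is a periodic stripe pattern
characterized by the slit width, the center-to-center pitch and the
peak-to-valley dose ratio (PVDR). Conventional radiotherapy instead uses a
spatially uniform broad beam (BB), but splits the dose into daily fractions.
`mrtfrac` models what happens when the two ideas are combined: several MRT
fractions delivered on consecutive days, either with the stripe pattern
held fixed (overlapping MRT) or rotated in-plane by 45° per fraction
(MRT + R, angles 0°/45°/90°/135°).

The package covers the full in-vitro analysis chain:

1. analytic construction of single- and multi-fraction dose fields
   (`fraction_dose_map()`, `pvdr_of_map()`);
2. spatially integrated linear-quadratic (LQ) survival and its equivalent
   uniform single-fraction dose (`sf_spatial()`, `eud_single_fraction()`,
   `eud_of_plan()`), plus inverse planning at equal survival
   (`peak_dose_for_target_sf()`);
3. clonogenic colony-formation-assay (CFA) reduction and LQ parameter
   fitting (`reduce_cfa()`, `fit_lq()`);
4. a synthetic CFA generator reproducing the study design
   (`simulate_study()`);
5. ANCOVA comparison of survival curves across treatment arms
   (`ancova_pairwise()`), and a config-driven pipeline
   (`run_simulate()`/`run_analyze()`/`run_plan()`).

## Dose-field model

The lateral profile is an ideal rectangular stripe pattern: dose
`peak_dose` on stripes of width `slit_width_um` (default 30 µm), dose
`peak_dose / pvdr` (default PVDR 45.77) in the valleys, repeating at pitch
`pitch_um`. The pitch is not determined by the headline collimator figures
(slit width and PVDR); we default to 300 µm, the midpoint of the 200–400 µm
range typical of multi-slit collimators, and make it configurable. An optional linear
penumbra of configurable width (default 0) joins peak and valley.

A peak is centered on the rotation center for every angle, which makes
"overlapping MRT" (all fractions sharing phase and angle) exact by
construction. Rotated fields are evaluated analytically at the rotated
coordinate $s = x\cos\theta + y\sin\theta$ — there is no raster resampling,
so rotation introduces no interpolation error, and a stripe pattern is
invariant under 180° rotation.

Integration uses a square (default) or disc domain centered on the rotation
axis, default 10 mm edge — comfortably inside the 2 × 2 cm field — sampled
at 5 µm (6 samples per 30 µm slit, the minimum the constructors accept).
Grid points sit at cell centers with the domain center at (0, 0) mm.

Dose-rate and protraction effects within a fraction are ignored; measured
peak/valley dose rates enter only through the bookkeeping identity
`valley_from_peak()` (4.31 Gy/min ÷ 45.77 ≈ 0.09 Gy/min).

## Survival model

Per fraction the LQ model gives cell kill $e^{-(\alpha d + \beta d^2)}$.
For a plan of $N$ fractions with dose fields $D_i(x,y)$ the surviving
fraction over dish area $A$ is the area-normalized integral

$$\mathrm{SF} = \frac{1}{|A|}\int_A
  \exp\Big(-\sum_{i=1}^{N}\big[\alpha D_i(x,y) + \beta D_i(x,y)^2\big]\Big)\,dA,$$

evaluated as the mean over grid points. The quadratic term acts per
fraction: with 24 h between fractions, sublethal damage is assumed fully
repaired (no incomplete-repair factor), and cells are assumed not to
migrate or communicate between fractions — each grid point accumulates its
own dose history independently. The normalization by $|A|$ makes SF a
fraction in $(0, 1]$.

The equivalent uniform single-fraction dose (EUD) is the uniform dose that
would produce the same survival in one broad-beam fraction:
$\mathrm{SF} = e^{-(\alpha E + \beta E^2)}$. With $L = -\ln \mathrm{SF}$ we
invert through the cancellation-stable form

$$E = \frac{2L}{\alpha + \sqrt{\alpha^2 + 4\beta L}},$$

which passes continuously to $L/\alpha$ as $\beta \to 0$. This matters in
practice: the normal lung fibroblast line MRC-5 has $\beta = 4\times10^{-5}$
Gy⁻², where the naive quadratic formula loses all precision to cancellation.

Reference radiosensitivities (`cell_line_params()`), fitted from uniform
single-dose assays at 1, 2, 4, 6, 8 Gy:

| cell line | α (Gy⁻¹) | β (Gy⁻²) |
|-----------|----------|----------|
| A549 (lung adenocarcinoma) | 0.29075 | 0.01928 |
| MRC-5 (normal lung fibroblast) | 0.56606 | 0.00004 |

### Why rotation raises the EUD

With the pattern held fixed, the same cells sit in the peaks every day: the
per-point dose ladder is maximally heterogeneous across the dish. Rotating
45° per fraction spreads peak exposure over the population. For $\beta > 0$
the survival-vs-dose curve is convex (see below), so the homogenized dose
history kills more cells: the rotated plan has strictly lower SF, hence
strictly higher EUD, at equal peak doses. At the study geometry and an
8 Gy peak per fraction (A549 parameters) the package computes an EUD of
about 1.0 Gy for overlapping MRT versus about 1.9 Gy for MRT + R.

```{r eud-ordering, eval = FALSE}
geom <- microbeam_geometry()
dom  <- integration_domain()
a549 <- lq_params(0.29075, 0.01928)
eud_sweep(a549, geom, rep(0, 4), 8, dom)$eud_single_fraction_gy       # ~1.00
eud_sweep(a549, geom, c(0, 45, 90, 135), 8, dom)$eud_single_fraction_gy # ~1.87
```

### Heterogeneity spares cells — with a caveat

The often-quoted rule "a heterogeneous field spares cells relative to its
mean dose" is a Jensen inequality and requires the single-fraction survival
curve $e^{-(\alpha d + \beta d^2)}$ to be convex in $d$, which holds for
all $d \ge 0$ exactly when $\alpha^2 \ge 2\beta$. Both cell lines satisfy
this by a wide margin (A549: $0.0845 \ge 0.0386$; MRC-5: trivially). For
hypothetical parameters outside that regime (e.g. $\alpha = 0.2$,
$\beta = 0.05$) the inequality can reverse on two-level fields. The
property tests therefore sample parameters inside the convex regime, the
one relevant to the study.

### Inverse planning

`peak_dose_for_target_sf()` finds the equal per-fraction peak dose whose
spatial survival equals a target, by monotone bisection to
$|{\rm SF} - {\rm target}| < 10^{-8}$ (dose tolerance $10^{-6}$ Gy). Because
every fraction's dose field scales linearly with the common peak dose $p$,
the grid sums $S_1 = \sum_i u_i$ and $S_2 = \sum_i u_i^2$ of the unit-peak
fields are precomputed once and the exponent $\alpha p S_1 + \beta p^2 S_2$
rescaled per trial dose; `eud_sweep()` exposes the same trick for dose
sweeps.

## CFA reduction and LQ fitting

Plating efficiency is $PE = 100\cdot\text{colonies}/\text{seeded}$ and the
survival fraction of a treated well is
$SF = \text{colonies} / (\text{seeded} \cdot PE/100)$, normalizing by the
unirradiated control of the *same biological replicate* (sham-handled 0 Gy
wells). Replicate-level SF values occasionally exceed 1 by sampling noise;
they are kept (with negative $-\ln SF$) rather than truncated, which would
bias the fit.

`fit_lq()` performs least squares of $-\ln SF = \alpha D + \beta D^2$ with
no intercept, unweighted by default (optional weights, e.g. $1/{\rm SEM}^2$).
Nonnegativity is enforced by projection: a negative estimate is clamped to
zero and the other parameter refitted. This is exactly the situation of the
MRC-5 line, whose tiny β makes roughly half of all unconstrained β
estimates negative under realistic noise. Reported standard errors and the
covariance come from the unconstrained fit. Two calibration caveats,
both measured by simulation during development:

* the projection slightly biases the companion estimate conditionally on
  clamping (about 0.6 per-replication SD when the true β is 0) while
  reducing its RMSE; the unconstrained estimates are returned alongside;
* normalizing by an *estimated* control PE induces correlated errors within
  a biological replicate that the OLS covariance ignores. Under pure
  Poisson noise the "within 3 SE" coverage of α is ≈ 99.7%; through the
  full control-normalized pipeline it is ≈ 94.9% (1000 replications).
  Users needing strict frequentist SEs at the replicate level should pool
  or model the replicate structure explicitly.

## The synthetic study generator

Raw colony counts for fractionated MRT experiments are rarely deposited, so
`simulate_study()` generates CFA datasets with the full experimental
design the package targets: two cell
lines, three arms (BB, overlapping MRT, MRT + R), four fractions at 24 h
intervals, three biological × six technical replicates, and 0 Gy sham
controls per biological replicate. Colony counts are Poisson with mean
$\text{seeded} \times PE \times SF_{\rm LQ}$ (optional negative-binomial
overdispersion); everything is deterministic under the design's master
seed, consumed in a documented canonical record order.

Choices made once and kept:

* **Dose ladder and matching.** Equal-survival experiments set fraction
  sizes by LQ inverse planning: the default design uses broad-beam fraction doses
  0.5/1/1.5/2 Gy and assigns each microbeam arm, per cell line, the peak
  dose matched at equal planned survival by inverse planning
  (`match_bb = TRUE`; `study_conditions()` shows the resulting plan). This
  aligns all arms on a common EUD axis reaching ≈ 6–8 Gy single-fraction,
  and reproduces the qualitative hallmark that overlapping MRT needs a
  higher matched peak dose than MRT + R. Set `match_bb = FALSE` to use the
  ladder directly as peak doses.
* **Plating efficiencies** default to 0.75 (A549) and 0.35 (MRC-5),
  typical clonogenic values for these lines.
* **Seeding ladder:** wells are seeded so the expected colony count stays
  near 120, clamped to 100–2000 cells/well (`cells_seeded` overrides).
* **Biological heterogeneity** (lognormal PE multiplier) is off by default
  so that recovery tests are sharp; switch on with `bio_sdlog`.

What the generator deliberately does **not** emulate: bystander signalling,
cell migration between fractions, cell-cycle redistribution, or any
mechanism that makes real survival deviate from the pointwise LQ
prediction. Under the generator's truth, arms matched at equal planned
survival are *exactly* exchangeable, so the pairwise ANCOVA is null by
construction. That is intentional: significant between-arm differences
observed in real experiments are evidence of intercellular communication,
i.e. of biology outside the LQ + EUD model, and a passing test suite here
shows the pipeline's statistics are calibrated — not that real cells
behave this way.

## ANCOVA comparison

`ancova_pairwise()` fits, per cell line and arm pair, the common-slope
model $y = b_0 + b_1 \cdot {\rm EUD} + b_2 \cdot {\rm arm}$ on
replicate-level observations with $y = \ln SF$ (variance-stabilizing;
`response = "identity"` available) and reports the partial-F p-value of the
arm term; an interaction model supplies a secondary slope-difference
p-value. An explicit `dose_range` argument restricts observations before
testing, mirroring analyses reported "for doses below" a threshold. Raw
pairwise p-values are reported by default (a Holm option exists);
`significance_table()` formats the symmetric matrix with `*` (p ≤ 0.05)
and `**` (p ≤ 0.001) markers.

Two modelling notes. Replicate-level observations preserve degrees of
freedom as in a textbook ANCOVA, but technical replicates within a
biological replicate share its control normalization, so the effective
degrees of freedom are slightly overstated. And the model is linear in
EUD: for a strongly curved survival curve (A549's β) the shared lack of
fit inflates the residual variance and makes the arm test conservative;
size calibration at the nominal 5% level holds in the (near-)linear
regime, verified by simulation in the near-linear MRC-5 setting.

## Numerical contracts

* Survival integrals: mean over grid cell centers; square 10 mm domain at
  5 µm default. For axis-aligned stripes the 5 µm grid samples each 300 µm
  period exactly (grid means are exact to machine precision); for rotated
  stripes the sampling is quasi-uniform and the default domain keeps
  residual grid error ≈ $10^{-4}$ relative on SF (halving the resolution
  moves SF by < $10^{-4}$ relative; the 45° closed-form mean dose agrees to
  < $10^{-3}$ at the 10 mm domain but degrades on millimeter-scale domains,
  where partial edge periods carry triangular weight).
* Inverse planning: bisection, $10^{-8}$ in SF, $10^{-6}$ Gy in dose.
* EUD inversion: stable quadratic form, verified against bisection to
  $10^{-9}$ Gy over α ∈ [0.01, 2], β ∈ [0, 0.1], SF ∈ [10⁻⁶, 1).
* PVDR extraction from a map averages the central 50% of peak stripes and
  of valley stripes, classified analytically from geometry and angle; a
  zero valley mean is signalled as an infinite-PVDR condition.
* Degenerate inputs rejected with diagnostics: PVDR < 1, resolution
  coarser than slit/6, domains outside the field footprint, negative
  doses, SF outside (0, 1] for inversion, α = β = 0.

## Problem sizes used in the test suite

Module tests run on 0.8–1.5 mm domains at 5 µm, where every property above
is already decided; the acceptance suite exercises the full 10 mm / 5 µm
study domain for the EUD ordering and grid-convergence checks, 200
simulated calibration studies for parameter recovery, and 500 null
datasets for ANCOVA size. The whole suite completes in well under two
minutes on one core.

## Limitations

* The dose model is two-dimensional and ideal: no beam divergence,
  depth-dose, scatter tails, or film-calibration modelling; the penumbra is
  a linear ramp.
* LQ with full inter-fraction repair only — no repopulation, redistribution,
  reoxygenation, dose-rate effects, or alternative high-dose survival
  models.
* OLS standard errors at replicate level understate uncertainty when
  control normalization correlates wells (quantified above); a
  mixed-effects treatment is out of scope.
* The generator cannot — by design — reproduce the real study's
  between-arm differences; it provides the null background against which
  such differences would be detected.
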