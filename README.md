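# mrtfrac

Analysis of **combined temporal and spatial dose fractionation** in
microbeam radiotherapy (MRT), for radiobiologists and medical physicists
studying clonogenic survival under spatially fractionated fields.

MRT collimates x-rays into planar beams tens of micrometers wide separated
by low-dose valleys, characterized by slit width, center-to-center pitch
and the peak-to-valley dose ratio (PVDR). `mrtfrac` models what happens
when such fields are also fractionated in time — several fractions on
consecutive days, with the stripe pattern either held fixed (overlapping
MRT) or rotated 45° per fraction (MRT + R) — and compares them with
conventional broad-beam (BB) fractionation.

## The model

Per fraction, cell kill follows the linear-quadratic (LQ) model. For a
plan of $N$ fractions with dose fields $D_i(x,y)$ over dish area $A$
(sublethal damage fully repaired across the 24 h intervals, no migration):

$$\mathrm{SF} = \frac{1}{|A|}\int_A \exp\Big(-\sum_{i=1}^{N}\big[\alpha D_i + \beta D_i^2\big]\Big)\,dA$$

The **equivalent uniform single-fraction dose** (EUD) is the uniform dose
with the same survival, $\mathrm{SF} = e^{-(\alpha E + \beta E^2)}$,
inverted through the cancellation-stable root
$E = 2L/(\alpha + \sqrt{\alpha^2 + 4\beta L})$, $L = -\ln\mathrm{SF}$.
Because the survival curve is convex for these cell lines, rotating the
pattern homogenizes each cell's dose history and *lowers* survival:
MRT + R has a strictly higher EUD than overlapping MRT at equal peak doses.

The package also reduces colony-formation-assay (CFA) data (plating
efficiency, survival fractions, LQ fits with nonnegativity projection),
generates synthetic CFA studies with the full experimental design (three
arms, four daily fractions, 3 × 6 replicates, Poisson colony noise), performs
pairwise ANCOVA of survival curves, and wraps everything in a
config-driven pipeline.

## Worked example

```r
library(mrtfrac)

geom <- microbeam_geometry()   # 30 um slits, 300 um pitch, PVDR 45.77, 2x2 cm
geom
#> <microbeam_geometry> slit 30 um | pitch 300 um | PVDR 45.77 | field 20 mm | penumbra 0 um

valley_from_peak(4.31, 45.77)  # measured peak dose rate -> valley rate, Gy/min
#> [1] 0.09416648
```

A 4.31 Gy/min peak at PVDR 45.77 gives the familiar ~0.09 Gy/min valley.
Four 8 Gy-peak microbeam fractions, overlapping vs rotated (A549
parameters, α = 0.29075 Gy⁻¹, β = 0.01928 Gy⁻²):

```r
dom  <- integration_domain(extent_mm = 1.5, resolution_um = 5)
a549 <- lq_params(0.29075, 0.01928)
eud_of_plan(a549, study_plan("MRT",   8, geom), dom)
#>   n_fractions    sf eud_single_fraction_gy
#>             4 0.733                   1.00
eud_of_plan(a549, study_plan("MRT+R", 8, geom), dom)
#>             4 0.537                   1.90
```

Overlapping fractions spare 73% of cells (EUD ≈ 1.0 Gy); rotating the
pattern per fraction drops survival to 54% (EUD ≈ 1.9 Gy) at the same
peak dose. Simulate a full study (arms matched at equal planned survival,
as in the experimental design), re-fit the LQ parameters from the BB arm,
and compare arms:

```r
d <- default_study_design(seed = 1, domain = dom)
records <- simulate_study(d)            # 468 wells incl. 0 Gy controls
points  <- reduce_cfa(records, d$cell_lines, d$geometry, dom)

fit_lq(dplyr::filter(points, cell_line == "A549", modality == "BB") |>
         dplyr::mutate(sf_fx = sf^(1/4)),   # per-fraction survival
       dose = dose_level_gy, sf = sf_fx)
#> <lq_fit> alpha = 0.28675 +/- 0.00779 /Gy, beta = 0.02193 +/- 0.00454 /Gy^2 (n = 72)

significance_table(ancova_pairwise(dplyr::filter(points, sf > 0)))
#>   cell_line modality BB     MRT    `MRT+R`
#> 1 A549      BB       -      0.0647 0.482
#> 2 A549      MRT      0.0647 -      0.255
#> ...
```

The fitted α and β recover the generating values within their standard
errors, and the ANCOVA finds no between-arm differences — as it must:
under the pointwise LQ model, arms matched at equal survival are
exchangeable. Real experiments showing significant differences are
therefore evidence of biology beyond the LQ + EUD model (intercellular
communication); see the methods vignette
(`vignettes/mrt-fractionation.Rmd`).

The same workflow runs from a config file:

```sh
Rscript inst/cli/mrtfrac.R all --config my_run.yaml --out results/
```

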