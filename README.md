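# pastureSOC

Soil organic carbon (SOC) stock accounting and loss partitioning for
degrading alpine pastures.

High-alpine *Kobresia* pastures degrade through a recognizable sequence:
the intact felty root mat (stage S0) cracks into polygons (S1–S4) and ends
as bare soil (S5). Two distinct processes deplete the SOC stock along the
way — physical **erosion** of the carbon-rich topsoil, and **reduced root
carbon input plus accelerated mineralization** of the horizons that remain.
pastureSOC is for soil scientists and rangeland ecologists who have
horizon-resolved pedon data (depths, SOC contents, bulk densities, crack
extents) along such a gradient and want to separate the two processes with
a defensible mass balance, screen and aggregate the surrounding
literature, and test how much of a bulk δ¹³C shift lignin accumulation can
explain.

## What it computes

**Stocks.** Layer stocks follow the standard unit chain,
`stock [kg ha⁻¹] = 100 · content [g kg⁻¹] · BD [g cm⁻³] · depth [cm]`,
integrated horizon-wise to a fixed depth (default 30 cm) with proration of
the horizon crossing the limit.

**Partition.** For each degraded stage *s* with crack (erosion) depth *e*:

- erosion component `L_E = ∫₀^e c_S0(z) ρ_S0(z) dz` — the removed column
  priced at reference content × BD (plus the eroded soil mass `∫₀^e ρ_S0`);
- mineralization component
  `L_M = Σ_h (c_S0,h ρ_S0,h − c_s,h ρ_s,h) · T̄_S0,h` over the surviving
  reference horizons down to 30 cm (reference frame);
- total loss `L_T` as the difference of mean stocks, in both each
  profile's own 0–30 cm window (headline) and the reference-frame window,
  under which `L_T = L_E + L_M` is an exact identity on noiseless data;
- a per-stage Welch closure test of `L_T` vs `L_E + L_M` across field
  replicates ("n.s." = the partition accounts for the measured loss).

**Meta-analysis.** Five inclusion rules (stage classification, SOC/N/BD
data, in-study reference, depth + location, exact 10-cm intervals),
explicit label→stage regrouping, SOM→SOC conversion (factor 2.0), effect
sizes `ES = 100·(D − R)/R` on stocks where BD allows and contents
otherwise, and unweighted mean ± SE aggregation.

**Isotope mixing.** A two-pool model: lignin C (δ¹³C depleted 4.3 ‰ below
bulk plant material; measured as VSC phenols recovering 38% of lignin C)
against a fixed non-lignin pool. `lignin_delta_shift()` converts a VSC
change into a bulk δ¹³C shift; `fraction_of_observed_shift()` expresses it
as a share of the observed shift.

**Synthetic data.** `sequence_scenario()` / `generate_sequence()` build
degradation sequences with analytically known erosion/mineralization
truth; `generate_literature_corpus()` builds literature tables with known
stage effects. Both drive the validation suite.

## Worked example

```r
library(pastureSOC)

sim <- generate_sequence(sequence_scenario(noise_cv = 0.05, seed = 1))
stage_stocks(sim$ensembles)
#>   stage element depth_limit_cm mean_kg_m2  se_kg_m2 n
#> 1    S0       C             30  17.110994 0.1849628 4
#> 2    S1       C             30  15.402830 0.3203390 4
#> 3    S2       C             30  14.678284 0.5308348 4
#> 4    S3       C             30  12.956118 0.1862588 4
#> 5    S4       C             30  10.430337 0.1252465 4
#> 6    S5       C             30   8.695091 0.2776609 4

partition_sequence(sim$ensembles)
#>   stage crack_cm total_loss erosion_loss mineralization_loss percent_loss closure_p
#> 1    S1      0.5      1.708        0.412               1.489        9.983     0.987
#> 2    S2      1.5      2.433        1.237               1.797       14.217     0.992
#> 3    S3      3.0      4.155        2.474               2.716       24.282     0.981
#> 4    S4      6.0      6.681        4.793               3.674       39.043     0.957
#> 5    S5     10.0      8.416        7.469               3.351       49.184     0.987
```

Reading the S5 row: of the ~8.4 kg C m⁻² lost from the 0–30 cm stock
(≈49% of the reference), ~7.5 kg C m⁻² left with the eroded topsoil
(10 cm of cracking, ≈81 kg soil m⁻²) and ~3.4 kg C m⁻² thinned out of the
surviving horizons; `closure_p ≥ 0.95` says the two components jointly
account for the measured loss at every stage (the small surplus of the
components over the own-window total reflects the frame difference, see
the vignette).

```r
isotope_attribution(data.frame(stage = c("S0", "S5"),
                               vsc_frac = c(0.009, 0.047),
                               d13c_permil = c(-26.60, -28.47)))
#>   stage vsc_frac lignin_frac observed_shift_permil lignin_shift_permil attribution_pct
#> 1    S0    0.009  0.02368421                  0.00                0.00              NA
#> 2    S5    0.047  0.12368421                 -1.87               -0.43        22.99465
```

A VSC rise from 0.9% to 4.7% of SOC implies a −0.43 ‰ lignin-driven bulk
shift — here about 23% of the observed −1.87 ‰.

A command-line wrapper (`inst/scripts/pasturesoc`) exposes the same
pipeline as `stocks`, `partition`, `meta`, `simulate` and `isotope`
subcommands over CSV files.

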