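# percebe

Biophysical analysis of larval dispersal and fishery productivity for the
gooseneck barnacle (*Pollicipes pollicipes*) on an upwelling-influenced
coast, for fisheries scientists and coastal oceanographers working at the
scale of co-managed rock-by-rock shellfish fisheries.

Barnacle larvae drift for 60 days — roughly 30 as surface-dwelling nauplii
(0–10 m) and 30 as deeper cyprids (10–20 m) — before they can settle, so
the summer circulation decides both how far alongshore a cohort travels
and whether it returns to shore at all. `percebe` turns a moored current
profiler record into that answer, and connects it to the fishery's catch
records through wind-derived upwelling indices.

## The model at its core

For each release event and each axis (x alongshore +east, y cross-shore
+offshore; coast along y = 0), the record yields an advective and a
stochastic dispersal length scale

    L_A = ū_surf·T_s + ū_bot·T_b
    L_S = √( τ_L · (σ²_surf·T_s + σ²_bot·T_b) )

with τ_L = 12 h the Lagrangian decorrelation time. Settlement positions
are Gaussian per axis, D(d) = (1/(√(2π)·L_S))·exp(−(d−L_A)²/(2·L_S²)),
multiplied across the two independent axes on a 1 km × 5 km grid whose
coastal row is centred on the shoreline; inland mass is folded into the
coastal row (a "sticky" shore — larvae that touch land settle), so the
kernel always sums to 1. The coastal-row mass is the theoretical
recruitment success, Φ((dy/2 − L_Ay)/L_Sy) for a single event.

Upwelling is quantified by Bakun's daily index
DUI = offshore Ekman transport τ_alongshore/(ρ_sw·f) per km of coast
(wind stress τ = ρ_air·C_d·|W|·W, speeds under 7 km h⁻¹ zeroed), its
4-df GAM seasonal cycle, and the June–October integral IUI (km³ km⁻¹).
Catch rate (landings/effort) is regressed on IUI lagged 1–5 seasons plus
a quota-change dummy; lags are compared by AIC and Akaike weights, and
explained variance is partitioned between quota and upwelling.

Seeded generators (`gen_currents()`, AR(1) layered flow; `gen_wind()`;
`gen_catch()`) provide ground-truth synthetic data for every stage.

## Worked example

Kernel metrics from a high-upwelling summer's season-mean length scales
(alongshore L_A = −56.12, L_S = 42.79; cross-shore L_A = −67.79,
L_S = 46.645 km):

```r
library(percebe)
k09 <- event_kernel(list(LA_x = -56.12, LS_x = 42.790,
                         LA_y = -67.79, LS_y = 46.645))
k09
#> <dispersal_kernel> 687 x 63 cells ( 1 km x 5 km ), 1 event(s)
#>   total mass 1.000000000, coastal-row mass 0.9341
peak_recruitment(k09)
#> $offset_km
#> [1] -56
#> $density_per_km2
#> [1] 0.001741694
```

93.4% of competent larvae are retained at the coast, with peak settlement
56 km west of the emission point at a density of 174×10⁻⁵ km⁻² — the
signature of an upwelling year: westward drift, onshore return flow,
strong recruitment. The same call with a low-upwelling summer's scales
(12.95, 24.294, 31.61, 28.478 km) returns 15.3% retention peaking 13 km
east, with the bulk of the cohort stranded offshore.

A full synthetic season, end to end:

```r
cfg <- pipeline_config(outdir = "run1", seed = 1, year = 2009)
res <- run_dispersal(cfg)      # currents -> 4465 events -> ensemble kernel
res$metrics
#>   year n_events recruitment_success peak_offset_km peak_density_per_km2
#> 1 2009     4465           0.7456969            -83          0.001237361

ca <- run_catch_analysis(cfg)  # wind -> DUI -> IUI -> lagged regression
ca$models
#> <lag_model_set> 5 candidate lag(s); best lag 4
#>   lag  p_value beta_iui    p_iui    p_tac adj_r2      aic akaike_weight
#> 1   1 8.06e-03  -0.0056 9.56e-01 2.47e-03 0.5425   0.0155             0
#> 2   2 3.08e-03  -0.1128 1.76e-01 9.96e-04 0.6225  -2.4849             0
#> 3   3 7.88e-03  -0.0182 8.30e-01 2.37e-03 0.5445  -0.0429             0
#> 4   4 1.20e-07   0.2604 3.83e-06 2.89e-07 0.9505 -28.8899             1
#> 5   5 7.66e-03  -0.0306 7.53e-01 2.90e-03 0.5471  -0.1162             0
```

The one-seed season recruits 74.6% with its peak 83 km west — individual
simulated seasons scatter widely around the regime mean, as the methods
vignette quantifies. The regression recovers the generating 4-season lag
with an IUI coefficient of 0.26 (truth 0.24) and hands it essentially all
the Akaike weight. Artifacts (`season_scales.csv`, `ensemble_kernel.csv`,
`lag_models.csv`, `variance_partition.csv`, `pipeline.log`) land in
`outdir`; `inst/scripts/run-pipeline.R` wraps the same calls for shell
use with a YAML config.

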