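# diffpop

Drug-target deconvolution from differential precipitation (DiffPOP)
proteomics, with the companion analyses such a study needs: TMT/DIA
differential proteomics with multi-cell-line intersection,
four-parameter logistic IC50 fitting with a cytotoxic selectivity
index, and noncompartmental pharmacokinetics. A synthetic-data module
generates every input the pipeline consumes — with planted ground
truth — so the whole analysis runs and is calibrated without any
external download.

## Who it is for

Chemical-biology and proteomics groups running solvent-induced
precipitation profiling (or similar stability-shift experiments) to
find the protein target of an unmodified small molecule, starting from
protein-level intensity tables (one row per protein × condition ×
replicate × fraction).

## The core statistic

Each protein's per-fraction intensities are normalized to shares and
averaged across replicates within condition. With mean vehicle shares
*a* and compound shares *b* over the ordered solvent fractions, the
shift statistic is

> D = max_j | Σ_{i≤j} a_i − Σ_{i≤j} b_i |  ∈ [0, 1]

the Kolmogorov–Smirnov distance between the cumulative precipitation
profiles. Because nine fractions invalidate the asymptotic KS null,
significance is a quantile rule — the top 3% of D scores (exactly
`ceiling(0.03 · N)` proteins) pass the rank cut — and candidates must
additionally be *stabilized*: an intensity-weighted centroid (in
solvent %) that moves to higher methanol under compound, i.e. delayed
precipitation. Proteins whose replicate profiles have minimum pairwise
Spearman ρ ≤ 0.7 in either condition are gated out of the ranking.

## Worked example

```r
library(diffpop)
library(dplyr)

sim <- simulate_diffpop(n_proteins = 300, n_targets = 5,
                        shift_delta = 25, noise_cv = 0.1, seed = 42)
res <- score_shifts(sim$data)
call_targets(res) |>
  select(protein_id, ks_stat, centroid_shift, peak_vehicle,
         peak_compound, quantile_rank)
#> # A tibble: 7 × 6
#>   protein_id ks_stat centroid_shift peak_vehicle peak_compound quantile_rank
#>   <chr>        <dbl>          <dbl>        <int>         <int>         <int>
#> 1 P0146       0.986          21.0              7             8             1
#> 2 P0153       0.968          26.6              6             8             2
#> 3 P0049       0.959          22.5              7             8             3
#> 4 P0074       0.857          28.0              6             8             4
#> 5 P0228       0.781          18.2              7             9             5
#> 6 P0096       0.0616          0.713            5             5             7
#> 7 P0031       0.0602          0.594            5             5             8

sort(sim$truth$protein_id[sim$truth$is_target])
#> [1] "P0049" "P0074" "P0146" "P0153" "P0228"
```

The five planted stabilized targets occupy the top five ranks with
large D and centroid shifts of ~20 solvent points (peak fractions
moving from 6–7 under vehicle to 8–9 under compound); two low-D
proteins ride along in the 3% rank cut because their noisy centroid
shifts happen to be positive — the false-positive budget the quantile
rule accepts by construction. With `noise_cv = 0` the candidate list is
exactly the planted set.

Pharmacokinetics of an IV bolus profile (dose 1/kg, V = 0.1 L/kg,
k = ln 2 per h, sampled 5 min–24 h):

```r
prof <- simulate_pk_profile(dose = 1, volume = 0.1,
                            elimination_rate = log(2))
glance(nca(prof, dose = 1, route = "iv", threshold = 1))
#> # A tibble: 1 × 14
#>   route  dose    c0  cmax  tmax auc_last auc_inf lambda_z t_half   mrt     cl
#>   <chr> <dbl> <dbl> <dbl> <dbl>    <dbl>   <dbl>    <dbl>  <dbl> <dbl>  <dbl>
#> 1 iv        1    10    NA    NA     15.8    15.8    0.693      1  1.51 0.0634
#>    vd_ss time_above_threshold n_points
#>    <dbl>                <dbl>    <int>
#> 1 0.0955                 3.32        8
```

C0 back-extrapolates to 10 (dose/volume), the terminal slope recovers
k = 0.693/h (half-life 1 h), and the profile stays above the 1-unit
threshold for 3.3 h. At this sparse 8-point sampling, clearance
(0.0634) and V_ss (0.0955) carry a few percent of trapezoidal
discretization bias against the analytic V·k = 0.0693 and V = 0.1;
both converge to the closed forms as sampling densifies.

Other entry points: `impute_missing_tmt()` → `normalize_tmt()` →
`differential_test()` → `volcano_call()` for TMT 6-plex;
`dia_presence_filter()` → `dia_differential()` →
`intersect_significant()` for DIA panels; `fit_four_pl()` and
`selectivity_index()` for dose-response;
`run_diffpop_pipeline()` for a config-driven end-to-end run writing
TSV/JSON outputs and a manifest. `plot_profiles()`, `plot_volcano()`,
`plot_pk()` and `autoplot()` draw the standard figures. See
`vignettes/target-deconvolution.Rmd` for the methods account.

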