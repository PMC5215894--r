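# fluxmet

Reaction-flux inference for mammalian central energy metabolism from
replicate targeted-metabolomics intensity tables.

## The problem

Targeted LC-MS metabolomics gives replicate abundance measurements of a few
dozen central metabolites at a handful of time points (e.g. cells sampled at
0, 15 and 30 minutes, n = 4–5 per group). fluxmet estimates the **average
reaction fluxes** `v` of central energy metabolism — glycolysis, pyruvate
processing, the TCA cycle, the pentose phosphate pathway, the electron
transport chain, anaplerosis — over each interval, using nothing but the
network stoichiometry. It is aimed at cell-biology and mechanobiology labs
that have targeted metabolomics time courses and want pathway-level rate
estimates without kinetic modeling.

## The method

For each metabolite *i*, the accumulation rate over an interval is

    Δ_i = (center(a₁) − center(a₀)) / (t₁ − t₀)

(median centers by default; robust at n = 4–5), with the Welch variance of a
difference of means, `σ_i² = s₁²/n₁ + s₂²/n₂`, giving the weight
`w_i = σ_i⁻²`. Fluxes solve the weighted bounded-variable least-squares
(BVLS) problem over the stoichiometric matrix `S`:

    min_v ‖S_w v − Δ_w‖₂   s.t.  v_i ≥ 0 for irreversible reactions,

where row *i* of `S` and `Δ_i` are multiplied by `w_i`. Negative flux means a
reversible reaction running against its drawn direction. Hypothesis
("exemplar") profiles come from the linear program

    min_v cᵀv   s.t.  S_I v = 0,  A v ≥ 0,  v ≤ 1,

which maximizes flux through a biosynthesis column (collagen, aggrecan,
albumin, or lipid) subject to steady state of internal metabolites,
irreversibility, and a unit cap. Robustness is quantified by re-solving on
data randomized within each cell's 95% confidence interval, correlating the
randomized fluxes with the originals, and clustering samples by correlation
distance. A synthetic-data generator with known ground-truth fluxes makes
every stage testable end to end.

The packaged network is 52 metabolites × 38 reactions; reduced to the
measured set and augmented with one synthesis column it is 48 × 39 with full
column rank, so the weighted fit is unique.

## Worked example

```r
library(fluxmet)

# 1. model: packaged network, reduced to the measured set, plus a synthesis column
net   <- build_full_network()
syn   <- matrix_protein_synthesis()           # collagen2/collagen6/aggrecan/albumin
model <- add_synthesis_reaction(reduce_to_measured(net), syn$collagen2)
glance(model)
#> # A tibble: 1 × 5
#>   n_metabolites n_reactions n_measurable n_constrained_zero  rank
#>           <int>       <int>        <int>              <int> <int>
#> 1            48          39           45                  3    39

# 2. a synthetic study with known ground truth (protein-like compressed group)
sim <- generate_table(simulation_config(model, noise_cv = 0.05, seed = 42))

# 3. accumulation rates + Welch weights for the 0-15 min interval
acc <- estimate_accumulation(sim$table, "compressed", t0 = 0, t1 = 15) |>
  compute_weights()
head(acc, 3)
#> # A tibble: 3 × 6
#>   metabolite_id  delta variance    n0    n1   weight
#>   <chr>          <dbl>    <dbl> <int> <int>    <dbl>
#> 1 2PG           -31.8      373.     5     5 0.00268
#> 2 3PG           -72.4     7573.     5     5 0.000132
#> 3 6PG             8.59     114.     5     5 0.00879

# 4. weighted BVLS flux fit
fit <- solve_flux(assemble_flux_problem(model, acc))
glance(fit)
#> # A tibble: 1 × 7
#>   objective n_reactions n_at_bound iterations      kkt converged deficient
#>       <dbl>       <int>      <int>      <int>    <dbl> <lgl>     <lgl>
#> 1     0.269          39          5         12 2.53e-14 TRUE      FALSE
head(tidy(fit), 5)
#> # A tibble: 5 × 5
#>   reaction_id pathway reversible  flux at_bound
#>   <chr>       <chr>   <lgl>      <dbl> <lgl>
#> 1 G1          G       FALSE       80.9 FALSE
#> 2 G2          G       TRUE       -42.3 FALSE
#> 3 G3          G       FALSE       14.0 FALSE
#> 4 G4          G       TRUE        16.3 FALSE
#> 5 G5          G       TRUE        80.8 FALSE
```

`delta` and `flux` are in intensity units per minute: over 0–15 min, 2PG
*fell* at ≈32 units/min, and the fitted hexokinase flux (G1) is ≈81
units/min. `n_at_bound = 5` irreversible reactions sit at zero, and the KKT
residual certifies the fit is the global optimum of the convex program.

The fitted fluxes barely depend on which synthesis column is used — the
relative distance between fits computed with the collagen and the lipid
column is far below 1% of the smaller vector's norm:

```r
m2 <- add_synthesis_reaction(reduce_to_measured(net), lipid_synthesis_reaction())
f2 <- solve_flux(assemble_flux_problem(m2, acc))
n  <- nrow(net$reactions)
compare_profiles(tidy(fit)$flux[1:n], tidy(f2)$flux[1:n])$relative_distance
#> [1] 7.645665e-05
```

And the fluxes are robust to measurement uncertainty: re-solving on 100
tables randomized within each cell's 95% CI, 99% of the randomized flux
vectors correlate above 0.5 with the original:

```r
sens <- sensitivity_run(sim$table, model, intervals = list(c(0, 15)),
                        n_sets = 100, seed = 7)
glance(sens)
#> # A tibble: 1 × 6
#>   n_sets  seed n_intervals fraction_above median_correlation n_skipped
#>    <dbl> <dbl>       <int>          <dbl>              <dbl>     <int>
#> 1    100     7           1           0.99              0.869         0
```

`autoplot()` works on every result type (flux bar charts, correlation
histograms, clustered heatmaps), and `run_pipeline()` executes the whole
analysis into a directory of CSVs with a checksummed JSON manifest.

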