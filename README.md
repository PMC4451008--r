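# trilocus

Analysis of live-cell microscopy experiments in which **three chromosomal
loci** are fluorescently tagged (three colour channels) and their 3D
positions recorded per nucleus.  Because nuclei tumble freely, raw
microscope-frame coordinates from different nuclei are not comparable;
`trilocus` converts every nucleus into the frame-invariant variables of the
triangle the three spots form, and builds all downstream analysis on them.
It was designed around budding-yeast experiments on the chromosome-3 mating
type loci (*HML*, *MAT*, *HMR*), but applies to any three simultaneously
labelled sites.

The package provides four layers:

1. **Geometry** — per nucleus, the three inter-locus distances
   d_rg, d_rb, d_gb (µm) and interior angles θ_r, θ_g, θ_b (radians), exactly
   invariant under rigid motion of the acquisition frame.
2. **Density maps** — for each of the nine (distance, angle) projections, a
   Gaussian-kernel density estimate f(x) = (1/M) Σ_m exp(−‖x−y_m‖²/2t)/(2πt)
   on standardised axes, partitioned into ten nested occupancy regions
   U_1 ⊂ … ⊂ U_10 (U_k = the k·10 % densest sample points), with per-level
   mean and standard-deviation vectors in original units.
3. **Comparison** — between two cell populations: per-level ratio-of-
   statistics correlation factors ρ1 = Π min(|µ^A|,|µ^B|)/max(|µ^A|,|µ^B|)
   and ρ2 = ρ1 · Π min(σ^A,σ^B)/max(σ^A,σ^B) (headline `c` at the 30 % level),
   3D highest-density-region overlaps of the distance triple, and a Wilcoxon
   rank-sum battery over all six variables.
4. **Survival-zone inversion** — fits an abstract planar polymer model in
   which each locus roams uniformly in a rectangle ("survival zone").
   Centres are fixed from mean distances (node 1 at (0,0), node 3 at (5,0),
   node 2 by two-circle intersection); half-widths ε are found by exhaustive
   grid search minimising Σ_i ‖C_i − C_i^a‖_F, where C_i is the per-node
   correlation matrix of (d_i1, d_i2, θ_i) and C_i^a its Monte-Carlo
   counterpart under the candidate zones (common random numbers across
   candidates; deterministic lexicographic tie-break).  The field-default
   grid (step 0.2 on (0;5], six parameters) has 25⁶ = 5¹² candidates; desk
   runs use a coarse grid plus refinement.

A synthetic-data module generates datasets from any zone model (uniform
configurations, random rigid 3D embedding, optional anisotropic localisation
noise) and the uniform-sphere null control, so the full pipeline is testable
without any external data.

## Worked example

Simulate a "wild-type-like" population from the moderately constrained
reference regime and a more constrained mutant-like one, then run the full
pipeline:

```r
library(trilocus)

wt  <- simulate_from_zones(simulation_spec(s4_regimes()$moderate,    n = 300, seed = 11))
mut <- simulate_from_zones(simulation_spec(s4_regimes()$constrained, n = 300, seed = 12))
wt  <- qc_filter(wt);  mut <- qc_filter(mut)

tidy(build_map(wt, distance = "d_rg", angle = "theta_r"))
#> # A tibble: 10 × 8
#>   distance angle   level  card  mu_x  mu_y sigma_x sigma_y
#> 1 d_rg     theta_r     1    30 0.775 0.377  0.0766   0.124
#> 2 d_rg     theta_r     2    60 0.795 0.439  0.119    0.203
#> 3 d_rg     theta_r     3    90 0.815 0.502  0.135    0.259
#> ...
```

Level k holds the k·10 % densest nuclei; `mu_x` is the mean d_rg (µm) and
`mu_y` the mean θ_r (radians) inside U_k, with population SDs alongside —
the most frequent conformations here sit near d_rg ≈ 0.78 µm, θ_r ≈ 22°.

```r
cmp <- compare_experiments(wt, mut)
glance(cmp)
#>   n_maps c_median  c_min c_max   M_a   M_b
#> 1      9    0.142 0.0346 0.217   300   300

pairwise_tests(wt, mut)
#>   variable median_a median_b iqr_a iqr_b      p_value
#> 1 d_rg        0.658    0.538 0.475 0.221 0.0000000610
#> ...
```

The two populations' maps correlate poorly (median 30 %-level c ≈ 0.14;
duplicate samples of one population give ρ1 ≈ 0.9) and every distance
shifts significantly — the constrained population's spots are closer
together with tighter spread.

```r
fit <- solve_zones(wt, grid = eps_grid(1:5), m_configs = 2000, seed = 13)
tidy(fit)
#>    node center_x center_y  eps1  eps2  area
#> 1     1     0        0        1     3    12
#> 2     2     2.08     2.73     3     2    24
#> 3     3     5        0        1     5    20
```

The fitted zones put the middle locus in the largest zone, reproducing the
generating regime's ordering (total fitted area tracks the generating
regime's constraint level across regimes; individual half-widths are
calibrated to the fitted centre layout — see the methods vignette on
identifiability).

A command-line wrapper for the same pipeline is installed at
`<library>/trilocus/exec/trilocus` (`simulate`, `geometry`, `maps`,
`compare`, `solve` subcommands).

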