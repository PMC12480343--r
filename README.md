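# ecocycler

Tools for asking, of a simulated marine food web under compound pressures:
*how novel is the ecosystem becoming, when does that novelty shift abruptly,
and how do those shifts map onto the phases of the adaptive cycle?*

The package is aimed at ecosystem modellers who have (or want to emulate)
ensemble output from a temporal food-web model — annual biomasses per
functional group and the flow matrices they imply — under crossed forcing
scenarios (climate × nutrient load × fishing management). It provides the
full analysis chain as tested, composable R functions, plus a synthetic
generator so the chain can be exercised and validated without any external
model runs.

## What it computes

**Ecological network analysis (ENA) indices.** For a flow matrix
`T[i, j]` (flow from compartment *i* to *j*), with `TST = Σᵢⱼ Tᵢⱼ` the total
system throughput, row sums `Tᵢ.` and column sums `T.ⱼ`:

- ascendency `A = Σᵢⱼ Tᵢⱼ log₂( Tᵢⱼ · TST / (Tᵢ. · T.ⱼ) )` — throughput ×
  mutual information; the *connectedness* axis of the adaptive cycle,
- development capacity `C = − Σᵢⱼ Tᵢⱼ log₂( Tᵢⱼ / TST )` — throughput ×
  flow diversity, the upper bound of A; the *potential* axis,
- overhead `R = C − A` (computed directly from its own conditional-entropy
  formula and checked against the identity) — functional redundancy; the
  *resilience* axis.

**Novelty.** For each projection year *t*, novelty is the minimum
dissimilarity of that year's state to any state in the baseline window:
`Novelty(t) = min_b D(x_t, x_b)`, with the baseline pool spanning all
Monte-Carlo members × baseline years, and the member values averaged per
target year. Three dissimilarities `D` are provided: Euclidean distance on
biomasses, Hellinger distance on composition (range [0, √2]), and a
cumulative per-species measure (sum over groups of the per-group minimum
absolute difference to the baseline).

**Change points in mean.** Each novelty series is segmented by exact
penalized least-squares (dynamic programming, MBIC-type penalty, minimum
segment length 10 years), i.e. only shifts in the series mean are detected.
A brute-force enumeration oracle is included.

**Adaptive-cycle phases.** Change points are anchored as reorganization
onsets when the smoothed indices show falling connectedness, rising
potential, and high resilience; collapse is carved immediately before each
anchor, remaining years are growth (r/K merged) or unclassified; cycles are
counted as reorganization segments.

**Synthetic scenario ensembles.** A 28-group Baltic-type coastal food web
(7 fleets, 3 invasive species) with a documented diet matrix; biomass =
baseline × lognormal member perturbation × scenario trend × planted
multiplicative steps × AR(1) noise; flows follow the consumption rule
`T[i, j] = B_j · (Q/B)_j · DC[i, j]`. Planted shift years are recorded as
ground truth, so every downstream stage is testable.

## Worked example

```r
library(ecocycler)

cfg <- default_config()
run <- simulate_biomass(cfg, scenario_spec("RCP85", "REF", "SQ"),
                        members = 20, seed = 7)
run
#> <ensemble_run> RCP85_REF_SQ
#>   members: 20  years: 2000 - 2090  groups: 28
#>   planted shifts: filamentous_algae@2035 x2.5, benthic_bivalves@2069 x0.4

idx <- index_series(run)                       # yearly TST, A, C, R (+ smoothed)
nov <- novelty_series(run, "biomass_euclidean")
detect_mean_shifts(nov$value, years = nov$year, min_seg_len = 10)
#> <cpt_set> 5 change point(s) [min segment 10, penalty MBIC = 12.8]
#>   at: 2035, 2045, 2058, 2069, 2079
#>   start_year end_year   mean
#> 1       2019     2034  2.357
#> 2       2035     2044 26.898
#> 3       2045     2057 34.798
#> 4       2058     2068 44.256
#> 5       2069     2078 56.137
#> 6       2079     2090 68.074
```

The two planted shifts (2035, 2069) are recovered exactly; the intermediate
change points track the accelerating warming trend of this scenario, which
the mean-shift model approximates by a staircase. Anchoring and phase
classification then follow with `anchor_reorganization()` and
`classify_phases()`; in this trend-dominated synthetic scenario no year
shows the reorganization signature, so no cycle is counted — the phase
machinery is validated instead on schedule-driven index fixtures from
`simulate_phase_indices()` (see the methods vignette).

The whole chain over all 16 scenarios is one call:

```r
run_pipeline(default_pipeline_config(seed = 7), out_dir = "results/")
```

which writes `biomass.csv`, `indices.csv`, `novelty.csv` (48 series = 16
scenarios × 3 measures), `changepoints.csv`, `phases.csv`, `cycles.csv`,
`ground_truth.csv` and a JSON manifest. A thin CLI wrapper is installed at
`inst/cli/ecocycler`.

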