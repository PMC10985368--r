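# srdmsim

Individual-based simulation of **feminising sex-ratio-distorting microbes**
(SRDMs, e.g. *Wolbachia*-like endosymbionts) in arthropod host populations,
and of the extinction risk they create under environmental change.

Maternally inherited microbes gain nothing from sons, and several lineages
therefore feminise genetically male offspring. With vertical transmission
probability γ > 0.5 the infected matriline out-produces the uninfected one,
prevalence climbs, males grow scarce, and mate encounters — not resources —
become the limiting process. `srdmsim` asks when that dynamic kills the host
population, and how environmental variability changes the answer. It is a
tool for theoretical ecologists and conservation modellers studying
host–endosymbiont epidemiology.

## The model in brief

Daily time steps inside non-overlapping breeding seasons of δ days. Each
adult has a fixed phenotype P ∈ [0,1]; one environmental optimum E per
generation (constant, sine-wave `E_t = L + (U−L)/2 (1 + sin(t/R))`, or
uniform on [L,U]). The elementary rates are

* daily adult death `D = (1 − 1/(1 + c·|P − E|)) · (1 − S)` — mismatch
  kills, the symbiont's survival benefit S (infected adults only) rescues
  proportionally;
* daily female mate-encounter `m = (β/δ) · r/(r + θ)`, `r = M/F` — ratio-
  dependent male questing, weaker under poor male dispersal (large θ);
* brood of σ offspring per mating; infected mothers transmit to each
  offspring with probability γ; infected offspring are all daughters;
  uninfected offspring are coin-flip sexed; midparent phenotype inheritance
  with mutation probability φ to a uniform phenotype;
* one density-dependent juvenile cull per season, `d = J/(J + X)`.

A population is extinct when an emerging cohort lacks either sex. Four
analysis protocols sit on top: **ecological** trajectories, a Latin-
hypercube **sensitivity** analysis of extinction (binomial GLM) and mean
prevalence (OLS) over (γ, S, θ), a **mechanistic** growth-rate analysis
against log N and the operational sex ratio (4th-degree polynomial
smoothers), and an **evolutionary** analysis of phenotypic change
Σ|P̄ᵢ − P̄ᵢ₊₁|. See the methods vignette
(`vignettes/feminiser-epidemiology.Rmd`) for assumptions and design
rationale.

## Worked example

A high-transmission infection invading a population in a highly variable
environment:

```r
library(srdmsim)
p  <- sim_params(gamma = 0.95, n_generations = 50)
tr <- run_simulation(p, env_scenario("high"), seed = 42)
tr
#> Simulation trajectory: 18 generation(s) recorded; EXTINCT at generation 18
tr$records[c(1, 5, 10, 15, 18), c("generation", "E", "n_adults_start",
                                  "prevalence", "osr", "matings_per_female")]
#>    generation     E n_adults_start prevalence    osr matings_per_female
#> 1           1 0.520            500      0.058  0.887              0.472
#> 5           5 0.596            454      0.478  2.691              0.592
#> 10         10 0.668            402      0.828 11.562              0.111
#> 15         15 0.699            329      0.930 31.900              0.034
#> 18         18 0.695             82      0.976     NA                 NA
```

Reading the columns: prevalence climbs from the 10% founder infection to
near-fixation; the operational sex ratio (females per male) inflates from
parity to 32:1; matings per female per season collapse from ~0.5 to ~0.03;
and at generation 18 the emerging cohort of 82 adults contains no males at
all (`osr = NA`) — extinction by feminisation, not by resource limits.

The sensitivity protocol quantifies which microbe trait drives that risk:

```r
sens <- sensitivity_experiment(scenario = "high", n_reps = 100,
                               n_generations = 50, base_seed = 1)
sens
#> Sensitivity experiment: scenario=high mode=cyclical reps=100
#>   extinctions: 25 / 100
#> srdm_fit [extinction], n = 100, mean response = 0.2500
#>   separation detected: ridge-penalised fit
#>         term     estimate std_error
#>  (Intercept) -4.943502833 0.9409237
#>        gamma  3.191282326 0.8722142
#>            S  0.009029526 0.8598370
#>        theta  0.498223241 0.1843531
```

Transmission rate γ dominates (extinction concentrates above a γ
threshold — hence the flagged separation fallback); the survival benefit S
and male dispersal θ are comparatively negligible.

The same experiments run from a shell, writing provenance-stamped CSVs:

```sh
inst/cli/srdmsim sensitivity --env high --mode cyclical --reps 100 --seed 1 --out out/
inst/cli/srdmsim single-run --gamma 0 --prevalence 0 --env constant --seed 1 --out out/
```

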