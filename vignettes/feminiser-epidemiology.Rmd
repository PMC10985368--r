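---
title: "Modelling feminising sex-ratio distorters in variable environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling feminising sex-ratio distorters in variable environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Maternally inherited microbes such as *Wolbachia* infect a large fraction of
arthropod species. Because males are transmission dead ends, many of these
symbionts bias host broods towards daughters. One such mechanism is
*feminisation*: genetically male offspring of infected mothers are shifted
onto a female developmental path. A feminiser with vertical transmission
probability $\gamma > 0.5$ out-produces the uninfected female lineage, so
prevalence rises, males grow scarce, the operational sex ratio (OSR, females
per male) inflates, and mate encounters become limiting. `srdmsim` is an
individual-based model (IBM) of this epidemiology, built to ask how the risk
of host population extinction depends on the microbe's traits
($\gamma$, a survival benefit $S$, male dispersal $\theta$) and on how
variable the environment is.

An IBM — rather than a deterministic compartment model — is the right tool
here because extinction is driven jointly by demographic stochasticity
(binomial sexing and transmission in finite broods, last-male effects) and
environmental stochasticity, neither of which a mean-field model captures at
small population sizes.

## The model

Time runs in days within discrete, non-overlapping generations. Each
generation is one breeding season of $\delta$ days during which only adults
exist. Every adult carries a fixed phenotype $P \in [0,1]$, a sex, and an
infection flag (infection implies female, by construction).

**Environment.** One environmental optimum $E_t \in [0,1]$ is drawn per
generation and held for the whole season. In cyclical mode
$$E_t = L + \tfrac{U-L}{2}\,\bigl(1 + \sin(t/R)\bigr),$$
which sweeps exactly the band $[L, U]$ with period $2\pi R$ generations
(about 63 generations at the default $R = 10$). In stochastic mode $E_t$ is
uniform on $[L, U]$; in constant mode $E_t = U = L$. The three named
scenarios are symmetric about $0.5$: constant ($U = L = 0.5$), moderate
($U = 0.6$), high ($U = 0.7$). Cyclical and stochastic variants share a band
and differ only in temporal structure.

**Adult mortality.** Each day every adult dies with probability
$$D = \Bigl(1 - \frac{1}{1 + c\,\lvert P - E\rvert}\Bigr)(1 - S),$$
zero at a perfect phenotype–environment match and rising hyperbolically
with mismatch at a sensitivity set by the selection coefficient $c$. The
infection survival benefit $S$ scales death down proportionally and applies
to infected adults only. At the defaults ($c = 0.2$) the worst possible
daily death probability is $1 - 1/1.2 \approx 0.167$; a maximally
mismatched adult still survives a few days, a well-matched one the whole
season.

**Mating.** Males quest for females; the daily probability that a given
female is found is
$$m = \frac{\beta}{\delta}\,\frac{r}{r + \theta}, \qquad r = M/F,$$
which depends on the sex *ratio* only, saturates at $\beta/\delta$ under
male excess (so a female averages $\beta$ matings over a full-length life),
vanishes with the last male, and declines in $\theta$ — poor male dispersal
makes female scarcity bite harder. Since $\delta > \beta$, $m < 1$ always.
A female mates at most once per day; a brood's father is drawn uniformly
from the males alive that day, and males are not limited in daily matings.

**Reproduction and inheritance.** Each mating yields a brood of $\sigma$
offspring laid that evening. An infected mother transmits to each offspring
independently with probability $\gamma$ (binomial in the brood); infected
offspring are all female, uninfected offspring are sexed by a fair coin.
Offspring inherit the parental midpoint phenotype unless they mutate
(probability $\varphi$), in which case the phenotype is uniform on $[0,1]$.
Blending inheritance with rare uniform mutation keeps standing variation
alive without tracking loci.

**Juvenile regulation.** All broods of a season are pooled and culled once,
each juvenile dying independently with probability $d = J/(J+X)$ —
resource competition among $J$ juveniles at intensity set by $X$,
deliberately independent of $E$ (juveniles occupy microhabitats decoupled
from the broadscale environment adults experience). Survivors emerge as the
next season's adults. The expected number of emerging adults,
$J X/(J+X) < X$, makes $X$ the population's ceiling scale.

**Extinction.** A population is extinct when an *emerging* cohort has
fewer than one individual of either sex (or is empty). Within a season,
losing the last living adult of a sex merely ends mating for that season:
because generations do not overlap, every adult dies at season's end
anyway, so broods already laid must still emerge. We initially evaluated
the stricter alternative — declaring extinction the moment a living sex
count hits zero mid-season — and rejected it: late-season adult die-off is
near-certain in small or badly mismatched cohorts (a cohort of 100 adults
at a typical mismatch loses essentially all members within 90 days), and
the strict rule voids brood pools of thousands of juveniles laid weeks
earlier, producing extinctions of demographically healthy populations.
Under the census rule, uninfected populations never go extinct in the
standard protocols — which is the behaviour the underlying theory expects,
since without sex-ratio distortion the regulated population sits far from
the extinction boundary.

## Parameters

| Symbol | Meaning | Default | Range used |
|---|---|---|---|
| $\delta$ | season length (days) | 90 | fixed |
| $c$ | selection coefficient | 0.2 | fixed |
| $S$ | infection survival benefit | 0 | 0–0.5 |
| $\theta$ | male dispersal (dimensionless) | 1.5 | 0.05–5 |
| $\beta$ | lifetime matings per female | 4 | fixed |
| $\sigma$ | brood size | 50 | fixed |
| $\gamma$ | vertical transmission | 0.9 | 0.5–1 sampled; 0–1 accepted |
| $\varphi$ | mutation probability | 0.01 | fixed |
| $X$ | juvenile competition scale | 500 | fixed |
| $R$ | environmental wave frequency | 10 | fixed |

The sampled ranges for $\gamma$, $S$ and $\theta$ are the ones the
sensitivity protocol explores; the constructor accepts any $\gamma \in
[0,1]$ so that uninfected controls ($\gamma = 0$) and the evolutionary
protocol's low-transmission cells (0.2) are expressible.

**Initialisation** is not part of the core model and is config-exposed:
`init_size = 500` adults (the ceiling scale $X$), fair sexing, founder
phenotypes uniform on $[0,1]$, and 10% of founding females infected.
Uniform founder phenotypes supply the standing variation the evolutionary
analysis tracks; initial prevalence 0.1 lets invasion or loss of the
microbe emerge from the dynamics rather than being assumed. A `matched`
phenotype mode (all founders at the first optimum) exists for controlled
tests.

## The four analysis protocols

* **Ecological** (`ecological_experiment`): trajectory tables (abundance,
  matings per female per season, prevalence) over a $\gamma \times$
  scenario grid, 100 generations — for graphical sanity checks, no fitting.
* **Sensitivity** (`sensitivity_experiment`): Latin hypercube over
  $(\gamma, S, \theta)$, one triple per replicate, 100 replicates capped at
  50 generations per scenario and per variation mode; a binomial (logit)
  GLM for extinction and an OLS model for mean prevalence, with
  model-predicted curves (focal parameter varied over its range, the other
  two at range midpoints).
* **Mechanistic** (`mechanistic_experiment`): growth rate
  $\log N_{t+1} - \log N_t$ (natural log) against $\log N_t$ and against
  OSR at $\gamma = 0.9$, pooled across 100 replicates of 100 generations;
  summarised by 4th-degree polynomial least-squares smoothers. An Allee
  effect would appear as a significantly positive fitted slope at low
  abundance; its absence, together with a negative growth–OSR trend,
  identifies sex-ratio skew as the mechanism of decline.
* **Evolutionary** (`evolutionary_experiment`): the phenotypic travel
  $\sum_i \lvert \bar P_i - \bar P_{i+1}\rvert$ over 50 generations per
  (scenario, $\gamma$) cell. Replicates extinct before the horizon are
  excluded and counted — a truncated sum is not comparable to a full one —
  and all-extinct cells are flagged rather than averaged.

## Numerical and design choices

* **Smoother.** The growth-rate curves use ordinary least squares on a
  4th-degree polynomial basis (centred and scaled predictor; derivatives
  and delta-method standard errors are analytic). A penalised spline GAM
  would add a smoothing-parameter choice without changing what a global
  quartic can express on these data.
* **Separation.** When extinction separates cleanly in $\gamma$ (common:
  extinction concentrates above a threshold), the logistic GLM diverges;
  the fit then falls back to a ridge-penalised IRLS ($\lambda = 1$ on
  standardised-scale slopes) and is flagged `penalized`. Curves stay
  monotone and finite; flagged coefficients should not be read as unbiased
  effect sizes.
* **Exact thinning.** Within a season both $P$ and $E$ are fixed, so each
  adult's daily death probability is precomputed once. The juvenile cull is
  applied as per-brood Binomial($\sigma$, $1-d$) thinning with survivor
  attributes drawn i.i.d. afterwards; because the cull is independent of
  offspring attributes, this is *exactly* the distribution obtained by
  materialising all $\sigma$ offspring per brood and culling individuals —
  not an approximation. It makes a 50-generation run take a fraction of a
  second.
* **Seeding.** Every replicate has its own seed, `base_seed + offset + i`,
  recorded in the output tables; experiment cells occupy disjoint seed
  blocks so cross-scenario comparisons use independent randomness.
  Trajectories are bit-reproducible given a seed within this
  implementation (R's default Mersenne–Twister).
* **Degenerate inputs.** Zero-generation horizons return an empty,
  non-extinct trajectory; single-sex cohorts are contract violations for
  `run_season` and extinction events for `run_simulation`; all-extinct or
  no-extinct sensitivity tables skip fitting and carry a `degenerate`
  flag.

## Problem sizes in the shipped checks

The packaged test-suite runs the protocols at the sizes that make their
conclusions statistically meaningful while staying quick on one core: the
uninfected-control and scenario-ordering checks use the full 100 replicates
per cell (the ordering check at $\gamma = 0.95$, inside the extinction
transition region, where ordering is discriminable at all); the mechanistic
checks use 40 replicates per scenario; the evolutionary grid uses 50
replicates per cell. Monotonicity and ordering are tested one-sidedly at
$\alpha = 0.01$, so sampling noise cannot fail a true ordering; GLM and
smoother stages are additionally verified against synthetic data with known
coefficients.

## What the generator does and does not emulate

The simulator *is* the study system: there is no external data. It captures
demographic stochasticity, maternally inherited feminisation, ratio- (not
density-) dependent mate encounter, blending inheritance with mutation, and
band-limited environmental forcing. It does not represent overlapping
generations, within-season environmental change, spatial structure or
migration, male-killing or parthenogenesis induction, horizontal
transmission, resistance evolution, or any molecular detail of sex
determination. Conclusions from these simulations therefore speak to the
epidemiological logic of feminisation under environmental variation — not
to any particular species' demography, and real systems with immigration
or overlapping cohorts may be substantially more robust.

## Known limitations

* The death formula's placement of $c$ and $S$ follows the prose reading
  (sensitivity multiplier on mismatch; proportional survival benefit);
  other operationalisations of a "proportional increase in survival" exist
  and would rescale, though not reorder, the $S$ effects — which are weak
  in any case.
* Mean prevalence for extinct sensitivity replicates is averaged over the
  generations actually realised, which slightly overweights the
  high-prevalence death spiral of late-extinct replicates.
* The ridge fallback trades bias for existence under separation; if the
  coefficients themselves matter, enlarge the design instead.
* OSR can be large when males are nearly gone; the quartic in OSR is
  data-sparse in that tail, and slopes there carry wide standard errors.
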