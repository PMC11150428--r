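# closekin

Close-kin mark-recapture (CKMR) estimates the size of an adult population
from the frequency of kin pairs among sampled animals: every offspring
genetically "marks" its two parents, and each sampled pair is a Bernoulli
trial for a parent–offspring relationship. `closekin` implements the full
workflow for the hard practical case where **age is not observed** but must
be inferred from length through an assumed growth curve:

* an agent-based, pedigree-tracking simulator of age-structured shark-like
  populations (annual or biennial breeders, knife-edge maturity, constant
  survival calibrated by Leslie-matrix eigenvalue so the population is
  stationary);
* a parent–offspring-pair pseudo-likelihood for sex-specific adult
  abundance $(N_f, N_m)$, where each pairwise comparison has probability
  $A/N_{s_i} + B/N_{s_j}$ and the coefficients marginalize the unknown ages
  over length-based posteriors
  $f(a \mid \ell^*) \propto f(\ell^* \mid a)\, \phi^a$, with
  $f(\ell^* \mid a)$ a centimetre-discretised Normal around the von
  Bertalanffy expectation $\ell(a) = \ell_\infty(1 - e^{-k(a - a_0)})$;
* maximum pseudo-likelihood fitting with Hessian standard errors and 95%
  log-normal confidence intervals;
* an experiment driver that refits the same simulated data under grids of
  misspecified measurement-error SDs (ME−67 … ME+67) and shifted growth
  curves (GC−10 … GC+10), with scenario-exclusion rules and
  bias/coverage/SE-honesty metrics.

It is aimed at quantitative ecologists designing or stress-testing CKMR
studies for fish and elasmobranchs, where lengths are cheap and ages are
not.

## Worked example

```r
library(closekin)

sp <- species_simple()        # litter of 2, maturity 10, max age 19
sp$phi                        # survival calibrated to growth rate 1
#> [1] 0.8466143

sim <- simulate_population(sp, seed = 42)
sim
#> CKMR simulation of the 'simple' species (100 years)
#>   750 sample records, 38 true POPs, 11 recaptured individuals
#>   final-year adult abundance: 780 F / 796 M; realized growth 0.9997

model <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)  # correct spec
agg <- aggregate_comparisons(sim$samples, sim$pops, model, sp)
fit <- fit_ckmr(agg)
tidy(fit)
#> # A tibble: 2 × 5
#>   term  estimate std.error conf.low conf.high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 N_f       931.      208.     604.     1435.
#> 2 N_m      1194.      281.     757.     1883.
```

This replicate drew only 38 parent–offspring pairs (the ensemble mean is
about 53), so both estimates sit high; across replicates the median
relative error under correct specification is a few percent. The
interesting experiment is what happens when the *assumed* observation model
is wrong:

```r
fits <- run_scenario_grid(species_simple(), n_replicates = 100,
                          master_seed = 1)   # all 25 ME x GC scenarios
compute_metrics(fits)      # bias, coverage, SE honesty per scenario & sex
plot_scenario_errors(fits) # relative-error box plots, excluded cells blank
```

Down-shifting the growth curve 5% biases abundance upward by ~+30% or
more, up-shifting biases it down by a similar amount, while even a 67%
overstatement of the measurement-error SD leaves estimates nearly
unchanged; understating the SD mostly makes fits fail outright (observed
lengths become impossible under the assumed model), concentrated in the
low-SD / down-shifted corner of the grid.

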