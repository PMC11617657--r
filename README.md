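# scentselect

Phenotypic plasticity and natural selection on floral volatile emissions
under manipulated snowmelt timing and summer precipitation.

## The problem

Climate change in subalpine meadows shifts two things at once: snow melts
earlier and summer rainfall changes. For a monocarpic, hummingbird-pollinated
wildflower, both can move floral traits — scent emissions, corolla
dimensions, nectar — and both can move *selection* on those traits, via
pollinators and predispersal seed predators (anthomyiid flies whose larvae
consume the seeds of a fruit). Whether a plastic trait response helps or
hurts depends on the direction of selection in the new environment:
plasticity is **adaptive** when the trait moves the way selection favours
there, **maladaptive** when it moves against it.

`scentselect` is for field ecologists running (or simulating) split-plot
climate-manipulation experiments who need the full chain from raw GC-MS peak
tables to that adaptive-plasticity verdict:

1. **Volatile pipeline** — filter compounds (retention-time window,
   detection frequency, 4× ambient-control rule, contaminant list),
   calibrate against dilution series of class standards, convert areas to
   emission rates (ng flower⁻¹ h⁻¹), average repeated samples per plant.
2. **Plasticity** — canonical analysis of principal coordinates (CAP) on
   Bray–Curtis distances among emission profiles with sequential
   permutation tests and percent-inertia reporting, plus split-plot linear
   mixed models of class totals, estimated marginal means, and Cohen's *d*
   effect sizes.
3. **Fitness** — four female-fitness measures from fruit/seed censuses
   (total seeds, seeds initiated per flower, escape from seed predation,
   fly eggs per flower), with the field imputation rules, relativized to
   the grand mean.
4. **Selection** — standardized gradients β (slope of relative fitness *w*
   on a mean-0, SD-1 trait *z*) by three routes: compound-class models with
   treatment interactions; univariate models
   `w ~ z + S + P + z:S + z:P` (snowmelt date *S*, precipitation *P*,
   interactions dropped when both *P* > 0.05); and elastic-net
   (α = 0.5, λ by cross-validation) direct gradients with unpenalized
   environmental covariates.
5. **Concordance** — fold-change plasticity (EMM ratios) against β in the
   new environment, quadrant classification, exact binomial test of the
   adaptive : maladaptive balance.
6. **Synthetic generator** — a full split-plot study simulator
   (6 whole plots × 4 subplots × 3 years, correlated lognormal emissions
   of 29 compounds in 4 classes, soil-moisture-driven plasticity, fitness
   built from configurable true gradients and predation) so every stage is
   testable with known truth and no field data.

## Worked example

A synthetic study with one known truth: selection gradient β = 0.15 on
α-pinene through seeds initiated per flower.

```r
library(scentselect)

truth <- true_params(beta_poll = c(alpha_pinene = 0.15))
study <- simulate_study(seed = 1, n_total = 374, truth = truth)

# peak table -> filtered, calibrated, plant-averaged emission matrix
vol <- volatile_pipeline(study$peak_table, study$dilution_series)
em  <- vol$emissions[rowSums(vol$emissions) > 0, ]
tr  <- study$trait_table[match(rownames(em), study$trait_table$plant_id), ]

# constrained ordination of emission profiles on the design
mod <- cap_fit(pcoa(bray_curtis(transform_sqrt(em))),
               ~ factor(year) + snow_treatment + precip_treatment, tr)
sequential_perm_test(mod, n_perm = 199, seed = 1,
                     interaction_block = FALSE)[, 1:5]
#>               term df    inertia         F p_value
#> 1     factor(year)  2 0.17076701 1.0696701   0.345
#> 2   snow_treatment  1 0.09661467 1.2103722   0.215
#> 3 precip_treatment  3 0.22990736 0.9600801   0.575
percent_inertia(mod)$display
#> [1] 2

# fitness measures, then the univariate gradient on alpha-pinene
fit <- fitness_table(study$fitness_components)
fit <- fit[match(rownames(em), fit$plant_id), ]
z   <- standardize_traits(transform_sqrt(em))$z
univariate_env_selection(z[, "alpha_pinene"], fit$rel_seeds_per_flower,
                         tr$snowmelt_date, tr$summer_precip)[
  , c("beta", "se", "p", "interactions_retained")]
#>        beta          se            p interactions_retained
#> 1 0.1528373 0.008436494 5.774832e-53                 FALSE
```

Read: this null-plasticity world shows no treatment signal in the
ordination (all permutation *p* > 0.2; the design explains 2% of total
inertia), while the selection analysis recovers the planted gradient
(β̂ = 0.153 ± 0.008 against a truth of 0.15), with both trait × environment
interactions correctly dropped.

## Command line

```sh
SCENT=$(Rscript -e 'cat(system.file("exec/scentselect", package = "scentselect"))')
Rscript $SCENT simulate --seed 1 --outdir study_csvs   # write the 5 input CSVs + truth.json
Rscript $SCENT run      --seed 1 --outdir results      # full pipeline, CSV outputs + manifest.json
Rscript $SCENT validate --config cfg.yaml              # schema/invariant report
```

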