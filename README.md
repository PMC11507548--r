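# repdist

Replication distance between idealized experiments, measured in the
currency of reproducibility rates.

## The problem

When a replication study fails to reproduce a published result, two
explanations compete: the original finding was fragile, or the
"replication" was in fact a different experiment.  Telling them apart
requires a *distance* between studies — and a study is more than a
sampling distribution.  `repdist` is for metascientists and
methodologists who want that distance made operational.  It formalizes a
study as an **idealized experiment**, the ordered tuple

```
ξ = (K ≺ S_pre ≺ M ≺ S_post ≺ D)
```

(background knowledge, pre-data methods, statistical model, post-data
analysis, data structure + values), and fixes a binary result type `R`
with target value `r`.  Over exact replications — identical components,
independently regenerated data values — the **reproducibility rate**

```
φ = lim_{N→∞} N⁻¹ Σ I{R⁽ⁱ⁾ = r}
```

is a parameter of the experiment, estimated by plain Monte Carlo.  Given
an original ξᵒ and a replication ξ′, the package enumerates all
2⁴ = 16 component swaps between them and defines, per component, e.g.
for the model,

```
d(Mᵒ, M′) = (1/n(M)) · | Σ φ(r | S_pre, Mᵒ, S_post, D) − Σ φ(r | S_pre, M′, S_post, D) |
```

with the sums running over the 8 permutations of the remaining
components.  Swaps that do not yield a performable experiment score
φ = 0 by convention (dropping them would deflate the distance); at least
two performable cells are required (the permutation axiom).  The result
is a four-coordinate distance vector — pre-data, model, post-data, data
structure — deliberately never collapsed into one number.  Background
knowledge `K` is carried as annotation and is not permuted.

The package ships a complete worked example: two dugong growth-curve
studies (a linear log-age + weight model fit by OLS on a small biased
sample, versus an asymptotic nonlinear model fit by vague-prior Bayesian
MCMC on a large clean sample), with the result "does the predicted
breeding status at age 17 years / 250 kg (mean length > 2.50 m) match
the status under the true model".  Planned-modification sequences toward
a *minimum viable experiment* (MVE) are supported via
`study_sequence()` / `extend_sequence()` / `convergence_summary()`.

## Worked example

```r
library(repdist)
st <- dugong_studies()
st$original
#> <experiment_spec> Study 1 (linear model, OLS, n=20 biased)
#>   pre-data : predictors: age, weight
#>   model    : linear (log-age + weight)
#>   post-data: least squares (OLS / Levenberg-Marquardt NLS)
#>   data     : n=20 (age bias 0.8, weight bias 1.2)

# exact path: distances from the shipped reference rate table
distance_vector(dugong_printed_rates())
#> <distance_vector> (per-component replication distance)
#>   d(pre-data methods ) = 0.406
#>   d(model            ) = 0.539
#>   d(post-data methods) = 0.036
#>   d(data structure   ) = 0.111

# simulation path: fresh Monte Carlo rates for all 16 permutations
res <- run_dugong_example(n_reps = 2000, n_reps_bayes = 200, seed = 42)
res$distances
#> <distance_vector> (per-component replication distance)
#>   d(pre-data methods ) = 0.498
#>   d(model            ) = 0.496
#>   d(post-data methods) = 0.001
#>   d(data structure   ) = 0.007
```

Reading the exact-path vector: the result is most sensitive to the
pre-data methods (0.406) and the model (0.539) — both driven by the
non-performable stratum in which the age-only design cannot feed the
weight-requiring linear model (permutation cells 9–12, rate 0 by
convention) — while the choice between two well-behaved estimators
(0.036) barely matters, and the gap between a small biased sample and a
large clean one (0.111) is surprisingly small *for this result*.  In the
fresh simulation the same structure appears: the zero stratum dominates
the first two coordinates, and all performable cells have rates near 1,
so the last two coordinates nearly vanish.  The vignette
(`vignettes/replication-distance.Rmd`) explains why the fresh rates of
the noisy cells sit above the reference table's, and every tunable knob
involved.

Rates come with full bookkeeping: requested/valid/failed replicate
counts per cell (nonlinear least-squares failures are excluded from the
denominator and warned about past 5%), Monte Carlo standard errors, and
CSV export (`write_rate_table()`, `read_rate_table()`,
`write_distance_table()`).

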