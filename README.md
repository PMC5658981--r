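# mavtkit

Multi-attribute value theory (MAVT) for health technology appraisal:
MACBETH-style qualitative preference elicitation, reference-anchored
value functions, swing weighting, additive aggregation, rank-reversal
weight sensitivity, and cost-per-value efficiency analysis — with a
fully worked appraisal of three second-line treatments for metastatic
colorectal cancer (mCRC).

## Who this is for

Health-economics and decision-analysis practitioners who run (or study)
facilitated multi-criteria appraisals: evaluating a handful of
treatment options against an explicit tree of weighted benefit criteria,
where preferences are elicited from a stakeholder group rather than
taken from a tariff. The package is equally usable as a general MAVT /
MCDA engine outside health care.

## The model

Each option *a* receives an overall weighted preference value

    V(a) = sum_i  w_i * v_i(a)

where the partial value functions `v_i` are piecewise linear through
elicited anchor points, anchored so that a *lower reference* level
(satisfactory performance) scores 0 and a *higher reference* (best
plausible performance) scores 100 — performances worse than the lower
reference score below zero. Weights `w_i` come from qualitative swing
comparisons. Qualitative difference-of-attractiveness judgments
(*no / very weak / weak / moderate / strong / very strong / extreme*)
are converted into cardinal scales by linear programming, with ordinal
and cardinal consistency checking:

```r
library(mavtkit)
m <- matrix(NA, 3, 3, dimnames = list(c("a","b","c"), c("a","b","c")))
m["a","b"] <- "weak"; m["b","c"] <- "strong"; m["a","c"] <- "very strong"
derive_scale(judgment_matrix(m))
#> MACBETH unanchored scale:
#> a b c
#> 6 4 0
```

## Worked example: the mCRC appraisal

The packaged case study evaluates cetuximab, panitumumab and
aflibercept + FOLFIRI on nine attributes in four value clusters
(therapeutic impact, safety profile, innovation level, socioeconomic
impact), with the appraisal workshop's performances, partial scores,
weights and costs.

```r
library(mavtkit)
cs  <- mcrc_case_study()
res <- run_pipeline(cs$model, cs$performance, cs$costs,
                    out_dir = "results/case_study", verbose = FALSE)

res$evaluation
#> Overall weighted preference values:
#>               option value rank tie_group
#>            cetuximab  45.7    1         1
#>          panitumumab  42.3    2         2
#>  aflibercept_folfiri  14.3    3         3
```

Cetuximab ranks first with an overall value of 45.7 out of 100,
panitumumab second with 42.3. Aflibercept + FOLFIRI drops to 14.3
because its Grade 4 adverse-event rate (21% of patients) is worse than
the 10% lower reference, scoring −117.9 on that attribute and
contributing −27.5 weighted points. Cluster weights roll up from the
attribute weights:

```r
round(100 * res$cluster_weights, 1)
#>   therapeutic        safety    innovation socioeconomic
#>          46.5          23.3          18.6          11.6
```

One-way weight sensitivity finds the weight at which two options swap
ranks, all other weights rescaled proportionally — e.g. the Posology
weight would have to rise from 7.0 to 11.8 (of 100) before panitumumab
overtakes cetuximab; no single weight change of 50% or less alters any
rank:

```r
round(100 * weight_threshold("posology", "panitumumab", "cetuximab",
                             res$scores, res$weights)$w_star, 1)
#> [1] 11.8
```

Dividing rounded total costs (drug + administration) by overall value
puts cetuximab alone on the efficiency frontier:

```r
res$efficiency
#>                option value  cost efficient cost_per_value_unit
#> 1 aflibercept_folfiri  14.3 29400     FALSE           2055.9441
#> 2           cetuximab  45.7 18000      TRUE            393.8731
#> 3         panitumumab  42.3 27000     FALSE            638.2979
```

about £394 per value point for cetuximab versus £638 (panitumumab,
dominated by cetuximab) and £2,056 (aflibercept + FOLFIRI, dominated by
both).

The numbered scripts under `analysis/` run the full study as a
narrative workflow (`01_case_study.R`, `02_sensitivity.R`,
`03_efficiency.R`, `04_synthetic_validation.R`), writing their tables
under `results/`. The methods vignette
(`vignettes/value-appraisal-methods.Rmd`) documents the model,
elicitation LP, sensitivity semantics and the fixture's reconstruction
choices.

## Synthetic decision problems

Every pipeline stage is testable without external data:
`generate_problem()` builds random decision problems (monotone latent
value functions, interior lower references, positive normalized
weights, in-range performances) with known ground truth, and
`generate_judgments()` bins latent value differences into judgment
categories — consistent by construction, with an optional corruption
rate for exercising the inconsistency paths.
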