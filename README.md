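# opioidlca

Subtyping opioid misuse in hospitalized patients with latent class
analysis (LCA) of electronic-health-record (EHR) data — a fully seeded,
self-contained research pipeline.

Hospital encounters with opioid misuse are clinically heterogeneous: some
patients present with polysubstance use, some with an isolated unexplained
opiate-positive drug screen, some with alcohol and advanced liver disease.
This package simulates a realistic EHR cohort with that latent structure,
identifies misuse encounters with a rule-based computable phenotype,
discovers subtypes with a from-scratch latent class analysis, validates the
subtypes against clinical-note topic models, and compares 30-day unplanned
readmission and discharge dispositions across subtypes.

## What's inside

| Stage | Key functions |
|---|---|
| Synthetic EHR cohort | `cohort_config()`, `generate_cohort()`, `generate_notes()`, `write_cohort()` |
| Rule-based misuse phenotype | `evaluate_encounters()`, `build_cohort()`, `build_indicator_matrix()` |
| Latent class analysis (EM, from scratch) | `lca_em()`, `select_model()`, `posterior_matrix()`, `assign_classes()`, `match_classes()` |
| Note topic models (collapsed Gibbs LDA) | `build_vocabulary()`, `fit_topic_model()`, `topic_coherence()`, `class_topic_matrix()` |
| Outcomes (CMS-style readmission) | `flag_unplanned_readmission_30d()`, `outcome_table()`, `compare_classes()` |
| End-to-end | `run_pipeline()` and the `inst/cli/opioidlca.R` command line tool |

All randomness derives from a single integer seed; every stage is
deterministic given that seed.

## Worked example

Generate a 20,000-encounter cohort, phenotype it, and fit the LCA:

```r
library(opioidlca)

cfg <- cohort_config(n_encounters = 20000L, seed = 7L)
cohort <- generate_cohort(cfg)
ev <- evaluate_encounters(cohort$encounters, cohort$uds,
                          cohort$medications, cohort$diagnoses)
sum(ev$is_misuse)                    # 513 flagged (2.56%)

mis <- build_cohort(ev, cohort$encounters)
ind <- build_indicator_matrix(mis$encounter_id, cohort$encounters,
                              cohort$uds, cohort$medications,
                              cohort$diagnoses)
sel <- select_model(ind, C_range = 1:6, n_starts = 10, seed = 11L)
sel$table[, c("C", "loglik", "k", "bic")]
#>   C    loglik  k      bic
#> 1 1 -2972.024 13 6025.173
#> 2 2 -2860.188 27 5888.863
#> 3 3 -2810.221 41 5876.293
#> 4 4 -2788.818 55 5920.852
#> 5 5 -2776.539 69 5983.657
#> 6 6 -2765.187 83 6048.317
```

At this small cohort size the BIC elbow rule settles on 3 classes; at the
full default scale (228,884 encounters, ~6,200 flagged) the same rule
selects 4. Align the 4-class fit to the package's reference profiles and
inspect assignment:

```r
fit <- sel$fits[["4"]]
post <- posterior_matrix(ind, fit$params)
ref <- lca_params(calibrated_class_prevalences(), calibrated_item_response())
perm <- match_classes(fit$params, ref)
labels <- match(assign_classes(post), perm)
round(100 * tabulate(labels, 4) / length(labels), 1)
#> [1] 39.2 10.9 37.4 12.5

class_separation(post, assign_classes(post))
#>   class   n mean_posterior sd_posterior
#> 1     1 201      0.8513294   0.07671433
#> 2     2 192      0.9935830   0.03047323
#> 3     3  64      0.9518217   0.11233229
#> 4     4  56      0.8378775   0.14172364
```

Outcomes by subtype (readmissions planted at the calibrated class rates):

```r
gt <- ground_truth_table(cohort)
cls <- gt$true_class[match(mis$encounter_id, gt$encounter_id)]
oc <- simulate_class_outcomes(cls, seed = 8L)
fl <- flag_unplanned_readmission_30d(oc$encounters, oc$diagnoses,
                                     oc$study_end_day)
outcome_table(oc$encounters[oc$index_ids, ], labels, fl[oc$index_ids, ])
#>           n ... ama_pct  death_pct eligible_index_n readmission_pct
#> class1  201 ...  8.96      1.49           198            7.58
#> class2   56 ... 12.50      0.00            56           10.71
#> class3  192 ...  6.77      3.12           186           13.44
#> class4   64 ...  3.12      1.56            63           12.70
#> overall 513 ...  7.80      1.95           503           10.74
```

At full scale the class-1 readmission rate converges to ~13.9%, class-2
discharge against medical advice to ~12.3%, and pooled class-3/4 death to
~3.2%; `compare_classes()` provides the chi-square tests.

## One-shot pipeline

```r
res <- run_pipeline(cohort_config(seed = 42L), outdir = "runs/demo")
```

writes the cohort CSVs, notes JSONL, LCA fit table and assignments, topic
model summaries, outcome and characteristics tables, and a run manifest.
The same is available from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","opioidlca.R",package="opioidlca"))')" \
  run-all --seed 42 --n 20000 --out runs/demo
```

Subcommands `simulate`, `phenotype`, `lca`, `topics`, and `outcomes` run
individual stages against a cohort directory.

## Tests

The test suite (`tests/testthat/`) includes property-based checks against
independent brute-force oracles: an exhaustive truth table for the
phenotype rules, exhaustive short admission histories for the readmission
logic, a grid-search oracle and monotonicity checks for the EM, and
parameter-recovery experiments for both the LCA and the topic model.

```r
testthat::test_dir("tests/testthat", package = "opioidlca",
                   load_package = "installed")
```

See `vignettes/methods.Rmd` for the statistical methods and the rationale
behind the calibration defaults.
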