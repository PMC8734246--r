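# lookback

Lookback-window sensitivity analysis for claims-based prevalence and
incidence.

## The problem

Administrative health claims identify chronic-disease cases indirectly: a
case-finding algorithm (e.g. *one hospitalization OR two physician claims
within two years*, evaluated over ICD-coded encounters and drug
dispensations) is applied to the claims observed during a retrospective
**lookback window (LW)** of *k* years plus the estimation year. Too short a
window misses long-standing cases — deflating period prevalence — and then
mistakes their next encounter for a new diagnosis — inflating cumulative
incidence. Epidemiologists analysing claims data must pick *k*, and the
right choice depends on how often each disease generates healthcare
encounters and on the population's engagement with care.

`lookback` makes that choice a measurable, data-driven exercise. Taking the
classification obtained with the longest feasible window (16 years for 2012
estimates over data starting in 1996) as the reference standard, it
computes for every shorter window, on person **sets**:

- **misclassified prevalent proportion** — |Prev_ref \ Prev_k| / |Prev_ref|,
  the share of reference prevalent cases a k-year window fails to capture;
- **misclassified incident proportion** — the share of apparently incident
  cases under a k-year window that are prevalent under the reference.

Because real linked claims cohorts are access-restricted, the package
includes a fully seeded synthetic claims generator (two matched
populations, absorbing disease onset, Poisson encounter processes, three
claim sources), exact 1:5 birth-year/sex matching, configurable multi-source
case definitions, annual-trend analysis with year-varying maximum windows,
and publication-style shaded misclassification grids. Every stage is
testable end to end without external data.

## Worked example

```r
library(lookback)

cfg <- load_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "lookback"))
cfg$output_dir <- "demo-out"
res <- run_pipeline(cfg)   # simulate -> match -> ascertain -> sweep -> trends

est <- readr::read_csv("demo-out/estimates.csv", show_col_types = FALSE)
print(as.data.frame(subset(est, disease == "hypertension" &
                                population == "index" &
                                k %in% c(1, 8, 16))),
      row.names = FALSE)
```

```
 population      disease estimation_year  k n_denominator n_prevalent n_at_risk
      index hypertension            2012  1           290         131       219
      index hypertension            2012  8           290         158       134
      index hypertension            2012 16           290         158       134
 n_incident prevalence_pct incidence_pct flag
         60           45.2          27.4   NA
          2           54.5           1.5   NA
          2           54.5           1.5   NA
```

Reading: among the 290 index persons old enough for the hypertension
analysis, a 1-year window finds 45.2% prevalent, while 8- and 16-year
windows agree at 54.5% — the estimate has stabilised by k = 8. The 1-year
window also calls 60 persons "incident" (27.4% of its at-risk pool); almost
all of these are long-standing cases it failed to look back far enough to
see — by k = 8 only 2 genuine incident cases remain.

The misclassification grid mirrors that directly (rows by disease, cells =
percentage of reference prevalent cases missed, banded at <10 / <20 / <30%):

```r
render_misclass_table(res$misclassification, "prevalent") |>
  subset(population == "index",
         select = c(disease, lw_1, lw_4, lw_8, lw_16)) |>
  as.data.frame() |>
  print(row.names = FALSE)
```

```
             disease         lw_1         lw_4        lw_8     lw_16
 alzheimers_dementia 58.8 [>=30%]  23.5 [<30%] 11.8 [<20%] 0.0 [Ref]
                copd 58.7 [>=30%]  21.7 [<30%]  2.2 [<10%] 0.0 [Ref]
                 cvd 39.5 [>=30%]   7.0 [<10%]  0.0 [<10%] 0.0 [Ref]
            diabetes   0.0 [<10%]   0.0 [<10%]  0.0 [<10%] 0.0 [Ref]
        hypertension  17.1 [<20%]   0.0 [<10%]  0.0 [<10%] 0.0 [Ref]
      kidney_disease 71.2 [>=30%] 33.9 [>=30%]  1.7 [<10%] 0.0 [Ref]
       liver_disease 78.9 [>=30%] 47.4 [>=30%] 21.1 [<30%] 0.0 [Ref]
      osteoarthritis 81.4 [>=30%] 45.8 [>=30%] 23.7 [<30%] 0.0 [Ref]
```

Diabetes — identifiable from regular drug dispensations — is fully captured
by a 1-year window, while sparsely-encountered osteoarthritis and liver
disease still miss ~20–25% of prevalent cases at 8 years. That contrast in
required lookback length, driven purely by encounter frequency, is the
phenomenon the package quantifies.

A thin command-line wrapper over the same functions ships in
`inst/scripts/lookback_pipeline.R`
(subcommands `all`, `simulate`, `cohort`, `sweep`, `trends`; every run is
reproducible from `--config` + `--seed`). The shipped case definitions are
illustrative stand-ins for testing with the synthetic generator — replace
them (YAML via `read_case_definitions()`) before use on real data.

See `vignettes/lookback-methods.Rmd` for the classification model, the
closed-form Poisson anchor used to validate the misclassification
machinery, and known limitations.

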