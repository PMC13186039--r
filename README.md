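# soilcdrisk

Soil cadmium (Cd) health-risk assessments that use the *total* metal
concentration overstate exposure: only the fraction that dissolves in
simulated gastrointestinal fluid — the **bioaccessible** fraction — can
reach systemic circulation. `soilcdrisk` implements, as a tested and
reusable R pipeline, the full workflow of a national-scale bioaccessibility
study for Cd-contaminated soils:

1. **Data emulation** — a synthetic generator reproducing the statistical
   structure of compiled soil/bioaccessibility surveys: physicochemical
   properties inside published survey ranges (pH 3.01–11.37, SOM
   0.17–131.03 g/kg, texture triplets summing to 100), an in-vitro method
   mixture (PBET 73.3%, UBM 15.8%, others 10.9%), and an intestinal-phase
   bioaccessible Cd content that is log-linear in total Cd and sand
   fraction with a pH × Cd interaction.
2. **Preprocessing** — Kruskal–Wallis and Mann–Whitney screening of
   extraction methods, TOC→SOM conversion (factor 0.58), missForest-style
   iterative random-forest imputation, Cook's-distance outlier filtering,
   and Spearman correlation tables.
3. **Predictive models** of log bioaccessible Cd content: p-value-driven
   stepwise linear regression and a grid-searched random forest
   (5-fold CV), with impurity importances and exact interventional
   Shapley attributions.
4. **Spatial mapping** — ordinary kriging (Matheron variogram, WLS fit)
   and per-region geometric-mean aggregation onto property grids.
5. **Probabilistic risk** — Monte Carlo propagation of exposure-parameter
   distributions through the USEPA average-daily-dose equations

   ```
   ADD_ing  = C · BA · IngR · CF · EF · ED / (BW · AT)
   ADD_inh  = C · InhR · EF · ED / (PEF · BW · AT)
   ADD_derm = C · SA · AF · ABF · EF · ED · 1e-6 / (BW · AT)
   HQ = Σ ADD_i / RfD_i        CR = Σ ADD_i · SF_i
   ```

   with bioaccessibility entering the ingestion dose, paired
   adjusted/unadjusted runs under common random numbers, and
   contribution-to-variance sensitivity analysis (normalized squared
   Spearman correlations).

The audience is environmental risk assessors and soil scientists who want
a reproducible, inspectable version of this modelling chain without the
original compiled dataset: every stage runs on generated data with known
ground truth, so each statistical claim is testable.

## Worked example

```r
library(soilcdrisk)

soil  <- generate_soil_dataset(195, seed = 42)   # survey-scale dataset
frame <- prepare_model_frame(soil)               # log response, log Cd
parts <- split_data(frame, 0.2, seed = 42)       # 80/20 split

sw <- stepwise_fit(parts$train)                  # p-entry/removal at 0.05
rf <- rf_grid_fit(parts$train, seed = 42)        # grid search, 5-fold CV
print(sw)
#> Stepwise linear model of log_ba_ip
#> selected: log_cd, sand
#> (Intercept)      log_cd        sand
#> -2.86164621  0.96001168  0.01740898
model_metrics(sw, parts$train, parts$test)
#> R2 train 0.848 | test 0.895 | CV - | dR2 -0.047
model_metrics(rf, parts$train, parts$test)
#> R2 train 0.972 | test 0.837 | CV 0.811 | dR2 0.135
round(feature_importances(rf), 3)
#> log_cd     ph    som   clay   silt   sand
#>  0.891  0.039  0.010  0.013  0.026  0.023
```

The stepwise model recovers the generating structure (only total Cd and
sand survive the 0.05 entry/removal thresholds; the true slopes are 1 and
0.02), and total Cd dominates the forest's impurity importance. Feeding
the model's predicted bioaccessibility into a paired 10,000-iteration
Monte Carlo (child exposure profile; fixed geometric-mean soil Cd):

```r
c_spec <- fit_lognormal(soil$cd_total, "C")
c_spec$law <- "point"; c_spec$p1 <- exp(c_spec$p1)   # geometric mean
c_spec[c("p2", "lower", "upper")] <- NA
specs <- rbind(generate_exposure_distributions("child"), c_spec)
ba <- fit_lognormal(
  pmin(predict_bioaccessibility(rf, frame)$ba_percent / 100, 1),
  "BA", lower = 1e-4, upper = 1)
cmp <- compare_adjustment(specs, default_toxicity_values(), ba,
                          n_iter = 10000, seed = 42)
print(cmp$report, digits = 3)
#>   index mean_ratio p95_ratio p95_decrease_pct cv_unadjusted cv_adjusted
#> 1    HQ       3.94      4.19             76.1          57.5        53.2
#> 2    CR       9.13      8.23             87.8          61.2        72.4
```

Bioaccessibility adjustment lowers the mean hazard quotient ~3.9-fold and
the 95th-percentile carcinogenic risk by ~88% in this synthetic scenario
(CR responds more strongly than HQ because its inhalation/dermal terms
carry no slope factor here, so nearly all of CR flows through the
BA-adjusted ingestion pathway).

`run_pipeline(default_pipeline_config(out_dir = "run", seed = 1))`
executes the whole chain — simulate → preprocess → train → map → risk →
sensitivity — writing CSV/ASCII-grid artifacts, a config echo, a run log
and an MD5 manifest; identical seeds give byte-identical artifacts.

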