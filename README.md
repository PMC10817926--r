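# fluidresp

Predicting fluid responsiveness from the arterial blood pressure waveform.

## The problem

In circulatory shock, a fluid bolus helps only when the heart converts the
extra preload into output — a *fluid responsive* (FR) state, defined as a
post-bolus rise in stroke volume of ≥ 15%. Roughly half of boluses given
when judged clinically indicated are non-responsive, and the excess fluid is
harmful. The classical passive predictor is **pulse pressure variation**,

```
PPV% = 100 · (PPmax − PPmin) / ((PPmax + PPmin) / 2),
```

the relative swing of beat pulse pressure over the respiratory cycle, with
FR predicted at PPV ≥ 12%. PPV is informative but univariate and fragile.

`fluidresp` implements a full machine-learning alternative: from the 60 s of
arterial pressure immediately before a bolus it extracts a canonical
50-feature vector (median and SD of 25 per-beat physiologic features across
all beats of the window — pressures at the systolic peak, diastolic foot and
dicrotic notch, timings, slopes, areas, decay constant, shape moments) and
trains a random-forest classifier of FR (ridge logistic regression, RBF-SVM
and gradient boosting are available as comparators), evaluated strictly at
the subject (pig) level: stratified train/test splits and cross-validation
folds never let one animal's boluses appear on both sides.

Because the multi-animal shock data such pipelines are built on are not
public, the package includes a seeded synthetic hemodynamics generator —
multi-pig cohorts across three shock injury models, respiratory modulation
of the waveform, planted beat fiducials and planted stroke-volume responses
— so every stage is testable against ground truth. A latent preload reserve
drives both a PPV-like modulation channel and two secondary
waveform-variability channels (decay-constant and notch-timing
variability), each only partially informative, which is the regime in which
a multivariate classifier out-discriminates univariate PPV.

## Worked example

```r
library(fluidresp)

cohort <- simulate_cohort(n_pigs = 30, boluses_per_pig = 6, seed = 42)
#> <sim_cohort> 30 pigs, 192 boluses (seed 42)
#> EPACC   HEM   IRI
#>    15    11     4

features <- featurize_cohort(cohort)   # preprocess, detect beats, 50 features,
                                       # PPV, stroke-volume labels
head(features[, c("bolus_id", "pp_median", "pp_sd", "ppv_pct",
                  "delta_sv_pct", "label", "sv_zone")], 4)
#>     bolus_id pp_median     pp_sd   ppv_pct delta_sv_pct label sv_zone
#> 1 pig001_b01  26.86     0.638     8.13         13.59      NR    grey
#> 2 pig001_b02  24.92     0.438     6.28         15.16      FR    grey
#> 3 pig001_b03  26.74     0.607     8.19         15.13      FR    grey
#> 4 pig001_b04  25.24     1.222    15.78         14.77      NR    grey

pigs   <- pig_label_table(features)
splits <- make_splits(pigs, n_splits = 3, seed = 42)
splits[[1]]
#> <split_plan 1> 15 train / 15 test pigs; FR prev 0.52 / 0.50
```

Each feature row is one bolus: `pp_median`/`pp_sd` are the across-beat
median and SD of pulse pressure (mmHg), `ppv_pct` the PPV comparator,
`delta_sv_pct` the measured stroke-volume change used for the `label`
(FR iff ≥ 15%), and `sv_zone` flags the 10–20% grey zone where the binary
label is least certain. From a split you build pig-level folds
(`make_cv_folds`), select features (`select_statistical`, `select_rfe`,
`select_permutation`, `select_mutual_info`, `consensus_features`), tune and
fit (`tune_and_fit`), predict (`predict_proba`) and evaluate
(`evaluate_holdout`, `aggregate_splits`, `calibration_curve`,
`error_analysis`). `run_pipeline()` orchestrates the whole chain into an
artifact directory, and `inst/scripts/fluidresp-cli.R` exposes it on the
command line. Note that the classifier's advantage over PPV needs
study-scale training data; on toy cohorts of a dozen pigs the forest has
too few animals to learn the multivariate structure.

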