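# skinfoldrel

Tools for reliability studies of calliper anthropometry in overweight and
obese pregnant women. Skinfold thickness measurement (SFTM) is one of the
few body-composition methods usable in pregnancy, because — unlike BMI or
bioimpedance — it is not confounded by the fetal compartment. Its weak
point is the observer: pinching and landmarking are harder on adipose
tissue, so any study that pools measurements from multiple research
assistants needs to know how much of the measurement variance the
observers contribute. This package is for researchers designing or
analysing such measurement-protocol studies.

It implements, end to end:

* **The duplicate-reading protocol.** Two calliper readings per site; if
  they differ by more than 7.5% a third is taken. The reported value is
  the mean of two or the median of three, recorded to 0.1 mm (skinfolds,
  Harpenden calliper range 0–80 mm) or 0.1 cm (arm circumference).
  Sessions that violate the protocol are flagged, never silently dropped.
* **Body composition.** BMI with WHO categorisation (overweight
  25.0–29.9, obese ≥ 30.0 kg/m²) and a population-specific linear
  equation for body fat percentage:

  BF% = 12.7 + 0.457·triceps + 0.352·subscapular + 0.103·biceps
  − 0.057·height + 0.265·arm circumference

  (skinfolds in mm, height and arm circumference in cm; coefficients
  taken as given from their external derivation/validation samples).
* **Inter-observer reliability.** A random-observer variance-components
  model. When the observer pair differs between women the one-way
  random-effects estimator is canonical:

  ICC(1,1) = (MS_B − MS_W) / (MS_B + (k−1)·MS_W),  SEM = √MS_W,

  with MS_B/MS_W the between/within-subject mean squares and k = 2
  observers per woman. ICC(2,1) is available for fully crossed panels.
  Bands follow the Portney–Watkins convention: ICC ≤ 0.75 poor to
  moderate, > 0.75 good.
* **A synthetic-cohort generator** with known variance components
  (y_ij = μ + subject_i + observer_j + error_ij, plus replicate-reading
  noise), so the whole chain — raw readings → protocol aggregation →
  BF% → ICC/SEM — is validated by parameter recovery.

## Worked example

The analysis is organised as numbered scripts under `analysis/`
(simulate → aggregate → body composition → reliability → parameter
recovery), each a thin driver over the package functions. Running steps
1–4:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_aggregate.R
Rscript analysis/03_body_composition.R
Rscript analysis/04_reliability.R
```

prints, for the default simulated study (49 women, 2 of 4 observers
each, seed 42):

```
 Measure                Average (Range)     SEM  ICC  Band
 arm_circumference (cm) 34.87 (28.70-42.30) 0.53 0.97 good
 biceps (mm)            12.95 (4.50-23.50)  2.19 0.55 poor_to_moderate
 triceps (mm)           23.72 (15.90-31.60) 2.64 0.54 poor_to_moderate
 subscapular (mm)       25.58 (8.10-41.50)  3.23 0.75 poor_to_moderate
 bf_percent (%)         33.72 (23.91-39.91) 1.87 0.66 poor_to_moderate
```

Each row is one measure pooled over all observers and women: the
average and range of the reported values, the standard error of
measurement (the expected scatter of repeated measurements on the same
woman, in the measure's units), the intraclass correlation (the share of
variance due to true between-woman differences) and its reliability
band. The generative truth for this cohort was ICC 0.97 / 0.56 / 0.50 /
0.71 for arm circumference, biceps, triceps and subscapular — single-
cohort estimates at n = 49 scatter around those values, and step 5
(`analysis/05_parameter_recovery.R`) quantifies that scatter over 200
replicate cohorts per true ICC (bias ≤ 0.013, SEM within 2% of the
generative error SD).

The same pipeline runs on real data from two CSVs (long-format raw
readings plus a subject table) via `run_pipeline("readings.csv",
"subjects.csv", out_dir = "tables")`; see `?read_measurements` for the
schema.

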