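# affectfar

Facial-action-recognition features for multi-rater affect annotation in the
psychiatric mental status examination.

When several psychiatrists annotate the *affect* of the same patients —
its **quality** (dysphoric / euthymic / manic), **range** (full / restricted
/ blunt / flat) and **subtype** (12 finer labels) — their labels disagree
substantially. `affectfar` implements a video-analysis pipeline for studying
this problem: it extracts simple facial-dynamics features from face videos,
quantifies inter-rater agreement, tests which features and facial regions
are associated with each rater's labels, and predicts each rater's
annotations with a classifier under leave-one-out evaluation. It is aimed at
researchers in computational psychiatry and affective computing who want a
reproducible, fully testable reference implementation of this analysis.

## The method

For each video, frames are aligned by a least-squares similarity transform
mapping facial landmarks onto a canonical template, cropped to a normalized
face, and divided into a grid of equally sized cells; the mean gray level of
cell *r* at frame *n* is recorded as *X_r*[*n*]. Three mid-level per-video
features summarize this matrix:

* **expression** — per-frame scores of 7 expression classes (norm, anger,
  disgust, fear, happiness, sadness, surprise) from linear one-vs-all
  scorers, averaged over frames (length 7);
* **label** — the number of transitions of the per-frame dominating
  expression (length 1);
* **motion** — the population standard deviation over frames of the mean
  gray level of a cell set (whole face or one of six facial parts;
  length 1);

plus the concatenations **motion+label** and **motion+expression**.

Inter-rater agreement is the percentage of identically annotated patients
per rater pair, summarized by the mean ± sample SD of the unique
off-diagonal pairs. Feature–label association is tested per rater, domain,
and feature (and per facial region for motion) by multinomial logistic
regression against an intercepts-only baseline via the likelihood-ratio
test, LR = 2(ℓℓ_full − ℓℓ_null) ~ χ²((K−1)·p). Prediction uses one-vs-all
linear SVMs (LIBSVM via e1071) with the highest-response rule under
leave-one-out, reported as accuracy and as the **improvement coefficient**
(accuracy ÷ frequency of the rater's most common label).

Because clinical interview videos are private, the package ships a synthetic
cohort generator (parametric face renderer + latent affect states +
confusion-matrix rater model) whose planted effects make every stage of the
pipeline testable end to end. See the methods vignette
(`vignettes/affectfar-methods.Rmd`) for the model, the defaults, and their
rationale.

## Worked example

```r
library(affectfar)

cfg <- cohort_config(seed = 2)        # 25 patients, 5 raters, 300-frame videos
report <- run_study(cfg)
print(report)
#> Affect annotation study report
#>   quality agreement: 84% +/- 7 (mean +/- SD over 10 rater pairs)
#>   range agreement: 83% +/- 11 (mean +/- SD over 10 rater pairs)
#>   subtype agreement: 84% +/- 7 (mean +/- SD over 10 rater pairs)
#>   LOO prediction: mean accuracy 0.50, mean improvement 0.98 over 75 rater/domain/kind cells
#>   face-part regressions with p < 0.05: all_parts=6, cheeks=9, eyes=5, ...

subset(report$prediction$loo, feature_kind == "motion" & domain == "range",
       c(rater_id, accuracy, baseline, improvement))
#>  rater_id accuracy baseline improvement
#>   rater_1     0.76     0.36    2.111111
#>   rater_2     0.68     0.40    1.700000
#>   rater_3     0.64     0.36    1.777778
#>   rater_4     0.60     0.36    1.666667
#>   rater_5     0.72     0.36    2.000000
```

Reading the output: the five simulated raters (reliability 0.9) agree on
80–90% of patients; the motion feature predicts each rater's range labels at
0.60–0.76 accuracy against most-common-label baselines of 0.36–0.40, i.e.
improvement coefficients of 1.7–2.1. The full report also contains the
agreement matrices, per-rater label distributions, the feature-kind and
face-part regression grids, and provenance (seed, config hash, versions);
`run_study(..., out_dir = "out")` writes it as `report.json` plus CSV
tables. Single runs of a 25-patient cohort are noisy — averaged over ten
cohorts the mean motion/range improvement is about 1.5 (per-seed range
roughly 1.0–1.9), which is what `scripts/acceptance.R` reports.

A thin command-line front end with verbs `simulate` / `extract` / `stats` /
`predict` / `run` / `validate` is installed at
`system.file("cli", "affectfar.R", package = "affectfar")`.

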