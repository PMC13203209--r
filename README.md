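# kdeknn

Privacy-aware synthetic tabular data for imbalanced clinical classification
problems, with a built-in fidelity / privacy / utility audit suite.

## The problem

Clinical datasets — the motivating case is sepsis detection from a static
snapshot of ~27 continuous ICU features — are small, heavily imbalanced
(many more controls than cases) and unsharable, since each row is a
patient. Training on synthetic stand-ins only helps if two things hold at
once: a model trained on the synthetic records performs on *real* data
about as well as one trained on real records (**utility**), and no
synthetic record sits close enough to a real record to re-identify a
patient (**privacy**).

## The method

`kdeknn()` fits, on a median-imputed and z-scored training set
$D_\mathrm{train} = \{x_i\}_{i=1}^N \subset \mathbb{R}^d$:

* one multivariate Gaussian kernel density estimate per class,

  $$\hat p(x) = \frac{1}{L h^d}\sum_{i=1}^{L} K\!\Big(\frac{x-x_i}{h}\Big),
  \qquad K(u) = (2\pi)^{-d/2}e^{-\lVert u\rVert^2/2},$$

  with bandwidth $h = L^{-1/(d+4)}$ (Scott's rule) per class;
* a k-nearest-neighbour classifier $M$ on the full training set
  (default $k = 5$);
* the privacy reference
  $\sigma = \frac{1}{N}\sum_j \min_{i\neq j}\lVert x_j - x_i\rVert$,
  the mean distance-to-closest-record (DCR) within the real data.

`simulate()` then draws candidates from each class's KDE and keeps only
those that (1) $M$ classifies as the intended class and (2) keep a distance
of at least `sigma_multiplier` × σ from *every* real record, iterating
until both per-class targets (default a balanced 540 + 540) are met. The
result is a balanced, validated, privacy-floored synthetic cohort plus a
full acceptance/rejection accounting.

The audit suite implements the matching evaluation battery: DCR summaries
and histograms, density/coverage at $k=5$, per-feature two-sample
Kolmogorov–Smirnov tests, a Mann–Whitney + Bonferroni dataset-shift report,
and a train-on-synthetic / test-on-real (TSTR) AUC harness with a
rank-statistic AUC and a pluggable classifier contract.

## Worked example

Hospital sepsis cohorts are not publicly available, so the package ships a
fixture generator that emulates their shape (979 controls / 296 cases, 27
correlated features, 5% missing cells, weak class signal):

```r
library(kdeknn)

ds    <- make_clinical_fixture(seed = 42)          # 1275 x 27 stand-in cohort
split <- split_train_test(ds, test_fraction = 0.15, seed = 1)
prep  <- fit_preprocessor(split$train)             # median impute + z-score
train <- apply_preprocessor(prep, split$train)

fit <- kdeknn(train, k = 5, sigma_multiplier = 1)
fit
#> KDE-KNN synthesizer
#>   training records: 1085 (252 positive / 833 negative)
#>   kernel: isotropic; h = 0.8366 (pos), 0.8050 (neg)
#>   validator: KNN, k = 5
#>   sigma reference = 4.0860; privacy threshold = 4.0860

syn <- simulate(fit, nsim = c(540, 540), seed = 7)
attr(syn, "report")
#> generation_report: 6 iteration(s), seed 7
#>   sigma = 4.0860, multiplier = 1, threshold = 4.0860
#>   bandwidth: 0.8366 (pos), 0.8050 (neg)
#>     class target drawn rejected_utility rejected_privacy accepted
#>  positive    540  3240             2262              362      616
#>  negative    540  1080               43              497      540

audit_synthetic(train, syn)
#> metric_report
#>   real-real mean DCR (sigma): 4.0860
#>   synthetic mean DCR:         4.5593 (min 4.0862)
#>   density = 0.1181, coverage = 0.3493
#>   mean KS p-value over 27 features: 0.0000
```

Reading the report: the minority (sepsis) class pays most of the utility
rejections — the validator is trained on the imbalanced cohort, so minority
candidates are harder to accept, which is expected and reported rather than
corrected. Every kept record lies at least σ = 4.086 from every real
record (min synthetic DCR 4.0862), and the synthetic DCR distribution sits
*right* of the real-real baseline (mean 4.56 > 4.09): new records, not
copies. The near-zero KS p-values show the marginal-variance inflation an
isotropic Scott kernel causes at d = 27 — see the methods vignette for the
bandwidth/privacy trade-off this exposes.

Utility, with the bundled nearest-centroid reference classifier at matched
training sizes:

```r
test <- apply_preprocessor(prep, split$test)
# match the real training size to the 1080 synthetic rows
train_1080 <- tabular_dataset(train$values[1:1080, ], train$labels[1:1080],
                              feature_names = train$feature_names)
res  <- evaluate_tstr(train_1080, syn, test,
                      mixing_fractions = c(0, 1), replicates = 3, seed = 11)
summarize_tstr(res)
#>         classifier fraction  mean_auc var_auc
#> 1 nearest_centroid        0 0.7733499       0
#> 2 nearest_centroid        1 0.7686800       0
```

Training purely on the validated synthetic cohort costs less than 0.005
AUC against training on real data of the same size.

Synthetic records export back to the original clinical units with
`export_synthetic(syn, prep, "synthetic.csv")`. A command-line front end
(`inst/cli/kdeknn.R`) wraps the same functions as `fixture` / `generate` /
`audit` / `utility` subcommands.

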