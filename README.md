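# ifliver

Expression-pattern analysis of intermittent-fasting liver microarrays.

## The problem

Intermittent fasting (IF) drives the liver back and forth across the
metabolic switch between glucose-based and ketone/gluconeogenesis-based
metabolism. A four-group microarray design captures this: ad libitum controls
(**AL**), chronically restricted birds (**CR**), and IF birds sampled on the
second consecutive fed day (**F2**) or on the fasting day (**SK**). Two kinds
of genes matter downstream: *switching* genes whose F2 and SK expression
differ (tracking the fed/fasted cycle) and *chronically changed* genes whose
F2 and SK expression both differ from AL in the same direction (candidate
mediators of long-term IF effects).

ifliver packages that whole analysis as tested, reusable R functions, for
anyone running or re-analysing multi-group single-color microarray (or
microarray-like) experiments:

* probe-to-probe-set summarization, array QC (intensity stats, inter-array
  correlation, PCA outlier rule) and exclusion;
* per-gene four-group linear models with empirical-Bayes moderated
  t-statistics for all six pairwise contrasts — the moderated t is
  `t = delta / sqrt(s~^2 (1/nX + 1/nY))` with posterior variance
  `s~^2 = (d0*s0^2 + d*s^2) / (d0 + d)` on `d + d0` degrees of freedom, the
  prior `(d0, s0^2)` fitted by method of moments on `log s^2`;
* Benjamini–Hochberg adjustment and the joint inclusion filter
  (adjusted `p < 0.01` **and** fold change ≥ 1.4, per contrast);
* two-way hierarchical clustering of the filtered genes with a fixed `k = 4`
  cut and per-individual cluster mean profiles;
* the switching / chronic / robust-chronic pattern taxonomy over the six
  contrasts;
* local hypergeometric pathway over-representation against a GMT, with a
  shared/unique overlap partition;
* Pearson correlation of cluster (or gene) expression with ten physiological
  and appetite-gene traits, Bonferroni-controlled at `0.05 / 10 = 0.005`;
* a synthetic-data generator that plants every pattern class with known
  effect sizes, so each stage can be validated against ground truth.

See `vignettes/ifliver-methods.Rmd` for the full model description and the
reasoning behind every tunable default.

## Worked example

A complete synthetic run at the study design (6/6/4/6 arrays, 2,000 probe
sets, 0.8 log2 planted effects):

```r
library(ifliver)
cfg   <- sim_config(seed = 42L)
sim   <- simulate_dataset(cfg)
expr  <- summarize_probesets(sim$probe_matrix, sim$probe_map)
fit   <- fit_linear_model(expr, sim$sample_sheet)
prior <- estimate_variance_prior(fit)
tab   <- pairwise_contrasts(fit, prior)
deg   <- filter_de(tab, analysis_params())
```

The moderated-variance prior recovered from the data is close to the
generating one (`d0 = 4`, `s0^2 = 0.05`):

```
prior: d0 = 3.86, s0^2 = 0.0501
filtered genes: 640 of 2000
```

Up/down counts per contrast (higher in the first-named group counts as up);
note the F2–SK contrast dominated by switching genes and the quiet SK–CR
contrast, as expected when CR birds sit metabolically with the fasting day:

```
   pair  up down
1 F2-AL 180  181
2 SK-AL 374  197
3 CR-AL 339  166
4 F2-SK 182  362
5 F2-CR 210  388
6 SK-CR  27   28
```

Clustering the filtered genes and classifying patterns:

```r
std  <- standardize_rows(expr[deg, ])
cut4 <- cut_k(cluster_genes(std), 4)
calls <- classify_gene_patterns(tab, analysis_params())
summarize_patterns(calls)$counts
```

```
cut4
  1   2   3   4
 35 183 385  37

n_genes switching_broad switching_strict chronic chronic_and_switching
   2000             516              284      51                     6
chronic_pure robust_chronic chronic_up chronic_down strict_also_chronic
          45             41         27           24                   0
```

Scoring everything against the planted truth — the k = 4 cut recovers the
four planted expression archetypes exactly, and the sample dendrogram splits
fed (AL, F2) from underfed (CR, SK) states:

```r
rec <- evaluate_recovery(cfg)
```

```
ARI vs planted archetypes: 1.000; fed/underfed split: TRUE
```

The full pipeline (simulate/ingest → QC → summarize → DE filter →
cluster + enrich + correlate | patterns) runs from one config and writes
deterministic TSV/JSON artifacts:

```r
report <- run_pipeline(pipeline_config(out_dir = "run1", sim = cfg))
```

A thin command-line wrapper lives at `inst/cli/ifliver.R`
(`Rscript ifliver.R run --config pipeline.yaml`).

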