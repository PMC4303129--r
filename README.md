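# cpgclust

Consensus clustering and differential analysis of CpG promoter methylation
arrays.

## What this package is for

Promoter CpG methylation can silence cancer-related genes, and breast
tumors carry methylation profiles that track hormone-receptor (HR) status
and intrinsic subtype — including a CIMP-like subclass of mostly
HR-positive tumors with coordinated hypermethylation of developmental
genes and poorer clinical features. `cpgclust` is for analysts working
with two-channel methylation bead-array data (or precomputed β matrices)
who want a tested, reproducible implementation of the classic
subclassification chain:

1. **β computation and QC** — β = max(Cy5, 0) / (|Cy5| + |Cy3| + 100);
   samples with > 25% unreliable detection calls (p > 1e-5) removed; probe
   filters in fixed order (SNP/repeat overlap → detection failure →
   SD < 0.06); replicate averaging with per-pair Pearson concordance.
2. **Consensus clustering** — probes with SD ≥ 0.2 across tumors; for each
   k in 2..10, 100 iterations of k-means (squared Euclidean) on 80%
   subsamples; consensus M_ij = co-clustered / co-sampled; final labels by
   average-linkage agglomeration of 1 − M; chosen k = the largest k with
   every cluster's mean within-cluster consensus ≥ 0.9.
3. **Differential methylation** — Wilcoxon/Kruskal-Wallis rank tests on
   raw β, and covariate-adjusted OLS on logit β (age, race, menopausal
   status, stage, with the documented special cases), Benjamini-Hochberg
   FDR within each comparison, hyper/hypo direction counts, Venn overlaps,
   signature-agreement Fisher tests, and methylation-expression Pearson
   correlation by stratum.
4. **Survival** — Kaplan-Meier, log-rank, and univariate/multivariate Cox
   models of methylation cluster with clinical covariates (via the
   `survival` package), plus a scaled-Schoenfeld proportionality check.
5. **Enrichment** — one-sided hypergeometric over-representation of
   deduplicated gene lists against the filtered-array gene background,
   from standard GMT files.

A first-class **synthetic-data generator** (`sim_config()` /
`generate_dataset()`) emulates the cohort structure these methods assume —
four latent clusters (one globally hypermethylated), cluster-linked
clinical covariates, technical replicates, probes and samples designed to
fail each QC rule in controlled numbers, cluster-dependent survival, and
methylation-anticorrelated expression — so the whole pipeline is testable
offline.

## Worked example

```r
library(cpgclust)

cfg <- sim_config(seed = 1)          # 500 tumors x 1000 probes, 4 clusters
ds  <- generate_dataset(cfg)

qc <- preprocess_qc(ds$intensities, ds$manifest)
#> probes: 1000 -> 850 | tumors: 496

variant <- select_variant_probes(qc$beta)   # 167 probes with SD >= 0.2
cc <- consensus_cluster(qc$beta[variant, ], seed = 1)
print(cc)
#> Consensus clustering over k = 2..10 (100 iterations, 80% subsampling)
#> Chosen k: 4
#> Cluster sizes: 178 132 93 93
#> Cluster consensus: 1 0.994 0.988 0.996

res <- diff_methylation(qc$beta, ds$annotation, "hr_status",
                        covariates = covariate_spec("hr_status"),
                        ref = "positive")
sum(res$q < 0.05)          #> 701 significant CpGs
direction_summary(res)     #> n_hyper 275, n_hypo 426

ann <- ds$annotation[ds$annotation$tumor_id %in% names(cc$assignment), ]
log_rank(ann$time, ann$event, cc$assignment[ann$tumor_id])
#> chi-square = 46.81 (df 3), p = 3.8e-10

cluster_survival(ds$annotation, cc$assignment)$univariate
#> Cox proportional hazards (efron ties), n = 496, events = 357
#>      term  coef   hr ci_lower ci_upper        p
#>  cluster2 0.202 1.22    0.925     1.62 1.58e-01
#>  cluster3 0.922 2.52    1.860     3.40 1.69e-09
#>  cluster4 0.678 1.97    1.470     2.65 6.75e-06
```

Reading the output: QC removed the 150 probes designed to fail (80
SNP-flagged, 10 detection, 60 low-SD) and the 4 unreliable samples,
leaving 850 probes in 496 tumors. Consensus clustering on the 167 variant
probes recovers the four planted clusters (labels are ordered by size, so
cluster 1 is the largest, luminal-like group). The supervised HR-status
comparison flags CpGs in both directions, and the Cox table shows the
smaller hypermethylated and basal-like clusters with elevated hazards
relative to the largest cluster — the generator's planted survival
structure. One full pipeline call does all of the above and writes
TSV/JSON artifacts plus a run manifest:

```r
run_all(pipeline_config(sim = sim_config(seed = 1), seed = 1), "results/run1")
```

A command-line wrapper with the same behavior lives at
`inst/scripts/run_pipeline.R`.

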