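---
title: "Methylation-based tumor subclassification with cpgclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based tumor subclassification with cpgclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgclust)
```

## The problem

Promoter CpG-island methylation can silence tumor-suppressor genes, and
breast tumors differ systematically in their methylation profiles by
hormone-receptor (HR) status and intrinsic subtype (luminal A/B, basal-like,
HER2+/HR-). A recurring observation on cancer-gene promoter panels is a
subclass of predominantly HR-positive tumors with coordinated
hypermethylation of developmental and homeobox genes — a CpG island
methylator phenotype (CIMP)-like group — with poorer clinicopathologic
features. cpgclust implements the full analysis chain needed to find and
characterize such subclasses on two-channel methylation bead arrays:

1. **QC and filtering** of probe intensities into a clean beta matrix,
2. **subsampled consensus clustering** of the most variant CpGs,
3. **covariate-adjusted differential methylation** with FDR control,
4. **survival comparison** of the resulting clusters,
5. **gene-set over-representation** of cluster-defining genes,

together with a **synthetic-data generator** that emulates the statistical
structure of a population-based breast-tumor cohort, so every stage is
testable end to end without any data download.

## Beta values and quality control

Each array cell reports a methylated-allele signal (Cy5) and an
unmethylated-allele signal (Cy3), both background-subtracted and possibly
negative. The methylation fraction is

$$\beta = \frac{\max(\mathrm{Cy5}, 0)}{|\mathrm{Cy5}| + |\mathrm{Cy3}| + 100},$$

which lies in $[0, 1)$: the +100 offset stabilises low-intensity cells and
makes $\beta = 1$ unattainable (the synthetic intensity generator therefore
refuses targets of exactly 1). Filtering proceeds in a fixed order, with
each stage's removals logged so that the counts always reconcile:

* **Samples** with strictly more than 25% of probes at detection
  $p > 10^{-5}$ are removed (a sample at exactly 25% is retained — both
  comparisons are strict).
* **Probes** flagged as overlapping a SNP or repeat are removed first, then
  probes failing detection, then probes with standard deviation below 0.06
  across the retained samples.
* Tumors flagged ineligible are dropped, and technical replicates are
  averaged per probe; replicate agreement is reported as Pearson r per
  replicate pair.

Numerical conventions the upstream description leaves open, decided here
once: SD is always the sample (n-1) standard deviation; a probe "fails
detection" when its *median* detection p across retained samples exceeds
the threshold (the per-probe aggregation is not standardised anywhere, and
the median is robust to a few failing samples); missing cells are excluded
pairwise from SDs and correlations; and the logit transform used for
modelling clamps beta into $[\epsilon, 1-\epsilon]$ with $\epsilon = 10^{-3}$
(configurable) so boundary values stay finite.

## Consensus clustering

Clustering uses only the most variant probes (SD $\ge$ 0.2 across tumors,
on the beta scale). For each candidate $k$ from 2 to 10, 80% of tumors are
subsampled without replacement, partitioned with k-means (squared Euclidean
distance), and the procedure is repeated 100 times. The consensus entry for
a tumor pair is

$$M_{ij} = \frac{\#\{\text{iterations where } i, j \text{ co-clustered}\}}
               {\#\{\text{iterations where } i, j \text{ co-sampled}\}},$$

so it estimates the probability that two tumors land in the same cluster
when both are observed. Pairs never co-sampled (vanishingly rare at 100
iterations of 80%) are imputed as 0 with a warning rather than failing the
run.

Design choices where the procedure is under-specified by convention:

* **Base clustering**: k-means++ seeding, Lloyd iterations (at most 300),
  one restart per consensus iteration, each iteration seeded from the
  master seed. If Lloyd's algorithm empties a cluster the iteration is
  re-seeded (up to five times).
* **Final labels**: the consensus matrix is hierarchically agglomerated
  (average linkage) on dissimilarity $1 - M$ and cut at $k$; this is the
  common practice for deriving labels from a consensus matrix. Labels are
  renumbered by decreasing cluster size for reproducible reporting.
* **Choice of k**: per-cluster consensus is the mean of $M_{ij}$ over
  within-cluster pairs (singletons count as 1). The chosen $k$ is the
  *largest* $k$ whose *minimum* per-cluster consensus is at least 0.9 —
  reading "at least 90% cluster consensus across all clusters" as a
  minimum-over-clusters rule. If no $k \ge 2$ qualifies the pipeline
  returns a single cluster with a warning.

## Differential methylation

Two testing routes mirror their different uses:

* **Rank tests** (Wilcoxon rank-sum for two groups, Kruskal-Wallis for
  more) operate on raw beta values. Because rank tests are invariant under
  monotone transforms, the scale choice is inconsequential; raw beta is
  used for interpretability. Exact enumeration p-values are used for
  combined $n \le 12$ without ties, otherwise the normal approximation with
  tie and continuity corrections.
* **Linear models** are ordinary least squares on logit-transformed beta,
  with the group factor plus adjustment covariates. The default adjustment
  set is age (continuous), race, menopausal status, and stage
  (categorical), with the documented special cases: stage analyses adjust
  for age/race/menopause only; tumor-size analyses swap stage for nodal
  status, and nodal analyses adjust for size. No comparison adjusts for its
  own outcome. Complete cases only; dropped counts are recorded.

P-values are Benjamini-Hochberg adjusted *within* each comparison (the
multiple-testing family is the probes tested for that comparison, not the
union across comparisons), with discoveries at $q < 0.05$ partitioned into
hyper- and hypomethylated by the sign of the estimate. Volcano tables use
raw p-values. Signature agreement between probe sets is a one-sided
Fisher/hypergeometric enrichment test against the full probe background,
and methylation-expression coupling is Pearson correlation of beta against
log2 expression, overall and within strata (at least three pairs per
stratum).

## Survival

Kaplan-Meier curves, the log-rank test, and Cox proportional-hazards models
are delegated to the survival package (survfit, survdiff, coxph, cox.zph),
wrapped to produce the tidy tables the pipeline reports. Conventions:
Efron tie handling by default (Breslow switchable); stage enters Cox models
as an ordinal 1-4 trend term (one hazard ratio per unit stage), grade as a
binary 1 vs 2+3 contrast; the reference group for cluster models is the
largest (luminal-enriched) cluster; 95% intervals are normal-theory on the
log-hazard scale. Proportionality is checked by the scaled-Schoenfeld slope
test against event-time rank; fits with monotone likelihoods or
non-convergence within 50 iterations are flagged, and the PH check is
skipped with a diagnostic when fewer than two events remain.

## Gene-set over-representation

Cluster-defining or differentially methylated probe lists are mapped to
gene symbols, de-duplicated (a gene with several CpGs counts once), and
tested per annotation term with the one-sided hypergeometric upper tail
against the background of all genes surviving probe filtering. Terms are
intersected with the background first; disjoint terms are skipped and
reported. BH q-values are computed across terms, significant at $q < 0.05$.
An EASE-style variant (overlap deflated by one, more conservative) is
available behind a flag but is not the default, and no term clustering or
ontology-topology weighting is attempted. Gene sets are read from standard
GMT files.

## The synthetic cohort

The generator produces the structure the analysis assumes, with defaults
fixed to the study conditions the pipeline is designed for: 500 tumors on a
1000-probe panel, four latent clusters in proportions 123/108/99/187 of
517, 167 variant probes, and cluster 3 globally hypermethylated.

* **Beta noise**: two-level beta distributions parameterised by (mean,
  concentration). A tumor's true beta at a probe is drawn around its
  cluster-and-block mean with concentration 50 (between-tumor biological
  spread); each replicate measurement is drawn around the tumor value with
  concentration 200 (technical noise). The beta family is the natural
  bounded-support choice, and concentration 200 calibrates replicate
  Pearson r to about 0.95-0.99, comfortably above the 0.9 concordance the
  QC stage expects.
* **Probe blocks**: four variant blocks whose means separate the clusters
  (all elevated in the hypermethylated cluster) and two stable blocks whose
  mild cluster dependence keeps their SD between the 0.06 QC floor and the
  0.2 variant cut. Probes designated to fail QC are carved out separately:
  SNP-flagged probes (manifest flag), detection failures (all samples at
  detection $p = 10^{-3}$), and low-SD probes (near-constant, concentration
  5000), in exactly the configured numbers.
* **Covariates** are drawn per cluster from tabulated category
  probabilities reproducing a published cohort's composition (for example,
  80% HR-negative and 61% basal-like in the basal-enriched cluster, 25%
  p53-mutant in the hypermethylated cluster); continuous age is drawn
  uniformly within the sampled age band.
* **Survival**: exponential event times with cluster-specific rates
  (default log hazard ratios log(1.11), log(1.91), log(1.71), 0 against the
  largest cluster, the univariate effect sizes the pipeline should be able
  to recover) and independent exponential censoring calibrated to a 30%
  censoring fraction. The baseline hazard (0.003/month) gives a plausible
  mix of events over a follow-up measured in months.
* **Expression**: for 50 designated variant-block genes, expression is a
  standardized mixture $r z_\beta + \sqrt{1-r^2}\,\varepsilon$ with target
  correlation $r = -0.6$ (methylation silencing); an equal number of null
  genes is independent noise.

What the generator does *not* emulate: probe-level genomic sequence,
bisulfite-conversion chemistry, scanner artifacts, batch effects, spatially
correlated probe noise, or non-exponential hazards. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly under the
assumed generative structure — not that real cohorts satisfy that
structure.

## Problem sizes and determinism

Every stochastic step flows from one master seed: the generator seeds its
own stream, and each consensus run derives per-k seeds from the pipeline
seed, so identical configurations give byte-identical outputs. The test
suite exercises the full default cohort (500 tumors, 1000 probes, k = 2-10,
100 iterations — about 15 seconds), 200-replicate hazard-ratio recovery, a
1000-probe global-null FDR check, and brute-force oracle comparisons with
at least 100 random instances per statistic; the QC arithmetic is checked
at the published array scale (625 samples, 1505 probes).

## Known limitations

* Final-label derivation from the consensus matrix is a convention; other
  reasonable choices (partitioning around medoids on $1-M$, majority
  voting) can relabel borderline tumors.
* The per-probe detection rule (median across samples) is a declared
  choice, not a community standard; provenance logs make the consequence
  auditable.
* OLS on logit beta ignores heteroscedasticity near the boundaries; with
  hundreds of tumors per comparison the t-tests are robust in practice,
  and no empirical-Bayes variance moderation is attempted.
* Competing risks, time-dependent covariates, and treatment adjustment are
  out of scope; endpoints are modelled as independent censoring.
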