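# basalsub

Survival-driven subgroup discovery and cross-platform classification for
basal-like breast cancer.

Basal-like breast tumours (largely ER/PR/HER2-negative) share an intrinsic
expression subtype but differ widely in outcome. `basalsub` implements a
complete, tested pipeline for splitting a basal-like cohort into two
prognostic subgroups — Basal I (better prognosis) and Basal II — from log2
expression data, and for characterising the split at the microRNA and
copy-number levels. It is aimed at computational biologists analysing
microarray or array-CGH style cohorts with matched survival data.

## What it computes

1. **Probe screens.** A *differential* screen tests each probe between
   tumours and controls under three alternatives — tumours lower, higher,
   or both (values folded to |x − control mean| so bimodal probes become
   one-sided) — scoring each probe by the minimal Wilcoxon rank-sum p-value
   (exact by enumeration for group sizes ≤ 10). A *survival* screen
   compares the lowest and highest expression tertiles of each probe with
   the log-rank test. Both screens are sized by the elbow (maximal chord
   distance) of the ordered −log₁₀ p curve.
2. **Subgroup discovery.** Tumours are clustered on the survival probe set
   with the square-root Jensen–Shannon divergence (a bounded metric;
   vectors shift-normalised to distributions) under Ward linkage, cut at
   k = 2; the longer-surviving cluster is Basal I.
3. **Signature.** Probes ranked by two-sided rank-sum p between subgroups,
   sized by the same elbow rule, then grouped into three co-expression
   blocks (G1 over in Basal II, G2 over in Basal I, G3 under in Basal II)
   by Spearman-distance Ward clustering.
4. **Classification.** Nearest-centroid assignment with per-probe mean
   standardization `s_std = s / mean(s over N basal samples)`, which cancels
   probe-wise platform scale and enables Illumina→Affymetrix transfer via a
   user-supplied annotation table.
5. **Network.** Minimum spanning tree over signature probes with distance
   1 − |ρ_S|, deterministic Kruskal tie-breaking, normalized betweenness
   centrality and degree; key probes flagged at B ≥ 0.1 and degree ≥ 4.
6. **miRNA.** Two-sided rank-sum per probe, selected only when p < 0.01 in
   *both* a training and a validation cohort; per-subgroup Spearman
   correlation against user-supplied target genes.
7. **Copy number.** Cytoband gain/loss rates, exact binomial enrichment
   tests against the pooled per-band rate (two-sided by tail doubling), and
   length-weighted Percent Genome Altered with a between-subgroup rank test.
8. **Synthetic cohorts.** `generate_cohort()` plants all of the above
   structure with full ground truth, so every stage is testable offline.

## Worked example

```r
library(basalsub)

co <- generate_cohort(seed = 1)   # 115 tumours, 144 controls, 400 probes
diff <- differential_filter(co$expr)
surv <- survival_filter(expr_subset(co$expr, probes = passed_probes(diff)),
                        co$clinical)
d <- jsd_distance_matrix(co$expr, probes = passed_probes(surv))
subgroups <- ward_cluster(d, co$clinical)
subgroups
#> <subgroup_labeling> Basal I = 36, Basal II = 79

sig <- refine_signature(expr_subset(co$expr,
                                    samples = tumour_ids(co$expr)),
                        subgroups)
sig <- group_probes(co$expr, sig, subgroups)
head(sig[sig$in_signature, ], 4)
#> # A tibble: 4 × 6
#>   probe_id  p_value  rank in_signature degenerate block
#> 1 P0137    5.88e-11     1 TRUE         FALSE      G1
#> 2 P0188    2.00e- 9     2 TRUE         FALSE      G3
#> 3 P0121    4.42e- 8     3 TRUE         FALSE      G1
#> 4 P0177    1.25e- 7     4 TRUE         FALSE      G2

cl <- dplyr::inner_join(co$clinical, tidy(subgroups), by = "sample_id")
glance(logrank_test(cl))
#> # A tibble: 1 × 4
#>   statistic   p_value    df     n
#> 1      19.3 0.0000112     1   115

pg <- pga(co$cna, co$cytobands, subgroups)
attr(pg, "subgroup_test")
#> # A tibble: 2 × 2
#>   type   p_value
#> 1 gain  7.16e-12
#> 2 loss  9.07e- 7
```

The recovered labels agree with the planted truth for 95% of tumours; the
94-probe signature contains 79 of the 80 planted probes (blocks
G1/G2/G3 = 32/39/23); the log-rank test detects the planted hazard ratio of
3 at p ≈ 1e-5, and Basal II shows the planted excess of genomic gains. The
replicated miRNA screen selects exactly the 17 planted miRNAs:

```r
de <- mirna_de(co$mirna_train, co$mirna_valid,
               c(co$truth$subgroup, co$truth$subgroup_valid))
sum(de$selected)
#> [1] 17
```

`run_pipeline(list(cohort = co, seed = 1, out_dir = "results"))` runs every
stage and writes the filter tables, subgroup labels, signature, centroids,
assignments, network report, miRNA report, CNA reports and a survival
report, plus a `pipeline.log` recording every elbow decision (rank, p-value,
chord distance). Configs can also be YAML files pointing at tab-separated
input files; see `?run_pipeline`.

## Package layout

Results are tibbles designed for dplyr piping; fitted objects
(`km_fit`, `logrank_test`, `subgroup_labeling`, elbow decisions) have
`tidy()`/`glance()` methods, and `autoplot()`/`plot_*()` functions cover the
p-value elbow, Kaplan-Meier curves, PGA boxplots and the spanning tree. The
methods vignette (`vignettes/basalsub-methods.Rmd`) documents the models,
conventions, and the design decisions behind every tunable default.
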