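# uhrnb

Stratification of high-risk neuroblastoma (HR-NB) into an ultra-high-risk
(UHR) and a residual high-risk subtype from immune-gene expression, with
survival validation.

HR-NB patients have overall survival below 50% yet are treated uniformly.
This package implements, as a reusable and testable pipeline, an approach
that (i) filters a pan-cancer expression matrix down to genes specifically
upregulated in neuroblastoma versus every other pediatric tumor type
(fold > 2, raw t-test p < 1e-5 per comparison), (ii) biclusters HR-NB
samples and those genes simultaneously with bipartite spectral
co-clustering, (iii) merges the k sample clusters into a UHR/HR dichotomy
by worst Kaplan-Meier survival at 24 months and validates it with the
log-rank test and Cox proportional hazards, and (iv) derives subtype gene
panels (fold > 1.5, raw p < 1e-3 or 1e-4) whose cross-cohort
reproducibility is scored with the Jaccard index and a combinatorial
overlap null. A synthetic-cohort simulator with planted checkerboard and
exponential-survival structure backs every stage with recovery tests.

## The algorithm at the core

For an m x n samples-by-genes matrix X, treat samples and genes as the two
sides of a bipartite graph with biadjacency X. Normalize

    Xn = R^(-1/2) X C^(-1/2),

with R, C the diagonal matrices of row/column sums; the leading singular
pair of Xn is trivial (singular value 1). Keep the next
p = ceil(log2 k) singular vector pairs U, V, stack the joint embedding

    Z = [ R^(-1/2) U ; C^(-1/2) V ]  ((m+n) x p),

and run k-means on the rows of Z: the first m rows label samples, the rest
label genes. An independent small-scale solver of the equivalent
generalized eigenproblem L z = lambda D z (L = D - A, A the full bipartite
adjacency) is included as a cross-validation oracle
(`laplacian_cocluster_oracle`) and is required by the tests to agree with
the SVD path.

## Worked example

```r
library(uhrnb)

# a simulated 150-sample, 283-gene HR-NB cohort; the third planted cluster
# has hazard 0.12/month vs 0.05 for the rest
sim <- simulate_cohort(cohort_spec(hazards = c(0.05, 0.05, 0.12), seed = 7))

model <- spectral_cocluster(sim$expr, k = 3, seed = 7)
model
#> bicluster_model (svd path): k = 3, p = 2, 150 samples x 283 genes
#> sample cluster sizes: 50, 50, 50
#> gene cluster sizes:   94, 95, 94
adjusted_rand_index(model$sample_labels, sim$truth$sample_labels)
#> [1] 1

st <- define_uhr(model, sim$clinical$os_months, sim$clinical$os_event)
st
#> UHR cluster: 1 (50/150 samples)
#> KM at 24 months: UHR 0.055 vs HR 0.406; log-rank p = 2.5e-07
#> Cox HR (UHR vs HR): 2.814 (95% CI 1.871-4.232), p = 6.8e-07
#> log-rank among non-UHR clusters: p = 0.704
```

Reading this: the fitted cluster labeled 1 is the planted high-hazard
cluster (k-means labels are arbitrary; the ARI of 1 shows the partition is
exact). Its two-year survival is 5.5% versus 40.6% for the pooled rest,
the dichotomy is strongly significant by log-rank, and the two pooled
clusters are *not* separable from each other (p = 0.70) — the evidence
justifying the two-group merge. The Cox HR (2.81) exceeds the planted
marginal rate ratio of 2.4 only because of sampling noise at n = 150;
the acceptance suite shows calibrated recovery over 100 replicates.

Subtype panels and cross-cohort agreement:

```r
subtype <- factor(ifelse(model$sample_labels == st$uhr_cluster, "UHR", "HR"),
                  levels = c("HR", "UHR"))
de <- differential_genes(sim$expr, subtype)     # fold > 1.5, p < 1e-3
nrow(de$up); nrow(de$down)
#> [1] 94
#> [1] 188

cross_cohort_overlap(c("GAL", "TWIST1", "ADAM22", "KLHL13"),
                     c("GAL", "TWIST1", "CD4"))
#> overlap: 2 of 4 vs 3 genes; Jaccard = 0.400; P(random) = 0.0556
```

The full pipeline (gene selection, per-cohort co-clustering, UHR calls, DE
panels, overlaps, manifest) runs via `run_pipeline(pipeline_config(...))`
or the CLI launcher in `inst/cli/uhrnb` (subcommands `simulate`,
`select-genes`, `cocluster`, `stratify`, `de`, `overlap`, `associate`,
`run`).

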