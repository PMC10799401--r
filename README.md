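# mosd — multi-omics subtype discovery

`mosd` stratifies a patient cohort measured on several molecular layers
(gene expression, DNA methylation, miRNA, ...) into molecular subtypes.
It is aimed at analysts who have two or more samples-by-features matrices
over the same patients and want integrative cluster labels plus an
estimate of how many subtypes the data support.

## Method

For each omic *m* (an *n × d<sub>m</sub>* matrix), a self-tuning affinity
network is built:

- **Local-scaling affinity** — *A(i,j) = exp{ −d²(xᵢ,xⱼ) / (σᵢσⱼ) }*, with
  *σᵢ* the Euclidean distance from sample *i* to its *k*-th nearest
  neighbor (default *k* = 5). Bandwidths adapt per sample, so one *k*
  serves dense and sparse regions alike.
- **Feature-count weights** — each omic gets weight
  *wᵢ = pᵢ / Σ pₘ* with *pᵢ = exp(dᵢ / Σ dₘ)*: layers carrying more
  features contribute more. The fused network is *S = Σ wᵢ Aᵢ*.
- **Self-diffusion** — *S* is sharpened by iterating
  *S ← α S T + (1 − α) I* (default *α* = 0.8, *t* = 3 steps), where *T* is
  the kNN-masked row-stochastic transition matrix of the initial *S*.
  Reliable local similarities propagate outward; noise edges fade.
- **Spectral clustering** — normalized-Laplacian embedding
  (*L = I − D^{−1/2} S D^{−1/2}*) plus seeded k-means gives the labels.
- **Cluster-number estimate** — the separation cost
  *J(R) = Σᵢⱼ Z²ᵢⱼ / M²ᵢ* (*Z = XR*, *Mᵢ* the row's dominant entry) is
  minimized over Givens rotations of the embedding; *J\* = n* exactly when
  the network splits into *C* clean clusters. Two selection rules
  (cost minimizer, largest drop) are provided.

The package also ships synthetic-cohort generators (a grouped
negative-binomial count simulator and Gaussian blobs) and scoring utilities
(NMI, ARI, silhouette), so the entire pipeline is testable without any
external download. See the methods vignette
(`vignettes/mosd-methods.Rmd`) for assumptions, numerical conventions and
limitations.

## Worked example

Simulate a four-group cohort with three omics and recover the subtypes
with the number of clusters estimated automatically:

```r
library(mosd)

sim <- simulate_counts(n_samples = 150, n_groups = 4,
                       genes_per_omic = c(500, 1000, 2000),
                       de_fold = 1, seed = 7)
fit <- mosd(lapply(sim$omics, normalize_counts),
            n_clusters = "auto", c_min = 2, c_max = 7, seed = 7)
print(fit)
print(fit$cost_curve)
nmi(fit$labels, sim$truth); ari(fit$labels, sim$truth)
```

```
mosd fit: 150 samples in 4 clusters
  cluster sizes: 49, 32, 39, 30
  omic weights: omic1=0.271, omic2=0.313, omic3=0.416
  k = 5  t = 3  alpha = 0.8  seed = 7
  C chosen by separation cost (rule 'min')
separation-cost curve (n = 150)
  C    cost     drop
1 2 153.173  -3.1730
2 3 152.236   0.9368
3 4 153.071  -0.8351
4 5 180.722 -27.6500
5 6 185.729  -5.0070
6 7 205.168 -19.4400
chosen C = 4 (rule: min)
NMI vs truth: 1
ARI vs truth: 1
```

The weights increase with feature count (2000-gene omic: 0.416); the
separation cost sits near its floor *n* = 150 up to the true *C* = 4 and
jumps beyond it, so 4 is chosen; the recovered labels match the planted
groups exactly. (An advisory warning notes that the *drop* signal is small
here — that is expected when clusters separate cleanly; the full curve is
returned for inspection.)

The same pipeline is available from a shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mosd", package = "mosd"))')
Rscript $CLI simulate --type counts --n-samples 150 --n-groups 4 \
    --features 500,1000,2000 --de-fold 1 --seed 7 --outdir sim
Rscript $CLI run --input sim/omic1.tsv,sim/omic2.tsv,sim/omic3.tsv \
    --n-clusters auto --seed 7 --outdir out
Rscript $CLI score --labels out/labels.tsv --truth sim/truth.tsv
```

`run` writes `labels.tsv`, the fused network, the separation-cost curve
and a `provenance.json` recording weights, parameters and timings.

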