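# tracemap

Computational pipeline for quantitative neuroanatomical tracer studies of
brain connectivity, in R. The package covers the four analysis stages such
studies chain together, plus seeded synthetic-data generators with ground
truth for every input, so the whole pipeline is testable end to end
without an imaging archive.

**Who it is for.** Neuroanatomists and image-analysis developers who
quantify anterograde/retrograde tracing experiments: extracting injection
sites from section images, computing data-driven boundaries between
anatomical subdomains, grouping injections with their targets into
connectivity communities, and statistically comparing reconstructed
neuron morphologies across those subdomains.

## What it computes

- **Injection-site extraction** (`wavelet_decompose`, `modify_bands`,
  `adaptive_enhance`, `extract_injection_site`, `annotate_injection`).
  A 5-level 2D wavelet decomposition removes fine-scale detail (levels
  1–3), amplifies large coarse diagonal coefficients, dampens small
  horizontal/vertical ones and the deep low-pass band; the reconstruction
  is contrast-enhanced with the locally adaptive mapping
  `E = (f/f_g)·T(f,c) + (f/f_g)·(∂T/∂c)·(f − f_g)`, where
  `T(f,c) = (π²/4)·f^c` is the small-angle form of `sin²((π/2)·f^p)` and
  `c = c₁(f_g+ε)/((1−f_g)+ε) + c₂`; the injection site is then the
  largest maximally stable extremal region (MSER) containing the
  intensity maximum, annotated against a co-registered atlas raster.

- **Domain-boundary demarcation** (`train_ensemble`, `ensemble_predict`,
  `demarcate`, `agreement`). Per atlas level, an ensemble of 64
  RBF-kernel SVMs over power-of-two grids `C ∈ 2^(−2..5)`,
  `γ ∈ 2^(−5..2)`, each weighted by its mean accuracy `aᵢ` from 10
  repetitions of stratified 3-fold cross-validation; a pixel `x` is
  labeled `argmax_y Σᵢ aᵢ·I(yᵢ(x) = y)` over the domain set
  {medial, lateral, caudal}.

- **Connectivity communities** (`apply_thresholds`, `normalize_rows`,
  `louvain_runs`, `consensus_partition`, `reorder_for_matrix`,
  `color_code`, `stacked_bar_data`, `cluster_projection_vectors`,
  `tertile_bins`). Annotation entries below 0.0045 (anterograde pixel
  density) or 8 (retrograde cell count) are removed, rows are scaled to
  the maximum injection total, and the bipartite injection×target graph
  is partitioned by 100 Louvain runs at resolution γ = 1.0 summarized by
  consensus clustering, with community-ordered matrices, per-pixel
  community color maps, stacked-bar level summaries, tertile strength
  classes, and cosine-linkage hierarchical clustering of L1-normalized
  projection vectors.

- **Neuron morphometry** (`trim_neuron`, `loess_smooth_neuron`,
  `sholl_classic`, `sholl_surface`, `extract_features`, `pca_embed`,
  `pairwise_wilcoxon_fdr`, `persistence_diagram`, `wasserstein_dist`,
  `group_distance_summary`). SWC trees are trimmed at a Euclidean radius
  (default 300) and LOESS-smoothed (locally quadratic, five neighbors
  each side, endpoints/bifurcations untouched); profiles, standard
  morphometric features, PCA, pairwise two-sided Wilcoxon rank-sum tests
  with Benjamini–Hochberg FDR, and order-1 Wasserstein distances between
  path-distance persistence diagrams quantify group differences.

- **Synthetic data** (`gen_section_image`, `gen_domain_points`,
  `gen_annotation_matrix`, `gen_neuron`). Seeded generators for section
  images with known blob masks, domain point clouds with calibrated
  overlap and Bayes-rule ground-truth surfaces, planted block matrices,
  and branching-random-walk neurons with controllable soma, branching,
  and tortuosity.

## Worked example

```r
library(tracemap)

# --- injection site from a synthetic section -------------------------------
sp  <- section_spec(height = 192, width = 192, blob_center = c(96, 96),
                    blob_radius = 20, seed = 7)
g   <- gen_section_image(sp)
pyr <- wavelet_decompose(g$image, levels = 5)
enh <- adaptive_enhance(wavelet_reconstruct(modify_bands(pyr, band_modification())))
blob <- extract_injection_site(enh)
sprintf("blob: area = %d px, centroid = (%.1f, %.1f)", blob$area,
        blob$centroid[1], blob$centroid[2])
#> "blob: area = 1179 px, centroid = (95.8, 96.2)"

atlas <- matrix(1L, 192, 192); atlas[, 97:192] <- 2L
annotate_injection(blob, atlas, data.frame(id = 1:2, name = c("BLA.am", "BLA.al")))
#>   region pixels  fraction
#> 1 BLA.am    599 0.5080577
#> 2 BLA.al    580 0.4919423
```

The true blob was planted at (96, 96) with a nominal disk area of
π·20² ≈ 1257 px, straddling the two atlas regions — the extracted blob
recovers the center to a fraction of a pixel and splits its area 51/49
between them, with `BLA.am` reported as primary.

```r
# --- planted connectivity communities --------------------------------------
blocks <- list(list(injections = 1:5,   targets = 1:40,   mean = 2),
               list(injections = 6:10,  targets = 41:80,  mean = 2),
               list(injections = 11:15, targets = 81:120, mean = 2))
gen  <- gen_annotation_matrix(planted_matrix_spec(15, 120, blocks,
                                                  noise_rate = 0.02, seed = 1))
m    <- normalize_rows(apply_thresholds(gen$matrix))
cons <- consensus_partition(louvain_runs(m, gamma = 1.0, n_runs = 100,
                                         seed = 1), seed = 1)
table(planted = gen$partition, consensus = cons[names(gen$partition)])
#>        consensus
#> planted  0  1  2
#>       1 45  0  0
#>       2  0  0 45
#>       3  0 45  0
```

The consensus of 100 Louvain runs recovers the three planted
injection+target communities exactly (adjusted Rand index 1) despite 2%
off-block noise.

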