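# hant — hierarchical ant colony clustering for fMRI ROI identification

Brain network analysis from functional MRI starts by dividing the brain
into regions of interest (ROIs) whose voxels share temporal dynamics.
Atlas-based parcellations respect anatomy but ignore function; purely
data-driven clusterings fit the signal but cut across known anatomy.
`hant` implements a hierarchical, bioinspired compromise for neuroimaging
researchers: within every anatomical atlas label, simulated ants cluster
the voxels by the similarity of their underlying *neural events*, and the
number of ROIs per label is fixed automatically by a density criterion —
no preset cluster count anywhere.

## The method

For each voxel time series **y**ᵢ ∈ ℝᵀ the pipeline:

1. **Detrends** (3rd-order polynomial) and scales to unit norm.
2. **Deconvolves** the BOLD signal against the canonical Glover
   haemodynamic response function

   h(t) = (t/τ₁)^δ₁ e^{−(δ₁/τ₁)(t−τ₁)} − c (t/τ₂)^δ₂ e^{−(δ₂/τ₂)(t−τ₂)},

   with {τ₁, τ₂, δ₁, δ₂, c} = {5.4, 10.8, 6, 12, 0.35}, by Tikhonov-
   regularized least squares, recovering event series **e**ᵢ with much
   better SNR than the raw BOLD.
3. **Groups** voxels by their anatomical atlas label (e.g. Talairach).
4. **Embeds** each label's event series in 2D with UMAP (PCA available as
   a deterministic alternative).
5. **Clusters with ants.** Objects live on a toroidal grid; an ant of
   speed v evaluates the local similarity of object i at site r,

   f(i) = max(0, (1/s²) Σ_{k ∈ N_{s×s}(r)} [1 − d(i,k) / (α(1+(v−1)/v_max))]),

   picks up objects with probability P_p = (k₁/(k₁+f))² and drops them
   with probability P_d = min(2f, 1), reaching 1 at f ≥ k₂. Defaults
   {α, k₁, k₂} = {1.5, 1.1, 1.0} (from a grid search over [0.1, 2]³).
6. **Extracts ROIs** as the connected components of the thresholded
   mutual k-nearest-neighbour graph of the final grid positions — the
   ROI count emerges from the data.

For validation the package ships a dynamic-causal-model (DCM) simulator:
ẋ = A x + Σⱼ xⱼ B⁽ʲ⁾ x + C u with binary stimulus trains u, node courses
mapped to BOLD through the HRF, replicated, and mixed with standardized
AR(1) noise at an exact signal-to-noise ratio σ_signal/σ_noise. Partition
quality is measured by silhouette and Davies–Bouldin scores and, on
synthetic data, the adjusted Rand index (ARI) against ground truth.

## Worked example

Five uncoupled DCM nodes, 100 noisy replicates each (SNR 4), clustered
back into their source nodes:

```r
library(hant)

dataset <- make_benchmark_dataset(n_replicates = 100, snr = 4, seed = 1)
dataset
#> <synthetic_dataset> 500 signals (5 nodes x 100 replicates), T = 150, SNR = 4

cleaned <- apply(dataset$signals, 2, detrend_normalize)
events  <- deconvolve_events(cleaned, sample_hrf(dt = dataset$tr), ridge = 0.1)
emb  <- normalize_distances(embed_2d(events, embedding_config("umap", seed = 1)),
                            diameter = 10)
grid <- run_ants(emb, ant_params(seed = 1))
rois <- extract_clusters(grid)

rois$n_rois                                        # 5
adjusted_rand_index(rois$cluster, dataset$truth)   # 1
silhouette_score(t(cleaned), rois$cluster)         # 0.728
davies_bouldin(t(cleaned), rois$cluster)           # 0.398
```

The ants recover all five nodes exactly (5 ROIs, ARI 1): the partition is
compact and well separated (silhouette 0.728, Davies–Bouldin 0.398 on the
detrended time series). The same computation runs over NIfTI volumes with
`run_pipeline(bold, atlas, out_dir)`, which writes the ROI label volume,
`metrics.json` and a `config.yaml` snapshot; `inst/cli/hant.R` exposes
`run`, `simulate`, `gridsearch` and `score` subcommands for shell use.

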