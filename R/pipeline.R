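#' Export a synthetic dataset as NIfTI volumes
#'
#' Arranges the replicate signals of a [make_benchmark_dataset()] on a
#' synthetic 2D voxel sheet (a `nx x ny x 1 x T` volume) together with a
#' single-label atlas volume and a ground-truth node volume, so the whole
#' pipeline can be exercised end to end through its NIfTI interface.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param basename File stem (default `"synthetic"`). Files written are
#'   `<stem>_bold.nii`, `<stem>_atlas.nii`, `<stem>_truth.nii`.
#' @return Invisibly, a named list of the three file paths.
#' @export
dataset_to_nifti <- function(dataset, dir, basename = "synthetic") {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- ncol(dataset$signals)
  n_time <- nrow(dataset$signals)
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  bold <- array(0, c(nx, ny, 1, n_time))
  atlas <- array(0L, c(nx, ny, 1))
  truth <- array(0L, c(nx, ny, 1))
  for (i in seq_len(n)) {
    ix <- ((i - 1) %% nx) + 1
    iy <- ((i - 1) %/% nx) + 1
    bold[ix, iy, 1, ] <- dataset$signals[, i]
    atlas[ix, iy, 1] <- 1L
    truth[ix, iy, 1] <- dataset$truth[i]
  }
  paths <- list(
    bold = file.path(dir, paste0(basename, "_bold.nii")),
    atlas = file.path(dir, paste0(basename, "_atlas.nii")),
    truth = file.path(dir, paste0(basename, "_truth.nii")))
  RNifti::writeNifti(RNifti::asNifti(bold, pixdim = c(1, 1, 1, dataset$tr)),
                     paths$bold)
  RNifti::writeNifti(RNifti::asNifti(atlas), paths$atlas)
  RNifti::writeNifti(RNifti::asNifti(truth), paths$truth)
  invisible(paths)
}

#' Write a parcellation as a 3D integer NIfTI label volume
#'
#' Voxel values are ROI ids; 0 marks unassigned voxels. The file round-trips
#' losslessly through [RNifti::readNifti()].
#'
#' @param parc A `parcellation` from [hant()].
#' @param path Output `.nii` path.
#' @param reference Optional NIfTI object or path supplying header geometry.
#' @return Invisibly, `path`.
#' @export
write_parcellation <- function(parc, path, reference = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  sdim <- parc$spatial_dim
  if (is.null(sdim)) stop("parcellation has no spatial dimensions to export")
  vol <- array(0L, sdim)
  vol[as.integer(names(parc$roi))] <- as.integer(parc$roi)
  img <- if (is.null(reference)) RNifti::asNifti(vol)
         else RNifti::asNifti(vol, reference = RNifti::asNifti(reference))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Run the full HAnt pipeline on NIfTI inputs
#'
#' Detrends and unit-normalizes every voxel time series, deconvolves neural
#' events against the canonical HRF, groups voxels by anatomical atlas
#' label, embeds each group's events in 2D, clusters each group with the
#' ant dynamics, extracts ROIs by the density criterion, and scores the
#' resulting parcellation (silhouette and Davies-Bouldin on the
#' detrended/normalized time series by default). Outputs - the ROI label
#' volume, `metrics.json` and a `config.yaml` snapshot - are only written
#' once the whole run has succeeded.
#'
#' @param bold 4D BOLD NIfTI path (or object/array).
#' @param atlas 3D integer atlas NIfTI path (or object/array).
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @param mask Optional 3D binary mask NIfTI path (or object/array).
#' @param tr Repetition time in seconds; defaults to the BOLD header pixdim.
#' @param cfg An [embedding_config()].
#' @param params An [ant_params()].
#' @param ridge Deconvolution penalty.
#' @param poly_order Detrending order.
#' @param knn_k,density_quantile,min_roi_size Cluster-extraction settings.
#' @param metric_space Feature space for validity metrics: `"timeseries"`
#'   (detrended/normalized series; default) or `"embedding"`.
#' @param seed Run seed; overrides the seeds in `cfg` and `params`.
#' @return A list with `parcellation` and `metrics` (list with `silhouette`,
#'   `davies_bouldin`, `n_rois`, `seed`).
#' @export
run_pipeline <- function(bold, atlas, out_dir = NULL, mask = NULL, tr = NULL,
                         cfg = embedding_config(), params = ant_params(),
                         ridge = 0.1, poly_order = 3, knn_k = 10,
                         density_quantile = 0.9, min_roi_size = 5,
                         metric_space = c("timeseries", "embedding"),
                         seed = 1) {
  metric_space <- match.arg(metric_space)
  for (p in list(bold = bold, atlas = atlas, mask = mask))
    if (is.character(p) && !file.exists(p))
      stop(sprintf("input file not found: %s", p))
  if (is.character(bold) && is.null(tr)) {
    hdr <- RNifti::niftiHeader(RNifti::readNifti(bold))
    tr <- hdr$pixdim[5]
    if (!is.finite(tr) || tr <= 0) tr <- 1
  }
  tr <- tr %||% 1
  cfg$seed <- seed
  params$seed <- seed

  labeled <- assign_atlas_labels(bold, atlas, mask)
  cleaned <- lapply(labeled, function(g) {
    sig <- apply(g$signals, 2, detrend_normalize, poly_order = poly_order)
    ok <- apply(sig, 2, function(v) any(v != 0))
    list(label = g$label, voxels = g$voxels[ok],
         signals = sig[, ok, drop = FALSE])
  })
  cleaned <- structure(cleaned[vapply(cleaned, function(g)
    length(g$voxels) > 0, logical(1))],
    class = "labeled_signals", spatial_dim = attr(labeled, "spatial_dim"),
    n_time = attr(labeled, "n_time"))
  kernel <- sample_hrf(dt = tr)
  n_time <- attr(labeled, "n_time")
  solver <- deconvolution_operator(kernel, n_time, ridge)
  events <- structure(lapply(cleaned, function(g)
    list(label = g$label, voxels = g$voxels, signals = solver(g$signals))),
    class = "labeled_signals", spatial_dim = attr(labeled, "spatial_dim"),
    n_time = n_time)

  parc <- hant(events, cfg, params, knn_k = knn_k,
               density_quantile = density_quantile,
               min_roi_size = min_roi_size)

  feats <- parcellation_features(parc, cleaned, metric_space)
  metrics <- list(
    silhouette = if (parc$n_rois >= 2)
      silhouette_score(feats$X, feats$roi) else NA_real_,
    davies_bouldin = if (parc$n_rois >= 2)
      davies_bouldin(feats$X, feats$roi) else NA_real_,
    n_rois = parc$n_rois,
    seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_parcellation(parc, file.path(out_dir, "rois.nii"),
                       reference = if (is.character(atlas)) atlas else NULL)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    snapshot <- list(
      embedding = cfg[c("method", "n_neighbors", "min_dist", "seed")],
      ants = params[c("alpha", "k1", "k2", "v_max", "s", "t_max", "n_ants",
                      "seed")],
      deconvolution = list(ridge = ridge, poly_order = poly_order, tr = tr),
      extraction = list(knn_k = knn_k, density_quantile = density_quantile,
                        min_roi_size = min_roi_size),
      metric_space = metric_space, seed = seed)
    yaml::write_yaml(snapshot, file.path(out_dir, "config.yaml"))
  }
  list(parcellation = parc, metrics = metrics)
}

# Assemble the feature matrix (in parcellation voxel order) used for
# validity metrics, from either the cleaned time series or the embeddings.
#' @noRd
parcellation_features <- function(parc, cleaned, metric_space) {
  if (metric_space == "timeseries") {
    vox_order <- as.integer(names(parc$roi))
    all_vox <- unlist(lapply(cleaned, `[[`, "voxels"))
    X <- t(do.call(cbind, lapply(cleaned, `[[`, "signals")))
    X <- X[match(vox_order, all_vox), , drop = FALSE]
  } else {
    X <- do.call(rbind, lapply(parc$groups, function(g) {
      if (is.null(g$embedding)) matrix(0, length(g$voxels), 2) else g$embedding
    }))
  }
  list(X = X, roi = unname(parc$roi))
}

#' Score an existing parcellation against BOLD data
#'
#' Computes silhouette and Davies-Bouldin for any ROI label volume (for
#' example an atlas-based parcellation), using the same detrended/normalized
#' time-series feature space as [run_pipeline()].
#'
#' @param parcellation 3D integer ROI NIfTI (path, object or array).
#' @param bold 4D BOLD NIfTI (path, object or array).
#' @param poly_order Detrending order.
#' @return A list with `silhouette`, `davies_bouldin`, `n_rois`.
#' @export
score_parcellation <- function(parcellation, bold, poly_order = 3) {
  lab <- as_volume_array(parcellation, 3L)
  vol <- as_volume_array(bold, 4L)
  idx <- which(lab != 0)
  if (length(idx) < 2) stop("parcellation assigns fewer than 2 voxels")
  mat <- matrix(vol, prod(dim(vol)[1:3]), dim(vol)[4])[idx, , drop = FALSE]
  X <- t(apply(mat, 1, detrend_normalize, poly_order = poly_order))
  keep <- rowSums(X != 0) > 0
  X <- X[keep, , drop = FALSE]
  roi <- lab[idx][keep]
  list(silhouette = silhouette_score(X, roi),
       davies_bouldin = davies_bouldin(X, roi),
       n_rois = length(unique(roi)))
}

#' Grid search over the ant-dynamics constants
#'
#' Evaluates the within-label clustering stage for every combination of
#' `(alpha, k1, k2)`, scoring each candidate parcellation, and returns the
#' best parameters (maximum silhouette or minimum Davies-Bouldin). The
#' reference protocol searches `[0.1, 2]^3` in steps of 0.1 (8000
#' combinations); smaller grids are practical for exploration. Ties are
#' broken in favour of the lexicographically smallest `(alpha, k1, k2)`.
#'
#' @param labeled_events A `labeled_signals` object of event series.
#' @param alphas,k1s,k2s Numeric grids for the three constants.
#' @param objective `"silhouette"` (maximized) or `"davies_bouldin"`
#'   (minimized).
#' @param features Optional feature matrix (rows = voxels in group order)
#'   used for scoring; defaults to the event series themselves.
#' @param cfg An [embedding_config()].
#' @param params Base [ant_params()]; `alpha`, `k1`, `k2` are overridden.
#' @param ... Passed to [hant()].
#' @return A list with `best` (an `ant_params`), `best_score`, and `results`
#'   (data.frame of every combination with its score and ROI count).
#' @export
grid_search <- function(labeled_events, alphas = seq(0.1, 2, by = 0.1),
                        k1s = seq(0.1, 2, by = 0.1),
                        k2s = seq(0.1, 2, by = 0.1),
                        objective = c("silhouette", "davies_bouldin"),
                        features = NULL, cfg = embedding_config("pca"),
                        params = ant_params(), ...) {
  objective <- match.arg(objective)
  if (!length(alphas) || !length(k1s) || !length(k2s))
    stop("empty parameter grid")
  if (is.null(features))
    features <- t(do.call(cbind, lapply(labeled_events, `[[`, "signals")))
  combos <- expand.grid(k2 = k2s, k1 = k1s, alpha = alphas)[, 3:1]
  combos <- combos[order(combos$alpha, combos$k1, combos$k2), ]
  res <- vector("list", nrow(combos))
  failures <- character(0)
  for (i in seq_len(nrow(combos))) {
    p <- params
    p$alpha <- combos$alpha[i]; p$k1 <- combos$k1[i]; p$k2 <- combos$k2[i]
    row <- combos[i, ]
    res[[i]] <- tryCatch({
      parc <- hant(labeled_events, cfg, p, ...)
      score <- if (parc$n_rois < 2) NA_real_
               else if (objective == "silhouette")
                 silhouette_score(features, unname(parc$roi))
               else davies_bouldin(features, unname(parc$roi))
      cbind(row, score = score, n_rois = parc$n_rois)
    }, error = function(e) {
      failures <<- c(failures, sprintf("alpha=%g k1=%g k2=%g: %s",
                                       row$alpha, row$k1, row$k2,
                                       conditionMessage(e)))
      cbind(row, score = NA_real_, n_rois = NA_integer_)
    })
  }
  results <- do.call(rbind, res)
  if (all(is.na(results$score)))
    stop("grid search failed for every combination:\n  ",
         paste(head(failures, 10), collapse = "\n  "))
  sc <- results$score
  best_i <- if (objective == "silhouette") which.max(sc)
            else which.min(replace(sc, is.na(sc), Inf))
  best <- params
  best$alpha <- results$alpha[best_i]
  best$k1 <- results$k1[best_i]
  best$k2 <- results$k2[best_i]
  list(best = best, best_score = results$score[best_i], results = results)
}
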