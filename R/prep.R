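#' Polynomial detrending and unit-norm scaling
#'
#' Removes a least-squares polynomial trend of order `poly_order` (default
#' cubic) and scales the residual to unit Euclidean norm, so that Euclidean
#' distances between voxels become scaled correlation distances. A series
#' that is itself (numerically) an exact polynomial has no residual signal
#' and is flagged degenerate; such voxels are excluded downstream.
#'
#' @param series Numeric vector or [hant_ts()].
#' @param poly_order Polynomial order to remove (default 3).
#' @param degenerate_tol Residual-sd threshold below which the series is
#'   flagged degenerate, relative to the series sd.
#' @return Numeric vector of unit Euclidean norm (or, if degenerate, the zero
#'   vector) with logical attribute `degenerate`.
#' @examples
#' x <- detrend_normalize(sin(1:50) + 0.01 * (1:50)^2, poly_order = 3)
#' sqrt(sum(x^2))
#' @export
detrend_normalize <- function(series, poly_order = 3, degenerate_tol = 1e-8) {
  x <- ts_values(series)
  n <- length(x)
  if (n <= poly_order + 1L)
    stop("series too short for the requested polynomial order")
  tt <- seq_len(n)
  fit <- lm.fit(cbind(1, stats::poly(tt, poly_order)), x)
  r <- fit$residuals
  if (sd(x) == 0 || sd(r) / sd(x) < degenerate_tol) {
    out <- numeric(n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- r / sqrt(sum(r^2))
  attr(out, "degenerate") <- FALSE
  out
}

#' @importFrom stats lm.fit
NULL

#' Group voxel time series by anatomical atlas label
#'
#' Attaches to each voxel the label of the co-registered anatomical atlas and
#' collects the in-mask, non-background voxels into per-label groups. Each
#' voxel appears in exactly one group; background voxels are dropped.
#'
#' @param volume 4D numeric array `(x, y, z, t)` of BOLD data, or an object
#'   readable by [RNifti::asNifti()].
#' @param atlas 3D integer array of anatomical labels with the same spatial
#'   shape, or a NIfTI path/object.
#' @param mask Optional 3D logical/0-1 array restricting the voxels used.
#' @param background_id Atlas value denoting non-brain (default 0).
#' @return A list of class `labeled_signals`; one element per label, each a
#'   list with `label`, `voxels` (linear voxel indices) and `signals`
#'   (`T x n_voxels` matrix).
#' @export
assign_atlas_labels <- function(volume, atlas, mask = NULL, background_id = 0L) {
  vol <- as_volume_array(volume, ndim = 4L)
  atl <- as_volume_array(atlas, ndim = 3L)
  sdim <- dim(vol)[1:3]
  if (!all(dim(atl) == sdim))
    stop(sprintf("atlas shape (%s) does not match volume spatial shape (%s)",
                 paste(dim(atl), collapse = "x"), paste(sdim, collapse = "x")))
  keep <- atl != background_id
  if (!is.null(mask)) {
    msk <- as_volume_array(mask, ndim = 3L)
    if (!all(dim(msk) == sdim))
      stop(sprintf("mask shape (%s) does not match volume spatial shape (%s)",
                   paste(dim(msk), collapse = "x"), paste(sdim, collapse = "x")))
    keep <- keep & (msk != 0)
  }
  idx <- which(keep)
  if (!length(idx)) {
    warning("no in-mask, non-background voxels; empty labeling")
    return(structure(list(), class = "labeled_signals",
                     spatial_dim = sdim, n_time = dim(vol)[4]))
  }
  n_time <- dim(vol)[4]
  mat <- matrix(vol, prod(sdim), n_time)  # voxels x time
  labs <- atl[idx]
  groups <- lapply(split(idx, labs), function(vox) {
    list(label = atl[vox[1]], voxels = vox,
         signals = t(mat[vox, , drop = FALSE]))
  })
  structure(groups, class = "labeled_signals", spatial_dim = sdim,
            n_time = n_time)
}

# NIfTI readers drop trailing singleton dimensions; pad them back.
#' @noRd
as_volume_array <- function(x, ndim) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  a <- as.array(x)
  if (is.null(dim(a))) dim(a) <- length(a)
  while (length(dim(a)) < ndim) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != ndim)
    stop(sprintf("expected a %dD array, got %dD", ndim, length(dim(a))))
  a
}

#' @export
print.labeled_signals <- function(x, ...) {
  sizes <- vapply(x, function(g) length(g$voxels), integer(1))
  cat(sprintf("<labeled_signals> %d labels, %d voxels total\n",
              length(x), sum(sizes)))
  invisible(x)
}

#' Detrend and deconvolve every labelled voxel signal
#'
#' Applies [detrend_normalize()] followed by [deconvolve_events()] to every
#' signal in a [assign_atlas_labels()] grouping, preserving group structure
#' and voxel indices. Degenerate (zero-information) voxels are excluded with
#' a message.
#'
#' @param labeled A `labeled_signals` object.
#' @param kernel An `hrf_kernel` sampled at the scan TR.
#' @param ridge Deconvolution penalty (default 0.1).
#' @param poly_order Detrending order (default 3).
#' @return A `labeled_signals` object whose `signals` are event series.
#' @export
prepare_events <- function(labeled, kernel, ridge = 0.1, poly_order = 3) {
  stopifnot(inherits(labeled, "labeled_signals"))
  if (!length(labeled)) stop("no labelled groups to process")
  n_time <- attr(labeled, "n_time")
  solver <- deconvolution_operator(kernel, n_time, ridge)
  out <- lapply(labeled, function(g) {
    cleaned <- apply(g$signals, 2, detrend_normalize, poly_order = poly_order)
    ok <- apply(cleaned, 2, function(v) any(v != 0))
    if (!all(ok))
      message(sprintf("label %s: excluded %d degenerate voxel(s)",
                      g$label, sum(!ok)))
    list(label = g$label, voxels = g$voxels[ok],
         signals = solver(cleaned[, ok, drop = FALSE]))
  })
  out <- out[vapply(out, function(g) length(g$voxels) > 0, logical(1))]
  structure(out, class = "labeled_signals",
            spatial_dim = attr(labeled, "spatial_dim"), n_time = n_time)
}
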