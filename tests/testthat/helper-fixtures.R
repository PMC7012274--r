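# Shared fixture builders; everything is generated in code at test time.

# Two tight Gaussian blobs in 2D, far apart relative to their spread.
make_blob_points <- function(n_per = 50, sep = 1, sd = 0.01, seed = 1) {
  set.seed(seed)
  pts <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
               cbind(rnorm(n_per, sep, sd), rnorm(n_per, sep, sd)))
  list(points = pts, truth = rep(1:2, each = n_per))
}

# A small 4D BOLD volume + 3D atlas built from a benchmark dataset, written
# as NIfTI files under a temp dir.
make_synthetic_nifti <- function(n_replicates = 20, snr = 4, seed = 1,
                                 dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  d <- make_benchmark_dataset(n_replicates = n_replicates, snr = snr,
                              seed = seed)
  paths <- dataset_to_nifti(d, dir)
  c(paths, list(dataset = d))
}

# Grid state built directly from hand-chosen cells (bypassing the dynamics),
# for extraction and similarity tests.
make_grid_state <- function(cells, side, coords = NULL) {
  cells <- as.matrix(cells)
  occupancy <- rep(-1L, side * side)
  occupancy[cells[, 1] + cells[, 2] * side + 1L] <- seq_len(nrow(cells)) - 1L
  structure(list(side = as.integer(side),
                 cells = matrix(as.integer(cells), nrow(cells), 2),
                 occupancy = as.integer(occupancy),
                 coords = coords %||% cells),
            class = "grid_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
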