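#' Ant-colony clustering parameters
#'
#' Parameters of the ant dynamics. `alpha` scales the similarity measure
#' (distances are taken on embeddings normalized to unit diameter, so
#' `alpha` is comparable across anatomical regions); `k1` and `k2` are the
#' pick-up and drop constants; ants move up to `v_max` cells per step with a
#' speed drawn uniformly on `{1, ..., v_max}` at creation; `s` is the odd
#' side of the square grid neighbourhood. The defaults
#' `{alpha, k1, k2} = {1.5, 1.1, 1.0}` come from a grid search over
#' `[0.1, 2]^3` in steps of 0.1.
#'
#' @param alpha Similarity scale (> 0).
#' @param k1 Pick-up constant (> 0).
#' @param k2 Drop constant (> 0).
#' @param v_max Maximum ant speed in cells per step.
#' @param s Odd neighbourhood side (>= 3).
#' @param t_max Number of sweeps (every ant acts once per sweep); `NULL`
#'   scales with problem size so total ant actions are about `200 * n`.
#' @param n_ants Number of ants; `NULL` gives `ceiling(n / 10)`.
#' @param seed Integer seed for the whole run.
#' @return A list of class `ant_params`.
#' @export
ant_params <- function(alpha = 1.5, k1 = 1.1, k2 = 1.0, v_max = 5, s = 3,
                       t_max = NULL, n_ants = NULL, seed = 1) {
  if (alpha <= 0 || k1 <= 0 || k2 <= 0) stop("alpha, k1, k2 must be positive")
  if (s < 3 || s %% 2 == 0) stop("s must be an odd integer >= 3")
  if (v_max < 1) stop("v_max must be >= 1")
  structure(list(alpha = alpha, k1 = k1, k2 = k2, v_max = as.integer(v_max),
                 s = as.integer(s), t_max = t_max, n_ants = n_ants,
                 seed = seed),
            class = "ant_params")
}

#' @noRd
resolve_ant_counts <- function(params, n) {
  n_ants <- params$n_ants %||% max(1L, ceiling(n / 10))
  t_max <- params$t_max %||% max(1L, ceiling(200 * n / n_ants))
  list(n_ants = as.integer(n_ants), t_max = as.integer(t_max))
}

#' Default grid side for n objects
#'
#' About ten cells per object leaves the ants room to move.
#' @param n Number of objects.
#' @return Integer grid side.
#' @export
default_grid_side <- function(n) as.integer(ceiling(sqrt(10 * n)))

#' Place embedded points onto the toroidal grid
#'
#' Min-max scales each coordinate to the grid extent and rounds to a cell;
#' collisions are resolved to the nearest free cell by an in-bounds spiral
#' search over rings of increasing Chebyshev radius (ties broken
#' lexicographically).
#'
#' With `margin > 0` the points are scaled into the central
#' `[margin, side - 1 - margin]` band instead of the full extent. Because
#' opposite edges of the toroidal grid are adjacent, full-extent placement
#' puts the data's extremes right next to each other across the wrap;
#' [run_ants()] therefore places with a quarter-side margin, which separates
#' the extremes by half the torus - the maximum possible.
#'
#' @param points `n x 2` coordinate matrix (an `embedded_set`).
#' @param grid_side Cells per side; default [default_grid_side()].
#' @param seed Unused placeholder kept for interface stability (placement is
#'   deterministic); reserved for randomized tie-breaking variants.
#' @param margin Cells of empty border kept on each side (default 0).
#' @return A list of class `grid_state`: `side`, `cells` (`n x 2` 0-based),
#'   `occupancy` (length `side^2`, -1 = empty), `coords` (the input points).
#' @export
place_on_grid <- function(points, grid_side = NULL, seed = NULL, margin = 0) {
  P <- as.matrix(points)
  n <- nrow(P)
  side <- as.integer(grid_side %||% default_grid_side(n))
  if (side^2 < n)
    stop(sprintf("grid side %d too small for %d objects; use side >= %d",
                 side, n, default_grid_side(n)))
  margin <- as.integer(margin)
  if (margin < 0 || side - 2L * margin < 1L)
    stop("margin leaves no cells to place on")
  rng <- apply(P, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  desired <- sweep(sweep(P, 2, rng[1, ]), 2, span, "/") *
    (side - 1L - 2L * margin) + margin
  desired <- matrix(as.integer(round(desired)), n, 2)
  placed <- cpp_place_on_grid(desired, side)
  structure(list(side = side, cells = placed$cells,
                 occupancy = placed$occupancy, coords = P),
            class = "grid_state")
}

#' @export
print.grid_state <- function(x, ...) {
  cat(sprintf("<grid_state> %d x %d toroidal grid, %d objects\n",
              x$side, x$side, nrow(x$cells)))
  invisible(x)
}

#' Local similarity of an object to its grid neighbourhood
#'
#' \deqn{f = \max\left(0, \frac{1}{s^2} \sum_{k \in N_{s\times s}(r)}
#'   \left[1 - \frac{d(i, k)}{\alpha (1 + (v-1)/v_{max})}\right]\right)}
#' with `d` the Euclidean distance between embedded coordinates and the
#' evaluated object excluded from its own neighbourhood sum. An empty
#' neighbourhood gives `f = 0`.
#'
#' @param grid A `grid_state`.
#' @param r Cell `(x, y)` (0-based) at which the object is evaluated.
#' @param obj Object index (1-based row into `grid$coords`).
#' @param params An [ant_params()].
#' @param v Speed of the evaluating ant, in `[1, v_max]`.
#' @return Nonnegative similarity, at most `(s^2 - 1) / s^2` during pick-up.
#' @export
local_similarity <- function(grid, r, obj, params = ant_params(), v = 1) {
  stopifnot(inherits(grid, "grid_state"), v >= 1, v <= params$v_max)
  cpp_local_similarity(grid$occupancy, grid$side, grid$coords,
                       as.integer(r[1]), as.integer(r[2]), obj - 1L,
                       params$alpha, params$v_max, params$s, as.integer(v))
}

#' Pick-up probability
#'
#' `P_p = (k1 / (k1 + f))^2`: strictly decreasing in the local similarity,
#' equal to 1 for an isolated object.
#'
#' @param f Nonnegative local similarity.
#' @param k1 Positive pick-up constant.
#' @return Probability in `(0, 1]`.
#' @export
pick_probability <- function(f, k1 = 1.1) {
  if (any(f < 0)) stop("similarity f must be nonnegative")
  if (any(k1 <= 0)) stop("k1 must be positive")
  (k1 / (k1 + f))^2
}

#' Drop probability
#'
#' `P_d = 2 f` when `f < k2`, and 1 once `f >= k2`.
#'
#' @param f Nonnegative local similarity.
#' @param k2 Positive drop constant.
#' @return Probability in `[0, 1]`.
#' @export
drop_probability <- function(f, k2 = 1.0) {
  if (any(f < 0)) stop("similarity f must be nonnegative")
  if (any(k2 <= 0)) stop("k2 must be positive")
  ifelse(f >= k2, 1, pmin(2 * f, 1))
}

#' Create ants at random grid positions
#'
#' @param grid A `grid_state`.
#' @param n_ants Number of ants.
#' @param v_max Maximum speed; each ant draws a lifetime speed uniformly on
#'   `{1, ..., v_max}`.
#' @return A data.frame of class `ant_state` with columns `x`, `y` (0-based
#'   cells), `v`, `carrying` (0-based object id or -1).
#' @export
init_ants <- function(grid, n_ants, v_max = 5) {
  stopifnot(inherits(grid, "grid_state"), n_ants >= 1)
  ants <- data.frame(
    x = sample.int(grid$side, n_ants, replace = TRUE) - 1L,
    y = sample.int(grid$side, n_ants, replace = TRUE) - 1L,
    v = sample.int(v_max, n_ants, replace = TRUE),
    carrying = -1L)
  class(ants) <- c("ant_state", "data.frame")
  ants
}

#' Advance the ant dynamics
#'
#' Runs `n_steps` sweeps in which every ant acts once: an unladen ant on an
#' occupied cell picks the object up with probability [pick_probability()]
#' of its local similarity, then moves `v` cells in a uniformly random one of
#' the 8 directions (toroidal wrap); a laden ant moves first and then drops
#' its object with probability [drop_probability()], placing it on the
#' nearest empty cell.
#'
#' @param grid A `grid_state`.
#' @param ants An `ant_state` from [init_ants()].
#' @param params An [ant_params()].
#' @param n_steps Number of sweeps (default 1).
#' @param check Assert state-consistency invariants after every sweep
#'   (object conservation, at most one object per cell).
#' @param allow_pick Permit pick-ups; disabled during the settling phase at
#'   the end of a run so laden ants deliver their cargo without the colony
#'   lifting anything new.
#' @return A list with updated `grid` and `ants`.
#' @export
step_ants <- function(grid, ants, params = ant_params(), n_steps = 1,
                      check = FALSE, allow_pick = TRUE) {
  stopifnot(inherits(grid, "grid_state"), inherits(ants, "ant_state"))
  res <- cpp_ant_steps(grid$side, grid$occupancy, grid$cells,
                       ants$x, ants$y, ants$v, ants$carrying, grid$coords,
                       params$alpha, params$k1, params$k2, params$v_max,
                       params$s, as.integer(n_steps), isTRUE(check),
                       isTRUE(allow_pick))
  grid$occupancy <- res$occupancy
  grid$cells <- res$cells
  ants$x <- res$ant_x
  ants$y <- res$ant_y
  ants$carrying <- res$carrying
  list(grid = grid, ants = ants)
}

#' Run the full ant-clustering dynamics on an embedded point set
#'
#' Places the points on the grid, creates ants at random cells with random
#' speeds, and iterates [step_ants()] for `t_max` sweeps. A settling phase
#' follows in which ants may still move and drop but no longer pick up, so
#' cargo is delivered to matching neighbourhoods rather than abandoned; any
#' ant still laden after that drops its object at the nearest empty cell.
#' The run is a pure function of `(points, params)`.
#'
#' @param points `n x 2` coordinate matrix (at least 3 points), normally
#'   normalized with [normalize_distances()].
#' @param params An [ant_params()].
#' @param grid_side Optional grid side override. By default the points are
#'   placed on a central band of [default_grid_side()] cells (about ten
#'   cells per object) surrounded by an equally wide empty guard band, i.e.
#'   a full side of twice that, so that the embedding's extremes are not
#'   adjacent across the toroidal wrap.
#' @param check Assert engine invariants every sweep (slower; for testing).
#' @return The terminal `grid_state`.
#' @examples
#' pts <- normalize_distances(cbind(rnorm(30), rnorm(30)))
#' g <- run_ants(pts, ant_params(seed = 1))
#' @export
run_ants <- function(points, params = ant_params(), grid_side = NULL,
                     check = FALSE) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 3) stop("ant clustering needs at least 3 objects")
  counts <- resolve_ant_counts(params, n)
  side <- as.integer(grid_side %||% (2L * default_grid_side(n)))
  with_seed(params$seed, {
    grid <- place_on_grid(P, side, margin = side %/% 4)
    ants <- init_ants(grid, counts$n_ants, params$v_max)
    st <- step_ants(grid, ants, params, n_steps = counts$t_max, check = check)
    settle <- 0L
    while (any(st$ants$carrying >= 0) && settle < 20L) {
      st <- step_ants(st$grid, st$ants, params, n_steps = st$grid$side,
                      check = check, allow_pick = FALSE)
      settle <- settle + 1L
    }
    dropped <- cpp_force_drop(st$grid$side, st$grid$occupancy, st$grid$cells,
                              st$ants$x, st$ants$y, st$ants$carrying)
    st$grid$occupancy <- dropped$occupancy
    st$grid$cells <- dropped$cells
    st$grid
  })
}

#' Extract ROIs from a terminated grid by k-NN density
#'
#' The number of clusters is fixed automatically by a density criterion on
#' the k-nearest-neighbour graph of the objects' final grid coordinates
#' (unwrapped from the torus along its emptiest row and column bands).
#' Only *mutual* k-NN edges - pairs that list each other among their `k`
#' nearest neighbours - no longer than the `density_quantile` quantile of
#' all k-NN edge lengths are kept: sparse trails of in-transit objects point
#' at dense cores without being pointed back at, so they cannot bridge two
#' cores. The undirected connected components of the surviving graph become
#' the ROIs. Components smaller than `min_roi_size` are dissolved and their
#' members reassigned to the nearest surviving ROI - by centroid distance in
#' the embedding space when `points` is supplied, otherwise on the grid.
#'
#' @param grid A terminated `grid_state` (no carried objects).
#' @param points Optional `n x 2` embedded coordinates used to reassign
#'   members of dissolved fragments (defaults to `grid$coords`).
#' @param k Neighbours per object in the density graph (default 10).
#' @param density_quantile Edge-length survival quantile (default 0.9).
#' @param min_roi_size Minimum objects per ROI (default 5).
#' @return A list of class `cluster_assignment`: `cluster` (1-based ROI id
#'   per object, contiguous from 1) and `n_rois`.
#' @export
extract_clusters <- function(grid, points = NULL, k = 10,
                             density_quantile = 0.9, min_roi_size = 5) {
  stopifnot(inherits(grid, "grid_state"))
  cells <- grid$cells
  if (any(cells < 0)) stop("grid has carried objects; run to termination first")
  points <- points %||% grid$coords
  n <- nrow(cells)
  if (n == 1) {
    return(structure(list(cluster = 1L, n_rois = 1L),
                     class = "cluster_assignment"))
  }
  cells <- unwrap_torus(cells, grid$side)
  g <- build_knn_graph(cells, min(k, n - 1L))
  cut <- quantile(g$edges$length, density_quantile, names = FALSE, type = 7)
  key <- paste(pmin(g$edges$from, g$edges$to),
               pmax(g$edges$from, g$edges$to))
  mutual <- key %in% key[duplicated(key)]
  keep <- mutual & g$edges$length <= cut
  if (!any(keep)) {
    warning("all k-NN edges exceeded the density threshold; ",
            "every object is a singleton ROI")
    return(structure(list(cluster = seq_len(n), n_rois = n),
                     class = "cluster_assignment"))
  }
  ig <- igraph::graph_from_data_frame(
    g$edges[keep, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(ig)$membership
  comp <- as.integer(comp[as.character(seq_len(n))])
  comp <- dissolve_small_components(comp, points, min_roi_size)
  cl <- as.integer(factor(comp))
  structure(list(cluster = cl, n_rois = max(cl)),
            class = "cluster_assignment")
}

# Positions on the torus are only defined modulo the grid side, so a cluster
# can straddle the wrap boundary. Rotate the torus so the cut passes through
# the middle of the emptiest circular run of rows and of columns, then treat
# coordinates as plain Euclidean.
#' @noRd
unwrap_torus <- function(cells, side) {
  shift_for <- function(coord) {
    occ <- tabulate(coord + 1L, nbins = side)
    empty <- occ == 0
    if (!any(empty)) return(0L)
    # longest circular run of empty lines; cut at its middle
    runs <- rle(rep(empty, 2))
    ends <- cumsum(runs$lengths)
    cand <- which(runs$values & runs$lengths >= 1)
    best <- cand[which.max(runs$lengths[cand])]
    mid <- (ends[best] - runs$lengths[best] %/% 2 - 1L) %% side
    (side - 1L - mid) %% side
  }
  sx <- shift_for(cells[, 1])
  sy <- shift_for(cells[, 2])
  cbind((cells[, 1] + sx) %% side, (cells[, 2] + sy) %% side)
}

# Dissolve components below the size floor: each member individually joins
# the surviving component with the nearest centroid in `points` space. If no
# component reaches the floor, the partition is left as is.
#' @noRd
dissolve_small_components <- function(comp, points, min_size) {
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes >= min_size])
  if (!length(big) || length(big) == length(sizes)) return(comp)
  cents <- t(vapply(big,
                    function(cid) colMeans(points[comp == cid, , drop = FALSE]),
                    numeric(ncol(points))))
  loose <- which(!(comp %in% big))
  for (i in loose) {
    d <- sqrt(rowSums((cents - matrix(points[i, ], nrow(cents), ncol(points),
                                      byrow = TRUE))^2))
    comp[i] <- big[which.min(d)]
  }
  comp
}

#' Hierarchical ant clustering of labelled event signals
#'
#' The full within-label clustering stage: for every anatomical label group,
#' embeds the event series in 2D, normalizes the embedding to unit diameter,
#' runs the ant dynamics, and extracts ROIs by the density criterion. ROI
#' ids are made globally unique across labels. Groups with fewer than
#' `min_group` voxels are too small for a grid neighbourhood to be
#' meaningful and become singleton ROIs.
#'
#' @param labeled_events A `labeled_signals` object of event series (from
#'   [prepare_events()]).
#' @param cfg An [embedding_config()].
#' @param params An [ant_params()].
#' @param knn_k,density_quantile,min_roi_size Passed to [extract_clusters()].
#' @param min_group Minimum voxels for ant clustering (default 3).
#' @param diameter Embedding diameter after normalization (default 10; see
#'   [normalize_distances()]).
#' @return A list of class `parcellation`: `roi` (named integer vector,
#'   voxel linear index -> global ROI id), `roi_table` (data.frame `roi`,
#'   `label`, `size`), `n_rois`, `spatial_dim`, and per-label detail in
#'   `groups`.
#' @export
hant <- function(labeled_events, cfg = embedding_config(),
                 params = ant_params(), knn_k = 10, density_quantile = 0.9,
                 min_roi_size = 5, min_group = 3, diameter = 10) {
  stopifnot(inherits(labeled_events, "labeled_signals"))
  if (!length(labeled_events)) stop("no labelled groups to cluster")
  roi_offset <- 0L
  voxels <- integer(0)
  rois <- integer(0)
  tab <- list()
  groups <- list()
  for (g in labeled_events) {
    n <- length(g$voxels)
    if (n < min_group) {
      local <- rep(1L, n)
      emb <- NULL
    } else {
      emb <- normalize_distances(embed_2d(g$signals, cfg), diameter = diameter)
      grid <- run_ants(emb, params)
      local <- extract_clusters(grid, k = knn_k,
                                density_quantile = density_quantile,
                                min_roi_size = min_roi_size)$cluster
    }
    voxels <- c(voxels, g$voxels)
    rois <- c(rois, local + roi_offset)
    for (cid in sort(unique(local)))
      tab[[length(tab) + 1L]] <- data.frame(
        roi = cid + roi_offset, label = g$label, size = sum(local == cid))
    groups[[as.character(g$label)]] <- list(label = g$label,
                                            voxels = g$voxels,
                                            cluster = local,
                                            embedding = emb)
    roi_offset <- roi_offset + max(local)
  }
  roi <- rois
  names(roi) <- voxels
  structure(list(roi = roi, roi_table = do.call(rbind, tab),
                 n_rois = roi_offset,
                 spatial_dim = attr(labeled_events, "spatial_dim"),
                 groups = groups),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d ROIs over %d voxels (%d anatomical labels)\n",
              x$n_rois, length(x$roi), length(x$groups)))
  invisible(x)
}
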