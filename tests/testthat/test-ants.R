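test_that("grid placement is injective, scaled, and resolves collisions nearby", {
  set.seed(51)
  P <- cbind(runif(40), runif(40))
  g <- place_on_grid(P, grid_side = 20)
  expect_equal(nrow(g$cells), 40)
  # one object per cell
  keys <- g$cells[, 1] + g$cells[, 2] * g$side
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(sum(g$occupancy >= 0), 40)
  # corner point: the coordinate-wise minimum maps to cell (0, 0)
  Pc <- rbind(c(0, 0), c(1, 0.5), c(2, 1))
  gc <- place_on_grid(Pc, grid_side = 10)
  expect_equal(gc$cells[1, ], c(0L, 0L))
  # identical points end up on adjacent cells (spiral collision search)
  gi <- place_on_grid(rbind(c(0.5, 0.5), c(0.5, 0.5), c(0, 0), c(1, 1)),
                      grid_side = 11)
  expect_equal(max(abs(gi$cells[1, ] - gi$cells[2, ])), 1)
  expect_error(place_on_grid(P, grid_side = 3), "too small")
})

test_that("local similarity matches hand-computed values", {
  # 8 identical neighbours in a full 3x3 block: f = 8/9 exactly
  cells <- as.matrix(expand.grid(1:3, 1:3))
  coords <- matrix(0, 9, 2)
  g <- make_grid_state(cells, side = 7, coords = coords)
  centre <- which(cells[, 1] == 2 & cells[, 2] == 2)
  f <- local_similarity(g, c(2, 2), centre, ant_params(), v = 1)
  expect_equal(f, 8 / 9, tolerance = 1e-12)
  f5 <- local_similarity(g, c(2, 2), centre, ant_params(), v = 5)
  expect_equal(f5, 8 / 9, tolerance = 1e-12)

  # empty neighbourhood
  g1 <- make_grid_state(rbind(c(3, 3)), side = 9, coords = rbind(c(0, 0)))
  expect_equal(local_similarity(g1, c(3, 3), 1, ant_params(), v = 1), 0)

  # all neighbours beyond the similarity scale: every term <= 0, clamped
  far <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  g2 <- make_grid_state(rbind(c(2, 2), c(1, 2), c(3, 2), c(2, 1)), side = 7,
                        coords = far)
  p <- ant_params(alpha = 1.5, v_max = 5)
  expect_equal(local_similarity(g2, c(2, 2), 1, p, v = 5), 0)
})

test_that("similarity is bounded by (s^2 - 1) / s^2 when picking", {
  set.seed(52)
  for (rep in 1:20) {
    n <- 30
    P <- cbind(rnorm(n, sd = 0.1), rnorm(n, sd = 0.1))
    g <- place_on_grid(P, grid_side = 9)
    i <- sample.int(n, 1)
    f <- local_similarity(g, g$cells[i, ], i, ant_params(),
                          v = sample(1:5, 1))
    expect_gte(f, 0)
    expect_lte(f, 8 / 9 + 1e-12)
  }
})

test_that("pick and drop probabilities follow the stated rules", {
  expect_equal(pick_probability(0, 1.1), 1)
  expect_equal(pick_probability(1.1, 1.1), 0.25)
  expect_equal(pick_probability(2, 2), 0.25)
  expect_equal(drop_probability(0, 1), 0)
  expect_equal(drop_probability(0.3, 1), 0.6)
  expect_equal(drop_probability(1, 1), 1)
  expect_equal(drop_probability(5, 1), 1)
  expect_error(pick_probability(-1), "nonnegative")
  expect_error(drop_probability(-1), "nonnegative")
  # strictly decreasing in f
  f <- seq(0, 5, by = 0.25)
  expect_true(all(diff(pick_probability(f, 0.7)) < 0))
})

test_that("probabilities stay in range under fuzzed inputs", {
  set.seed(53)
  f <- runif(10000, 0, 100)
  k1 <- runif(10000, 1e-6, 10)
  k2 <- runif(10000, 1e-6, 10)
  pp <- pick_probability(f, k1)
  pd <- drop_probability(f, k2)
  expect_true(all(pp > 0 & pp <= 1))
  expect_true(all(pd >= 0 & pd <= 1))
})

test_that("stepping conserves objects and keeps one object per cell", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- cbind(rnorm(50), rnorm(50))
    g <- place_on_grid(normalize_distances(P, diameter = 10), grid_side = 23)
    ants <- init_ants(g, 5, 5)
    st <- list(grid = g, ants = ants)
    for (sweep in 1:40) {
      # check = TRUE asserts the engine invariants inside every sweep
      st <- step_ants(st$grid, st$ants, ant_params(), n_steps = 1,
                      check = TRUE)
      on_grid <- sum(st$grid$occupancy >= 0)
      carried <- sum(st$ants$carrying >= 0)
      expect_equal(on_grid + carried, 50)
      occ_cells <- st$grid$cells[st$grid$cells[, 1] >= 0, , drop = FALSE]
      expect_equal(anyDuplicated(occ_cells), 0L)
    }
  }
})

test_that("extreme parameters freeze or trigger the dynamics as expected", {
  set.seed(54)
  # all-identical objects, full neighbourhoods: f = 8/9 >= k2 would need
  # k2 <= 8/9; with k2 = 0.5 a laden ant always drops on arrival
  coords <- matrix(0, 9, 2)
  cells <- as.matrix(expand.grid(1:3, 1:3))
  g <- make_grid_state(cells, side = 11, coords = coords)
  centre <- which(cells[, 1] == 2 & cells[, 2] == 2)
  f <- local_similarity(g, c(2, 2), centre, ant_params(k2 = 0.5), v = 1)
  expect_equal(drop_probability(f, k2 = 0.5), 1)
  # k1 -> 0+: picking a well-connected object becomes vanishingly rare
  expect_lt(pick_probability(f, k1 = 1e-4), 1e-6)
})

test_that("full runs are seed-deterministic and conserve objects", {
  b <- make_blob_points(seed = 55)
  pn <- normalize_distances(b$points, diameter = 10)
  g1 <- run_ants(pn, ant_params(seed = 7))
  g2 <- run_ants(pn, ant_params(seed = 7))
  expect_identical(g1$cells, g2$cells)
  expect_identical(g1$occupancy, g2$occupancy)
  expect_equal(sum(g1$occupancy >= 0), nrow(b$points))
  expect_true(all(g1$cells >= 0))
  g3 <- run_ants(pn, ant_params(seed = 8))
  expect_false(identical(g1$cells, g3$cells))
})

test_that("ant sorting separates well-separated blobs on the grid", {
  b <- make_blob_points(seed = 56)
  pn <- normalize_distances(b$points, diameter = 10)
  for (seed in 1:5) {
    g <- run_ants(pn, ant_params(seed = seed))
    D <- as.matrix(dist(g$cells))
    within <- mean(D[b$truth == 1, b$truth == 1])
    between <- mean(D[b$truth == 1, b$truth == 2])
    expect_lt(within, between)
  }
})

test_that("cluster extraction finds the right component structure", {
  # two compact grid blobs far apart -> exactly 2 ROIs
  set.seed(57)
  cells <- rbind(as.matrix(expand.grid(2:6, 2:6))[1:20, ],
                 as.matrix(expand.grid(24:28, 24:28))[1:20, ])
  g <- make_grid_state(cells, side = 40)
  cl <- extract_clusters(g, k = 5, density_quantile = 0.9)
  expect_equal(cl$n_rois, 2)
  expect_equal(length(unique(cl$cluster[1:20])), 1)
  expect_equal(length(unique(cl$cluster[21:40])), 1)

  # single tight blob -> 1 ROI
  g1 <- make_grid_state(as.matrix(expand.grid(4:8, 4:8))[1:20, ], side = 30)
  expect_equal(extract_clusters(g1, k = 5)$n_rois, 1)

  # quantile 1 with k = n - 1: nothing deleted, graph connected -> 1 ROI
  cl1 <- extract_clusters(g, k = 39, density_quantile = 1)
  expect_equal(cl1$n_rois, 1)

  # assignments are contiguous ids starting at 1
  expect_equal(sort(unique(cl$cluster)), 1:2)
})

test_that("input order does not change the recovered partition structure", {
  b <- make_blob_points(seed = 58)
  pn <- normalize_distances(b$points, diameter = 10)
  perm <- sample(nrow(pn))
  cl1 <- extract_clusters(run_ants(pn, ant_params(seed = 3)))
  cl2 <- extract_clusters(run_ants(pn[perm, ], ant_params(seed = 3)))
  expect_equal(cl1$n_rois, cl2$n_rois)
  expect_gte(adjusted_rand_index(cl1$cluster[perm], cl2$cluster), 0.9)
})

test_that("hierarchical clustering assigns every voxel within its label", {
  # two anatomical labels, each holding two distinct signal populations
  set.seed(59)
  n_time <- 40
  proto <- matrix(rnorm(n_time * 4), n_time, 4)
  sig <- function(p, n) proto[, p] %o% rep(1, n) + rnorm(n_time * n, sd = 0.01)
  lab <- structure(list(
    list(label = 3L, voxels = 1:40,
         signals = cbind(sig(1, 20), sig(2, 20))),
    list(label = 9L, voxels = 41:80,
         signals = cbind(sig(3, 20), sig(4, 20)))),
    class = "labeled_signals", spatial_dim = c(80L, 1L, 1L),
    n_time = n_time)
  names(lab) <- c("3", "9")
  parc <- hant(lab, embedding_config("pca"), ant_params(seed = 1))
  expect_equal(parc$n_rois, 4)
  expect_setequal(as.integer(names(parc$roi)), 1:80)
  # voxels from different anatomical labels never share a ROI
  roi_l1 <- unique(parc$roi[as.character(1:40)])
  roi_l2 <- unique(parc$roi[as.character(41:80)])
  expect_length(intersect(roi_l1, roi_l2), 0)
  expect_equal(sum(parc$roi_table$size), 80)
  # tiny groups become singleton ROIs
  tiny <- structure(list(list(label = 1L, voxels = 1:2,
                              signals = matrix(rnorm(80), 40, 2))),
                    class = "labeled_signals", spatial_dim = c(2L, 1L, 1L),
                    n_time = 40L)
  names(tiny) <- "1"
  parc_t <- hant(tiny, embedding_config("pca"), ant_params(seed = 1))
  expect_equal(parc_t$n_rois, 1)
})
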