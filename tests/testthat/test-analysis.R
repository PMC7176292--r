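make_fes <- function(F, bins = length(F), lo = 0, hi = bins, visited = NULL,
                     periodic = FALSE, kT = 0.6) {
  if (is.null(visited)) visited <- rep(TRUE, length(F))
  F[visited] <- F[visited] - min(F[visited])
  F[!visited] <- NA_real_
  structure(list(bins = as.integer(bins), lo = lo, hi = hi,
                 periodic = periodic, F = F, visited = visited,
                 replicate_count = 1L, kT = kT),
            class = "fes_landscape")
}

test_that("landscape averaging is the visited-cell mean, re-shifted", {
  f1 <- make_fes(c(0, 2, 4, 1))
  expect_equal(average_landscapes(list(f1))$F, f1$F)
  f2 <- make_fes(c(2, 0, 6, 3))
  av <- average_landscapes(list(f1, f2))
  expect_equal(av$F, c(1, 1, 5, 2) - 1)
  expect_equal(av$replicate_count, 2L)
  # a cell visited by only one replicate takes that replicate's value
  f3 <- make_fes(c(0, 1, NA, NA), visited = c(TRUE, TRUE, FALSE, FALSE))
  av2 <- average_landscapes(list(f1, f3))
  expect_equal(av2$F, c(0, 1.5, 4, 1))
  expect_true(all(av2$visited))
  g <- make_fes(c(0, 1), bins = 2L)
  expect_error(average_landscapes(list(f1, g)), "geometry")
})

test_that("minima detection finds planted basins with bounding boxes", {
  # single well
  x <- seq(0.5, 59.5)
  f <- make_fes((x - 20)^2 / 40, bins = 60L, lo = 0, hi = 60)
  b <- find_minima(f, depth_threshold = 3)
  expect_length(b, 1)
  expect_true(b[[1]]$lo <= 20.5 && b[[1]]$hi >= 20.5)
  # symmetric double well: two basins of equal depth
  f2 <- make_fes(3 * (1 - exp(-(x - 15)^2 / 8) - exp(-(x - 45)^2 / 8)),
                 bins = 60L, lo = 0, hi = 60)
  b2 <- find_minima(f2, depth_threshold = 3)
  expect_length(b2, 2)
  expect_equal(b2[[1]]$depth, b2[[2]]$depth, tolerance = 1e-9)
  # planted 3-minimum 2D landscape via the fixture generator
  dir <- tempfile()
  fx <- generate_fixture("planted_fes", dir = dir, seed = 4)
  fes <- read_fes(file.path(dir, "planted_fes.tsv"))
  basins <- find_minima(fes, depth_threshold = 3)
  expect_length(basins, length(fx$truth$minima))
  for (ctr in fx$truth$minima) {
    hit <- vapply(basins, function(bb)
      all(bb$lo <= ctr & ctr <= bb$hi), logical(1))
    expect_true(any(hit))
  }
})

test_that("frame extraction selects exactly the frames inside the region", {
  traj <- structure(list(
    frames = matrix(seq_len(30), ncol = 3),
    cv_trace = cbind(c(rep(1, 4), rep(5, 6)), c(rep(1, 4), rep(5, 6))),
    monitor = NULL, stride = 1L, dt = 1,
    metadata = list(kind = "synthetic", seed = 0L, n_steps = 10L,
                    biased = FALSE)), class = "trajectory")
  all_of_it <- extract_frames(traj, basin_region(c(0, 0), c(10, 10)))
  expect_equal(n_frames(all_of_it), 10)
  low <- extract_frames(traj, basin_region(c(0, 0), c(2, 2)))
  expect_equal(n_frames(low), 4)
  expect_equal(attr(low, "indices"), 1:4)
  expect_warning(empty <- extract_frames(traj, basin_region(c(8, 8), c(9, 9))),
                 "no frames")
  expect_equal(n_frames(empty), 0)
  # complement partitions the trajectory
  hi <- extract_frames(traj, basin_region(c(2.5, 2.5), c(10, 10)))
  expect_equal(sort(c(attr(low, "indices"), attr(hi, "indices"))), 1:10)
})

test_that("pose clustering follows DBSCAN semantics on boundary cases", {
  one <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 30), nrow = 30)
  cl <- cluster_poses(one, eps = 0.7, min_pts = 25)
  expect_equal(cl$n_clusters, 1L)
  expect_true(all(cl$labels == 1L))
  expect_equal(cl$representative, 1L)
  # 24 identical frames: below min_pts, everything is noise
  few <- one[1:24, , drop = FALSE]
  cl24 <- cluster_poses(few, eps = 0.7, min_pts = 25)
  expect_equal(cl24$n_clusters, 0L)
  expect_true(all(cl24$labels == 0L))
  expect_true(is.na(cl24$representative))
})

test_that("pose clustering matches the brute-force oracle on planted blobs", {
  set.seed(17)
  for (rep in 1:50) {
    n_blob <- sample(1:3, 1)
    per <- sample(c(30, 60, 100), 1)
    natoms <- 4
    frames <- NULL
    for (kcl in seq_len(n_blob)) {
      ctr <- rep(c(kcl * 5, 0, 0), natoms)
      frames <- rbind(frames, matrix(rep(ctr, per), ncol = 3 * natoms,
                                     byrow = TRUE) +
                                matrix(rnorm(per * 3 * natoms, sd = 0.1),
                                       ncol = 3 * natoms))
    }
    # sprinkle a few isolated noise frames far away
    frames <- rbind(frames,
                    matrix(rep(c(-40, 0, 0), natoms), nrow = 1) +
                      rnorm(3 * natoms, sd = 0.1))
    got <- cluster_poses(frames, eps = 0.7, min_pts = 25)
    want <- brute_dbscan(frames, eps = 0.7, min_pts = 25)
    expect_true(same_partition(got$labels, want))
    expect_equal(got$n_clusters, n_blob)
  }
})

test_that("the representative pose is the medoid of the largest cluster", {
  set.seed(18)
  blob <- matrix(rnorm(40 * 6, sd = 0.2), ncol = 6)
  cl <- cluster_poses(blob, eps = 2, min_pts = 5)
  d <- as.matrix(dist(blob)) / sqrt(2)
  sums <- colSums(d)
  expect_equal(cl$representative, unname(which.min(sums)))
})

test_that("basin occupancy integrates Boltzmann weights on the circle", {
  nb <- 300L
  th <- (seq_len(nb) - 0.5) * 2 * pi / nb
  flat <- make_fes(rep(1, nb), bins = nb, lo = 0, hi = 2 * pi,
                   periodic = TRUE)
  quarter <- basin_region(0, pi / 2)
  expect_equal(basin_occupancy(flat, quarter), 0.25, tolerance = 1e-9)
  # a 10 kT deep well inside the basin dominates
  deep <- make_fes(ifelse(abs(th - pi / 4) < 0.2, 0, 10 * 0.6),
                   bins = nb, lo = 0, hi = 2 * pi, periodic = TRUE)
  expect_gt(basin_occupancy(deep, quarter), 0.999)
  # cosine profile vs dense quadrature, incl. a wrap-around basin
  fcos <- make_fes(2 * (1 - cos(th)), bins = nb, lo = 0, hi = 2 * pi,
                   periodic = TRUE)
  wrap <- basin_region(3 * pi / 2, pi / 2) # [-pi/2, pi/2] on the circle
  f <- function(t) exp(-2 * (1 - cos(t)) / 0.6)
  want <- integrate(f, -pi / 2, pi / 2, rel.tol = 1e-10)$value /
    integrate(f, -pi, pi, rel.tol = 1e-10)$value
  expect_equal(basin_occupancy(fcos, wrap), want, tolerance = 1e-3)
  # occupancies over a partition sum to one
  parts <- list(basin_region(0, pi / 2 - 1e-9), basin_region(pi / 2, pi - 1e-9),
                basin_region(pi, 3 * pi / 2 - 1e-9),
                basin_region(3 * pi / 2, 2 * pi))
  occ <- vapply(parts, function(p) basin_occupancy(fcos, p), numeric(1))
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  # unvisited cells inside the basin are an error
  holed <- make_fes(rep(1, nb), bins = nb, lo = 0, hi = 2 * pi,
                    periodic = TRUE,
                    visited = c(rep(FALSE, 10), rep(TRUE, nb - 10)))
  expect_error(basin_occupancy(holed, quarter), "unvisited")
})

test_that("replicate averaging does not degrade the landscape estimate", {
  sys <- toy_double_well()
  x <- NULL
  not_worse <- 0L
  for (r in 1:10) {
    f1 <- free_energy_estimate(run_mabp(sys, system_grid(sys, flim = 6),
                                        4e5, stride = 100,
                                        seed = 300 + 2 * r)$grid)
    f2 <- free_energy_estimate(run_mabp(sys, system_grid(sys, flim = 6),
                                        4e5, stride = 100,
                                        seed = 301 + 2 * r)$grid)
    av <- average_landscapes(list(f1, f2))
    if (is.null(x)) {
      h <- bin_width(av)
      x <- seq(av$lo + h / 2, av$hi, by = h)
    }
    U <- system_potential(sys, x)
    rmse <- function(f) {
      w <- f$visited & abs(x) < 1.3
      sqrt(mean(((f$F[w] - min(f$F[w])) - (U[w] - min(U[w])))^2))
    }
    if (rmse(av) <= max(rmse(f1), rmse(f2))) not_worse <- not_worse + 1L
  }
  expect_gte(not_worse, 8L)
})
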