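test_that("runs are a pure function of configuration and seed", {
  sys <- toy_double_well()
  g <- system_grid(sys, flim = 6)
  a <- run_mabp(sys, g, 20000, stride = 10, seed = 42)
  b <- run_mabp(sys, g, 20000, stride = 10, seed = 42)
  expect_identical(a$trajectory$frames, b$trajectory$frames)
  expect_identical(a$grid$weight, b$grid$weight)
  c <- run_mabp(sys, g, 20000, stride = 10, seed = 43)
  expect_false(identical(a$trajectory$frames, c$trajectory$frames))
  # the input grid is not mutated by the run
  expect_true(all(g$weight == 0))
  u1 <- run_unbiased(sys, 20000, stride = 10, seed = 7)
  u2 <- run_unbiased(sys, 20000, stride = 10, seed = 7)
  expect_identical(u1$frames, u2$frames)
})

test_that("unbiased harmonic sampling satisfies equipartition", {
  h <- toy_harmonic(k = 1)
  tr <- run_unbiased(h, 1e7, stride = 1000, seed = 5)
  expect_equal(var(tr$frames[, 1]) * 1 / h$kT, 1, tolerance = 0.05)
})

test_that("unbiased double-well histogram recovers the analytic potential", {
  sys <- toy_double_well()
  tr <- run_unbiased(sys, 2e6, stride = 20, seed = 3)
  hh <- hist(tr$frames[, 1], breaks = seq(-2, 2, by = 0.05), plot = FALSE)
  keep <- is.finite(log(hh$density)) & abs(hh$mids) < 1.3
  Fh <- -sys$kT * log(hh$density[keep])
  U <- system_potential(sys, hh$mids[keep])
  expect_lt(sqrt(mean(((Fh - min(Fh)) - (U - min(U)))^2)), 0.3)
})

test_that("a bias-free grid leaves the trajectory identical to unbiased", {
  # an mABP run whose grid never receives bias force (empty, no deposits)
  # must reproduce the unbiased integrator exactly at equal seed
  sys <- toy_harmonic()
  g <- system_grid(sys, flim = 5)
  biased_off <- mabpr:::run_dynamics(sys, g, 20000, 10L, 21L, deposit = FALSE)
  unb <- run_unbiased(sys, 20000, stride = 10, seed = 21)
  expect_identical(biased_off$trajectory$frames, unb$frames)
})

test_that("mABP accelerates well crossings in a deep double well", {
  sys <- toy_double_well(h = 4)
  wellcross <- function(x) {
    s <- sign(x[abs(x) > 0.8])
    sum(diff(s) != 0)
  }
  for (seed in 1:3) {
    unb <- wellcross(run_unbiased(sys, 1e6, stride = 10,
                                  seed = seed)$frames[, 1])
    bia <- wellcross(run_mabp(sys, system_grid(sys, flim = 8), 1e6,
                              stride = 10, seed = seed)$trajectory$frames[, 1])
    expect_lte(unb, 10)
    expect_gte(bia, 10)
    expect_gt(bia, 2 * unb)
  }
})

test_that("the 2D landscape of a Mueller-Brown-type surface is recovered", {
  mb <- toy_mueller_brown()
  res <- run_mabp(mb, system_grid(mb, flim = 8), 2e6, stride = 100, seed = 5)
  fes <- free_energy_estimate(res$grid)
  U <- analytic_fes(mb, fes)
  low <- fes$visited & U < 3 # the wells and connecting valley
  expect_gt(sum(low), 200)
  dF <- fes$F[low] - min(fes$F[low])
  dU <- U[low] - min(U[low])
  expect_lt(sqrt(mean((dF - dU)^2)), 0.5)
})

test_that("CV traces are recomputable from stored frames", {
  sys <- toy_double_well()
  tr <- run_mabp(sys, system_grid(sys, flim = 6), 5e4, stride = 10,
                 seed = 2)$trajectory
  expect_identical(tr$cv_trace, tr$frames)
  hg <- toy_host_guest()
  thg <- run_mabp(hg, system_grid(hg, flim = 10), 5e4, stride = 10,
                  seed = 2)$trajectory
  recomputed <- t(apply(thg$frames, 1, function(fr) {
    xm <- matrix(fr, ncol = 3, byrow = TRUE)
    c(rms_distance_cv(xm[1:2, ], hg$hg$refA),
      rms_distance_cv(xm[3:4, ], hg$hg$refB))
  }))
  expect_equal(unname(thg$cv_trace), unname(recomputed), tolerance = 1e-12)
})

test_that("compiled host-guest forces match finite differences of the energy", {
  sys <- toy_host_guest()
  set.seed(31)
  for (i in 1:20) {
    x <- sys$x0 + rnorm(12, sd = 2)
    got <- hostguest_energy_cpp(sys$hg, x)
    expect_equal(got$energy, r_hostguest_energy(sys, x), tolerance = 1e-10)
    fd <- -fd_grad(function(v) r_hostguest_energy(sys, v), x, h = 1e-6)
    expect_equal(got$force, fd, tolerance = 1e-5)
  }
})

test_that("restraints confine the ligand centroid to the cylinder", {
  hg <- toy_host_guest()
  res <- run_mabp(hg, system_grid(hg, flim = 10), 5e5, stride = 10, seed = 3)
  fr <- res$trajectory$frames
  rho <- sqrt(rowMeans(fr[, c(1, 4, 7, 10)])^2 +
              rowMeans(fr[, c(2, 5, 8, 11)])^2)
  # soft flat-bottom wall: penetration beyond 1 A is vanishingly rare
  expect_lt(mean(rho > hg$hg$cyl_R + 1), 0.001)
})

test_that("numerical blow-up aborts with a diagnostic", {
  sys <- toy_harmonic(k = 1, dt = 10) # grossly unstable step
  expect_error(run_unbiased(sys, 1000, stride = 10, seed = 1), "blow-up")
})

test_that("trajectories round-trip through XYZ and CV-trace files", {
  hg <- toy_host_guest()
  tr <- run_mabp(hg, system_grid(hg, flim = 10), 2e4, stride = 100,
                 seed = 9)$trajectory
  xyz <- tempfile(fileext = ".xyz")
  cvf <- tempfile(fileext = ".tsv")
  write_xyz(tr, xyz)
  write_cv_trace(tr, cvf)
  back <- read_xyz(xyz)
  expect_equal(dim(back$frames), dim(tr$frames))
  expect_equal(back$frames, unname(tr$frames), tolerance = 1e-5)
  cv <- read_cv_trace(cvf)
  expect_equal(cv$cv1, tr$cv_trace[, 1], tolerance = 1e-12)
  expect_equal(cv$monitor_A, tr$monitor, tolerance = 1e-12)
})
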