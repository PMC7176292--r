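test_that("grid construction computes bin widths and rejects bad configs", {
  g <- make_grid(c(480L, 480L), list(c(0, 60), c(0, 60)))
  expect_identical(bin_width(g), c(0.125, 0.125))
  expect_equal(bin_width(make_grid(300L, c(0, 2 * pi), periodic = TRUE,
                                   b = 0.8, c = 0.1, alpha = 5L)),
               2 * pi / 300)
  # empty grid has zero bias everywhere
  expect_true(all(bias_potential_and_force(g, cbind(runif(5, 0, 60),
                                                    runif(5, 0, 60)))$energy == 0))
  expect_error(make_grid(30L, c(0, 10), alpha = 15L), "wider than grid")
  expect_error(make_grid(100L, c(5, 5)), "hi > lo")
  expect_error(make_grid(100L, c(0, 1), b = 1.2), "'b'")
  expect_error(make_grid(100L, c(0, 1), c = 0), "'c'")
  expect_error(make_grid(100L, c(0, 1), flim = -1), "'flim'")
  expect_error(make_grid(100L, c(0, 1), kT = 0), "'kT'")
})

test_that("mollifier kernel is symmetric, compact and unit-mass", {
  for (a in c(1L, 3L, 5L, 20L)) {
    w <- mollifier_profile(a)
    expect_length(w, 2 * a + 1)
    expect_equal(sum(w), 1)
    expect_equal(w, rev(w))
    expect_true(all(w >= 0))
    expect_equal(w[1], 0) # vanishes at the support boundary
  }
})

test_that("a single deposit places a symmetric kernel at the center cell", {
  g <- make_grid(101L, c(0, 101), alpha = 5L, flim = 50)
  g <- deposit(g, 50.5) # center of cell 51
  w <- mollifier_profile(5L)
  expect_equal(g$weight[51], w[6])
  expect_equal(g$weight[46:56], w)
  expect_equal(sum(g$weight), 1) # g = 1 on an empty grid
  expect_equal(g$step_count, 1L)
})

test_that("deposits conserve kernel mass up to edge truncation", {
  g <- make_grid(50L, c(0, 50), alpha = 4L, flim = 100)
  g1 <- deposit(g, 25)
  expect_equal(sum(g1$weight), attr(g1, "g"))
  # at the edge the out-of-range kernel tail is truncated
  g2 <- deposit(g, 0.1)
  w <- mollifier_profile(4L)
  expect_equal(sum(g2$weight), sum(w[5:9]) * attr(g2, "g"))
  expect_identical(attr(g2, "n_clamped"), 0L)
  # out-of-range points clamp to the edge cell and are flagged
  g3 <- deposit(g, -3)
  expect_identical(attr(g3, "n_clamped"), 1L)
  expect_equal(which.max(g3$weight), 1L)
  expect_error(deposit(g, NaN), "non-finite")
})

test_that("overfill protection caps the center-cell bias at flim", {
  g <- make_grid(60L, c(0, 6), alpha = 3L, flim = 0.5, c = 1)
  for (i in 1:400) g <- deposit(g, 3.05)
  V <- g$b * g$kT * log1p(g$c * g$weight)
  expect_lte(max(V), g$flim + 1e-12)
  # converged: the cap is actually attained
  expect_gt(max(V), 0.45)
  # once at flim, further deposits add nothing
  before <- sum(g$weight)
  g <- deposit(g, 3.05)
  expect_equal(attr(g, "g"), 0)
  expect_equal(sum(g$weight), before)
})

test_that("uniform deposits reproduce the brute-force kernel histogram", {
  set.seed(91)
  n <- 10000
  xs <- runif(n, 0, 30)
  g <- make_grid(60L, c(0, 30), periodic = TRUE, alpha = 5L, flim = 1e6)
  g <- deposit(g, matrix(xs, ncol = 1))
  oracle <- brute_kernel_hist(xs, 60L, 0, 30, 5L, periodic = TRUE)
  # far below the fill limit the overfill scale is 1 - O(V/flim) ~ 1 - 1e-7:
  # the accumulated field matches the unscaled kernel histogram to that order
  expect_equal(g$weight, oracle, tolerance = 1e-6)
  # and the mollified density is flat within 3 sigma multinomial error
  p <- 1 / 60
  expect_true(all(abs(g$weight / n - p) < 3 * sqrt(p * (1 - p) / n) + 3 / n))
})

test_that("periodic deposits wrap: 0+eps and 2pi-eps give mirrored fields", {
  ga <- make_grid(300L, c(0, 2 * pi), periodic = TRUE, alpha = 5L,
                  b = 0.8, c = 0.1, flim = 10)
  gb <- deposit(ga, 2 * pi - 1e-9)
  ga <- deposit(ga, 1e-9)
  expect_equal(ga$weight, rev(gb$weight), tolerance = 1e-12)
})

test_that("bias interpolation is exact at centers and linear between them", {
  g <- make_grid(10L, c(0, 10), alpha = 2L, flim = 100)
  # hand-build weights giving V = 1 and 3 kcal/mol in cells 4 and 5
  V_target <- c(1, 3)
  g$weight[4:5] <- (exp(V_target / (g$b * g$kT)) - 1) / g$c
  at4 <- bias_potential_and_force(g, 3.5)
  expect_equal(at4$energy, 1)
  mid <- bias_potential_and_force(g, 4.0) # halfway between centers 3.5, 4.5
  expect_equal(mid$energy, 2)
  expect_equal(mid$gradient[1, 1], (3 - 1) / 1)
  # beyond the edge: clamped value, zero outward gradient
  out <- bias_potential_and_force(g, 12)
  expect_equal(out$energy, bias_potential_and_force(g, 9.5)$energy)
  expect_equal(out$gradient[1, 1], 0)
})

test_that("free-energy estimation flags unvisited cells and flat landscapes", {
  g <- make_grid(20L, c(0, 20), alpha = 2L, flim = 10)
  expect_error(free_energy_estimate(g), "no sampling")
  for (x in c(5.5, 10.5, 15.5)) g <- deposit(g, x)
  fes <- free_energy_estimate(g)
  expect_s3_class(fes, "fes_landscape")
  expect_equal(min(fes$F[fes$visited]), 0)
  expect_true(all(is.na(fes$F[!fes$visited])))
  expect_identical(fes$visited, g$weight > 0)
  # equal weight everywhere visited => flat landscape
  g2 <- make_grid(20L, c(0, 20), alpha = 2L, flim = 10)
  g2$weight[5:10] <- 7
  f2 <- free_energy_estimate(g2)
  expect_equal(f2$F[f2$visited], rep(0, 6))
})

test_that("checkpoints and FES tables round-trip through their file formats", {
  g <- make_grid(c(30L, 40L), list(c(0, 3), c(-1, 1)),
                 periodic = c(FALSE, TRUE), alpha = 3L, flim = 7,
                 b = 0.85, c = 0.02, kT = 0.61)
  set.seed(5)
  g <- deposit(g, cbind(runif(200, 0, 3), runif(200, -1, 1)))
  path <- tempfile(fileext = ".mabp")
  write_checkpoint(g, path)
  g2 <- read_checkpoint(path)
  expect_equal(g2[names(g2) != "weight"], g[names(g) != "weight"])
  expect_identical(g2$weight, g$weight) # float64 block is lossless
  fes <- free_energy_estimate(g)
  fpath <- tempfile(fileext = ".tsv")
  write_fes(fes, fpath)
  f2 <- read_fes(fpath)
  expect_equal(f2$F, fes$F, tolerance = 1e-12)
  expect_identical(f2$visited, fes$visited)
  expect_equal(f2$bins, fes$bins)
  expect_identical(f2$periodic, fes$periodic)
})
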