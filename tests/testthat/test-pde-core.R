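# Solver verification against closed-form oracles. The expected values here
# are computed from independent formulas (error function, Fourier series,
# Gaussian moments), never from the solver itself.

test_that("uniform field with no-flux boundaries is a fixed point", {
  m <- mesh1d(1e-3, 32)
  fs <- solve_diffusion(m, 0.5e6, 1e-10, bc_no_flux(), bc_no_flux(),
                        times = c(0, 100, 1000))
  expect_lt(max(abs(fs$values - 0.5e6)) / 0.5e6, 1e-12)
})

test_that("diffusion matches the semi-infinite erf solution", {
  kap <- 1e-10; tend <- 400
  Lc <- sqrt(4 * kap * tend)
  m <- mesh1d(10 * Lc, 800)
  fs <- solve_diffusion(m, -0.2e6, kap, bc_fixed(0), bc_no_flux(),
                        times = c(0, tend), theta = 0.5, n_sub = 200)
  exact <- -0.2e6 * erf(m$centers / Lc)
  expect_lt(max(abs(fs$values[2, ] - exact)) / 0.2e6, 1e-4)
  # the printed spot value: P(x = sqrt(4 kappa t)) = -0.2 erf(1) MPa
  p1 <- stats::approx(m$centers, fs$values[2, ], xout = Lc)$y
  expect_equal(p1, -0.2e6 * erf(1), tolerance = 1e-3)
  expect_equal(-0.2 * erf(1), -0.16854, tolerance = 1e-4) # frozen oracle value
})

test_that("slab uptake matches the Fourier-series oracle", {
  W <- 2e-4; kap <- 1e-10
  m <- mesh1d(W, 256)
  for (sdim in c(0.05, 0.2, 1)) {
    t <- sdim * W^2 / kap
    fs <- solve_diffusion(m, 0, kap, bc_fixed(1), bc_no_flux(),
                          times = c(0, t), theta = 0.5, n_sub = 400)
    expect_equal(mean(fs$values[2, ]), slab_uptake_fraction(kap, W, t),
                 tolerance = 1e-4, info = paste("kt/W^2 =", sdim))
  }
})

test_that("slab_uptake_fraction limits and frozen value", {
  expect_equal(slab_uptake_fraction(1, 1, 1e-12), 0, tolerance = 1e-5)
  expect_equal(slab_uptake_fraction(1, 1, 50), 1, tolerance = 1e-12)
  # value computed from the series itself and cross-checked against a
  # fine Crank-Nicolson PDE solve during development
  expect_equal(slab_uptake_fraction(1, 1, 0.32), 0.6319, tolerance = 1e-4)
  # monotone in t
  tt <- 10^seq(-4, 1, length.out = 40)
  expect_true(all(diff(slab_uptake_fraction(1, 1, tt)) > 0))
})

test_that("grid refinement reduces erf-oracle L2 error by >= 3x per halving", {
  kap <- 1e-10; tend <- 400
  Lc <- sqrt(4 * kap * tend)
  err <- vapply(c(100, 200, 400), function(n) {
    m <- mesh1d(10 * Lc, n)
    fs <- solve_diffusion(m, -0.2e6, kap, bc_fixed(0), bc_no_flux(),
                          times = c(0, tend), theta = 0.5, n_sub = 400)
    sqrt(mean((fs$values[2, ] + 0.2e6 * erf(m$centers / Lc))^2))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})

test_that("fully implicit diffusion obeys the discrete maximum principle", {
  m <- mesh1d(1e-3, 64)
  set.seed(42)
  init <- runif(64, -2e5, 6e5)
  bcv <- 1e5
  fs <- solve_diffusion(m, init, 1e-9, bc_fixed(bcv), bc_no_flux(),
                        times = c(0, 10^(0:4)), theta = 1)
  lo <- min(init, bcv); hi <- max(init, bcv)
  expect_true(all(fs$values >= lo - 1e-6 * (hi - lo)))
  expect_true(all(fs$values <= hi + 1e-6 * (hi - lo)))
})

test_that("pure advection translates a pulse at the exact speed", {
  m <- mesh1d(0.02, 400)
  init <- exp(-((m$centers - 0.004) / 5e-4)^2)
  fs <- advect_diffuse(m, init, 1e-4, 0, bc_no_flux(), bc_no_flux(),
                       times = c(0, 100))
  centroid <- function(v) sum(m$centers * v) / sum(v)
  expect_equal(centroid(fs$values[2, ]) - centroid(fs$values[1, ]), 1.0e-2,
               tolerance = 1e-3)
  # mass conserved to roundoff with closed boundaries
  mass <- attr(fs, "mass")
  expect_lt(abs(mass[2] - mass[1]) / mass[1], 1e-10)
})

test_that("advect_diffuse with u = 0 reduces to solve_diffusion", {
  m <- mesh1d(1e-3, 128)
  init <- exp(-((m$centers - 5e-4) / 1e-4)^2)
  times <- c(0, 200, 400)
  a <- advect_diffuse(m, init, 0, 1e-10, bc_no_flux(), bc_no_flux(),
                      times = times)
  d <- solve_diffusion(m, init, 1e-10, bc_no_flux(), bc_no_flux(),
                       times = times, theta = 1)
  expect_lt(max(abs(a$values - d$values)), 1e-8)
})

test_that("point release spreads with sd = sqrt(2 D t)", {
  D <- 1e-10; tend <- 400
  m <- mesh1d(4e-3, 2000)
  init <- numeric(2000); init[1000] <- 1 / m$dx
  fs <- advect_diffuse(m, init, 0, D, bc_no_flux(), bc_no_flux(),
                       times = c(0, seq(1, tend, length.out = 80)))
  v <- fs$values[nrow(fs$values), ]
  mu <- sum(m$centers * v) / sum(v)
  sdev <- sqrt(sum((m$centers - mu)^2 * v) / sum(v))
  expect_equal(sdev, sqrt(2 * D * tend), tolerance = 0.02)
  expect_equal(sqrt(2 * D * tend), 2.83e-4, tolerance = 1e-3)
})

test_that("mirror symmetry: reversed velocity on mirrored initial condition", {
  m <- mesh1d(0.02, 200)
  init <- exp(-((m$centers - 0.006) / 8e-4)^2)
  fwd <- advect_diffuse(m, init, 5e-5, 1e-9, bc_no_flux(), bc_no_flux(),
                        times = c(0, 50, 100), auto_refine = FALSE)
  mir <- advect_diffuse(m, rev(init), -5e-5, 1e-9, bc_no_flux(), bc_no_flux(),
                        times = c(0, 50, 100), auto_refine = FALSE)
  expect_lt(max(abs(fwd$values - mir$values[, 200:1])), 1e-10)
})

test_that("conductance boundary relaxes the field to the far value", {
  # slab coupled to a reservoir through a boundary conductance: the content
  # equilibrates to far_value, with initial rate g (f_far - f0) / length
  m <- mesh1d(1e-3, 32)
  g <- 1e-7; far <- 2e5
  fs <- solve_diffusion(m, 0, 1e-8, bc_conductance(g, far), bc_no_flux(),
                        times = c(0, 10, 3e5), theta = 1, n_sub = 120)
  expect_equal(mean(fs$values[3, ]), far, tolerance = 1e-6)
  rate0 <- mean(fs$values[2, ]) / 10
  expect_equal(rate0, g * far / m$length, tolerance = 0.05)
})

test_that("invalid inputs are rejected, not regularized", {
  m <- mesh1d(1e-3, 16)
  expect_error(solve_diffusion(m, c(NA, rep(0, 15)), 1e-10, bc_no_flux(),
                               bc_no_flux(), times = c(0, 1)), "non-finite")
  expect_error(solve_diffusion(m, 0, 1e-10, bc_no_flux(), bc_no_flux(),
                               times = c(0, 1), theta = 0.2), "theta")
  expect_error(mesh1d(1e-3, 4), "n_cells >= 8")
  expect_error(field_series(m, c(1, 2), matrix(0, 2, 16)), "start at 0")
})
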