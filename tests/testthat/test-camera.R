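test_that("attenuation factor: limits, closed form and monotonicity", {
  mu0 <- array(0, c(8, 8, 8))
  expect_equal(attenuation_factor(mu0, voxel_size_mm = 4),
               array(1, c(8, 8, 8)))

  # uniform mu = 0.1/cm, single +x ray, voxel 10 mm from the boundary
  mu <- array(0.1, c(8, 8, 8))
  f <- attenuation_factor(mu, directions = list(c(1, 0, 0)),
                          voxel_size_mm = 4)
  expect_equal(f[6, 4, 4], exp(-0.1 * 1.0), tolerance = 1e-12)

  f2 <- attenuation_factor(2 * mu, directions = list(c(1, 0, 0)),
                           voxel_size_mm = 4)
  expect_true(all(f2 <= f + 1e-15))

  expect_error(attenuation_factor(mu, directions = list(), voxel_size_mm = 4),
               "non-empty")
})

test_that("axis ray integrals match an independent scalar-loop oracle", {
  set.seed(4)
  d <- c(6, 5, 7)
  mu <- array(stats::runif(prod(d), 0, 0.3), d)
  vox <- c(3, 4, 5)
  f <- attenuation_factor(mu, directions = list(c(0, 1, 0)),
                          voxel_size_mm = vox)
  # oracle: exact piecewise-constant integral, literal triple loop
  oracle <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    path <- 0.5 * mu[i, j, k]
    if (j < d[2]) path <- path + sum(mu[i, (j + 1):d[2], k])
    oracle[i, j, k] <- exp(-path * vox[2] / 10)
  }
  expect_equal(f, oracle, tolerance = 1e-12)
})

test_that("Chang correction inverts a matching attenuation exactly", {
  ph <- make_hoffman_like(SMALL, VOX)
  fac <- attenuation_factor(ph)
  img <- ph$activity * fac
  rec <- chang_correction(img, ph, chang_mu = 0.1)
  expect_equal(rec[ph$labels > 0], ph$activity[ph$labels > 0],
               tolerance = 1e-12)

  # mu == 0 is the identity
  ph0 <- ph; ph0$attenuation[] <- 0
  expect_equal(chang_correction(img, ph0, chang_mu = 0), img)

  # mismatched coefficients leave the closed-form residual, single +x ray
  mu <- array(0.1, c(8, 8, 8))
  att <- attenuation_factor(mu, directions = list(c(1, 0, 0)),
                            voxel_size_mm = 4)
  half <- attenuation_factor(mu / 2, directions = list(c(1, 0, 0)),
                             voxel_size_mm = 4)
  img8 <- array(7, c(8, 8, 8)) * att
  res <- img8 / half
  path_cm <- (8 - seq_len(8) + 0.5) * 4 / 10
  expected <- 7 * exp(-0.05 * path_cm)
  expect_equal(res[, 4, 4], expected, tolerance = 1e-12)
})

test_that("Butterworth filter: DC gain, half-power point, Nyquist warning", {
  const <- array(3.2, c(16, 16, 16))
  expect_equal(butterworth_filter(const, 0.5, 8, 10), const,
               tolerance = 1e-12)

  # a pure sinusoid at the cut-off frequency is attenuated by 1/sqrt(2)
  n <- 32; dx <- 3.5; k <- 4
  fx <- k / (n * dx) * 10                       # cycles/cm
  x1 <- sin(2 * pi * k * (0:(n - 1)) / n)
  img <- array(rep(x1, times = n * n), c(n, n, n))
  out <- butterworth_filter(img, fx, order = 8, voxel_size_mm = dx)
  expect_equal(out, img / sqrt(2), tolerance = 1e-10)

  expect_warning(butterworth_filter(const, 100, 8, 10), "Nyquist")
  expect_error(butterworth_filter(const, -1, 8, 10), "positive")
})

test_that("filter output equals a literal DFT-matrix oracle", {
  set.seed(7)
  n <- 16; vox <- 4
  x <- array(stats::rnorm(n^3), c(n, n, n))
  got <- butterworth_filter(x, 0.6, order = 6, voxel_size_mm = vox)

  # independent oracle: explicit DFT matrices, H from first principles
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  Winv <- Conj(W) / n
  dft_axis <- function(a, axis, M) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = n)
    aperm(array(M %*% m, dim(a)[perm]), order(perm))
  }
  X <- dft_axis(dft_axis(dft_axis(x + 0i, 1, W), 2, W), 3, W)
  kk <- 0:(n - 1); kk[kk > n / 2] <- kk[kk > n / 2] - n
  fax <- kk / (n * vox) * 10
  fr <- sqrt(outer(outer(fax^2, fax^2, "+"), fax^2, "+"))
  H <- 1 / sqrt(1 + (fr / 0.6)^12)
  Y <- X * H
  oracle <- Re(dft_axis(dft_axis(dft_axis(Y, 1, Winv), 2, Winv), 3, Winv))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("acquisition chain degenerates to proportionality and is seeded", {
  ph <- make_hoffman_like(SMALL, VOX)
  ph$attenuation[] <- 0                       # no attenuation
  cam <- ideal_camera()
  sv <- acquire_quiet(ph, cam, attenuation_correction = FALSE)
  expect_equal(sv$counts, ph$activity, tolerance = 1e-10)

  # determinism: same seed, same inputs -> bit-identical (Poisson + session)
  ph2 <- make_hoffman_like(SMALL, VOX)
  cam2 <- ideal_camera(count_budget = 2e5)
  a <- acquire_quiet(ph2, cam2, seed = 5, session_cv = 0.04)
  b <- acquire_quiet(ph2, cam2, seed = 5, session_cv = 0.04)
  expect_identical(a$counts, b$counts)

  # two cameras with identical parameters produce identical images
  cam3 <- ideal_camera(id = "other", count_budget = 2e5)
  c2 <- acquire_quiet(ph2, cam3, seed = 5, session_cv = 0.04)
  expect_identical(a$counts, c2$counts)
})

test_that("attenuate-then-correct matches the unattenuated acquisition", {
  ph <- make_hoffman_like(SMALL, VOX)
  cam <- ideal_camera()
  with_att <- acquire_quiet(ph, cam, attenuation_correction = TRUE)
  ph0 <- ph; ph0$attenuation[] <- 0
  without <- acquire_quiet(ph0, cam, attenuation_correction = FALSE)
  brain <- ph$labels > 0
  expect_equal(with_att$counts[brain], without$counts[brain],
               tolerance = 1e-8)
})

test_that("Poisson stage is calibrated: variance/mean near 1 on uniform fill", {
  pool <- make_pool(SMALL, VOX)
  cam <- ideal_camera(count_budget = 5e5)
  sv <- acquire_quiet(pool, cam, attenuation_correction = FALSE, seed = 3)
  interior <- ellipsoid_interior <- pool$labels > 0 &
    gaussian_smooth(array(as.numeric(pool$labels > 0), dim(pool$labels)),
                    15, VOX) > 0.999           # away from the edge
  vals <- sv$counts[interior]
  ratio <- stats::var(vals) / mean(vals)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)

  # expected total counts scale with the budget
  cam2 <- ideal_camera(count_budget = 1e6)
  sv2 <- acquire_quiet(pool, cam2, attenuation_correction = FALSE, seed = 3)
  expect_equal(sum(sv2$counts) / sum(sv$counts), 2, tolerance = 0.05)
})
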