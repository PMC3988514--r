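test_that("pooled t map matches the hand-computed example", {
  d <- c(6, 6, 6)
  mask <- array(TRUE, d)
  mk <- function(v) subject_volume(array(v, d), c(2, 2, 2))
  a <- lapply(c(52, 48, 50), mk)
  b <- lapply(c(40, 44, 42), mk)
  dm <- two_sample_tmap(a, b, mask, extent_voxels = 1)
  expect_equal(dm$t[1, 1, 1], 8 / sqrt(4 * (1 / 3 + 1 / 3)),
               tolerance = 1e-12)
  expect_equal(dm$df, 4)

  same <- two_sample_tmap(a, a, mask, extent_voxels = 1)
  expect_true(all(same$t == 0))
  expect_false(any(same$decrease_mask) || any(same$increase_mask))
  expect_error(two_sample_tmap(a[1], b, mask), "at least 2")
})

test_that("t map equals a per-voxel t.test loop on a random fixture", {
  set.seed(12)
  d <- c(8, 8, 8)
  mask <- array(TRUE, d)
  a <- lapply(1:4, function(i) array(stats::rnorm(prod(d), 10, 2), d))
  b <- lapply(1:3, function(i) array(stats::rnorm(prod(d), 11, 2), d))
  dm <- two_sample_tmap(a, b, mask, extent_voxels = 1)
  oracle <- array(NA_real_, d)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    av <- vapply(a, function(x) x[i, j, k], numeric(1))
    bv <- vapply(b, function(x) x[i, j, k], numeric(1))
    oracle[i, j, k] <- stats::t.test(av, bv, var.equal = TRUE)$statistic
  }
  expect_equal(dm$t, oracle, tolerance = 1e-10)
  tc <- stats::qt(0.95, 5)
  expect_identical(dm$decrease_raw, dm$t >= tc & mask)
  expect_identical(dm$increase_raw, dm$t <= -tc & mask)
})

test_that("extent filtering removes small clusters without splitting large", {
  d <- c(12, 12, 12)
  mask <- array(FALSE, d)
  mask[2:5, 2:5, 2:5] <- TRUE                  # 64-voxel block
  mask[9, 9, 9:11] <- TRUE                     # 3-voxel run
  kept <- spectharm:::filter_small_components(mask, 50, 26)
  big <- array(FALSE, d); big[2:5, 2:5, 2:5] <- TRUE
  expect_identical(kept, big)
  expect_true(all(kept[mask] | !kept[mask]))   # never adds voxels
  expect_true(!any(kept & !mask))

  # diagonal contact merges under 26- but not 6-connectivity
  two <- array(FALSE, d)
  two[2:3, 2:3, 2:3] <- TRUE
  two[4:5, 4:5, 4:5] <- TRUE
  lab26 <- spectharm:::label_components(two, 26)
  lab6 <- spectharm:::label_components(two, 6)
  expect_equal(max(lab26), 1)
  expect_equal(max(lab6), 2)
  expect_identical(spectharm:::filter_small_components(two, 10, 26), two)
  expect_identical(spectharm:::filter_small_components(two, 10, 6),
                   array(FALSE, d))
})

test_that("central/marginal partition halves the brain and splits a diff", {
  base <- make_brain_like(SMALL, VOX)
  brain <- base$labels > 0
  part <- partition_central_marginal(brain, voxel_size_mm = VOX)
  expect_identical(part$central | part$marginal, brain)
  expect_false(any(part$central & part$marginal))
  nb <- sum(brain)
  expect_lt(abs(sum(part$central) - sum(part$marginal)) / nb, 0.05)

  deep <- part$central & !part$marginal
  p2 <- partition_central_marginal(brain, diff_mask = deep,
                                   voxel_size_mm = VOX)
  expect_identical(p2$central_diff, deep)
  expect_false(any(p2$marginal_diff))
  expect_error(partition_central_marginal(array(FALSE, SMALL)), "empty")
})

test_that("region mean Z and region correlations match hand oracles", {
  d <- c(3, 1, 1)
  z <- array(c(1, 2, 3), d)
  expect_equal(region_mean_z(z, array(TRUE, d)), 2)
  expect_error(region_mean_z(z, array(FALSE, d)), "empty")

  base <- make_brain_like(SMALL, VOX)
  brain <- base$labels > 0
  atlas <- make_region_atlas(brain, VOX)
  expect_setequal(unique(as.integer(atlas$labels[brain])), 1:5)

  set.seed(3)
  a <- array(stats::runif(prod(SMALL), 1, 9), SMALL)
  self <- region_correlation(a, a, atlas)
  expect_true(all(abs(self$corr - 1) < 1e-12))

  # region-wise negation about the region mean gives -1 everywhere
  b <- a
  for (l in atlas$regions) {
    m <- atlas$labels == l
    b[m] <- 2 * mean(a[m]) - a[m]
  }
  neg <- region_correlation(a, b, atlas,
                            region_ids = names(atlas$regions))
  expect_true(all(abs(neg$corr + 1) < 1e-12))

  flat <- array(1, SMALL)
  zv <- region_correlation(a, flat, atlas, region_ids = "frontal")
  expect_true(is.na(zv$corr))

  tiny <- array(0L, SMALL); tiny[1:2] <- 1L
  expect_error(region_correlation(a, a, tiny), "fewer than 3")

  # independent scalar Pearson oracle on one region
  m <- atlas$labels == atlas$regions[["occipital"]]
  va <- a[m]; vb <- (a * 1.3 + 0.2)[m] + stats::rnorm(sum(m), 0, 0.1)
  b2 <- a * 1.3 + 0.2; b2[m] <- vb
  got <- region_correlation(a, b2, atlas, region_ids = "occipital")$corr
  ora <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(got, ora, tolerance = 1e-12)
})

test_that("evaluation is invariant to a common rescaling after normalization", {
  base <- make_brain_like(SMALL, VOX)
  brain <- base$labels > 0
  cohort <- as_subjects(make_subject_cohort(base, 4, seed = 19))
  norm <- lapply(cohort, global_normalize, brain_mask = brain, target = 50)
  scaled <- lapply(cohort, function(s) { s$counts <- s$counts * 7; s })
  norm_s <- lapply(scaled, global_normalize, brain_mask = brain, target = 50)
  dm1 <- two_sample_tmap(norm[1:2], norm[3:4], brain, extent_voxels = 1)
  dm2 <- two_sample_tmap(norm_s[1:2], norm_s[3:4], brain, extent_voxels = 1)
  expect_equal(dm1$t, dm2$t, tolerance = 1e-9)
})
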