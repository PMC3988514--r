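test_that("proportional normalization hits the target exactly", {
  d <- c(8, 8, 8)
  mask <- array(TRUE, d)
  sv <- subject_volume(array(25, d), c(2, 2, 2))
  out <- global_normalize(sv, mask, 50)
  expect_true(all(out$counts == 50))

  set.seed(2)
  rnd <- subject_volume(array(stats::runif(prod(d), 1, 9), d), c(2, 2, 2))
  n1 <- global_normalize(rnd, mask, 50)
  expect_equal(mean(n1$counts[mask]), 50, tolerance = 1e-9)
  n2 <- global_normalize(n1, mask, 50)
  expect_equal(n2$counts, n1$counts, tolerance = 1e-12)

  zero <- subject_volume(array(0, d), c(2, 2, 2))
  expect_error(global_normalize(zero, mask), "not positive")
})

test_that("normal database: two-point SD, floors and target mean", {
  d <- c(6, 6, 6)
  mask <- array(FALSE, d); mask[3, 3, 3] <- mask[4, 4, 4] <- TRUE
  v1 <- array(0, d); v1[3, 3, 3] <- 40; v1[4, 4, 4] <- 60
  v2 <- array(0, d); v2[3, 3, 3] <- 60; v2[4, 4, 4] <- 40
  subs <- list(subject_volume(v1, c(2, 2, 2)), subject_volume(v2, c(2, 2, 2)))
  ndb <- build_ndb(subs, mask, smoothing_fwhm_mm = 0,
                   sd_floor_fraction = 0.1)
  expect_equal(ndb$mean[3, 3, 3], 50)
  expect_equal(ndb$sd[3, 3, 3], sqrt(200), tolerance = 1e-9)

  # identical subjects: every masked SD sits at the (positive) floor
  same <- list(subs[[1]], subs[[1]], subs[[1]])
  flat <- build_ndb(same, mask, smoothing_fwhm_mm = 0,
                    sd_floor_fraction = 0.1)
  expect_true(all(flat$sd[mask] == flat$sd_floor))
  expect_gt(flat$sd_floor, 0)
  expect_error(build_ndb(subs[1], mask), "at least 2")
})

test_that("cohort NDB variability reflects the generator's CV", {
  base <- make_brain_like(SMALL, VOX)
  cohort <- make_subject_cohort(base, 20, between_subject_cv = 0.08,
                                local_cv = 0.05, seed = 5)
  brain <- base$labels > 0
  ndb <- build_ndb(as_subjects(cohort), brain, smoothing_fwhm_mm = 0)
  expect_equal(mean(ndb$mean[brain]), ndb$normalization_target,
               tolerance = 1e-6)
  med_cv <- stats::median(ndb$sd[brain] / ndb$mean[brain])
  gen_cv <- 0.05   # the global scalar is removed by normalization
  expect_gt(med_cv, 0.5 * gen_cv)
  expect_lt(med_cv, 2 * gen_cv)
})

test_that("Z map arithmetic and sign convention", {
  d <- c(6, 6, 6)
  mask <- array(TRUE, d)
  ndb <- structure(list(mean = array(50, d), sd = array(5, d), n = 10,
                        brain_mask = mask, normalization_target = 50,
                        smoothing_fwhm_mm = 0, sd_floor = 0.5,
                        camera_id = "x", voxel_size_mm = c(2, 2, 2)),
                   class = "ndb")
  self <- subject_volume(array(50, d), c(2, 2, 2))
  expect_true(all(zscore_map(self, ndb)$z == 0))

  low <- subject_volume(array(40, d), c(2, 2, 2))
  z <- zscore_map(low, ndb)
  expect_true(all(z$z == 2))                  # decrease -> positive Z
})

test_that("lesioned NDB mean recovers the closed-form Z inside the VOI", {
  base <- make_brain_like(SMALL, VOX)
  cohort <- make_subject_cohort(base, 15, seed = 8)
  brain <- base$labels > 0
  ndb <- build_ndb(as_subjects(cohort), brain, smoothing_fwhm_mm = 12)
  voi <- default_sva_voi(brain, VOX)
  subj <- subject_volume(ndb$mean, VOX, subject_id = "mean_subject")
  les <- apply_ad_lesion(subj, voi, 0.2)
  z <- zscore_map(les, ndb)
  expect_equal(mean(z$z[voi]), mean(0.2 * ndb$mean[voi] / ndb$sd[voi]),
               tolerance = 1e-6)
  expect_true(all(z$z[brain & !voi] == 0))
})

test_that("display threshold zeroes sub-threshold Z only", {
  d <- c(4, 1, 1)
  z <- array(c(1.4, 1.5, -2, 0.2), d)
  zm <- make_zmap(z, array(TRUE, d))
  expect_equal(as.vector(threshold_zmap(zm, 1.5)$z), c(0, 1.5, -2, 0))
  expect_equal(threshold_zmap(zm, 0)$z, z)
  n_surv <- vapply(c(0, 1, 1.6, 2.5), function(t)
    sum(threshold_zmap(zm, t)$z != 0), numeric(1))
  expect_true(all(diff(n_surv) <= 0))
})

test_that("held-out normal subjects score near zero against the NDB", {
  base <- make_brain_like(SMALL, VOX)
  brain <- base$labels > 0
  means <- numeric(4)
  for (r in 1:4) {
    cohort <- as_subjects(make_subject_cohort(base, 11, seed = 40 + r))
    ndb <- build_ndb(cohort[1:10], brain, smoothing_fwhm_mm = 12)
    held <- preprocess_subject(cohort[[11]], brain, 12, 50)
    means[r] <- mean(zscore_map(held, ndb)$z[brain])
  }
  expect_lt(max(abs(means)), 0.3)
})

test_that("null suprathreshold tail is heavier than the Gaussian rate", {
  base <- make_brain_like(SMALL, VOX)
  brain <- base$labels > 0
  n <- 10
  cohort <- as_subjects(make_subject_cohort(base, n + 20, seed = 77))
  ndb <- build_ndb(cohort[1:n], brain, smoothing_fwhm_mm = 0)
  frac <- vapply(cohort[(n + 1):(n + 20)], function(s) {
    z <- zscore_map(global_normalize(s, brain, 50), ndb)
    mean(z$z[brain] >= 2)
  }, numeric(1))
  # a new subject against an n-subject NDB follows t_{n-1} scaled by
  # sqrt(1 + 1/n), not a standard normal
  t_pred <- stats::pt(2 / sqrt(1 + 1 / n), df = n - 1, lower.tail = FALSE)
  expect_gt(mean(frac), stats::pnorm(2, lower.tail = FALSE))
  expect_lt(abs(mean(frac) - t_pred), 0.025)
})

test_that("Z maps are invariant under common rescaling of all inputs", {
  base <- make_brain_like(SMALL, VOX)
  brain <- base$labels > 0
  cohort <- as_subjects(make_subject_cohort(base, 6, seed = 13))
  scaled <- lapply(cohort, function(s) { s$counts <- s$counts * 3.1; s })
  ndb1 <- build_ndb(cohort[1:5], brain, smoothing_fwhm_mm = 0)
  ndb2 <- build_ndb(scaled[1:5], brain, smoothing_fwhm_mm = 0)
  z1 <- zscore_map(global_normalize(cohort[[6]], brain, 50), ndb1)
  z2 <- zscore_map(global_normalize(scaled[[6]], brain, 50), ndb2)
  expect_equal(z1$z, z2$z, tolerance = 1e-9)
})
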