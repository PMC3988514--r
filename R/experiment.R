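# End-to-end experiment driver: the four-way comparison of compensation
# sources (Hoffman-style phantom, skull/gray-matter phantom, uniform pool,
# averaged normal-subject scans) against no correction and the reference
# camera, measured by t-map difference images, central/marginal Z
# summaries, region-wise count correlations and disease-VOI indices on a
# simulated hypoperfusion case.

#' Default run configuration
#'
#' One plain list drives the whole experiment; it is YAML-serializable (see
#' [write_config()]) and embeds every seed, so a run is reproducible from
#' the configuration alone.
#'
#' @param seed Root seed; all stage seeds are derived from it.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 20140125) {
  list(
    seed = as.integer(seed),
    grid = list(shape = c(64L, 64L, 64L),
                voxel_size_mm = c(3.5, 3.5, 3.5)),
    phantoms = list(gm_wm_ratio = 4, fill = 0.3, mu_soft = 0.1,
                    skull_mu = 0.15),
    cameras = list(
      reference = list(camera_id = "ecam", psf_fwhm_mm = 8,
                       butterworth_cutoff = 0.45, cutoff_unit = "nyquist",
                       butterworth_order = 8L, sensitivity_gradient = 0,
                       chang_mu = 0.1, count_budget = 5e6),
      target = list(camera_id = "irix", psf_fwhm_mm = 10,
                    butterworth_cutoff = 0.75, cutoff_unit = "cyc_per_cm",
                    butterworth_order = 8L, sensitivity_gradient = 0.05,
                    chang_mu = 0.1, count_budget = 5e6)),
    cohort = list(n = 20L, between_subject_cv = 0.08, local_cv = 0.05,
                  field_smoothness_mm = 20),
    acquisition = list(session_cv = 0.04, session_smoothness_mm = 30,
                       pool_shape = "cylinder"),
    compensation = list(n_acquisitions = 3L, count_floor = 0.05,
                        smoothing_fwhm_mm = 0),
    ndb = list(smoothing_fwhm_mm = 12, sd_floor_fraction = 0.1,
               normalization_target = 50),
    analysis = list(height_p = 0.05, extent_voxels = 50L,
                    connectivity = 26L, z_display_threshold = 1.5,
                    sva_z_threshold = 2, radius_quantile = 0.5),
    lesion = list(reduction_fraction = 0.2))
}

#' @keywords internal
camera_from_config <- function(cc) do.call(camera_model, cc)

#' Run the full camera-harmonization experiment
#'
#' Builds the digital phantoms and a synthetic normal cohort, acquires every
#' subject on both cameras (reference with attenuation correction; target
#' both with and without — the AC- arm deliberately exaggerates the camera
#' difference), constructs the four compensation maps, and evaluates each
#' correction by (i) two-sample t difference maps against the reference
#' group, (ii) central/marginal mean Z against the reference-camera normal
#' database, (iii) region-wise count correlations on the
#' attenuation-corrected arm, and (iv) Severity/Extent/Ratio indices for a
#' simulated 20%-reduction disease case.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional output directory for CSV tables and a text
#'   summary.
#' @param write_volumes Also write key volumes (maps, NDB, sample Z maps) as
#'   NIfTI-1 under `out_dir`.
#' @param quiet Suppress progress messages.
#' @return An object of class `spectharm_experiment`: tables
#'   (`zscore_summary`, `central_abs_z`, `correlation`,
#'   `correlation_by_region`, `sva`), `rankings`, the `config`, and the
#'   compensation maps.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           write_volumes = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("experiment stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  cg <- config$grid; shape <- cg$shape; voxel <- cg$voxel_size_mm
  ph <- config$phantoms
  seed0 <- config$seed

  say("stage phantoms")
  phantoms <- stage("phantoms", list(
    hoffman = make_hoffman_like(shape, voxel, ph$gm_wm_ratio, ph$fill,
                                ph$mu_soft),
    brain3d = make_3dbrain_like(shape, voxel, gm_only = TRUE,
                                skull_mu = ph$skull_mu,
                                gm_wm_ratio = ph$gm_wm_ratio,
                                fill = ph$fill, mu_soft = ph$mu_soft),
    pool = make_pool(shape, voxel, ph$fill, ph$mu_soft,
                     shape_kind = config$acquisition$pool_shape %||%
                       "brain")))
  base <- make_brain_like(shape, voxel, ph$gm_wm_ratio, ph$fill, ph$mu_soft)
  brain_mask <- base$labels > 0L

  cam_a <- camera_from_config(config$cameras$reference)
  cam_b <- camera_from_config(config$cameras$target)

  # attenuation and Chang factors per distinct geometry, amortized
  say("stage attenuation factors")
  fac <- stage("attenuation", {
    chang_of <- function(p, mu) {
      m <- array(0, dim(p$labels)); m[p$labels > 0L] <- mu
      attenuation_factor(m, voxel_size_mm = p$voxel_size_mm)
    }
    list(att_soft = attenuation_factor(base),
         att_3d = attenuation_factor(phantoms$brain3d),
         att_pool = attenuation_factor(phantoms$pool),
         ch_soft = chang_of(base, cam_a$chang_mu),
         ch_3d = chang_of(phantoms$brain3d, cam_a$chang_mu),
         ch_pool = chang_of(phantoms$pool, cam_a$chang_mu))
  })
  facs_for <- function(name) {
    switch(name,
           brain3d = list(att = fac$att_3d, ch = fac$ch_3d),
           pool = list(att = fac$att_pool, ch = fac$ch_pool),
           list(att = fac$att_soft, ch = fac$ch_soft))
  }

  say("stage cohort")
  co <- config$cohort
  cohort <- stage("cohort", make_subject_cohort(
    base, co$n, co$between_subject_cv, co$local_cv,
    co$field_smoothness_mm, seed = seed0 + 1L))

  say("stage subject acquisitions")
  aq <- config$acquisition
  acq <- function(phan, cam, ac, seed, att, ch, id)
    acquire(phan, cam, attenuation_correction = ac, seed = seed,
            att = att, chang_fac = ch,
            session_cv = aq$session_cv %||% 0,
            session_smoothness_mm = aq$session_smoothness_mm %||% 30,
            subject_id = id)
  subj <- stage("acquisition", {
    a_ref <- b_acm <- b_acp <- vector("list", co$n)
    for (i in seq_len(co$n)) {
      id <- sprintf("subj%02d", i)
      a_ref[[i]] <- acq(cohort[[i]], cam_a, TRUE, seed0 + 1000L + 3L * i,
                        fac$att_soft, fac$ch_soft, id)
      b_acm[[i]] <- acq(cohort[[i]], cam_b, FALSE, seed0 + 1001L + 3L * i,
                        fac$att_soft, NULL, id)
      b_acp[[i]] <- acq(cohort[[i]], cam_b, TRUE, seed0 + 1002L + 3L * i,
                        fac$att_soft, fac$ch_soft, id)
    }
    list(a_ref = a_ref, b_acm = b_acm, b_acp = b_acp)
  })

  say("stage compensation maps")
  cmp <- config$compensation
  maps <- stage("compensation", {
    out <- list(corr = list(), z = list())
    sidx <- 0L
    for (nm in names(phantoms)) {
      p <- phantoms[[nm]]
      f <- facs_for(nm)
      reps <- function(cam, ac, ch) lapply(seq_len(cmp$n_acquisitions),
        function(r) {
          sidx <<- sidx + 1L
          acq(p, cam, ac, seed0 + 5000L + sidx, f$att, ch, nm)
        })
      a_plus <- reps(cam_a, TRUE, f$ch)
      b_plus <- reps(cam_b, TRUE, f$ch)
      b_minus <- reps(cam_b, FALSE, NULL)
      out$corr[[nm]] <- build_compensation_map(
        a_plus, b_plus, cmp$count_floor, cmp$smoothing_fwhm_mm, source = nm)
      out$z[[nm]] <- build_compensation_map(
        a_plus, b_minus, cmp$count_floor, cmp$smoothing_fwhm_mm, source = nm)
    }
    # normal-subject compensation data: the cohort's own averaged scans
    out$corr$normal_spect <- build_compensation_map(
      subj$a_ref, subj$b_acp, cmp$count_floor, cmp$smoothing_fwhm_mm,
      source = "normal_spect")
    out$z$normal_spect <- build_compensation_map(
      subj$a_ref, subj$b_acm, cmp$count_floor, cmp$smoothing_fwhm_mm,
      source = "normal_spect")
    out
  })
  sources <- c("hoffman", "brain3d", "pool", "normal_spect")

  say("stage normal database")
  nd <- config$ndb
  ndb_a <- stage("ndb", build_ndb(subj$a_ref, brain_mask,
                                  nd$smoothing_fwhm_mm,
                                  nd$sd_floor_fraction,
                                  nd$normalization_target))
  prep <- function(s) preprocess_subject(s, brain_mask,
                                         nd$smoothing_fwhm_mm,
                                         nd$normalization_target)

  say("stage Z-score arm")
  an <- config$analysis
  zarm <- stage("zscore_arm", {
    methods <- c("no_correction", sources, "reference")
    vols_of <- function(m) switch(
      m,
      no_correction = subj$b_acm,
      reference = subj$a_ref,
      lapply(subj$b_acm, apply_compensation, comp = maps$z[[m]]))
    prepped <- lapply(methods, function(m) lapply(vols_of(m), prep))
    names(prepped) <- methods
    zmaps <- lapply(prepped, function(vs) lapply(vs, zscore_map, ndb = ndb_a))
    # difference image of the uncompensated AC- arm defines the areas
    dm <- two_sample_tmap(prepped$reference, prepped$no_correction,
                          brain_mask, an$height_p, an$extent_voxels,
                          an$connectivity)
    part <- partition_central_marginal(brain_mask, voxel_size_mm = voxel,
                                       radius_quantile = an$radius_quantile)
    areas <- list(
      central_decrease = part$central & dm$decrease_mask,
      central_increase = part$central & dm$increase_mask,
      marginal_decrease = part$marginal & dm$decrease_mask,
      marginal_increase = part$marginal & dm$increase_mask)
    rows <- list()
    cz <- list()
    for (m in methods) {
      for (a in names(areas)) {
        if (!any(areas[[a]])) next
        vals <- vapply(zmaps[[m]], region_mean_z,
                       numeric(1), region_mask = areas[[a]])
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, area = a, mean_z = mean(vals), sd_z = stats::sd(vals),
          n = length(vals), stringsAsFactors = FALSE)
      }
      cz[[m]] <- mean(vapply(zmaps[[m]], function(zm)
        mean(abs(zm$z[part$central])), numeric(1)))
    }
    list(table = do.call(rbind, rows),
         central_abs_z = data.frame(method = methods,
                                    mean_abs_z = unlist(cz[methods]),
                                    stringsAsFactors = FALSE),
         diff_map = dm, partition = part, zmaps_example = zmaps[[1]][[1]])
  })

  say("stage correlation arm")
  atlas <- make_region_atlas(brain_mask, voxel)
  corr_arm <- stage("correlation_arm", {
    methods <- c("no_correction", sources)
    ref_prepped <- lapply(subj$a_ref, prep)
    rows <- list()
    for (m in methods) {
      vols <- if (m == "no_correction") subj$b_acp
              else lapply(subj$b_acp, apply_compensation,
                          comp = maps$corr[[m]])
      for (i in seq_along(vols)) {
        rc <- region_correlation(prep(vols[[i]]), ref_prepped[[i]], atlas)
        rc$method <- m
        rc$subject <- vols[[i]]$subject_id
        rows[[length(rows) + 1L]] <- rc
      }
    }
    long <- do.call(rbind, rows)
    by_region <- stats::aggregate(corr ~ method + region, long,
                                  function(v) c(mean = mean(v),
                                                sd = stats::sd(v)))
    by_region <- data.frame(method = by_region$method,
                            region = by_region$region,
                            mean_corr = by_region$corr[, "mean"],
                            sd_corr = by_region$corr[, "sd"],
                            stringsAsFactors = FALSE)
    overall <- stats::aggregate(mean_corr ~ method, by_region, mean)
    names(overall)[2] <- "mean_corr"
    list(long = long, by_region = by_region, overall = overall)
  })

  say("stage disease simulation arm")
  voi <- default_sva_voi(brain_mask, voxel)
  les <- config$lesion$reduction_fraction
  sva_arm <- stage("sva_arm", {
    ndb_b <- build_ndb(subj$b_acp, brain_mask, nd$smoothing_fwhm_mm,
                       nd$sd_floor_fraction, nd$normalization_target)
    lesioned <- function(s) apply_ad_lesion(s, voi, les)
    cases <- list(
      standard = list(vol = lesioned(subj$a_ref[[1]]), ndb = ndb_a),
      target_own_ndb = list(vol = lesioned(subj$b_acp[[1]]), ndb = ndb_b),
      no_correction = list(vol = lesioned(subj$b_acm[[1]]), ndb = ndb_a))
    for (m in sources)
      cases[[m]] <- list(
        vol = apply_compensation(lesioned(subj$b_acm[[1]]), maps$z[[m]]),
        ndb = ndb_a)
    rows <- lapply(names(cases), function(nm) {
      zc <- zscore_map(prep(cases[[nm]]$vol), cases[[nm]]$ndb)
      s <- sva_indices(zc, voi, an$sva_z_threshold)
      data.frame(method = nm, severity = s$severity, extent = s$extent,
                 ratio = s$ratio, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  rank_of <- function(df, col, decreasing) {
    df$method[order(df[[col]], decreasing = decreasing)]
  }
  rankings <- list(
    correlation = rank_of(corr_arm$overall, "mean_corr", TRUE),
    central_abs_z = rank_of(zarm$central_abs_z, "mean_abs_z", FALSE))

  report <- structure(
    list(config = config,
         tables = list(zscore_summary = zarm$table,
                       central_abs_z = zarm$central_abs_z,
                       correlation = corr_arm$overall,
                       correlation_by_region = corr_arm$by_region,
                       sva = sva_arm),
         rankings = rankings,
         maps = maps, ndb = ndb_a, atlas = atlas, voi = voi,
         diff_map = zarm$diff_map, brain_mask = brain_mask),
    class = "spectharm_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(zarm$table,
                     file.path(out_dir, "zscore_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(zarm$central_abs_z,
                     file.path(out_dir, "central_abs_z.csv"),
                     row.names = FALSE)
    utils::write.csv(corr_arm$by_region,
                     file.path(out_dir, "correlation_by_region.csv"),
                     row.names = FALSE)
    utils::write.csv(corr_arm$overall,
                     file.path(out_dir, "correlation.csv"),
                     row.names = FALSE)
    utils::write.csv(sva_arm, file.path(out_dir, "sva.csv"),
                     row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "summary.txt"))
    if (write_volumes) {
      for (nm in names(maps$corr))
        write_compensation_map(maps$corr[[nm]],
                               file.path(out_dir, paste0("comp_", nm)))
      write_volume(ndb_a$mean, file.path(out_dir, "ndb_mean.nii.gz"), voxel)
      write_volume(ndb_a$sd, file.path(out_dir, "ndb_sd.nii.gz"), voxel)
      write_volume(brain_mask, file.path(out_dir, "brain_mask.nii.gz"),
                   voxel)
    }
  }
  report
}

#' @export
print.spectharm_experiment <- function(x, ...) {
  cat("<spectharm_experiment>\n")
  cat(sprintf("  grid %s @ %s mm, cohort n = %d, seed %d\n",
              paste(x$config$grid$shape, collapse = "x"),
              paste(format(x$config$grid$voxel_size_mm), collapse = "x"),
              x$config$cohort$n, x$config$seed))
  cat("\n  mean region correlation vs reference camera (higher is better):\n")
  o <- x$tables$correlation[order(-x$tables$correlation$mean_corr), ]
  for (i in seq_len(nrow(o)))
    cat(sprintf("    %-14s %.4f\n", o$method[i], o$mean_corr[i]))
  cat("\n  central-area mean |Z| (lower is better):\n")
  o <- x$tables$central_abs_z[order(x$tables$central_abs_z$mean_abs_z), ]
  for (i in seq_len(nrow(o)))
    cat(sprintf("    %-14s %.4f\n", o$method[i], o$mean_abs_z[i]))
  cat("\n  disease-VOI indices (Z >= ",
      x$config$analysis$sva_z_threshold, "):\n", sep = "")
  s <- x$tables$sva
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-14s Severity %.3f  Extent %6.2f%%  Ratio %.3f\n",
                s$method[i], s$severity[i], s$extent[i], s$ratio[i]))
  invisible(x)
}
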