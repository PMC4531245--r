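test_that("motion parameter generator honors amplitude, determinism and errors", {
  z <- generate_motion_params(50, 0)
  expect_true(all(z == 0))
  expect_identical(attr(z, "mean_relative_displacement"), 0)

  m1 <- generate_motion_params(160, 0.07, seed = 3)
  m2 <- generate_motion_params(160, 0.07, seed = 3)
  expect_identical(m1, m2)
  expect_equal(mean_relative_displacement(m1), 0.07, tolerance = 1e-10)
  expect_equal(dim(m1), c(160L, 6L))

  expect_error(generate_motion_params(160, -0.1), "amplitude")
  expect_error(generate_motion_params(1, 0.07), "n_volumes")
})

test_that("cohort has the study design: 41 subjects, 20/21 split, shared grid", {
  sim <- smoke_sim()
  cohort <- sim$cohort
  expect_length(cohort$subjects, 41L)
  tab <- table(vapply(cohort$subjects, `[[`, character(1), "group"))
  expect_equal(as.integer(tab[c("HC", "AD")]), c(20L, 21L))
  dims <- unique(lapply(cohort$subjects, function(s) dim(s$data)))
  expect_length(dims, 1L)
  expect_equal(dims[[1]], c(12L, 14L, 10L, 40L))
  expect_true(all(vapply(cohort$subjects,
                         function(s) nrow(s$motion6) == 40L, logical(1))))
  expect_true(all(vapply(cohort$subjects,
                         function(s) all(is.finite(s$data)), logical(1))))
})

test_that("group-average relative displacement sits in the plausible range", {
  st <- subjects_table(smoke_sim()$cohort)
  mrd <- tapply(st$mean_relative_displacement, st$group, mean)
  expect_true(all(mrd > 0.05 & mrd < 0.15))
})

test_that("mask geometry invariants hold", {
  masks <- smoke_sim()$cohort$masks
  for (nm in c("gm", "wm", "csf", "ventricle_roi", "wm_roi",
               "seed_sphere", "posterior_roi")) {
    expect_true(all(masks$brain[masks[[nm]]]), info = nm)
  }
  expect_false(any(masks$gm & masks$wm))
  expect_false(any(masks$gm & masks$csf))
  expect_false(any(masks$wm & masks$csf))
  expect_true(all(masks$posterior_roi[masks$seed_sphere]))
  expect_true(all(masks$gm[masks$posterior_roi]))
  expect_error(build_mask_set(c(3, 3, 3)), "grid")
})

test_that("DMN template overlaps the seed sphere and artifacts stay in-brain", {
  sim <- smoke_sim()
  truth <- sim$truth
  masks <- sim$cohort$masks
  dmn <- truth$template_maps[[truth$dmn_index]]
  expect_gt(mean(dmn[masks$seed_sphere] > 0.5), 0.5)
  for (nm in names(truth$artifact_maps)) {
    expect_equal(sum(abs(truth$artifact_maps[[nm]][!masks$brain])), 0,
                 info = nm)
  }
  expect_equal(sum(abs(truth$artifact_maps$csf[!masks$csf])), 0)
  expect_equal(sum(abs(truth$artifact_maps$wm_drift[!masks$wm])), 0)
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- smoke_config(random_seed = 7, n_hc = 3L, n_ad = 3L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (i in seq_along(a$cohort$subjects)) {
    expect_identical(a$cohort$subjects[[i]]$data, b$cohort$subjects[[i]]$data)
    expect_identical(a$cohort$subjects[[i]]$motion6,
                     b$cohort$subjects[[i]]$motion6)
  }
  expect_identical(a$truth$gm_volume, b$truth$gm_volume)
})

test_that("noise- and artifact-free data reconstruct exactly from ground truth", {
  sim <- clean_sim()
  truth <- sim$truth
  masks <- sim$cohort$masks
  V <- prod(dim(masks$brain))
  tpl <- vapply(truth$template_maps, as.numeric, numeric(V))
  for (i in c(1L, 25L)) {
    s <- sim$cohort$subjects[[i]]
    eff_tpl <- tpl
    eff_tpl[, truth$dmn_index] <-
      as.numeric(truth$dmn_anterior_map) +
      truth$node_gain[i] * truth$planted_effect[i] *
        as.numeric(truth$dmn_posterior_map)
    recon <- eff_tpl %*% t(truth$network_timecourses[[i]]) +
      truth$baseline * as.numeric(masks$brain)
    expect_equal(as.numeric(s$data), as.numeric(recon), tolerance = 1e-12)
  }
})

test_that("planted deficit is recorded and scales only the patient group", {
  truth <- smoke_sim()$truth
  groups <- vapply(smoke_sim()$cohort$subjects, `[[`, character(1), "group")
  expect_true(all(truth$planted_effect[groups == "HC"] == 1))
  expect_true(all(truth$planted_effect[groups == "AD"] == 0.6))
})

test_that("seed-sphere signal tracks the planted DMN timecourse best", {
  # default full-scale conditions: the mean data series inside the seed
  # sphere correlates more with the planted DMN timecourse than with any
  # other network's, averaged over controls
  sim <- cached("fullscale_sim0", generate_cohort(sim_config(random_seed = 0)))
  cohort <- sim$cohort
  truth <- sim$truth
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  hc <- which(groups == "HC")
  cors <- matrix(0, length(hc), ncol(truth$network_timecourses[[1]]))
  for (j in seq_along(hc)) {
    i <- hc[j]
    ts <- extract_mean_timeseries(cohort$subjects[[i]]$data,
                                  cohort$masks$seed_sphere)
    cors[j, ] <- abs(cor(ts, truth$network_timecourses[[i]]))
  }
  avg <- colMeans(cors)
  expect_equal(which.max(avg), truth$dmn_index)
  expect_gt(avg[truth$dmn_index], max(avg[-truth$dmn_index]))
})

test_that("with artifacts disabled, seed-posterior coupling is lower in patients", {
  sim <- clean_sim()
  cohort <- sim$cohort
  masks <- cohort$masks
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  roi_not_seed <- masks$posterior_roi & !masks$seed_sphere
  mean_cor <- vapply(cohort$subjects, function(s) {
    seed_ts <- extract_mean_timeseries(s$data, masks$seed_sphere)
    Y <- t(apply(s$data, 4, function(v) v[roi_not_seed]))
    mean(cor(seed_ts, Y))
  }, numeric(1))
  expect_gt(mean(mean_cor[groups == "HC"]), mean(mean_cor[groups == "AD"]))
})

test_that("CSF-only artifact leaves no variance outside the CSF mask", {
  cfg <- smoke_config(
    random_seed = 9, noise_sd = 0, n_hc = 2L, n_ad = 2L,
    network_amplitude = 0,
    artifact_amplitudes = c(motion = 0, csf = 30, wm_drift = 0,
                            vessel = 0, scanner_drift = 0))
  sim <- generate_cohort(cfg)
  masks <- sim$cohort$masks
  for (s in sim$cohort$subjects) {
    v <- apply(matrix(s$data, ncol = dim(s$data)[4]), 1L, stats::var)
    vmap <- array(v, dim(masks$brain))
    expect_equal(max(vmap[!masks$csf]), 0)
    expect_gt(max(vmap[masks$csf]), 0)
  }
})

test_that("cohort round-trips through NIfTI + sidecar files bit-exactly", {
  cfg <- smoke_config(random_seed = 11, n_hc = 2L, n_ad = 2L)
  sim <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(sim$cohort, dir)
  expect_equal(sum(manifest$kind == "bold"), 4L)
  back <- read_cohort(dir)
  for (i in seq_along(back$subjects)) {
    expect_identical(as.numeric(back$subjects[[i]]$data),
                     as.numeric(sim$cohort$subjects[[i]]$data))
    expect_equal(back$subjects[[i]]$motion6,
                 unname(sim$cohort$subjects[[i]]$motion6),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back$subjects[[i]]$gm_volume,
                 sim$cohort$subjects[[i]]$gm_volume, tolerance = 1e-9)
  }
  for (nm in c("brain", "gm", "seed_sphere", "posterior_roi")) {
    expect_identical(as.logical(back$masks[[nm]]),
                     as.logical(sim$cohort$masks[[nm]]))
  }
  m6 <- read_motion_par(file.path(dir, "sub-001_motion.par"))
  expect_equal(dim(m6), c(cfg$n_volumes, 6L))
})

test_that("default-config manifest lists one image file per subject (41)", {
  sim <- smoke_sim()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(sim$cohort, dir)
  expect_equal(sum(manifest$kind == "bold"), 41L)
})
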