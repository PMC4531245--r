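test_that("three planted sources are recovered up to permutation and sign", {
  set.seed(1)
  V <- 2000; T_ <- 50
  maps <- rbind(c(rep(3, 200), rep(0, 1800)),
                c(rep(0, 800), rep(3, 200), rep(0, 1000)),
                c(rep(0, 1600), rep(3, 200), rep(0, 200)))
  maps <- maps + matrix(rnorm(3 * V, 0, 0.05), 3)
  tcs <- matrix(rnorm(T_ * 3), T_)
  arr <- array(t(tcs %*% maps), c(V, 1, 1, T_))
  mask <- array(TRUE, c(V, 1, 1))
  dec <- spatial_ica(arr, mask, 3, seed = 2)
  cc <- abs(cor(t(dec$spatial_maps), t(maps)))
  expect_true(all(apply(cc, 2, max) > 0.95))
  # each truth map matched by a distinct component
  expect_equal(sort(apply(cc, 2, which.max)), 1:3)
})

test_that("decomposition is deterministic and satisfies the variance contract", {
  # structured data: five sparse sources on top of weak noise
  set.seed(3)
  gs <- c(8, 8, 6); V <- prod(gs); T_ <- 30
  maps <- matrix(0, 5, V)
  for (j in 1:5) maps[j, ((j - 1) * 70 + 1):((j - 1) * 70 + 60)] <- 4
  tcs <- matrix(rnorm(T_ * 5), T_)
  arr <- array(t(tcs %*% maps) + rnorm(V * T_, 0, 0.3), c(gs, T_))
  mask <- array(TRUE, gs)
  a <- spatial_ica(arr, mask, 5, seed = 9)
  b <- spatial_ica(arr, mask, 5, seed = 9)
  expect_identical(a$spatial_maps, b$spatial_maps)
  expect_identical(a$timecourses, b$timecourses)

  # ordering and accounting
  expect_true(all(diff(a$explained_variance) <= 1e-12))
  expect_lte(sum(a$explained_variance), 1 + 1e-12)
  # spatial maps have unit variance and non-negative skewness
  expect_equal(unname(apply(a$spatial_maps, 1, function(r) mean(r^2))),
               rep(1, 5), tolerance = 1e-8)
  expect_true(all(rowMeans(a$spatial_maps^3) >= -1e-10))

  # reconstruction residual equals the discarded PCA variance
  Y <- apply(arr, 4, as.numeric)            # V x T
  Yc <- Y - rowMeans(Y)
  recon <- t(a$timecourses %*% a$spatial_maps)
  resid_var <- sum((Yc - recon)^2) / length(Yc)
  total_var <- sum(Yc^2) / length(Yc)
  expect_equal(resid_var / total_var, 1 - sum(a$explained_variance),
               tolerance = 1e-6)
})

test_that("pure white noise decomposes under the auto rule without error", {
  arr <- tiny_4d(c(10, 9, 7, 25), seed = 5)
  mask <- array(TRUE, c(10, 9, 7))
  dec <- spatial_ica(arr, mask, "auto", seed = 1)
  expect_s3_class(dec, "component_decomposition")
  expect_true(nrow(dec$spatial_maps) >= 2)
  expect_error(spatial_ica(arr, mask, 400, seed = 1), "n_components")
})

test_that("ground-truth labeling separates artifact-only from network-only data", {
  sim <- smoke_sim()
  truth <- sim$truth
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config

  art_cfg <- smoke_config(random_seed = 31, n_hc = 1L, n_ad = 1L,
                          network_amplitude = 0, noise_sd = 1)
  art_sim <- generate_cohort(art_cfg)
  s <- art_sim$cohort$subjects[[1]]
  dec <- spatial_ica(s$data, masks$brain, "signal", seed = 3)
  dec <- label_by_ground_truth(dec, art_sim$truth)
  matched <- dec$labels != "unlabeled"
  expect_true(any(matched))
  expect_true(all(dec$labels[matched] == "noise"))

  net_cfg <- smoke_config(random_seed = 32, n_hc = 1L, n_ad = 1L,
                          noise_sd = 1,
                          artifact_amplitudes = c(motion = 0, csf = 0,
                                                  wm_drift = 0, vessel = 0,
                                                  scanner_drift = 0))
  net_sim <- generate_cohort(net_cfg)
  s2 <- net_sim$cohort$subjects[[1]]
  dec2 <- spatial_ica(s2$data, masks$brain, "signal", seed = 4)
  dec2 <- label_by_ground_truth(dec2, net_sim$truth)
  matched2 <- dec2$labels != "unlabeled"
  expect_true(any(matched2))
  expect_true(all(dec2$labels[matched2] == "signal"))
})

test_that("the planted CSF artifact's best-matching component is labeled noise", {
  sim <- mid_sim()
  s <- sim$cohort$subjects[[1]]
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config
  prep <- preprocess_subject(s$data, preprocess_config(), cfg$tr_s,
                             cfg$voxel_size_mm)
  dec <- label_by_ground_truth(
    spatial_ica(prep, masks$brain, "signal", seed = 8), sim$truth)
  csf_map <- as.numeric(sim$truth$artifact_maps$csf)[masks$brain]
  cc <- abs(cor(t(dec$spatial_maps), csf_map))
  expect_equal(dec$labels[which.max(cc)], "noise")
})

test_that("labels are invariant to component sign flips", {
  sim <- mid_sim()
  s <- sim$cohort$subjects[[2]]
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config
  prep <- preprocess_subject(s$data, preprocess_config(), cfg$tr_s,
                             cfg$voxel_size_mm)
  dec <- spatial_ica(prep, masks$brain, "signal", seed = 9)
  flipped <- dec
  flipped$spatial_maps <- -flipped$spatial_maps
  flipped$timecourses <- -flipped$timecourses
  a <- label_by_ground_truth(dec, sim$truth)$labels
  b <- label_by_ground_truth(flipped, sim$truth)$labels
  expect_identical(a, b)
  ra <- label_by_rules(dec, masks, expand_motion_24(s$motion6), cfg$tr_s)$labels
  rb <- label_by_rules(flipped, masks, expand_motion_24(s$motion6),
                       cfg$tr_s)$labels
  expect_identical(ra, rb)
})

test_that("rule-based labels catch motion-locked and pass clean components", {
  sim <- mid_sim()
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config
  s <- sim$cohort$subjects[[3]]
  m24 <- expand_motion_24(s$motion6)
  T_ <- cfg$n_volumes
  nvox <- sum(masks$brain)

  gm_v <- as.numeric(masks$gm)[masks$brain]
  smooth_map <- as.numeric(sim$truth$template_maps[[1]])[masks$brain]
  tt <- seq_len(T_) * cfg$tr_s
  slow_tc <- sin(2 * pi * 0.03 * tt)

  dec <- list(
    spatial_maps = rbind(scale(smooth_map)[, 1],
                         scale(smooth_map * gm_v)[, 1]),
    timecourses = cbind(m24$values[, 1] + 1e-8, slow_tc),
    labels = c("unlabeled", "unlabeled"),
    mask = masks$brain)
  class(dec) <- "component_decomposition"
  lab <- label_by_rules(dec, masks, m24, cfg$tr_s)$labels
  expect_equal(lab[1], "noise")   # timecourse IS a motion regressor
  expect_equal(lab[2], "signal")  # smooth, slow, gray-matter, motion-free
})

test_that("rule-based labels agree with ground truth for most components", {
  sim <- mid_sim()
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config
  agree <- vapply(1:6, function(i) {
    s <- sim$cohort$subjects[[i]]
    prep <- preprocess_subject(s$data, preprocess_config(), cfg$tr_s,
                               cfg$voxel_size_mm)
    dec <- spatial_ica(prep, masks$brain, "signal", seed = i)
    gt <- label_by_ground_truth(dec, sim$truth)$labels
    rl <- label_by_rules(dec, masks, expand_motion_24(s$motion6),
                         cfg$tr_s)$labels
    mean(ifelse(gt == "noise", "noise", "signal") == rl)
  }, numeric(1))
  expect_gte(mean(agree), 0.8)
})
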