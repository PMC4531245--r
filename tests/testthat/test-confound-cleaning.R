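test_that("24-parameter motion expansion follows the derivative/square recipe", {
  z <- expand_motion_24(matrix(0, 10, 6))
  expect_equal(dim(z$values), c(10L, 24L))
  expect_true(all(z$values == 0))

  m <- matrix(0, 3, 6)
  m[, 1] <- c(1, 2, 4)
  e <- expand_motion_24(m)
  # hand-computed: derivative [0,1,2], squares [1,4,16] and [0,1,4],
  # then demeaned
  expect_equal(e$values[, 1], c(1, 2, 4) - mean(c(1, 2, 4)))
  expect_equal(e$values[, 7], c(0, 1, 2) - 1)
  expect_equal(e$values[, 13], c(1, 4, 16) - 7)
  expect_equal(e$values[, 19], c(0, 1, 4) - mean(c(0, 1, 4)))
  expect_true(e$demeaned)
  expect_equal(max(abs(colMeans(e$values))), 0, tolerance = 1e-12)
  expect_error(expand_motion_24(matrix(0, 10, 5)), "6")
})

test_that("mask mean timeseries extraction", {
  x <- tiny_4d(c(3, 3, 2, 7), seed = 2)
  one <- array(FALSE, c(3, 3, 2)); one[2, 3, 1] <- TRUE
  expect_equal(extract_mean_timeseries(x, one), x[2, 3, 1, ])

  two <- array(FALSE, c(3, 3, 2)); two[1, 1, 1] <- TRUE; two[3, 3, 2] <- TRUE
  x[3, 3, 2, ] <- -x[1, 1, 1, ]
  expect_equal(extract_mean_timeseries(x, two), rep(0, 7))

  set.seed(4)
  two2 <- array(FALSE, c(3, 3, 2)); two2[1, 2, 1] <- TRUE; two2[2, 2, 2] <- TRUE
  expect_equal(extract_mean_timeseries(x, two2),
               (x[1, 2, 1, ] + x[2, 2, 2, ]) / 2)
  expect_error(extract_mean_timeseries(x, array(FALSE, c(3, 3, 2))), "empty")
})

test_that("full-variance regression matches an independent least-squares oracle", {
  x <- tiny_4d(c(2, 2, 2, 30), seed = 6)
  expect_identical(regress_out_full(x, matrix(0, 30, 0)), x)

  set.seed(7)
  X <- scale(matrix(rnorm(90), 30, 3), scale = FALSE)
  cleaned <- regress_out_full(x, X)
  for (v in 1:8) {
    idx <- arrayInd(v, c(2, 2, 2))
    y <- x[idx[1], idx[2], idx[3], ]
    oracle <- residuals(lm(y ~ X)) + mean(y)
    expect_equal(cleaned[idx[1], idx[2], idx[3], ], unname(oracle),
                 tolerance = 1e-10)
    resid_demeaned <- cleaned[idx[1], idx[2], idx[3], ] -
      mean(cleaned[idx[1], idx[2], idx[3], ])
    expect_lt(max(abs(crossprod(X, resid_demeaned))), 1e-8)
  }

  # a series equal to a design column plus a constant leaves the constant
  y1 <- X[, 2] + 3
  arr <- array(rep(y1, each = 1), c(1, 1, 1, 30))
  out <- regress_out_full(arr, X)
  expect_equal(as.numeric(out), rep(3, 30), tolerance = 1e-10)
})

test_that("cleanup modes reduce to each other as designed", {
  sim <- smoke_sim()
  s <- sim$cohort$subjects[[1]]
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config
  prep <- preprocess_subject(s$data, preprocess_config(), cfg$tr_s,
                             cfg$voxel_size_mm)
  dec <- spatial_ica(prep, masks$brain, "signal", seed = 55)
  dec_all_signal <- dec
  dec_all_signal$labels <- rep("signal", nrow(dec$spatial_maps))

  expect_identical(clean(prep, s$motion6, masks, NULL, "none"), prep)
  motreg <- clean(prep, s$motion6, masks, NULL, "motreg")
  soft0 <- clean(prep, s$motion6, masks, dec_all_signal, "comp_soft")
  expect_equal(soft0, motreg, tolerance = 1e-10)

  expect_error(clean(prep, s$motion6, masks, NULL, "comp_agg"), "decomposition")
  dec_nolab <- dec
  dec_nolab$labels <- NULL
  expect_error(clean(prep, s$motion6, masks, dec_nolab, "comp_agg"), "label")
})

test_that("aggressive residuals are orthogonal to motion and noise regressors", {
  sim <- smoke_sim()
  s <- sim$cohort$subjects[[2]]
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config
  prep <- preprocess_subject(s$data, preprocess_config(), cfg$tr_s,
                             cfg$voxel_size_mm)
  dec <- label_by_ground_truth(
    spatial_ica(prep, masks$brain, "signal", seed = 56), sim$truth)
  agg <- clean(prep, s$motion6, masks, dec, "comp_agg")
  Y <- t(apply(agg, 4, as.numeric))
  Yc <- sweep(Y, 2, colMeans(Y))
  X <- cbind(expand_motion_24(s$motion6)$values,
             scale(dec$timecourses[, dec$labels == "noise"], scale = FALSE))
  ip <- crossprod(X, Yc)
  expect_lt(max(abs(ip)) / nrow(X), 1e-6)
})

test_that("soft equals aggressive when noise timecourses are orthogonal to signal", {
  set.seed(20)
  T_ <- 60
  motion6 <- generate_motion_params(T_, 0.05, seed = 2)
  m24 <- expand_motion_24(motion6)$values
  # build orthonormal timecourses orthogonal to the motion span
  base <- qr.Q(qr(cbind(m24, matrix(rnorm(T_ * 6), T_))))[, 25:30]
  base <- scale(base, scale = FALSE)
  tcs <- qr.Q(qr(base)) # mutually orthogonal, orthogonal to m24
  maps <- matrix(rnorm(6 * 50), 6, 50)
  dat <- tcs %*% maps + 100
  arr <- array(t(dat), c(50, 1, 1, T_))
  dec <- list(timecourses = tcs, spatial_maps = maps,
              labels = c("noise", "noise", rep("signal", 4)))
  class(dec) <- "component_decomposition"
  soft <- clean(arr, motion6, NULL, dec, "comp_soft")
  agg <- clean(arr, motion6, NULL, dec, "comp_agg")
  expect_equal(soft, agg, tolerance = 1e-8)
})

test_that("cleaning is idempotent and collinear designs are rejected", {
  sim <- smoke_sim()
  s <- sim$cohort$subjects[[3]]
  masks <- sim$cohort$masks
  cfg <- sim$cohort$config
  prep <- preprocess_subject(s$data, preprocess_config(), cfg$tr_s,
                             cfg$voxel_size_mm)
  dec <- label_by_ground_truth(
    spatial_ica(prep, masks$brain, "signal", seed = 57), sim$truth)
  # fixed-design modes are exactly idempotent; mwcreg is excluded because its
  # tissue-mean regressors are re-extracted from the data being cleaned
  for (mode in c("motreg", "comp_soft", "comp_agg")) {
    once <- clean(prep, s$motion6, masks, dec, mode)
    twice <- clean(once, s$motion6, masks, dec, mode)
    expect_equal(twice, once, tolerance = 1e-7, info = mode)
  }
  dec_dup <- dec
  dup <- which(dec$labels == "noise")[1]
  dec_dup$timecourses <- cbind(dec$timecourses, dec$timecourses[, dup])
  dec_dup$spatial_maps <- rbind(dec$spatial_maps, dec$spatial_maps[dup, ])
  dec_dup$labels <- c(dec$labels, "noise")
  expect_error(clean(prep, s$motion6, masks, dec_dup, "comp_agg"), "collinear")
})

test_that("temporal variance obeys the design-nesting order on every subject", {
  vt <- smoke_variance_tables()
  for (v in vt) {
    expect_true(all(v$motreg <= v$none + 1e-9))
    expect_true(all(v$mwcreg <= v$motreg + 1e-9))
    expect_true(all(v$comp_agg <= v$comp_soft + 1e-9))
  }
})
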