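#' ROI-test power study over replicate cohorts
#'
#' Generates `n_cohorts` independent cohorts from `sim`, runs each subject
#' through preprocessing, component decomposition with ground-truth labeling
#' and the requested cleanups, and applies the posterior-ROI two-sample
#' t-test (HC vs patients) to the per-subject DMN connectivity statistic.
#' Power is the fraction of cohorts whose two-tailed p falls below `alpha`.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param sim a [sim_config()]; replicate r uses `derive`d seed r.
#' @param cleanups cleanup modes to compare (default the three the
#'   soft-vs-aggressive question needs).
#' @param fc_method `"dualreg"` (default) or `"seed"`.
#' @param preprocess a [preprocess_config()].
#' @param n_components passed to [spatial_ica()].
#' @param alpha test level (default 0.05).
#' @param seed integer master seed.
#' @return A list with `results` (tibble: cohort, cleanup, t, df, p) and
#'   `power` (tibble: cleanup, power, n_cohorts).
#' @export
roi_power_study <- function(n_cohorts,
                            sim = smoke_config(grid_shape = c(14L, 16L, 12L),
                                               n_volumes = 120L),
                            cleanups = c("none", "comp_soft", "comp_agg"),
                            fc_method = c("dualreg", "seed"),
                            preprocess = preprocess_config(),
                            n_components = "signal",
                            alpha = 0.05, seed = 1L) {
  fc_method <- match.arg(fc_method)
  need_comp <- any(c("comp_soft", "comp_agg") %in% cleanups)
  rows <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    cfg <- sim
    cfg$random_seed <- derive_seed(seed, "cohort", r)
    out <- generate_cohort(cfg)
    cohort <- out$cohort
    truth <- out$truth
    masks <- cohort$masks
    n <- length(cohort$subjects)
    groups <- character(n)
    roi <- matrix(NA_real_, n, length(cleanups),
                  dimnames = list(NULL, cleanups))
    for (i in seq_len(n)) {
      s <- cohort$subjects[[i]]
      groups[i] <- s$group
      prep <- preprocess_subject(s$data, preprocess, cfg$tr_s,
                                 cfg$voxel_size_mm)
      decomp <- NULL
      if (need_comp) {
        decomp <- spatial_ica(prep, masks$brain, n_components,
                              seed = derive_seed(cfg$random_seed, "ica", i))
        decomp <- label_by_ground_truth(decomp, truth)
      }
      for (mode in cleanups) {
        cleaned <- clean(prep, s$motion6, masks, decomp, mode)
        m <- if (fc_method == "seed") {
          seed_fc_zmap(cleaned, masks$seed_sphere, masks$brain)$values
        } else {
          dr <- dual_regression(cleaned, truth$template_maps, masks$brain)
          select_dmn_map(dr$pe_maps, truth$dmn_index)
        }
        roi[i, mode] <- roi_mean_pe(m, masks$posterior_roi)
      }
      cohort$subjects[[i]]$data <- NULL
    }
    rows[[r]] <- purrr::map_dfr(cleanups, function(mode) {
      a <- roi[groups == "HC", mode]
      b <- roi[groups == "AD", mode]
      res <- two_sample_t_summary(
        list(mean = mean(a), sd = stats::sd(a), n = length(a)),
        list(mean = mean(b), sd = stats::sd(b), n = length(b)))
      tibble::tibble(cohort = r, cleanup = mode, t = res$t, df = res$df,
                     p = res$p)
    })
  }
  results <- dplyr::bind_rows(rows)
  power <- results |>
    dplyr::group_by(.data$cleanup) |>
    dplyr::summarize(power = mean(.data$p < alpha),
                     mean_t = mean(.data$t),
                     n_cohorts = dplyr::n(), .groups = "drop")
  list(results = results, power = power)
}

#' Type-I-error calibration of the permutation GLM
#'
#' Monte-Carlo calibration harness for [permutation_group_glm()] and
#' [cluster_correct()]: each replicate draws per-subject null statistic maps
#' (Gaussian noise, optionally spatially smoothed into random fields with
#' realistic cluster structure) plus a covariate that truly influences the
#' maps but carries no group information, splits subjects into two arbitrary
#' groups, and tests at `alpha`. Under this null the voxelwise rejection
#' rate and the familywise error rate of cluster correction should both sit
#' at `alpha` up to binomial noise.
#'
#' With `n_perm = 199` the rejection threshold `p <= 0.05` is exactly
#' attainable (10 of 200 permutation ranks), so the voxel-level test is
#' exact up to the Freedman-Lane approximation.
#'
#' @param n_cohorts number of replicate null cohorts.
#' @param grid_shape small map grid (default 10 x 10 x 8).
#' @param n_per_group subjects per group (default 12).
#' @param smooth_fwhm_mm FWHM of map smoothing in mm (0 = independent
#'   voxels, the right choice for voxel-level calibration; > 0 gives random
#'   fields for cluster-level calibration).
#' @param covariate_effect scale of the covariate's true effect on the maps.
#' @param n_perm permutations per test (default 199).
#' @param alpha nominal level.
#' @param seed master seed.
#' @return A list with `voxel_rate` (overall voxelwise rejection rate),
#'   `voxel_n` (number of voxel tests), `fwer` (fraction of cohorts with
#'   any significant cluster), `per_cohort` tibble.
#' @export
permutation_calibration_study <- function(n_cohorts,
                                          grid_shape = c(10L, 10L, 8L),
                                          n_per_group = 12L,
                                          smooth_fwhm_mm = 0,
                                          covariate_effect = 0.5,
                                          n_perm = 199L, alpha = 0.05,
                                          seed = 1L) {
  mask <- array(TRUE, grid_shape)
  V <- prod(grid_shape)
  n <- 2L * n_per_group
  groups <- rep(c("HC", "AD"), each = n_per_group)
  rows <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    set.seed(derive_seed(seed, "calib", r))
    covariate <- stats::rnorm(n)
    maps <- lapply(seq_len(n), function(i) {
      m <- array(stats::rnorm(V), grid_shape)
      if (smooth_fwhm_mm > 0) {
        m <- gaussian_smooth(m, smooth_fwhm_mm, voxel_size_mm = 1)
      }
      m + covariate_effect * covariate[i]
    })
    res <- permutation_group_glm(maps, groups, covariate, mask,
                                 n_perm = n_perm,
                                 seed = derive_seed(seed, "perm", r))
    vox_rej <- sum(res$uncorrected_p_map[mask] <= alpha)
    res <- cluster_correct(res, primary_p = alpha)
    any_sig <- nrow(res$cluster_table) > 0 &&
      any(res$cluster_table$corrected_p < alpha)
    rows[[r]] <- tibble::tibble(cohort = r, voxel_rejections = vox_rej,
                                n_voxels = V, fwer_hit = any_sig)
  }
  per_cohort <- dplyr::bind_rows(rows)
  list(voxel_rate = sum(per_cohort$voxel_rejections) / sum(per_cohort$n_voxels),
       voxel_n = sum(per_cohort$n_voxels),
       fwer = mean(per_cohort$fwer_hit),
       per_cohort = per_cohort)
}
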