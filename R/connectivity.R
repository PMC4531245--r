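#' Seed-based functional connectivity z-map
#'
#' Pearson correlation of every voxel's timeseries with the mean timeseries
#' of the seed mask, Fisher r-to-z transformed. Correlations are clamped to
#' +/- (1 - 1e-7) before `atanh` so z stays finite; voxels with zero
#' temporal variance get z = 0 and their count is attached as the
#' `n_zero_variance` attribute.
#'
#' @param data 4D array.
#' @param seed_mask non-empty logical 3D array.
#' @param brain_mask logical 3D array; z is computed inside it (0 outside).
#' @return A list of class `fc_zmap`: `values` (3D z image), `method =
#'   "seed"`, `n_zero_variance`.
#' @export
seed_fc_zmap <- function(data, seed_mask, brain_mask) {
  assert_that(any(seed_mask), "seed mask is empty")
  seed_ts <- extract_mean_timeseries(data, seed_mask)
  assert_that(stats::sd(seed_ts) > 1e-12, "seed mean timeseries has zero variance")
  Y <- flatten_time(data, brain_mask)
  s <- scale_to_unit_sd(seed_ts)
  n <- length(s)
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  sds <- sqrt(colSums(Yc^2) / (n - 1))
  zero_var <- sds < 1e-12
  r <- as.numeric(crossprod(Yc, s)) / ((n - 1) * pmax(sds, 1e-300))
  r[zero_var] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[zero_var] <- 0
  structure(list(values = embed_in_grid(z, brain_mask), method = "seed",
                 n_zero_variance = sum(zero_var)),
            class = "fc_zmap")
}

#' Template-based dual regression
#'
#' Stage 1 regresses each volume's voxel pattern (within the mask) on all
#' spatial templates simultaneously (templates demeaned across voxels and
#' variance-normalized, plus an intercept), giving one timecourse per
#' template. Stage 2 regresses each voxel's timeseries on all stage-1
#' timecourses simultaneously (demeaned, plus an intercept), giving one
#' parameter-estimate (PE) map per template.
#'
#' @param data 4D array.
#' @param templates list of 3D template maps on the data grid (mutually
#'   non-collinear within the mask).
#' @param brain_mask logical 3D array.
#' @return A list of class `dual_regression_result`: `timecourses`
#'   (T x n_templates) and `pe_maps` (list of 3D images).
#' @export
dual_regression <- function(data, templates, brain_mask) {
  mask_l <- as.logical(brain_mask)
  Tm <- vapply(templates, function(m) as.numeric(m)[mask_l],
               numeric(sum(mask_l)))
  Tm <- demean_cols(Tm)
  sds <- sqrt(colMeans(Tm^2))
  assert_that(all(sds > 1e-12), "a template is constant within the mask")
  Tm <- sweep(Tm, 2L, sds, "/")
  cc <- stats::cor(Tm)
  cc[!upper.tri(cc)] <- 0
  bad <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("collinear templates: %d ~ %d", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  }
  Y <- flatten_time(data, brain_mask) # T x V

  X1 <- cbind(1, Tm)
  B1 <- t(pinv_fit(X1, t(Y))) # T x (K+1)
  tc <- B1[, -1, drop = FALSE]

  X2 <- cbind(1, demean_cols(tc))
  B2 <- pinv_fit(X2, Y) # (K+1) x V
  pe_maps <- lapply(seq_along(templates), function(k) {
    embed_in_grid(B2[k + 1, ], brain_mask)
  })
  structure(list(timecourses = tc, pe_maps = pe_maps),
            class = "dual_regression_result")
}

#' Select the DMN parameter-estimate map
#'
#' @param pe_maps list of PE maps from [dual_regression()].
#' @param dmn_index 1-based index of the DMN template.
#' @return The indexed 3D map.
#' @export
select_dmn_map <- function(pe_maps, dmn_index) {
  assert_that(dmn_index >= 1 && dmn_index <= length(pe_maps),
              sprintf("dmn_index must be in 1..%d", length(pe_maps)))
  pe_maps[[dmn_index]]
}
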