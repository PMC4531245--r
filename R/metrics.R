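#' Temporal signal-to-noise ratio
#'
#' Voxelwise temporal mean divided by temporal standard deviation. The
#' summary statistic is the median over the eroded brain mask (erosion
#' excludes brain-edge effects); voxels with temporal SD below 1e-12 are
#' excluded from the median and counted.
#'
#' @param data 4D array.
#' @param brain_mask logical 3D array.
#' @param erosion_iters erosion passes before taking the median (default 2).
#' @return A list of class `tsnr_result`: `tsnr_map` (3D), `median_tsnr`,
#'   `eroded_mask`, `n_zero_variance`.
#' @export
temporal_snr <- function(data, brain_mask, erosion_iters = 2L) {
  assert_that(dim(data)[4] >= 2, "need at least 2 time points")
  Y <- flatten_time(data, brain_mask)
  mu <- colMeans(Y)
  sds <- col_sds(Y)
  ok <- sds > 1e-12
  tsnr <- ifelse(ok, mu / pmax(sds, 1e-300), 0)
  tsnr_map <- embed_in_grid(tsnr, brain_mask)
  em <- erode_mask(brain_mask, erosion_iters)
  assert_that(any(em), "eroded mask is empty")
  ok_map <- embed_in_grid(ok, brain_mask, fill = FALSE)
  sel <- em & array(as.logical(ok_map), dim(em))
  assert_that(any(sel), "no nonzero-variance voxels inside the eroded mask")
  structure(list(tsnr_map = tsnr_map,
                 median_tsnr = stats::median(tsnr_map[sel]),
                 eroded_mask = em,
                 n_zero_variance = sum(!ok)),
            class = "tsnr_result")
}

#' Percentage of temporal fluctuation suppressed by cleaning
#'
#' Per voxel, `100 * STD_t(uncleaned - cleaned) / STD_t(uncleaned)`: the
#' percentage of the uncleaned data's temporal fluctuation amplitude removed
#' by the cleanup. Voxels whose uncleaned temporal SD is below 1e-12 are set
#' to 0 and counted.
#'
#' @param uncleaned,cleaned 4D arrays on the same grid with equal T.
#' @return A list of class `delta_std_map`: `values` (3D, percent),
#'   `n_zero_variance`.
#' @export
delta_std_map <- function(uncleaned, cleaned) {
  assert_that(all(dim(uncleaned) == dim(cleaned)), "shape mismatch")
  Yu <- flatten_time(uncleaned)
  Yd <- Yu - flatten_time(cleaned)
  s_u <- col_sds(Yu)
  s_d <- col_sds(Yd)
  ok <- s_u > 1e-12
  pct <- ifelse(ok, 100 * s_d / pmax(s_u, 1e-300), 0)
  structure(list(values = array(pct, dim(uncleaned)[1:3]),
                 n_zero_variance = sum(!ok)),
            class = "delta_std_map")
}

#' Probability map of fluctuation suppression exceeding a threshold
#'
#' Per voxel, the fraction of subjects whose suppression map exceeds
#' `threshold_pct` (strictly).
#'
#' @param delta_maps non-empty list of `delta_std_map`s (or 3D arrays) on a
#'   common grid.
#' @param threshold_pct exceedance threshold in percent (default 25).
#' @return A 3D array of fractions in \[0, 1\].
#' @export
exceedance_probability_map <- function(delta_maps, threshold_pct = 25) {
  assert_that(length(delta_maps) >= 1, "need at least one map")
  arrs <- lapply(delta_maps, function(m) if (is.list(m)) m$values else m)
  out <- array(0, dim(arrs[[1]]))
  for (a in arrs) {
    assert_that(all(dim(a) == dim(out)), "maps must share one grid")
    out <- out + (a > threshold_pct)
  }
  out / length(arrs)
}

#' Across-subject consistency (standard-deviation) map
#'
#' Voxelwise sample standard deviation (n-1 denominator) across subjects of
#' per-subject statistic maps (z or PE). Lower values mean higher
#' within-group consistency.
#'
#' @param maps list (>= 2) of 3D arrays or `fc_zmap`s on a common grid.
#' @param brain_mask logical 3D array; values outside are 0.
#' @return A list of class `consistency_map`: `values` (3D), `n_subjects`.
#' @export
consistency_map <- function(maps, brain_mask) {
  assert_that(length(maps) >= 2, "need at least 2 subject maps")
  arrs <- lapply(maps, function(m) if (is.list(m)) m$values else m)
  M <- vapply(arrs, function(a) as.numeric(a)[as.logical(brain_mask)],
              numeric(sum(brain_mask)))
  sds <- col_sds(t(M))
  structure(list(values = embed_in_grid(sds, brain_mask),
                 n_subjects = length(maps)),
            class = "consistency_map")
}

#' Paired t-test over voxels of two maps
#'
#' Treats voxels within the mask as paired observations of (A - B); df is
#' the number of mask voxels minus one. Spatial autocorrelation inflates the
#' effective df, so p-values are descriptive (the convention followed when
#' comparing consistency maps across cleanups).
#'
#' @param mapA,mapB 3D arrays on the same grid.
#' @param mask logical 3D array with >= 2 voxels.
#' @return A one-row tibble: `t`, `df`, `p`. Zero-variance differences give
#'   `t = NaN`, `p = NaN` with a warning.
#' @export
paired_t_over_voxels <- function(mapA, mapB, mask) {
  n <- sum(mask)
  assert_that(n >= 2, "mask must contain at least 2 voxels")
  d <- as.numeric(mapA)[as.logical(mask)] - as.numeric(mapB)[as.logical(mask)]
  sd_d <- stats::sd(d)
  if (sd_d < 1e-12) {
    if (mean(d) == 0) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1))
    }
    warning("zero-variance difference: t undefined", call. = FALSE)
    return(tibble::tibble(t = NaN, df = n - 1, p = NaN))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  tibble::tibble(t = t_stat, df = n - 1,
                 p = 2 * stats::pt(-abs(t_stat), n - 1))
}
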