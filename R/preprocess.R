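#' Preprocessing configuration
#'
#' The common preprocessing shared by every cleanup variant: isotropic
#' Gaussian spatial smoothing followed by high-pass temporal filtering.
#'
#' @param fwhm_mm smoothing kernel full width at half maximum in mm (>= 0).
#' @param highpass_cutoff_hz high-pass cutoff in Hz (must be below Nyquist).
#' @param keep_temporal_mean re-add the voxelwise temporal mean after
#'   filtering so temporal SNR stays defined (default TRUE).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(fwhm_mm = 5.0, highpass_cutoff_hz = 0.01,
                              keep_temporal_mean = TRUE) {
  assert_that(fwhm_mm >= 0, "fwhm_mm must be >= 0")
  assert_that(highpass_cutoff_hz > 0, "highpass cutoff must be positive")
  structure(list(fwhm_mm = fwhm_mm, highpass_cutoff_hz = highpass_cutoff_hz,
                 keep_temporal_mean = keep_temporal_mean),
            class = "preprocess_config")
}

#' Convert between Gaussian FWHM and sigma
#'
#' `FWHM = 2 sqrt(2 ln 2) sigma ~= 2.3548 sigma`; e.g. sigma 3 mm
#' corresponds to FWHM 7.06 mm.
#'
#' @param fwhm_mm,sigma_mm kernel width (>= 0), any length unit.
#' @return The converted width.
#' @export
#' @examples
#' fwhm_to_sigma(5)
#' sigma_to_fwhm(3)
fwhm_to_sigma <- function(fwhm_mm) {
  assert_that(all(fwhm_mm >= 0), "fwhm must be >= 0")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma_mm) {
  assert_that(all(sigma_mm >= 0), "sigma must be >= 0")
  sigma_mm * 2 * sqrt(2 * log(2))
}

#' Isotropic Gaussian spatial smoothing of a 4D series
#'
#' Each volume is convolved with an isotropic Gaussian of
#' `fwhm_to_sigma(fwhm_mm) / voxel_size_mm` voxels via FFT (periodic
#' boundary), which preserves the spatial sum of each volume exactly and is
#' shift-equivariant. The discrete kernel is normalized to unit sum.
#'
#' @param data 4D array (x, y, z, t) or 3D array (treated as one volume).
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return An array of the same shape.
#' @export
gaussian_smooth <- function(data, fwhm_mm, voxel_size_mm) {
  assert_that(fwhm_mm >= 0, "fwhm must be >= 0")
  if (fwhm_mm == 0) return(data)
  was_3d <- length(dim(data)) == 3L
  if (was_3d) dim(data) <- c(dim(data), 1L)
  gs <- dim(data)[1:3]
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  kern1 <- function(n) {
    # wrapped (periodic) sampled Gaussian along one axis
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-d^2 / (2 * sigma_vox^2))
    k / sum(k)
  }
  k3 <- outer(outer(kern1(gs[1]), kern1(gs[2])), kern1(gs[3]))
  K <- stats::fft(k3)
  out <- data
  for (t in seq_len(dim(data)[4])) {
    vol <- data[, , , t]
    out[, , , t] <- Re(stats::fft(stats::fft(vol) * K, inverse = TRUE)) /
      prod(gs)
  }
  if (was_3d) dim(out) <- gs
  out
}

# Discrete-cosine drift basis: all DCT-II components with frequency strictly
# below `cutoff_hz`. Returns a T x K matrix (possibly K = 0).
dct_drift_basis <- function(n, tr_s, cutoff_hz) {
  kmax <- floor(2 * n * tr_s * cutoff_hz - 1e-12)
  if (kmax < 1) return(matrix(0, n, 0))
  tt <- (seq_len(n) - 0.5) / n
  vapply(seq_len(kmax), function(k) cos(pi * k * tt), numeric(n))
}

#' High-pass temporal filtering by discrete-cosine drift regression
#'
#' Removes slow drifts by regressing each voxel's timeseries on a DCT basis
#' containing every component with frequency below `cutoff_hz` (frequency of
#' DCT component k over T samples is k / (2 T TR)). The projection is linear
#' and exactly idempotent. With `keep_temporal_mean`, the voxelwise temporal
#' mean of the input is re-added after filtering.
#'
#' @param timeseries a numeric vector (one series) or 4D array.
#' @param cutoff_hz high-pass cutoff in Hz; must be below Nyquist `1/(2 TR)`.
#' @param tr_s repetition time in seconds.
#' @param keep_temporal_mean re-add the temporal mean (default TRUE).
#' @return Same shape as the input.
#' @export
highpass_filter <- function(timeseries, cutoff_hz, tr_s,
                            keep_temporal_mean = TRUE) {
  is_vec <- is.null(dim(timeseries))
  if (is_vec) {
    n <- length(timeseries)
  } else {
    assert_that(length(dim(timeseries)) == 4L,
                "timeseries must be a vector or 4D array")
    n <- dim(timeseries)[4]
  }
  assert_that(n >= 4, "need at least 4 time points")
  assert_that(cutoff_hz < 1 / (2 * tr_s), "cutoff must be below Nyquist")
  D <- dct_drift_basis(n, tr_s, cutoff_hz)
  filt <- function(Y) { # T x V
    mu <- colMeans(Y)
    Yc <- sweep(Y, 2L, mu, "-")
    if (ncol(D) > 0) Yc <- Yc - D %*% pinv_fit(D, Yc)
    if (keep_temporal_mean) Yc <- sweep(Yc, 2L, mu, "+")
    Yc
  }
  if (is_vec) return(as.numeric(filt(matrix(timeseries, ncol = 1))))
  gs <- dim(timeseries)[1:3]
  unflatten_time(filt(flatten_time(timeseries)), gs)
}

#' Morphological erosion of a binary mask
#'
#' Iterative erosion with a 6-connected (face-neighbor) structuring element:
#' a voxel survives one iteration iff it and all six face neighbors are in
#' the mask (out-of-grid neighbors count as background).
#'
#' @param mask logical/0-1 3D array.
#' @param iterations number of erosion passes (>= 0; 0 = identity).
#' @return A logical 3D array.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  assert_that(iterations >= 0, "iterations must be >= 0")
  m <- array(as.logical(mask), dim = dim(mask))
  if (iterations == 0) return(m)
  gs <- dim(m)
  shift_pad <- function(a, axis, by) {
    out <- array(FALSE, gs)
    idx_src <- lapply(gs, seq_len)
    idx_dst <- idx_src
    rng <- seq_len(gs[axis] - abs(by))
    if (by > 0) { idx_dst[[axis]] <- rng + by; idx_src[[axis]] <- rng }
    else { idx_dst[[axis]] <- rng; idx_src[[axis]] <- rng + abs(by) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (it in seq_len(iterations)) {
    keep <- m
    for (axis in 1:3) for (by in c(-1L, 1L)) {
      keep <- keep & shift_pad(m, axis, by)
    }
    m <- keep
    if (!any(m)) break
  }
  m
}

#' Apply the common preprocessing to one subject's 4D series
#'
#' Smoothing first, then high-pass filtering, matching the pipeline order in
#' which cleanup is applied to common-preprocessed data.
#'
#' @param data 4D array.
#' @param config a [preprocess_config()].
#' @param tr_s repetition time in seconds.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return A 4D array.
#' @export
preprocess_subject <- function(data, config, tr_s, voxel_size_mm) {
  sm <- gaussian_smooth(data, config$fwhm_mm, voxel_size_mm)
  highpass_filter(sm, config$highpass_cutoff_hz, tr_s,
                  keep_temporal_mean = config$keep_temporal_mean)
}
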