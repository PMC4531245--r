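#' Expand six rigid-body motion parameters to the 24-parameter set
#'
#' Columns 1-6 are the original parameters, 7-12 their backward-looking
#' temporal derivatives (first row zero), and 13-24 the elementwise squares
#' of the first twelve. All 24 columns are then demeaned.
#'
#' @param motion6 T x 6 numeric matrix (translations mm, rotations rad).
#' @return A `confound_matrix`: list with `values` (T x 24, demeaned),
#'   `column_names`, `demeaned = TRUE`.
#' @export
expand_motion_24 <- function(motion6) {
  assert_that(is.matrix(motion6) && ncol(motion6) == 6,
              "motion6 must be a T x 6 matrix")
  assert_that(nrow(motion6) >= 2, "need at least 2 time points")
  d <- rbind(0, diff(motion6))
  x12 <- cbind(motion6, d)
  vals <- cbind(x12, x12^2)
  nm <- c(paste0("mp", 1:6), paste0("mp_d", 1:6),
          paste0("mp_sq", 1:6), paste0("mp_dsq", 1:6))
  colnames(vals) <- nm
  confound_matrix(demean_cols(vals), demeaned = TRUE)
}

#' Construct a confound design matrix
#'
#' @param values T x K numeric matrix.
#' @param demeaned whether the columns have been demeaned.
#' @return A list of class `confound_matrix`.
#' @export
confound_matrix <- function(values, demeaned = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) && ncol(values) > 0) {
    colnames(values) <- paste0("x", seq_len(ncol(values)))
  }
  structure(list(values = values, column_names = colnames(values),
                 demeaned = demeaned),
            class = "confound_matrix")
}

#' Mean timeseries within a mask
#'
#' @param data 4D array.
#' @param mask non-empty logical 3D array on the same grid.
#' @return A length-T numeric vector (per-volume arithmetic mean over mask
#'   voxels).
#' @export
extract_mean_timeseries <- function(data, mask) {
  assert_that(any(mask), "mask is empty")
  assert_that(all(dim(data)[1:3] == dim(mask)), "mask/data grid mismatch")
  rowMeans(flatten_time(data, mask))
}

#' Remove the full variance of a confound design from a 4D series
#'
#' Per voxel, ordinary-least-squares residualization: the voxel's temporal
#' mean is removed, the projection onto the (demeaned) design columns is
#' subtracted, and the mean is re-added. Rank deficiency is resolved by the
#' pseudoinverse; the mean-removed residual is orthogonal to every design
#' column.
#'
#' @param data 4D array (or T x V matrix).
#' @param X a `confound_matrix` or T x K matrix (K = 0 gives the identity).
#' @return Cleaned data, same shape as the input.
#' @export
regress_out_full <- function(data, X) {
  Xv <- if (inherits(X, "confound_matrix")) X$values else as.matrix(X)
  is_mat <- is.matrix(data)
  Y <- if (is_mat) data else flatten_time(data)
  if (ncol(Xv) > 0) {
    assert_that(nrow(Xv) == nrow(Y), "design/data time dimension mismatch")
    Xc <- demean_cols(Xv)
    # unit-RMS column scaling: a no-op for the projection, but it keeps the
    # pseudoinverse truncation from discarding small-scale regressors (e.g.
    # squared rotations in rad^2) next to large-scale ones (tissue signals)
    rms <- sqrt(colMeans(Xc^2))
    keep <- rms > 1e-300
    Xc <- sweep(Xc[, keep, drop = FALSE], 2L, rms[keep], "/")
    mu <- colMeans(Y)
    Yc <- sweep(Y, 2L, mu, "-")
    if (ncol(Xc) > 0) Yc <- Yc - Xc %*% pinv_fit(Xc, Yc)
    Y <- sweep(Yc, 2L, mu, "+")
  }
  if (is_mat) Y else unflatten_time(Y, dim(data)[1:3])
}

cleanup_modes <- c("none", "motreg", "mwcreg", "comp_soft", "comp_agg")

# Error if a design has exactly collinear columns; names the offenders.
check_collinear <- function(X, context = "design") {
  if (ncol(X) < 2) return(invisible())
  Xc <- demean_cols(X)
  sds <- sqrt(colMeans(Xc^2))
  ok <- sds > 1e-12
  if (sum(ok) < 2) return(invisible())
  cc <- suppressWarnings(stats::cor(Xc[, ok, drop = FALSE]))
  cc[!upper.tri(cc)] <- 0
  bad <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    nm <- colnames(X)[ok]
    stop(sprintf("collinear columns in %s: %s ~ %s", context,
                 nm[bad[1, 1]], nm[bad[1, 2]]), call. = FALSE)
  }
  invisible()
}

#' Apply one of the five cleanup strategies
#'
#' Produces the benchmark's datasets from common-preprocessed data:
#' \describe{
#'   \item{none}{identity (the "uncleaned" dataset).}
#'   \item{motreg}{full OLS removal of the 24 motion parameters.}
#'   \item{mwcreg}{full removal of \[24 motion | mean WM signal | mean CSF
#'     signal\], the tissue means extracted from the 1-voxel-eroded
#'     `wm_roi` and `ventricle_roi` and demeaned.}
#'   \item{comp_soft}{soft component cleanup: the data and every component
#'     timecourse are first residualized on the 24 motion parameters (full
#'     motion removal); the data are then jointly regressed on *all*
#'     component timecourses and only the noise-labeled components' fitted
#'     contribution is subtracted — the unique variance of the noise
#'     components.}
#'   \item{comp_agg}{aggressive cleanup: full OLS removal of \[24 motion |
#'     noise-labeled component timecourses\].}
#' }
#' Voxel temporal means are preserved through every mode.
#'
#' @param data preprocessed 4D array.
#' @param motion6 T x 6 motion parameters.
#' @param masks a `mask_set` (needed for `mwcreg`).
#' @param decomposition a `component_decomposition` with labels (needed for
#'   the `comp_*` modes).
#' @param mode one of `"none"`, `"motreg"`, `"mwcreg"`, `"comp_soft"`,
#'   `"comp_agg"`.
#' @return Cleaned 4D array.
#' @export
clean <- function(data, motion6, masks = NULL, decomposition = NULL,
                  mode = c("none", "motreg", "mwcreg", "comp_soft", "comp_agg")) {
  mode <- match.arg(mode)
  if (mode == "none") return(data)
  m24 <- expand_motion_24(motion6)

  if (mode == "motreg") return(regress_out_full(data, m24))

  if (mode == "mwcreg") {
    assert_that(!is.null(masks), "mwcreg needs a mask_set")
    wm_roi <- erode_mask(masks$wm_roi, 1L)
    vent <- erode_mask(masks$ventricle_roi, 1L)
    if (!any(wm_roi)) wm_roi <- masks$wm_roi
    if (!any(vent)) vent <- masks$ventricle_roi
    wm_ts <- extract_mean_timeseries(data, wm_roi)
    csf_ts <- extract_mean_timeseries(data, vent)
    X <- cbind(m24$values, wm = wm_ts - mean(wm_ts),
               csf = csf_ts - mean(csf_ts))
    check_collinear(X, "mwcreg design")
    return(regress_out_full(data, X))
  }

  # component-based modes
  assert_that(!is.null(decomposition), "component modes need a decomposition")
  labels <- decomposition$labels
  assert_that(!is.null(labels) && length(labels) == ncol(decomposition$timecourses),
              "decomposition must carry one label per component")
  noise_idx <- which(labels == "noise")

  if (mode == "comp_agg") {
    X <- cbind(m24$values,
               demean_cols(decomposition$timecourses[, noise_idx, drop = FALSE]))
    check_collinear(X, "comp_agg design")
    return(regress_out_full(data, X))
  }

  # comp_soft: motion-residualize data and all component timecourses, then
  # joint fit on all components, subtract only the noise part.
  data_r <- regress_out_full(data, m24)
  if (length(noise_idx) == 0) return(data_r)
  tc_r <- regress_out_full(demean_cols(decomposition$timecourses), m24$values)
  tc_r <- demean_cols(tc_r)
  rms <- sqrt(colMeans(tc_r^2))
  tc_r <- sweep(tc_r, 2L, pmax(rms, 1e-300), "/")
  check_collinear(tc_r, "component timecourses")
  Y <- flatten_time(data_r)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu, "-")
  beta <- pinv_fit(tc_r, Yc)
  Yc <- Yc - tc_r[, noise_idx, drop = FALSE] %*% beta[noise_idx, , drop = FALSE]
  unflatten_time(sweep(Yc, 2L, mu, "+"), dim(data)[1:3])
}
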