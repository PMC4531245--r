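#' Single-subject spatial ICA
#'
#' Voxel timeseries are temporally demeaned, reduced by PCA to
#' `n_components` dimensions (`"auto"` = smallest number of components
#' explaining at least 90% of the variance, capped at 40), spatially
#' whitened, and unmixed by symmetric fixed-point iteration maximizing
#' spatial non-Gaussianity (tanh contrast). Components are ordered by
#' explained variance and sign-fixed so each spatial map's skewness is
#' non-negative. The decomposition is deterministic given `seed`.
#'
#' The reconstruction `baseline + timecourses %*% spatial_maps` equals the
#' rank-k PCA reconstruction, so the residual variance equals the discarded
#' PCA variance.
#'
#' @param data 4D array.
#' @param brain_mask logical 3D array; only mask voxels are decomposed.
#' @param n_components integer; `"auto"` (smallest k explaining 90% of the
#'   variance, capped at 40); or `"signal"` (eigenvalues above twice the
#'   median eigenvalue, i.e. clearly above the noise bulk — the most robust
#'   choice for fixed-point convergence and the pipeline default).
#' @param seed integer seed for the random orthogonal initialization.
#' @param max_iter,tol fixed-point iteration controls. Non-convergence is an
#'   error carrying the iteration count.
#' @return A list of class `component_decomposition`: `spatial_maps`
#'   (n_comp x V_mask, unit variance rows), `timecourses` (T x n_comp),
#'   `explained_variance` (fractions, non-increasing), `labels` (all
#'   `"unlabeled"`), `mask`, `voxel_means`, `n_iter`.
#' @export
spatial_ica <- function(data, brain_mask, n_components = "auto", seed = 1L,
                        max_iter = 1000L, tol = 1e-4) {
  Y <- flatten_time(data, brain_mask) # T x V
  T_ <- nrow(Y); V <- ncol(Y)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu, "-")

  Cov <- tcrossprod(Yc) / V # T x T temporal covariance over voxels
  eg <- eigen(Cov, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total_var <- sum(ev)
  assert_that(total_var > 0, "data has no variance within the mask")
  cum <- cumsum(ev) / total_var
  if (identical(n_components, "auto")) {
    k <- min(which(cum >= 0.90), 40L)
  } else if (identical(n_components, "signal")) {
    # eigenvalues clearly above the noise bulk (3x the median eigenvalue,
    # comfortably past the Marchenko-Pastur upper edge even when T/V is not
    # small); keeps the unmixing away from the degenerate noise floor
    k <- max(2L, min(sum(ev > 3 * stats::median(ev)), 40L))
  } else {
    k <- as.integer(n_components)
  }
  assert_that(k >= 1 && k < min(T_, V), "n_components must satisfy 1 <= k < min(T, V)")
  assert_that(ev[k] > 1e-12 * total_var, "requested rank exceeds data rank")

  E <- eg$vectors[, 1:k, drop = FALSE]
  d <- ev[1:k]
  Z <- (t(E) / sqrt(d)) %*% Yc # k x V, rows unit variance, uncorrelated

  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  run_fixed_point <- function(Z, k, seed_off) {
    # symmetric fixed-point iteration; a few deterministic restarts guard
    # against stalled initializations
    for (restart in 0:1) {
      set.seed(as.integer(seed) + seed_off + restart)
      W <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
      n_iter <- 0L
      while (n_iter < max_iter) {
        n_iter <- n_iter + 1L
        G <- tanh(W %*% Z)
        W_new <- (G %*% t(Z)) / V - diag(rowMeans(1 - G^2)) %*% W
        W_new <- sym_decorrelate(W_new)
        delta <- max(abs(1 - abs(rowSums(W_new * W))))
        W <- W_new
        if (delta < tol) return(list(W = W, n_iter = n_iter))
      }
    }
    NULL
  }

  # A trailing source sitting barely above the noise floor is near-Gaussian
  # after whitening and can make the fixed point oscillate indefinitely. For
  # the rule-based dimensionality choices the weakest direction is then not
  # separable and k is reduced by one before retrying; an explicit integer k
  # fails hard instead.
  adaptive <- is.character(n_components)
  k_min <- if (adaptive) 2L else k
  fit <- NULL
  while (is.null(fit) && k >= k_min) {
    fit <- run_fixed_point(Z[seq_len(k), , drop = FALSE], k, seed_off = 0L)
    if (is.null(fit)) {
      if (!adaptive || k == k_min) {
        stop(sprintf("spatial ICA did not converge after %d iterations",
                     max_iter), call. = FALSE)
      }
      k <- k - 1L
    }
  }
  W <- fit$W
  n_iter <- fit$n_iter
  E <- E[, 1:k, drop = FALSE]
  d <- d[1:k]

  S <- W %*% Z[seq_len(k), , drop = FALSE] # k x V sources, unit spatial variance
  # mixing back to data space: Yc ~ A S with A = Yc S' / V (rows of S white)
  A <- Yc %*% t(S) / V # T x k timecourses

  # with spatially white sources, component j contributes ||A_j||^2 of the
  # total variance trace(Yc Yc^T)/V = sum(ev)
  expl <- colSums(A^2) / total_var

  ord <- order(expl, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  expl <- expl[ord]

  sk <- rowMeans(S^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  A <- sweep(A, 2L, flip, "*")

  structure(list(spatial_maps = S, timecourses = A,
                 explained_variance = expl,
                 labels = rep("unlabeled", k),
                 mask = array(as.logical(brain_mask), dim = dim(brain_mask)),
                 voxel_means = mu, n_iter = n_iter),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d components, %d voxels, %d timepoints\n",
              nrow(x$spatial_maps), ncol(x$spatial_maps), nrow(x$timecourses)))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

# correlation of each component map with a reference 3D map, within mask
component_map_cor <- function(decomp, ref_map) {
  ref <- as.numeric(ref_map)[as.logical(decomp$mask)]
  if (stats::sd(ref) < 1e-12) return(rep(0, nrow(decomp$spatial_maps)))
  as.numeric(abs(stats::cor(t(decomp$spatial_maps), ref)))
}

#' Label components against the simulator's ground truth
#'
#' A component is labeled `noise` if its spatial map's absolute correlation
#' with any planted artifact map exceeds `threshold` and exceeds its best
#' network-template correlation; `signal` in the reverse case; `unlabeled`
#' otherwise (treated as signal downstream). Labels are invariant to
#' component sign flips (correlations are taken in absolute value).
#'
#' @param decomp a `component_decomposition`.
#' @param truth an `fc_ground_truth` on the same grid.
#' @param threshold absolute spatial correlation threshold (default 0.4).
#' @return The decomposition with `labels` filled in.
#' @export
label_by_ground_truth <- function(decomp, truth, threshold = 0.4) {
  art <- vapply(truth$artifact_maps, function(m) component_map_cor(decomp, m),
                numeric(nrow(decomp$spatial_maps)))
  net <- vapply(truth$template_maps, function(m) component_map_cor(decomp, m),
                numeric(nrow(decomp$spatial_maps)))
  best_art <- apply(as.matrix(art), 1L, max)
  best_net <- apply(as.matrix(net), 1L, max)
  labels <- rep("unlabeled", nrow(decomp$spatial_maps))
  labels[best_art > threshold & best_art > best_net] <- "noise"
  labels[best_net > threshold & best_net >= best_art] <- "signal"
  decomp$labels <- labels
  decomp
}

#' Rule-based component labeling
#'
#' A surrogate for trained-classifier component labeling on real data. A
#' component is labeled `noise` if ANY of the following holds:
#' \itemize{
#'   \item edge fraction — share of its top-5% absolute map weight lying in
#'     the brain-boundary shell — exceeds `edge_frac`;
#'   \item CSF fraction of the top-5% weight exceeds `csf_frac`;
#'   \item high-frequency power ratio of its timecourse (fraction of
#'     spectral power above 0.1 Hz) exceeds `hf_ratio`;
#'   \item maximum absolute correlation of its timecourse with any motion
#'     regressor exceeds `motion_cor`.
#' }
#' Otherwise `signal`.
#'
#' @param decomp a `component_decomposition`.
#' @param masks a `mask_set`.
#' @param motion24 a `confound_matrix` from [expand_motion_24()].
#' @param tr_s repetition time in seconds.
#' @param rules thresholds: named list/vector with `edge_frac`, `csf_frac`,
#'   `hf_ratio`, `motion_cor` (defaults 0.5, 0.5, 0.5, 0.6).
#' @return The decomposition with `labels` filled in.
#' @export
label_by_rules <- function(decomp, masks, motion24, tr_s,
                           rules = c(edge_frac = 0.5, csf_frac = 0.5,
                                     hf_ratio = 0.5, motion_cor = 0.6)) {
  k <- nrow(decomp$spatial_maps)
  mask_l <- as.logical(decomp$mask)
  shell <- masks$brain & !erode_mask(masks$brain, 1L)
  shell_v <- as.numeric(shell)[mask_l] > 0
  csf_v <- as.numeric(masks$csf)[mask_l] > 0

  T_ <- nrow(decomp$timecourses)
  f <- (0:(T_ - 1)) / (T_ * tr_s)
  f <- pmin(f, 1 / tr_s - f)
  hi <- f > 0.1

  mcols <- motion24$values
  msd <- apply(mcols, 2L, stats::sd)
  mok <- msd > 1e-12

  labels <- character(k)
  for (j in seq_len(k)) {
    w <- abs(decomp$spatial_maps[j, ])
    top <- w >= stats::quantile(w, 0.95)
    edge_fraction <- sum(w[top & shell_v]) / sum(w[top])
    csf_fraction <- sum(w[top & csf_v]) / sum(w[top])
    spec <- Mod(stats::fft(decomp$timecourses[, j] -
                             mean(decomp$timecourses[, j])))^2
    hf <- sum(spec[hi]) / max(sum(spec[-1]), 1e-300)
    mc <- if (any(mok)) {
      max(abs(suppressWarnings(
        stats::cor(decomp$timecourses[, j], mcols[, mok]))), na.rm = TRUE)
    } else 0
    noisy <- edge_fraction > rules[["edge_frac"]] ||
      csf_fraction > rules[["csf_frac"]] ||
      hf > rules[["hf_ratio"]] ||
      (is.finite(mc) && mc > rules[["motion_cor"]])
    labels[j] <- if (noisy) "noise" else "signal"
  }
  decomp$labels <- labels
  decomp
}
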