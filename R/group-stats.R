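#' Two-sample pooled-variance t-test from summary statistics
#'
#' `t = (mean_a - mean_b) / (s_p sqrt(1/n_a + 1/n_b))` with pooled variance
#' `s_p^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)` and
#' `df = n_a + n_b - 2`. Pooled (not Welch) variance is used: it reproduces
#' published ROI t statistics from their printed group means and SDs.
#'
#' @param a,b lists or named vectors with `mean`, `sd` (>= 0), `n` (>= 2).
#' @return A one-row tibble: `mean_diff`, `t`, `df`, `p` (two-tailed).
#' @export
#' @examples
#' two_sample_t_summary(list(mean = 10.639, sd = 2.493, n = 20),
#'                      list(mean = 8.117, sd = 2.527, n = 21))
two_sample_t_summary <- function(a, b) {
  g <- function(x, f) as.numeric(x[[f]])
  for (x in list(a, b)) {
    assert_that(g(x, "sd") >= 0, "sd must be >= 0")
    assert_that(g(x, "n") >= 2, "n must be >= 2")
  }
  if (g(a, "sd") == 0 && g(b, "sd") == 0) {
    stop("both groups have zero SD: t undefined", call. = FALSE)
  }
  na <- g(a, "n"); nb <- g(b, "n")
  sp2 <- ((na - 1) * g(a, "sd")^2 + (nb - 1) * g(b, "sd")^2) / (na + nb - 2)
  df <- na + nb - 2
  t_stat <- (g(a, "mean") - g(b, "mean")) / sqrt(sp2 * (1 / na + 1 / nb))
  tibble::tibble(mean_diff = g(a, "mean") - g(b, "mean"), t = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df))
}

#' Mean statistic within an ROI
#'
#' @param map 3D array (or `fc_zmap`-like list with `values`).
#' @param roi_mask non-empty logical 3D array.
#' @return Scalar arithmetic mean over ROI voxels.
#' @export
roi_mean_pe <- function(map, roi_mask) {
  assert_that(any(roi_mask), "ROI mask is empty")
  a <- if (is.list(map)) map$values else map
  mean(as.numeric(a)[as.logical(roi_mask)])
}

#' Group gray-matter analysis mask
#'
#' Averages per-subject GM probability maps and keeps voxels whose average
#' probability reaches `threshold_fraction` (default 0.20).
#'
#' @param gm_probability_maps non-empty list of 3D arrays in \[0, 1\].
#' @param threshold_fraction inclusion threshold on the mean map.
#' @return A logical 3D array; empty result is an error.
#' @export
build_group_gm_mask <- function(gm_probability_maps, threshold_fraction = 0.20) {
  assert_that(length(gm_probability_maps) >= 1, "need at least one map")
  avg <- Reduce(`+`, gm_probability_maps) / length(gm_probability_maps)
  out <- avg >= threshold_fraction
  assert_that(any(out), "group GM mask is empty at this threshold")
  out
}

# 26-connected component labeling of a logical 3D array. Returns an integer
# array (0 = background) plus sizes. Supra-threshold sets are typically
# sparse, so a union-find over adjacent supra voxel pairs is fast.
label_clusters_26 <- function(supra) {
  gs <- dim(supra)
  lab <- array(0L, gs)
  idx <- which(supra)
  n <- length(idx)
  if (n == 0) return(list(labels = lab, sizes = integer(0)))
  coord <- arrayInd(idx, gs)
  pos <- integer(prod(gs))
  pos[idx] <- seq_len(n)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[offsets[, 1] != 0 | offsets[, 2] != 0 | offsets[, 3] != 0, ]
  # half the offsets suffice (each undirected adjacency seen once)
  offsets <- offsets[1:(nrow(offsets) / 2), , drop = FALSE]
  for (o in seq_len(nrow(offsets))) {
    nb <- sweep(coord, 2L, as.integer(offsets[o, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] &
      nb[, 2] >= 1 & nb[, 2] <= gs[2] &
      nb[, 3] >= 1 & nb[, 3] <= gs[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * gs[1] * gs[2] + (nb[ok, 2] - 1L) * gs[1] + nb[ok, 1]
    src <- which(ok)[pos[nb_lin] > 0]
    dst <- pos[nb_lin][pos[nb_lin] > 0]
    for (p in seq_along(src)) {
      a <- find(src[p]); b <- find(dst[p])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  rl <- as.integer(factor(roots))
  lab[idx] <- rl
  list(labels = lab, sizes = as.integer(table(rl)))
}

# GLM machinery shared by the observed fit and the permutations:
# y = b0 + b1 group + b2 covariate, voxelwise t for b1.
glm_tmap <- function(Y, X, contrast_col) {
  n <- nrow(X); p <- ncol(X)
  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / (n - p)
  se <- sqrt(pmax(sigma2, 1e-300) * XtX_inv[contrast_col, contrast_col])
  t_stat <- B[contrast_col, ] / se
  t_stat[sigma2 < 1e-24] <- 0
  list(t = t_stat, df = n - p)
}

#' Voxelwise two-group permutation GLM with a nuisance covariate
#'
#' Fits `y = b0 + b1 group + b2 covariate` at every voxel and tests `b1`
#' (group coded so positive t means first-level group > second). The null
#' distribution uses Freedman-Lane permutation: residuals of the reduced
#' (covariate-only) model are permuted, the full model refitted, and the
#' uncorrected two-tailed p at each voxel is
#' `(1 + #\{|t*| >= |t|\}) / (1 + n_perm)`. Deterministic given `seed`. A
#' constant or group-collinear covariate is dropped with a warning.
#'
#' @param maps list of per-subject 3D statistic maps (or an n x V matrix
#'   already restricted to the mask).
#' @param group_labels character/factor of length n with exactly two levels;
#'   both groups need >= 2 subjects.
#' @param covariate numeric length n, or NULL.
#' @param mask logical 3D array.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return A list of class `fc_group_comparison`: `t_map`,
#'   `uncorrected_p_map` (3D), `cluster_table` (empty until
#'   [cluster_correct()]), `df`, `mask`, `n_permutations`, `seed`, plus the
#'   internal matrices needed to re-run permutations.
#' @export
permutation_group_glm <- function(maps, group_labels, covariate, mask,
                                  n_perm = 1000L, seed = 1L) {
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  gl <- as.character(group_labels)
  lev <- unique(gl)
  assert_that(length(lev) == 2, "group_labels must contain exactly two groups")
  assert_that(min(table(gl)) >= 2, "each group needs at least 2 subjects")
  Y <- if (is.matrix(maps)) maps else
    t(vapply(maps, function(m) {
      a <- if (is.list(m)) m$values else m
      as.numeric(a)[as.logical(mask)]
    }, numeric(sum(mask))))
  n <- nrow(Y)
  assert_that(n == length(gl), "one map per subject required")

  g <- ifelse(gl == lev[1], 1, 0)
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariate)) {
    cov <- as.numeric(covariate)
    drop_cov <- FALSE
    if (stats::sd(cov) < 1e-12) {
      drop_cov <- TRUE
    } else if (abs(suppressWarnings(stats::cor(cov, g))) > 1 - 1e-10) {
      drop_cov <- TRUE
    }
    if (drop_cov) {
      warning("covariate constant or collinear with group: dropped",
              call. = FALSE)
    } else {
      X <- cbind(X, covariate = cov - mean(cov))
    }
  }

  obs <- glm_tmap(Y, X, 2L)

  # Freedman-Lane: permute residuals of the reduced (no-group) model
  Z <- X[, -2L, drop = FALSE]
  Rz <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z)
  E <- Rz %*% Y
  set.seed(as.integer(seed))
  exceed <- numeric(ncol(Y))
  abs_t <- abs(obs$t)
  for (b in seq_len(n_perm)) {
    pi_b <- sample.int(n)
    tb <- glm_tmap(E[pi_b, , drop = FALSE], X, 2L)$t
    exceed <- exceed + (abs(tb) >= abs_t)
  }
  p_unc <- (1 + exceed) / (1 + n_perm)

  structure(list(
    t_map = embed_in_grid(obs$t, mask),
    uncorrected_p_map = embed_in_grid(p_unc, mask, fill = 1),
    cluster_table = tibble::tibble(cluster_id = integer(0),
                                   size_voxels = integer(0),
                                   corrected_p = numeric(0),
                                   peak_x = integer(0), peak_y = integer(0),
                                   peak_z = integer(0)),
    df = obs$df, mask = array(as.logical(mask), dim(mask)),
    n_permutations = as.integer(n_perm), seed = as.integer(seed),
    groups = lev,
    .Y = Y, .X = X, .Rz = Rz
  ), class = "fc_group_comparison")
}

#' Cluster-extent multiple-comparison correction
#'
#' Thresholds the observed |t| map at the two-tailed primary threshold
#' (default `primary_p = 0.05`), labels 26-connected supra-threshold
#' clusters, and corrects each cluster's p by the permutation distribution
#' of the maximum supra-threshold cluster size (Freedman-Lane permutations,
#' same scheme as [permutation_group_glm()]):
#' `p_corr = (1 + #\{max size* >= size\}) / (1 + n_perm)`.
#'
#' @param result an `fc_group_comparison`.
#' @param primary_p two-tailed voxel-level primary threshold (default 0.05).
#' @param n_perm permutations for the max-cluster-size null (defaults to the
#'   result's).
#' @param seed integer seed (defaults to the result's).
#' @return The result with `cluster_table` filled in (possibly empty),
#'   plus `primary_t_threshold`.
#' @export
cluster_correct <- function(result, primary_p = 0.05, n_perm = NULL,
                            seed = NULL) {
  n_perm <- as.integer(n_perm %||% result$n_permutations)
  seed <- as.integer(seed %||% result$seed)
  t_crit <- stats::qt(1 - primary_p / 2, result$df)
  mask <- result$mask
  t_obs <- result$t_map

  supra <- abs(t_obs) > t_crit & mask
  cl <- label_clusters_26(supra)
  result$primary_t_threshold <- t_crit
  if (length(cl$sizes) == 0) {
    result$cluster_table <- result$cluster_table[0, ]
    return(result)
  }

  # permutation null of the max cluster size
  Y <- result$.Y; X <- result$.X; Rz <- result$.Rz
  E <- Rz %*% Y
  set.seed(seed)
  max_sizes <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    pi_b <- sample.int(nrow(Y))
    tb <- glm_tmap(E[pi_b, , drop = FALSE], X, 2L)$t
    sup_b <- embed_in_grid(abs(tb) > t_crit, mask, fill = FALSE)
    sizes_b <- label_clusters_26(array(as.logical(sup_b), dim(mask)))$sizes
    max_sizes[b] <- if (length(sizes_b)) max(sizes_b) else 0L
  }

  rows <- lapply(seq_along(cl$sizes), function(k) {
    vox <- which(cl$labels == k)
    peak <- vox[which.max(abs(t_obs[vox]))]
    pc <- arrayInd(peak, dim(mask))
    tibble::tibble(cluster_id = k, size_voxels = cl$sizes[k],
                   corrected_p = (1 + sum(max_sizes >= cl$sizes[k])) /
                     (1 + n_perm),
                   peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  })
  result$cluster_table <- dplyr::arrange(dplyr::bind_rows(rows),
                                         .data$corrected_p,
                                         dplyr::desc(.data$size_voxels))
  result
}

#' @export
print.fc_group_comparison <- function(x, ...) {
  cat(sprintf("<fc_group_comparison> %s vs %s, df = %d, %d permutations\n",
              x$groups[1], x$groups[2], x$df, x$n_permutations))
  if (nrow(x$cluster_table)) {
    cat(sprintf("  %d clusters, min corrected p = %.4f\n",
                nrow(x$cluster_table), min(x$cluster_table$corrected_p)))
  } else {
    cat("  no supra-threshold clusters (run cluster_correct())\n")
  }
  invisible(x)
}

#' Bundled reference ROI summary statistics
#'
#' Published group summary statistics (mean, SD, n) of DMN parameter
#' estimates in a posterior-cingulate/precuneus ROI from a 1.5 T elderly
#' HC-vs-AD benchmark of the five cleanup strategies, for both FC methods.
#' Used as worked-example inputs to [two_sample_t_summary()].
#'
#' @return A tibble: `fc_method`, `cleanup`, `group`, `mean`, `sd`, `n`.
#' @export
reference_roi_stats <- function() {
  tibble::tribble(
    ~fc_method, ~cleanup,    ~group, ~mean,  ~sd,    ~n,
    "seed",     "none",      "HC",   0.280,  0.195,  20,
    "seed",     "none",      "AD",   0.314,  0.208,  21,
    "seed",     "motreg",    "HC",   0.203,  0.084,  20,
    "seed",     "motreg",    "AD",   0.233,  0.139,  21,
    "seed",     "mwcreg",    "HC",   0.190,  0.068,  20,
    "seed",     "mwcreg",    "AD",   0.186,  0.086,  21,
    "seed",     "comp_soft", "HC",   0.222,  0.080,  20,
    "seed",     "comp_soft", "AD",   0.177,  0.107,  21,
    "seed",     "comp_agg",  "HC",   0.175,  0.062,  20,
    "seed",     "comp_agg",  "AD",   0.133,  0.054,  21,
    "dualreg",  "none",      "HC",   17.640, 10.337, 20,
    "dualreg",  "none",      "AD",   19.588, 11.971, 21,
    "dualreg",  "motreg",    "HC",   12.296, 4.089,  20,
    "dualreg",  "motreg",    "AD",   12.222, 5.332,  21,
    "dualreg",  "mwcreg",    "HC",   11.712, 3.471,  20,
    "dualreg",  "mwcreg",    "AD",   10.619, 3.446,  21,
    "dualreg",  "comp_soft", "HC",   12.223, 3.194,  20,
    "dualreg",  "comp_soft", "AD",   10.109, 4.345,  21,
    "dualreg",  "comp_agg",  "HC",   10.639, 2.493,  20,
    "dualreg",  "comp_agg",  "AD",   8.117,  2.527,  21
  )
}

#' ROI t-tests from a table of group summary statistics
#'
#' Applies [two_sample_t_summary()] (first group vs second) to each
#' `(fc_method, cleanup)` stratum of a summary table shaped like
#' [reference_roi_stats()].
#'
#' @param stats_tbl tibble with columns `fc_method`, `cleanup`, `group`,
#'   `mean`, `sd`, `n`.
#' @param group_order character(2): which group is "a" (first) in the test.
#' @return A tibble with one row per stratum: `fc_method`, `cleanup`,
#'   `mean_diff`, `t`, `df`, `p`.
#' @export
roi_t_table <- function(stats_tbl, group_order = c("HC", "AD")) {
  stats_tbl |>
    dplyr::group_by(.data$fc_method, .data$cleanup) |>
    dplyr::group_modify(function(d, key) {
      a <- d[d$group == group_order[1], ]
      b <- d[d$group == group_order[2], ]
      two_sample_t_summary(list(mean = a$mean, sd = a$sd, n = a$n),
                           list(mean = b$mean, sd = b$sd, n = b$n))
    }) |>
    dplyr::ungroup()
}
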