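#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a voxelwise group comparison
#'
#' @param x an `fc_group_comparison`.
#' @param ... unused.
#' @return The cluster table as a tibble (one row per supra-threshold
#'   cluster), empty if [cluster_correct()] has not been run or found none.
#' @export
tidy.fc_group_comparison <- function(x, ...) {
  x$cluster_table
}

#' @rdname tidy.fc_group_comparison
#' @return `glance()` returns a one-row tibble: `df`, `n_permutations`,
#'   `n_clusters`, `min_corrected_p`, `max_abs_t`.
#' @export
glance.fc_group_comparison <- function(x, ...) {
  tibble::tibble(
    df = x$df, n_permutations = x$n_permutations,
    n_clusters = nrow(x$cluster_table),
    min_corrected_p = if (nrow(x$cluster_table)) min(x$cluster_table$corrected_p)
                      else NA_real_,
    max_abs_t = max(abs(x$t_map[x$mask])))
}

#' Tidy a benchmark run
#'
#' @param x an `fc_benchmark`.
#' @param ... unused.
#' @return The ROI statistics table (one row per FC method x cleanup).
#' @export
tidy.fc_benchmark <- function(x, ...) x$roi

#' @rdname tidy.fc_benchmark
#' @export
glance.fc_benchmark <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_cleanups = length(unique(x$roi$cleanup)),
    n_fc_methods = length(unique(x$roi$fc_method)),
    n_voxelwise = length(x$comparisons),
    seed = x$config$seed)
}

#' Boxplot of median temporal SNR by cleanup and group
#'
#' @param object an `fc_benchmark`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fc_benchmark <- function(object, ...) {
  d <- dplyr::mutate(object$tsnr,
                     cleanup = factor(.data$cleanup, levels = cleanup_modes))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cleanup, y = .data$median_tsnr,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "cleanup", y = "median temporal SNR",
                  title = "Temporal SNR by cleanup strategy") +
    ggplot2::theme_minimal()
}

#' Within-group consistency by cleanup
#'
#' Mean within-brain across-subject SD of the FC maps (lower = more
#' consistent), by cleanup, FC method and group.
#'
#' @param bench an `fc_benchmark`.
#' @return A ggplot.
#' @export
plot_consistency <- function(bench) {
  d <- dplyr::mutate(bench$consistency,
                     cleanup = factor(.data$cleanup, levels = cleanup_modes))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cleanup, y = .data$mean_sd,
                                  colour = .data$group,
                                  group = .data$group)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~fc_method, scales = "free_y") +
    ggplot2::labs(x = "cleanup", y = "mean across-subject SD",
                  title = "Within-group FC consistency") +
    ggplot2::theme_minimal()
}

#' Axial montage of a 3D statistic map
#'
#' @param map 3D array.
#' @param slices z indices to show (default: 4 evenly spaced).
#' @return A ggplot.
#' @export
plot_map_slices <- function(map, slices = NULL) {
  gs <- dim(map)
  slices <- slices %||% unique(round(seq(2, gs[3] - 1, length.out = 4)))
  d <- purrr::map_dfr(slices, function(z) {
    tibble::tibble(x = rep(seq_len(gs[1]), gs[2]),
                   y = rep(seq_len(gs[2]), each = gs[1]),
                   value = as.numeric(map[, , z]), z = z)
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, nrow = 1) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
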