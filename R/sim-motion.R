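#' Generate rigid-body motion parameter traces
#'
#' Produces a smooth random-walk realization of six rigid-body parameters
#' (3 translations in mm, then 3 rotations in rad), rescaled so the mean
#' relative displacement — the mean over time of the Euclidean norm of the
#' frame-to-frame translation difference — equals `amplitude` mm. Rotations
#' follow walks of proportionally smaller magnitude.
#'
#' @param n_volumes number of time points (>= 2).
#' @param amplitude target mean relative displacement in mm (>= 0; 0 returns
#'   an all-zero matrix).
#' @param seed integer seed; fixed seed gives identical output.
#' @return An `n_volumes` x 6 numeric matrix with attribute
#'   `mean_relative_displacement`.
#' @export
#' @examples
#' m <- generate_motion_params(160, 0.07, seed = 1)
#' attr(m, "mean_relative_displacement")
generate_motion_params <- function(n_volumes, amplitude, seed = 1L) {
  assert_that(n_volumes >= 2, "n_volumes must be >= 2")
  assert_that(amplitude >= 0, "amplitude must be >= 0")
  n_volumes <- as.integer(n_volumes)
  if (amplitude == 0) {
    out <- matrix(0, n_volumes, 6)
    attr(out, "mean_relative_displacement") <- 0
    return(out)
  }
  set.seed(as.integer(seed))
  smooth_walk <- function(n) {
    w <- cumsum(stats::rnorm(n))
    k <- min(5L, n)
    stats::filter(w, rep(1 / k, k), sides = 2) -> sm
    sm[is.na(sm)] <- w[is.na(sm)]
    as.numeric(sm - mean(sm))
  }
  m <- vapply(1:6, function(j) smooth_walk(n_volumes), numeric(n_volumes))
  mrd0 <- mean_relative_displacement(m)
  if (mrd0 < .Machine$double.eps) {
    out <- matrix(0, n_volumes, 6)
    attr(out, "mean_relative_displacement") <- 0
    return(out)
  }
  m[, 1:3] <- m[, 1:3] * (amplitude / mrd0)
  # rotations ~ amplitude/50 rad scale, i.e. small angles
  for (j in 4:6) m[, j] <- m[, j] * (amplitude / 50) / max(stats::sd(m[, j]), 1e-12)
  attr(m, "mean_relative_displacement") <- mean_relative_displacement(m)
  m
}

#' Mean relative displacement of a motion trace
#'
#' Mean over frames of the Euclidean norm of the frame-to-frame translation
#' difference (first three columns), the scalar summarized per group in
#' cohort demographics tables.
#'
#' @param motion6 T x 6 motion-parameter matrix.
#' @return A scalar (mm).
#' @export
mean_relative_displacement <- function(motion6) {
  assert_that(is.matrix(motion6) && ncol(motion6) == 6,
              "motion6 must be a T x 6 matrix")
  d <- diff(motion6[, 1:3, drop = FALSE])
  mean(sqrt(rowSums(d^2)))
}
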