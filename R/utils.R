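# Internal helpers shared across modules. Voxel data travel as base-R arrays
# (3D masks/maps, 4D time series); most temporal math happens on T x V
# matrices obtained by flattening space.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Flatten a 4D (x,y,z,t) array to a T x V matrix (voxels in column-major
# spatial order). If `mask` is given, only mask voxels are kept.
flatten_time <- function(data, mask = NULL) {
  assert_that(length(dim(data)) == 4L, "`data` must be a 4D array (x, y, z, t)")
  d <- dim(data)
  m <- matrix(data, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(mask)) m <- m[as.logical(mask), , drop = FALSE]
  t(m)
}

# Inverse of flatten_time for full-grid matrices.
unflatten_time <- function(mat, grid_shape) {
  assert_that(ncol(mat) == prod(grid_shape), "matrix/grid size mismatch")
  array(t(mat), dim = c(grid_shape, nrow(mat)))
}

# Put a vector of per-voxel values (over mask voxels) back into a 3D image,
# `fill` elsewhere.
embed_in_grid <- function(values, mask, fill = 0) {
  out <- array(fill, dim = dim(mask))
  out[as.logical(mask)] <- values
  out
}

# Deterministic derived seeds: one global seed expands into per-stage,
# per-unit seeds so stages can be re-run in isolation. Kept below 2^31.
derive_seed <- function(seed, stage, index = 0L) {
  stage_id <- sum(utf8ToInt(as.character(stage))) %% 997L
  as.integer((as.double(seed %% 100000L) * 20011 +
                as.double(stage_id) * 130003 +
                as.double(index) * 7919) %% 2147483629) + 1L
}

# Column-demean a matrix.
demean_cols <- function(x) sweep(x, 2L, colMeans(x), "-")

# Moore-Penrose least squares fit: coefficients for Y ~ X (no intercept
# handling here; callers demean). Uses SVD so rank-deficient designs are
# resolved by the pseudoinverse.
pinv_fit <- function(X, Y, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(X), ncol(Y)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * (t(s$u[, keep, drop = FALSE]) %*% Y))
}

# Sample SD over rows of a matrix, returned per column (n-1 denominator).
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

# Band-limited Gaussian series: white noise FFT-masked to [f_lo, f_hi] Hz,
# rescaled to unit SD (zeros if the band is empty on this grid).
bandlimited_noise <- function(n, tr_s, f_lo, f_hi) {
  f <- (0:(n - 1)) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f) # two-sided frequency magnitude
  keep <- f >= f_lo & f <= f_hi
  if (!any(keep)) return(numeric(n))
  spec <- stats::fft(stats::rnorm(n))
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(numeric(n))
  (x - mean(x)) / s
}

scale_to_unit_sd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(x * 0)
  (x - mean(x)) / s
}
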