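#' Tissue and region masks for the synthetic cohort grid
#'
#' Builds a self-contained "standard space": an ellipsoidal brain with
#' concentric CSF (ventricle), white-matter and gray-matter compartments,
#' plus the analysis regions — a posterior seed sphere (the PCC stand-in),
#' a surrounding posterior ROI (PCC + precuneus stand-in), a ventricular
#' ROI and a deep white-matter ROI used for mean-signal confound extraction.
#'
#' Tissue classes are mutually exclusive and all masks are subsets of the
#' brain mask; `seed_sphere` is a subset of `posterior_roi`, itself a subset
#' of gray matter. Posterior is the low-y side of the grid.
#'
#' @param grid_shape integer(3) voxels per axis.
#' @param voxel_size_mm isotropic voxel size (the seed sphere has a 6 mm
#'   radius in world units).
#' @return A list of class `mask_set` with logical 3D arrays `brain`, `gm`,
#'   `wm`, `csf`, `ventricle_roi`, `wm_roi`, `seed_sphere`, `posterior_roi`,
#'   plus `seed_center` (voxel indices) and `grid_shape`.
#' @export
build_mask_set <- function(grid_shape, voxel_size_mm = 3.0) {
  grid_shape <- as.integer(grid_shape)
  assert_that(length(grid_shape) == 3L && all(grid_shape >= 4L),
              "grid_shape must be three axis lengths >= 4")
  ctr <- (grid_shape + 1) / 2
  semi <- 0.45 * grid_shape

  ax <- lapply(1:3, function(i) ((1:grid_shape[i]) - ctr[i]) / semi[i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  r <- sqrt(r2)

  brain <- r <= 1
  csf <- r <= 0.25
  wm <- r > 0.25 & r <= 0.62
  gm <- r > 0.62 & r <= 1

  # Seed centered on the posterior gray-matter shell (low y), mid x/z.
  seed_center <- c(round(ctr[1]), round(ctr[2] - 0.80 * semi[2]), round(ctr[3]))
  seed_center <- pmin(pmax(seed_center, 1L), grid_shape)

  ball <- function(center, radius_vox) {
    dx <- lapply(1:3, function(i) (1:grid_shape[i]) - center[i])
    d2 <- outer(outer(dx[[1]]^2, dx[[2]]^2, "+"), dx[[3]]^2, "+")
    d2 <= radius_vox^2
  }

  # analysis regions scale with the anatomy (fractions of the ellipsoid
  # semi-axes), so reduced-scale grids keep the same relative geometry
  posterior_roi <- ball(seed_center, 0.36 * semi[2]) & gm
  seed_radius_vox <- max(1, 6 / voxel_size_mm)
  seed_sphere <- ball(seed_center, seed_radius_vox) & posterior_roi

  ventricle_roi <- csf
  wm_roi <- ball(round(ctr + c(0, 0.41 * semi[2], 0)), 0.28 * semi[2]) & wm

  if (!any(seed_sphere) || !any(wm_roi) || !any(ventricle_roi)) {
    stop("grid too small to contain all masks", call. = FALSE)
  }

  structure(list(brain = brain, gm = gm, wm = wm, csf = csf,
                 ventricle_roi = ventricle_roi, wm_roi = wm_roi,
                 seed_sphere = seed_sphere, posterior_roi = posterior_roi,
                 seed_center = seed_center, grid_shape = grid_shape),
            class = "mask_set")
}
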