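#' Simulation configuration for a synthetic two-group rsfMRI cohort
#'
#' Bundles every knob of the cohort generator. Defaults mirror the study
#' design the package benchmarks: 20 healthy controls vs 21 patients,
#' 160 volumes at TR = 2.5 s on a ~3 mm grid, ten resting-state network
#' templates of which one is a four-node default mode network (DMN), and a
#' multiplicative deficit applied to the patients' posterior-DMN amplitude.
#'
#' Artifact amplitudes are expressed in the same arbitrary signal units as
#' the networks (`network_amplitude`) and thermal noise (`noise_sd`); the
#' positive `baseline` keeps temporal SNR well defined. Per-subject artifact
#' strengths are log-normally dispersed around these amplitudes
#' (`artifact_cv`), which is what makes uncleaned between-subject FC maps
#' inconsistent.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_volumes number of time points (>= 2).
#' @param tr_s repetition time in seconds.
#' @param n_hc,n_ad group sizes (healthy controls / patients).
#' @param n_templates number of network templates (>= 2; template 1 is the DMN).
#' @param dmn_deficit multiplicative factor in \[0, 1\] applied to the
#'   patients' posterior-DMN amplitude (1 = no group effect).
#' @param artifact_amplitudes named numeric scales for the five artifact
#'   classes: `motion`, `csf`, `wm_drift`, `vessel`, `scanner_drift`.
#'   Set entries to 0 to disable a source.
#' @param artifact_cv named log-SD of the per-subject multiplicative jitter
#'   applied to each artifact amplitude.
#' @param network_amplitude SD of each network's contribution at its peak voxel.
#' @param network_amp_sdlog log-SD of per-subject network amplitude jitter.
#' @param dmn_node_sdlog log-SD of the per-subject posterior-node weight of
#'   the DMN — the biological between-subject FC variability that cleanup
#'   must preserve (FC statistics are invariant to overall amplitude, so
#'   between-subject variability of interest has to live in network shape).
#' @param noise_sd thermal (white) noise standard deviation.
#' @param baseline positive mean intensity added inside the brain mask.
#' @param motion_mrd named mean relative displacement targets (mm) per group.
#' @param motion_mrd_sd named between-subject SDs of the displacement target.
#' @param gm_volume list with `hc_mean`, `ad_mean`, `sd`: normalized
#'   gray-matter volume covariate distribution per group.
#' @param vessel_dmn_rho correlation planted between the vessel artifact
#'   timecourse and the DMN timecourse (vascular signal rides on the network).
#' @param vessel_jitter_sd SD (voxels) of the per-subject in-plane offset of
#'   the vessel course (rounded, clipped to +/- 2): vascular anatomy differs
#'   across subjects, which is what makes uncleaned FC maps spatially
#'   inconsistent.
#' @param random_seed integer seed; identical config + seed gives a
#'   bit-identical cohort.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(grid_shape = c(12, 14, 10), n_volumes = 40)
#' cfg$n_hc + cfg$n_ad
sim_config <- function(grid_shape = c(24L, 28L, 22L),
                       voxel_size_mm = 3.0,
                       n_volumes = 160L,
                       tr_s = 2.5,
                       n_hc = 20L,
                       n_ad = 21L,
                       n_templates = 10L,
                       dmn_deficit = 0.6,
                       artifact_amplitudes = c(motion = 18, csf = 30,
                                               wm_drift = 12, vessel = 35,
                                               scanner_drift = 4),
                       artifact_cv = c(motion = 0.5, csf = 0.4,
                                       wm_drift = 0.4, vessel = 0.7,
                                       scanner_drift = 0.3),
                       network_amplitude = 10,
                       network_amp_sdlog = 0.1,
                       dmn_node_sdlog = 0.2,
                       noise_sd = 5,
                       baseline = 1000,
                       motion_mrd = c(hc = 0.07, ad = 0.09),
                       motion_mrd_sd = c(hc = 0.04, ad = 0.06),
                       gm_volume = list(hc_mean = 0.45, ad_mean = 0.40, sd = 0.03),
                       vessel_dmn_rho = 0.15,
                       vessel_jitter_sd = 1.2,
                       random_seed = 1L) {
  cfg <- list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_volumes = as.integer(n_volumes), tr_s = tr_s,
    n_hc = as.integer(n_hc), n_ad = as.integer(n_ad),
    n_templates = as.integer(n_templates), dmn_deficit = dmn_deficit,
    artifact_amplitudes = artifact_amplitudes, artifact_cv = artifact_cv,
    network_amplitude = network_amplitude,
    network_amp_sdlog = network_amp_sdlog,
    dmn_node_sdlog = dmn_node_sdlog,
    noise_sd = noise_sd, baseline = baseline,
    motion_mrd = motion_mrd, motion_mrd_sd = motion_mrd_sd,
    gm_volume = gm_volume, vessel_dmn_rho = vessel_dmn_rho,
    vessel_jitter_sd = vessel_jitter_sd,
    random_seed = as.integer(random_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

artifact_names <- c("motion", "csf", "wm_drift", "vessel", "scanner_drift")

validate_sim_config <- function(cfg) {
  assert_that(length(cfg$grid_shape) == 3L && all(cfg$grid_shape >= 4L),
              "grid_shape must be three axis lengths >= 4")
  assert_that(cfg$n_volumes >= 2L, "n_volumes must be >= 2")
  assert_that(cfg$tr_s > 0, "tr_s must be positive")
  assert_that(cfg$n_hc >= 1L && cfg$n_ad >= 1L, "group sizes must be >= 1")
  assert_that(cfg$n_templates >= 2L, "need at least 2 network templates")
  assert_that(cfg$dmn_deficit >= 0 && cfg$dmn_deficit <= 1,
              "dmn_deficit must lie in [0, 1]")
  assert_that(all(artifact_names %in% names(cfg$artifact_amplitudes)),
              paste("artifact_amplitudes must name:",
                    paste(artifact_names, collapse = ", ")))
  assert_that(all(cfg$artifact_amplitudes >= 0), "artifact amplitudes must be >= 0")
  assert_that(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(cfg$baseline > 0, "baseline must be positive")
  invisible(cfg)
}

#' A reduced-scale configuration for fast simulation studies
#'
#' Same study design (group sizes, TR, deficit, artifact mix) on a smaller
#' grid with fewer volumes. Used by the package's own replicate simulations
#' (power and calibration studies) where hundreds of cohorts are generated.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
smoke_config <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(12L, 14L, 10L),
                                 n_volumes = 40L), list(...))
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n",
      sprintf("  grid %s @ %.1f mm, T = %d, TR = %.2f s\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              x$n_volumes, x$tr_s),
      sprintf("  groups: %d HC / %d AD, dmn_deficit = %.2f\n",
              x$n_hc, x$n_ad, x$dmn_deficit),
      sprintf("  templates: %d, noise_sd = %.2f, seed = %d\n",
              x$n_templates, x$noise_sd, x$random_seed), sep = "")
  invisible(x)
}
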