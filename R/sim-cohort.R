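#' @title Synthetic two-group rsfMRI cohort with known ground truth
#' @description
#' `generate_cohort()` simulates every subject's 4D BOLD series as
#' \deqn{data = baseline + \sum_k map_k \cdot tc_k + \sum_j artifact_j \cdot
#' atc_j + noise,}
#' where the `map_k` are ten spatial network templates (template 1 a four-node
#' DMN whose posterior node overlaps the seed sphere), the `tc_k` are
#' band-limited (0.01-0.1 Hz) network timecourses with subject-specific
#' amplitudes, and the artifact terms are the five planted noise sources
#' (edge-dominant motion, ventricular CSF pulsation, white-matter drift, a
#' thin vessel-like map near the posterior node, and global scanner drift).
#' Patients' posterior-DMN contribution is multiplied by
#' `config$dmn_deficit`, the planted group effect. The motion artifact
#' timecourse is a fixed linear mix of the 24-parameter expansion of the
#' subject's own motion trace, so full motion regression can remove it
#' exactly; the vessel timecourse carries a planted correlation with the DMN
#' timecourse (vascular signal riding on the network), which is what
#' distinguishes soft from aggressive component cleanup.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cohort` (class `fc_cohort`: `subjects`,
#'   `masks`, `grid`) and `truth` (class `fc_ground_truth`: canonical
#'   `template_maps`, `dmn_index`, the split `dmn_anterior_map` (the non-posterior nodes) /
#'   `dmn_posterior_map`, per-subject `network_timecourses` and
#'   `artifact_timecourses` (amplitudes baked in), `artifact_maps`, `masks`,
#'   `gm_volume`, `planted_effect`).
#' @export
#' @examples
#' sim <- generate_cohort(smoke_config(random_seed = 7))
#' length(sim$cohort$subjects)
generate_cohort <- function(config) {
  validate_sim_config(config)
  masks <- build_mask_set(config$grid_shape, config$voxel_size_mm)
  tpl <- build_templates(config, masks)
  amaps <- build_artifact_maps(masks)

  n <- config$n_hc + config$n_ad
  groups <- rep(c("HC", "AD"), c(config$n_hc, config$n_ad))
  K <- config$n_templates
  T_ <- config$n_volumes
  brain <- masks$brain
  V <- prod(config$grid_shape)

  amap_mat <- vapply(amaps, as.numeric, numeric(V)) # V x 5
  tpl_mat <- vapply(tpl$maps, as.numeric, numeric(V)) # V x K
  ant_vec <- as.numeric(tpl$dmn_anterior)
  post_vec <- as.numeric(tpl$dmn_posterior)

  subjects <- vector("list", n)
  net_tcs <- vector("list", n)
  art_tcs <- vector("list", n)
  vessel_maps <- vector("list", n)
  gm_volume <- numeric(n)
  planted <- numeric(n)
  node_gains <- numeric(n)

  for (i in seq_len(n)) {
    set.seed(derive_seed(config$random_seed, "subject", i))
    g <- tolower(groups[i])

    mrd_target <- max(0.01, stats::rnorm(1, config$motion_mrd[[g]],
                                         config$motion_mrd_sd[[g]]))
    motion6 <- generate_motion_params(T_, mrd_target,
                                      seed = derive_seed(config$random_seed,
                                                         "motion", i))
    set.seed(derive_seed(config$random_seed, "signal", i))

    amp_k <- config$network_amplitude *
      exp(stats::rnorm(K, 0, config$network_amp_sdlog))
    tc <- vapply(seq_len(K),
                 function(k) bandlimited_noise(T_, config$tr_s, 0.01, 0.10),
                 numeric(T_))
    tc <- sweep(tc, 2L, amp_k, "*") # T x K, amplitudes baked in

    effect <- if (groups[i] == "AD") config$dmn_deficit else 1
    planted[i] <- effect
    # biological posterior-node weight, preserved by any valid cleanup
    node_gain <- exp(stats::rnorm(1, 0, config$dmn_node_sdlog))

    a_amp <- config$artifact_amplitudes[artifact_names] *
      exp(stats::rnorm(5, 0, config$artifact_cv[artifact_names]))
    atc <- matrix(0, T_, 5, dimnames = list(NULL, artifact_names))
    atc[, "motion"] <- motion_artifact_timecourse(motion6)
    atc[, "csf"] <- scale_to_unit_sd(
      0.6 * sin(2 * pi * 0.13 * config$tr_s * seq_len(T_)) +
        0.8 * bandlimited_noise(T_, config$tr_s, 0.08, 0.19))
    atc[, "wm_drift"] <- bandlimited_noise(T_, config$tr_s, 0.005, 0.04)
    rho <- config$vessel_dmn_rho
    dmn_unit <- scale_to_unit_sd(tc[, tpl$dmn_index])
    atc[, "vessel"] <- scale_to_unit_sd(
      rho * dmn_unit + sqrt(max(0, 1 - rho^2)) *
        bandlimited_noise(T_, config$tr_s, 0.05, 0.19))
    tt <- seq_len(T_) / T_
    atc[, "scanner_drift"] <- scale_to_unit_sd(tt - 0.5 + 0.3 * (tt - 0.5)^2)
    atc <- sweep(atc, 2L, a_amp, "*")

    # subject-effective DMN map: anterior node + (node gain x planted
    # effect) x posterior node
    eff_tpl <- tpl_mat
    eff_tpl[, tpl$dmn_index] <- ant_vec + node_gain * effect * post_vec
    node_gains[i] <- node_gain

    # per-subject vascular anatomy: displaced vessel course
    shift <- pmin(pmax(round(stats::rnorm(2, 0, config$vessel_jitter_sd)),
                       -2L), 2L)
    vessel_maps[[i]] <- vessel_map(masks, shift)
    amap_i <- amap_mat
    amap_i[, which(artifact_names == "vessel")] <- as.numeric(vessel_maps[[i]])

    dat <- eff_tpl %*% t(tc) + amap_i %*% t(atc) # V x T
    dat <- dat + config$baseline * as.numeric(brain)
    if (config$noise_sd > 0) {
      dat <- dat + as.numeric(brain) *
        matrix(stats::rnorm(V * T_, 0, config$noise_sd), V, T_)
    }

    gm_volume[i] <- stats::rnorm(
      1,
      if (groups[i] == "AD") config$gm_volume$ad_mean else config$gm_volume$hc_mean,
      config$gm_volume$sd)

    subjects[[i]] <- structure(list(
      subject_id = sprintf("sub-%03d", i),
      group = groups[i],
      data = array(dat, dim = c(config$grid_shape, T_)),
      motion6 = motion6,
      gm_volume = gm_volume[i]
    ), class = "fc_subject")
    net_tcs[[i]] <- tc
    art_tcs[[i]] <- atc
  }

  grid <- list(shape = config$grid_shape,
               voxel_size_mm = config$voxel_size_mm,
               affine = diag(c(rep(config$voxel_size_mm, 3), 1)))
  cohort <- structure(list(subjects = subjects, masks = masks, grid = grid,
                           config = config),
                      class = "fc_cohort")
  truth <- structure(list(
    template_maps = tpl$maps, dmn_index = tpl$dmn_index,
    dmn_anterior_map = tpl$dmn_anterior, dmn_posterior_map = tpl$dmn_posterior,
    network_timecourses = net_tcs, artifact_maps = amaps,
    vessel_maps = vessel_maps,
    artifact_timecourses = art_tcs, masks = masks,
    gm_volume = gm_volume, planted_effect = planted,
    node_gain = node_gains,
    baseline = config$baseline
  ), class = "fc_ground_truth")
  list(cohort = cohort, truth = truth)
}

# Ten fixed template centers in normalized ellipsoid coordinates; template 1
# is the four-node DMN (posterior node at the seed center).
template_centers_norm <- function() {
  rbind(
    c(0.00, -0.80, 0.00),  # DMN posterior node (other nodes added separately)
    c(0.75, -0.35, 0.30),
    c(0.80, 0.00, 0.25),
    c(-0.80, 0.00, 0.25),
    c(0.00, 0.00, 0.85),
    c(0.55, 0.55, -0.15),
    c(-0.55, 0.55, -0.15),
    c(0.60, -0.45, -0.35),
    c(-0.60, -0.45, -0.35),
    c(0.00, 0.45, -0.70)
  )
}

gaussian_blob <- function(grid_shape, center_vox, sigma_vox) {
  dx <- lapply(1:3, function(i) (1:grid_shape[i]) - center_vox[i])
  d2 <- outer(outer(dx[[1]]^2, dx[[2]]^2, "+"), dx[[3]]^2, "+")
  exp(-d2 / (2 * sigma_vox^2))
}

build_templates <- function(config, masks) {
  gs <- config$grid_shape
  ctr <- (gs + 1) / 2
  semi <- 0.45 * gs
  sigma <- 0.14 * mean(gs)
  centers <- template_centers_norm()
  K <- config$n_templates
  assert_that(K <= nrow(centers) + 1,
              sprintf("at most %d templates supported", nrow(centers) + 1))
  to_vox <- function(cn) ctr + cn * semi

  # four-node DMN: posterior cingulate/precuneus node (peak 1, the node
  # carrying the planted deficit), medial prefrontal node (0.8), and
  # bilateral lateral-parietal nodes (0.55 each). The spatial extent keeps a
  # focal vessel from resembling the whole network template.
  post <- gaussian_blob(gs, to_vox(centers[1, ]), sigma) * masks$brain
  fixed <- (0.8 * gaussian_blob(gs, to_vox(c(0, 0.80, 0)), sigma) +
              0.55 * gaussian_blob(gs, to_vox(c(0.55, -0.55, 0.25)), sigma) +
              0.55 * gaussian_blob(gs, to_vox(c(-0.55, -0.55, 0.25)), sigma)) *
    masks$brain
  maps <- vector("list", K)
  dmn <- post + fixed
  maps[[1]] <- dmn / max(dmn)
  for (k in 2:K) {
    b <- gaussian_blob(gs, to_vox(centers[k, ]), sigma) * masks$brain
    maps[[k]] <- b / max(b)
  }
  sc <- 1 / max(dmn)
  list(maps = maps, dmn_index = 1L,
       dmn_posterior = post * sc, dmn_anterior = fixed * sc)
}

build_artifact_maps <- function(masks, vessel_shift = c(0L, 0L)) {
  gs <- masks$grid_shape
  interior <- erode_mask(masks$brain, 1L)
  shell <- masks$brain & !interior
  motion <- as.numeric(shell) + 0.35 * as.numeric(interior)
  motion <- array(motion, gs)

  csf <- array(as.numeric(masks$csf), gs)
  wm <- array(as.numeric(masks$wm), gs)
  drift <- array(as.numeric(masks$brain), gs)

  list(motion = motion, csf = csf, wm_drift = wm,
       vessel = vessel_map(masks, vessel_shift), scanner_drift = drift)
}

# Thin elongated vessel emulating the sagittal/straight sinus: a narrow
# midline arc hugging the posterior brain surface (normalized ellipsoid
# radius ~0.9), passing within a voxel or two of the seed sphere but
# spatially extended over the whole posterior rim, so its map stays distinct
# from the (compact-node) network templates. `shift` displaces the course
# laterally (x) and radially, emulating between-subject vascular anatomy.
vessel_map <- function(masks, shift = c(0L, 0L)) {
  gs <- masks$grid_shape
  ctr <- (gs + 1) / 2
  semi <- 0.45 * gs
  ax <- lapply(1:3, function(i) ((1:gs[i]) - ctr[i]) / semi[i])
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  r0 <- 0.90 + 0.025 * shift[2]
  radial <- exp(-((r - r0) / 0.06)^2 / 2)
  x0 <- ctr[1] + shift[1]
  lateral <- exp(-((1:gs[1]) - x0)^2 / (2 * 1.2^2))
  posterior <- as.numeric((1:gs[2]) < ctr[2])
  arr <- radial * array(rep(outer(lateral, posterior), gs[3]), gs)
  arr * masks$brain
}

# Fixed deterministic mix of the 24-parameter motion expansion; unit SD.
motion_artifact_timecourse <- function(motion6) {
  e24 <- expand_motion_24(motion6)$values
  w <- ((-1)^(1:24)) / sqrt(1:24)
  scale_to_unit_sd(as.numeric(e24 %*% w))
}

#' Subject table of a simulated cohort
#'
#' @param cohort an `fc_cohort`.
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `gm_volume`, `mean_relative_displacement`.
#' @export
subjects_table <- function(cohort) {
  tibble::tibble(
    subject_id = purrr::map_chr(cohort$subjects, "subject_id"),
    group = purrr::map_chr(cohort$subjects, "group"),
    gm_volume = purrr::map_dbl(cohort$subjects, "gm_volume"),
    mean_relative_displacement =
      purrr::map_dbl(cohort$subjects,
                     ~ mean_relative_displacement(.x$motion6))
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  tab <- table(purrr::map_chr(x$subjects, "group"))
  cat(sprintf("<fc_cohort> %d subjects (%s), grid %s, T = %d\n",
              length(x$subjects),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              paste(x$grid$shape, collapse = "x"),
              dim(x$subjects[[1]]$data)[4]))
  invisible(x)
}

#' Write a cohort to disk (NIfTI + text sidecars)
#'
#' One 4D NIfTI per subject, each mask as a 3D NIfTI, motion parameters as
#' 6-column whitespace-delimited text, covariates and the file manifest as
#' TSV. A read-back with [read_cohort()] reproduces the arrays bit-exactly.
#'
#' @param cohort an `fc_cohort`.
#' @param directory output directory (created if missing).
#' @return Invisibly, the manifest tibble (`file`, `kind`, `subject_id`).
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  vox <- rep(cohort$grid$voxel_size_mm, 3)
  rows <- list()
  add <- function(file, kind, sid = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(file = file, kind = kind,
                                                subject_id = sid)
  }
  tr <- cohort$config$tr_s %||% 1
  for (s in cohort$subjects) {
    f <- file.path(directory, paste0(s$subject_id, "_bold.nii.gz"))
    img <- RNifti::asNifti(s$data,
                           reference = list(pixdim = c(-1, vox, tr, 0, 0, 0)),
                           datatype = "double")
    RNifti::writeNifti(img, f)
    add(basename(f), "bold", s$subject_id)
    mf <- file.path(directory, paste0(s$subject_id, "_motion.par"))
    write_motion_par(s$motion6, mf)
    add(basename(mf), "motion", s$subject_id)
  }
  mask_names <- c("brain", "gm", "wm", "csf", "ventricle_roi", "wm_roi",
                  "seed_sphere", "posterior_roi")
  for (mn in mask_names) {
    f <- file.path(directory, paste0("mask_", mn, ".nii.gz"))
    img <- RNifti::asNifti(array(as.integer(cohort$masks[[mn]]),
                                 cohort$grid$shape),
                           reference = list(pixdim = c(-1, vox, 0, 0, 0, 0)),
                           datatype = "uint8")
    RNifti::writeNifti(img, f)
    add(basename(f), "mask", NA_character_)
  }
  cov <- subjects_table(cohort)
  cov_f <- file.path(directory, "participants.tsv")
  utils::write.table(cov, cov_f, sep = "\t", quote = FALSE, row.names = FALSE)
  add(basename(cov_f), "covariates", NA_character_)
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory containing `manifest.tsv`.
#' @return An `fc_cohort` (without the generating config).
#' @export
read_cohort <- function(directory) {
  man <- utils::read.delim(file.path(directory, "manifest.tsv"))
  cov <- utils::read.delim(file.path(directory, "participants.tsv"))
  bold <- man[man$kind == "bold", ]
  subjects <- vector("list", nrow(bold))
  for (i in seq_len(nrow(bold))) {
    sid <- bold$subject_id[i]
    img <- RNifti::readNifti(file.path(directory, bold$file[i]))
    dat <- array(as.numeric(img), dim = dim(img))
    m6 <- read_motion_par(file.path(directory, paste0(sid, "_motion.par")))
    row <- cov[cov$subject_id == sid, ]
    subjects[[i]] <- structure(list(
      subject_id = sid, group = row$group, data = dat, motion6 = m6,
      gm_volume = row$gm_volume), class = "fc_subject")
  }
  gs <- dim(subjects[[1]]$data)[1:3]
  first_mask <- RNifti::readNifti(file.path(directory, "mask_brain.nii.gz"))
  vox <- RNifti::pixdim(first_mask)[1]
  masks <- lapply(c("brain", "gm", "wm", "csf", "ventricle_roi", "wm_roi",
                    "seed_sphere", "posterior_roi"), function(mn) {
    img <- RNifti::readNifti(file.path(directory, paste0("mask_", mn, ".nii.gz")))
    array(as.numeric(img) > 0.5, dim = gs)
  })
  names(masks) <- c("brain", "gm", "wm", "csf", "ventricle_roi", "wm_roi",
                    "seed_sphere", "posterior_roi")
  masks$grid_shape <- gs
  class(masks) <- "mask_set"
  structure(list(subjects = subjects, masks = masks,
                 grid = list(shape = gs, voxel_size_mm = vox,
                             affine = diag(c(rep(vox, 3), 1)))),
            class = "fc_cohort")
}
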