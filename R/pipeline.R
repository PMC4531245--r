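#' Full-benchmark run configuration
#'
#' Bundles the simulation, preprocessing, decomposition and statistics
#' settings of one benchmark run. Serializable to/from YAML with
#' [write_run_config()] / [read_run_config()].
#'
#' @param sim a [sim_config()].
#' @param preprocess a [preprocess_config()].
#' @param cleanups character subset of
#'   `c("none","motreg","mwcreg","comp_soft","comp_agg")`.
#' @param fc_methods character subset of `c("seed", "dualreg")`.
#' @param n_components ICA dimensionality per subject: an integer, `"auto"`
#'   (90% variance) or `"signal"` (above-noise-floor eigenvalues; default).
#' @param labeler `"ground_truth"` (simulation oracle) or `"rules"`.
#' @param n_perm permutations for voxelwise inference.
#' @param primary_p two-tailed voxel-level primary threshold for clusters.
#' @param voxelwise list of `fc_method`/`cleanup` pairs to test voxelwise
#'   (each a character vector of length 2), or NULL to skip; default tests
#'   aggressive component cleanup with dual regression.
#' @param gm_threshold group GM-mask inclusion threshold.
#' @param delta_threshold_pct exceedance threshold for suppression maps.
#' @param seed global seed expanded into per-stage seeds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       preprocess = preprocess_config(),
                       cleanups = cleanup_modes,
                       fc_methods = c("seed", "dualreg"),
                       n_components = "signal",
                       labeler = c("ground_truth", "rules"),
                       n_perm = 1000L,
                       primary_p = 0.05,
                       voxelwise = list(c("dualreg", "comp_agg")),
                       gm_threshold = 0.20,
                       delta_threshold_pct = 25,
                       seed = 1L) {
  labeler <- match.arg(labeler)
  assert_that(all(cleanups %in% cleanup_modes), "unknown cleanup mode")
  assert_that(all(fc_methods %in% c("seed", "dualreg")), "unknown fc method")
  structure(list(sim = sim, preprocess = preprocess, cleanups = cleanups,
                 fc_methods = fc_methods, n_components = n_components,
                 labeler = labeler, n_perm = as.integer(n_perm),
                 primary_p = primary_p, voxelwise = voxelwise,
                 gm_threshold = gm_threshold,
                 delta_threshold_pct = delta_threshold_pct,
                 seed = as.integer(seed)),
            class = "run_config")
}

run_config_keys <- c("sim", "preprocess", "cleanups", "fc_methods",
                     "n_components", "labeler", "n_perm", "primary_p",
                     "voxelwise", "gm_threshold", "delta_threshold_pct",
                     "seed")

#' Write / read a run configuration as YAML
#'
#' The YAML round-trip is lossless; unknown keys in a file are rejected.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$artifact_amplitudes <- as.list(x$sim$artifact_amplitudes)
  x$sim$artifact_cv <- as.list(x$sim$artifact_cv)
  x$sim$motion_mrd <- as.list(x$sim$motion_mrd)
  x$sim$motion_mrd_sd <- as.list(x$sim$motion_mrd_sd)
  x$preprocess <- unclass(x$preprocess)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), run_config_keys)
  if (length(unknown)) {
    stop("unknown run_config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim_args <- x$sim
  for (f in c("artifact_amplitudes", "artifact_cv", "motion_mrd",
              "motion_mrd_sd")) {
    sim_args[[f]] <- unlist(sim_args[[f]])
  }
  sim_known <- names(formals(sim_config))
  unknown_sim <- setdiff(names(sim_args), sim_known)
  if (length(unknown_sim)) {
    stop("unknown sim keys: ", paste(unknown_sim, collapse = ", "),
         call. = FALSE)
  }
  sim <- do.call(sim_config, sim_args)
  pp <- do.call(preprocess_config, x$preprocess)
  vw <- if (is.null(x$voxelwise)) NULL else lapply(x$voxelwise, unlist)
  run_config(sim = sim, preprocess = pp, cleanups = unlist(x$cleanups),
             fc_methods = unlist(x$fc_methods),
             n_components = if (is.character(x$n_components)) x$n_components
                            else as.integer(x$n_components),
             labeler = x$labeler, n_perm = x$n_perm, primary_p = x$primary_p,
             voxelwise = vw, gm_threshold = x$gm_threshold,
             delta_threshold_pct = x$delta_threshold_pct, seed = x$seed)
}

#' Read / write 6-column motion parameter files
#'
#' Whitespace-delimited text, one row per volume, translations (mm) in
#' columns 1-3 and rotations (rad) in 4-6. Values survive a round-trip to 6
#' significant digits. Malformed lines are an error naming the line number.
#'
#' @param path file path.
#' @return `read_motion_par()` returns a T x 6 matrix.
#' @export
read_motion_par <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty motion file: ", path, call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 6 || anyNA(v)) {
      stop(sprintf("malformed motion file %s at line %d", path, i),
           call. = FALSE)
    }
    v
  })
  do.call(rbind, rows)
}

#' @rdname read_motion_par
#' @param motion6 T x 6 matrix.
#' @export
write_motion_par <- function(motion6, path) {
  assert_that(is.matrix(motion6) && ncol(motion6) == 6,
              "motion6 must be a T x 6 matrix")
  lines <- apply(motion6, 1L, function(r)
    paste(formatC(r, format = "g", digits = 8), collapse = "  "))
  writeLines(lines, path)
  invisible(path)
}

# One subject through preprocess -> ICA -> all requested cleanups -> metrics
# and FC maps. Returns small per-subject summaries; the 4D arrays are
# discarded so cohorts stream through memory subject by subject.
process_subject <- function(subject, masks, truth, rc) {
  tr_s <- rc$sim$tr_s
  prep <- preprocess_subject(subject$data, rc$preprocess, tr_s,
                             rc$sim$voxel_size_mm)
  need_comp <- any(c("comp_soft", "comp_agg") %in% rc$cleanups)
  decomp <- NULL
  if (need_comp) {
    decomp <- spatial_ica(prep, masks$brain, n_components = rc$n_components,
                          seed = derive_seed(rc$seed, "ica",
                                             as.integer(sub("sub-", "",
                                                            subject$subject_id))))
    decomp <- if (rc$labeler == "ground_truth") {
      label_by_ground_truth(decomp, truth)
    } else {
      label_by_rules(decomp, masks, expand_motion_24(subject$motion6), tr_s)
    }
  }

  out <- list(tsnr = list(), delta = list(), zmaps = list(), roi = list())
  for (mode in rc$cleanups) {
    cleaned <- clean(prep, subject$motion6, masks, decomp, mode)
    out$tsnr[[mode]] <- temporal_snr(cleaned, masks$brain)$median_tsnr
    if (mode != "none") out$delta[[mode]] <- delta_std_map(prep, cleaned)$values
    for (fm in rc$fc_methods) {
      m <- if (fm == "seed") {
        seed_fc_zmap(cleaned, masks$seed_sphere, masks$brain)$values
      } else {
        dr <- dual_regression(cleaned, truth$template_maps, masks$brain)
        select_dmn_map(dr$pe_maps, truth$dmn_index)
      }
      key <- paste(fm, mode, sep = ".")
      out$zmaps[[key]] <- m
      out$roi[[key]] <- roi_mean_pe(m, masks$posterior_roi)
    }
  }
  out
}

#' Run the full denoising benchmark on a simulated cohort
#'
#' Simulates a cohort from `config$sim`, streams every subject through
#' common preprocessing, single-subject spatial ICA with component labeling,
#' and each requested cleanup, computes per-subject FC maps with each
#' requested method, and assembles the group-level evaluation: median tSNR
#' per subject/cleanup, suppression-exceedance probability maps per group,
#' within-group consistency maps with paired-t comparisons against the
#' uncleaned variant, an ROI statistics table (group mean, SD, pooled t, p
#' per method/cleanup), and — for the configured `voxelwise` combinations —
#' a permutation GLM with GM-volume covariate and cluster-extent correction
#' inside the group GM mask.
#'
#' Re-running with an identical config reproduces every table exactly.
#'
#' @param config a [run_config()].
#' @return A list of class `fc_benchmark`: tibbles `tsnr`, `roi`,
#'   `consistency`, `consistency_tests`, `subjects`; list `exceedance`
#'   (per cleanup x group); list `comparisons` (per voxelwise combo, class
#'   `fc_group_comparison`); `gm_mask`, `config`.
#' @export
run_full_benchmark <- function(config) {
  rc <- config
  sim <- generate_cohort(rc$sim)
  cohort <- sim$cohort
  truth <- sim$truth
  masks <- cohort$masks
  subj_tbl <- subjects_table(cohort)
  n <- nrow(subj_tbl)

  per <- vector("list", n)
  for (i in seq_len(n)) {
    per[[i]] <- process_subject(cohort$subjects[[i]], masks, truth, rc)
    cohort$subjects[[i]]$data <- NULL # release the 4D array
  }
  groups <- subj_tbl$group

  tsnr_tbl <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(subject_id = subj_tbl$subject_id[i], group = groups[i],
                   cleanup = names(per[[i]]$tsnr),
                   median_tsnr = unlist(per[[i]]$tsnr))
  })

  exceedance <- list()
  for (mode in setdiff(rc$cleanups, "none")) {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      maps <- lapply(idx, function(i) per[[i]]$delta[[mode]])
      exceedance[[paste(mode, g, sep = ".")]] <-
        exceedance_probability_map(maps, rc$delta_threshold_pct)
    }
  }

  combos <- expand.grid(fc_method = rc$fc_methods, cleanup = rc$cleanups,
                        stringsAsFactors = FALSE)
  roi_tbl <- purrr::map_dfr(seq_len(nrow(combos)), function(j) {
    key <- paste(combos$fc_method[j], combos$cleanup[j], sep = ".")
    vals <- vapply(per, function(p) p$roi[[key]], numeric(1))
    a <- vals[groups == "HC"]; b <- vals[groups == "AD"]
    res <- two_sample_t_summary(list(mean = mean(a), sd = stats::sd(a), n = length(a)),
                                list(mean = mean(b), sd = stats::sd(b), n = length(b)))
    tibble::tibble(fc_method = combos$fc_method[j], cleanup = combos$cleanup[j],
                   mean_hc = mean(a), sd_hc = stats::sd(a), n_hc = length(a),
                   mean_ad = mean(b), sd_ad = stats::sd(b), n_ad = length(b),
                   t = res$t, df = res$df, p = res$p)
  })

  cons_rows <- list(); cons_maps <- list()
  for (j in seq_len(nrow(combos))) {
    key <- paste(combos$fc_method[j], combos$cleanup[j], sep = ".")
    for (g in unique(groups)) {
      idx <- which(groups == g)
      cm <- consistency_map(lapply(idx, function(i) per[[i]]$zmaps[[key]]),
                            masks$brain)
      cons_maps[[paste(key, g, sep = ".")]] <- cm$values
      cons_rows[[paste(key, g, sep = ".")]] <- tibble::tibble(
        fc_method = combos$fc_method[j], cleanup = combos$cleanup[j],
        group = g, mean_sd = mean(cm$values[masks$brain]))
    }
  }
  consistency_tbl <- dplyr::bind_rows(cons_rows)

  cons_tests <- purrr::map_dfr(
    seq_len(nrow(combos)), function(j) {
      if (combos$cleanup[j] == "none" || !"none" %in% rc$cleanups) {
        return(tibble::tibble())
      }
      purrr::map_dfr(unique(groups), function(g) {
        key_c <- paste(combos$fc_method[j], combos$cleanup[j], g, sep = ".")
        key_u <- paste(combos$fc_method[j], "none", g, sep = ".")
        tt <- paired_t_over_voxels(cons_maps[[key_c]], cons_maps[[key_u]],
                                   masks$brain)
        dplyr::mutate(tt, fc_method = combos$fc_method[j],
                      cleanup = combos$cleanup[j], group = g,
                      .before = 1)
      })
    })

  gm_mask <- build_group_gm_mask(
    lapply(seq_len(n), function(i) array(as.numeric(masks$gm), dim(masks$gm))),
    rc$gm_threshold)

  comparisons <- list()
  vws <- rc$voxelwise %||% list()
  for (v in seq_along(vws)) {
    vw <- vws[[v]]
    key <- paste(vw[1], vw[2], sep = ".")
    maps <- lapply(per, function(p) p$zmaps[[key]])
    res <- permutation_group_glm(maps, groups, subj_tbl$gm_volume, gm_mask,
                                 n_perm = rc$n_perm,
                                 seed = derive_seed(rc$seed, "perm", v))
    comparisons[[key]] <- cluster_correct(res, primary_p = rc$primary_p)
  }

  structure(list(tsnr = tsnr_tbl, roi = roi_tbl,
                 consistency = consistency_tbl,
                 consistency_tests = cons_tests,
                 subjects = subj_tbl, exceedance = exceedance,
                 comparisons = comparisons, gm_mask = gm_mask,
                 config = rc),
            class = "fc_benchmark")
}

#' Write the benchmark's tables as TSV files
#'
#' @param bench an `fc_benchmark`.
#' @param directory output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_benchmark_tsvs <- function(bench, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    utils::write.table(as.data.frame(x), file.path(directory, f),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    file.path(directory, f)
  }
  paths <- c(w(bench$tsnr, "tsnr.tsv"), w(bench$roi, "roi_stats.tsv"),
             w(bench$consistency, "consistency.tsv"),
             w(bench$consistency_tests, "consistency_tests.tsv"),
             w(bench$subjects, "participants.tsv"))
  if (length(bench$comparisons)) {
    ct <- purrr::map_dfr(names(bench$comparisons), function(k) {
      tab <- bench$comparisons[[k]]$cluster_table
      if (nrow(tab)) dplyr::mutate(tab, combo = k, .before = 1) else tab
    })
    paths <- c(paths, w(ct, "cluster_tables.tsv"))
  }
  invisible(paths)
}

#' @export
print.fc_benchmark <- function(x, ...) {
  cat(sprintf("<fc_benchmark> %d subjects, %d cleanups x %d FC methods\n",
              nrow(x$subjects), length(unique(x$roi$cleanup)),
              length(unique(x$roi$fc_method))))
  print(x$roi[, c("fc_method", "cleanup", "t", "p")], n = nrow(x$roi))
  invisible(x)
}
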