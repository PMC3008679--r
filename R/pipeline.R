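#' Pipeline run configuration
#'
#' Aggregates every stage's settings. Defaults are the package's standard
#' analysis conditions: 5 discarded volumes, 0.01--0.08 Hz band, model order
#' 1, 500 permutations for single-pair tests, FDR q = 0.05, 10-voxel minimum
#' cluster extent, 26-connectivity, and motion limits of 1.5 mm / 1.5
#' degrees.
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_config()] (synthetic input definition).
#' @param preprocess a [preprocess_config()].
#' @param seeds character vector of ROI names used as seeds.
#' @param order autoregressive model order.
#' @param n_perm permutations for single-pair significance (default 500).
#' @param n_perm_null permutation draws per subject for the group null-mean
#'   maps (vectorized across voxels).
#' @param q FDR level.
#' @param min_cluster_size cluster extent threshold (voxels).
#' @param connectivity cluster connectivity (6/18/26).
#' @param group_method group significance rule, see
#'   [significance_mask_for_group()].
#' @param correlate_scores clinical columns for post-hoc correlations.
#' @param rng_seed master seed for all pipeline randomness.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       cohort = cohort_config(),
                       preprocess = preprocess_config(),
                       seeds = c("amygdala_left", "amygdala_right"),
                       order = 1L, n_perm = 500L, n_perm_null = 20L,
                       q = 0.05, min_cluster_size = 10L, connectivity = 26L,
                       group_method = "t_vs_null",
                       correlate_scores = c("lsas_total", "lsas_fear",
                                            "lsas_avoidance"),
                       rng_seed = 20101222L) {
  structure(list(out_dir = out_dir, cohort = cohort, preprocess = preprocess,
                 seeds = seeds, order = as.integer(order),
                 n_perm = as.integer(n_perm),
                 n_perm_null = as.integer(n_perm_null), q = q,
                 min_cluster_size = as.integer(min_cluster_size),
                 connectivity = as.integer(connectivity),
                 group_method = group_method,
                 correlate_scores = correlate_scores,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> preprocess -> influence mapping -> group statistics
#' -> post-hoc correlations, writing all artifacts under
#' `config$out_dir` and a JSON manifest with MD5 hashes of every output, the
#' seeds, settings and QC counts. Two runs with identical configuration
#' produce byte-identical outputs.
#'
#' Stages:
#' \enumerate{
#'   \item synthesize the cohort ([synthesize_cohort()]) and apply the
#'     motion exclusion rule;
#'   \item preprocess every retained subject ([preprocess_voxelwise()]);
#'   \item per subject and per seed, compute bidirectional influence maps
#'     ([influence_maps()]) plus permutation null-mean maps;
#'   \item per seed, direction and group: mean maps (the 2 seeds x 2
#'     directions x 2 groups group-level maps), FDR + cluster-extent
#'     significance masks, the SAD-or-HC union analysis mask, and the
#'     two-sample contrast ([two_sample_t_map()]);
#'   \item extract contrast clusters and correlate cluster means with the
#'     clinical scores ([cluster_correlation()]); write the behavioral
#'     comparison table.
#' }
#'
#' @param config a [run_config()].
#' @return invisible list with the manifest and in-memory group results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_msg <- function(...) message(sprintf(...))

  cohort_cfg <- config$cohort
  cohort_cfg$rng_seed <- config$rng_seed
  log_msg("stage simulate: %d + %d subjects", cohort_cfg$n_group_a, cohort_cfg$n_group_b)
  cohort <- synthesize_cohort(cohort_cfg)
  masks <- cohort$masks
  tr <- cohort_cfg$tr_seconds

  # motion QC
  qc <- lapply(cohort$subjects, function(s) {
    ms <- motion_summary(s$motion)
    ex <- motion_exclusion(s$motion, config$preprocess$motion_limit_mm,
                           config$preprocess$motion_limit_deg)
    data.frame(subject_id = s$subject_id, group = s$group,
               translation_mm = ms[["translation_mm"]],
               rotation_deg = ms[["rotation_deg"]],
               excluded = ex$exclude,
               offending = if (ex$exclude) ex$parameter else "",
               stringsAsFactors = FALSE)
  })
  qc <- do.call(rbind, qc)
  utils::write.table(qc, file.path(config$out_dir, "motion_qc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  retained <- which(!qc$excluded)
  if (length(retained) < length(cohort$subjects)) {
    log_msg("motion exclusion dropped %d subject(s)",
            length(cohort$subjects) - length(retained))
  }

  seed_masks <- masks$roi_masks[config$seeds]
  subject_maps <- list()   # [[seed]][[direction]][[subject]]
  null_means <- list()
  for (sd_name in config$seeds) {
    subject_maps[[sd_name]] <- list(from_seed = list(), to_seed = list())
    null_means[[sd_name]] <- list(from_seed = list(), to_seed = list())
  }
  records <- cohort$records[retained, , drop = FALSE]

  log_msg("stage preprocess+gca: %d subjects", length(retained))
  for (jj in seq_along(retained)) {
    s <- cohort$subjects[[retained[jj]]]
    prep <- preprocess_voxelwise(s$volume, s$motion, masks$wm_mask,
                                 masks$csf_mask, config$preprocess,
                                 brain_mask = masks$brain_mask,
                                 tr_seconds = tr)
    for (sd_name in config$seeds) {
      seed_series <- extract_mean_series(prep$cleaned, seed_masks[[sd_name]])
      imaps <- influence_maps(seed_series, prep$cleaned, masks$brain_mask,
                              p = config$order, seed_label = sd_name)
      nm <- influence_null_mean(seed_series, prep$cleaned, masks$brain_mask,
                                p = config$order, n_perm = config$n_perm_null,
                                rng_seed = (config$rng_seed + 7L * jj) %% .Machine$integer.max)
      subject_maps[[sd_name]]$from_seed[[jj]] <- imaps$map_from_seed
      subject_maps[[sd_name]]$to_seed[[jj]] <- imaps$map_to_seed
      null_means[[sd_name]]$from_seed[[jj]] <- nm$from_seed
      null_means[[sd_name]]$to_seed[[jj]] <- nm$to_seed
      for (dir_name in c("from_seed", "to_seed")) {
        f <- file.path(config$out_dir,
                       sprintf("%s_%s_%s.nii.gz", s$subject_id, sd_name, dir_name))
        write_volume(subject_maps[[sd_name]][[dir_name]][[jj]], f, tr_seconds = tr)
      }
    }
  }

  log_msg("stage group")
  is_a <- records$group == "SAD"
  group_results <- list()
  cluster_rows <- list()
  for (sd_name in config$seeds) {
    for (dir_name in c("from_seed", "to_seed")) {
      maps <- subject_maps[[sd_name]][[dir_name]]
      pooled_null <- group_mean_map(null_means[[sd_name]][[dir_name]])$mean
      sig <- list()
      for (g in c("SAD", "HC")) {
        sel <- if (g == "SAD") which(is_a) else which(!is_a)
        gm <- group_mean_map(maps[sel])
        write_volume(gm$mean,
                     file.path(config$out_dir,
                               sprintf("group_%s_%s_%s_mean.nii.gz", g, sd_name, dir_name)),
                     tr_seconds = tr)
        sig[[g]] <- significance_mask_for_group(
          maps[sel], null_mean = pooled_null, q = config$q,
          min_cluster_size = config$min_cluster_size,
          connectivity = config$connectivity, method = config$group_method)
      }
      union_mask <- sig$SAD$mask | sig$HC$mask
      write_volume(union_mask,
                   file.path(config$out_dir,
                             sprintf("analysis_mask_%s_%s.nii.gz", sd_name, dir_name)))
      if (!any(union_mask)) {
        log_msg("no significant voxels for %s/%s; group comparison skipped",
                sd_name, dir_name)
        group_results[[paste(sd_name, dir_name, sep = "_")]] <-
          list(skipped = TRUE)
        next
      }
      contrast <- two_sample_t_map(maps[which(is_a)], maps[which(!is_a)],
                                   union_mask, q = config$q)
      write_volume(contrast$t_values,
                   file.path(config$out_dir,
                             sprintf("contrast_%s_%s_t.nii.gz", sd_name, dir_name)))
      clusters <- extract_clusters(contrast, config$min_cluster_size,
                                   config$connectivity)
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        for (sc in config$correlate_scores) {
          cc <- cluster_correlation(cl$voxels, maps, records, sc)
          for (ri in seq_len(nrow(cc))) {
            cluster_rows[[length(cluster_rows) + 1]] <- data.frame(
              seed = sd_name, direction_map = dir_name, cluster = ci,
              contrast_direction = cl$direction, size = cl$size,
              peak_voxel = cl$peak_voxel, score = sc,
              group = cc$group[ri], n = cc$n[ri], r = cc$r[ri], p = cc$p[ri],
              stringsAsFactors = FALSE)
          }
        }
      }
      group_results[[paste(sd_name, dir_name, sep = "_")]] <-
        list(contrast = contrast, clusters = clusters, union_mask = union_mask)
    }
  }
  if (length(cluster_rows)) {
    ctab <- do.call(rbind, cluster_rows)
    ctab$n_correlations_tested <- nrow(ctab)
    utils::write.table(ctab, file.path(config$out_dir, "cluster_correlations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(behavioral_table(records),
                     file.path(config$out_dir, "behavioral_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_subjects(records, file.path(config$out_dir, "subjects.csv"))

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("restgca")),
    rng_seed = config$rng_seed,
    settings = list(order = config$order, n_perm = config$n_perm,
                    n_perm_null = config$n_perm_null, q = config$q,
                    min_cluster_size = config$min_cluster_size,
                    connectivity = config$connectivity,
                    n_discard = config$preprocess$n_discard,
                    band_hz = c(config$preprocess$band_low_hz,
                                config$preprocess$band_high_hz),
                    motion_limits = c(config$preprocess$motion_limit_mm,
                                      config$preprocess$motion_limit_deg)),
    qc = list(n_subjects = length(cohort$subjects),
              n_retained = length(retained),
              n_excluded = sum(qc$excluded)),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("pipeline finished in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(manifest = manifest, group_results = group_results,
                 records = records))
}
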