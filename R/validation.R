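#' Validation-study conditions
#'
#' The package validates its pipeline on a fixed synthetic design: a
#' three-region network (a left-amygdala seed, a `target` region receiving
#' seed influence, and an inferior-temporal `itg` region sending influence to
#' the seed), 22 patients versus 21 controls on the 24 x 24 x 12 phantom grid
#' with 205 volumes at TR = 2 s.
#'
#' Two relations are planted:
#' \itemize{
#'   \item a group difference: the seed -> target coupling is 0.30 in the
#'     patient group and reduced by `planted_delta` (default 0.22, i.e. a
#'     near-ablation) in controls, emulating a directed connection that the
#'     group contrast should report as increased in patients;
#'   \item a clinical relation: the avoidance-like score is a negative linear
#'     function of each patient's realized itg -> seed coupling, with slope
#'     and noise giving a population coupling-score correlation of -0.6.
#' }
#'
#' @param planted_delta reduction of the seed -> target coupling in the
#'   control group; 0 gives a null cohort.
#' @param rng_seed master seed.
#' @return `validation_cohort_config()`: a [cohort_config()];
#'   `validation_network_spec()`: a [network_spec()].
#' @export
validation_network_spec <- function() {
  labels <- c("amygdala_left", "target", "itg")
  C <- matrix(0, 3, 3, dimnames = list(labels, labels))
  C["amygdala_left", "target"] <- 0.30
  C["itg", "amygdala_left"] <- 0.35
  network_spec(labels, rep(0.7, 3), C)
}

#' @rdname validation_network_spec
#' @export
validation_cohort_config <- function(planted_delta = 0.22, rng_seed = 1L) {
  labels <- c("amygdala_left", "target", "itg")
  d <- matrix(0, 3, 3, dimnames = list(labels, labels))
  d["amygdala_left", "target"] <- -planted_delta
  cohort_config(
    n_group_a = 22, n_group_b = 21,
    grid_dims = c(24, 24, 12),
    region_layout = list(
      amygdala_left = c(4, 7, 10, 13, 5, 7),
      target = c(16, 19, 16, 19, 4, 6),
      itg = c(4, 7, 18, 21, 3, 5),
      wm = c(10, 14, 4, 7, 9, 11),
      csf = c(17, 20, 4, 6, 9, 11)),
    group_b_coupling_delta = d,
    score_model = list(from = "itg", to = "amygdala_left",
                       score = "lsas_avoidance", intercept = 39.95,
                       slope = -60, noise_sd = 4.8),
    rng_seed = rng_seed)
}

#' Subject-level influence maps for a whole cohort
#'
#' Runs the standard preprocessing and bidirectional influence mapping for
#' every subject of a synthetic cohort from one seed region, and estimates
#' the pooled permutation null-mean map from the first `n_null_subjects`
#' subjects (the null mean is a property of the reshuffled-target null and is
#' essentially common across subjects, so a subsample suffices).
#'
#' @param cohort a [synthesize_cohort()] result.
#' @param seed_roi name of the ROI mask used as the seed.
#' @param config a [preprocess_config()].
#' @param n_null_subjects subjects contributing to the pooled null mean.
#' @param n_null_perm permutation draws per contributing subject.
#' @return list: `from_maps`, `to_maps` (lists of 3D arrays, one per
#'   subject), `null_from` (pooled from-seed null-mean 3D array).
#' @export
cohort_influence_maps <- function(cohort, seed_roi = "amygdala_left",
                                  config = preprocess_config(),
                                  n_null_subjects = 4, n_null_perm = 25) {
  stopifnot(inherits(cohort, "cohort"))
  masks <- cohort$masks
  tr <- cohort$config$tr_seconds
  n <- length(cohort$subjects)
  from_maps <- to_maps <- vector("list", n)
  nulls_from <- nulls_to <- list()
  for (j in seq_len(n)) {
    s <- cohort$subjects[[j]]
    prep <- preprocess_voxelwise(s$volume, s$motion, masks$wm_mask,
                                 masks$csf_mask, config,
                                 brain_mask = masks$brain_mask,
                                 tr_seconds = tr)
    seed_series <- extract_mean_series(prep$cleaned, masks$roi_masks[[seed_roi]])
    im <- influence_maps(seed_series, prep$cleaned, masks$brain_mask,
                         seed_label = seed_roi)
    from_maps[[j]] <- im$map_from_seed
    to_maps[[j]] <- im$map_to_seed
    if (j <= n_null_subjects) {
      nm <- influence_null_mean(seed_series, prep$cleaned, masks$brain_mask,
                                n_perm = n_null_perm,
                                rng_seed = (cohort$config$rng_seed + 13L * j) %%
                                  .Machine$integer.max,
                                directions = "from_seed")
      nulls_from[[length(nulls_from) + 1]] <- nm$from_seed
    }
  }
  list(from_maps = from_maps, to_maps = to_maps,
       null_from = group_mean_map(nulls_from)$mean)
}

#' One validation replicate: group detection and clinical correlation
#'
#' Synthesizes one validation cohort, computes all subject influence maps,
#' follows the group pipeline (per-group significance masks against the
#' pooled permutation null, their union as analysis mask, FDR-corrected
#' two-sample contrast, cluster extraction), and reports whether an
#' "increased" cluster overlaps the planted target block. The clinical check
#' correlates patients' mean to-seed influence over the planted itg block
#' with the avoidance score.
#'
#' @param rng_seed replicate seed.
#' @param planted_delta group coupling difference (0 for a null replicate).
#' @param q FDR level.
#' @param min_cluster_size cluster extent threshold.
#' @return list: `detected`, `block_mean_t`, `union_size`, `r_sad`, `p_sad`,
#'   plus the subject maps and cohort for reuse.
#' @export
validation_replicate <- function(rng_seed, planted_delta = 0.22, q = 0.05,
                                 min_cluster_size = 10) {
  cohort <- synthesize_cohort(validation_cohort_config(planted_delta, rng_seed),
                              validation_network_spec())
  maps <- cohort_influence_maps(cohort)
  is_a <- cohort$records$group == "SAD"
  block <- which(cohort$masks$roi_masks$target)

  sig_a <- significance_mask_for_group(maps$from_maps[is_a], maps$null_from,
                                       q = q, min_cluster_size = min_cluster_size)
  sig_b <- significance_mask_for_group(maps$from_maps[!is_a], maps$null_from,
                                       q = q, min_cluster_size = min_cluster_size)
  union_mask <- sig_a$mask | sig_b$mask
  detected <- FALSE
  block_mean_t <- NA_real_
  if (any(union_mask)) {
    contrast <- two_sample_t_map(maps$from_maps[is_a], maps$from_maps[!is_a],
                                 union_mask, q = q)
    clusters <- extract_clusters(contrast, min_cluster_size)
    detected <- any(vapply(clusters, function(cl) {
      cl$direction == "increased" && length(intersect(cl$voxels, block)) > 0
    }, logical(1)))
    block_mean_t <- mean(contrast$t_values[block], na.rm = TRUE)
  }

  itg <- which(cohort$masks$roi_masks$itg)
  cc <- cluster_correlation(itg, maps$to_maps, cohort$records, "lsas_avoidance")
  sad <- cc[cc$group == "SAD", ]
  list(detected = detected, block_mean_t = block_mean_t,
       union_size = sum(union_mask),
       r_sad = sad$r, p_sad = sad$p,
       maps = maps, cohort = cohort)
}

#' Empirical false-discovery proportion on null cohorts
#'
#' Generates `n_base` cohorts with no planted group difference, and for each
#' applies `n_relabel` random relabelings of the group assignment before the
#' FDR-corrected contrast over the brain mask. Every rejection is false, so
#' the per-run false discovery proportion is 1 whenever anything is rejected.
#'
#' @param rng_seed master seed.
#' @param n_base null cohorts to synthesize.
#' @param n_relabel relabelings per cohort.
#' @param q FDR level.
#' @return mean false discovery proportion across the `n_base * n_relabel`
#'   null contrasts.
#' @export
validation_null_fdr <- function(rng_seed, n_base = 2, n_relabel = 25, q = 0.05) {
  fdp <- numeric(0)
  for (b in seq_len(n_base)) {
    rep0 <- validation_replicate((rng_seed + 1000L * b) %% .Machine$integer.max,
                                 planted_delta = 0)
    maps <- rep0$maps$from_maps
    mask <- rep0$cohort$masks$brain_mask
    n1 <- sum(rep0$cohort$records$group == "SAD")
    set.seed((rng_seed + b) %% .Machine$integer.max)
    for (r in seq_len(n_relabel)) {
      lab <- sample(rep(c(TRUE, FALSE), c(n1, length(maps) - n1)))
      ct <- two_sample_t_map(maps[lab], maps[!lab], mask, q = q)
      fdp <- c(fdp, as.numeric(sum(ct$significance_mask) > 0))
    }
  }
  mean(fdp)
}
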