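#' Simulate coupled regional signals from a lag-1 network
#'
#' Draws one time series per node from the first-order vector autoregression
#' defined by `spec`, with independent Gaussian innovations. A burn-in segment
#' is generated from a zero state and discarded so the retained samples are
#' (approximately) stationary. Identical seeds give identical output.
#'
#' @param spec a [network_spec()]; must be stationary.
#' @param n_volumes number of retained time points (>= 20).
#' @param rng_seed integer seed.
#' @param burn_in discarded initial samples (default 200).
#' @return numeric matrix `n_volumes` x k with node labels as column names.
#' @export
simulate_coupled_var <- function(spec, n_volumes, rng_seed, burn_in = 200) {
  stopifnot(inherits(spec, "network_spec"), n_volumes >= 20, burn_in >= 0)
  A <- transition_matrix(spec)
  rho <- spectral_radius(A)
  if (rho >= 1) {
    stop(sprintf("network is non-stationary: spectral radius %.4f >= 1", rho))
  }
  k <- length(spec$node_labels)
  total <- burn_in + n_volumes
  set.seed(as.integer(rng_seed))
  eps <- matrix(stats::rnorm(total * k), nrow = k) * spec$innovation_sd
  z <- matrix(0, nrow = k, ncol = total)
  z[, 1] <- eps[, 1]
  for (t in 2:total) {
    z[, t] <- A %*% z[, t - 1] + eps[, t]
  }
  out <- t(z[, (burn_in + 1):total, drop = FALSE])
  colnames(out) <- spec$node_labels
  out
}

#' Construct a rigid-body motion trace
#'
#' @param translations numeric L x 3 matrix (mm).
#' @param rotations numeric L x 3 matrix (degrees).
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3, ncol(rotations) == 3,
            nrow(translations) == nrow(rotations), nrow(translations) >= 2)
  structure(list(translations = unname(translations),
                 rotations = unname(rotations),
                 n_volumes = nrow(translations)),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  s <- motion_summary(x)
  cat(sprintf("motion_trace: %d volumes; mean step %.4f mm / %.4f deg\n",
              x$n_volumes, s[["translation_mm"]], s[["rotation_deg"]]))
  invisible(x)
}

#' Simulate a head-motion parameter trace
#'
#' Cumulative Gaussian random walk in three translations (mm) and three
#' rotations (degrees), with an optional injected translation spike for
#' exercising the exclusion rule.
#'
#' @param n_volumes number of volumes (>= 2).
#' @param step_sd_mm per-step translation sd (mm).
#' @param step_sd_deg per-step rotation sd (degrees).
#' @param spike optional `list(index =, magnitude =)`: adds `magnitude` mm to
#'   the x-translation at the given volume.
#' @param rng_seed integer seed.
#' @return a [motion_trace()].
#' @export
simulate_motion_trace <- function(n_volumes, step_sd_mm, step_sd_deg,
                                  spike = NULL, rng_seed = 1L) {
  stopifnot(n_volumes >= 2, step_sd_mm >= 0, step_sd_deg >= 0)
  set.seed(as.integer(rng_seed))
  steps_t <- matrix(stats::rnorm(n_volumes * 3, sd = step_sd_mm), ncol = 3)
  steps_r <- matrix(stats::rnorm(n_volumes * 3, sd = step_sd_deg), ncol = 3)
  steps_t[1, ] <- 0
  steps_r[1, ] <- 0
  trans <- apply(steps_t, 2, cumsum)
  rot <- apply(steps_r, 2, cumsum)
  if (!is.null(spike)) {
    stopifnot(spike$index >= 1, spike$index <= n_volumes)
    trans[spike$index, 1] <- trans[spike$index, 1] + spike$magnitude
  }
  motion_trace(trans, rot)
}

#' Embed regional signals in a 4D phantom volume
#'
#' Every voxel inside a node's block carries that node's time series plus
#' i.i.d. Gaussian observation noise; the reserved `wm` and `csf` blocks carry
#' independent AR(1) nuisance series; voxels outside all blocks carry pure
#' noise. The brain mask covers the whole grid except the nuisance blocks.
#'
#' @param series_set matrix T x k of node series (from
#'   [simulate_coupled_var()]); column names must match the non-reserved
#'   entries of `config$region_layout`.
#' @param config a [cohort_config()].
#' @param observation_noise_sd noise sd added to every voxel (signal units).
#' @param rng_seed integer seed.
#' @return list with `volume` (4D array x,y,z,t), `roi_masks` (named list of
#'   logical 3D arrays, one per node), `brain_mask`, `wm_mask`, `csf_mask`.
#' @export
build_phantom <- function(series_set, config, observation_noise_sd = NULL,
                          rng_seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), is.matrix(series_set))
  if (is.null(observation_noise_sd)) observation_noise_sd <- config$observation_noise_sd
  layout <- config$region_layout
  dims <- config$grid_dims
  check_region_layout(layout, dims)
  n_t <- nrow(series_set)
  nodes <- setdiff(names(layout), c("wm", "csf"))
  missing_nodes <- setdiff(nodes, colnames(series_set))
  if (length(missing_nodes)) {
    stop("series_set lacks columns for nodes: ", paste(missing_nodes, collapse = ", "))
  }

  set.seed(as.integer(rng_seed))
  n_vox <- prod(dims)
  # voxel-major matrix: one row per voxel
  vmat <- matrix(stats::rnorm(n_vox * n_t, sd = observation_noise_sd),
                 nrow = n_vox, ncol = n_t)

  roi_masks <- list()
  for (nd in nodes) {
    m <- block_mask(layout[[nd]], dims)
    roi_masks[[nd]] <- m
    idx <- which(m)
    vmat[idx, ] <- vmat[idx, , drop = FALSE] +
      matrix(series_set[, nd], nrow = length(idx), ncol = n_t, byrow = TRUE)
  }
  # independent AR(1) nuisance compartments
  nuis <- function(n) {
    e <- stats::rnorm(n + 100)
    x <- stats::filter(e, 0.5, method = "recursive")
    as.numeric(x[101:(n + 100)])
  }
  wm_mask <- csf_mask <- array(FALSE, dim = dims)
  if (!is.null(layout$wm)) {
    wm_mask <- block_mask(layout$wm, dims)
    idx <- which(wm_mask)
    vmat[idx, ] <- vmat[idx, , drop = FALSE] +
      matrix(nuis(n_t), nrow = length(idx), ncol = n_t, byrow = TRUE)
  }
  if (!is.null(layout$csf)) {
    csf_mask <- block_mask(layout$csf, dims)
    idx <- which(csf_mask)
    vmat[idx, ] <- vmat[idx, , drop = FALSE] +
      matrix(nuis(n_t), nrow = length(idx), ncol = n_t, byrow = TRUE)
  }
  list(volume = array(vmat, dim = c(dims, n_t)),
       roi_masks = roi_masks,
       brain_mask = array(!(wm_mask | csf_mask), dim = dims),
       wm_mask = wm_mask, csf_mask = csf_mask)
}

#' Synthesize a full two-group cohort
#'
#' Generates one subject at a time: a realized coupling matrix (group mean,
#' plus `group_b_coupling_delta` for group B, plus a Gaussian per-subject
#' perturbation of each nonzero structural entry), regional VAR signals, a 4D
#' phantom, a motion trace and a clinical record. The avoidance-like score is
#' a linear function of the subject's realized target coupling plus noise;
#' the remaining clinical columns are drawn from group-typical distributions.
#'
#' All randomness derives from `config$rng_seed`: per-subject seeds are drawn
#' up front with `sample.int`, so subject j is reproducible given the master
#' seed alone.
#'
#' @param config a [cohort_config()].
#' @param spec a [network_spec()]; defaults to [default_network_spec()].
#' @return object of class `cohort`: list with `subjects` (each holding
#'   `volume`, `motion`, `realized_coupling`), shared `masks`, a `records`
#'   data frame, and the generating `config`/`spec`.
#' @export
synthesize_cohort <- function(config = cohort_config(), spec = default_network_spec()) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "network_spec"))
  sm <- config$score_model
  if (!is.null(sm) && sm$slope == 0 && sm$noise_sd == 0) {
    warning("degenerate score model: zero slope and zero noise")
  }
  n_a <- config$n_group_a
  n_b <- config$n_group_b
  n <- n_a + n_b
  set.seed(config$rng_seed)
  # one independent seed per subject per randomness source:
  # 1 coupling jitter, 2 VAR innovations, 3 phantom noise, 4 motion, 5 record
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 5L * n)
  seed_mat <- matrix(subject_seeds, ncol = 5)

  structural <- spec$coupling != 0 | config$group_b_coupling_delta != 0
  groups <- c(rep("SAD", n_a), rep("HC", n_b))

  subjects <- vector("list", n)
  records <- vector("list", n)
  masks <- NULL
  for (j in seq_len(n)) {
    base <- spec$coupling
    if (groups[j] == "HC") base <- base + config$group_b_coupling_delta
    set.seed(seed_mat[j, 1])
    repeat {
      jitter <- matrix(0, nrow(base), ncol(base))
      jitter[structural] <- stats::rnorm(sum(structural), sd = config$coupling_jitter_sd)
      realized <- base + jitter
      A <- diag(spec$self_coefficients, nrow = length(spec$node_labels)) + t(realized)
      if (spectral_radius(A) < 1) break
    }
    spec_j <- network_spec(spec$node_labels, spec$self_coefficients, realized,
                           spec$innovation_sd)
    series <- simulate_coupled_var(spec_j, config$n_volumes, rng_seed = seed_mat[j, 2])
    ph <- build_phantom(series, config, rng_seed = seed_mat[j, 3])
    motion <- simulate_motion_trace(config$n_volumes, config$motion_step_sd_mm,
                                    config$motion_step_sd_deg,
                                    rng_seed = seed_mat[j, 4])
    if (is.null(masks)) {
      masks <- ph[c("roi_masks", "brain_mask", "wm_mask", "csf_mask")]
    }
    set.seed(seed_mat[j, 5])
    records[[j]] <- synth_record(j, groups[j], realized, sm)
    subjects[[j]] <- list(subject_id = sprintf("sub%03d", j),
                          group = groups[j],
                          volume = ph$volume,
                          motion = motion,
                          realized_coupling = realized)
  }
  structure(list(subjects = subjects,
                 masks = masks,
                 records = do.call(rbind, records),
                 config = config, spec = spec),
            class = "cohort")
}

# One clinical record; score-model column is coupling-linked, the rest are
# drawn from group-typical normal distributions (means/sds in scale points).
synth_record <- function(j, group, realized, sm) {
  g <- if (group == "SAD") {
    list(fear = c(26.55, 4.82), hamd = c(8.45, 6.00), hama = c(6.32, 4.42),
         stai_t = c(46.77, 7.86), stai_s_pre = c(40.95, 8.38),
         stai_s_post = c(38.14, 9.54), avoid = c(24.95, 6.40))
  } else {
    list(fear = c(8.76, 4.97), hamd = c(1.29, 1.82), hama = c(1.24, 1.81),
         stai_t = c(33.29, 5.12), stai_s_pre = c(31.48, 4.74),
         stai_s_post = c(33.14, 6.90), avoid = c(11.71, 5.78))
  }
  draw <- function(p) stats::rnorm(1, p[1], p[2])
  avoidance <- draw(g$avoid)
  coupling_value <- NA_real_
  if (!is.null(sm)) {
    coupling_value <- realized[sm$from, sm$to]
    linked <- sm$intercept + sm$slope * coupling_value +
      stats::rnorm(1, sd = sm$noise_sd)
    if (identical(sm$score, "lsas_avoidance")) avoidance <- linked
  }
  fear <- draw(g$fear)
  data.frame(subject_id = sprintf("sub%03d", j), group = group,
             sex = if (stats::runif(1) < 16 / 22) "male" else "female",
             age = round(draw(c(22.2, 3.8)), 1),
             education = round(draw(c(13.95, 1.7)), 1),
             lsas_total = fear + avoidance,
             lsas_fear = fear, lsas_avoidance = avoidance,
             hamd = draw(g$hamd), hama = draw(g$hama),
             stai_t = draw(g$stai_t), stai_s_pre = draw(g$stai_s_pre),
             stai_s_post = draw(g$stai_s_post),
             target_coupling = coupling_value,
             stringsAsFactors = FALSE)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d SAD / %d HC), grid %s, %d volumes\n",
              length(x$subjects), x$config$n_group_a, x$config$n_group_b,
              paste(x$config$grid_dims, collapse = "x"), x$config$n_volumes))
  invisible(x)
}
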