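#' Directed lag-1 network specification
#'
#' Defines the latent regional dynamics used by the cohort simulator: a
#' first-order vector autoregression in which each region (node) carries an
#' AR(1) self term and directed lag-1 couplings from other regions.
#'
#' The process is \eqn{z_t = A z_{t-1} + \epsilon_t} with
#' \eqn{A = diag(a) + C^T}, where `C[i, j]` is the weight of node *i*'s past
#' on node *j* and \eqn{\epsilon_t} is independent Gaussian noise. Stationarity
#' requires the spectral radius of `A` to be below 1; non-stationary
#' specifications are rejected.
#'
#' @param node_labels character vector of region names.
#' @param self_coefficients numeric, per-node AR(1) weight (dimensionless).
#' @param coupling square numeric matrix; `coupling[i, j]` is the lag-1 weight
#'   of node `i`'s past on node `j`. The diagonal must be zero (self terms
#'   live in `self_coefficients`).
#' @param innovation_sd per-node innovation standard deviation (signal units).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(node_labels, self_coefficients, coupling,
                         innovation_sd = rep(1, length(node_labels))) {
  k <- length(node_labels)
  stopifnot(k >= 1, length(self_coefficients) == k,
            is.matrix(coupling), nrow(coupling) == k, ncol(coupling) == k,
            length(innovation_sd) == k, all(innovation_sd >= 0))
  if (any(abs(diag(coupling)) > 0)) {
    stop("diagonal of 'coupling' must be zero; self terms belong in 'self_coefficients'")
  }
  dimnames(coupling) <- list(node_labels, node_labels)
  spec <- structure(
    list(node_labels = node_labels,
         self_coefficients = stats::setNames(as.numeric(self_coefficients), node_labels),
         coupling = coupling,
         innovation_sd = stats::setNames(as.numeric(innovation_sd), node_labels)),
    class = "network_spec")
  rho <- spectral_radius(transition_matrix(spec))
  if (rho >= 1) {
    stop(sprintf("network is non-stationary: spectral radius %.4f >= 1", rho))
  }
  spec
}

#' Lag-1 transition matrix of a network specification
#'
#' @param spec a [network_spec()].
#' @return the k x k matrix `A` with `A[j, i]` the weight of node i's past on
#'   node j (so that `z_t = A z_{t-1} + noise`).
#' @export
transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  diag(spec$self_coefficients, nrow = length(spec$node_labels)) + t(spec$coupling)
}

#' Spectral radius of a square matrix
#' @param m square numeric matrix.
#' @return largest eigenvalue modulus.
#' @export
spectral_radius <- function(m) {
  max(Mod(eigen(m, only.values = TRUE)$values))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("network_spec with", length(x$node_labels), "nodes:",
      paste(x$node_labels, collapse = ", "), "\n")
  cat("spectral radius:", format(spectral_radius(transition_matrix(x)), digits = 4), "\n")
  nz <- which(x$coupling != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    for (r in seq_len(nrow(nz))) {
      cat(sprintf("  %s -> %s : %.3f\n", x$node_labels[nz[r, 1]],
                  x$node_labels[nz[r, 2]], x$coupling[nz[r, 1], nz[r, 2]]))
    }
  }
  invisible(x)
}

#' Default network used by the synthetic cohort
#'
#' Four regions: left and right amygdala seeds, an inferior-temporal source
#' region coupled into both seeds, and a visual region receiving coupling from
#' the right seed. Baseline couplings describe the patient (group A) condition;
#' group differences are planted through `group_b_coupling_delta` in
#' [cohort_config()].
#'
#' The self coefficient 0.7 gives slow, BOLD-like dynamics: at TR = 2 s it
#' matches typical resting-state lag-1 autocorrelation and places the bulk of
#' the signal variance inside the 0.01--0.08 Hz analysis band, so band-pass
#' filtering retains -- rather than removes -- the coupled structure, as it
#' does for real BOLD fluctuations.
#'
#' @return a [network_spec()].
#' @export
default_network_spec <- function() {
  labels <- c("amygdala_left", "amygdala_right", "itg", "visual")
  C <- matrix(0, 4, 4, dimnames = list(labels, labels))
  C["itg", "amygdala_left"] <- 0.25
  C["itg", "amygdala_right"] <- 0.25
  C["amygdala_right", "visual"] <- 0.30
  network_spec(labels, self_coefficients = rep(0.7, 4), coupling = C)
}

#' Cohort-level simulation configuration
#'
#' Bundles the acquisition geometry, group sizes, planted group difference and
#' clinical-score model for [synthesize_cohort()]. Defaults mirror the study
#' conditions the package targets: 22 patients (group A, "SAD") versus 21
#' controls (group B, "HC"), 205 volumes at TR = 2 s, and a desk-scale
#' 24 x 24 x 12 voxel grid.
#'
#' @param n_group_a,n_group_b subject counts per group (>= 2).
#' @param grid_dims integer length-3 voxel grid dimensions.
#' @param n_volumes time points acquired (pre-discard; > 10).
#' @param tr_seconds repetition time in seconds.
#' @param region_layout named list mapping each network node (plus the
#'   reserved names `"wm"` and `"csf"`) to an axis-aligned voxel block given as
#'   `c(x0, x1, y0, y1, z0, z1)` (1-based, inclusive). Blocks must be disjoint
#'   and inside the grid.
#' @param group_b_coupling_delta matrix of the same shape as the network
#'   coupling; added to group B subjects' coupling entries.
#' @param coupling_jitter_sd per-subject Gaussian perturbation of each nonzero
#'   structural coupling entry (between-subject heterogeneity).
#' @param observation_noise_sd i.i.d. Gaussian noise added to every in-block
#'   voxel (signal units).
#' @param score_model list with fields `from`, `to` (node labels selecting the
#'   coupling entry that drives the score), `score` (clinical column name),
#'   `intercept`, `slope`, `noise_sd`: the avoidance-like score is
#'   `intercept + slope * realized_coupling + N(0, noise_sd)`.
#' @param motion_step_sd_mm,motion_step_sd_deg random-walk step scales for the
#'   simulated motion traces.
#' @param rng_seed master seed; every source of randomness derives from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_group_a = 22, n_group_b = 21,
                          grid_dims = c(24, 24, 12),
                          n_volumes = 205, tr_seconds = 2,
                          region_layout = default_region_layout(),
                          group_b_coupling_delta = default_group_delta(),
                          coupling_jitter_sd = 0.06,
                          observation_noise_sd = 0.3,
                          score_model = default_score_model(),
                          motion_step_sd_mm = 0.02,
                          motion_step_sd_deg = 0.02,
                          rng_seed = 20101222L) {
  stopifnot(n_group_a >= 2, n_group_b >= 2, length(grid_dims) == 3,
            all(grid_dims >= 1), n_volumes > 10, tr_seconds > 0,
            coupling_jitter_sd >= 0, observation_noise_sd >= 0)
  check_region_layout(region_layout, grid_dims)
  structure(
    list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
         grid_dims = as.integer(grid_dims), n_volumes = as.integer(n_volumes),
         tr_seconds = tr_seconds, region_layout = region_layout,
         group_b_coupling_delta = group_b_coupling_delta,
         coupling_jitter_sd = coupling_jitter_sd,
         observation_noise_sd = observation_noise_sd,
         score_model = score_model,
         motion_step_sd_mm = motion_step_sd_mm,
         motion_step_sd_deg = motion_step_sd_deg,
         rng_seed = as.integer(rng_seed)),
    class = "cohort_config")
}

#' Default voxel-block layout on the 24 x 24 x 12 grid
#' @return named list of `c(x0, x1, y0, y1, z0, z1)` blocks.
#' @export
default_region_layout <- function() {
  list(
    amygdala_left  = c(4, 7, 10, 13, 5, 7),
    amygdala_right = c(18, 21, 10, 13, 5, 7),
    itg            = c(4, 7, 18, 21, 3, 5),
    visual         = c(10, 14, 20, 23, 6, 8),
    wm             = c(10, 14, 4, 7, 9, 11),
    csf            = c(17, 20, 4, 6, 9, 11)
  )
}

#' Default planted group-B coupling change
#'
#' Controls (group B) receive +0.15 on both inferior-temporal-to-amygdala
#' couplings, i.e. patients have the reduced influence.
#' @return 4 x 4 delta matrix aligned with [default_network_spec()].
#' @export
default_group_delta <- function() {
  labels <- c("amygdala_left", "amygdala_right", "itg", "visual")
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  d["itg", "amygdala_left"] <- 0.15
  d["itg", "amygdala_right"] <- 0.15
  d
}

#' Default clinical-score generator
#'
#' Maps a subject's realized itg -> right-amygdala coupling to an
#' avoidance-like score with negative slope. With coupling jitter sd 0.06 the
#' implied population correlation is slope*0.06 / sqrt((slope*0.06)^2 +
#' noise_sd^2) = -0.6.
#' @return list consumed by [synthesize_cohort()].
#' @export
default_score_model <- function() {
  list(from = "itg", to = "amygdala_right", score = "lsas_avoidance",
       intercept = 39.95, slope = -60, noise_sd = 4.8)
}

check_region_layout <- function(layout, grid_dims) {
  stopifnot(is.list(layout), length(names(layout)) == length(layout))
  occupied <- array(FALSE, dim = grid_dims)
  for (nm in names(layout)) {
    b <- layout[[nm]]
    if (length(b) != 6) stop("region block '", nm, "' must have 6 entries")
    if (b[1] < 1 || b[3] < 1 || b[5] < 1 ||
        b[2] > grid_dims[1] || b[4] > grid_dims[2] || b[6] > grid_dims[3] ||
        b[1] > b[2] || b[3] > b[4] || b[5] > b[6]) {
      stop("region block '", nm, "' does not fit the grid")
    }
    sel <- occupied[b[1]:b[2], b[3]:b[4], b[5]:b[6]]
    if (any(sel)) stop("region block '", nm, "' overlaps another block")
    occupied[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- TRUE
  }
  invisible(TRUE)
}

block_mask <- function(block, grid_dims) {
  m <- array(FALSE, dim = grid_dims)
  m[block[1]:block[2], block[3]:block[4], block[5]:block[6]] <- TRUE
  m
}
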