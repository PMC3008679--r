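#' Preprocessing configuration
#'
#' Defaults are the conventional resting-state settings this package targets:
#' discard 5 initial volumes, 0.01--0.08 Hz pass band, 8 mm FWHM smoothing
#' (off by default for synthetic runs), and exclusion limits of 1.5 mm
#' translation / 1.5 degrees rotation.
#'
#' @param n_discard initial volumes to drop.
#' @param band_low_hz,band_high_hz pass-band edges (Hz); must satisfy
#'   `0 <= low < high < 1/(2 TR)` at use time.
#' @param smoothing_fwhm_mm isotropic Gaussian FWHM in mm; `NULL` or 0
#'   disables smoothing.
#' @param voxel_size_mm per-axis voxel size in mm (used by smoothing).
#' @param motion_limit_mm,motion_limit_deg exclusion thresholds; a subject is
#'   excluded when any motion parameter strictly exceeds its limit.
#' @param use_motion_regressors,use_wm_regressor,use_csf_regressor nuisance
#'   regressor switches.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 5L,
                              band_low_hz = 0.01, band_high_hz = 0.08,
                              smoothing_fwhm_mm = NULL,
                              voxel_size_mm = c(3, 3, 3),
                              motion_limit_mm = 1.5, motion_limit_deg = 1.5,
                              use_motion_regressors = TRUE,
                              use_wm_regressor = TRUE,
                              use_csf_regressor = TRUE) {
  stopifnot(n_discard >= 0, band_low_hz >= 0, band_low_hz < band_high_hz,
            motion_limit_mm > 0, motion_limit_deg > 0,
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  structure(list(n_discard = as.integer(n_discard),
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 voxel_size_mm = voxel_size_mm,
                 motion_limit_mm = motion_limit_mm,
                 motion_limit_deg = motion_limit_deg,
                 use_motion_regressors = use_motion_regressors,
                 use_wm_regressor = use_wm_regressor,
                 use_csf_regressor = use_csf_regressor),
            class = "preprocess_config")
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` time points of a 4D volume (steady-state
#' magnetization settling).
#'
#' @param volume 4D array (x, y, z, t).
#' @param n_discard number of leading volumes to drop; must be < T.
#' @return 4D array with the time dimension reduced by `n_discard`.
#' @export
discard_initial <- function(volume, n_discard) {
  stopifnot(length(dim(volume)) == 4, n_discard >= 0)
  n_t <- dim(volume)[4]
  if (n_discard >= n_t) {
    stop(sprintf("cannot discard %d of %d volumes", n_discard, n_t))
  }
  if (n_discard == 0) return(volume)
  volume[, , , (n_discard + 1):n_t, drop = FALSE]
}

#' Head-motion summary: mean frame-to-frame displacement
#'
#' Summarizes a rigid-body motion trace as the mean Euclidean frame-to-frame
#' step, separately for the three translations (mm) and the three rotation
#' angles (degrees):
#' \deqn{\frac{1}{L-1}\sum_{i=2}^{L}\sqrt{(x_i-x_{i-1})^2+(y_i-y_{i-1})^2+(z_i-z_{i-1})^2}}
#'
#' @param trace a [motion_trace()].
#' @return named numeric: `translation_mm`, `rotation_deg`.
#' @export
motion_summary <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"), trace$n_volumes >= 2)
  step <- function(m) {
    d <- diff(m)
    mean(sqrt(rowSums(d^2)))
  }
  c(translation_mm = step(trace$translations),
    rotation_deg = step(trace$rotations))
}

#' Motion-based subject exclusion
#'
#' Excludes a subject when any translation parameter strictly exceeds
#' `limit_mm` in absolute value, or any rotation angle strictly exceeds
#' `limit_deg`. A value exactly at the limit is retained.
#'
#' @param trace a [motion_trace()].
#' @param limit_mm,limit_deg exclusion thresholds (default 1.5 / 1.5).
#' @return list: `exclude` (logical), and when excluded `parameter`
#'   (`"translation"`/`"rotation"`), `axis` (1..3) and `volume` of the worst
#'   offender.
#' @export
motion_exclusion <- function(trace, limit_mm = 1.5, limit_deg = 1.5) {
  stopifnot(inherits(trace, "motion_trace"))
  at <- abs(trace$translations)
  ar <- abs(trace$rotations)
  out <- list(exclude = FALSE, parameter = NA_character_,
              axis = NA_integer_, volume = NA_integer_)
  worst_t <- max(at)
  worst_r <- max(ar)
  if (worst_t > limit_mm || worst_r > limit_deg) {
    out$exclude <- TRUE
    if (worst_t / limit_mm >= worst_r / limit_deg) {
      idx <- which(at == worst_t, arr.ind = TRUE)[1, ]
      out$parameter <- "translation"
    } else {
      idx <- which(ar == worst_r, arr.ind = TRUE)[1, ]
      out$parameter <- "rotation"
    }
    out$volume <- unname(idx[1])
    out$axis <- unname(idx[2])
  }
  out
}

#' Mean time series over a mask
#'
#' @param volume 4D array (x, y, z, t).
#' @param mask logical/0-1 3D array on the same spatial grid; must be
#'   non-empty.
#' @return numeric vector of length T: the unweighted per-timepoint mean over
#'   in-mask voxels.
#' @export
extract_mean_series <- function(volume, mask) {
  stopifnot(length(dim(volume)) == 4)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(volume)[1:3], dim(mask))) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match volume grid ", paste(dim(volume)[1:3], collapse = "x"))
  }
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  vm <- matrix(volume, nrow = prod(dim(volume)[1:3]))
  colMeans(vm[idx, , drop = FALSE])
}

#' Regress nuisance signals out of a time series
#'
#' Ordinary-least-squares residuals of `series` on an intercept plus the
#' given regressors. Rank-deficient (collinear) designs are handled by the
#' minimum-norm least-squares solution with a warning.
#'
#' @param series numeric vector.
#' @param regressors list of numeric vectors (or a matrix with T rows), all
#'   the same length as `series`.
#' @return residual vector; sums to ~0 and is orthogonal to every regressor.
#' @export
regress_nuisance <- function(series, regressors) {
  X <- if (is.matrix(regressors)) regressors else do.call(cbind, regressors)
  stopifnot(nrow(X) == length(series))
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("collinear nuisance regressors: using minimum-norm least squares")
    beta <- c(svd_lstsq(D, series))
    return(series - c(D %*% beta))
  }
  c(qr.resid(qrD, series))
}

# minimum-norm least squares via SVD (rank-deficient designs)
svd_lstsq <- function(D, y) {
  s <- svd(D)
  tol <- max(dim(D)) * .Machine$double.eps * s$d[1]
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos])
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain filter: the series is transformed with the FFT, Fourier
#' coefficients outside the pass band are zeroed, and coefficients near the
#' band edges are attenuated with a raised-cosine taper of half-width
#' `taper_hz`; the result is transformed back. The response is exactly zero
#' phase and the output has the same length as the input.
#'
#' @param series numeric vector (length >= 8).
#' @param low_hz,high_hz pass-band edges; require `0 <= low < high < Nyquist`.
#' @param tr_seconds sampling interval (s).
#' @param taper_hz transition half-width (Hz).
#' @return filtered series.
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.08,
                            tr_seconds = 2, taper_hz = 0.002) {
  n <- length(series)
  stopifnot(n >= 8, tr_seconds > 0)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz",
                 low_hz, high_hz, nyquist))
  }
  gain <- bandpass_gain(n, tr_seconds, low_hz, high_hz, taper_hz)
  Re(stats::fft(stats::fft(series) * gain, inverse = TRUE)) / n
}

# per-bin gain vector shared by the vector and matrix filter paths
bandpass_gain <- function(n, tr_seconds, low_hz, high_hz, taper_hz) {
  freq <- (seq_len(n) - 1) / (n * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)   # two-sided (aliased) frequency
  ramp <- function(f, edge, width) {
    # 0 below edge-width, raised cosine to 1 at edge+width
    x <- (f - (edge - width)) / (2 * width)
    0.5 - 0.5 * cos(pi * pmin(pmax(x, 0), 1))
  }
  ramp(freq, low_hz, taper_hz) * (1 - ramp(freq, high_hz, taper_hz))
}

#' Remove a linear trend
#'
#' Subtracts the OLS line (intercept + slope * t) from the series.
#'
#' @param series numeric vector, length >= 3.
#' @return detrended series; refitting a line to it gives slope and intercept
#'   below 1e-10.
#' @export
detrend_linear <- function(series) {
  n <- length(series)
  stopifnot(n >= 3)
  t_c <- seq_len(n) - (n + 1) / 2
  series - mean(series) - t_c * (sum(t_c * series) / sum(t_c^2))
}

#' Spatial Gaussian smoothing of a 4D volume
#'
#' Per-timepoint separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, expressed in voxel units via
#' `voxel_size_mm`. Kernels are normalized to unit mass (truncated at 4
#' sigma), so constant volumes pass through unchanged and interior mass is
#' preserved.
#'
#' @param volume 4D array (x, y, z, t).
#' @param fwhm_mm isotropic kernel FWHM in mm; 0 returns the input.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @return smoothed 4D array.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_size_mm = c(3, 3, 3)) {
  stopifnot(length(dim(volume)) == 4, fwhm_mm >= 0, all(voxel_size_mm > 0))
  if (fwhm_mm == 0) return(volume)
  dims <- dim(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  kmats <- lapply(1:3, function(ax) conv_matrix(dims[ax], sigma_vox[ax]))
  out <- volume
  for (t in seq_len(dims[4])) {
    v <- out[, , , t]
    # axis 1
    v <- array(kmats[[1]] %*% matrix(v, nrow = dims[1]), dim = dims[1:3])
    # axis 2
    v <- aperm(array(kmats[[2]] %*% matrix(aperm(v, c(2, 1, 3)), nrow = dims[2]),
                     dim = dims[c(2, 1, 3)]), c(2, 1, 3))
    # axis 3
    v <- aperm(array(kmats[[3]] %*% matrix(aperm(v, c(3, 1, 2)), nrow = dims[3]),
                     dim = dims[c(3, 1, 2)]), c(2, 3, 1))
    out[, , , t] <- v
  }
  out
}

# n x n convolution matrix for a unit-mass Gaussian kernel; truncated rows at
# the boundaries are renormalized so constants pass through unchanged
conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

#' Full voxel-wise nuisance preprocessing
#'
#' Composition of the per-subject cleaning pipeline, applied to every in-brain
#' voxel in this order: discard initial volumes, optional spatial smoothing,
#' nuisance regression (6 motion parameters + white-matter mean + CSF mean,
#' with intercept), zero-phase band-pass filtering, linear detrending.
#' Tissue nuisance means are extracted from the unsmoothed post-discard data.
#' Voxels with (numerically) zero variance are passed through as zeros and
#' flagged rather than erroring.
#'
#' @param volume 4D array (x, y, z, t), pre-discard.
#' @param trace a [motion_trace()] with one row per pre-discard volume, or
#'   `NULL` to skip motion regressors.
#' @param wm_mask,csf_mask logical 3D arrays (tissue compartments).
#' @param config a [preprocess_config()].
#' @param brain_mask logical 3D array of voxels to clean (default: all).
#' @param tr_seconds sampling interval (s).
#' @return list: `cleaned` 4D array (out-of-mask voxels zero), `brain_mask`,
#'   `constant_voxels` (logical 3D array of flagged voxels), `n_discarded`.
#' @export
preprocess_voxelwise <- function(volume, trace, wm_mask, csf_mask, config,
                                 brain_mask = NULL, tr_seconds = 2) {
  stopifnot(inherits(config, "preprocess_config"), length(dim(volume)) == 4)
  dims <- dim(volume)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dims[1:3])

  vol <- discard_initial(volume, config$n_discard)
  n_t <- dim(vol)[4]

  regs <- list()
  if (config$use_motion_regressors && !is.null(trace)) {
    stopifnot(inherits(trace, "motion_trace"))
    if (trace$n_volumes != dims[4]) {
      stop("motion trace has ", trace$n_volumes, " rows but volume has ",
           dims[4], " time points")
    }
    keep <- (config$n_discard + 1):dims[4]
    regs <- c(regs, asplit(cbind(trace$translations[keep, , drop = FALSE],
                                 trace$rotations[keep, , drop = FALSE]), 2))
  }
  if (config$use_wm_regressor && !is.null(wm_mask) && any(wm_mask)) {
    regs <- c(regs, list(extract_mean_series(vol, wm_mask)))
  }
  if (config$use_csf_regressor && !is.null(csf_mask) && any(csf_mask)) {
    regs <- c(regs, list(extract_mean_series(vol, csf_mask)))
  }

  if (!is.null(config$smoothing_fwhm_mm) && config$smoothing_fwhm_mm > 0) {
    vol <- smooth_gaussian(vol, config$smoothing_fwhm_mm, config$voxel_size_mm)
  }

  vm <- matrix(vol, nrow = prod(dims[1:3]))   # voxels x time
  idx <- which(brain_mask)
  V <- vm[idx, , drop = FALSE]

  const <- apply_constant_flag(V)
  # nuisance regression (vectorized across voxels)
  D <- cbind(1, do.call(cbind, regs))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("collinear nuisance design: dropping dependent columns")
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
    qrD <- qr(D)
  }
  V <- V - t(qr.fitted(qrD, t(V)))
  # band-pass (vectorized FFT over columns of t(V))
  gain <- bandpass_gain(n_t, tr_seconds, config$band_low_hz,
                        config$band_high_hz, 0.002)
  V <- t(filter_columns(t(V), gain))
  # linear detrend
  t_c <- seq_len(n_t) - (n_t + 1) / 2
  V <- V - rowMeans(V)
  V <- V - outer(c(V %*% t_c) / sum(t_c^2), t_c)
  V[const, ] <- 0

  out <- matrix(0, nrow = prod(dims[1:3]), ncol = n_t)
  out[idx, ] <- V
  const_map <- array(FALSE, dim = dims[1:3])
  const_map[idx[const]] <- TRUE
  list(cleaned = array(out, dim = c(dims[1:3], n_t)),
       brain_mask = brain_mask,
       constant_voxels = const_map,
       n_discarded = config$n_discard)
}

# Apply a real symmetric frequency-domain gain to every column. Columns are
# packed in pairs into one complex series (filtering is linear with real
# coefficients, so real and imaginary parts filter independently), halving
# the FFT work.
filter_columns <- function(X, gain) {
  n <- nrow(X)
  m <- ncol(X)
  half <- ceiling(m / 2)
  idx1 <- seq_len(half)
  idx2 <- half + seq_len(m - half)
  Z <- X[, idx1, drop = FALSE] + 0i
  Z[, seq_along(idx2)] <- Z[, seq_along(idx2), drop = FALSE] +
    1i * X[, idx2, drop = FALSE]
  Zf <- stats::mvfft(stats::mvfft(Z) * gain, inverse = TRUE) / n
  out <- X
  out[, idx1] <- Re(Zf)
  out[, idx2] <- Im(Zf[, seq_along(idx2), drop = FALSE])
  out
}

apply_constant_flag <- function(V) {
  mu <- rowMeans(V)
  ss <- rowSums((V - mu)^2)
  ss <= (1e-12 * pmax(1, abs(mu)))^2 * (ncol(V) - 1)
}
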