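#' Bivariate Granger causality with Geweke's influence measure
#'
#' Fits nested autoregressions for both directions between a seed series `x`
#' and a target series `y`. For each direction the restricted model predicts
#' the target from an intercept and its own `p` lags; the full model adds the
#' other series' `p` lags. Both fits use ordinary least squares on the same
#' `T - p` aligned samples, and the influence measure is Geweke's log variance
#' ratio \eqn{F = \ln(\sigma^2_{restricted} / \sigma^2_{full})} (nats), with
#' residual variances computed as RSS / (T - p) in both models.
#'
#' `F` is nonnegative up to numerical noise (nested least squares cannot
#' increase the residual sum of squares) and invariant to positive rescaling
#' of either series.
#'
#' @param x seed time series (numeric vector).
#' @param y target time series, same length; `T >= p + 10`.
#' @param p model order (>= 1).
#' @return list with `fit_y` (VAR fit for target `y`, direction x -> y),
#'   `fit_x` (VAR fit for target `x`), and `influence`, a named numeric
#'   vector `c(f_x_to_y =, f_y_to_x =)`.
#' @export
granger_pair <- function(x, y, p = 1L) {
  stopifnot(length(x) == length(y), p >= 1, length(x) >= p + 10)
  if (is_constant(x)) stop("seed series is constant")
  if (is_constant(y)) stop("target series is constant")
  fit_y <- nested_ar_fit(source = x, target = y, p = p)
  fit_x <- nested_ar_fit(source = y, target = x, p = p)
  list(fit_y = fit_y, fit_x = fit_x,
       influence = c(f_x_to_y = fit_y$f, f_y_to_x = fit_x$f))
}

is_constant <- function(v) diff(range(v)) <= 1e-12 * max(1, abs(mean(v)))

# Nested OLS fits for one direction; general order p.
nested_ar_fit <- function(source, target, p) {
  T <- length(target)
  n_eff <- T - p
  yy <- target[(p + 1):T]
  own <- lag_matrix(target, p)
  oth <- lag_matrix(source, p)
  Xr <- cbind(1, own)
  Xf <- cbind(Xr, oth)
  qr_r <- qr(Xr)
  qr_f <- qr(Xf)
  singular <- qr_f$rank < ncol(Xf)
  if (singular) {
    warning("near-singular full design: using minimum-norm least squares")
    beta_f <- c(svd_lstsq(Xf, yy))
    res_f <- yy - c(Xf %*% beta_f)
  } else {
    beta_f <- qr.coef(qr_f, yy)
    res_f <- qr.resid(qr_f, yy)
  }
  beta_r <- qr.coef(qr_r, yy)
  res_r <- qr.resid(qr_r, yy)
  s2_r <- sum(res_r^2) / n_eff
  s2_f <- sum(res_f^2) / n_eff
  f <- if (s2_f <= 0) Inf else log(s2_r / s2_f)
  list(order = p,
       restricted_coefficients = unname(beta_r),
       full_coefficients = unname(beta_f),
       restricted_residual_variance = s2_r,
       full_residual_variance = s2_f,
       n_effective = n_eff,
       singular = singular,
       f = f)
}

# rows t = p+1..T, columns lag 1..p
lag_matrix <- function(v, p) {
  T <- length(v)
  vapply(seq_len(p), function(l) v[(p + 1 - l):(T - l)], numeric(T - p))
}

# Fast single-direction F (closed form for p = 1; qr path otherwise).
f_influence <- function(source, target, p = 1L) {
  if (p == 1L) {
    T <- length(target)
    y1 <- target[-1]
    y0 <- target[-T]
    x0 <- source[-T]
    cy1 <- y1 - mean(y1)
    cy0 <- y0 - mean(y0)
    cx0 <- x0 - mean(x0)
    syy <- sum(cy1 * cy1)
    s00 <- sum(cy0 * cy0)
    sxx <- sum(cx0 * cx0)
    s0x <- sum(cy0 * cx0)
    g1 <- sum(cy0 * cy1)
    g2 <- sum(cx0 * cy1)
    rss_r <- syy - g1 * g1 / s00
    det <- s00 * sxx - s0x * s0x
    rss_f <- syy - (sxx * g1 * g1 - 2 * s0x * g1 * g2 + s00 * g2 * g2) / det
    return(log(rss_r / rss_f))
  }
  nested_ar_fit(source, target, p)$f
}

#' Model-order selection by the Schwarz criterion
#'
#' Fits the bivariate full VAR at each candidate order `1..p_max` on the same
#' `T - p_max` aligned samples and returns the order minimizing
#' \eqn{\ln\det\hat\Sigma + k \ln(n) / n}, where \eqn{\hat\Sigma} is the 2 x 2
#' residual covariance and `k` the number of estimated coefficients.
#'
#' @param x,y equal-length series; `T > 10 * p_max`.
#' @param p_max largest order considered (>= 1).
#' @return selected order (integer).
#' @export
select_order <- function(x, y, p_max = 4L) {
  stopifnot(length(x) == length(y), p_max >= 1, length(x) > 10 * p_max)
  if (p_max == 1L) return(1L)
  T <- length(x)
  n <- T - p_max
  rows <- (p_max + 1):T
  sc <- vapply(seq_len(p_max), function(p) {
    lag_cols <- lapply(seq_len(p), function(l) cbind(x[rows - l], y[rows - l]))
    D <- cbind(1, do.call(cbind, lag_cols))
    res <- qr.resid(qr(D), cbind(x[rows], y[rows]))
    sigma <- crossprod(res) / n
    k <- 2 * (1 + 2 * p)
    determinant(sigma)$modulus[1] + k * log(n) / n
  }, numeric(1))
  which.min(sc)
}

#' Voxel-wise influence maps from a seed
#'
#' Computes Geweke's influence measure in both directions between the seed
#' series and every in-mask voxel series. Out-of-mask voxels carry `NA`;
#' degenerate voxels (constant series, or collinear with the seed) are
#' flagged and set `NA`. Order 1 uses a closed-form vectorized solver that is
#' algebraically identical to [granger_pair()].
#'
#' @param seed seed time series (length T).
#' @param cleaned 4D array (x, y, z, T) of cleaned voxel series.
#' @param brain_mask logical 3D array; must be non-empty.
#' @param p model order (default 1).
#' @param seed_label optional label stored with the maps.
#' @return object of class `influence_maps`: list with `map_from_seed`,
#'   `map_to_seed` (3D arrays, nats), `brain_mask`, `degenerate` (logical 3D
#'   array), `order`, `seed_label`.
#' @export
influence_maps <- function(seed, cleaned, brain_mask, p = 1L, seed_label = "seed") {
  stopifnot(length(dim(cleaned)) == 4)
  dims <- dim(cleaned)
  if (dims[4] != length(seed)) stop("seed length does not match volume time dimension")
  brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
  if (!identical(dim(brain_mask), dims[1:3])) stop("mask grid mismatch")
  idx <- which(brain_mask)
  if (!length(idx)) stop("brain mask is empty")
  if (is_constant(seed)) stop("seed series is constant")

  V <- matrix(cleaned, nrow = prod(dims[1:3]))[idx, , drop = FALSE]
  if (p == 1L) {
    res <- vox_gca_p1(seed, V)
  } else {
    f_from <- f_to <- rep(NA_real_, length(idx))
    degen <- logical(length(idx))
    for (i in seq_along(idx)) {
      v <- V[i, ]
      if (is_constant(v)) {
        degen[i] <- TRUE
        next
      }
      fy <- nested_ar_fit(seed, v, p)
      fx <- nested_ar_fit(v, seed, p)
      if (fy$singular || fx$singular) {
        degen[i] <- TRUE
        next
      }
      f_from[i] <- fy$f
      f_to[i] <- fx$f
    }
    res <- list(f_from = f_from, f_to = f_to, degenerate = degen)
  }
  map_from <- map_to <- array(NA_real_, dim = dims[1:3])
  degen_map <- array(FALSE, dim = dims[1:3])
  map_from[idx] <- res$f_from
  map_to[idx] <- res$f_to
  degen_map[idx] <- res$degenerate
  structure(list(map_from_seed = map_from, map_to_seed = map_to,
                 brain_mask = brain_mask, degenerate = degen_map,
                 order = as.integer(p), seed_label = seed_label),
            class = "influence_maps")
}

# Vectorized order-1 bidirectional Geweke measures for a voxel matrix
# (voxels x T). Suppressed warnings: degenerate rows produce NaN and are
# masked afterwards.
vox_gca_p1 <- function(seed, V) {
  T <- length(seed)
  n <- T - 1
  s1 <- seed[-1]
  s0 <- seed[-T]
  cs1 <- s1 - mean(s1)
  cs0 <- s0 - mean(s0)
  Y1 <- V[, -1, drop = FALSE]
  Y0 <- V[, -T, drop = FALSE]
  Y1 <- Y1 - rowMeans(Y1)
  Y0 <- Y0 - rowMeans(Y0)
  syy <- rowSums(Y1 * Y1)
  s00 <- rowSums(Y0 * Y0)
  sxx <- sum(cs0 * cs0)
  s0x <- c(Y0 %*% cs0)
  det <- s00 * sxx - s0x * s0x
  scale <- pmax(s00 * sxx, .Machine$double.xmin)
  degenerate <- s00 <= 1e-12 * n | syy <= 1e-12 * n | det <= 1e-10 * scale
  # direction seed -> voxel (target = voxel)
  g1 <- rowSums(Y0 * Y1)
  g2 <- c(Y1 %*% cs0)
  rss_r <- syy - g1 * g1 / s00
  rss_f <- syy - (sxx * g1 * g1 - 2 * s0x * g1 * g2 + s00 * g2 * g2) / det
  f_from <- log(rss_r / rss_f)
  # direction voxel -> seed (target = seed)
  sss <- sum(cs1 * cs1)
  gs <- sum(cs0 * cs1)
  gv <- c(Y0 %*% cs1)
  rss_r_s <- sss - gs * gs / sxx
  rss_f_s <- sss - (s00 * gs * gs - 2 * s0x * gs * gv + sxx * gv * gv) / det
  f_to <- log(rss_r_s / rss_f_s)
  f_from[degenerate] <- NA_real_
  f_to[degenerate] <- NA_real_
  list(f_from = f_from, f_to = f_to, degenerate = degenerate)
}

#' Permutation significance of one influence measure
#'
#' Builds the null distribution by reshuffling the *target* time course with
#' uniform random permutations (the source is untouched), recomputing the
#' influence measure each time. The permutation destroys the target's
#' temporal structure entirely. The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{F_{null} \ge F_{obs}\}) / (n_{perm} + 1)} and therefore
#' never returns 0.
#'
#' @param x seed series; `y` target series (equal length).
#' @param p model order.
#' @param direction `"x_to_y"` (target `y` is reshuffled) or `"y_to_x"`
#'   (target `x` is reshuffled).
#' @param n_perm number of permutations (>= 100; default 500).
#' @param rng_seed integer seed.
#' @return list: `observed` (nats), `null_samples` (length `n_perm`),
#'   `p_value`.
#' @export
permutation_pvalue <- function(x, y, p = 1L, direction = c("x_to_y", "y_to_x"),
                               n_perm = 500L, rng_seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(n_perm >= 100, length(x) == length(y))
  if (direction == "x_to_y") {
    source <- x
    target <- y
  } else {
    source <- y
    target <- x
  }
  observed <- f_influence(source, target, p)
  T <- length(target)
  set.seed(as.integer(rng_seed))
  null_samples <- vapply(seq_len(n_perm), function(k) {
    f_influence(source, target[sample.int(T)], p)
  }, numeric(1))
  list(observed = observed,
       null_samples = null_samples,
       p_value = (1 + sum(null_samples >= observed)) / (n_perm + 1))
}

#' Permutation null-mean maps for group-level inference
#'
#' For each of `n_perm` draws, the target side of every seed-voxel pair is
#' reshuffled with one shared random time permutation and both influence maps
#' are recomputed; the per-voxel mean over draws estimates the null mean of
#' the influence measure under no temporal dependence. Used as the reference
#' value in [significance_mask_for_group()].
#'
#' @param seed seed series.
#' @param cleaned 4D cleaned volume.
#' @param brain_mask logical 3D array.
#' @param p model order (only 1 is supported on this vectorized path).
#' @param n_perm permutation draws.
#' @param rng_seed integer seed.
#' @param directions which null-mean maps to compute.
#' @return list of 3D arrays: `from_seed` and/or `to_seed` null-mean maps
#'   (`NULL` when not requested).
#' @export
influence_null_mean <- function(seed, cleaned, brain_mask, p = 1L,
                                n_perm = 20L, rng_seed = 1L,
                                directions = c("from_seed", "to_seed")) {
  stopifnot(p == 1L, n_perm >= 1)
  directions <- match.arg(directions, several.ok = TRUE)
  dims <- dim(cleaned)
  idx <- which(brain_mask)
  V <- matrix(cleaned, nrow = prod(dims[1:3]))[idx, , drop = FALSE]
  T <- dims[4]
  acc_from <- acc_to <- numeric(length(idx))
  set.seed(as.integer(rng_seed))
  for (k in seq_len(n_perm)) {
    perm <- sample.int(T)
    # targets reshuffled: voxels for the from-seed direction,
    # the seed itself for the to-seed direction
    if ("from_seed" %in% directions) {
      acc_from <- acc_from + vox_gca_p1(seed, V[, perm, drop = FALSE])$f_from
    }
    if ("to_seed" %in% directions) {
      acc_to <- acc_to + vox_gca_p1(seed[perm], V)$f_to
    }
  }
  mk <- function(v) {
    m <- array(NA_real_, dim = dims[1:3])
    m[idx] <- v / n_perm
    m
  }
  list(from_seed = if ("from_seed" %in% directions) mk(acc_from),
       to_seed = if ("to_seed" %in% directions) mk(acc_to))
}
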