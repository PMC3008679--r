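test_that("initial-volume discarding reduces 205 volumes to 200 and checks bounds", {
  vol <- array(rnorm(4 * 4 * 2 * 205), dim = c(4, 4, 2, 205))
  out <- discard_initial(vol, 5)
  expect_equal(dim(out), c(4, 4, 2, 200))
  expect_identical(out[, , , 1], vol[, , , 6])
  expect_identical(discard_initial(vol, 0), vol)
  expect_error(discard_initial(vol, 205), "cannot discard")
})

test_that("motion summary is the mean frame-to-frame Euclidean step", {
  zeros <- matrix(0, 3, 3)
  const <- motion_trace(matrix(1.2, 4, 3), matrix(-0.4, 4, 3))
  expect_equal(unname(motion_summary(const)), c(0, 0))

  tr <- motion_trace(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), zeros)
  expect_equal(unname(motion_summary(tr)), c(1, 0))   # steps 1 and 1

  tr2 <- motion_trace(rbind(c(0, 0, 0), c(3, 4, 0)), matrix(0, 2, 3))
  expect_equal(motion_summary(tr2)[["translation_mm"]], 5)

  # translation invariance: constant offset leaves the summary unchanged
  set.seed(1)
  t1 <- matrix(rnorm(30), 10, 3)
  r1 <- matrix(rnorm(30), 10, 3)
  s1 <- motion_summary(motion_trace(t1, r1))
  s2 <- motion_summary(motion_trace(t1 + 7, r1 - 2))
  expect_equal(s1, s2)
})

test_that("motion exclusion is strict at the 1.5 mm / 1.5 degree limits", {
  mk <- function(tmax) {
    tr <- matrix(0, 5, 3)
    tr[3, 2] <- tmax
    motion_trace(tr, matrix(0, 5, 3))
  }
  ex <- motion_exclusion(mk(1.6))
  expect_true(ex$exclude)
  expect_equal(ex$parameter, "translation")
  expect_equal(ex$axis, 2)
  expect_equal(ex$volume, 3)
  expect_false(motion_exclusion(mk(0))$exclude)
  expect_false(motion_exclusion(mk(1.5))$exclude)   # at the limit: retained
  rot <- motion_trace(matrix(0, 5, 3), matrix(c(rep(0, 12), 2, 0, 0), 5, 3, byrow = TRUE))
  expect_true(motion_exclusion(rot)$exclude)
})

test_that("mask-mean extraction averages exactly and validates inputs", {
  vol <- array(rnorm(3 * 3 * 2 * 10), dim = c(3, 3, 2, 10))
  m1 <- array(FALSE, c(3, 3, 2))
  m1[2, 2, 1] <- TRUE
  expect_equal(extract_mean_series(vol, m1), vol[2, 2, 1, ])

  uni <- array(4.2, dim = c(3, 3, 2, 5))
  mall <- array(TRUE, c(3, 3, 2))
  expect_equal(extract_mean_series(uni, mall), rep(4.2, 5))

  m2 <- m1
  m2[1, 3, 2] <- TRUE
  expect_equal(extract_mean_series(vol, m2), (vol[2, 2, 1, ] + vol[1, 3, 2, ]) / 2)

  expect_error(extract_mean_series(vol, array(FALSE, c(3, 3, 2))), "empty")
  expect_error(extract_mean_series(vol, array(TRUE, c(2, 3, 2))), "does not match")
})

test_that("nuisance regression returns exact OLS residuals orthogonal to the design", {
  x <- c(1, 2, 3, 4)
  expect_lt(max(abs(regress_nuisance(x, list(x)))), 1e-10)

  # mean-zero series orthogonal to the regressor passes through
  s <- c(1, -1, 1, -1)
  r <- c(1, 1, 1, 1) * 2   # collinear with intercept -> s unchanged
  expect_warning(out <- regress_nuisance(s, list(r)), "collinear")
  expect_lt(max(abs(out - s)), 1e-10)

  # hand-solved normal equations: y=(1,2,3,5) on x=(1,2,3,4)
  res <- regress_nuisance(c(1, 2, 3, 5), list(c(1, 2, 3, 4)))
  expect_equal(res, c(0.2, -0.1, -0.4, 0.3), tolerance = 1e-10)

  # orthogonality property on random designs
  set.seed(4)
  for (k in 1:20) {
    y <- rnorm(40)
    R <- replicate(3, rnorm(40))
    resid <- regress_nuisance(y, asplit(R, 2))
    expect_lt(abs(sum(resid)), 1e-8 * sqrt(sum(resid^2)) * sqrt(40))
    for (j in 1:3) {
      expect_lt(abs(sum(resid * R[, j])),
                1e-8 * sqrt(sum(resid^2)) * sqrt(sum(R[, j]^2)))
    }
  }
})

test_that("band-pass keeps 0.04 Hz, removes DC and 0.2 Hz, with zero phase", {
  tt <- seq_len(400) * 2   # TR = 2 s

  dc <- rep(3, 400)
  expect_lt(max(abs(bandpass_filter(dc, tr_seconds = 2))), 1e-6 * 3)

  amp <- function(series, f) {
    # FFT amplitude oracle at frequency f
    n <- length(series)
    2 * Mod(fft(series))[round(f * n * 2) + 1] / n
  }
  in_band <- sin(2 * pi * 0.04 * tt)
  out <- bandpass_filter(in_band, tr_seconds = 2)
  expect_gt(amp(out, 0.04), 0.9)
  expect_lt(amp(out, 0.04), 1.1)
  # zero phase: output is in phase with the input
  expect_gt(cor(out, in_band), 0.99)

  hi <- sin(2 * pi * 0.2 * tt)
  expect_lt(max(abs(bandpass_filter(hi, tr_seconds = 2))), 0.1)

  # idempotence in the pass band
  once <- bandpass_filter(in_band, tr_seconds = 2)
  twice <- bandpass_filter(once, tr_seconds = 2)
  expect_lt(max(abs(twice - once)), 0.01)

  expect_error(bandpass_filter(in_band, 0.1, 0.3, tr_seconds = 2), "invalid band")
})

test_that("linear detrending removes exactly the OLS line", {
  t <- 1:50
  expect_lt(max(abs(detrend_linear(2 * t + 1))), 1e-10)
  expect_equal(detrend_linear(c(0, 1, 2, 3)), rep(0, 4), tolerance = 1e-12)
  set.seed(2)
  y <- rnorm(100)
  out <- detrend_linear(y)
  refit <- coef(lm(out ~ seq_along(out)))
  expect_lt(max(abs(refit)), 1e-10)
})

test_that("gaussian smoothing matches the separable closed form and conserves mass", {
  vol <- array(0, dim = c(15, 15, 15, 1))
  vol[8, 8, 8, 1] <- 1
  expect_identical(smooth_gaussian(vol, 0), vol)

  sm <- smooth_gaussian(vol, 8, voxel_size_mm = c(3, 3, 3))
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  expect_lt(abs(sm[8, 8, 8, 1] - dnorm(0, sd = sigma)^3) / dnorm(0, sd = sigma)^3,
            0.01)
  expect_lt(abs(sum(sm) - 1), 1e-3)   # interior impulse mass preserved

  const <- array(2.5, dim = c(8, 8, 8, 2))
  smc <- smooth_gaussian(const, 8)
  expect_lt(max(abs(smc - 2.5)), 1e-8)
})

test_that("voxelwise preprocessing removes its own regressors and follows the stated order", {
  dims <- c(4, 4, 2)
  n_t <- 45
  set.seed(9)
  wm_series <- ar1_series(n_t, 0.6, seed = 21)
  vol <- array(0, dim = c(dims, n_t))
  wm_mask <- array(FALSE, dims)
  wm_mask[1:2, 1:2, 1] <- TRUE
  csf_mask <- array(FALSE, dims)
  csf_mask[3:4, 1:2, 1] <- TRUE
  # every brain voxel equals the WM signal exactly
  for (t in seq_len(n_t)) vol[, , , t] <- wm_series[t]
  cfg <- preprocess_config(n_discard = 5)
  # WM and CSF means coincide here, so the design is deliberately collinear
  expect_warning(
    out <- preprocess_voxelwise(vol, NULL, wm_mask, csf_mask, cfg, tr_seconds = 2),
    "collinear")
  expect_equal(dim(out$cleaned), c(dims, n_t - 5))
  expect_lt(max(abs(out$cleaned)), 1e-8 * sd(wm_series))

  # order witness: band-pass before detrend (as composed) differs from the swap
  set.seed(10)
  y <- cumsum(rnorm(200)) + 40
  a <- detrend_linear(bandpass_filter(y, tr_seconds = 2))
  b <- bandpass_filter(detrend_linear(y), tr_seconds = 2)
  expect_gt(max(abs(a - b)), 1e-6)

  # smoke on a default synthetic subject: grid preserved, deterministic
  lay <- list(amygdala_left = c(1, 2, 1, 2, 1, 1),
              amygdala_right = c(4, 5, 1, 2, 1, 1),
              itg = c(1, 1, 4, 4, 2, 2), visual = c(4, 5, 4, 5, 2, 2),
              wm = c(1, 2, 1, 2, 3, 3), csf = c(4, 5, 1, 2, 3, 3))
  cc <- cohort_config(n_group_a = 2, n_group_b = 2, grid_dims = c(6, 6, 3),
                      n_volumes = 40, region_layout = lay)
  co <- synthesize_cohort(cc)
  s <- co$subjects[[1]]
  p1 <- preprocess_voxelwise(s$volume, s$motion, co$masks$wm_mask,
                             co$masks$csf_mask, cfg,
                             brain_mask = co$masks$brain_mask, tr_seconds = 2)
  p2 <- preprocess_voxelwise(s$volume, s$motion, co$masks$wm_mask,
                             co$masks$csf_mask, cfg,
                             brain_mask = co$masks$brain_mask, tr_seconds = 2)
  expect_equal(dim(p1$cleaned)[1:3], dim(s$volume)[1:3])
  expect_identical(p1$cleaned, p2$cleaned)
})
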