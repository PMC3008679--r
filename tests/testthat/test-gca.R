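test_that("influence measures are nonnegative and match the normal-equations oracle", {
  set.seed(100)
  for (k in 1:25) {
    x <- ar1_series(50, 0.4, seed = 200 + k)
    y <- ar1_series(50, 0.6, seed = 400 + k)
    gp <- granger_pair(x, y, 1)
    or <- oracle_granger(x, y, 1)
    expect_lt(max(abs(gp$influence - or$f)), 1e-10)
    expect_gt(gp$influence[["f_x_to_y"]], -1e-12)
    expect_gt(gp$influence[["f_y_to_x"]], -1e-12)
    expect_lt(max(abs(gp$fit_y$full_coefficients - or$fy$beta_f)), 1e-8)
    expect_lte(gp$fit_y$full_residual_variance,
               gp$fit_y$restricted_residual_variance + 1e-12)
  }
  # higher orders agree with the oracle too
  x <- ar1_series(80, 0.5, seed = 31)
  y <- ar1_series(80, 0.5, seed = 32)
  gp2 <- granger_pair(x, y, 3)
  or2 <- oracle_granger(x, y, 3)
  expect_lt(max(abs(gp2$influence - or2$f)), 1e-10)
})

test_that("estimated influence matches the Lyapunov closed-form population value", {
  # y_t = 0.5 y_{t-1} + 0.4 x_{t-1} + e;  x_t = 0.5 x_{t-1} + h
  pop <- oracle_population_f(a_x = 0.5, a_y = 0.5, c_xy = 0.4)
  expect_gt(pop[["f_x_to_y"]], 0)
  expect_equal(pop[["f_y_to_x"]], 0, tolerance = 1e-12)

  labels <- c("x", "y")
  C <- matrix(0, 2, 2, dimnames = list(labels, labels))
  C["x", "y"] <- 0.4
  spec <- network_spec(labels, c(0.5, 0.5), C)
  fs <- t(vapply(1:12, function(k) {
    z <- simulate_coupled_var(spec, 5000, rng_seed = 700 + k)
    granger_pair(z[, "x"], z[, "y"], 1)$influence
  }, numeric(2)))
  se <- apply(fs, 2, sd) / sqrt(nrow(fs))
  expect_lt(abs(mean(fs[, "f_x_to_y"]) - pop[["f_x_to_y"]]), 3 * se[1])
  expect_true(all(fs[, "f_y_to_x"] < fs[, "f_x_to_y"]))
})

test_that("null influence has asymptotic mean p/T for independent white series", {
  T <- 2000
  fs <- t(vapply(1:500, function(k) {
    set.seed(3000 + k)
    granger_pair(rnorm(T), rnorm(T), 1)$influence
  }, numeric(2)))
  for (j in 1:2) {
    se <- sd(fs[, j]) / sqrt(nrow(fs))
    expect_lt(abs(mean(fs[, j]) - 1 / T), 3 * se)
  }
})

test_that("influence is invariant to positive rescaling of either series", {
  x <- ar1_series(120, 0.5, seed = 51)
  y <- ar1_series(120, 0.5, seed = 52)
  base <- granger_pair(x, y, 1)$influence
  expect_lt(max(abs(granger_pair(7.3 * x, y, 1)$influence - base)), 1e-10)
  expect_lt(max(abs(granger_pair(x, 0.002 * y, 1)$influence - base)), 1e-10)
  expect_lt(max(abs(granger_pair(11 * x, 5 * y, 1)$influence - base)), 1e-10)
})

test_that("constant or degenerate series are rejected or flagged", {
  x <- ar1_series(60, 0.5, seed = 61)
  expect_error(granger_pair(rep(1, 60), x, 1), "constant")
  expect_error(granger_pair(x, rep(0, 60), 1), "constant")
})

test_that("Schwarz criterion selects the generating order", {
  labels <- c("x", "y")
  C <- matrix(0, 2, 2, dimnames = list(labels, labels))
  C["x", "y"] <- 0.4
  spec <- network_spec(labels, c(0.5, 0.5), C)
  z <- simulate_coupled_var(spec, 200, rng_seed = 77)
  expect_equal(select_order(z[, "x"], z[, "y"], p_max = 4), 1L)
  expect_equal(select_order(z[, "x"], z[, "y"], p_max = 1), 1L)

  # VAR(2) pair with substantial lag-2 cross weight
  set.seed(88)
  T <- 2000 + 200
  x <- as.numeric(stats::filter(rnorm(T), 0.3, method = "recursive"))
  y <- numeric(T)
  e <- rnorm(T)
  for (t in 3:T) y[t] <- 0.2 * y[t - 1] + 0.4 * x[t - 2] + e[t]
  expect_equal(select_order(x[201:T], y[201:T], p_max = 4), 2L)
})

test_that("influence maps: planted coupling elevates F, degenerate voxels flagged", {
  labels <- c("seed", "partner")
  C <- matrix(0, 2, 2, dimnames = list(labels, labels))
  C["seed", "partner"] <- 0.5
  spec <- network_spec(labels, c(0.5, 0.5), C)
  z <- simulate_coupled_var(spec, 300, rng_seed = 13)
  dims <- c(5, 5, 2)
  vol <- array(rnorm(prod(dims) * 300, sd = 1), dim = c(dims, 300))
  blk <- array(FALSE, dims)
  blk[1:2, 1:2, 1] <- TRUE
  for (v in which(blk)) {
    co <- arrayInd(v, dims)
    vol[co[1], co[2], co[3], ] <- z[, "partner"] + rnorm(300, sd = 0.3)
  }
  # one voxel duplicates the seed (degenerate full design)
  vol[5, 5, 2, ] <- z[, "seed"]
  mask <- array(TRUE, dims)
  im <- influence_maps(z[, "seed"], vol, mask, p = 1, seed_label = "left")
  expect_true(is.na(im$map_from_seed[5, 5, 2]))
  expect_true(im$degenerate[5, 5, 2])
  inb <- im$map_from_seed[blk]
  outb <- im$map_from_seed[!blk & !im$degenerate]
  expect_lt(wilcox.test(inb, outb, alternative = "greater")$p.value, 0.01)

  expect_error(influence_maps(z[, "seed"], vol, array(FALSE, dims)), "empty")
})

test_that("vectorized map solver agrees with granger_pair voxel by voxel", {
  set.seed(5)
  dims <- c(3, 3, 2)
  vol <- array(rnorm(prod(dims) * 80), dim = c(dims, 80))
  seed <- ar1_series(80, 0.5, seed = 6)
  im <- influence_maps(seed, vol, array(TRUE, dims), p = 1)
  for (v in seq_len(prod(dims))) {
    co <- arrayInd(v, dims)
    gp <- granger_pair(seed, vol[co[1], co[2], co[3], ], 1)$influence
    expect_lt(abs(im$map_from_seed[v] - gp[["f_x_to_y"]]), 1e-10)
    expect_lt(abs(im$map_to_seed[v] - gp[["f_y_to_x"]]), 1e-10)
  }
})

test_that("permutation p-values: add-one formula, default draws, reproducibility", {
  expect_equal(eval(formals(permutation_pvalue)$n_perm), 500L)

  labels <- c("x", "y")
  C <- matrix(0, 2, 2, dimnames = list(labels, labels))
  C["x", "y"] <- 0.8
  spec <- network_spec(labels, c(0.4, 0.4), C)
  z <- simulate_coupled_var(spec, 400, rng_seed = 9)
  pr <- permutation_pvalue(z[, "x"], z[, "y"], 1, "x_to_y",
                           n_perm = 500, rng_seed = 1)
  expect_equal(length(pr$null_samples), 500)
  expect_true(all(pr$null_samples < pr$observed))
  expect_equal(pr$p_value, 1 / 501)

  pr2 <- permutation_pvalue(z[, "x"], z[, "y"], 1, "x_to_y",
                            n_perm = 500, rng_seed = 1)
  expect_identical(pr$null_samples, pr2$null_samples)
})

test_that("permutation p-values are (super-)uniform under independence", {
  ps <- vapply(1:1000, function(k) {
    set.seed(6000 + k)
    x <- rnorm(120)
    y <- rnorm(120)
    permutation_pvalue(x, y, 1, "x_to_y", n_perm = 199,
                       rng_seed = 9000 + k)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lte(mean(ps <= 0.05), 0.08)
})
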