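test_that("group mean maps average voxel-wise and track coverage under missingness", {
  a <- array(1, c(2, 2, 2))
  b <- array(3, c(2, 2, 2))
  gm <- group_mean_map(list(a, a, a))
  expect_equal(gm$mean, a)
  expect_equal(group_mean_map(list(a, b))$mean, array(2, c(2, 2, 2)))

  maps <- replicate(5, array(2, c(2, 2, 2)), simplify = FALSE)
  maps[[3]][1, 1, 1] <- NA
  maps[[1]][1, 1, 1] <- 6
  gm <- group_mean_map(maps)
  expect_equal(gm$mean[1, 1, 1], (6 + 2 + 2 + 2) / 4)   # mean over remaining 4
  expect_equal(gm$coverage[1, 1, 1], 4)
  expect_equal(gm$coverage[2, 2, 2], 5)
  expect_error(group_mean_map(list(a, array(1, c(3, 2, 2)))), "congruent")
})

test_that("BH step-up matches hand cases and the brute-force oracle", {
  out <- fdr_threshold(c(0.01, 0.02, 0.03, 0.2, 0.5), q = 0.05)
  expect_equal(out$cutoff, 0.03)
  expect_equal(sum(out$reject), 3)

  out1 <- fdr_threshold(rep(1, 10), q = 0.05)
  expect_equal(out1$cutoff, 0)
  expect_false(any(out1$reject))

  set.seed(77)
  for (k in 1:300) {
    m <- sample(1:50, 1)
    p <- round(runif(m), 3)
    q <- runif(1, 0.01, 0.2)
    mine <- fdr_threshold(p, q)
    orc <- oracle_bh(p, q)
    expect_equal(mine$cutoff, orc$cutoff)
    expect_identical(mine$reject, orc$reject)
    # cross-check against stats::p.adjust (skip numerically ambiguous draws
    # where an adjusted p sits within floating-point error of q)
    padj <- p.adjust(p, "BH")
    if (min(abs(padj - q)) > 1e-9) {
      expect_identical(which(mine$reject), which(padj <= q))
    }
  }
  expect_error(fdr_threshold(numeric(0)), "empty")
})

test_that("cluster labeling honours connectivity and the extent threshold", {
  m <- array(FALSE, c(6, 6, 3))
  m[1:5, 1, 1] <- TRUE          # 5-voxel line
  m[1:5, 3:4, 3] <- TRUE        # 10-voxel slab
  lab <- label_clusters(m, 26)
  expect_equal(sort(lab$sizes), c(5, 10))
  kept <- filter_clusters(m, 10, 26)
  expect_equal(sum(kept), 10)
  expect_false(any(kept[, 1, 1]))
  # 9-voxel component is removed at the 10-voxel threshold
  m9 <- array(FALSE, c(4, 4, 3))
  m9[1:3, 1:3, 1] <- TRUE
  expect_equal(sum(filter_clusters(m9, 10)), 0)
  expect_equal(sum(filter_clusters(m9, 9)), 9)

  # corner contact: one component under 26-connectivity, two under 6
  corner <- array(FALSE, c(3, 3, 3))
  corner[1, 1, 1] <- TRUE
  corner[2, 2, 2] <- TRUE
  expect_length(label_clusters(corner, 26)$sizes, 1)
  expect_length(label_clusters(corner, 18)$sizes, 2)
  expect_length(label_clusters(corner, 6)$sizes, 2)

  # monotone in the threshold
  set.seed(3)
  rnd <- array(runif(6 * 6 * 6) < 0.4, c(6, 6, 6))
  prev <- filter_clusters(rnd, 1)
  for (k in c(2, 5, 9, 20)) {
    cur <- filter_clusters(rnd, k)
    expect_true(all(prev | !cur))   # raising the threshold never adds voxels
    prev <- cur
  }
})

test_that("group significance mask finds elevated blocks and returns empty under the null", {
  dims <- c(8, 8, 4)
  set.seed(21)
  null_mean <- array(0.01, dims)
  blk <- array(FALSE, dims)
  blk[2:4, 2:5, 2:3] <- TRUE     # 24 voxels
  maps <- lapply(1:15, function(j) {
    m <- array(rnorm(prod(dims), mean = 0.01, sd = 0.005), dims)
    m[blk] <- m[blk] + 0.05
    m
  })
  sig <- significance_mask_for_group(maps, null_mean, q = 0.05,
                                     min_cluster_size = 10)
  expect_true(all(sig$mask[blk]))
  expect_lt(mean(sig$mask[!blk]), 0.05)

  null_maps <- lapply(1:15, function(j) array(rnorm(prod(dims), 0.01, 0.005), dims))
  sig0 <- significance_mask_for_group(null_maps, null_mean, q = 0.05)
  expect_lt(sum(sig0$mask), 10)

  # fisher variant flags uniformly small subject p-values
  pmaps <- lapply(1:10, function(j) {
    pm <- array(runif(prod(dims)), dims)
    pm[blk] <- pm[blk] / 500
    pm
  })
  sigf <- significance_mask_for_group(subject_maps = maps, q = 0.05,
                                      method = "fisher", subject_p_maps = pmaps)
  expect_true(all(sigf$mask[blk]))
})

test_that("two-sample t maps are antisymmetric, match t.test, and flag degenerate voxels", {
  dims <- c(4, 4, 2)
  set.seed(31)
  A <- lapply(1:6, function(j) array(rnorm(prod(dims)), dims))
  B <- lapply(1:5, function(j) array(rnorm(prod(dims)), dims))
  mask <- array(TRUE, dims)
  ab <- two_sample_t_map(A, B, mask)
  ba <- two_sample_t_map(B, A, mask)
  expect_equal(ab$t_values, -ba$t_values)
  expect_equal(ab$p_values, ba$p_values)

  # agreement with stats::t.test at a handful of voxels
  for (v in c(1, 9, 20, 32)) {
    av <- vapply(A, `[`, numeric(1), v)
    bv <- vapply(B, `[`, numeric(1), v)
    tt <- t.test(av, bv, var.equal = TRUE)
    expect_equal(ab$t_values[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(ab$p_values[v], tt$p.value, tolerance = 1e-10)
  }

  # welch variant
  abw <- two_sample_t_map(A, B, mask, var_equal = FALSE)
  ttw <- t.test(vapply(A, `[`, numeric(1), 5), vapply(B, `[`, numeric(1), 5))
  expect_equal(abw$t_values[5], unname(ttw$statistic), tolerance = 1e-10)

  # zero-variance voxel -> flagged missing
  A0 <- lapply(A, function(m) { m[1] <- 1; m })
  B0 <- lapply(B, function(m) { m[1] <- 1; m })
  ab0 <- two_sample_t_map(A0, B0, mask)
  expect_true(is.na(ab0$t_values[1]))
})

test_that("planted map-level group difference is detected with FDR and clusters", {
  # power check at the map level: block shifted by one pooled-sd unit scaled
  # for a population two-sample t of about 4 at n = 22/21
  dims <- c(12, 12, 6)
  blk <- array(FALSE, dims)
  blk[4:7, 4:7, 2:4] <- TRUE   # 48 voxels
  n1 <- 22; n2 <- 21
  delta <- 4 * sqrt(1 / n1 + 1 / n2)   # population t = 4 at unit voxel sd
  hits <- vapply(1:20, function(rep) {
    set.seed(4000 + rep)
    A <- lapply(seq_len(n1), function(j) {
      m <- array(rnorm(prod(dims)), dims)
      m[blk] <- m[blk] + delta
      m
    })
    B <- lapply(seq_len(n2), function(j) array(rnorm(prod(dims)), dims))
    ct <- two_sample_t_map(A, B, array(TRUE, dims), q = 0.05)
    cl <- extract_clusters(ct, 10, 26)
    any(vapply(cl, function(x) x$direction == "increased" &&
                 length(intersect(x$voxels, which(blk))) > 0, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null cohorts keep the empirical FDR of the contrast map controlled", {
  dims <- c(10, 10, 4)
  mask <- array(TRUE, dims)
  any_rej <- vapply(1:50, function(r) {
    set.seed(600 + r)
    maps <- lapply(1:43, function(j) array(rnorm(prod(dims)), dims))
    ct <- two_sample_t_map(maps[1:22], maps[23:43], mask, q = 0.05)
    sum(ct$significance_mask) > 0
  }, logical(1))
  # every rejection is false under the null, so FDR = P(any rejection)
  expect_lte(mean(any_rej), 0.10)
})

test_that("cluster correlations recover exact, null and degenerate relations", {
  dims <- c(4, 4, 2)
  vox <- 1:5
  means <- c(-1, 0, 1, 0.5, -0.5, 0.2, 0.9, -0.3, 0.1, 0.4)
  maps <- lapply(means, function(m) array(m, dims))
  rec <- data.frame(group = rep(c("SAD", "HC"), each = 5),
                    score = 2 * means + 1)
  cc <- cluster_correlation(vox, maps, rec, "score")
  expect_equal(cc$r[cc$group == "SAD"], 1, tolerance = 1e-10)
  expect_equal(cc$r[cc$group == "HC"], 1, tolerance = 1e-10)

  rec$neg <- -3 * means + 2
  ccn <- cluster_correlation(vox, maps, rec, "neg")
  expect_equal(ccn$r, c(-1, -1), tolerance = 1e-10)

  # orthogonal contrast: means (-1, 0, 1) vs scores (1, -2, 1)
  maps3 <- lapply(c(-1, 0, 1), function(m) array(m, dims))
  rec3 <- data.frame(group = "SAD", score = c(1, -2, 1))
  cc3 <- cluster_correlation(vox, maps3, rec3, "score")
  expect_equal(cc3$r, 0, tolerance = 1e-12)

  # zero-variance score -> undefined
  rec0 <- data.frame(group = "SAD", score = rep(4, 10))
  cc0 <- cluster_correlation(vox, maps, rec0, "score")
  expect_true(is.na(cc0$r))
})
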