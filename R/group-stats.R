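#' Voxel-wise group mean of influence maps
#'
#' @param maps list of 3D arrays (one per subject, congruent grids); `NA`
#'   marks flagged/degenerate voxels and is ignored.
#' @return list: `mean` (3D array; `NA` where no subject contributes),
#'   `coverage` (3D integer array of contributing subject counts).
#' @export
group_mean_map <- function(maps) {
  stopifnot(length(maps) >= 2)
  dims <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), dims)) stop("influence map grids are not congruent")
  }
  stack <- matrix(unlist(maps), nrow = prod(dims))
  ok <- !is.na(stack)
  coverage <- rowSums(ok)
  sums <- rowSums(stack, na.rm = TRUE)
  mean_map <- ifelse(coverage > 0, sums / coverage, NA_real_)
  list(mean = array(mean_map, dims), coverage = array(coverage, dims))
}

#' Benjamini-Hochberg step-up threshold
#'
#' Sorts the p-values ascending and finds the largest rank `i` with
#' `p_(i) <= i * q / m`; the cutoff is that `p_(i)` (0 when no rank
#' qualifies) and every p-value at or below the cutoff is rejected.
#'
#' @param p_values numeric vector in \[0, 1\] (NA entries are not allowed).
#' @param q target false discovery rate, in (0, 1).
#' @return list: `cutoff` (p-value threshold), `reject` (logical vector
#'   aligned with the input).
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector")
  stopifnot(all(is.finite(p_values)), all(p_values >= 0 & p_values <= 1),
            q > 0, q < 1)
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok)) {
    cutoff <- ps[max(ok)]
    reject <- p_values <= cutoff
  } else {
    cutoff <- 0
    reject <- rep(FALSE, m)
  }
  list(cutoff = cutoff, reject = reject)
}

#' Group significance mask from subject influence maps
#'
#' Combines subject-level evidence that the influence measure exceeds its
#' permutation null into one group map, applies Benjamini-Hochberg FDR at
#' `q`, and removes connected components smaller than `min_cluster_size`.
#'
#' Two combination rules are available:
#' \describe{
#'   \item{`"t_vs_null"`}{per-voxel one-sample t of the subjects' influence
#'     values against that voxel's permutation null mean (`null_mean`), with
#'     a one-sided (greater) p-value;}
#'   \item{`"fisher"`}{Fisher's combination of per-subject permutation
#'     p-values (`subject_p_maps`), referred to a chi-square with 2k df.}
#' }
#'
#' @param subject_maps list of 3D influence arrays (one per subject).
#' @param null_mean 3D array (or scalar) of permutation null means; required
#'   for `method = "t_vs_null"`.
#' @param q FDR level.
#' @param min_cluster_size minimum surviving component size (voxels).
#' @param connectivity cluster connectivity (6/18/26).
#' @param method combination rule, see above.
#' @param subject_p_maps list of 3D permutation p-value arrays; required for
#'   `method = "fisher"`.
#' @return list: `mask` (logical 3D array), `p_map` (3D array of combined
#'   p-values), `fdr_cutoff`.
#' @export
significance_mask_for_group <- function(subject_maps, null_mean = NULL,
                                        q = 0.05, min_cluster_size = 10,
                                        connectivity = 26,
                                        method = c("t_vs_null", "fisher"),
                                        subject_p_maps = NULL) {
  method <- match.arg(method)
  dims <- dim(subject_maps[[1]])
  n <- length(subject_maps)
  stack <- array(unlist(subject_maps), dim = c(prod(dims), n))
  p_map <- rep(NA_real_, prod(dims))
  if (method == "t_vs_null") {
    if (is.null(null_mean)) stop("method 't_vs_null' requires null_mean")
    mu0 <- if (length(null_mean) == 1) rep(null_mean, prod(dims)) else c(null_mean)
    counts <- rowSums(!is.na(stack))
    means <- rowMeans(stack, na.rm = TRUE)
    sds <- sqrt(rowSums((stack - means)^2, na.rm = TRUE) / pmax(counts - 1, 1))
    ok <- counts >= 2 & !is.na(mu0) & sds > 0
    tt <- (means[ok] - mu0[ok]) / (sds[ok] / sqrt(counts[ok]))
    p_map[ok] <- stats::pt(tt, df = counts[ok] - 1, lower.tail = FALSE)
  } else {
    if (is.null(subject_p_maps)) stop("method 'fisher' requires subject_p_maps")
    pstack <- array(unlist(subject_p_maps), dim = c(prod(dims), n))
    counts <- rowSums(!is.na(pstack))
    ok <- counts >= 1
    xf <- -2 * rowSums(log(pstack), na.rm = TRUE)
    p_map[ok] <- stats::pchisq(xf[ok], df = 2 * counts[ok], lower.tail = FALSE)
  }
  in_test <- which(!is.na(p_map))
  if (!length(in_test)) {
    return(list(mask = array(FALSE, dims), p_map = array(p_map, dims),
                fdr_cutoff = 0))
  }
  fdr <- fdr_threshold(p_map[in_test], q)
  raw <- array(FALSE, dims)
  raw[in_test[fdr$reject]] <- TRUE
  list(mask = filter_clusters(raw, min_cluster_size, connectivity),
       p_map = array(p_map, dims),
       fdr_cutoff = fdr$cutoff)
}

#' Voxel-wise two-sample t contrast between groups
#'
#' Pooled-variance (Student) two-tailed two-sample t at every voxel of the
#' analysis mask, with `n1 + n2 - 2` degrees of freedom, Benjamini-Hochberg
#' FDR over in-mask voxels, and a signed significance direction
#' (increased = group A > group B). Welch's unequal-variance t is available
#' behind `var_equal = FALSE`. Subjects with `NA` at a voxel are dropped
#' listwise for that voxel; zero-pooled-variance voxels are flagged missing.
#'
#' @param maps_a,maps_b lists of 3D arrays (subjects of each group).
#' @param analysis_mask logical 3D array restricting the test.
#' @param q FDR level.
#' @param var_equal pooled-variance t when `TRUE` (default), Welch otherwise.
#' @return object of class `group_stat_map`: list with `t_values`,
#'   `p_values` (3D arrays), `fdr_cutoff`, `significance_mask`,
#'   `direction` (3D: +1 increased, -1 decreased, 0), `analysis_mask`.
#' @export
two_sample_t_map <- function(maps_a, maps_b, analysis_mask, q = 0.05,
                             var_equal = TRUE) {
  stopifnot(length(maps_a) >= 2, length(maps_b) >= 2)
  dims <- dim(maps_a[[1]])
  stopifnot(identical(dim(analysis_mask), dims))
  A <- array(unlist(maps_a), dim = c(prod(dims), length(maps_a)))
  B <- array(unlist(maps_b), dim = c(prod(dims), length(maps_b)))
  idx <- which(analysis_mask)
  A <- A[idx, , drop = FALSE]
  B <- B[idx, , drop = FALSE]
  n1 <- rowSums(!is.na(A))
  n2 <- rowSums(!is.na(B))
  m1 <- rowMeans(A, na.rm = TRUE)
  m2 <- rowMeans(B, na.rm = TRUE)
  v1 <- rowSums((A - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((B - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  tt <- pp <- rep(NA_real_, length(idx))
  valid <- n1 >= 2 & n2 >= 2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  valid <- valid & se > 0
  tt[valid] <- (m1[valid] - m2[valid]) / se[valid]
  pp[valid] <- 2 * stats::pt(abs(tt[valid]), df = df[valid], lower.tail = FALSE)

  t_map <- p_map <- array(NA_real_, dims)
  t_map[idx] <- tt
  p_map[idx] <- pp
  tested <- idx[valid]
  if (length(tested)) {
    fdr <- fdr_threshold(p_map[tested], q)
    cutoff <- fdr$cutoff
    sig <- array(FALSE, dims)
    sig[tested[fdr$reject]] <- TRUE
  } else {
    cutoff <- 0
    sig <- array(FALSE, dims)
  }
  direction <- array(0L, dims)
  direction[sig & t_map > 0] <- 1L
  direction[sig & t_map < 0] <- -1L
  structure(list(t_values = t_map, p_values = p_map, fdr_cutoff = cutoff,
                 significance_mask = sig, direction = direction,
                 analysis_mask = analysis_mask, q = q,
                 var_equal = var_equal),
            class = "group_stat_map")
}

#' Extract signed clusters from a group contrast map
#'
#' Splits the FDR-surviving voxels of a [two_sample_t_map()] result by sign
#' and labels connected components, keeping those at or above
#' `min_cluster_size`.
#'
#' @param stat_map a `group_stat_map`.
#' @param min_cluster_size minimum component extent (voxels).
#' @param connectivity 6/18/26.
#' @return list of clusters; each has `voxels` (linear indices), `size`,
#'   `direction` (`"increased"`/`"decreased"`), `peak_voxel` (linear index of
#'   max |t|), `peak_t`.
#' @export
extract_clusters <- function(stat_map, min_cluster_size = 10, connectivity = 26) {
  stopifnot(inherits(stat_map, "group_stat_map"))
  out <- list()
  for (sgn in c(1L, -1L)) {
    mask <- stat_map$direction == sgn
    if (!any(mask)) next
    lab <- label_clusters(mask, connectivity)
    for (k in seq_along(lab$sizes)) {
      if (lab$sizes[k] < min_cluster_size) next
      vox <- which(lab$labels == k)
      pk <- vox[which.max(abs(stat_map$t_values[vox]))]
      out[[length(out) + 1]] <- list(
        voxels = vox, size = lab$sizes[k],
        direction = if (sgn > 0) "increased" else "decreased",
        peak_voxel = pk, peak_t = stat_map$t_values[pk])
    }
  }
  out
}

#' Cluster-mean influence versus clinical score
#'
#' For each subject, averages the influence map over the cluster's voxels
#' (ignoring flagged `NA` voxels), then computes the Pearson correlation with
#' the chosen clinical score, separately per group, with the two-tailed
#' p-value of `cor.test`. Significance is flagged at p < 0.05, uncorrected.
#'
#' @param cluster_voxels linear voxel indices of the cluster (non-empty).
#' @param subject_maps named-by-nothing list of 3D arrays ordered as
#'   `records` rows.
#' @param records data frame with at least `group` and the score column.
#' @param score clinical column name (e.g. `"lsas_avoidance"`).
#' @param per_group compute separately for each group level (default) or
#'   pooled.
#' @return data frame: group, n, r, p, significant.
#' @export
cluster_correlation <- function(cluster_voxels, subject_maps, records,
                                score, per_group = TRUE) {
  stopifnot(length(cluster_voxels) >= 1,
            length(subject_maps) == nrow(records),
            score %in% names(records))
  means <- vapply(subject_maps, function(m) {
    mean(m[cluster_voxels], na.rm = TRUE)
  }, numeric(1))
  scores <- records[[score]]
  groups <- if (per_group) unique(records$group) else "all"
  rows <- lapply(groups, function(g) {
    sel <- if (identical(g, "all")) rep(TRUE, nrow(records)) else records$group == g
    x <- means[sel]
    y <- scores[sel]
    if (stats::sd(y) == 0 || stats::sd(x) == 0 || sum(sel) < 3) {
      return(data.frame(group = g, n = sum(sel), r = NA_real_, p = NA_real_,
                        significant = NA))
    }
    ct <- stats::cor.test(x, y)
    data.frame(group = g, n = sum(sel), r = unname(ct$estimate),
               p = ct$p.value, significant = ct$p.value < 0.05)
  })
  do.call(rbind, rows)
}
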