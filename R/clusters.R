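#' Label connected components in a 3D binary mask
#'
#' Flood-fill labeling under 6-, 18- or 26-neighborhood connectivity
#' (face, face+edge, face+edge+corner adjacency).
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list: `labels` (integer 3D array, 0 = background), `sizes`
#'   (integer vector, one entry per component).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 18, 26))
  dims <- dim(mask)
  offsets <- neighbor_offsets(connectivity)
  labels <- array(0L, dim = dims)
  idx_all <- which(mask)
  sizes <- integer(0)
  current <- 0L
  for (start in idx_all) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    size <- 0L
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      co <- arrayInd(v, dims)
      nb <- sweep(offsets, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- current
        queue <- c(queue, lin)
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = labels, sizes = sizes)
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  colnames(g) <- NULL
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  matrix(as.integer(g[keep, ]), ncol = 3)
}

#' Remove connected components smaller than a minimum extent
#'
#' @param mask logical 3D array.
#' @param min_cluster_size minimum voxel count a component must reach.
#' @param connectivity 6, 18 or 26.
#' @return logical 3D array with small components removed. Monotone in
#'   `min_cluster_size`: raising it never adds voxels.
#' @export
filter_clusters <- function(mask, min_cluster_size = 10, connectivity = 26) {
  lab <- label_clusters(mask, connectivity)
  keep <- which(lab$sizes >= min_cluster_size)
  array(lab$labels %in% keep & mask, dim = dim(mask))
}
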