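#' Quantize tumor SUVs to discrete gray levels
#'
#' Equal-width min-max quantization within the tumor mask, the convention
#' used by co-occurrence texture analysis: bin edges span the SUV range
#' observed inside the mask, the top bin is right-closed so the maximum
#' voxel is assigned level `n_bins`. Because binning is relative to the
#' within-mask range, all derived texture features are invariant under
#' monotone affine rescaling of SUV.
#'
#' @param volume a [suv_volume()].
#' @param seg segmentation whose logical `mask` selects tumor voxels.
#' @param n_bins number of gray levels (default 64).
#' @return An object of class `quantized_tumor`: `levels` (integer array,
#'   `NA` outside the mask), `n_bins`, `bin_edges`, `mask` and `degenerate`
#'   (TRUE when the tumor is constant and all voxels fall in level 1).
#' @export
quantize <- function(volume, seg, n_bins = 64L) {
  stopifnot(inherits(volume, "suv_volume"))
  mask <- as_array3d(seg$mask)
  stop_if(!any(mask), "empty mask")
  stop_if(!is_count(n_bins) || n_bins < 2, "n_bins must be an integer >= 2")
  v <- volume$values[mask]
  lo <- min(v); hi <- max(v)
  levels <- array(NA_integer_, dim(mask))
  if (hi == lo) {
    levels[mask] <- 1L
    return(structure(list(levels = levels, n_bins = as.integer(n_bins),
                          bin_edges = c(lo, hi), mask = mask, degenerate = TRUE),
                     class = "quantized_tumor"))
  }
  w <- (hi - lo) / n_bins
  lev <- pmin(floor((v - lo) / w) + 1L, n_bins)
  levels[mask] <- as.integer(lev)
  structure(list(levels = levels, n_bins = as.integer(n_bins),
                 bin_edges = lo + w * (0:n_bins), mask = mask, degenerate = FALSE),
            class = "quantized_tumor")
}

#' Normalized gray-level co-occurrence matrix (3-D)
#'
#' Accumulates co-occurrence counts of quantized gray levels over all 13
#' unique 3-D direction vectors at a given voxel distance, in both orderings
#' (so the matrix is symmetric), skipping pairs where either voxel lies
#' outside the tumor mask, and normalizes the counts to sum to one.
#'
#' @param q a [quantize()] result.
#' @param distance voxel distance of the co-occurrence offset (default 1).
#' @return An object of class `nglcm_matrix`: `p` (n_bins x n_bins),
#'   `n_pairs` (ordered pair count), `n_directions`, `distance_voxels`.
#' @export
nglcm <- function(q, distance = 1L) {
  stopifnot(inherits(q, "quantized_tumor"))
  nb <- q$n_bins
  counts <- matrix(0, nb, nb)
  total <- 0L
  for (r in seq_len(nrow(DIRECTIONS_13))) {
    off <- DIRECTIONS_13[r, ] * distance
    pr <- shifted_pairs(q$levels, off)
    keep <- !is.na(pr$a) & !is.na(pr$b)
    if (!any(keep)) next
    a <- pr$a[keep]; b <- pr$b[keep]
    # both orderings -> symmetric matrix
    idx <- c((b - 1L) * nb + a, (a - 1L) * nb + b)
    tab <- tabulate(idx, nbins = nb * nb)
    counts <- counts + matrix(tab, nb, nb)
    total <- total + 2L * length(a)
  }
  stop_if(total == 0L, "no valid voxel pairs: mask has no interior neighbors at this distance")
  structure(list(p = counts / total, n_pairs = total,
                 n_directions = 26L, distance_voxels = as.integer(distance)),
            class = "nglcm_matrix")
}

#' Second-order (co-occurrence) texture features
#'
#' The five gray-level co-occurrence features used for PET heterogeneity:
#' uniformity (angular second moment), entropy in bits, dissimilarity,
#' homogeneity and inverse difference moment,
#' \deqn{\mathrm{uniformity}=\sum p^2,\;
#'       \mathrm{entropy}=-\sum p\log_2 p,\;
#'       \mathrm{dissimilarity}=\sum p\,|i-j|,}
#' \deqn{\mathrm{homogeneity}=\sum \frac{p}{1+|i-j|},\;
#'       \mathrm{IDM}=\sum \frac{p}{1+(i-j)^2}.}
#'
#' @param m an [nglcm()] result.
#' @return Named list with `uniformity`, `entropy_bits`, `dissimilarity`,
#'   `homogeneity`, `inverse_difference_moment`.
#' @export
nglcm_features <- function(m) {
  stopifnot(inherits(m, "nglcm_matrix"))
  p <- m$p
  nb <- nrow(p)
  i <- row(p); j <- col(p)
  nz <- p > 0
  list(
    uniformity = sum(p^2),
    entropy_bits = -sum(p[nz] * log2(p[nz])),
    dissimilarity = sum(p * abs(i - j)),
    homogeneity = sum(p / (1 + abs(i - j))),
    inverse_difference_moment = sum(p / (1 + (i - j)^2))
  )
}

#' Neighborhood gray-tone difference matrix (3-D)
#'
#' For every tumor voxel with at least one in-mask neighbor in its
#' 26-neighborhood, the neighborhood mean gray level `A` is computed over
#' the in-mask neighbors (center excluded). The matrix records, per gray
#' level `i`, the total absolute difference `s(i) = sum |i - A|` over
#' contributing voxels at that level, and the occurrence probability `p_i`.
#'
#' @param q a [quantize()] result.
#' @return An object of class `ngtdm_matrix`: `s` (length `n_bins`), `p_i`
#'   (length `n_bins`, sums to 1 over occupied levels), `n_valid_voxels`.
#' @export
ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_tumor"))
  lev <- q$levels
  mask <- q$mask
  d <- dim(lev)
  nb_sum <- array(0, d)
  nb_cnt <- array(0L, d)
  levz <- lev; levz[is.na(levz)] <- 0L
  for (r in seq_len(nrow(OFFSETS_26))) {
    off <- OFFSETS_26[r, ]
    d1 <- dim(lev)
    i1 <- axis_range(d1[1], off[1])
    j1 <- axis_range(d1[2], off[2])
    k1 <- axis_range(d1[3], off[3])
    if (!length(i1) || !length(j1) || !length(k1)) next
    nb_lev <- levz[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE]
    nb_in <- mask[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE]
    nb_sum[i1, j1, k1] <- nb_sum[i1, j1, k1] + as.vector(nb_lev * nb_in)
    nb_cnt[i1, j1, k1] <- nb_cnt[i1, j1, k1] + as.vector(nb_in)
  }
  contributing <- mask & nb_cnt > 0L
  stop_if(!any(contributing), "no voxel has any in-mask neighbor")
  abar <- nb_sum[contributing] / nb_cnt[contributing]
  li <- lev[contributing]
  n <- length(li)
  s <- vapply(seq_len(q$n_bins), function(i) sum(abs(i - abar)[li == i]), numeric(1))
  p_i <- tabulate(li, nbins = q$n_bins) / n
  structure(list(s = s, p_i = p_i, n_valid_voxels = n, n_bins = q$n_bins),
            class = "ngtdm_matrix")
}

#' Higher-order (gray-tone difference) texture features
#'
#' The four Amadasun-King features over occupied gray levels:
#' coarseness `1 / (eps + sum p_i s_i)` with `eps = 1e-6` capping the
#' homogeneous case; contrast, busyness and complexity as
#' \deqn{\mathrm{contrast} = \Big[\tfrac{1}{N_G(N_G-1)}\sum_i\sum_j p_i p_j (i-j)^2\Big]
#'       \Big[\tfrac{1}{n}\sum_i s_i\Big],}
#' \deqn{\mathrm{busyness} = \frac{\sum_i p_i s_i}{\sum_i\sum_{j\ne i} |i\,p_i - j\,p_j|},\;
#'       \mathrm{complexity} = \tfrac{1}{n}\sum_i\sum_{j\neq i} |i-j|
#'         \frac{p_i s_i + p_j s_j}{p_i + p_j},}
#' sums over occupied levels, `n` the number of contributing voxels and
#' `N_G` the number of occupied levels. With a single occupied level
#' contrast and busyness are undefined and returned as flagged `NA`.
#'
#' @param t an [ngtdm()] result.
#' @param eps coarseness guard (default 1e-6).
#' @return Named list with `coarseness`, `contrast`, `busyness`,
#'   `complexity` plus `n_gray_levels` and the `eps` used.
#' @export
ngtdm_features <- function(t, eps = 1e-6) {
  stopifnot(inherits(t, "ngtdm_matrix"))
  occ <- which(t$p_i > 0)
  ng <- length(occ)
  n <- t$n_valid_voxels
  p <- t$p_i[occ]; s <- t$s[occ]; g <- occ
  coarse <- 1 / (eps + sum(p * s))
  if (ng < 2) {
    return(list(coarseness = coarse, contrast = NA_real_, busyness = NA_real_,
                complexity = 0, n_gray_levels = ng, eps = eps))
  }
  dij2 <- outer(g, g, `-`)^2
  pp <- outer(p, p)
  contrast <- sum(pp * dij2) / (ng * (ng - 1)) * sum(s) / n
  den <- sum(abs(outer(g * p, g * p, `-`))[outer(g, g, `!=`)])
  busy <- sum(p * s) / den
  ps <- p * s
  num <- outer(ps, ps, `+`)
  psum <- outer(p, p, `+`)
  offd <- outer(g, g, `!=`)
  complexity <- sum((abs(outer(g, g, `-`)) * num / psum)[offd]) / n
  list(coarseness = coarse, contrast = contrast, busyness = busy,
       complexity = complexity, n_gray_levels = ng, eps = eps)
}

#' All nine PET heterogeneity features of a segmented lesion
#'
#' Convenience wrapper: quantizes the tumor, builds the co-occurrence and
#' gray-tone difference matrices and returns the five second-order plus four
#' higher-order features in one named list.
#'
#' @inheritParams quantize
#' @param distance co-occurrence offset distance in voxels.
#' @return Named list of the nine features plus quantization metadata
#'   (`n_bins`, `degenerate_quantization`).
#' @export
texture_features <- function(volume, seg, n_bins = 64L, distance = 1L) {
  q <- quantize(volume, seg, n_bins)
  f2 <- nglcm_features(nglcm(q, distance))
  f4 <- ngtdm_features(ngtdm(q))
  c(f2, f4[c("coarseness", "contrast", "busyness", "complexity")],
    list(n_bins = q$n_bins, degenerate_quantization = q$degenerate))
}
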