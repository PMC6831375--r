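# Independent brute-force oracles used to validate the vectorized
# implementations. Deliberately written as plain per-voxel loops.

ALL_OFFSETS_26 <- {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# O(N * 26) ordered-pair enumeration of the co-occurrence matrix.
oracle_nglcm <- function(levels, mask, n_bins, distance = 1) {
  d <- dim(mask)
  counts <- matrix(0, n_bins, n_bins)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    for (o in seq_len(nrow(ALL_OFFSETS_26))) {
      nb <- c(x, y, z) + ALL_OFFSETS_26[o, ] * distance
      if (any(nb < 1) || any(nb > d)) next
      if (!mask[nb[1], nb[2], nb[3]]) next
      a <- levels[x, y, z]; b <- levels[nb[1], nb[2], nb[3]]
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

# Per-voxel neighborhood enumeration of the gray-tone difference table.
oracle_ngtdm <- function(levels, mask, n_bins) {
  d <- dim(mask)
  s <- numeric(n_bins); cnt <- integer(n_bins); n <- 0L
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    nbv <- numeric(0)
    for (o in seq_len(nrow(ALL_OFFSETS_26))) {
      nb <- c(x, y, z) + ALL_OFFSETS_26[o, ]
      if (any(nb < 1) || any(nb > d)) next
      if (mask[nb[1], nb[2], nb[3]]) nbv <- c(nbv, levels[nb[1], nb[2], nb[3]])
    }
    if (!length(nbv)) next
    i <- levels[x, y, z]
    s[i] <- s[i] + abs(i - mean(nbv))
    cnt[i] <- cnt[i] + 1L
    n <- n + 1L
  }
  list(s = s, p_i = cnt / n, n = n)
}

# Scalar-formula recomputation of the nine features from the matrices.
oracle_features <- function(p, s, p_i, n) {
  nb <- nrow(p)
  uni <- 0; ent <- 0; dis <- 0; hom <- 0; idm <- 0
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    v <- p[i, j]
    if (v > 0) ent <- ent - v * log2(v)
    uni <- uni + v^2
    dis <- dis + v * abs(i - j)
    hom <- hom + v / (1 + abs(i - j))
    idm <- idm + v / (1 + (i - j)^2)
  }
  occ <- which(p_i > 0)
  ng <- length(occ)
  coarse <- 1 / (1e-6 + sum(p_i[occ] * s[occ]))
  contrast <- busy <- NA_real_
  cplx <- 0
  if (ng > 1) {
    acc <- 0
    for (i in occ) for (j in occ) acc <- acc + p_i[i] * p_i[j] * (i - j)^2
    contrast <- acc / (ng * (ng - 1)) * sum(s[occ]) / n
    den <- 0; num <- 0; cx <- 0
    for (i in occ) for (j in occ) {
      if (i == j) next
      den <- den + abs(i * p_i[i] - j * p_i[j])
      cx <- cx + abs(i - j) * (p_i[i] * s[i] + p_i[j] * s[j]) / (p_i[i] + p_i[j])
    }
    busy <- sum(p_i[occ] * s[occ]) / den
    cplx <- cx / n
  }
  list(uniformity = uni, entropy_bits = ent, dissimilarity = dis,
       homogeneity = hom, inverse_difference_moment = idm,
       coarseness = coarse, contrast = contrast, busyness = busy,
       complexity = cplx)
}

# Stack-based flood fill from a seed voxel (26-connectivity).
oracle_flood_fill <- function(mask, seed_xyz) {
  d <- dim(mask)
  out <- array(FALSE, d)
  stack <- list(seed_xyz)
  out[seed_xyz[1], seed_xyz[2], seed_xyz[3]] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (o in seq_len(nrow(ALL_OFFSETS_26))) {
      nb <- v + ALL_OFFSETS_26[o, ]
      if (any(nb < 1) || any(nb > d)) next
      if (mask[nb[1], nb[2], nb[3]] && !out[nb[1], nb[2], nb[3]]) {
        out[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1L]] <- nb
      }
    }
  }
  out
}

# Quick builders ------------------------------------------------------------

# A random quantized phantom on a full-grid mask (optionally with holes).
random_quantized <- function(dims, n_bins, seed, p_mask = 1) {
  set.seed(seed)
  vol <- suv_volume(array(runif(prod(dims), 2.5, 12), dims), c(2, 2, 2))
  mask <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(mask)) mask[1] <- TRUE
  quantize(vol, list(mask = mask), n_bins)
}

make_volume <- function(values, spacing = c(2, 2, 2)) {
  suv_volume(as_array3d_test(values), spacing)
}

as_array3d_test <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}
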