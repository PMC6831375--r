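# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)

#' @keywords internal
as_array3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stop_if(length(dim(x)) != 3L, "expected a 3-D array (or something coercible to one)")
  x
}

# The 13 unique 3-D direction vectors (half of the 26-neighborhood, one per
# antipodal pair); co-occurrence accumulates both orderings so the full 26
# directions are covered.
DIRECTIONS_13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

# All 26 neighbor offsets.
OFFSETS_26 <- {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Extract the aligned sub-arrays of `arr` for an integer offset, i.e. the
# values at x and at x+off for every x where both fall inside the grid.
# Returns a list(a, b, keep_a_idx) of equal-length vectors.
shifted_pairs <- function(arr, off) {
  d <- dim(arr)
  i1 <- axis_range(d[1], off[1])
  j1 <- axis_range(d[2], off[2])
  k1 <- axis_range(d[3], off[3])
  if (!length(i1) || !length(j1) || !length(k1)) {
    return(list(a = arr[0], b = arr[0]))
  }
  list(
    a = arr[i1, j1, k1, drop = FALSE],
    b = arr[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE]
  )
}

# Valid start indices along one axis for a shift by `off` (empty when the
# shift exceeds the axis).
axis_range <- function(n, off) {
  lo <- max(1L, 1L - off); hi <- min(n, n - off)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

# Separable Gaussian smoothing of a 3-D array; sigma_vox is per-axis in
# voxels. Edge-normalized (convolution of a constant field returns it).
gauss_smooth3d <- function(a, sigma_vox) {
  a <- as_array3d(a)
  sigma_vox <- rep_len(sigma_vox, 3L)
  ones <- array(1, dim(a))
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
    ones <- conv_axis(ones, k, ax)
  }
  a / ones
}

# 1-D convolution of a 3-D array along one axis with zero padding.
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = dim(ap)[1])
  n <- nrow(m)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, n, ncol(m))
  for (s in -r:r) {
    rows_dst <- seq.int(max(1L, 1L + s), min(n, n + s))
    rows_src <- rows_dst - s
    out[rows_dst, ] <- out[rows_dst, ] + k[s + r + 1L] * m[rows_src, ]
  }
  ap <- array(out, dim(ap))
  aperm(ap, order(perm))
}

# Label 26-connected components of a logical 3-D mask (breadth-first search).
# Returns an integer array of labels, 0 outside the mask.
label_components <- function(mask) {
  mask <- as_array3d(mask)
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  nxy <- d[1] * d[2]
  cur <- 0L
  for (seed in idx) {
    if (labels[seed] > 0L) next
    cur <- cur + 1L
    queue <- integer(length(idx))
    queue[1L] <- seed
    labels[seed] <- cur
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      v0 <- v - 1L
      x <- v0 %% d[1] + 1L
      y <- (v0 %/% d[1]) %% d[2] + 1L
      z <- v0 %/% nxy + 1L
      nx <- x + OFFSETS_26[, 1]; ny <- y + OFFSETS_26[, 2]; nz <- z + OFFSETS_26[, 3]
      ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
      nb <- (nz[ok] - 1L) * nxy + (ny[ok] - 1L) * d[1] + nx[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- cur
        queue[tail + seq_along(nb)] <- nb
        tail <- tail + length(nb)
      }
    }
  }
  labels
}

# Derive a stream-specific 32-bit seed from a base seed without collisions
# across streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 97L + as.integer(stream) * 7919L) %% 2147483647L
}
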