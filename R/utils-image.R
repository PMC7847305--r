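# Low-level volume utilities shared by the simulator and the contact pipeline.
# Volumes are plain 3D numeric arrays indexed [x, y, z]; physical coordinates
# are voxel-centre based, 0-based: the centre of voxel (i, j, k) sits at
# ((i - 1) * voxel_xy, (j - 1) * voxel_xy, (k - 1) * voxel_z) in micrometres.

# Shift an array along one dimension by `by` voxels, zero-filling the border.
shift_array <- function(a, dim, by) {
  if (by == 0L) return(a)
  d <- base::dim(a)
  out <- array(0, d)
  n <- d[dim]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  idx_src <- vector("list", 3)
  idx_dst <- vector("list", 3)
  for (k in 1:3) {
    idx_src[[k]] <- seq_len(d[k])
    idx_dst[[k]] <- seq_len(d[k])
  }
  idx_src[[dim]] <- src
  idx_dst[[dim]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Separable Gaussian blur of a 3D array. Sigmas are in voxels per dimension;
# a sigma of 0 skips that dimension. Kernels are truncated at 3 sigma and
# renormalized, so total intensity is conserved away from the borders.
gaussian_blur3d <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3, length(sigma) == 3)
  for (d in 1:3) {
    s <- sigma[d]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_array(a, d, j - r - 1L)
    }
    a <- acc
  }
  a
}

# Trilinear interpolation of volume `a` at physical points (n x 3 matrix, um).
# Points outside the volume return NA.
interp_trilinear <- function(a, pts, voxel_xy, voxel_z) {
  d <- dim(a)
  # to 0-based continuous voxel coordinates
  u <- cbind(pts[, 1] / voxel_xy, pts[, 2] / voxel_xy, pts[, 3] / voxel_z)
  i0 <- floor(u)
  f <- u - i0
  ok <- i0[, 1] >= 0 & i0[, 1] <= d[1] - 2 &
        i0[, 2] >= 0 & i0[, 2] <= d[2] - 2 &
        i0[, 3] >= 0 & i0[, 3] <= d[3] - 2
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1L  # back to 1-based array index
  f <- f[ok, , drop = FALSE]
  at <- function(dx, dy, dz) {
    a[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  v <- at(0L, 0L, 0L) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
       at(1L, 0L, 0L) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
       at(0L, 1L, 0L) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
       at(1L, 1L, 0L) * f[, 1] * f[, 2] * (1 - f[, 3]) +
       at(0L, 0L, 1L) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
       at(1L, 0L, 1L) * f[, 1] * (1 - f[, 2]) * f[, 3] +
       at(0L, 1L, 1L) * (1 - f[, 1]) * f[, 2] * f[, 3] +
       at(1L, 1L, 1L) * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- v
  out
}

# Label 6-connected components of a logical 3D mask. Returns an integer array
# of the same shape (0 = background). Component graph built from voxel index
# arithmetic and solved with igraph; suitable for the sparse foregrounds the
# pipeline works with.
label_components3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  ai <- arrayInd(fg, d)
  # linear index lookup for foreground voxels
  pos <- integer(prod(d))
  pos[fg] <- seq_along(fg)
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  for (dim_i in 1:3) {
    keep <- ai[, dim_i] < d[dim_i]
    nb <- fg[keep] + strides[dim_i]
    nb_fg <- pos[nb] > 0L
    if (any(nb_fg)) {
      edges[[length(edges) + 1L]] <-
        cbind(pos[fg[keep]][nb_fg], pos[nb[nb_fg]])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# Global Otsu threshold of a numeric array (wraps EBImage; EBImage expects
# [0, 1]). The volume is flattened to a single frame first: EBImage computes
# one threshold per frame of a 3D image, and per-plane thresholds collapse to
# the noise level on planes that contain no signal.
otsu_threshold <- function(a) {
  rng <- range(a)
  if (rng[2] <= rng[1]) return(rng[1])
  x <- (as.numeric(a) - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(x, dim = c(length(x), 1L)),
                      range = c(0, 1), levels = 256)
  rng[1] + th * (rng[2] - rng[1])
}
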