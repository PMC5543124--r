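# Internal array helpers shared by the imaging modules.

# Separable Gaussian smoothing of a 3D array with reflected boundaries.
# `sigma_vox` is in voxels; sigma = 0 returns the input unchanged.
gauss_smooth3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  m <- max(1L, ceiling(3.5 * sigma_vox))
  x <- (-m):m
  w <- exp(-x^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  for (a in 1:3) arr <- conv_along(arr, w, a)
  arr
}

# Convolve along axis `a` with kernel `w` (odd length), reflecting at edges.
conv_along <- function(arr, w, a) {
  d <- dim(arr)
  m <- (length(w) - 1L) / 2L
  n <- d[a]
  # reflected index lookup (mirror without repeating the edge sample when
  # possible; falls back to clamping for very short axes)
  refl <- function(i) {
    if (n == 1L) return(rep(1L, length(i)))
    i <- abs(i - 1L) + 1L
    over <- i > n
    i[over] <- 2L * n - i[over]
    pmin(pmax(i, 1L), n)
  }
  perm <- c(a, setdiff(1:3, a))
  ap <- aperm(arr, perm)
  mat <- matrix(ap, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(mat))
  for (t in seq_along(w)) {
    k <- t - m - 1L
    out <- out + w[t] * mat[refl(seq_len(n) + k), , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

# Central-difference gradient along axis `a` (one-sided at the edges),
# in intensity units per voxel.
diff_along <- function(arr, a) {
  d <- dim(arr)
  n <- d[a]
  perm <- c(a, setdiff(1:3, a))
  ap <- aperm(arr, perm)
  mat <- matrix(ap, nrow = n)
  out <- matrix(0, n, ncol(mat))
  if (n > 2) out[2:(n - 1), ] <- (mat[3:n, ] - mat[1:(n - 2), ]) / 2
  if (n > 1) {
    out[1, ] <- mat[2, ] - mat[1, ]
    out[n, ] <- mat[n, ] - mat[n - 1, ]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

# World-coordinate grids (mm) for every voxel of a volume; returns a list of
# three arrays (x, y, z).
coord_grids <- function(shape, pitch_um, origin_mm = c(0, 0, 0)) {
  h <- pitch_um / 1000
  ax <- lapply(1:3, function(a) origin_mm[a] + (seq_len(shape[a]) - 1) * h)
  list(
    x = array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}

# Mark voxels within `radius_mm` of the segment p0-p1 (world mm) in a logical
# array; returns the linear indices touched. Optionally writes the segment
# direction into a fiber array.
voxelize_capsule <- function(shape, pitch_um, origin_mm, p0, p1, radius_mm) {
  h <- pitch_um / 1000
  lo <- pmax(floor((pmin(p0, p1) - radius_mm - origin_mm) / h) + 1, 1)
  hi <- pmin(ceiling((pmax(p0, p1) + radius_mm - origin_mm) / h) + 1, shape)
  if (any(lo > hi)) return(integer(0))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  px <- origin_mm[1] + (g$i - 1) * h
  py <- origin_mm[2] + (g$j - 1) * h
  pz <- origin_mm[3] + (g$k - 1) * h
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 < 1e-20) {
    t <- 0
  } else {
    t <- ((px - p0[1]) * d[1] + (py - p0[2]) * d[2] + (pz - p0[3]) * d[3]) / len2
    t <- pmin(pmax(t, 0), 1)
  }
  dx <- px - (p0[1] + t * d[1]); dy <- py - (p0[2] + t * d[2])
  dz <- pz - (p0[3] + t * d[3])
  inside <- dx * dx + dy * dy + dz * dz <= radius_mm^2
  g$i[inside] + shape[1] * (g$j[inside] - 1) +
    shape[1] * shape[2] * (g$k[inside] - 1)
}

# Orthonormal basis completing a unit vector `n` to a right-handed frame.
complete_basis <- function(n) {
  n <- n / sqrt(sum(n^2))
  seed <- diag(3)[, which.min(abs(n))]
  u <- seed - sum(seed * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u, v, n)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return 2|A∩B| / (|A|+|B|), or NA if both masks are empty.
#' @export
dice <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

# 26-connected binary dilation by one voxel.
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst <- src
    for (a in 1:3) {
      s <- c(dx, dy, dz)[a]
      if (s == 1) { src[[a]] <- 1:(d[a] - 1); dst[[a]] <- 2:d[a] }
      if (s == -1) { src[[a]] <- 2:d[a]; dst[[a]] <- 1:(d[a] - 1) }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

# Boundary voxels of a mask: in the mask with a 6-neighbour outside (array
# edges count as outside).
boundary_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (a in 1:3) {
    n <- d[a]
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    for (s in c(-1L, 1L)) {
      nb <- array(FALSE, d)
      src <- idx; dst <- idx
      if (s == 1L) { src[[a]] <- 1:(n - 1); dst[[a]] <- 2:n } else {
        src[[a]] <- 2:n; dst[[a]] <- 1:(n - 1)
      }
      nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
      interior <- interior & nb
    }
  }
  mask & !interior
}
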