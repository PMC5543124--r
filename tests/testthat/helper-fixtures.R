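# Shared fixtures: a scaled-down phantom for fast tissue tests and small
# utilities used across files.

small_heart_spec <- function(seed = 42) {
  phantom_spec(shape = c(36, 36, 56), pitch_um = 250,
               node_semiaxes_mm = c(1.4, 0.5, 0.5), seed = seed)
}

# memoised phantoms (generation is cheap, simulation is not; several files
# reuse the same geometry)
.fixture_env <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixture_env$ph)) .fixture_env$ph <- generate_phantom(phantom_spec())
  .fixture_env$ph
}

small_phantom <- function() {
  if (is.null(.fixture_env$sph))
    .fixture_env$sph <- generate_phantom(small_heart_spec())
  .fixture_env$sph
}

# independent breadth-first flood fill (reference oracle for region growing)
bfs_flood <- function(inband, seed, connectivity = 26) {
  d <- dim(inband)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= c("6" = 1, "18" = 2, "26" = 3)[as.character(connectivity)], ]
  out <- array(FALSE, d)
  out[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, 1)
  while (nrow(frontier)) {
    nxt <- NULL
    for (r in seq_len(nrow(frontier))) {
      nb <- sweep(offs, 2, frontier[r, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        if (inband[nb[q, 1], nb[q, 2], nb[q, 3]] &&
            !out[nb[q, 1], nb[q, 2], nb[q, 3]]) {
          out[nb[q, 1], nb[q, 2], nb[q, 3]] <- TRUE
          nxt <- rbind(nxt, nb[q, , drop = FALSE])
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(0, 0, 3) else nxt
  }
  out
}

# digitize a solid ellipsoid mask (semi-axes in mm) on an isotropic grid
ellipsoid_mask <- function(semi_axes_mm, pitch_um, margin_vox = 3) {
  h <- pitch_um / 1000
  dims <- ceiling(2 * semi_axes_mm / h) + 2 * margin_vox
  centre <- (dims - 1) * h / 2
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) * h - centre[a]) / semi_axes_mm[a])
  outer3 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  outer3 <= 1
}
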