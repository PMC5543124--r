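#' Principal-axis extents of a binary structure
#'
#' Length and width of a segmented structure, operationalized as the ranges
#' of voxel-centre coordinates projected on the mask's principal component
#' axes, plus one voxel pitch for the voxel footprint. The first extent is
#' the length, the second the width.
#'
#' @param mask Logical 3D array (nonempty).
#' @param pitch_um Voxel pitch in micrometres.
#' @return Numeric triple of extents in mm, sorted descending.
#' @export
principal_dimensions <- function(mask, pitch_um) {
  w <- which(mask)
  if (!length(w)) stop("empty mask")
  h <- pitch_um / 1000
  pts <- (arrayInd(w, dim(mask)) - 1) * h
  if (length(w) == 1) return(rep(h, 3))
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  sc <- pts %*% pc$rotation
  ext <- apply(sc, 2, function(v) diff(range(v))) + h
  sort(unname(ext), decreasing = TRUE)
}

#' Minimum surface distance between two structures
#'
#' Euclidean minimum over boundary-voxel centres of the two masks (or given
#' landmark points), with the realizing point pair. Returns 0 if the masks
#' intersect. Distances are between voxel centres, so the value can differ
#' from the true surface distance by up to one voxel diagonal.
#'
#' @param a,b Logical 3D arrays, or n-by-3 matrices of mm points (landmark
#'   sets).
#' @param pitch_um Voxel pitch (needed when masks are given).
#' @param origin_mm World position of voxel (1,1,1).
#' @return List with `distance_mm`, `point_a`, `point_b` (mm).
#' @export
min_surface_distance <- function(a, b, pitch_um = NULL, origin_mm = c(0, 0, 0)) {
  to_pts <- function(m) {
    if (is.matrix(m) && ncol(m) == 3 && !is.logical(m)) return(m)
    if (!any(m)) stop("empty mask")
    if (is.null(pitch_um)) stop("pitch_um required for mask input")
    bd <- boundary_mask(m)
    sweep((arrayInd(which(bd), dim(m)) - 1) * pitch_um / 1000, 2, origin_mm, "+")
  }
  if (is.array(a) && is.logical(a) && is.array(b) && is.logical(b) &&
      identical(dim(a), dim(b)) && any(a & b)) {
    w <- which(a & b)[1]
    p <- (arrayInd(w, dim(a)) - 1) * pitch_um / 1000 + origin_mm
    return(list(distance_mm = 0, point_a = drop(p), point_b = drop(p)))
  }
  pa <- to_pts(a); pb <- to_pts(b)
  best <- Inf; bi <- 1L; bj <- 1L
  chunk <- max(1L, floor(2e7 / nrow(pb)))
  for (s in seq(1L, nrow(pa), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(pa))
    d2 <- outer(rowSums(pa[rows, , drop = FALSE]^2), rowSums(pb^2), "+") -
      2 * pa[rows, , drop = FALSE] %*% t(pb)
    m <- which.min(d2)
    if (d2[m] < best) {
      best <- d2[m]
      bi <- rows[(m - 1L) %% length(rows) + 1L]
      bj <- (m - 1L) %/% length(rows) + 1L
    }
  }
  list(distance_mm = sqrt(max(best, 0)), point_a = pa[bi, ], point_b = pb[bj, ])
}

#' Morphometry census of a label volume
#'
#' Per label: voxel count, volume in mm^3 (count x pitch^3), connected
#' component count (26-connectivity), and principal-axis extents.
#'
#' @param labels A [cs_labels()].
#' @param connectivity Component connectivity (default 26).
#' @return A data frame with one row per legend entry.
#' @export
component_census <- function(labels, connectivity = 26) {
  leg <- labels$legend
  h <- pitch_mm(labels)
  rows <- lapply(names(leg), function(nm) {
    m <- labels$labels == leg[[nm]]
    n <- sum(m)
    if (n == 0)
      return(data.frame(structure = nm, label = leg[[nm]], voxels = 0L,
                        volume_mm3 = 0, components = 0L,
                        length_mm = NA_real_, width_mm = NA_real_,
                        depth_mm = NA_real_))
    comp <- label_components_cpp(as.vector(m), dim(m), as.integer(connectivity))
    ext <- principal_dimensions(m, labels$pitch_um)
    data.frame(structure = nm, label = leg[[nm]], voxels = n,
               volume_mm3 = n * h^3, components = max(comp),
               length_mm = ext[1], width_mm = ext[2], depth_mm = ext[3])
  })
  do.call(rbind, rows)
}
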