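#' Structure-tensor scales
#'
#' Gaussian scales (micrometres) for the structure tensor: `sigma_gradient`
#' smooths the image before differentiation, `sigma_tensor` averages the
#' gradient outer products over a neighbourhood. Myocyte chains are only a
#' few voxels across at micro-CT pitch, so the defaults are one voxel pitch
#' for the gradient scale and three pitches for the tensor scale.
#'
#' @param sigma_gradient_um,sigma_tensor_um Positive scales in micrometres,
#'   with `sigma_tensor_um >= sigma_gradient_um`.
#' @return A `tensor_scales` list.
#' @export
tensor_scales <- function(sigma_gradient_um, sigma_tensor_um) {
  if (sigma_gradient_um <= 0 || sigma_tensor_um <= 0)
    stop("scales must be positive")
  if (sigma_tensor_um < sigma_gradient_um)
    stop("sigma_tensor_um must be >= sigma_gradient_um")
  structure(list(sigma_gradient_um = sigma_gradient_um,
                 sigma_tensor_um = sigma_tensor_um), class = "tensor_scales")
}

default_scales <- function(pitch_um) tensor_scales(pitch_um, 3 * pitch_um)

#' Compute the 3D structure tensor field
#'
#' Per voxel, J = G_sigma_t * (grad_sigma_g I  (x)  grad_sigma_g I): the
#' image is smoothed at the gradient scale, differentiated by central
#' differences, and the six unique products of gradient components are
#' averaged with a Gaussian at the tensor scale. J is symmetric positive
#' semidefinite by construction (up to round-off).
#'
#' @param volume A [cs_volume()].
#' @param scales A [tensor_scales()]; defaults to (1, 3) voxel pitches.
#' @return List of six arrays `xx, yy, zz, xy, xz, yz` plus the scales.
#' @export
structure_tensor <- function(volume, scales = NULL) {
  if (is.null(scales)) scales <- default_scales(volume$pitch_um)
  if (scales$sigma_gradient_um < volume$pitch_um - 1e-9)
    stop("sigma_gradient_um smaller than one voxel pitch")
  sg <- scales$sigma_gradient_um / volume$pitch_um
  st <- scales$sigma_tensor_um / volume$pitch_um
  d <- dim(volume$data)
  if (any(d < 6 * st))
    stop("volume smaller than 6 x sigma_tensor in at least one axis")
  sm <- gauss_smooth3(volume$data, sg)
  gx <- diff_along(sm, 1); gy <- diff_along(sm, 2); gz <- diff_along(sm, 3)
  list(xx = gauss_smooth3(gx * gx, st), yy = gauss_smooth3(gy * gy, st),
       zz = gauss_smooth3(gz * gz, st), xy = gauss_smooth3(gx * gy, st),
       xz = gauss_smooth3(gx * gz, st), yz = gauss_smooth3(gy * gz, st),
       scales = scales)
}

#' Extract per-voxel fiber orientation by eigen-analysis
#'
#' Image gradients of an elongated texture are perpendicular to it, so the
#' fiber axis at a voxel is the eigenvector of the *smallest* eigenvalue of
#' the gradient structure tensor. Directions are sign-ambiguous and are
#' canonicalised with a nonnegative z component. Coherence is the
#' Westin-style linear measure (l2 - l3) / (l1 + l2 + l3) (eigenvalues
#' descending), clipped to [0, 1]; voxels whose tensor trace falls below
#' `trace_tol` times the field maximum are marked invalid with coherence 0.
#'
#' @param volume A [cs_volume()].
#' @param scales A [tensor_scales()] or NULL for defaults.
#' @param mask Optional logical array: restrict the output to these voxels.
#' @param trace_tol Relative trace threshold for validity.
#' @return An `orientation_field`: list with `direction` (shape x 3 array),
#'   `coherence`, `valid`, and the pitch.
#' @export
extract_orientation <- function(volume, scales = NULL, mask = NULL,
                                trace_tol = 1e-6) {
  J <- structure_tensor(volume, scales)
  d <- dim(volume$data)
  eg <- smallest_eig_cpp(as.vector(J$xx), as.vector(J$yy), as.vector(J$zz),
                         as.vector(J$xy), as.vector(J$xz), as.vector(J$yz))
  ev <- eg$eigenvalues                    # descending per row
  tr <- ev[, 1] + ev[, 2] + ev[, 3]
  coher <- pmin(pmax(ifelse(tr > 0, (ev[, 2] - ev[, 3]) / tr, 0), 0), 1)
  valid <- tr > trace_tol * max(tr, 0)
  if (!is.null(mask)) valid <- valid & as.vector(mask)
  coher[!valid] <- 0
  dir <- array(eg$direction, c(d, 3))
  if (!any(valid))
    warning("orientation field is entirely invalid (flat volume?)")
  structure(list(direction = dir, coherence = array(coher, d),
                 valid = array(valid, d), pitch_um = volume$pitch_um),
            class = "orientation_field")
}

#' Cardiac coordinate frame
#'
#' @param long_axis Unit vector of the heart's long axis (base to apex).
#' @param centre_mm A point on the long axis (mm).
#' @return A `cardiac_frame` list.
#' @export
cardiac_frame <- function(long_axis = c(0, 0, 1), centre_mm = c(0, 0, 0)) {
  n <- sqrt(sum(long_axis^2))
  if (n < 1e-12) stop("long axis must be a nonzero vector")
  structure(list(long_axis = long_axis / n, centre_mm = centre_mm),
            class = "cardiac_frame")
}

#' Map a fiber orientation field to helical angles
#'
#' For every wall voxel a local wall frame is built: the transmural normal
#' comes from the gradient of the (lightly smoothed) distance transform of
#' the wall mask, which also works for non-cylindrical shells; its sign is
#' disambiguated to point outward using the frame's radial direction, and
#' where the transform is degenerate (the mid-wall ridge, where the
#' gradient vanishes) the radial direction itself substitutes for the
#' normal. The circumferential direction is `long_axis x normal` and the
#' longitudinal direction is the long axis projected into the wall-tangent
#' plane. The helix angle is the signed angle in (-90, 90] degrees between
#' the fiber's tangent-plane projection and the circumferential direction,
#' positive toward the longitudinal direction. Sign-ambiguity of the fiber
#' makes the angle well defined modulo 180 degrees, which the mapping to
#' (-90, 90] resolves. The `absolute` variant returns |angle|.
#'
#' Voxels where the radial direction is undefined (on the long axis), where
#' the fiber is orthogonal to the tangent plane, or that are invalid in the
#' input field come back as NA.
#'
#' @param field An `orientation_field` (or a shape x 3 fiber array plus
#'   `valid` passed via `field = list(direction =, valid =, pitch_um =)`).
#' @param frame A [cardiac_frame()].
#' @param wall_mask Logical array of wall voxels.
#' @param absolute Return absolute angles (as used for colour maps).
#' @param origin_mm World position of voxel (1,1,1) (must match the frame).
#' @return Array of helix angles in degrees (NA where undefined).
#' @export
helical_angle_map <- function(field, frame, wall_mask, absolute = FALSE,
                              origin_mm = c(0, 0, 0)) {
  d <- dim(wall_mask)
  h <- field$pitch_um / 1000
  # transmural normal: gradient of the distance into the wall (smoothed so
  # the mid-wall ridge does not produce spurious directions)
  dist_in <- array(edt_cpp(as.vector(!wall_mask), d, 1), d)  # voxels, >0 inside
  dist_in <- gauss_smooth3(dist_in, 1)
  gxa <- diff_along(dist_in, 1); gya <- diff_along(dist_in, 2)
  gza <- diff_along(dist_in, 3)
  w <- which(wall_mask & field$valid)
  np <- prod(d)
  la <- frame$long_axis
  out <- array(NA_real_, d)
  # radial reference: voxel position relative to the long axis
  ijk <- arrayInd(w, d)
  pos <- sweep((ijk - 1) * h, 2, origin_mm, "+")
  rel <- sweep(pos, 2, frame$centre_mm)
  proj <- as.vector(rel %*% la)
  r0 <- rel - proj %o% la
  r0n <- sqrt(rowSums(r0^2))
  on_axis <- r0n < 1e-9
  r0 <- r0 / pmax(r0n, 1e-12)
  nv <- cbind(gxa[w], gya[w], gza[w])
  nn <- sqrt(rowSums(nv^2))
  # the distance gradient points outward in the inner half of the wall and
  # inward in the outer half: flip inward-pointing rows, and fall back to
  # the radial direction where the gradient is degenerate near the ridge
  flip <- rowSums(nv * r0) < 0
  nv[flip, ] <- -nv[flip, ]
  weak <- nn < 0.4
  nv[weak, ] <- r0[weak, ]
  nn[weak] <- 1
  ok <- nn > 1e-9 & !on_axis
  nv <- nv / pmax(nn, 1e-12)
  cx <- la[2] * nv[, 3] - la[3] * nv[, 2]
  cy <- la[3] * nv[, 1] - la[1] * nv[, 3]
  cz <- la[1] * nv[, 2] - la[2] * nv[, 1]
  cn <- sqrt(cx^2 + cy^2 + cz^2)
  ok <- ok & cn > 1e-6            # voxel on the long axis: circumferential undefined
  cx <- cx / pmax(cn, 1e-12); cy <- cy / pmax(cn, 1e-12); cz <- cz / pmax(cn, 1e-12)
  dotln <- la[1] * nv[, 1] + la[2] * nv[, 2] + la[3] * nv[, 3]
  lx <- la[1] - dotln * nv[, 1]; ly <- la[2] - dotln * nv[, 2]
  lz <- la[3] - dotln * nv[, 3]
  ln <- sqrt(lx^2 + ly^2 + lz^2)
  ok <- ok & ln > 1e-6
  lx <- lx / pmax(ln, 1e-12); ly <- ly / pmax(ln, 1e-12); lz <- lz / pmax(ln, 1e-12)
  fx <- field$direction[w]; fy <- field$direction[w + np]
  fz <- field$direction[w + 2 * np]
  fdotn <- fx * nv[, 1] + fy * nv[, 2] + fz * nv[, 3]
  tx <- fx - fdotn * nv[, 1]; ty <- fy - fdotn * nv[, 2]; tz <- fz - fdotn * nv[, 3]
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  ok <- ok & tn > 1e-6            # fiber orthogonal to the tangent plane
  ang <- atan2(tx * lx + ty * ly + tz * lz, tx * cx + ty * cy + tz * cz) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  ang[!ok] <- NA_real_
  out[w] <- if (absolute) abs(ang) else ang
  out
}

#' Transmural helix-angle profile
#'
#' Bins wall voxels by normalized transmural depth (one bin per voxel of
#' wall thickness by default) and averages the helix angle per bin - the
#' transmural profile as plotted in cardiac fiber studies. Bins at the
#' wall surfaces can be excluded, where the tensor window inevitably blends
#' across the boundary.
#'
#' @param angles Helix angle array from [helical_angle_map()].
#' @param depth Normalized transmural depth array (0 = endo, 1 = epi).
#' @param wall_mask Logical wall mask.
#' @param n_bins Number of depth bins.
#' @param exclude_bins Bins dropped at each surface.
#' @return Data frame with `depth` (bin centre), `angle_deg` (mean),
#'   `n` (voxels).
#' @export
helix_profile <- function(angles, depth, wall_mask, n_bins,
                          exclude_bins = 2) {
  sel <- which(wall_mask & !is.na(angles))
  bin <- pmin(pmax(ceiling(depth[sel] * n_bins), 1L), n_bins)
  keep <- bin > exclude_bins & bin <= n_bins - exclude_bins
  b <- bin[keep]
  data.frame(depth = (as.numeric(names(tapply(angles[sel][keep], b, mean))) - 0.5) / n_bins,
             angle_deg = as.numeric(tapply(angles[sel][keep], b, mean)),
             n = as.integer(table(b)))
}
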