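#' Construct a scalar image volume
#'
#' A `cs_volume` wraps a 3D numeric array together with its geometry: an
#' isotropic voxel pitch in micrometres and the world position (mm) of the
#' centre of voxel (1,1,1). Voxel indices are 1-based in R; world coordinates
#' are voxel-centre positions in millimetres. Intensities are in arbitrary
#' units and are never rescaled on read: the attenuation ordering of tissues
#' is relative.
#'
#' @param data 3D numeric array of intensities (finite values).
#' @param pitch_um Isotropic voxel pitch in micrometres (> 0).
#' @param origin_mm World coordinate (mm) of the centre of voxel (1,1,1).
#' @param axis_names Ordered axis names.
#' @return An object of class `cs_volume`.
#' @export
cs_volume <- function(data, pitch_um, origin_mm = c(0, 0, 0),
                      axis_names = c("x", "y", "z")) {
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("`data` must be a 3D array with positive dimensions")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || !is.finite(pitch_um) ||
      pitch_um <= 0)
    stop("`pitch_um` must be a single positive number")
  if (any(!is.finite(data)))
    stop("intensity values must be finite")
  structure(list(data = data, pitch_um = pitch_um,
                 origin_mm = as.numeric(origin_mm),
                 axis_names = axis_names),
            class = "cs_volume")
}

#' Construct a label volume
#'
#' Integer tissue/structure labels on the same grid as a source volume.
#' Label 0 is background and needs no legend entry; every other label that
#' occurs must be named in the legend.
#'
#' @param labels 3D integer array.
#' @param legend Named integer vector mapping structure name to label code.
#' @param pitch_um,origin_mm Geometry, as for [cs_volume()].
#' @return An object of class `cs_labels`.
#' @export
cs_labels <- function(labels, legend, pitch_um, origin_mm = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, legend)
  if (length(missing))
    stop("labels without legend entry: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, legend = legend, pitch_um = pitch_um,
                 origin_mm = as.numeric(origin_mm)),
            class = "cs_labels")
}

#' @export
print.cs_volume <- function(x, ...) {
  cat(sprintf("<cs_volume> %s voxels @ %g um, origin (%s) mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"), x$pitch_um,
              paste(signif(x$origin_mm, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.cs_labels <- function(x, ...) {
  cat(sprintf("<cs_labels> %s voxels @ %g um; %d labelled classes\n",
              paste(dim(x$labels), collapse = "x"), x$pitch_um,
              length(x$legend)))
  invisible(x)
}

vol_data <- function(v) if (inherits(v, "cs_labels")) v$labels else v$data

pitch_mm <- function(v) v$pitch_um / 1000

#' Voxel index to world coordinate
#'
#' Affine map from 1-based voxel indices to world mm (voxel centres).
#'
#' @param volume A `cs_volume` or `cs_labels`.
#' @param ijk Integer triple or n-by-3 matrix of 1-based indices.
#' @return Numeric mm coordinates, same shape as `ijk`.
#' @export
voxel_to_world <- function(volume, ijk) {
  h <- pitch_mm(volume)
  if (is.matrix(ijk))
    sweep((ijk - 1) * h, 2, volume$origin_mm, "+")
  else
    volume$origin_mm + (ijk - 1) * h
}

#' World coordinate to (fractional) voxel index
#' @inheritParams voxel_to_world
#' @param xyz_mm Numeric triple or n-by-3 matrix of world mm positions.
#' @export
world_to_voxel <- function(volume, xyz_mm) {
  h <- pitch_mm(volume)
  if (is.matrix(xyz_mm))
    sweep(xyz_mm, 2, volume$origin_mm, "-") / h + 1
  else
    (xyz_mm - volume$origin_mm) / h + 1
}

#' Read a volume from disk
#'
#' Supports NIfTI-1 (`.nii`/`.nii.gz`, pitch taken from the header) and
#' TIFF (multi-page file or a directory of numbered single-page files;
#' TIFF carries no voxel size, so `pitch_um` must be given). Intensities are
#' read as stored; anisotropic NIfTI voxels are rejected unless
#' `resample_isotropic = TRUE`, which resamples trilinearly to the smallest
#' pitch.
#'
#' @param path File (NIfTI, multi-page TIFF) or directory (TIFF stack).
#' @param format "nifti" or "tiff_stack"; inferred from `path` by default.
#' @param pitch_um Voxel pitch in micrometres; required for TIFF, overrides
#'   the header for NIfTI if given.
#' @param resample_isotropic Resample anisotropic NIfTI input to isotropic
#'   pitch instead of failing.
#' @return A [cs_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff_stack"),
                        pitch_um = NULL, resample_isotropic = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "nifti"
  }
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3] * 1000  # mm -> um
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    if (is.null(pitch_um)) {
      if (max(pd) - min(pd) > 1e-6 * max(pd)) {
        if (!resample_isotropic)
          stop("anisotropic voxel pitch (", paste(signif(pd, 6), collapse = " x "),
               " um); pass resample_isotropic = TRUE or an explicit pitch_um")
        v <- resample_to_isotropic(arr, pd)
        return(cs_volume(v$data, v$pitch_um))
      }
      pitch_um <- pd[1]
    }
    return(cs_volume(arr, pitch_um))
  }
  # TIFF stack
  if (is.null(pitch_um))
    stop("TIFF carries no voxel size: supply pitch_um")
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF files in directory: ", path)
    lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    p <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(p)) p <- list(p)
    p
  }
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[2], d[1], length(pages)))  # rows are y
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  cs_volume(arr, pitch_um)
}

resample_to_isotropic <- function(arr, pd_um) {
  target <- min(pd_um)
  dims <- dim(arr)
  grids <- lapply(1:3, function(a) {
    extent <- (dims[a] - 1) * pd_um[a]
    seq(0, extent, by = target) / pd_um[a] + 1
  })
  pts <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  out <- array(trilinear_sample(arr, pts, fill = 0),
               dim = vapply(grids, length, 1L))
  list(data = out, pitch_um = target)
}

#' Write a volume or label volume to disk
#'
#' NIfTI stores the voxel pitch in the header and round-trips any numeric
#' data. TIFF output is 16-bit unsigned (the native depth of micro-CT
#' reconstructions); values must be integers in \[0, 65535\].
#'
#' @param volume A `cs_volume` or `cs_labels`.
#' @param path Output file (`.nii`, `.nii.gz`, `.tif`) .
#' @param format "nifti" or "tiff_stack"; inferred from extension by default.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "tiff_stack")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff_stack" else "nifti"
  arr <- vol_data(volume)
  if (format == "nifti") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(pitch_mm(volume), 3)
    RNifti::writeNifti(img, path)
  } else {
    if (any(arr != round(arr)) || min(arr) < 0 || max(arr) > 65535)
      stop("TIFF output is 16-bit unsigned: values must be integers in [0, 65535]")
    pages <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Crop a volume to an index box
#'
#' The origin shifts so that world coordinates of retained voxels are
#' unchanged.
#'
#' @param volume A `cs_volume` or `cs_labels`.
#' @param bounds 3x2 matrix (or list of 3 ranges) of inclusive 1-based voxel
#'   index ranges, rows = axes.
#' @return Cropped object of the same class.
#' @export
crop_volume <- function(volume, bounds) {
  if (is.list(bounds)) bounds <- do.call(rbind, lapply(bounds, range))
  bounds <- matrix(as.integer(bounds), nrow = 3)
  d <- dim(vol_data(volume))
  if (any(bounds[, 1] > bounds[, 2])) stop("empty crop bounds")
  if (any(bounds[, 1] < 1) || any(bounds[, 2] > d))
    stop("crop bounds outside volume")
  idx <- lapply(1:3, function(a) bounds[a, 1]:bounds[a, 2])
  new_origin <- voxel_to_world(volume, bounds[, 1])
  if (inherits(volume, "cs_labels")) {
    cs_labels(volume$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              volume$legend, volume$pitch_um, new_origin)
  } else {
    cs_volume(volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              volume$pitch_um, new_origin, volume$axis_names)
  }
}

#' Trilinear (or nearest) sampling at arbitrary fractional voxel positions
#'
#' @param arr 3D array.
#' @param pts n-by-3 matrix of fractional 1-based voxel coordinates.
#' @param fill Value for out-of-bounds samples.
#' @param nearest Use nearest-neighbour instead of trilinear interpolation.
#' @return Numeric vector of samples.
#' @keywords internal
trilinear_sample <- function(arr, pts, fill = NA_real_, nearest = FALSE) {
  d <- dim(arr)
  out <- rep(fill, nrow(pts))
  if (nearest) {
    ijk <- round(pts)
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    out[ok] <- arr[ijk[ok, , drop = FALSE]]
    return(out)
  }
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 & pts[, 2] <= d[2] &
    pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(ok)) return(out)
  p <- pts[ok, , drop = FALSE]
  i0 <- pmin(pmax(floor(p[, 1]), 1), d[1] - 1); fx <- p[, 1] - i0
  j0 <- pmin(pmax(floor(p[, 2]), 1), d[2] - 1); fy <- p[, 2] - j0
  k0 <- pmin(pmax(floor(p[, 3]), 1), d[3] - 1); fz <- p[, 3] - k0
  # degenerate axes (size-1) handled by clamping
  if (d[1] == 1) { i0 <- rep(1, nrow(p)); fx <- 0 }
  if (d[2] == 1) { j0 <- rep(1, nrow(p)); fy <- 0 }
  if (d[3] == 1) { k0 <- rep(1, nrow(p)); fz <- 0 }
  at <- function(di, dj, dk)
    arr[cbind(pmin(i0 + di, d[1]), pmin(j0 + dj, d[2]), pmin(k0 + dk, d[3]))]
  val <-
    at(0,0,0) * (1-fx)*(1-fy)*(1-fz) + at(1,0,0) * fx*(1-fy)*(1-fz) +
    at(0,1,0) * (1-fx)*fy*(1-fz)     + at(1,1,0) * fx*fy*(1-fz) +
    at(0,0,1) * (1-fx)*(1-fy)*fz     + at(1,0,1) * fx*(1-fy)*fz +
    at(0,1,1) * (1-fx)*fy*fz         + at(1,1,1) * fx*fy*fz
  out[ok] <- val
  out
}

#' Virtually reslice a volume along an arbitrary plane
#'
#' Returns a 2D slab resampled on a regular grid at the source pitch. With an
#' axis-aligned normal the plane snaps to the nearest voxel slice and the
#' result is exact (no interpolation). Out-of-bounds samples get `fill`.
#'
#' @param volume A `cs_volume` or `cs_labels`.
#' @param plane_normal Unit normal of the reslicing plane (world axes).
#' @param plane_point_mm A world point (mm) on the plane.
#' @param interpolation "trilinear" or "nearest" (labels force nearest).
#' @param fill Fill value for samples outside the volume.
#' @return A `cs_slice`: 2D matrix plus in-plane basis and geometry.
#' @export
reslice <- function(volume, plane_normal, plane_point_mm,
                    interpolation = c("trilinear", "nearest"), fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  if (inherits(volume, "cs_labels")) interpolation <- "nearest"
  n <- as.numeric(plane_normal)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("zero-length plane normal")
  n <- n / nn
  arr <- vol_data(volume)
  d <- dim(arr)
  h <- pitch_mm(volume)
  ax <- which(abs(abs(n) - 1) < 1e-9)
  if (length(ax) == 1) {
    # axis-aligned: snap to nearest slice, exact extraction
    k <- round(world_to_voxel(volume, plane_point_mm)[ax])
    if (k < 1 || k > d[ax]) stop("plane outside volume")
    uv <- setdiff(1:3, ax)
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- k
    sl <- arr[idx[[1]], idx[[2]], idx[[3]]]
    slab <- matrix(sl, d[uv[1]], d[uv[2]])
    basis <- diag(3)[, uv, drop = FALSE]
    origin <- voxel_to_world(volume, replace(c(1, 1, 1), ax, k))
    return(structure(list(data = slab, pitch_um = volume$pitch_um,
                          u = basis[, 1], v = basis[, 2], normal = n,
                          origin_mm = origin), class = "cs_slice"))
  }
  # oblique plane: in-plane orthonormal basis
  seed <- diag(3)[, which.min(abs(n))]
  u <- seed - sum(seed * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  cw <- voxel_to_world(volume, corners)
  rel <- sweep(cw, 2, plane_point_mm)
  ru <- range(rel %*% u); rv <- range(rel %*% v)
  # plane must intersect the volume's bounding slab
  dist_n <- rel %*% n
  if (min(dist_n) > 0 || max(dist_n) < 0) stop("plane outside volume")
  su <- seq(ru[1], ru[2], by = h); sv <- seq(rv[1], rv[2], by = h)
  g <- as.matrix(expand.grid(su, sv))
  pts_mm <- sweep(g[, 1] %o% u + g[, 2] %o% v, 2, plane_point_mm, "+")
  pts <- world_to_voxel(volume, pts_mm)
  val <- trilinear_sample(arr, pts, fill = fill,
                          nearest = interpolation == "nearest")
  structure(list(data = matrix(val, length(su), length(sv)),
                 pitch_um = volume$pitch_um, u = u, v = v, normal = n,
                 origin_mm = plane_point_mm + ru[1] * u + rv[1] * v),
            class = "cs_slice")
}

#' Export a scalar volume as VTK XML image data (.vti, ASCII)
#'
#' Minimal legacy-free exporter for rendering segmented volumes or
#' activation maps in ParaView-class viewers.
#'
#' @param volume A `cs_volume` or `cs_labels`.
#' @param path Output `.vti` path.
#' @param name Array name in the file.
#' @return `path`, invisibly.
#' @export
write_vti <- function(volume, path, name = "intensity") {
  arr <- vol_data(volume)
  d <- dim(arr)
  h <- pitch_mm(volume)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%g %g %g" Spacing="%g %g %g">',
            d[1] - 1, d[2] - 1, d[3] - 1,
            volume$origin_mm[1], volume$origin_mm[2], volume$origin_mm[3], h, h, h),
    sprintf('    <Piece Extent="0 %d 0 %d 0 %d">', d[1] - 1, d[2] - 1, d[3] - 1),
    sprintf('      <PointData Scalars="%s">', name),
    sprintf('        <DataArray type="Float32" Name="%s" format="ascii">', name)),
    con)
  writeLines(paste(as.vector(arr), collapse = " "), con)
  writeLines(c('        </DataArray>', '      </PointData>', '    </Piece>',
               '  </ImageData>', '</VTKFile>'), con)
  invisible(path)
}
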