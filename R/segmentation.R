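#' Estimate attenuation bands from a volume's intensity histogram
#'
#' Contrast-enhanced micro-CT separates tissue types by their differential
#' attenuation, so tissue classes occupy ordered intensity bands. Two
#' estimators are provided: fixed `percentile` splits, and deterministic 1D
#' k-means (`kmeans_1d`, Lloyd iterations from quantile-initialised centres)
#' with band boundaries at midpoints between adjacent class centres.
#'
#' Because the background typically dominates the voxel count, plain
#' k-means (equivalently multi-Otsu) can lower its objective by splitting
#' the background mode instead of separating small tissue classes; the
#' `density_valley` estimator is therefore the default: it locates the
#' `n_classes` modes of a kernel density estimate (adapting the bandwidth
#' until exactly that many modes remain) and places boundaries at the
#' density minima between them, which is insensitive to class imbalance.
#'
#' @param volume A [cs_volume()].
#' @param method "density_valley", "kmeans_1d" or "percentile".
#' @param n_classes Number of bands.
#' @param class_names Optional names, ordered from the lowest band upward;
#'   defaults to "class_1" (lowest) .. "class_k".
#' @param probs For "percentile": boundary quantile probabilities
#'   (length `n_classes - 1`); defaults to equal splits.
#' @param max_iter Lloyd iteration cap for "kmeans_1d".
#' @return An `attenuation_bands` data frame with columns `class`, `lo`,
#'   `hi` (half-open intervals `[lo, hi)`), ordered by increasing intensity.
#' @export
estimate_bands <- function(volume, method = c("density_valley", "kmeans_1d",
                                              "percentile"),
                           n_classes, class_names = NULL, probs = NULL,
                           max_iter = 100) {
  method <- match.arg(method)
  x <- as.vector(vol_data(volume))
  if (length(unique(x)) < n_classes)
    stop("volume has fewer than n_classes distinct values")
  if (method == "density_valley") {
    peaks_at <- function(bw) {
      de <- stats::density(x, bw = bw, n = 1024)
      pk <- which(diff(sign(diff(de$y))) == -2) + 1L
      list(pk = pk[de$y[pk] > 1e-9 * max(de$y)], de = de)
    }
    bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0) bw <- diff(range(x)) / 100
    # descend into the ripple regime, then grow the bandwidth until the
    # spurious modes have merged away: the first bandwidth with <= n_classes
    # modes keeps the genuine, well-separated class modes
    it <- 0
    while (length(peaks_at(bw)$pk) < n_classes && it < 40) {
      bw <- bw / 1.5; it <- it + 1
    }
    res <- peaks_at(bw)
    it <- 0
    while (length(res$pk) > n_classes && it < 200) {
      bw <- bw * 1.1; it <- it + 1
      res <- peaks_at(bw)
    }
    pk <- res$pk; de <- res$de
    if (length(pk) != n_classes)
      stop("could not resolve ", n_classes, " density modes; intensity ",
           "distribution not separable")
    cuts <- vapply(seq_len(n_classes - 1), function(i) {
      seg <- pk[i]:pk[i + 1]
      de$x[seg[which.min(de$y[seg])]]
    }, numeric(1))
  } else if (method == "percentile") {
    if (is.null(probs)) probs <- seq_len(n_classes - 1) / n_classes
    cuts <- unname(quantile(x, probs))
  } else {
    # centres start evenly spread over the intensity range (quantile
    # initialisation collapses when one class, e.g. background, dominates)
    rg <- range(x)
    centres <- rg[1] + (seq_len(n_classes) - 0.5) / n_classes * diff(rg)
    for (it in seq_len(max_iter)) {
      cuts <- (head(centres, -1) + tail(centres, -1)) / 2
      grp <- findInterval(x, cuts) + 1L
      new_centres <- vapply(seq_len(n_classes), function(k) {
        v <- x[grp == k]
        if (length(v)) mean(v) else centres[k]
      }, numeric(1))
      if (max(abs(new_centres - centres)) < 1e-10 * max(1, diff(range(x)))) {
        centres <- new_centres
        break
      }
      centres <- new_centres
    }
    centres <- sort(centres)
    cuts <- (head(centres, -1) + tail(centres, -1)) / 2
  }
  if (any(duplicated(cuts)))
    stop("degenerate band boundaries; intensity distribution not separable ",
         "into ", n_classes, " classes")
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes))
  bands <- data.frame(class = class_names,
                      lo = c(-Inf, cuts), hi = c(cuts, Inf),
                      stringsAsFactors = FALSE)
  class(bands) <- c("attenuation_bands", "data.frame")
  bands
}

#' Bands object from explicit boundaries
#' @param class_names Class names, lowest band first.
#' @param cuts Increasing boundary values (length `length(class_names) - 1`).
#' @export
attenuation_bands <- function(class_names, cuts) {
  if (is.unsorted(cuts, strictly = TRUE)) stop("cuts must be increasing")
  bands <- data.frame(class = unname(class_names), lo = unname(c(-Inf, cuts)),
                      hi = unname(c(cuts, Inf)), stringsAsFactors = FALSE)
  class(bands) <- c("attenuation_bands", "data.frame")
  bands
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("class", "lo", "hi") %in% names(bands)))
  b <- bands[order(bands$lo), ]
  if (any(b$hi <= b$lo)) stop("empty band interval")
  if (nrow(b) > 1 && any(b$lo[-1] < b$hi[-nrow(b)] - 1e-12))
    stop("overlapping attenuation bands")
  b
}

band_of <- function(bands, values) {
  # half-open [lo, hi): a value exactly at lo belongs to that band
  b <- validate_bands(bands)
  idx <- rep(0L, length(values))
  for (r in seq_len(nrow(b)))
    idx[values >= b$lo[r] & values < b$hi[r]] <- r
  list(idx = idx, bands = b)
}

#' Classify tissues by attenuation band
#'
#' Pure per-voxel map: each voxel is assigned the unique band containing its
#' intensity (half-open `[lo, hi)` intervals), label 0 (background) if no
#' band contains it. No spatial regularization is applied.
#'
#' @param volume A [cs_volume()].
#' @param bands An `attenuation_bands` object. If a class is named
#'   "background" it is mapped to label 0.
#' @return A [cs_labels()], one label per band (numbered from the lowest
#'   band upward, skipping "background").
#' @export
classify_tissues <- function(volume, bands) {
  bo <- band_of(bands, as.vector(volume$data))
  b <- bo$bands
  codes <- integer(nrow(b))
  nxt <- 1L
  for (r in seq_len(nrow(b))) {
    if (identical(b$class[r], "background")) codes[r] <- 0L
    else { codes[r] <- nxt; nxt <- nxt + 1L }
  }
  lab <- array(ifelse(bo$idx > 0, codes[pmax(bo$idx, 1L)], 0L), dim(volume$data))
  legend <- setNames(codes[codes > 0], b$class[codes > 0])
  cs_labels(lab, legend, volume$pitch_um, volume$origin_mm)
}

#' Seeded region growing within an attenuation band
#'
#' Returns the maximal connected set of voxels (given the connectivity)
#' containing the seed whose intensities lie inside `band` and, optionally,
#' inside a spatial mask. Deterministic; the result is invariant to the
#' choice of seed within the same connected component.
#'
#' @param volume A [cs_volume()].
#' @param seed Voxel index triple (1-based) whose intensity must lie in the
#'   band.
#' @param band Numeric `c(lo, hi)`: half-open intensity interval `[lo, hi)`.
#' @param connectivity 6, 18 or 26 (default 26, matching interactive
#'   region-growing tools).
#' @param mask Optional logical array restricting the growth.
#' @return Logical array: the grown region.
#' @export
region_grow <- function(volume, seed, band, connectivity = 26, mask = NULL) {
  arr <- vol_data(volume)
  d <- dim(arr)
  seed <- as.integer(seed)
  if (length(seed) != 3 || any(seed < 1) || any(seed > d))
    stop("seed outside the volume")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  val <- arr[seed[1], seed[2], seed[3]]
  if (val < band[1] || val >= band[2])
    stop(sprintf("seed intensity %g outside target band [%g, %g)",
                 val, band[1], band[2]))
  inband <- arr >= band[1] & arr < band[2]
  if (!is.null(mask)) inband <- inband & mask
  out <- region_grow_cpp(as.vector(inband), d, seed - 1L, as.integer(connectivity))
  array(out, d)
}

#' Segment the conduction system from a classified volume
#'
#' Reproduces the segmentation logic used on contrast-enhanced data: the
#' sinus-node body is grown automatically from a seed in the node band; the
#' paranodal area is taken as the connected components of the intermediate
#' band that lie within one voxel (26-connectivity) of the node body or the
#' working myocardium - the "projections and islands" - after discarding
#' components smaller than `min_component_voxels` (noise speckle); the
#' conduction axis and Purkinje network are grown in the node band but
#' restricted to landmark-derived corridor masks (the reproducible surrogate
#' for manually guided, semi-automatic segmentation). Output labels are
#' mutually exclusive with precedence node > paranodal > axis > purkinje >
#' myocardium.
#'
#' @param volume A [cs_volume()].
#' @param bands `attenuation_bands` with classes named "node", "paranodal"
#'   and "working_myocardium" (others optional).
#' @param seeds Named list of 1-based seed voxel triples; `node` required,
#'   `axis`/`purkinje` optional.
#' @param corridors Named list of logical corridor masks for the
#'   semi-automatic structures; required for every structure in `seeds`
#'   beyond `node`.
#' @param connectivity Neighbourhood for growing/labelling (default 26).
#' @param min_component_voxels Minimum paranodal component size.
#' @return A [cs_labels()] with labels node=1, paranodal=2, axis=3,
#'   purkinje=4.
#' @export
segment_conduction_system <- function(volume, bands, seeds, corridors = list(),
                                      connectivity = 26,
                                      min_component_voxels = 10) {
  b <- validate_bands(bands)
  get_band <- function(nm) {
    r <- which(b$class == nm)
    if (!length(r)) stop("bands must contain a class named '", nm, "'")
    c(b$lo[r], b$hi[r])
  }
  if (is.null(seeds$node)) stop("a 'node' seed is required")
  node_band <- get_band("node")
  para_band <- get_band("paranodal")
  myo_band <- get_band("working_myocardium")
  d <- dim(volume$data)
  out <- array(0L, d)

  node_mask <- region_grow(volume, seeds$node, node_band, connectivity)

  # paranodal: components of the intermediate band adjacent to node/myocardium
  para_in <- volume$data >= para_band[1] & volume$data < para_band[2]
  comp <- array(label_components_cpp(as.vector(para_in), d,
                                     as.integer(connectivity)), d)
  para_mask <- array(FALSE, d)
  if (max(comp) > 0) {
    myo_mask <- volume$data >= myo_band[1] & volume$data < myo_band[2]
    touch <- dilate1(node_mask | myo_mask)
    sizes <- tabulate(comp[comp > 0], nbins = max(comp))
    adjacent <- rep(FALSE, max(comp))
    tc <- comp[touch & comp > 0]
    if (length(tc)) adjacent[unique(tc)] <- TRUE
    keep <- which(sizes >= min_component_voxels & adjacent)
    if (length(keep)) para_mask <- array(comp %in% keep, d)
  }

  grow_corridor <- function(nm) {
    if (is.null(seeds[[nm]])) return(NULL)
    if (is.null(corridors[[nm]]))
      stop("structure '", nm, "' needs a corridor mask for semi-automatic growth")
    region_grow(volume, seeds[[nm]], node_band, connectivity,
                mask = corridors[[nm]])
  }
  axis_mask <- grow_corridor("axis")
  purk_mask <- grow_corridor("purkinje")

  legend <- c(node = 1L, paranodal = 2L, axis = 3L, purkinje = 4L)
  if (!is.null(purk_mask)) out[purk_mask] <- legend[["purkinje"]]
  if (!is.null(axis_mask)) out[axis_mask] <- legend[["axis"]]
  out[para_mask] <- legend[["paranodal"]]
  out[node_mask] <- legend[["node"]]
  cs_labels(out, legend, volume$pitch_um, volume$origin_mm)
}
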