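#' Specification for the synthetic heart phantom
#'
#' Builds the parameter set for [generate_phantom()]: a two-chamber voxel
#' phantom with the attenuation ordering seen in iodine-enhanced micro-CT
#' (fat > working myocardium > paranodal > node > connective, in arbitrary
#' intensity units), an embedded conduction system (sinus node with
#' paranodal projections, an insulated atrioventricular axis, a branching
#' Purkinje tree with a free-running root chord), and a ground-truth fiber
#' field (transmural helix in the ventricular shell, circumferential atrial
#' fibers).
#'
#' Chamber geometry defaults are proportional to the grid extent, so smaller
#' grids give geometrically similar (faster) phantoms. All distances in mm.
#'
#' @param shape Grid dimensions (voxels).
#' @param pitch_um Isotropic voxel pitch in micrometres.
#' @param class_means Named mean intensities for the six tissue classes.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param node_semiaxes_mm Sinus-node ellipsoid semi-axes (long axis first).
#' @param paranodal_n Number of paranodal projections radiating from the node.
#' @param paranodal_radius_mm,paranodal_length_mm Projection tube geometry.
#' @param axis_radius_mm Conduction-axis tube radius.
#' @param purkinje_depth Binary branching generations of the Purkinje tree.
#' @param purkinje_radius_mm Purkinje segment radius.
#' @param ventricular_wall_mm Ventricular shell wall thickness.
#' @param atrial_wall_mm Atrial shell wall thickness.
#' @param helix_endo_deg,helix_epi_deg Endocardial/epicardial helix angles of
#'   the ventricular fiber rule (linear transmural ramp).
#' @param include_decoy Add a node-intensity decoy blob in the ventricular
#'   wall (exercises corridor-restricted segmentation).
#' @param seed RNG seed for the noise field.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(44, 44, 72), pitch_um = 250,
                         class_means = c(fat = 200, working_myocardium = 160,
                                         paranodal = 130, node = 100,
                                         connective = 70, background = 20),
                         noise_sd = 7,
                         node_semiaxes_mm = c(2.0, 0.7, 0.7),
                         paranodal_n = 3,
                         paranodal_radius_mm = 0.35,
                         paranodal_length_mm = 1.6,
                         axis_radius_mm = 0.45,
                         purkinje_depth = 4,
                         purkinje_radius_mm = 0.3,
                         ventricular_wall_mm = 1.5,
                         atrial_wall_mm = NULL,
                         helix_endo_deg = 60, helix_epi_deg = -60,
                         include_decoy = TRUE,
                         seed = 42) {
  need <- c("fat", "working_myocardium", "paranodal", "node", "connective",
            "background")
  if (!all(need %in% names(class_means)))
    stop("class_means must name: ", paste(need, collapse = ", "))
  ord <- class_means[c("fat", "working_myocardium", "paranodal", "node",
                       "connective")]
  if (any(diff(ord) >= 0))
    stop("class means must be strictly ordered fat > working_myocardium > ",
         "paranodal > node > connective")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(helix_endo_deg) > 90 || abs(helix_epi_deg) > 90)
    stop("helix angles must lie in [-90, 90] degrees")
  h <- pitch_um / 1000
  L <- shape * h
  Lmin <- min(L[1], L[2])
  atrium <- list(centre = c(L[1] / 2, L[2] / 2, 0.235 * L[3]),
                 r_outer = 0.33 * Lmin,
                 wall = if (is.null(atrial_wall_mm)) 0.10 * Lmin else atrial_wall_mm)
  if (atrium$wall <= 0 || atrium$wall >= atrium$r_outer)
    stop("degenerate atrial shell")
  ventricle <- list(centre = c(L[1] / 2, L[2] / 2, 0.70 * L[3]),
                    ab = 0.38 * Lmin, c = 0.27 * L[3],
                    wall = ventricular_wall_mm,
                    z_base = 0.56 * L[3])
  if (ventricle$wall <= 0 || ventricle$wall >= ventricle$ab)
    stop("degenerate ventricular shell")
  if (ventricle$centre[3] + ventricle$c > L[3] ||
      ventricle$ab * 2 > Lmin ||
      atrium$centre[3] - atrium$r_outer < -h)
    stop("phantom geometry exceeds the grid")
  disc <- list(z = c(0.45, 0.49) * L[3], radius = 0.42 * Lmin)
  structure(list(
    shape = as.integer(shape), pitch_um = pitch_um,
    class_means = class_means, noise_sd = noise_sd,
    node_semiaxes_mm = node_semiaxes_mm,
    paranodal_n = paranodal_n,
    paranodal_radius_mm = paranodal_radius_mm,
    paranodal_length_mm = paranodal_length_mm,
    axis_radius_mm = axis_radius_mm,
    purkinje_depth = purkinje_depth,
    purkinje_radius_mm = purkinje_radius_mm,
    helix_endo_deg = helix_endo_deg, helix_epi_deg = helix_epi_deg,
    include_decoy = include_decoy,
    atrium = atrium, ventricle = ventricle, disc = disc,
    seed = seed), class = "phantom_spec")
}

#' Structural label codes used by the phantom and the virtual heart
#' @return Named integer vector (legend).
#' @export
phantom_legend <- function() {
  c(fat = 1L, atrial_myocardium = 2L, ventricular_myocardium = 3L,
    paranodal = 4L, node = 5L, connective = 6L, axis = 7L, purkinje = 8L,
    decoy = 9L)
}

#' Intensity class codes (attenuation bands) for the phantom tissues
#' @return Named integer vector; background is 0.
#' @export
intensity_legend <- function() {
  c(fat = 1L, working_myocardium = 2L, paranodal = 3L, node = 4L,
    connective = 5L)
}

#' Calibrated attenuation bands for a phantom specification
#'
#' Band boundaries at the midpoints between the phantom's known class mean
#' intensities - the reproducible analogue of an operator calibrating
#' thresholds against known attenuation anchors. Classes whose voxel mass
#' is a fraction of a percent (the paranodal projections) cannot be
#' resolved by unsupervised mode finding, so calibrated bands are what the
#' segmentation stage uses on phantom data.
#'
#' @param spec A [phantom_spec()].
#' @return An `attenuation_bands` object (classes ordered by intensity).
#' @export
phantom_bands <- function(spec) {
  mu <- sort(spec$class_means)
  attenuation_bands(names(mu), (head(mu, -1) + tail(mu, -1)) / 2)
}

# structural label -> intensity class name
structure_to_class <- c(
  fat = "fat", atrial_myocardium = "working_myocardium",
  ventricular_myocardium = "working_myocardium", paranodal = "paranodal",
  node = "node", connective = "connective", axis = "node", purkinje = "node",
  decoy = "node")

#' Generate the synthetic heart phantom
#'
#' Deterministic given `spec$seed`. Voxel intensity is the tissue-class mean
#' plus independent Gaussian noise; the label geometry itself never depends
#' on the noise parameters. The node body is a single connected component,
#' every paranodal projection emerges from the node into the atrial wall,
#' Purkinje terminals lie on the ventricular endocardial surface, and the
#' ventricular fiber field follows the linear transmural helix rule.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [cs_volume()]) and `truth`, which holds
#'   `labels` (structural [cs_labels()]), `intensity_class` ([cs_labels()]
#'   of attenuation classes), `fibers` (shape x 3 array of unit vectors),
#'   `fiber_valid`, `frame` (long axis + centre), `landmarks` (mm points),
#'   `corridors` (masks for semi-automatic growth), `seeds` (suggested seed
#'   voxels per structure), and the `spec` itself.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  h <- spec$pitch_um / 1000
  leg <- phantom_legend()
  g <- coord_grids(shp, spec$pitch_um)
  lab <- array(0L, shp)
  fib <- array(0, c(shp, 3))

  at <- spec$atrium; ve <- spec$ventricle; dc <- spec$disc
  ra <- sqrt((g$x - at$centre[1])^2 + (g$y - at$centre[2])^2 +
               (g$z - at$centre[3])^2)
  lab[ra <= at$r_outer & ra > at$r_outer - at$wall] <- leg[["atrial_myocardium"]]
  # epicardial fat cap above the atrium
  lab[ra > at$r_outer & ra <= at$r_outer + 0.5 &
        g$z < at$centre[3] - 0.45 * at$r_outer] <- leg[["fat"]]

  rho <- sqrt(((g$x - ve$centre[1]) / ve$ab)^2 + ((g$y - ve$centre[2]) / ve$ab)^2 +
                ((g$z - ve$centre[3]) / ve$c)^2)
  rho_i <- 1 - ve$wall / ve$ab
  vent <- rho <= 1 & rho > rho_i & g$z >= ve$z_base
  lab[vent] <- leg[["ventricular_myocardium"]]

  lab[g$z >= dc$z[1] & g$z <= dc$z[2] &
        (g$x - at$centre[1])^2 + (g$y - at$centre[2])^2 <= dc$radius^2] <-
    leg[["connective"]]

  # decoy blob of node-band intensity inside the ventricular wall
  if (spec$include_decoy) {
    rho_m <- (rho_i + 1) / 2
    pd <- ve$centre + rho_m * c(-ve$ab * sin(1.5), 0, ve$c * cos(1.5))
    dd <- sqrt((g$x - pd[1])^2 + (g$y - pd[2])^2 + (g$z - pd[3])^2)
    lab[dd <= 0.5] <- leg[["decoy"]]
  }

  # --- conduction axis: vertical tube through the insulating plane --------
  r_mid <- at$r_outer - at$wall / 2
  axis_start <- c(at$centre[1], at$centre[2],
                  at$centre[3] + (at$r_outer - at$wall) - 0.3)
  axis_end <- c(at$centre[1], at$centre[2], ve$z_base + 0.4)
  idx_axis <- voxelize_capsule(shp, spec$pitch_um, c(0, 0, 0),
                               axis_start, axis_end, spec$axis_radius_mm)
  lab[idx_axis] <- leg[["axis"]]
  for (a in 1:3) fib[idx_axis + (a - 1) * prod(shp)] <- c(0, 0, 1)[a]

  # --- Purkinje tree on the ventricular endocardial surface ---------------
  surf <- function(theta, phi)
    ve$centre + rho_i * c(ve$ab * sin(phi) * cos(theta),
                          ve$ab * sin(phi) * sin(theta),
                          ve$c * cos(phi))
  phi_root <- 2.3; phi_apex <- 0.3
  dphi <- (phi_root - phi_apex) / max(1, spec$purkinje_depth)
  pk_segments <- list(rbind(axis_end, surf(0, phi_root)))  # free-running chord
  if (spec$purkinje_depth > 0) {
    grow <- function(theta, phi, gdepth) {
      if (gdepth > spec$purkinje_depth) return()
      for (s in c(-1, 1)) {
        th2 <- theta + s * pi / 2^gdepth
        p1 <- surf(theta, phi); p2 <- surf(th2, phi - dphi)
        nseg <- 6
        tt <- seq(0, 1, length.out = nseg + 1)
        pts <- t(vapply(tt, function(u)
          surf(theta + u * (th2 - theta), phi - u * dphi), numeric(3)))
        pk_segments[[length(pk_segments) + 1]] <<- pts
        grow(th2, phi - dphi, gdepth + 1)
      }
    }
    grow(0, phi_root, 1)
  }
  pk_mask_idx <- integer(0)
  for (seg in pk_segments) {
    for (r in seq_len(nrow(seg) - 1)) {
      idx <- voxelize_capsule(shp, spec$pitch_um, c(0, 0, 0),
                              seg[r, ], seg[r + 1, ], spec$purkinje_radius_mm)
      dirv <- seg[r + 1, ] - seg[r, ]
      dirv <- dirv / max(sqrt(sum(dirv^2)), 1e-12)
      keep <- lab[idx] != leg[["axis"]]
      idx <- idx[keep]
      lab[idx] <- leg[["purkinje"]]
      for (a in 1:3) fib[idx + (a - 1) * prod(shp)] <- dirv[a]
      pk_mask_idx <- c(pk_mask_idx, idx)
    }
  }

  # --- paranodal projections walking along the atrial wall mid-surface ----
  node_c <- c(at$centre[1], at$centre[2], at$centre[3] - r_mid)
  sa <- spec$node_semiaxes_mm
  para_ids <- integer(0)
  if (spec$paranodal_n > 0) {
    azim <- (seq_len(spec$paranodal_n) - 1) * 2 * pi / spec$paranodal_n +
      20 * pi / 180
    for (phi in azim) {
      dir0 <- c(cos(phi), sin(phi), 0)
      r_node_dir <- 1 / sqrt(sum((dir0 / sa)^2))
      total_len <- r_node_dir + spec$paranodal_length_mm
      p <- node_c
      travelled <- 0
      tdir <- dir0
      while (travelled < total_len) {
        step <- min(0.3, total_len - travelled)
        # project direction onto the sphere tangent plane at p
        nrm <- (p - at$centre) / sqrt(sum((p - at$centre)^2))
        tdir <- tdir - sum(tdir * nrm) * nrm
        tdir <- tdir / sqrt(sum(tdir^2))
        p2 <- p + step * tdir
        p2 <- at$centre + (p2 - at$centre) / sqrt(sum((p2 - at$centre)^2)) * r_mid
        idx <- voxelize_capsule(shp, spec$pitch_um, c(0, 0, 0), p, p2,
                                spec$paranodal_radius_mm)
        idx <- idx[!(lab[idx] %in% c(leg[["axis"]], leg[["purkinje"]]))]
        lab[idx] <- leg[["paranodal"]]
        dirv <- (p2 - p) / max(sqrt(sum((p2 - p)^2)), 1e-12)
        for (a in 1:3) fib[idx + (a - 1) * prod(shp)] <- dirv[a]
        para_ids <- c(para_ids, idx)
        p <- p2
        travelled <- travelled + step
      }
    }
  }

  # --- sinus node body (highest precedence) --------------------------------
  node_mask <- ((g$x - node_c[1]) / sa[1])^2 + ((g$y - node_c[2]) / sa[2])^2 +
    ((g$z - node_c[3]) / sa[3])^2 <= 1
  lab[node_mask] <- leg[["node"]]
  np <- prod(shp)
  fib[which(node_mask)] <- 1
  fib[which(node_mask) + np] <- 0
  fib[which(node_mask) + 2 * np] <- 0

  # --- fiber fields for the chamber walls ---------------------------------
  valid <- array(FALSE, shp)
  set_wall_fibers <- function(sel, nx, ny, nz, alpha) {
    cx <- -ny; cy <- nx; cz <- rep(0, length(nx))     # z-hat cross n
    cn <- sqrt(cx^2 + cy^2)
    ok <- cn > 0.05
    cx <- cx / cn; cy <- cy / cn
    lx <- -nx * nz; ly <- -ny * nz; lz <- 1 - nz^2    # z-hat minus (z.n)n
    ln <- sqrt(lx^2 + ly^2 + lz^2)
    lx <- lx / ln; ly <- ly / ln; lz <- lz / ln
    fx <- cos(alpha) * cx + sin(alpha) * lx
    fy <- cos(alpha) * cy + sin(alpha) * ly
    fz <- sin(alpha) * lz
    w <- which(sel)[ok]
    fib[w] <<- fx[ok]; fib[w + np] <<- fy[ok]; fib[w + 2 * np] <<- fz[ok]
    valid[w] <<- TRUE
  }
  vsel <- lab == leg[["ventricular_myocardium"]] | lab == leg[["decoy"]]
  if (any(vsel)) {
    nx <- (g$x[vsel] - ve$centre[1]) / ve$ab^2
    ny <- (g$y[vsel] - ve$centre[2]) / ve$ab^2
    nz <- (g$z[vsel] - ve$centre[3]) / ve$c^2
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
    depth <- pmin(pmax((rho[vsel] - rho_i) / (1 - rho_i), 0), 1)
    alpha <- (spec$helix_endo_deg +
                (spec$helix_epi_deg - spec$helix_endo_deg) * depth) * pi / 180
    set_wall_fibers(vsel, nx, ny, nz, alpha)
  }
  asel <- lab == leg[["atrial_myocardium"]]
  if (any(asel)) {
    nx <- g$x[asel] - at$centre[1]; ny <- g$y[asel] - at$centre[2]
    nz <- g$z[asel] - at$centre[3]
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    set_wall_fibers(asel, nx / nn, ny / nn, nz / nn, 0)
  }
  for (code in leg[c("node", "paranodal", "axis", "purkinje")])
    valid[lab == code] <- TRUE
  # decoy fibers: treated as part of the working myocardium (helix rule)

  # --- intensities ---------------------------------------------------------
  cls_leg <- intensity_legend()
  cls <- array(0L, shp)
  for (nm in names(leg)) {
    sel <- lab == leg[[nm]]
    if (any(sel)) cls[sel] <- cls_leg[[structure_to_class[[nm]]]]
  }
  mean_of_class <- c(spec$class_means[["background"]],
                     spec$class_means[c("fat", "working_myocardium",
                                        "paranodal", "node", "connective")])
  intensity <- array(mean_of_class[cls + 1L], shp)
  set.seed(spec$seed)
  if (spec$noise_sd > 0)
    intensity <- intensity + array(rnorm(prod(shp), 0, spec$noise_sd), shp)

  # --- landmarks, corridors, suggested seeds ------------------------------
  zmid <- mean(dc$z)
  landmarks <- list(
    valve_hinge = t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(th)
      c(at$centre[1] + 0.8 * dc$radius * cos(th),
        at$centre[2] + 0.8 * dc$radius * sin(th), zmid), numeric(3))),
    apex = ve$centre + c(0, 0, ve$c),
    node_centre = node_c)
  corridors <- list(
    axis = dilate1(dilate1(lab == leg[["axis"]])),
    purkinje = dilate1(dilate1(lab == leg[["purkinje"]])))
  to_vox <- function(p) pmin(pmax(round(p / h) + 1L, 1L), shp)
  seeds <- list(node = to_vox(node_c),
                axis = to_vox((axis_start + axis_end) / 2),
                purkinje = to_vox((axis_end + surf(0, phi_root)) / 2))

  vol <- cs_volume(intensity, spec$pitch_um)
  truth <- list(
    labels = cs_labels(lab, leg, spec$pitch_um),
    intensity_class = cs_labels(cls, cls_leg, spec$pitch_um),
    fibers = fib, fiber_valid = valid,
    frame = list(long_axis = c(0, 0, 1), centre = ve$centre,
                 rho = rho, rho_inner = rho_i),
    landmarks = landmarks, corridors = corridors, seeds = seeds,
    spec = spec)
  list(volume = vol, truth = truth)
}

#' Textured test volume with a known constant fiber orientation
#'
#' Produces a texture elongated along `axis`: either a lattice of parallel
#' rods ("parallel_cylinders") or a doubly periodic cross-grating
#' ("sinusoidal_grating"); both are constant along `axis` so the true local
#' orientation is `axis` everywhere. Used to validate structure-tensor
#' orientation recovery.
#'
#' @param pattern "parallel_cylinders" or "sinusoidal_grating".
#' @param axis Unit 3-vector: the true orientation.
#' @param period_um Transverse texture period (>= 4 voxels).
#' @param noise_sd Additive Gaussian noise sd; the texture contrast
#'   (peak-to-trough) is 100 intensity units.
#' @param shape Grid size in voxels.
#' @param pitch_um Voxel pitch.
#' @param seed RNG seed for the noise.
#' @return List with `volume` and `axis` (the true unit orientation).
#' @export
generate_fiber_test_volume <- function(pattern = c("parallel_cylinders",
                                                   "sinusoidal_grating"),
                                       axis = c(0, 0, 1), period_um = 280,
                                       noise_sd = 0, shape = c(64, 64, 64),
                                       pitch_um = 28, seed = 1) {
  pattern <- match.arg(pattern)
  if (period_um < 4 * pitch_um)
    stop("texture period below the resolvable limit (4 voxels)")
  axis <- axis / sqrt(sum(axis^2))
  B <- complete_basis(axis)
  g <- coord_grids(shape, pitch_um)
  lam <- period_um / 1000
  d1 <- g$x * B[1, 1] + g$y * B[2, 1] + g$z * B[3, 1]
  d2 <- g$x * B[1, 2] + g$y * B[2, 2] + g$z * B[3, 2]
  if (pattern == "sinusoidal_grating") {
    tex <- 50 * cos(2 * pi * d1 / lam) * cos(2 * pi * d2 / lam)
  } else {
    sg <- lam / 6
    bump <- function(t) {
      m <- t - lam * floor(t / lam) - lam / 2
      exp(-m^2 / (2 * sg^2))
    }
    tex <- 100 * bump(d1) * bump(d2)
  }
  set.seed(seed)
  if (noise_sd > 0) tex <- tex + array(rnorm(prod(shape), 0, noise_sd), shape)
  list(volume = cs_volume(tex, pitch_um), axis = axis)
}

#' Cylindrical shell phantom with a transmural helical fiber field
#'
#' A hollow cylinder (axis z) whose fiber helix angle ramps linearly with
#' normalized transmural depth from `helix_endo_deg` at the inner surface to
#' `helix_epi_deg` at the outer surface (so the mid-wall angle is their
#' mean). The intensity texture is a dense set of short rods drawn along the
#' local fiber direction - a stand-in for chains of iodine-stained
#' cardiomyocytes - so the full orientation + helix-angle pipeline can be
#' validated against the analytic ground truth. Fibers are everywhere
#' tangent to the shell surface by construction.
#'
#' @param shape Grid size (voxels).
#' @param pitch_um Voxel pitch.
#' @param r_inner_mm,r_outer_mm Shell radii; the wall must span >= 6 voxels.
#' @param helix_endo_deg,helix_epi_deg Helix angles at the surfaces.
#' @param rod_length_mm,rod_radius_mm Texture rod geometry.
#' @param rods_per_voxel Expected rod-volume fill fraction.
#' @param noise_sd Additive Gaussian noise sd (rod intensity is 100).
#' @param seed RNG seed.
#' @return List with `volume` and `truth` (`fibers`, `fiber_valid`,
#'   `wall_mask`, `depth`, `helix_deg`, `frame`).
#' @export
generate_shell_phantom <- function(shape = c(128, 128, 40), pitch_um = 100,
                                   r_inner_mm = 2.6, r_outer_mm = 5.6,
                                   helix_endo_deg = 60, helix_epi_deg = -60,
                                   rod_length_mm = 1.0, rod_radius_mm = 0.1,
                                   rods_per_voxel = 1.2, noise_sd = 5,
                                   seed = 7) {
  h <- pitch_um / 1000
  if ((r_outer_mm - r_inner_mm) / h < 6)
    stop("wall thinner than 6 voxels: the helix ramp is unresolvable")
  centre <- c(shape[1], shape[2]) * h / 2
  g <- coord_grids(shape, pitch_um)
  rx <- g$x - centre[1]; ry <- g$y - centre[2]
  r <- sqrt(rx^2 + ry^2)
  wall <- r >= r_inner_mm & r <= r_outer_mm
  depth <- pmin(pmax((r - r_inner_mm) / (r_outer_mm - r_inner_mm), 0), 1)
  alpha <- (helix_endo_deg + (helix_epi_deg - helix_endo_deg) * depth) * pi / 180
  np <- prod(shape)
  fib <- array(0, c(shape, 3))
  w <- which(wall)
  cn <- r[w]
  cx <- -ry[w] / cn; cy <- rx[w] / cn        # circumferential = z-hat cross r-hat
  fib[w] <- cos(alpha[w]) * cx
  fib[w + np] <- cos(alpha[w]) * cy
  fib[w + 2 * np] <- sin(alpha[w])

  set.seed(seed)
  vol_shell_mm3 <- pi * (r_outer_mm^2 - r_inner_mm^2) * shape[3] * h
  rod_vol_mm3 <- pi * rod_radius_mm^2 * rod_length_mm
  n_rods <- ceiling(rods_per_voxel * vol_shell_mm3 / rod_vol_mm3)
  arr <- array(0, shape)
  fiber_at <- function(p) {
    rr <- sqrt((p[1] - centre[1])^2 + (p[2] - centre[2])^2)
    dd <- min(max((rr - r_inner_mm) / (r_outer_mm - r_inner_mm), 0), 1)
    aa <- (helix_endo_deg + (helix_epi_deg - helix_endo_deg) * dd) * pi / 180
    ch <- c(-(p[2] - centre[2]), p[1] - centre[1], 0) / rr
    cos(aa) * ch + sin(aa) * c(0, 0, 1)
  }
  for (i in seq_len(n_rods)) {
    rr <- sqrt(runif(1, r_inner_mm^2, r_outer_mm^2))
    th <- runif(1, 0, 2 * pi)
    zz <- runif(1, 0.05, (shape[3] - 1) * h - 0.05)
    p <- c(centre[1] + rr * cos(th), centre[2] + rr * sin(th), zz)
    f <- fiber_at(p)
    idx <- voxelize_capsule(shape, pitch_um, c(0, 0, 0),
                            p - f * rod_length_mm / 2, p + f * rod_length_mm / 2,
                            rod_radius_mm)
    arr[idx] <- arr[idx] + 100
  }
  if (noise_sd > 0) arr <- arr + array(rnorm(np, 0, noise_sd), shape)
  truth <- list(fibers = fib, fiber_valid = wall, wall_mask = wall,
                depth = depth, helix_deg = alpha * 180 / pi,
                frame = list(long_axis = c(0, 0, 1),
                             centre = c(centre, shape[3] * h / 2)))
  list(volume = cs_volume(arr, pitch_um), truth = truth)
}
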