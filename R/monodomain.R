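#' Default tissue conductivity pairs (d_L, d_T) in mm^2/ms
#'
#' Chosen to give physiological conduction velocities with the two-variable
#' tissue model: ~0.3 mm/ms longitudinal in working myocardium with a 2:1
#' longitudinal:transverse velocity ratio (d ratio 4:1), about 3x faster in
#' the Purkinje network, and about 5x slower in the node and the compact
#' atrioventricular axis; the paranodal area is intermediate. All values
#' are configuration, not measurements.
#'
#' @return Named list of `c(d_L, d_T)` pairs, one per conducting label.
#' @export
default_tissue_conductivities <- function() {
  list(atrial_myocardium = c(0.1, 0.025),
       ventricular_myocardium = c(0.1, 0.025),
       decoy = c(0.1, 0.025),
       node = c(0.004, 0.004),
       paranodal = c(0.025, 0.01),
       axis = c(0.004, 0.004),
       purkinje = c(0.9, 0.1))
}

#' Build a fiber-anisotropic conductivity tensor field
#'
#' Per conducting voxel, D = d_T I + (d_L - d_T) f (x) f with f the local
#' fiber direction, so the eigenvalues of D are d_L (along the fiber) and
#' d_T (twice, across it). Where the fiber is invalid the isotropic
#' fallback D = mean(d_L, d_T) I is used. Labels without an entry in
#' `tissue_params` do not conduct (D = 0): connective tissue, fat and
#' background insulate.
#'
#' @param labels A [cs_labels()].
#' @param fibers shape x 3 array of unit fiber vectors (or NULL for
#'   isotropic tissue everywhere).
#' @param fiber_valid Logical array marking voxels where `fibers` is defined.
#' @param tissue_params Named list label name -> c(d_L, d_T); its names
#'   define the conducting label set.
#' @param conducting Optional character vector naming labels that must
#'   conduct; an entry missing from `tissue_params` is an error.
#' @return A `conductivity_field` list: six tensor-component arrays, the
#'   conducting mask, and the voxel pitch.
#' @export
build_conductivity <- function(labels, fibers = NULL, fiber_valid = NULL,
                               tissue_params = default_tissue_conductivities(),
                               conducting = NULL) {
  if (!is.null(conducting)) {
    miss <- setdiff(conducting, names(tissue_params))
    if (length(miss))
      stop("missing tissue parameters for conducting label(s): ",
           paste(miss, collapse = ", "))
  }
  use <- intersect(names(tissue_params), names(labels$legend))
  d <- dim(labels$labels)
  np <- prod(d)
  Z <- function() array(0, d)
  Dxx <- Z(); Dyy <- Z(); Dzz <- Z(); Dxy <- Z(); Dxz <- Z(); Dyz <- Z()
  cond <- array(FALSE, d)
  for (nm in use) {
    pr <- tissue_params[[nm]]
    if (any(pr <= 0) || pr[1] < pr[2])
      stop("need d_L >= d_T > 0 for label '", nm, "'")
    sel <- labels$labels == labels$legend[[nm]]
    if (!any(sel)) next
    cond[sel] <- TRUE
    w <- which(sel)
    if (!is.null(fibers)) {
      fv <- if (is.null(fiber_valid)) rep(TRUE, length(w)) else fiber_valid[w]
      fx <- fibers[w]; fy <- fibers[w + np]; fz <- fibers[w + 2 * np]
      nn <- sqrt(fx^2 + fy^2 + fz^2)
      fv <- fv & nn > 0.5
      fx <- fx / pmax(nn, 1e-12); fy <- fy / pmax(nn, 1e-12)
      fz <- fz / pmax(nn, 1e-12)
      dl <- pr[1]; dtv <- pr[2]
      iso <- mean(pr)
      Dxx[w] <- ifelse(fv, dtv + (dl - dtv) * fx * fx, iso)
      Dyy[w] <- ifelse(fv, dtv + (dl - dtv) * fy * fy, iso)
      Dzz[w] <- ifelse(fv, dtv + (dl - dtv) * fz * fz, iso)
      Dxy[w] <- ifelse(fv, (dl - dtv) * fx * fy, 0)
      Dxz[w] <- ifelse(fv, (dl - dtv) * fx * fz, 0)
      Dyz[w] <- ifelse(fv, (dl - dtv) * fy * fz, 0)
    } else {
      iso <- mean(pr)
      Dxx[w] <- iso; Dyy[w] <- iso; Dzz[w] <- iso
    }
  }
  structure(list(xx = Dxx, yy = Dyy, zz = Dzz, xy = Dxy, xz = Dxz, yz = Dyz,
                 conducting = cond, pitch_um = labels$pitch_um),
            class = "conductivity_field")
}

#' Rectangular stimulus protocol
#'
#' @param centre_mm Stimulus site centre (mm) for a spherical site, or NULL
#'   if `voxels` is given.
#' @param radius_mm Sphere radius (mm).
#' @param voxels Optional n-by-3 matrix of 1-based voxel indices.
#' @param onset_ms,duration_ms Stimulus window.
#' @param amplitude Stimulus current in model units (negative =
#'   depolarising).
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(centre_mm = NULL, radius_mm = 0.6, voxels = NULL,
                              onset_ms = 0, duration_ms = 2,
                              amplitude = -60) {
  if (is.null(centre_mm) && is.null(voxels))
    stop("stimulus needs a centre or explicit voxels")
  structure(list(centre_mm = centre_mm, radius_mm = radius_mm,
                 voxels = voxels, onset_ms = onset_ms,
                 duration_ms = duration_ms, amplitude = amplitude),
            class = "stimulus_protocol")
}

stim_indices <- function(stim, labels) {
  d <- dim(labels$labels)
  if (!is.null(stim$voxels)) {
    v <- stim$voxels
    return(v[, 1] + d[1] * (v[, 2] - 1) + d[1] * d[2] * (v[, 3] - 1))
  }
  h <- pitch_mm(labels)
  g <- coord_grids(d, labels$pitch_um, labels$origin_mm)
  which((g$x - stim$centre_mm[1])^2 + (g$y - stim$centre_mm[2])^2 +
          (g$z - stim$centre_mm[3])^2 <= stim$radius_mm^2)
}

#' Activation times from a sampled voltage history
#'
#' First upward threshold crossing, linearly interpolated between stored
#' samples; voxels that never cross get NA (the "never activated"
#' sentinel). If the threshold lies outside the simulated voltage range the
#' result is all-sentinel with a warning.
#'
#' @param times_ms Sample times (increasing).
#' @param V Matrix, one row per voxel, one column per sample (mV).
#' @param threshold_mV Detection threshold.
#' @return Numeric vector of activation times (ms), NA where never crossed.
#' @export
activation_from_history <- function(times_ms, V, threshold_mV = -40) {
  if (is.vector(V)) V <- matrix(V, nrow = 1)
  if (threshold_mV <= min(V) || threshold_mV >= max(V))
    warning("threshold outside the simulated voltage range: all-sentinel map")
  out <- rep(NA_real_, nrow(V))
  for (r in seq_len(nrow(V))) {
    above <- V[r, ] >= threshold_mV
    cross <- which(!above[-length(above)] & above[-1])
    if (length(cross)) {
      k <- cross[1]
      f <- (threshold_mV - V[r, k]) / (V[r, k + 1] - V[r, k])
      out[r] <- times_ms[k] + f * (times_ms[k + 1] - times_ms[k])
    } else if (above[1]) out[r] <- times_ms[1]
  }
  out
}

#' Monodomain tissue simulation on a labelled voxel grid
#'
#' Explicit operator-split update: the diffusion term div(D grad V) is a
#' conservative finite-volume stencil with no-flux boundaries at
#' non-conducting voxels; the reaction term advances each voxel's ionic
#' model (Rush-Larsen gates, forward-Euler states). Activation times are
#' detected online as the first upward crossing of `threshold_mV`, linearly
#' interpolated within the step. Deterministic given inputs.
#'
#' @param labels A [cs_labels()].
#' @param conductivity A [build_conductivity()] field.
#' @param model_assignment Named list label name -> [ionic_model()] (or
#'   model id string); labels sharing a model are integrated together.
#'   Conducting labels default to `mitchell_schaeffer`.
#' @param stimuli List of [stimulus_protocol()]s.
#' @param duration_ms,dt_ms Simulation window and step. `dt_ms = NULL`
#'   picks 0.9x the diffusion stability limit (capped by the cell models).
#' @param threshold_mV Activation detection threshold.
#' @param record_voxels Optional n-by-3 matrix of voxel indices whose
#'   voltage traces are kept.
#' @param record_every_ms Trace sampling interval.
#' @param stop_when_activated Stop early once every conducting voxel has
#'   activated (plus a short tail).
#' @return List: `activation` (array of ms, NA sentinel), `threshold_mV`,
#'   `traces` (data frame or NULL), `dt_ms`, `t_end_ms`.
#' @export
simulate_monodomain <- function(labels, conductivity, model_assignment = list(),
                                stimuli, duration_ms, dt_ms = NULL,
                                threshold_mV = -40, record_voxels = NULL,
                                record_every_ms = 1,
                                stop_when_activated = FALSE) {
  d <- dim(labels$labels)
  h <- pitch_mm(labels)
  cond <- conductivity$conducting
  w <- which(cond)
  if (!length(w)) stop("no conducting tissue")
  trD <- conductivity$xx[w] + conductivity$yy[w] + conductivity$zz[w]
  dt_stab <- h^2 / (2 * max(trD))
  # resolve models per conducting label
  leg_names <- names(labels$legend)[vapply(names(labels$legend), function(nm)
    any(labels$labels[w] == labels$legend[[nm]]), logical(1))]
  models <- list()
  for (nm in leg_names) {
    m <- model_assignment[[nm]]
    if (is.null(m)) m <- "mitchell_schaeffer"
    if (is.character(m)) m <- ionic_model(m)
    models[[nm]] <- m
  }
  if (is.null(dt_ms))
    dt_ms <- min(0.9 * dt_stab,
                 min(vapply(models, function(m) m$max_dt_ms, numeric(1))))
  if (dt_ms > dt_stab + 1e-12)
    stop(sprintf(
      "stability violation: dt = %g ms exceeds h^2/(2 max trace D) = %g ms",
      dt_ms, dt_stab))
  # group conducting voxels by model object (labels may share one)
  mid <- vapply(models, function(m) m$id, character(1))
  groups <- list()
  for (u in unique(mid)) {
    nms <- names(mid)[mid == u]
    sel <- labels$labels[w] %in% unlist(labels$legend[nms])
    groups[[u]] <- list(model = models[[nms[1]]], idx = w[sel])
  }
  V <- array(0, d)
  for (gr in groups) V[gr$idx] <- gr$model$v_init
  states <- lapply(groups, function(gr)
    lapply(gr$model$init, function(v) rep(v, length(gr$idx))))
  stim_idx <- lapply(stimuli, function(s) {
    si <- intersect(stim_indices(s, labels), w)
    if (!length(si)) stop("stimulus site contains no conducting voxels")
    si
  })
  act <- array(NA_real_, d)
  nstep <- ceiling(duration_ms / dt_ms)
  last_stim <- max(vapply(stimuli, function(s) s$onset_ms + s$duration_ms,
                          numeric(1)))
  rec_idx <- NULL; rec_t <- numeric(0); rec_v <- NULL
  if (!is.null(record_voxels)) {
    rec_idx <- record_voxels[, 1] + d[1] * (record_voxels[, 2] - 1) +
      d[1] * d[2] * (record_voxels[, 3] - 1)
    rec_v <- matrix(NA_real_, length(rec_idx), 0)
  }
  every <- max(1L, round(record_every_ms / dt_ms))
  t <- 0
  for (k in seq_len(nstep)) {
    diff <- diffusion_cpp(as.vector(V), as.vector(conductivity$xx),
                          as.vector(conductivity$yy), as.vector(conductivity$zz),
                          as.vector(conductivity$xy), as.vector(conductivity$xz),
                          as.vector(conductivity$yz), as.integer(cond), d, h)
    Vprev_w <- V[w]
    for (gi in seq_along(groups)) {
      gr <- groups[[gi]]
      Vg <- V[gr$idx]
      Ist <- rep(0, length(gr$idx))
      for (si in seq_along(stimuli)) {
        s <- stimuli[[si]]
        if (t >= s$onset_ms && t < s$onset_ms + s$duration_ms) {
          hit <- match(stim_idx[[si]], gr$idx)
          hit <- hit[!is.na(hit)]
          Ist[hit] <- Ist[hit] + s$amplitude
        }
      }
      st <- ionic_step(gr$model, states[[gi]], Vg, dt_ms, Ist)
      states[[gi]] <- st$state
      V[gr$idx] <- Vg + dt_ms * (st$dVdt + diff[gr$idx])
    }
    tnew <- t + dt_ms
    Vnew_w <- V[w]
    crossed <- is.na(act[w]) & Vprev_w < threshold_mV & Vnew_w >= threshold_mV
    if (any(crossed)) {
      f <- (threshold_mV - Vprev_w[crossed]) /
        (Vnew_w[crossed] - Vprev_w[crossed])
      act[w[crossed]] <- t + f * dt_ms
    }
    t <- tnew
    if (!is.null(rec_idx) && k %% every == 0) {
      rec_t <- c(rec_t, t)
      rec_v <- cbind(rec_v, V[rec_idx])
    }
    if (stop_when_activated && t > last_stim + 5 && !anyNA(act[w])) break
  }
  traces <- NULL
  if (!is.null(rec_idx))
    traces <- list(time_ms = rec_t, V = rec_v, voxels = record_voxels)
  list(activation = act, threshold_mV = threshold_mV, traces = traces,
       dt_ms = dt_ms, t_end_ms = t)
}

#' Run the virtual heart on a phantom ground truth
#'
#' Builds fiber-anisotropic conductivities from the phantom's ground-truth
#' labels and fiber field, stimulates the centre of the sinus-node body,
#' simulates monodomain propagation, and checks the physiological
#' activation ordering: the node activates first, every atrial voxel
#' activates before any ventricular voxel (the atrioventricular axis is the
#' only pathway and adds delay), and Purkinje-coupled endocardial voxels
#' activate before mid-wall voxels on the same transmural line. Any failed
#' assertion is reported in the returned ordering report, never silently
#' dropped.
#'
#' @param truth The `truth` component of [generate_phantom()].
#' @param duration_ms Simulation cap (early-stops when fully activated).
#' @param dt_ms Time step (NULL = stability-limited default).
#' @param tissue_params Conductivities, as in [build_conductivity()].
#' @param model_assignment Per-label ionic models (default: the fast
#'   two-variable model everywhere; regional ten Tusscher / Courtemanche
#'   assignments are supported at much higher cost).
#' @param exclude Labels to remove (set non-conducting), e.g. "axis".
#' @return List: `activation` array, `report` (ordering booleans and
#'   summary times), `sim` (full solver output).
#' @export
run_virtual_heart <- function(truth, duration_ms = 400, dt_ms = NULL,
                              tissue_params = default_tissue_conductivities(),
                              model_assignment = list(), exclude = character(0)) {
  labels <- truth$labels
  if (length(exclude)) {
    lab <- labels$labels
    for (nm in exclude) lab[lab == labels$legend[[nm]]] <- 0L
    labels <- cs_labels(lab, labels$legend, labels$pitch_um, labels$origin_mm)
  }
  tissue_params <- tissue_params[setdiff(names(tissue_params), exclude)]
  condf <- build_conductivity(labels, truth$fibers, truth$fiber_valid,
                              tissue_params)
  leg <- labels$legend
  node_mask <- labels$labels == leg[["node"]]
  node_idx <- which(node_mask)
  ij <- arrayInd(node_idx, dim(node_mask))
  centroid <- voxel_to_world(labels, colMeans(ij))
  stim <- stimulus_protocol(centre_mm = centroid, radius_mm = 0.6,
                            onset_ms = 0, duration_ms = 2, amplitude = -60)
  sim <- simulate_monodomain(labels, condf, model_assignment, list(stim),
                             duration_ms, dt_ms, stop_when_activated = TRUE)
  act <- sim$activation
  atrial <- labels$labels %in% leg[c("atrial_myocardium", "node", "paranodal")]
  ventr <- labels$labels %in% leg[c("ventricular_myocardium", "decoy")]
  cond <- condf$conducting
  tmin <- function(m) if (any(m & cond)) suppressWarnings(min(act[m & cond], na.rm = TRUE)) else NA_real_
  tmax <- function(m) {
    v <- act[m & cond]
    if (!length(v) || anyNA(v)) NA_real_ else max(v)
  }
  report <- list(
    node_first = isTRUE(tmin(node_mask) <= tmin(!node_mask & cond)),
    atria_complete = !anyNA(act[atrial & cond]),
    ventricles_activated = any(ventr & cond) && !anyNA(act[ventr & cond]),
    atria_before_ventricles =
      isTRUE(tmax(atrial) < tmin(ventr)),
    atrial_last_ms = tmax(atrial),
    ventricular_first_ms = tmin(ventr),
    ventricular_last_ms = tmax(ventr))
  # Purkinje-junction endocardium vs mid-wall at the same transmural line
  pk <- labels$labels == leg[["purkinje"]]
  if (any(pk) && report$ventricles_activated) {
    rho <- truth$frame$rho
    rho_i <- truth$frame$rho_inner
    depth <- (rho - rho_i) / (1 - rho_i)
    junc <- which(dilate1(pk) & ventr & depth < 0.3)
    ctr <- truth$frame$centre
    h <- pitch_mm(labels)
    n_pairs <- 0L; n_endo_first <- 0L
    for (ji in junc) {
      p <- voxel_to_world(labels, arrayInd(ji, dim(act))[1, ])
      rel <- p - ctr
      rho_p <- rho[ji]
      if (rho_p < 1e-6) next
      target <- ctr + rel * ((rho_i + 0.5 * (1 - rho_i)) / rho_p)
      vx <- round(world_to_voxel(labels, target))
      if (any(vx < 1) || any(vx > dim(act))) next
      li <- vx[1] + dim(act)[1] * (vx[2] - 1) + dim(act)[1] * dim(act)[2] * (vx[3] - 1)
      if (!ventr[li] || is.na(act[li]) || is.na(act[ji])) next
      n_pairs <- n_pairs + 1L
      if (act[ji] < act[li]) n_endo_first <- n_endo_first + 1L
    }
    report$endo_midwall_pairs <- n_pairs
    report$endo_before_midwall <- n_pairs > 0 && n_endo_first == n_pairs
    report$endo_before_midwall_fraction <-
      if (n_pairs > 0) n_endo_first / n_pairs else NA_real_
  } else {
    report$endo_midwall_pairs <- 0L
    report$endo_before_midwall <- NA
    report$endo_before_midwall_fraction <- NA_real_
  }
  report$all_pass <- isTRUE(report$node_first) &&
    isTRUE(report$atria_complete) && isTRUE(report$ventricles_activated) &&
    isTRUE(report$atria_before_ventricles) &&
    isTRUE(report$endo_before_midwall)
  list(activation = act, report = report, sim = sim)
}
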