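test_that("structure tensor: zero on constant input, analytic on a ramp, PSD", {
  const <- cs_volume(array(5, c(24, 24, 24)), 100)
  J <- structure_tensor(const)
  expect_lt(max(abs(J$xx), abs(J$yy), abs(J$zz), abs(J$xy)), 1e-18)

  g <- conductionscan:::coord_grids(c(24, 24, 24), 100)
  ramp <- cs_volume(g$x, 100)
  Jr <- structure_tensor(ramp)
  inner <- 8:16
  expect_gt(min(Jr$xx[inner, inner, inner]), 1e-6)
  expect_lt(max(abs(Jr$yy[inner, inner, inner])), 1e-12)
  expect_lt(max(abs(Jr$zz[inner, inner, inner])), 1e-12)

  set.seed(4)
  noise <- cs_volume(array(rnorm(20^3), c(20, 20, 20)), 100)
  Jn <- structure_tensor(noise)
  eg <- conductionscan:::smallest_eig_cpp(
    as.vector(Jn$xx), as.vector(Jn$yy), as.vector(Jn$zz),
    as.vector(Jn$xy), as.vector(Jn$xz), as.vector(Jn$yz))
  expect_gt(min(eg$eigenvalues), -1e-10)   # PSD within round-off

  expect_error(structure_tensor(const, tensor_scales(50, 300)), "pitch")
  expect_error(tensor_scales(300, 100), "sigma_tensor")
  expect_error(structure_tensor(cs_volume(array(1, c(5, 5, 5)), 100)),
               "smaller than 6")
})

test_that("orientation recovery: invalid on flat input, accurate on cylinders", {
  expect_warning(fld0 <- extract_orientation(
    cs_volume(array(1, c(24, 24, 24)), 100)), "invalid")
  expect_false(any(fld0$valid))
  expect_true(all(fld0$coherence == 0))

  fv <- generate_fiber_test_volume("parallel_cylinders", axis = c(0, 0, 1),
                                   shape = c(48, 48, 48), seed = 1)
  fld <- extract_orientation(fv$volume)
  d <- dim(fv$volume$data); np <- prod(d)
  m <- array(FALSE, d); m[9:40, 9:40, 9:40] <- TRUE
  w <- which(m & fld$valid)
  expect_gt(length(w), 1000)
  expect_true(all(abs(fld$direction[w + 2 * np]) > 0.999))
  # sign canonicalisation: stored z-component nonnegative
  expect_true(all(fld$direction[, , , 3][fld$valid] >= 0))

  th <- 30 * pi / 180
  fv2 <- generate_fiber_test_volume("parallel_cylinders",
                                    axis = c(sin(th), 0, cos(th)),
                                    noise_sd = 30, shape = c(48, 48, 48),
                                    seed = 2)
  fld2 <- extract_orientation(fv2$volume)
  w2 <- which(m & fld2$valid)
  dots <- abs(fld2$direction[w2] * sin(th) + fld2$direction[w2 + 2 * np] * cos(th))
  expect_lt(median(acos(pmin(dots, 1)) * 180 / pi), 2)
})

test_that("orientation is invariant to intensity scaling and inversion", {
  fv <- generate_fiber_test_volume("parallel_cylinders",
                                   axis = c(1, 0, 1) / sqrt(2),
                                   shape = c(40, 40, 40), seed = 6)
  base <- extract_orientation(fv$volume)
  for (tf in list(function(x) 3.7 * x, function(x) -x, function(x) 100 - 2 * x)) {
    mod <- extract_orientation(cs_volume(tf(fv$volume$data), fv$volume$pitch_um))
    w <- which(base$valid & mod$valid)
    np <- prod(dim(fv$volume$data))
    dots <- abs(base$direction[w] * mod$direction[w] +
                  base$direction[w + np] * mod$direction[w + np] +
                  base$direction[w + 2 * np] * mod$direction[w + 2 * np])
    expect_gt(min(dots), 1 - 1e-9)
  }
})

test_that("rotating the volume by 90 degrees rotates recovered directions", {
  th <- 25 * pi / 180
  fv <- generate_fiber_test_volume("parallel_cylinders",
                                   axis = c(sin(th), 0, cos(th)),
                                   shape = c(40, 40, 40), seed = 9)
  fld <- extract_orientation(fv$volume)
  # rotate +90 deg about z: (x, y, z) -> (-y, x, z)
  rot <- aperm(fv$volume$data, c(2, 1, 3))[dim(fv$volume$data)[2]:1, , ]
  fldr <- extract_orientation(cs_volume(rot, fv$volume$pitch_um))
  d <- dim(fv$volume$data); np <- prod(d)
  m <- array(FALSE, d); m[9:32, 9:32, 9:32] <- TRUE
  w <- which(m & fld$valid)
  ijk <- arrayInd(w, d)
  ijk_r <- cbind(d[2] + 1 - ijk[, 2], ijk[, 1], ijk[, 3])
  wr <- ijk_r[, 1] + d[2] * (ijk_r[, 2] - 1) + d[2] * d[1] * (ijk_r[, 3] - 1)
  # R f = (-fy, fx, fz)
  dots <- abs(fldr$direction[wr] * (-fld$direction[w + np]) +
                fldr$direction[wr + np] * fld$direction[w] +
                fldr$direction[wr + 2 * np] * fld$direction[w + 2 * np])
  expect_gt(median(dots), 1 - 1e-6)
})

test_that("coherence decreases monotonically with texture noise", {
  meds <- vapply(c(0, 20, 40, 80, 160), function(ns) {
    fv <- generate_fiber_test_volume("sinusoidal_grating", axis = c(0, 0, 1),
                                     noise_sd = ns, shape = c(40, 40, 40),
                                     seed = 12)
    fld <- extract_orientation(fv$volume)
    median(fld$coherence[9:32, 9:32, 9:32])
  }, numeric(1))
  expect_lt(cor(seq_along(meds), meds, method = "spearman"), 0)
  expect_true(all(diff(meds) < 0))
})

test_that("helix angles: circumferential is 0, longitudinal is +90", {
  # synthetic cylinder-shell fiber fields with known angles
  d <- c(40, 40, 16); h <- 0.1; np <- prod(d)
  ctr <- c(d[1], d[2]) * h / 2
  g <- conductionscan:::coord_grids(d, 100)
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
  wall <- r >= 0.8 & r <= 1.6
  frame <- cardiac_frame(c(0, 0, 1), c(ctr, d[3] * h / 2))
  mk_field <- function(fx, fy, fz) {
    fib <- array(0, c(d, 3))
    w <- which(wall)
    fib[w] <- fx[w]; fib[w + np] <- fy[w]; fib[w + 2 * np] <- fz[w]
    list(direction = fib, valid = wall, pitch_um = 100)
  }
  circ <- mk_field(-(g$y - ctr[2]) / r, (g$x - ctr[1]) / r, array(0, d))
  a0 <- helical_angle_map(circ, frame, wall)
  expect_lt(max(abs(a0[wall & !is.na(a0)])), 1.5)

  long <- mk_field(array(0, d), array(0, d), array(1, d))
  a90 <- helical_angle_map(long, frame, wall)
  expect_lt(max(abs(abs(a90[wall & !is.na(a90)]) - 90)), 1.5)
  # absolute variant folds the sign
  aabs <- helical_angle_map(long, frame, wall, absolute = TRUE)
  expect_true(all(aabs[wall & !is.na(aabs)] >= 0))

  # sign-flip of the fiber leaves the angle unchanged
  flip <- mk_field((g$y - ctr[2]) / r, -(g$x - ctr[1]) / r, array(0, d))
  af <- helical_angle_map(flip, frame, wall)
  expect_equal(af, a0, tolerance = 1e-9)
})

test_that("the full chain recovers the shell transmural helix profile", {
  sp <- generate_shell_phantom(shape = c(96, 96, 32), r_inner_mm = 2.0,
                               r_outer_mm = 4.4, seed = 3)
  fld <- extract_orientation(sp$volume)
  frame <- cardiac_frame(sp$truth$frame$long_axis, sp$truth$frame$centre)
  ang <- helical_angle_map(fld, frame, sp$truth$wall_mask)
  d <- dim(sp$volume$data)
  zmask <- array(FALSE, d); zmask[, , 7:(d[3] - 6)] <- TRUE
  nb <- round((4.4 - 2.0) / 0.1)
  prof <- helix_profile(ang, sp$truth$depth, sp$truth$wall_mask & zmask, nb)
  truth <- 60 - 120 * prof$depth
  expect_lt(sqrt(mean((prof$angle_deg - truth)^2)), 5)
})
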