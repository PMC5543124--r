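test_that("phantom generation is deterministic and noise-independent in geometry", {
  a <- generate_phantom(small_heart_spec(seed = 7))
  b <- generate_phantom(small_heart_spec(seed = 7))
  expect_identical(a$volume$data, b$volume$data)
  c_ <- generate_phantom(small_heart_spec(seed = 8))
  expect_false(identical(a$volume$data, c_$volume$data))
  expect_identical(a$truth$labels$labels, c_$truth$labels$labels)

  spec0 <- small_heart_spec(); spec0$noise_sd <- 0
  d <- generate_phantom(spec0)
  expect_identical(d$truth$labels$labels, a$truth$labels$labels)
})

test_that("noiseless intensities equal the class means on their labels", {
  spec0 <- small_heart_spec(); spec0$noise_sd <- 0
  ph <- generate_phantom(spec0)
  cls <- ph$truth$intensity_class$labels
  mu <- spec0$class_means
  expect_true(all(ph$volume$data[cls == 0] == mu[["background"]]))
  for (nm in names(intensity_legend())) {
    sel <- cls == intensity_legend()[[nm]]
    expect_true(all(ph$volume$data[sel] == mu[[nm]]), label = nm)
  }
})

test_that("empirical class means respect the attenuation ordering (seed 42)", {
  ph <- default_phantom()
  cls <- ph$truth$intensity_class$labels
  m <- vapply(names(intensity_legend()), function(nm)
    mean(ph$volume$data[cls == intensity_legend()[[nm]]]), numeric(1))
  expect_true(m[["fat"]] > m[["working_myocardium"]])
  expect_true(m[["working_myocardium"]] > m[["paranodal"]])
  expect_true(m[["paranodal"]] > m[["node"]])
  expect_true(m[["node"]] > m[["connective"]])
})

test_that("phantom anatomy satisfies its structural contracts", {
  ph <- default_phantom()
  lab <- ph$truth$labels$labels
  leg <- ph$truth$labels$legend
  node <- lab == leg[["node"]]
  comp <- conductionscan:::label_components_cpp(as.vector(node), dim(node), 26L)
  expect_equal(max(comp), 1)             # node body is one connected piece

  para <- lab == leg[["paranodal"]]
  pcomp <- conductionscan:::label_components_cpp(as.vector(para), dim(para), 26L)
  expect_equal(max(pcomp), ph$truth$spec$paranodal_n)
  touch_node <- conductionscan:::dilate1(node)
  touch_myo <- conductionscan:::dilate1(lab == leg[["atrial_myocardium"]])
  for (k in seq_len(max(pcomp))) {
    m <- array(pcomp == k, dim(para))
    expect_true(any(m & touch_node) && any(m & touch_myo),
                label = sprintf("projection %d contacts node and myocardium", k))
  }

  pk <- lab == leg[["purkinje"]]
  vent <- lab == leg[["ventricular_myocardium"]]
  expect_gt(sum(conductionscan:::dilate1(pk) & vent), 0)

  # fibers are unit-norm exactly where marked valid
  np <- prod(dim(lab))
  w <- which(ph$truth$fiber_valid)
  nn <- sqrt(ph$truth$fibers[w]^2 + ph$truth$fibers[w + np]^2 +
               ph$truth$fibers[w + 2 * np]^2)
  expect_lt(max(abs(nn - 1)), 1e-9)
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(class_means = c(fat = 100, working_myocardium = 160,
                                            paranodal = 130, node = 100,
                                            connective = 70, background = 20)),
               "ordered")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(helix_endo_deg = 120), "helix")
  expect_error(phantom_spec(ventricular_wall_mm = 0), "degenerate")
  expect_error(phantom_spec(shape = c(10, 10, 10)), "grid|degenerate")
})

test_that("fiber test volumes encode the requested orientation", {
  fv <- generate_fiber_test_volume("parallel_cylinders", axis = c(0, 0, 1),
                                   shape = c(32, 32, 32), seed = 3)
  # constant along the axis by construction
  expect_lt(max(abs(fv$volume$data[, , 2:32] - fv$volume$data[, , 1:31])), 1e-9)
  th <- 30 * pi / 180
  fv2 <- generate_fiber_test_volume("sinusoidal_grating",
                                    axis = c(sin(th), 0, cos(th)),
                                    shape = c(24, 24, 24), seed = 3)
  expect_equal(fv2$axis, c(sin(th), 0, cos(th)), tolerance = 1e-12)
  a <- generate_fiber_test_volume("parallel_cylinders", noise_sd = 50,
                                  shape = c(16, 16, 16), seed = 5)
  b <- generate_fiber_test_volume("parallel_cylinders", noise_sd = 50,
                                  shape = c(16, 16, 16), seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_error(generate_fiber_test_volume(period_um = 50, pitch_um = 28),
               "resolvable")
})

test_that("shell phantom fiber rule: linear ramp, tangency, degenerate wall", {
  sp <- generate_shell_phantom(shape = c(48, 48, 16), r_inner_mm = 0.8,
                               r_outer_mm = 1.6, rods_per_voxel = 0.1,
                               seed = 2)
  # mid-wall angle is the mean of the surface angles (0 for +60/-60)
  mid <- sp$truth$wall_mask & abs(sp$truth$depth - 0.5) < 0.04
  expect_lt(max(abs(sp$truth$helix_deg[mid])), 6)
  # fibers tangent to the shell: no radial component
  d <- dim(sp$volume$data); np <- prod(d)
  h <- sp$volume$pitch_um / 1000
  ctr <- c(d[1], d[2]) * h / 2
  g <- conductionscan:::coord_grids(d, sp$volume$pitch_um)
  w <- which(sp$truth$wall_mask)
  rx <- g$x[w] - ctr[1]; ry <- g$y[w] - ctr[2]
  rn <- sqrt(rx^2 + ry^2)
  dt <- sp$truth$fibers[w] * rx / rn + sp$truth$fibers[w + np] * ry / rn
  expect_lt(max(abs(dt)), 1e-6)

  flat <- generate_shell_phantom(shape = c(48, 48, 16), r_inner_mm = 0.8,
                                 r_outer_mm = 1.6, helix_endo_deg = 0,
                                 helix_epi_deg = 0, rods_per_voxel = 0.1,
                                 seed = 2)
  expect_lt(max(abs(flat$truth$fibers[, , , 3][flat$truth$wall_mask])), 1e-12)
  expect_error(generate_shell_phantom(r_inner_mm = 2, r_outer_mm = 2.3,
                                      pitch_um = 100), "6 voxels")
})
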