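test_that("principal dimensions: ellipsoid, single voxel, brute-force oracle", {
  mask <- ellipsoid_mask(c(7.4, 2.15, 2.15), 73)
  ext <- principal_dimensions(mask, 73)
  expect_lt(abs(ext[1] - 14.8), 0.073)
  expect_lt(abs(ext[2] - 4.3), 0.073)
  expect_lt(abs(ext[3] - 4.3), 0.073)

  single <- array(FALSE, c(5, 5, 5)); single[2, 3, 4] <- TRUE
  expect_equal(principal_dimensions(single, 73), rep(0.073, 3))
  expect_error(principal_dimensions(array(FALSE, c(3, 3, 3)), 73), "empty")

  # random connected blob: extent = max projected voxel-centre separation + pitch
  set.seed(21)
  blob <- array(FALSE, c(12, 12, 12)); blob[6, 6, 6] <- TRUE
  for (i in 1:60) {
    w <- which(conductionscan:::dilate1(blob) & !blob)
    blob[sample(w, 1)] <- TRUE
  }
  ext <- principal_dimensions(blob, 100)
  pts <- (which(blob, arr.ind = TRUE) - 1) * 0.1
  rot <- prcomp(pts)$rotation
  brute <- sort(vapply(1:3, function(a) {
    proj <- drop(pts %*% rot[, a])
    max(outer(proj, proj, "-")) + 0.1      # all-pairs max separation + footprint
  }, numeric(1)), decreasing = TRUE)
  expect_equal(ext, brute, tolerance = 1e-12)
})

test_that("extents are invariant under 90-degree grid rotations and grow under dilation", {
  set.seed(31)
  blob <- array(FALSE, c(10, 14, 8)); blob[5, 7, 4] <- TRUE
  for (i in 1:40) {
    w <- which(conductionscan:::dilate1(blob) & !blob)
    blob[sample(w, 1)] <- TRUE
  }
  ext <- principal_dimensions(blob, 100)
  rot <- aperm(blob, c(2, 1, 3))[dim(blob)[2]:1, , ]   # 90 deg about z
  expect_equal(principal_dimensions(rot, 100), ext, tolerance = 1e-9)
  ext_d <- principal_dimensions(conductionscan:::dilate1(blob), 100)
  expect_true(all(ext_d >= ext - 1e-12))
})

test_that("minimum surface distance: spheres, overlap, exhaustive oracle", {
  h <- 0.25
  d <- c(24, 24, 64)
  g <- conductionscan:::coord_grids(d, 250)
  A <- (g$x - 3)^2 + (g$y - 3)^2 + (g$z - 3)^2 <= 2^2
  B <- (g$x - 3)^2 + (g$y - 3)^2 + (g$z - 13)^2 <= 1^2
  md <- min_surface_distance(A, B, 250)
  expect_lt(abs(md$distance_mm - 7), sqrt(3) * h)   # within one voxel diagonal
  expect_equal(md$distance_mm,
               sqrt(sum((md$point_a - md$point_b)^2)), tolerance = 1e-9)

  expect_equal(min_surface_distance(A, A, 250)$distance_mm, 0)

  set.seed(41)
  m1 <- array(runif(10 * 10 * 10) < 0.05, c(10, 10, 10))
  m2 <- array(runif(10 * 10 * 10) < 0.05, c(10, 10, 10))
  m2[m1] <- FALSE
  md2 <- min_surface_distance(m1, m2, 100)
  p1 <- (which(m1, arr.ind = TRUE) - 1) * 0.1
  p2 <- (which(m2, arr.ind = TRUE) - 1) * 0.1
  brute <- min(sqrt(outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)))
  expect_equal(md2$distance_mm, brute, tolerance = 1e-9)
  # symmetry
  expect_equal(min_surface_distance(m2, m1, 100)$distance_mm,
               md2$distance_mm, tolerance = 1e-12)
  expect_error(min_surface_distance(array(FALSE, c(3, 3, 3)), m1, 100), "empty")
})

test_that("distance satisfies the triangle inequality on mask triples", {
  set.seed(51)
  mk <- function() {
    m <- array(FALSE, c(8, 8, 8))
    m[sample(length(m), 6)] <- TRUE
    m
  }
  for (rep in 1:5) {
    a <- mk(); b <- mk(); c_ <- mk()
    dab <- min_surface_distance(a, b, 100)$distance_mm
    dbc <- min_surface_distance(b, c_, 100)$distance_mm
    dac <- min_surface_distance(a, c_, 100)$distance_mm
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("component census counts structures and volumes correctly", {
  ph <- default_phantom()
  cen <- component_census(ph$truth$labels)
  para <- cen[cen$structure == "paranodal", ]
  expect_equal(para$components, ph$truth$spec$paranodal_n)
  node <- cen[cen$structure == "node", ]
  expect_equal(node$components, 1L)
  expect_equal(node$volume_mm3, node$voxels * 0.25^3, tolerance = 1e-12)

  # empty label row
  lab <- cs_labels(array(0L, c(4, 4, 4)), c(ghost = 1L), 73)
  cen0 <- component_census(lab)
  expect_equal(cen0$voxels, 0L)
  expect_equal(cen0$components, 0L)
  expect_equal(cen0$volume_mm3, 0)

  # n-voxel arithmetic at 73 um pitch
  lab2 <- cs_labels(array(c(rep(1L, 10), rep(0L, 54)), c(4, 4, 4)),
                    c(s = 1L), 73)
  expect_equal(component_census(lab2)$volume_mm3, 10 * 0.073^3,
               tolerance = 1e-12)
})
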