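test_that("band estimation separates well-separated intensity classes", {
  two <- cs_volume(array(rep(c(10, 90), each = 32), c(4, 4, 4)), 100)
  for (m in c("kmeans_1d", "density_valley", "percentile")) {
    b <- estimate_bands(two, m, 2)
    expect_gt(b$hi[1], 10)
    expect_lt(b$hi[1], 90)
  }
  expect_error(estimate_bands(cs_volume(array(5, c(3, 3, 3)), 100),
                              "kmeans_1d", 2), "distinct")

  spec0 <- small_heart_spec(); spec0$noise_sd <- 0
  ph0 <- generate_phantom(spec0)
  mu <- sort(spec0$class_means)
  for (m in c("kmeans_1d", "density_valley")) {
    b <- estimate_bands(ph0$volume, m, 6)
    # every boundary falls strictly between two adjacent true class means
    expect_equal(findInterval(b$hi[-6], mu), 1:5, label = m)
  }
})

test_that("tissue classification is a pure per-voxel band map", {
  bands <- attenuation_bands(c("low", "high"), 50)
  v <- cs_volume(array(c(49.999, 50, 50.001, 10, 90, 120, 30, 50), c(2, 2, 2)),
                 100)
  lab <- classify_tissues(v, bands)
  # half-open [lo, hi): the boundary value belongs to the upper band
  expect_equal(lab$labels[2, 1, 1], lab$legend[["high"]])
  expect_equal(lab$labels[1, 1, 1], lab$legend[["low"]])

  spec0 <- small_heart_spec(); spec0$noise_sd <- 0
  ph0 <- generate_phantom(spec0)
  cls <- classify_tissues(ph0$volume, phantom_bands(spec0))
  truec <- ph0$truth$intensity_class$labels
  for (nm in names(intensity_legend())) {
    sel <- truec == intensity_legend()[[nm]]
    expect_true(all(cls$labels[sel] == cls$legend[[nm]]), label = nm)
  }
  expect_true(all(cls$labels[truec == 0] == 0))
})

test_that("noisy classification accuracy matches the Gaussian-tail bound", {
  ph <- default_phantom()
  spec <- ph$truth$spec
  cls <- classify_tissues(ph$volume, phantom_bands(spec))
  truec <- ph$truth$intensity_class$labels
  gap <- min(abs(diff(sort(spec$class_means))))
  bound <- pnorm(gap / (2 * spec$noise_sd)) - 0.02
  for (nm in names(intensity_legend())) {
    sel <- truec == intensity_legend()[[nm]]
    acc <- mean(cls$labels[sel] == cls$legend[[nm]])
    expect_gte(acc, bound)
  }
})

test_that("region growing matches an independent flood fill and its contracts", {
  v <- cs_volume(array(100, c(6, 6, 6)), 100)
  m <- region_grow(v, c(3, 3, 3), c(50, 150))
  expect_true(all(m))                     # uniform volume floods entirely

  # two same-band blobs separated by an out-of-band wall
  arr <- array(200, c(10, 10, 6))
  arr[2:4, 2:9, 2:5] <- 100
  arr[7:9, 2:9, 2:5] <- 100
  v2 <- cs_volume(arr, 100)
  grown <- region_grow(v2, c(3, 3, 3), c(50, 150))
  oracle <- bfs_flood(arr >= 50 & arr < 150, c(3, 3, 3))
  expect_identical(grown, oracle)
  expect_false(any(grown[7:9, 2:9, 2:5]))

  # seed-choice invariance within the component
  grown2 <- region_grow(v2, c(4, 8, 4), c(50, 150))
  expect_identical(grown2, grown)
  expect_true(grown[3, 3, 3])
  expect_error(region_grow(v2, c(1, 1, 1), c(50, 150)), "outside target band")

  # 6- vs 26-connectivity: diagonal-only contact
  arr3 <- array(0, c(4, 4, 4)); arr3[1, 1, 1] <- 1; arr3[2, 2, 2] <- 1
  v3 <- cs_volume(arr3, 100)
  expect_equal(sum(region_grow(v3, c(1, 1, 1), c(0.5, 1.5), connectivity = 6)), 1)
  expect_equal(sum(region_grow(v3, c(1, 1, 1), c(0.5, 1.5), connectivity = 26)), 2)
})

test_that("conduction-system segmentation recovers the phantom structures", {
  ph <- default_phantom()
  bands <- phantom_bands(ph$truth$spec)
  seg <- segment_conduction_system(ph$volume, bands, seeds = ph$truth$seeds,
                                   corridors = ph$truth$corridors)
  leg_t <- ph$truth$labels$legend
  node_true <- ph$truth$labels$labels == leg_t[["node"]]
  expect_gte(dice(node_true, seg$labels == seg$legend[["node"]]), 0.95)

  para <- seg$labels == seg$legend[["paranodal"]]
  comp <- conductionscan:::label_components_cpp(as.vector(para), dim(para), 26L)
  expect_equal(max(comp), ph$truth$spec$paranodal_n)

  # the decoy blob shares the axis band but lies outside the corridor
  decoy <- ph$truth$labels$labels == leg_t[["decoy"]]
  expect_equal(sum((seg$labels == seg$legend[["axis"]]) & decoy), 0)
  expect_equal(sum((seg$labels == seg$legend[["purkinje"]]) & decoy), 0)

  # every recovered paranodal component lies within one voxel of the node
  # body or the working myocardium (the adjacency rule for "projections
  # and islands")
  touch <- conductionscan:::dilate1(
    (seg$labels == seg$legend[["node"]]) |
      (ph$volume$data >= 145 & ph$volume$data < 180))
  for (k in seq_len(max(comp)))
    expect_true(any(array(comp == k, dim(para)) & touch))

  expect_error(
    segment_conduction_system(ph$volume, bands, seeds = ph$truth$seeds,
                              corridors = list()),
    "corridor")
})

test_that("a phantom without projections yields an empty paranodal label", {
  spec <- small_heart_spec()
  spec$paranodal_n <- 0
  ph <- generate_phantom(spec)
  seg <- segment_conduction_system(ph$volume, phantom_bands(spec),
                                   seeds = ph$truth$seeds,
                                   corridors = ph$truth$corridors)
  expect_equal(sum(seg$labels == seg$legend[["paranodal"]]), 0)
})
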