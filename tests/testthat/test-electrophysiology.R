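test_that("conductivity tensors: isotropic limit, axis-aligned, eigenvalues", {
  lab <- cs_labels(array(1L, c(4, 4, 4)), c(t = 1L), 250)
  iso <- build_conductivity(lab, tissue_params = list(t = c(0.1, 0.1)))
  expect_true(all(iso$xx == 0.1 & iso$yy == 0.1 & iso$zz == 0.1 &
                    iso$xy == 0 & iso$xz == 0 & iso$yz == 0))

  fib <- array(0, c(4, 4, 4, 3)); fib[, , , 1] <- 1
  ax <- build_conductivity(lab, fib, array(TRUE, c(4, 4, 4)),
                           list(t = c(0.1, 0.025)))
  expect_true(all(ax$xx == 0.1 & ax$yy == 0.025 & ax$zz == 0.025 & ax$xy == 0))

  set.seed(61)
  f <- rnorm(3); f <- f / sqrt(sum(f^2))
  fib2 <- array(rep(f, each = 64), c(4, 4, 4, 3))
  arb <- build_conductivity(lab, fib2, array(TRUE, c(4, 4, 4)),
                            list(t = c(0.1, 0.025)))
  D <- matrix(c(arb$xx[1], arb$xy[1], arb$xz[1],
                arb$xy[1], arb$yy[1], arb$yz[1],
                arb$xz[1], arb$yz[1], arb$zz[1]), 3, 3)
  expect_equal(sort(eigen(D, symmetric = TRUE)$values),
               c(0.025, 0.025, 0.1), tolerance = 1e-12)

  # isotropic fallback where the fiber is invalid
  fb <- build_conductivity(lab, fib, array(FALSE, c(4, 4, 4)),
                           list(t = c(0.1, 0.025)))
  expect_true(all(fb$xx == 0.0625 & fb$xy == 0))
  expect_error(build_conductivity(lab, tissue_params = list(),
                                  conducting = "t"), "missing tissue")
})

test_that("activation detection interpolates crossings and flags non-crossers", {
  expect_equal(activation_from_history(c(12, 13), c(-50, -30), -40), 12.5)
  expect_warning(
    out <- activation_from_history(1:5, matrix(seq(-80, -60, 5), 1), -40),
    "threshold")
  expect_true(is.na(out))
  # synthetic travelling wave: activation linear in x with slope 1/c
  cspeed <- 0.4; xs <- (0:49) * 0.1
  ts <- seq(0, 30, 0.5)
  V <- outer(xs, ts, function(x, t) -80 + 100 / (1 + exp((x - cspeed * t) / 0.3)))
  act <- activation_from_history(ts, V, -40)
  fit <- coef(lm(act ~ xs))
  expect_equal(unname(fit[2]), 1 / cspeed, tolerance = 0.01)
})

test_that("quiescent tissue stays at rest with an all-sentinel map", {
  lab <- cs_labels(array(1L, c(3, 3, 10)), c(t = 1L), 250)
  cf <- build_conductivity(lab, tissue_params = list(t = c(0.1, 0.1)))
  stim <- stimulus_protocol(voxels = cbind(1, 1, 1), onset_ms = 1e6,
                            duration_ms = 1, amplitude = -60)
  sim <- simulate_monodomain(lab, cf, list(), list(stim), duration_ms = 20,
                             record_voxels = cbind(2, 2, 5))
  expect_true(all(is.na(sim$activation[cf$conducting])))
  expect_lt(max(abs(sim$traces$V - (-80))), 1e-12)   # exact fixed point
})

test_that("ionic-model tissue drifts less than 0.01 mV/s at rest", {
  for (id in c("ten_tusscher_2004_epi", "courtemanche_1998")) {
    lab <- cs_labels(array(1L, c(1, 1, 4)), c(t = 1L), 250)
    cf <- build_conductivity(lab, tissue_params = list(t = c(0.1, 0.1)))
    stim <- stimulus_protocol(voxels = cbind(1, 1, 1), onset_ms = 1e6,
                              duration_ms = 1, amplitude = -60)
    sim <- simulate_monodomain(lab, cf, list(t = id), list(stim),
                               duration_ms = 1000,
                               record_voxels = cbind(1, 1, 2))
    v0 <- ionic_model(id)$v_init
    drift <- abs(tail(sim$traces$V[1, ], 1) - v0) / 1   # mV over 1 s
    expect_lt(drift, 0.01)
  }
})

test_that("the solver is deterministic and enforces stability and seeding rules", {
  lab <- cs_labels(array(1L, c(1, 1, 40)), c(t = 1L), 250)
  cf <- build_conductivity(lab, tissue_params = list(t = c(0.1, 0.1)))
  stim <- stimulus_protocol(voxels = cbind(1, 1, 1:2), onset_ms = 0,
                            duration_ms = 1, amplitude = -60)
  s1 <- simulate_monodomain(lab, cf, list(), list(stim), duration_ms = 40)
  s2 <- simulate_monodomain(lab, cf, list(), list(stim), duration_ms = 40)
  expect_identical(s1$activation, s2$activation)
  expect_false(anyNA(s1$activation[cf$conducting]))
  # activation increases monotonically along the cable
  act <- s1$activation[1, 1, ]
  expect_true(all(diff(act[3:38]) > 0))

  expect_error(simulate_monodomain(lab, cf, list(), list(stim),
                                   duration_ms = 10, dt_ms = 5),
               "stability")
  bad <- stimulus_protocol(centre_mm = c(50, 50, 50), onset_ms = 0,
                           duration_ms = 1, amplitude = -60)
  expect_error(simulate_monodomain(lab, cf, list(), list(bad), 10),
               "no conducting voxels")
})

test_that("faster Purkinje conduction shortens ventricular activation duration", {
  ph <- small_phantom()
  dur <- vapply(c(0.9, 1.8), function(dl) {
    tp <- default_tissue_conductivities()
    tp$purkinje <- c(dl, 0.1)
    vh <- run_virtual_heart(ph$truth, tissue_params = tp, dt_ms = 0.0125)
    vh$report$ventricular_last_ms - vh$report$ventricular_first_ms
  }, numeric(1))
  # doubling d_L speeds the network: the spread of ventricular activation
  # (last minus first) strictly shrinks. Note the absolute onset can move
  # later: the faster network loads the slow axis tip harder at the
  # junction (source-sink mismatch), a real electrophysiological effect.
  expect_lt(dur[2], dur[1])
})

test_that("the diffusion stencil conserves total charge with no-flux borders", {
  set.seed(71)
  d <- c(20, 20, 20)
  V <- array(rnorm(prod(d)), d)
  cond <- array(FALSE, d); cond[3:18, 3:18, 3:18] <- TRUE
  f <- c(0.6, 0.25, 0.75); f <- f / sqrt(sum(f^2))
  dl <- 0.1; dt_ <- 0.025
  Dxx <- array((dt_ + (dl - dt_) * f[1]^2), d)
  Dyy <- array((dt_ + (dl - dt_) * f[2]^2), d)
  Dzz <- array((dt_ + (dl - dt_) * f[3]^2), d)
  Dxy <- array((dl - dt_) * f[1] * f[2], d)
  Dxz <- array((dl - dt_) * f[1] * f[3], d)
  Dyz <- array((dl - dt_) * f[2] * f[3], d)
  dv <- conductionscan:::diffusion_cpp(
    as.vector(V), as.vector(Dxx), as.vector(Dyy), as.vector(Dzz),
    as.vector(Dxy), as.vector(Dxz), as.vector(Dyz),
    as.integer(cond), as.integer(d), 0.25)
  expect_lt(abs(sum(dv)), 1e-10)
  expect_true(all(dv[!cond] == 0))
})
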