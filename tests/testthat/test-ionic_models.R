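test_that("Mitchell-Schaeffer rest is an exact fixed point and gates respect dt", {
  ms <- ionic_model("mitchell_schaeffer")
  st <- ionic_step(ms, ms$init, ms$v_init, 0.05, 0)
  expect_identical(st$dVdt, 0)
  expect_identical(st$state$h, 1)
  expect_error(ionic_step(ms, ms$init, ms$v_init, 1, 0), "stability")
})

test_that("Mitchell-Schaeffer fires an action potential on suprathreshold stimulus", {
  ms <- ionic_model("mitchell_schaeffer")
  tr <- simulate_cell(ms, 400, dt = 0.05, stim_onset_ms = 10,
                      stim_duration_ms = 1, stim_amplitude = -60)
  expect_gt(max(tr$V_mV), 0)
  expect_lt(abs(tail(tr$V_mV, 1) - ms$v_init), 1)
})

test_that("ten Tusscher and Courtemanche rest near their published potentials", {
  tt <- ionic_model("ten_tusscher_2004_epi")
  tr <- simulate_cell(tt, 1000, dt = 0.05, record_every_ms = 100)
  expect_lt(abs(tail(tr$V_mV, 1) - (-86.2)), 1)    # published resting V ~ -86.2 mV
  crn <- ionic_model("courtemanche_1998")
  tr2 <- simulate_cell(crn, 1000, dt = 0.05, record_every_ms = 100)
  expect_lt(abs(tail(tr2$V_mV, 1) - (-81.18)), 1)  # published resting V ~ -81.2 mV
})

test_that("Rush-Larsen integration agrees with a stiff-solver reference (2 s)", {
  for (id in c("ten_tusscher_2004_epi", "courtemanche_1998")) {
    m <- ionic_model(id)
    y0 <- c(V = m$v_init, unlist(m$init))
    ref <- deSolve::lsoda(y0, c(0, 2000), ionic_rhs,
                          parms = list(model = m), rtol = 1e-8, atol = 1e-8)
    tr <- simulate_cell(m, 2000, dt = 0.05, record_every_ms = 200)
    expect_lt(abs(tail(tr$V_mV, 1) - ref[nrow(ref), "V"]), 0.1)
  }
})

test_that("stimulated action potentials have physiological shape and reset", {
  tt <- ionic_model("ten_tusscher_2004_epi")
  tr <- simulate_cell(tt, 1500, dt = 0.02, stim_onset_ms = 20,
                      stim_duration_ms = 1, stim_amplitude = -52)
  expect_gt(max(tr$V_mV), 10)                       # overshoot
  apd <- sum(tr$V_mV > -40)                         # ~ APD in ms at 1 ms sampling
  expect_gt(apd, 200); expect_lt(apd, 450)
  expect_lt(abs(tail(tr$V_mV, 1) - tt$v_init), 1)   # back to rest

  crn <- ionic_model("courtemanche_1998")
  tr2 <- simulate_cell(crn, 2000, dt = 0.02, stim_onset_ms = 20,
                       stim_duration_ms = 2, stim_amplitude = -20)
  expect_gt(max(tr2$V_mV), 10)
  expect_lt(abs(tail(tr2$V_mV, 1) - crn$v_init), 1)
})
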