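# Ionic cell models. Each model object exposes the same surface:
#   gates        gating variables advanced by Rush-Larsen exponential updates
#   others       remaining state variables advanced by forward Euler
#   init         named resting state (published initial conditions)
#   v_init       resting membrane potential (mV)
#   max_dt_ms    documented stability step for the explicit integrator
#   calc(V, state) -> list(inf, tau, dother, dV)
# where inf/tau are per-gate steady states and time constants (tau = Inf
# encodes a conditionally locked gate), dother are time derivatives of the
# non-gating states, and dV is -I_ion in mV/ms (no stimulus). All entries
# are vectorized over cells. Units: mV, ms, mM.

safe_ratio <- function(num, den, limit) {
  # num/den with a supplied analytic limit where den ~ 0
  out <- num / den
  bad <- !is.finite(out) | abs(den) < 1e-12
  out[bad] <- limit[bad]
  out
}

#' Construct an ionic cell model
#'
#' Three human cardiac cell models: the ten Tusscher et al. 2004 epicardial
#' ventricular model (`ten_tusscher_2004_epi`), the Courtemanche, Ramirez &
#' Nattel 1998 atrial model (`courtemanche_1998`), and the two-variable
#' Mitchell-Schaeffer 2003 reduced model (`mitchell_schaeffer`, mapped to
#' mV with resting potential -80 mV and ~100 mV amplitude) for fast tissue
#' simulations. Gating variables are integrated with Rush-Larsen
#' exponential updates and all other states with forward Euler; the
#' stimulus convention is a current in model units added to the total ionic
#' current, so depolarising stimuli are negative.
#'
#' @param id Model identifier.
#' @param params Named overrides of model parameters (Mitchell-Schaeffer
#'   only: tau_in, tau_out, tau_open, tau_close, v_gate).
#' @return An object of class `ionic_model`.
#' @export
ionic_model <- function(id = c("mitchell_schaeffer", "ten_tusscher_2004_epi",
                               "courtemanche_1998"), params = list()) {
  id <- match.arg(id)
  m <- switch(id,
    mitchell_schaeffer = model_ms(params),
    ten_tusscher_2004_epi = model_tt04_epi(),
    courtemanche_1998 = model_crn98())
  m$id <- id
  class(m) <- "ionic_model"
  m
}

#' Advance an ionic model one time step
#'
#' Gating variables are advanced by the Rush-Larsen exponential update
#' evaluated at the current potential; other states by forward Euler. The
#' membrane potential itself is not advanced here: the returned `dVdt`
#' (mV/ms, evaluated at the input state) is integrated by the caller, which
#' lets the tissue solver interleave the diffusion update.
#'
#' @param model An [ionic_model()].
#' @param state Named list of state-variable vectors.
#' @param V Membrane potential vector (mV).
#' @param dt Time step (ms); must not exceed `model$max_dt_ms`.
#' @param I_stim Stimulus current in model units (negative = depolarising).
#' @return List with `state` (advanced) and `dVdt`.
#' @export
ionic_step <- function(model, state, V, dt, I_stim = 0) {
  if (dt > model$max_dt_ms + 1e-12)
    stop(sprintf("dt = %g ms exceeds the %s stability step (%g ms)",
                 dt, model$id, model$max_dt_ms))
  cc <- model$calc(V, state)
  if (any(!is.finite(cc$dV)))
    stop("non-finite membrane current at cell(s) ",
         paste(head(which(!is.finite(cc$dV)), 3), collapse = ", "))
  for (g in model$gates) {
    tau <- cc$tau[[g]]
    state[[g]] <- cc$inf[[g]] + (state[[g]] - cc$inf[[g]]) * exp(-dt / tau)
  }
  for (s in model$others)
    state[[s]] <- state[[s]] + dt * cc$dother[[s]]
  list(state = state, dVdt = cc$dV - I_stim)
}

#' Right-hand side of an ionic model (reference form)
#'
#' The same model equations arranged as a plain ODE right-hand side
#' suitable for a general-purpose integrator such as [deSolve::lsoda()]:
#' gating variables contribute (inf - g)/tau. Used as the independent
#' integration route when validating the Rush-Larsen stepper.
#'
#' @param model An [ionic_model()].
#' @param t Time (unused; the models are autonomous).
#' @param y Named state vector, first element `V`.
#' @param parms List with optional `I_stim` function of t.
#' @return List of derivatives (deSolve convention).
#' @export
ionic_rhs <- function(t, y, parms, model = parms$model) {
  state <- as.list(y[-1])
  V <- y[[1]]
  cc <- model$calc(V, state)
  dy <- numeric(length(y))
  dy[1] <- cc$dV - if (is.null(parms$I_stim)) 0 else parms$I_stim(t)
  nm <- names(y)[-1]
  for (i in seq_along(nm)) {
    v <- nm[i]
    dy[i + 1] <- if (v %in% model$gates) {
      tau <- cc$tau[[v]]
      if (is.infinite(tau)) 0 else (cc$inf[[v]] - state[[v]]) / tau
    } else cc$dother[[v]]
  }
  list(dy)
}

#' Integrate a single cell with the package's explicit stepper
#'
#' @param model An [ionic_model()].
#' @param duration_ms,dt Integration window and step.
#' @param stim_onset_ms,stim_duration_ms,stim_amplitude Rectangular
#'   stimulus pulses (amplitude in model units, negative = depolarising);
#'   `stim_onset_ms` may be a vector.
#' @param record_every_ms Sampling interval of the returned trace.
#' @return Data frame with `time_ms`, `V_mV`, plus the final `state`
#'   attribute.
#' @export
simulate_cell <- function(model, duration_ms, dt = 0.02,
                          stim_onset_ms = numeric(0), stim_duration_ms = 1,
                          stim_amplitude = -52, record_every_ms = 1) {
  state <- lapply(model$init, identity)
  V <- model$v_init
  nstep <- ceiling(duration_ms / dt)
  every <- max(1L, round(record_every_ms / dt))
  times <- numeric(0); volts <- numeric(0)
  t <- 0
  for (k in seq_len(nstep)) {
    stim <- if (length(stim_onset_ms) &&
                any(t >= stim_onset_ms & t < stim_onset_ms + stim_duration_ms))
      stim_amplitude else 0
    st <- ionic_step(model, state, V, dt, stim)
    state <- st$state
    V <- V + dt * st$dVdt
    t <- t + dt
    if (k %% every == 0) { times <- c(times, t); volts <- c(volts, V) }
  }
  out <- data.frame(time_ms = times, V_mV = volts)
  attr(out, "state") <- state
  attr(out, "V") <- V
  out
}

# ---------------------------------------------------------------------------
# Mitchell-Schaeffer 2003 two-variable model, mapped to mV.
model_ms <- function(params = list()) {
  p <- modifyList(list(tau_in = 0.3, tau_out = 6, tau_open = 120,
                       tau_close = 150, v_gate = 0.13,
                       v_min = -80, v_range = 100), params)
  list(
    gates = "h", others = character(0),
    init = list(h = 1), v_init = p$v_min, max_dt_ms = 0.1, params = p,
    calc = function(V, state) {
      u <- (V - p$v_min) / p$v_range
      open <- u < p$v_gate
      list(
        inf = list(h = as.numeric(open)),
        tau = list(h = ifelse(open, p$tau_open, p$tau_close)),
        dother = list(),
        dV = p$v_range * (state$h * u^2 * (1 - u) / p$tau_in - u / p$tau_out))
    })
}

# ---------------------------------------------------------------------------
# ten Tusscher, Noble, Noble & Panfilov 2004, epicardial parameter set.
model_tt04_epi <- function() {
  Rg <- 8314.472; Temp <- 310; Fd <- 96485.3415
  RTF <- Rg * Temp / Fd
  Cm <- 0.185; Vc <- 0.016404; Vsr <- 0.001094
  Ko <- 5.4; Nao <- 140; Cao <- 2
  GNa <- 14.838; GK1 <- 5.405; Gto <- 0.294; GKr <- 0.096; GKs <- 0.245
  pKNa <- 0.03; GCaL <- 1.75e-4; kNaCa <- 1000; gam <- 0.35; KmCa <- 1.38
  KmNai <- 87.5; ksat <- 0.1; anaca <- 2.5; PNaK <- 1.362; KmK <- 1
  KmNa <- 40; GpK <- 0.0146; GpCa <- 0.825; KpCa <- 5e-4
  GbNa <- 2.9e-4; GbCa <- 5.92e-4
  Vmaxup <- 4.25e-4; Kup <- 2.5e-4
  arel <- 0.016464; brel <- 0.25; crel <- 0.008232; Vleak <- 8e-5
  Bufc <- 0.15; Kbufc <- 1e-3; Bufsr <- 10; Kbufsr <- 0.3
  list(
    gates = c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f",
              "fca", "g"),
    others = c("Cai", "CaSR", "Nai", "Ki"),
    # quiescent steady state (30 s unstimulated settle from the published
    # initial conditions), so rest is a fixed point to solver accuracy
    init = list(m = 0.00129222, h = 0.779524, j = 0.779519,
                xr1 = 0.000174838, xr2 = 0.485009, xs = 0.00294192,
                r = 1.93597e-08, s = 0.999998, d = 1.89303e-05,
                f = 0.999926, fca = 1.00751, g = 0.999999,
                Cai = 3.54207e-05, CaSR = 0.118728, Nai = 10.9604,
                Ki = 139.146),
    v_init = -86.5604, max_dt_ms = 0.05,
    calc = function(V, st) {
      ENa <- RTF * log(Nao / st$Nai)
      EK <- RTF * log(Ko / st$Ki)
      EKs <- RTF * log((Ko + pKNa * Nao) / (st$Ki + pKNa * st$Nai))
      ECa <- 0.5 * RTF * log(Cao / st$Cai)
      # fast sodium current
      minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
      am <- 1 / (1 + exp((-60 - V) / 5))
      bm <- 0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200))
      taum <- am * bm
      hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
      lo <- V < -40
      ah <- ifelse(lo, 0.057 * exp(-(V + 80) / 6.8), 0)
      bh <- ifelse(lo, 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V),
                   0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1))))
      tauh <- 1 / (ah + bh)
      jinf <- hinf
      aj <- ifelse(lo,
                   (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
                     (V + 37.78) / (1 + exp(0.311 * (V + 79.23))), 0)
      bj <- ifelse(lo,
                   0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14))),
                   0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32))))
      tauj <- 1 / (aj + bj)
      INa <- GNa * st$m^3 * st$h * st$j * (V - ENa)
      # L-type calcium current
      dinf <- 1 / (1 + exp((-5 - V) / 7.5))
      ad <- 1.4 / (1 + exp((-35 - V) / 13)) + 0.25
      bd <- 1.4 / (1 + exp((V + 5) / 5))
      gd <- 1 / (1 + exp((50 - V) / 20))
      taud <- ad * bd + gd
      finf <- 1 / (1 + exp((V + 20) / 7))
      tauf <- 1125 * exp(-(V + 27)^2 / 240) + 80 + 165 / (1 + exp((25 - V) / 10))
      afca <- 1 / (1 + (st$Cai / 3.25e-4)^8)
      bfca <- 0.1 / (1 + exp((st$Cai - 5e-4) / 1e-4))
      gfca <- 0.2 / (1 + exp((st$Cai - 7.5e-4) / 8e-4))
      fcainf <- (afca + bfca + gfca + 0.23) / 1.46
      # gate locked (tau = Inf) while it would increase during depolarisation
      taufca <- ifelse(fcainf > st$fca & V > -60, Inf, 2)
      # the GHK-type driving term is 0/0 at V = 0: nudge V off the pole
      Vg <- ifelse(abs(V) < 1e-6, 1e-6, V)
      expf <- exp(2 * Vg / RTF)
      ICaL <- GCaL * st$d * st$f * st$fca * 4 * Vg * Fd / RTF *
        (st$Cai * expf - 0.341 * Cao) / (expf - 1)
      # transient outward
      rinf <- 1 / (1 + exp((20 - V) / 6))
      taur <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
      sinf <- 1 / (1 + exp((V + 20) / 5))
      taus <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
      Ito <- Gto * st$r * st$s * (V - EK)
      # delayed rectifiers
      xr1inf <- 1 / (1 + exp((-26 - V) / 7))
      axr1 <- 450 / (1 + exp((-45 - V) / 10))
      bxr1 <- 6 / (1 + exp((V + 30) / 11.5))
      xr2inf <- 1 / (1 + exp((V + 88) / 24))
      axr2 <- 3 / (1 + exp((-60 - V) / 20))
      bxr2 <- 1.12 / (1 + exp((V - 60) / 20))
      IKr <- GKr * sqrt(Ko / 5.4) * st$xr1 * st$xr2 * (V - EK)
      xsinf <- 1 / (1 + exp((-5 - V) / 14))
      axs <- 1100 / sqrt(1 + exp((-10 - V) / 6))
      bxs <- 1 / (1 + exp((V - 60) / 20))
      IKs <- GKs * st$xs^2 * (V - EKs)
      # inward rectifier
      ak1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
      bk1 <- (3 * exp(2e-4 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
        (1 + exp(-0.5 * (V - EK)))
      IK1 <- GK1 * sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (V - EK)
      # pumps, exchangers, background
      INaCa <- kNaCa *
        (exp(gam * V / RTF) * st$Nai^3 * Cao -
           exp((gam - 1) * V / RTF) * Nao^3 * st$Cai * anaca) /
        ((KmNai^3 + Nao^3) * (KmCa + Cao) *
           (1 + ksat * exp((gam - 1) * V / RTF)))
      INaK <- PNaK * Ko * st$Nai /
        ((Ko + KmK) * (st$Nai + KmNa) *
           (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)))
      IpCa <- GpCa * st$Cai / (KpCa + st$Cai)
      IpK <- GpK * (V - EK) / (1 + exp((25 - V) / 5.98))
      IbNa <- GbNa * (V - ENa)
      IbCa <- GbCa * (V - ECa)
      # calcium handling
      Ileak <- Vleak * (st$CaSR - st$Cai)
      Iup <- Vmaxup / (1 + (Kup / st$Cai)^2)
      Irel <- (arel * st$CaSR^2 / (brel^2 + st$CaSR^2) + crel) * st$d * st$g
      ginf <- ifelse(st$Cai < 3.5e-4,
                     1 / (1 + (st$Cai / 3.5e-4)^6),
                     1 / (1 + (st$Cai / 3.5e-4)^16))
      taug <- ifelse(ginf > st$g & V > -60, Inf, 2)
      bufc <- 1 / (1 + Bufc * Kbufc / (st$Cai + Kbufc)^2)
      bufsr <- 1 / (1 + Bufsr * Kbufsr / (st$CaSR + Kbufsr)^2)
      dCai <- bufc * (Ileak - Iup + Irel -
                        (ICaL + IbCa + IpCa - 2 * INaCa) * Cm / (2 * Vc * Fd))
      dCaSR <- bufsr * Vc / Vsr * (Iup - Irel - Ileak)
      dNai <- -(INa + IbNa + 3 * INaK + 3 * INaCa) * Cm / (Vc * Fd)
      dKi <- -(IK1 + Ito + IKr + IKs - 2 * INaK + IpK) * Cm / (Vc * Fd)
      Iion <- INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK + IpCa +
        IpK + IbNa + IbCa
      list(inf = list(m = minf, h = hinf, j = jinf, xr1 = xr1inf,
                      xr2 = xr2inf, xs = xsinf, r = rinf, s = sinf,
                      d = dinf, f = finf, fca = fcainf, g = ginf),
           tau = list(m = taum, h = tauh, j = tauj, xr1 = axr1 * bxr1,
                      xr2 = axr2 * bxr2, xs = axs * bxs, r = taur, s = taus,
                      d = taud, f = tauf, fca = taufca, g = taug),
           dother = list(Cai = dCai, CaSR = dCaSR, Nai = dNai, Ki = dKi),
           dV = -Iion)
    })
}

# ---------------------------------------------------------------------------
# Courtemanche, Ramirez & Nattel 1998 human atrial model.
model_crn98 <- function() {
  Rg <- 8.3143; Temp <- 310; Fd <- 96.4867
  RTF <- Rg * Temp / Fd
  Cm <- 100; Vi <- 13668; Vup <- 1109.52; Vrel <- 96.48
  Ko <- 5.4; Nao <- 140; Cao <- 1.8
  gNa <- 7.8; gK1 <- 0.09; gto <- 0.1652; gKr <- 0.029411765
  gKs <- 0.12941176; gCaL <- 0.12375; gbCa <- 0.001131; gbNa <- 6.744375e-4
  INaKmax <- 0.59933874; KmNai <- 10; KmKo <- 1.5
  INaCamax <- 1600; KmNa <- 87.5; KmCa <- 1.38; ksat <- 0.1; gam <- 0.35
  IpCamax <- 0.275; Iupmax <- 0.005; Kup <- 9.2e-4; krel <- 30
  Caupmax <- 15; Cmdnmax <- 0.05; Trpnmax <- 0.07; Csqnmax <- 10
  KmCmdn <- 0.00238; KmTrpn <- 5e-4; KmCsqn <- 0.8
  tautr <- 180; KQ10 <- 3
  list(
    gates = c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f",
              "fca", "u", "v", "w"),
    others = c("Nai", "Ki", "Cai", "Caup", "Carel"),
    # quiescent steady state (30 s unstimulated settle from the published
    # initial conditions)
    init = list(m = 0.00290528, h = 0.964978, j = 0.977527, oa = 0.0304233,
                oi = 0.999244, ua = 0.00496302, ui = 0.998605,
                xr = 3.29288e-5, xs = 0.0186858, d = 0.000136586,
                f = 0.999551, fca = 0.77551, u = 0, v = 1, w = 0.999199,
                Nai = 11.1655, Ki = 139.004, Cai = 0.000101316,
                Caup = 1.48799, Carel = 1.48799),
    v_init = -81.1873, max_dt_ms = 0.05,
    calc = function(V, st) {
      ENa <- RTF * log(Nao / st$Nai)
      EK <- RTF * log(Ko / st$Ki)
      ECa <- 0.5 * RTF * log(Cao / st$Cai)
      # fast sodium (Luo-Rudy formulations)
      am <- safe_ratio(0.32 * (V + 47.13), 1 - exp(-0.1 * (V + 47.13)),
                       rep(3.2, length(V)))
      bm <- 0.08 * exp(-V / 11)
      lo <- V < -40
      ah <- ifelse(lo, 0.135 * exp(-(V + 80) / 6.8), 0)
      bh <- ifelse(lo, 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V),
                   1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1))))
      aj <- ifelse(lo,
                   (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
                     (V + 37.78) / (1 + exp(0.311 * (V + 79.23))), 0)
      bj <- ifelse(lo,
                   0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14))),
                   0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32))))
      INa <- Cm * gNa * st$m^3 * st$h * st$j * (V - ENa)
      # transient outward
      aoa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
      boa <- 0.65 / (2.5 + exp((V + 82) / 17))
      oainf <- 1 / (1 + exp(-(V + 20.47) / 17.54))
      aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
      boi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
      oiinf <- 1 / (1 + exp((V + 43.1) / 5.3))
      Ito <- Cm * gto * st$oa^3 * st$oi * (V - EK)
      # ultrarapid delayed rectifier
      gKur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
      aua <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
      bua <- 0.65 / (2.5 + exp((V + 82) / 17))
      uainf <- 1 / (1 + exp(-(V + 30.3) / 9.6))
      aui <- 1 / (21 + exp(-(V - 185) / 28))
      bui <- exp((V - 158) / 16)
      uiinf <- 1 / (1 + exp((V - 99.45) / 27.48))
      IKur <- Cm * gKur * st$ua^3 * st$ui * (V - EK)
      # rapid and slow delayed rectifiers
      axr <- safe_ratio(3e-4 * (V + 14.1), 1 - exp(-(V + 14.1) / 5),
                        rep(3e-4 * 5, length(V)))
      bxr <- safe_ratio(7.3898e-5 * (V - 3.3328),
                        exp((V - 3.3328) / 5.1237) - 1,
                        rep(7.3898e-5 * 5.1237, length(V)))
      xrinf <- 1 / (1 + exp(-(V + 14.1) / 6.5))
      IKr <- Cm * gKr * st$xr * (V - EK) / (1 + exp((V + 15) / 22.4))
      axs <- safe_ratio(4e-5 * (V - 19.9), 1 - exp(-(V - 19.9) / 17),
                        rep(4e-5 * 17, length(V)))
      bxs <- safe_ratio(3.5e-5 * (V - 19.9), exp((V - 19.9) / 9) - 1,
                        rep(3.5e-5 * 9, length(V)))
      xsinf <- 1 / sqrt(1 + exp(-(V - 19.9) / 12.7))
      IKs <- Cm * gKs * st$xs^2 * (V - EK)
      # L-type calcium
      dinf <- 1 / (1 + exp(-(V + 10) / 8))
      ed <- exp(-(V + 10) / 6.24)
      taud <- safe_ratio(1 - ed, 0.035 * (V + 10) * (1 + ed),
                         rep(1 / (0.035 * 6.24 * 2), length(V)))
      finf <- 1 / (1 + exp((V + 28) / 6.9))
      tauf <- 9 / (0.0197 * exp(-(0.0337^2) * (V + 10)^2) + 0.02)
      fcainf <- 1 / (1 + st$Cai / 3.5e-4)
      ICaL <- Cm * gCaL * st$d * st$f * st$fca * (V - 65)
      # inward rectifier, pumps, background
      IK1 <- Cm * gK1 * (V - EK) / (1 + exp(0.07 * (V + 80)))
      sig <- (exp(Nao / 67.3) - 1) / 7
      fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) +
                     0.0365 * sig * exp(-V / RTF))
      INaK <- Cm * INaKmax * fNaK * (Ko / (Ko + KmKo)) /
        (1 + (KmNai / st$Nai)^1.5)
      INaCa <- Cm * INaCamax *
        (exp(gam * V / RTF) * st$Nai^3 * Cao -
           exp((gam - 1) * V / RTF) * Nao^3 * st$Cai) /
        ((KmNa^3 + Nao^3) * (KmCa + Cao) *
           (1 + ksat * exp((gam - 1) * V / RTF)))
      IbNa <- Cm * gbNa * (V - ENa)
      IbCa <- Cm * gbCa * (V - ECa)
      IpCa <- Cm * IpCamax * st$Cai / (5e-4 + st$Cai)
      # sarcoplasmic reticulum calcium handling
      Irel <- krel * st$u^2 * st$v * st$w * (st$Carel - st$Cai)
      Fn <- 1e-12 * Vrel * Irel - 5e-13 / Fd * (0.5 * ICaL - 0.2 * INaCa)
      uinf <- 1 / (1 + exp(-(Fn - 3.4175e-13) / 1.367e-15))
      vinf <- 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / 1.367e-15))
      tauv <- 1.91 + 2.09 / (1 + exp(-(Fn - 3.4175e-13) / 1.367e-15))
      winf <- 1 - 1 / (1 + exp(-(V - 40) / 17))
      ew <- exp(-(V - 7.9) / 5)
      tauw <- safe_ratio(6 * (1 - ew), (1 + 0.3 * ew) * (V - 7.9),
                         rep(6 / (5 * 1.3), length(V)))
      Iup <- Iupmax / (1 + Kup / st$Cai)
      Iupleak <- Iupmax * st$Caup / Caupmax
      Itr <- (st$Caup - st$Carel) / tautr
      dNai <- (-3 * INaK - 3 * INaCa - IbNa - INa) / (Fd * Vi)
      dKi <- (2 * INaK - IK1 - Ito - IKur - IKr - IKs) / (Fd * Vi)
      B1 <- (2 * INaCa - IpCa - ICaL - IbCa) / (2 * Fd * Vi) +
        (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi
      B2 <- 1 + Trpnmax * KmTrpn / (st$Cai + KmTrpn)^2 +
        Cmdnmax * KmCmdn / (st$Cai + KmCmdn)^2
      dCaup <- Iup - Iupleak - Itr * Vrel / Vup
      dCarel <- (Itr - Irel) /
        (1 + Csqnmax * KmCsqn / (st$Carel + KmCsqn)^2)
      Iion <- INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
        INaCa + IbNa + IbCa
      list(inf = list(m = am / (am + bm), h = ah / (ah + bh),
                      j = aj / (aj + bj), oa = oainf, oi = oiinf,
                      ua = uainf, ui = uiinf, xr = xrinf, xs = xsinf,
                      d = dinf, f = finf, fca = fcainf, u = uinf,
                      v = vinf, w = winf),
           tau = list(m = 1 / (am + bm), h = 1 / (ah + bh),
                      j = 1 / (aj + bj),
                      oa = 1 / (KQ10 * (aoa + boa)),
                      oi = 1 / (KQ10 * (aoi + boi)),
                      ua = 1 / (KQ10 * (aua + bua)),
                      ui = 1 / (KQ10 * (aui + bui)),
                      xr = 1 / (axr + bxr), xs = 0.5 / (axs + bxs),
                      d = taud, f = tauf, fca = 2, u = 8, v = tauv,
                      w = tauw),
           dother = list(Nai = dNai, Ki = dKi, Cai = B1 / B2,
                         Caup = dCaup, Carel = dCarel),
           dV = -Iion / Cm)
    })
}
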