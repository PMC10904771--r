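#' Equilibrium toxin-binding model
#'
#' Describes an alpha-toxin acting on voltage-gated Na+ channels: occupancy
#' follows a Hill curve of concentration, and the bound channel population
#' inactivates more slowly (`slowdown` times the control time constant) and
#' may keep a non-inactivating (persistent) fraction of its conductance.
#'
#' @param ec50 Half-occupancy concentration in nM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param slowdown Multiplicative factor (>= 1) on the inactivation time
#'   constant of toxin-bound channels.
#' @param persistent_frac Fraction in `[0, 1]` of bound-channel conductance
#'   that does not inactivate during a depolarisation.
#'
#' @return An object of class `axf_toxin`.
#' @export
#' @examples
#' tox <- toxin_model(ec50 = 0.3, slowdown = 3, persistent_frac = 0.2)
#' hill_occupancy(0.3, tox) # 0.5 by construction
toxin_model <- function(ec50 = 0.3, hill_n = 1.5, slowdown = 4,
                        persistent_frac = 0.15) {
  stopifnot(
    is.numeric(ec50), length(ec50) == 1L, ec50 > 0,
    is.numeric(hill_n), length(hill_n) == 1L, hill_n > 0,
    is.numeric(slowdown), length(slowdown) == 1L, slowdown >= 1,
    is.numeric(persistent_frac), length(persistent_frac) == 1L,
    persistent_frac >= 0, persistent_frac <= 1
  )
  structure(
    list(ec50 = ec50, hill_n = hill_n, slowdown = slowdown,
         persistent_frac = persistent_frac),
    class = "axf_toxin"
  )
}

#' Hill occupancy of the toxin at a given concentration
#'
#' `conc^n / (conc^n + ec50^n)`: 0 at zero concentration, exactly 0.5 at the
#' EC50, strictly increasing and saturating at 1.
#'
#' @param conc Concentration in nM (>= 0, vectorised).
#' @param toxin A [toxin_model()].
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @export
hill_occupancy <- function(conc, toxin) {
  stopifnot(inherits(toxin, "axf_toxin"), is.numeric(conc))
  if (any(conc < 0)) stop("concentration must be non-negative")
  cn <- conc^toxin$hill_n
  cn / (cn + toxin$ec50^toxin$hill_n)
}

#' Voltage-clamp step protocol
#'
#' Default is the standard whole-cell protocol for fast Na+ currents: hold
#' at -100 mV, step to 0 mV for 50 ms, sampled at 20 kHz.
#'
#' @param hold_mv Holding potential, mV.
#' @param step_mv Step potential, mV.
#' @param step_ms Step duration, ms (> 0).
#' @param sample_khz Sampling rate, kHz (> 0).
#' @return An object of class `axf_vcp`.
#' @export
vc_protocol <- function(hold_mv = -100, step_mv = 0, step_ms = 50,
                        sample_khz = 20) {
  stopifnot(step_ms > 0, sample_khz > 0)
  structure(
    list(hold_mv = hold_mv, step_mv = step_mv, step_ms = step_ms,
         sample_khz = sample_khz),
    class = "axf_vcp"
  )
}

#' Parameter set for a voltage-clamp Na+ channel population
#'
#' A minimal activation/inactivation description of the whole-cell current:
#' activation gate `m = (1 - exp(-t/tau_act))^3`, inactivation decaying
#' exponentially with `tau_inact`, reversal `e_rev`.
#'
#' @param gmax_us Maximal conductance, uS (>= 0).
#' @param tau_act_ms Activation time constant, ms.
#' @param tau_inact_ms Inactivation time constant, ms.
#' @param e_rev_mv Reversal potential, mV.
#' @return A named list of class `axf_channel`.
#' @export
na_channel <- function(gmax_us = 0.02, tau_act_ms = 0.15,
                       tau_inact_ms = 1, e_rev_mv = 60) {
  stopifnot(gmax_us >= 0, tau_act_ms > 0, tau_inact_ms > 0)
  structure(
    list(gmax_us = gmax_us, tau_act_ms = tau_act_ms,
         tau_inact_ms = tau_inact_ms, e_rev_mv = e_rev_mv),
    class = "axf_channel"
  )
}

#' Simulate a voltage-clamp Na+ current under toxin
#'
#' Deterministic, noise-free inward current for a depolarising step. The
#' channel population is split by Hill occupancy into a free pool, which
#' inactivates with `tau_inact`, and a toxin-bound pool, which inactivates
#' with `slowdown * tau_inact` and retains `persistent_frac` of its
#' conductance at the end of the step.
#'
#' @param protocol A [vc_protocol()].
#' @param channel A [na_channel()] parameter set.
#' @param toxin A [toxin_model()].
#' @param conc Toxin concentration, nM (>= 0).
#' @return A [vc_current_trace()] of length `step_ms * sample_khz`.
#' @export
#' @examples
#' tr <- simulate_vc_current(vc_protocol(), na_channel(), toxin_model(), 0)
#' compute_t50(tr)$t50
simulate_vc_current <- function(protocol = vc_protocol(),
                                channel = na_channel(),
                                toxin = toxin_model(), conc = 0) {
  stopifnot(inherits(protocol, "axf_vcp"), inherits(channel, "axf_channel"))
  occ <- hill_occupancy(conc, toxin)
  dt <- 1 / protocol$sample_khz
  n <- round(protocol$step_ms * protocol$sample_khz)
  t <- (seq_len(n) - 1L) * dt
  m3 <- (1 - exp(-t / channel$tau_act_ms))^3
  h_free <- exp(-t / channel$tau_inact_ms)
  pf <- toxin$persistent_frac
  h_bound <- pf + (1 - pf) * exp(-t / (toxin$slowdown * channel$tau_inact_ms))
  g <- channel$gmax_us * m3 * ((1 - occ) * h_free + occ * h_bound)
  i <- g * (protocol$step_mv - channel$e_rev_mv) # inward (negative) for step below e_rev
  vc_current_trace(i, dt = dt, t0 = 0, protocol = protocol)
}

#' Configuration of the soma-plus-axon action-potential simulator
#'
#' A soma coupled resistively to a chain of axonal compartments (default
#' 5 um steps out to 45 um) with Hodgkin-Huxley-style conductances.
#' Axial density profiles encode the biology of the axon initial segment:
#' Na_v density peaks in the AIS, the Ca2+ permeability of Na_v channels
#' rises towards the distal AIS, and voltage-gated Ca2+ channel (VGCC)
#' density falls with distance from the soma.
#'
#' Density functions take position in um (0 = soma) and return conductance
#' per compartment (uS); `ca_perm_frac` returns the dimensionless fraction
#' of Na_v flux carried as Ca2+.
#'
#' @param compartments Strictly increasing axial positions in um; first
#'   element 0 (the soma).
#' @param nav_density,kv_density,vgcc_density Functions of position -> uS.
#' @param ca_perm_frac Function of position -> fraction in `[0, 1]`.
#' @param pulse List with `amp_nA`, `dur_ms`, `onset_ms`: somatic current
#'   injection.
#' @param v_init Initial membrane potential, mV.
#' @param record_ms Total simulated duration, ms.
#' @param biophys Named list of membrane/gating constants; see
#'   [default_biophys()].
#' @return An object of class `axf_simcfg`.
#' @export
neuron_sim_config <- function(compartments = c(0, seq(5, 45, by = 5)),
                              nav_density = NULL,
                              kv_density = NULL,
                              vgcc_density = NULL,
                              ca_perm_frac = NULL,
                              pulse = list(amp_nA = 2.5, dur_ms = 3,
                                           onset_ms = 0.5),
                              v_init = -80,
                              record_ms = 8,
                              biophys = default_biophys()) {
  stopifnot(
    length(compartments) >= 2L,
    all(diff(compartments) > 0),
    compartments[1] == 0,
    pulse$dur_ms > 0, record_ms > 0
  )
  if (is.null(nav_density)) nav_density <- default_nav_density
  if (is.null(kv_density)) kv_density <- default_kv_density
  if (is.null(vgcc_density)) vgcc_density <- default_vgcc_density
  if (is.null(ca_perm_frac)) ca_perm_frac <- default_ca_perm_frac
  dens <- list(nav = nav_density(compartments),
               kv = kv_density(compartments),
               vgcc = vgcc_density(compartments),
               caf = ca_perm_frac(compartments))
  if (any(unlist(dens[c("nav", "kv", "vgcc")]) < 0)) {
    stop("conductance densities must be non-negative")
  }
  if (any(dens$caf < 0 | dens$caf > 1)) {
    stop("ca_perm_frac must return fractions in [0, 1]")
  }
  structure(
    list(compartments = compartments,
         nav_density = nav_density, kv_density = kv_density,
         vgcc_density = vgcc_density, ca_perm_frac = ca_perm_frac,
         pulse = pulse, v_init = v_init, record_ms = record_ms,
         biophys = biophys),
    class = "axf_simcfg"
  )
}

#' Membrane and gating constants of the AP simulator
#'
#' Values are phenomenological: they were chosen once so that the control
#' (no toxin) action potential width, measured as time above -30 mV, falls
#' in the range reported for layer-5 pyramidal neurons (0.7-1.4 ms at the
#' soma, 0.45-1 ms in the AIS).
#'
#' @return Named list of constants (units in names/comments).
#' @export
default_biophys <- function() {
  list(
    c_soma_nf = 0.12,   # somatic capacitance, nF
    c_axon_nf = 0.004,  # per-compartment axonal capacitance, nF
    g_axial_us = 0.10,  # axial coupling conductance between neighbours, uS
    e_na = 60, e_k = -90, e_leak = -80, e_ca = 80, # reversals, mV
    g_leak_soma = 0.02, g_leak_axon = 0.001,       # uS
    # Na activation gate m (steady state + fixed tau)
    m_vhalf = -48, m_k = 6, m_tau = 0.07,
    # Na inactivation gate h: bell-shaped time constant (fast at spike
    # voltages, slow subthreshold recovery -> refractoriness, faster at rest)
    h_vhalf = -52, h_k = 6, h_tau = 0.45,
    h_tau_amp = 2.6, h_tau_vc = -55, h_tau_w = 10,
    # slow adaptation K+ gate z (M-type-like); terminates the late
    # persistent-Na depolarisation so every AP repolarises in-record
    z_vhalf = -40, z_k = 5, z_tau = 2, g_adapt_soma = 0.15,
    g_adapt_axon = 0.08,
    # delayed-rectifier gate n (fast axonal Kv)
    n_vhalf_soma = -35, n_vhalf_axon = -25, n_k = 9,
    n_tau_soma = 0.6, n_tau_axon = 0.35,
    # VGCC: instantaneous high-voltage activation (squared) with a fast
    # inactivation gate, so its charge is dominated by the spike upstroke
    s_vhalf = 0, s_k = 4,
    u_vhalf = -40, u_k = 5, u_tau = 0.10, u_tau_hi = 0.03,
    dt_internal = 0.01, # ms: 100 kHz fixed-step integration
    out_khz = 20        # output sampling of the ground-truth bundle
  )
}

#' @rdname neuron_sim_config
#' @param x Axial position(s), um.
#' @export
default_nav_density <- function(x) {
  # soma strong (keeps the somatic AP peak comparable to the AIS one);
  # AIS density rising to a 20-35 um plateau
  ifelse(x == 0, 2.4, 0.35 + 0.75 * pmin(x, 25) / 25)
}

#' @rdname neuron_sim_config
#' @export
default_kv_density <- function(x) {
  ifelse(x == 0, 1.2, 0.32 + 0.46 * pmin(x, 25) / 25)
}

#' @rdname neuron_sim_config
#' @export
default_vgcc_density <- function(x) {
  # VGCC contribution falls off with distance from the soma
  ifelse(x == 0, 0.08, pmax(0.10 * (1 - x / 40), 0))
}

#' @rdname neuron_sim_config
#' @export
default_ca_perm_frac <- function(x) {
  # Na_v Ca2+ permeability, negligible proximally, rising into the distal AIS
  0.04 * pmax((x - 20) / 20, 0)^1.5
}

sigmoid_gate <- function(v, vhalf, k) 1 / (1 + exp(-(v - vhalf) / k))

#' Simulate an action-potential experiment with Na+/Ca2+ influx ground truth
#'
#' Integrates the soma-plus-axon model (fixed-step 4th-order Runge-Kutta at
#' 100 kHz via [deSolve::rk4()]) for a somatic current pulse, with the Na+
#' conductance split into toxin-free and toxin-bound pools exactly as in
#' [simulate_vc_current()]. Returns, per compartment: membrane potential,
#' cumulative Na+ influx, cumulative Ca2+ influx (Na_v-mediated plus VGCC-
#' mediated), and the instantaneous Na+/Ca2+ influx rates. The simulation is
#' noise-free and fully deterministic.
#'
#' @param config A [neuron_sim_config()].
#' @param toxin A [toxin_model()].
#' @param conc Toxin concentration, nM.
#' @return An object of class `axf_ap_sim`: list with `positions` (um), `dt`
#'   (ms), `time` (ms), matrices `vm`, `na_influx`, `ca_influx`,
#'   `ca_influx_nav`, `ca_influx_vgcc`, `i_na`, `i_ca` (rows = time,
#'   columns = compartments), and `soma_vm` (a [vm_trace()]).
#' @export
simulate_ap_experiment <- function(config = neuron_sim_config(),
                                   toxin = toxin_model(), conc = 0) {
  stopifnot(inherits(config, "axf_simcfg"), inherits(toxin, "axf_toxin"))
  occ <- hill_occupancy(conc, toxin)
  bp <- config$biophys
  x <- config$compartments
  nc <- length(x)
  gna <- config$nav_density(x)
  gk <- config$kv_density(x)
  gca <- config$vgcc_density(x)
  caf <- config$ca_perm_frac(x)
  gl <- c(bp$g_leak_soma, rep(bp$g_leak_axon, nc - 1L))
  g_adapt <- c(bp$g_adapt_soma, rep(bp$g_adapt_axon, nc - 1L))
  cm <- c(bp$c_soma_nf, rep(bp$c_axon_nf, nc - 1L))
  n_tau <- c(bp$n_tau_soma, rep(bp$n_tau_axon, nc - 1L))
  n_vhalf <- c(bp$n_vhalf_soma, rep(bp$n_vhalf_axon, nc - 1L))
  pf <- toxin$persistent_frac
  slow <- toxin$slowdown

  pulse_on <- config$pulse$onset_ms
  pulse_off <- pulse_on + config$pulse$dur_ms
  amp <- config$pulse$amp_nA

  # state: v[nc], m[nc], h[nc], hb[nc], n[nc], u[nc], z[nc],
  #        qna[nc], qca_nav[nc], qca_vgcc[nc]
  ix <- function(k) ((k - 1L) * nc + 1L):(k * nc)
  deriv <- function(t, y, parms) {
    v <- y[ix(1)]; m <- y[ix(2)]; h <- y[ix(3)]
    hb <- y[ix(4)]; n <- y[ix(5)]; u <- y[ix(6)]; z <- y[ix(7)]
    minf <- sigmoid_gate(v, bp$m_vhalf, bp$m_k)
    hinf <- 1 - sigmoid_gate(v, bp$h_vhalf, bp$h_k)
    h_tau <- bp$h_tau + bp$h_tau_amp * exp(-((v - bp$h_tau_vc) / bp$h_tau_w)^2)
    ninf <- sigmoid_gate(v, n_vhalf, bp$n_k)
    uinf <- 1 - sigmoid_gate(v, bp$u_vhalf, bp$u_k)
    # inactivation accelerates at spike-top voltages
    w_hi <- sigmoid_gate(v, -20, 5)
    u_tau_v <- bp$u_tau * (1 - w_hi) + bp$u_tau_hi * w_hi
    h_eff <- (1 - occ) * h + occ * (pf + (1 - pf) * hb)
    g_na_open <- gna * m^3 * h_eff
    i_na <- g_na_open * (v - bp$e_na)           # nA, negative = inward
    i_k <- gk * n^2 * (v - bp$e_k)
    i_adapt <- g_adapt * z * (v - bp$e_k)
    i_l <- gl * (v - bp$e_leak)
    sinf <- sigmoid_gate(v, bp$s_vhalf, bp$s_k)
    j_ca_vgcc <- gca * sinf^2 * u * pmax(bp$e_ca - v, 0) # influx rate >= 0
    j_na <- pmax(-i_na, 0)                          # Na influx rate >= 0
    j_ca_nav <- caf * j_na
    i_ax <- numeric(nc)
    dvn <- diff(v)                                  # v[i+1] - v[i]
    i_ax[-nc] <- i_ax[-nc] + bp$g_axial_us * dvn
    i_ax[-1] <- i_ax[-1] - bp$g_axial_us * dvn
    i_inj <- c(if (t >= pulse_on && t < pulse_off) amp else 0,
               rep(0, nc - 1L))
    dv <- (i_inj + i_ax - i_na - i_k - i_adapt - i_l) / cm
    list(c(dv,
           (minf - m) / bp$m_tau,
           (hinf - h) / h_tau,
           (hinf - hb) / (h_tau * slow),
           (ninf - n) / n_tau,
           (uinf - u) / u_tau_v,
           (sigmoid_gate(v, bp$z_vhalf, bp$z_k) - z) / bp$z_tau,
           j_na, j_ca_nav, j_ca_vgcc))
  }

  v0 <- rep(config$v_init, nc)
  m0 <- sigmoid_gate(v0, bp$m_vhalf, bp$m_k)
  h0 <- 1 - sigmoid_gate(v0, bp$h_vhalf, bp$h_k)
  n0 <- sigmoid_gate(v0, n_vhalf, bp$n_k)
  u0 <- 1 - sigmoid_gate(v0, bp$u_vhalf, bp$u_k)
  z0 <- sigmoid_gate(v0, bp$z_vhalf, bp$z_k)
  y0 <- c(v0, m0, h0, h0, n0, u0, z0, rep(0, 3L * nc))
  times <- seq(0, config$record_ms, by = bp$dt_internal)
  sol <- deSolve::rk4(y0, times, deriv, parms = NULL)
  if (anyNA(sol) || any(!is.finite(sol))) {
    stop("numerical integration failed (non-finite state); ",
         "reduce dt_internal or check conductances")
  }
  # downsample to the output rate
  stride <- max(1L, round(1 / (bp$out_khz * bp$dt_internal)))
  keep <- seq(1L, length(times), by = stride)
  tt <- sol[keep, 1L]
  grab <- function(k) unname(sol[keep, 1L + ix(k), drop = FALSE])
  vm <- grab(1)
  qna <- grab(8); qca_nav <- grab(9); qca_vgcc <- grab(10)
  # instantaneous influx rates from state recomputation at kept samples
  m_s <- grab(2); h_s <- grab(3); hb_s <- grab(4)
  h_eff <- (1 - occ) * h_s + occ * (pf + (1 - pf) * hb_s)
  j_na <- sweep(m_s^3 * h_eff, 2, gna, `*`) * pmax(bp$e_na - vm, 0)
  sinf <- sigmoid_gate(vm, bp$s_vhalf, bp$s_k)
  u_s <- grab(6)
  j_ca <- sweep(sinf^2 * u_s * pmax(bp$e_ca - vm, 0), 2, gca, `*`) +
    sweep(j_na, 2, caf, `*`)
  dt_out <- bp$dt_internal * stride
  structure(
    list(positions = x, dt = dt_out, time = tt,
         vm = vm,
         na_influx = qna,
         ca_influx = qca_nav + qca_vgcc,
         ca_influx_nav = qca_nav,
         ca_influx_vgcc = qca_vgcc,
         i_na = j_na, i_ca = j_ca,
         soma_vm = vm_trace(vm[, 1L], dt = dt_out, t0 = 0),
         conc = conc, occupancy = occ,
         config = config, toxin = toxin),
    class = "axf_ap_sim"
  )
}

#' Spatially averaged ground-truth trace from an AP simulation
#'
#' Averages one of the simulated per-compartment signals over the
#' compartments whose position falls in an ROI span (half-open `[a, b)`).
#'
#' @param sim An `axf_ap_sim` bundle.
#' @param what One of "vm", "na_influx", "ca_influx", "i_na", "i_ca".
#' @param roi A [roi_spec()] or preset name understood by [roi_spec()].
#' @return An `axf_ts` trace.
#' @export
sim_roi_trace <- function(sim, what = c("vm", "na_influx", "ca_influx",
                                        "ca_influx_nav", "ca_influx_vgcc",
                                        "i_na", "i_ca"),
                          roi = "mid") {
  stopifnot(inherits(sim, "axf_ap_sim"))
  what <- match.arg(what)
  roi <- as_roi_spec(roi)
  sel <- sim$positions >= roi$span_um[1] & sim$positions < roi$span_um[2]
  if (!any(sel)) {
    stop(sprintf("ROI '%s' [%g, %g) um covers no simulated compartment",
                 roi$label, roi$span_um[1], roi$span_um[2]))
  }
  vals <- rowMeans(sim[[what]][, sel, drop = FALSE])
  if (what == "vm") {
    vm_trace(vals, dt = sim$dt, t0 = 0, source = "optical")
  } else {
    time_series(vals, dt = sim$dt, t0 = 0)
  }
}
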