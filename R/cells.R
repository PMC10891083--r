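#' Pyramidal-neuron parameters (two-compartment adaptive LIF)
#'
#' The pyramidal cell is reduced to two electrically coupled compartments, a
#' somatic-basal compartment carrying the spike mechanism and an apical
#' compartment receiving SST inhibition, apical tonic inhibition and distal
#' background drive.  Spiking is adaptive leaky integrate-and-fire: threshold
#' crossing at the soma emits a spike, resets the somatic voltage, starts a
#' refractory clock and increments a spike-triggered adaptation current.
#'
#' @param C_m capacitance per compartment (pF), named `somatic`/`apical`.
#' @param g_L leak conductance per compartment (nS).
#' @param E_L leak reversal potential (mV).
#' @param V_th spike threshold (mV).
#' @param V_reset post-spike reset voltage (mV).
#' @param t_ref absolute refractory period (ms), must be positive.
#' @param g_c somato-apical coupling conductance (nS).
#' @param w_adapt spike-triggered adaptation increment (pA).
#' @param tau_adapt adaptation decay time constant (ms).
#' @param bap_g back-propagating action potential modeled as a
#'   spike-triggered brief excitatory conductance on the apical
#'   compartment (nS); the resulting stereotyped apical depolarization
#'   gives each spike a dipole signature.
#' @param bap_tau decay time of the bAP conductance (ms).
#' @param area_cm2 membrane area per compartment (cm^2), used to fold
#'   per-area tonic conductances (mS/cm^2) into absolute conductances (nS).
#' @return an object of class `neuron_params` with two compartments.
#' @export
pyr_params <- function(C_m = c(somatic = 100, apical = 60),
                       g_L = c(somatic = 6, apical = 4),
                       E_L = -70, V_th = -50, V_reset = -60, t_ref = 3,
                       g_c = 8, w_adapt = 10, tau_adapt = 150,
                       bap_g = 200, bap_tau = 2,
                       area_cm2 = c(somatic = 0.25e-4, apical = 1.5e-4)) {
  stopifnot(length(C_m) == 2, length(g_L) == 2, length(area_cm2) == 2)
  p <- list(type = "Pyr", n_comp = 2L,
            compartments = c("somatic", "apical"),
            C_m = unname(C_m), g_L = unname(g_L), E_L = E_L, V_th = V_th,
            V_reset = V_reset, t_ref = t_ref, g_c = g_c,
            w_adapt = w_adapt, tau_adapt = tau_adapt,
            bap_g = bap_g, bap_tau = bap_tau,
            area_cm2 = unname(area_cm2))
  validate_neuron_params(p)
}

#' Interneuron parameters (single-compartment adaptive LIF)
#'
#' One parameter set per interneuron class.  Defaults give a
#' faster membrane and weak adaptation for PV (fast-spiking), moderate
#' adaptation for SST and VIP.
#'
#' @param class one of `"SST"`, `"PV"`, `"VIP"`.
#' @param ... overrides for any of the fields of [pyr_params()] (scalar
#'   versions; interneurons have a single compartment and no coupling).
#' @return an object of class `neuron_params` with one compartment.
#' @export
interneuron_params <- function(class = c("SST", "PV", "VIP"), ...) {
  class <- match.arg(class)
  def <- switch(class,
    SST = list(C_m = 80, g_L = 5, V_th = -52, t_ref = 2.5, w_adapt = 5,
               tau_adapt = 120, area_cm2 = 3e-4),
    PV  = list(C_m = 80, g_L = 8, V_th = -52, t_ref = 1.5, w_adapt = 0,
               tau_adapt = 50, area_cm2 = 4e-4),
    VIP = list(C_m = 60, g_L = 4, V_th = -52, t_ref = 2.5, w_adapt = 3,
               tau_adapt = 100, area_cm2 = 2e-4))
  def <- utils::modifyList(
    c(def, list(E_L = -70, V_reset = -60, g_c = 0)), list(...))
  p <- list(type = class, n_comp = 1L, compartments = "somatic",
            C_m = def$C_m, g_L = def$g_L, E_L = def$E_L, V_th = def$V_th,
            V_reset = def$V_reset, t_ref = def$t_ref, g_c = def$g_c,
            w_adapt = def$w_adapt, tau_adapt = def$tau_adapt,
            area_cm2 = def$area_cm2)
  validate_neuron_params(p)
}

validate_neuron_params <- function(p) {
  if (any(p$C_m <= 0) || any(p$g_L < 0) || p$g_c < 0 || any(p$area_cm2 <= 0))
    stop("conductances and areas must be non-negative, capacitances positive")
  if (p$t_ref <= 0) stop("t_ref must be positive")
  if (p$n_comp == 2L && length(p$C_m) != 2L)
    stop("two-compartment neurons need two capacitances")
  structure(p, class = "neuron_params")
}

#' Outwardly rectifying tonic GABA-A conductance
#'
#' Tonic inhibition is modelled as a persistent conductance with a sigmoidal
#' voltage-dependent open fraction
#' \deqn{r(V) = f_{min} + (1 - f_{min}) / (1 + e^{-(V - V_{half})/k})}
#' so the conductance rectifies outwardly: it is largest at depolarized
#' potentials and floors at `f_min * G_tonic` when hyperpolarized.
#'
#' @param G_tonic conductance density (mS/cm^2); folded to nS with the
#'   compartment area where absolute currents are needed.
#' @param E_GABA chloride reversal potential (mV); -75 mV physiological
#'   default, -5 mV under the high-chloride clamp solution.
#' @param V_half half-activation voltage of the rectification (mV).
#' @param k rectification slope (mV).
#' @param f_min open-fraction floor, in `[0, 1]`.
#' @return an object of class `tonic_conductance`.
#' @export
tonic_conductance <- function(G_tonic, E_GABA = -75, V_half = -50, k = 10,
                              f_min = 0.4) {
  if (G_tonic < 0) stop("G_tonic must be non-negative")
  if (f_min < 0 || f_min > 1) stop("f_min must lie in [0, 1]")
  if (k <= 0) stop("rectification slope k must be positive")
  structure(list(G_tonic = G_tonic, E_GABA = E_GABA, V_half = V_half,
                 k = k, f_min = f_min),
            class = "tonic_conductance")
}

#' Rectification factor of a tonic conductance
#'
#' @param V membrane potential (mV), vectorized.
#' @param tc a [tonic_conductance()].
#' @return open fraction in `[f_min, 1]`.
#' @export
tonic_rectification <- function(V, tc) {
  stopifnot(inherits(tc, "tonic_conductance"))
  tc$f_min + (1 - tc$f_min) / (1 + exp(-(V - tc$V_half) / tc$k))
}

#' Tonic inhibition current
#'
#' Returns `G_tonic * r(V) * (V - E_GABA)`.  With `area_cm2 = NULL` the
#' result is a current density in uA/cm^2 (mS/cm^2 times mV); with an area it
#' is an absolute current in pA.  Sign convention: negative values are inward
#' at the electrode in voltage clamp.
#'
#' @inheritParams tonic_rectification
#' @param area_cm2 optional compartment area (cm^2) to fold density into pA.
#' @return current (uA/cm^2 or pA), vectorized over `V`.
#' @export
tonic_current <- function(V, tc, area_cm2 = NULL) {
  stopifnot(all(is.finite(V)))
  i_dens <- tc$G_tonic * tonic_rectification(V, tc) * (V - tc$E_GABA)
  if (is.null(area_cm2)) i_dens else i_dens * area_cm2 * 1e6
}

#' Synaptic connection-class parameters
#'
#' A connection class is a (presynaptic type, postsynaptic type, target
#' compartment) triple with bi-exponential conductance kinetics.  The
#' waveform is normalized so a single presynaptic spike reaches a peak
#' conductance of exactly `g_syn`.  SST to Pyr connections target the apical
#' compartment, PV to Pyr the somatic-basal compartment, and Pyr to Pyr
#' both.  A `plasticity` hook is kept for short-term dynamics but is unused
#' by default.
#'
#' @param pre,post presynaptic and postsynaptic population names.
#' @param target `"somatic"`, `"apical"` or `"both"` (Pyr targets only).
#' @param g_syn peak conductance (nS).
#' @param tau_r,tau_d rise and decay time constants (ms), `tau_d > tau_r > 0`.
#' @param E_syn reversal potential (mV).
#' @param plasticity reserved hook, `NULL` by default.
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(pre, post, target = "somatic", g_syn, tau_r,
                           tau_d, E_syn, plasticity = NULL) {
  if (tau_r <= 0 || tau_d <= tau_r)
    stop("time constants must satisfy tau_d > tau_r > 0")
  if (!target %in% c("somatic", "apical", "both"))
    stop("unknown target compartment: ", target)
  structure(list(pre = pre, post = post, target = target, g_syn = g_syn,
                 tau_r = tau_r, tau_d = tau_d, E_syn = E_syn,
                 plasticity = plasticity),
            class = "synapse_params")
}

#' Time-to-peak of the bi-exponential conductance
#'
#' @param tau_r,tau_d rise and decay time constants (ms).
#' @return peak latency after synapse onset (ms).
#' @export
syn_peak_time <- function(tau_r, tau_d) {
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Bi-exponential synaptic conductance waveform
#'
#' Superposition of peak-normalized bi-exponentials, one per presynaptic
#' spike.
#'
#' @param t evaluation times (ms).
#' @param sp a [synapse_params()].
#' @param spike_times sorted presynaptic spike times (ms).
#' @return conductance at `t` (nS).
#' @export
syn_conductance <- function(t, sp, spike_times) {
  stopifnot(inherits(sp, "synapse_params"))
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  tpk <- syn_peak_time(sp$tau_r, sp$tau_d)
  norm <- 1 / (exp(-tpk / sp$tau_d) - exp(-tpk / sp$tau_r))
  g <- numeric(length(t))
  for (ts in spike_times) {
    dt <- t - ts
    on <- dt >= 0
    g[on] <- g[on] + sp$g_syn * norm *
      (exp(-dt[on] / sp$tau_d) - exp(-dt[on] / sp$tau_r))
  }
  g
}

#' Synaptic current
#'
#' `I(t) = g(t) * (V - E_syn)`; negative values are inward.
#'
#' @inheritParams syn_conductance
#' @param V postsynaptic membrane potential (mV), scalar or same length
#'   as `t`.
#' @return current (pA).
#' @export
synaptic_current <- function(t, V, sp, spike_times) {
  syn_conductance(t, sp, spike_times) * (V - sp$E_syn)
}

#' Integrate a single neuron for one time step (reference integrator)
#'
#' Plain-R exponential-Euler update used as the single-neuron oracle against
#' the compiled network engine and for closed-form checks.  The `state` list
#' carries `V` (vector over compartments), `w` (adaptation, pA) and `refr`
#' (remaining refractory time, ms).
#'
#' @param state list with `V`, `w`, `refr`.
#' @param params a [pyr_params()] or [interneuron_params()].
#' @param I_ext external current per compartment (pA; positive depolarizes).
#' @param dt time step (ms), positive and at most 0.1 by default usage.
#' @param g_ext external conductance per compartment (nS) with reversal
#'   `E_ext` (mV); used for conductance-based drive.
#' @param E_ext reversal of `g_ext` (mV).
#' @param tonic optional list of [tonic_conductance()] per compartment
#'   (absolute nS in `G_tonic`).
#' @return updated state with logical `spike`.
#' @export
step_neuron <- function(state, params, I_ext = 0, dt = 0.1, g_ext = 0,
                        E_ext = 0, tonic = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(state$V))) stop("non-finite membrane state")
  nc <- params$n_comp
  I_ext <- rep_len(I_ext, nc)
  g_ext <- rep_len(g_ext, nc)
  V <- state$V
  w <- state$w * exp(-dt / params$tau_adapt)
  Vnew <- V
  spike <- FALSE
  for (i in seq_len(nc)) {
    gt <- 0; gtE <- 0
    if (!is.null(tonic) && !is.null(tonic[[i]])) {
      tc <- tonic[[i]]
      gt <- tc$G_tonic * tonic_rectification(V[i], tc)
      gtE <- gt * tc$E_GABA
    }
    gc <- if (nc == 2L) params$g_c else 0
    Vother <- if (nc == 2L) V[3 - i] else 0
    gtot <- params$g_L[i] + g_ext[i] + gt + gc
    num <- params$g_L[i] * params$E_L + g_ext[i] * E_ext + gtE +
      gc * Vother + I_ext[i] - (if (i == 1L) w else 0)
    vinf <- num / gtot
    Vnew[i] <- vinf + (V[i] - vinf) * exp(-dt * gtot / params$C_m[i])
  }
  refr <- state$refr
  if (refr > 0) {
    refr <- refr - dt
    Vnew[1] <- params$V_reset
  } else if (Vnew[1] >= params$V_th) {
    spike <- TRUE
    Vnew[1] <- params$V_reset
    refr <- params$t_ref
    w <- w + params$w_adapt
  }
  list(V = Vnew, w = w, refr = refr, spike = spike)
}

#' Simulate a single neuron with constant or pre-sampled input
#'
#' Convenience loop over [step_neuron()]; used in tests as an oracle for
#' inter-spike intervals and for cross-checking the network engine.
#'
#' @inheritParams step_neuron
#' @param duration simulated time (ms).
#' @param I_ext constant current (pA) per compartment, or a matrix
#'   (steps x compartments) of pre-sampled currents.
#' @param g_ext as `I_ext`, conductance drive (nS).
#' @return list with `spikes` (ms) and the voltage trace matrix `V`.
#' @export
simulate_neuron <- function(params, duration, dt = 0.1, I_ext = 0,
                            g_ext = 0, E_ext = 0, tonic = NULL) {
  nsteps <- round(duration / dt)
  nc <- params$n_comp
  Imat <- if (is.matrix(I_ext)) I_ext else
    matrix(rep_len(I_ext, nc), nsteps, nc, byrow = TRUE)
  gmat <- if (is.matrix(g_ext)) g_ext else
    matrix(rep_len(g_ext, nc), nsteps, nc, byrow = TRUE)
  state <- list(V = rep(params$E_L, nc), w = 0, refr = 0)
  Vtrace <- matrix(NA_real_, nsteps, nc)
  spikes <- numeric(0)
  for (s in seq_len(nsteps)) {
    state <- step_neuron(state, params, I_ext = Imat[s, ], dt = dt,
                         g_ext = gmat[s, ], E_ext = E_ext, tonic = tonic)
    Vtrace[s, ] <- state$V
    if (state$spike) spikes <- c(spikes, s * dt)
  }
  list(spikes = spikes, V = Vtrace)
}
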