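#' Somatic voltage-clamp protocol
#'
#' Emulates the in-vitro tonic-current protocol: high-chloride internal
#' solution (GABA-A reversal -5 mV), holding potential -75 mV, and three
#' conditions (GABA, alpha5-PAM + GABA, picrotoxin).  Currents are reported
#' relative to the picrotoxin condition, where the tonic conductance is
#' zero.
#'
#' @param V_hold holding potential (mV).
#' @param E_GABA chloride reversal under the recording solution (mV).
#' @param targets target current magnitudes (pA), named `GABA` and `a5pam`;
#'   the picrotoxin reference is 0 by construction.
#' @return object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(V_hold = -75, E_GABA = -5,
                           targets = c(GABA = -65.9, a5pam = -95.3)) {
  structure(list(V_hold = V_hold, E_GABA = E_GABA, targets = targets),
            class = "clamp_protocol")
}

# steady-state apical voltage of a clamped two-compartment passive neuron
steady_apical_V <- function(neuron, Gt_a_nS, tc, gc, V_hold) {
  f <- function(V) {
    neuron$g_L[2] * (V - neuron$E_L) +
      Gt_a_nS * tonic_rectification(V, tc) * (V - tc$E_GABA) +
      gc * (V - V_hold)
  }
  stats::uniroot(f, lower = -150, upper = 60, tol = 1e-10)$root
}

#' Steady-state somatic clamp current
#'
#' Solves the passive steady state of the neuron with the soma clamped at
#' the holding potential (spiking disabled) and returns the electrode
#' current relative to the zero-conductance (picrotoxin) condition.
#'
#' @param neuron a [pyr_params()] or [interneuron_params()].
#' @param G_tonic tonic conductance density (mS/cm^2), scalar (uniform) or
#'   one value per compartment.
#' @param proto a [clamp_protocol()].
#' @param rect rectification parameters (`V_half`, `k`, `f_min`).
#' @param apical_scale extra multiplicative factor on the apical tonic
#'   conductance (models the alpha5-PAM modulation during fitting).
#' @return relative clamp current (pA); negative is inward.
#' @export
run_voltage_clamp <- function(neuron, G_tonic, proto = clamp_protocol(),
                              rect = list(V_half = -50, k = 10,
                                          f_min = 0.4),
                              apical_scale = 1) {
  stopifnot(inherits(neuron, "neuron_params"))
  nc <- neuron$n_comp
  G <- rep_len(G_tonic, nc)
  tc <- tonic_conductance(1, E_GABA = proto$E_GABA, V_half = rect$V_half,
                          k = rect$k, f_min = rect$f_min)
  Vh <- proto$V_hold
  electrode_current <- function(Gs, Ga) {
    # currents out of the clamped soma; the electrode supplies their sum
    i_s <- neuron$g_L[1] * (Vh - neuron$E_L) +
      Gs * tonic_rectification(Vh, tc) * (Vh - proto$E_GABA)
    if (nc == 2L) {
      Va <- steady_apical_V(neuron, Ga, tc, neuron$g_c, Vh)
      i_s <- i_s + neuron$g_c * (Vh - Va)
    }
    i_s
  }
  Gs_nS <- G[1] * neuron$area_cm2[1] * 1e6
  Ga_nS <- if (nc == 2L) G[2] * neuron$area_cm2[2] * 1e6 * apical_scale
           else 0
  electrode_current(Gs_nS, Ga_nS) - electrode_current(0, 0)
}

#' Fit the tonic conductance to a clamp current target
#'
#' Finds the uniform tonic conductance density reproducing the target
#' relative clamp current, by bracketed root finding (the clamp current is
#' monotone in the conductance, so the root is unique).
#'
#' @inheritParams run_voltage_clamp
#' @param target target relative current (pA, negative = inward).
#' @param tol_pA residual tolerance (pA).
#' @return list with `G_tonic` (mS/cm^2), `current` and `residual` (pA).
#' @export
fit_tonic_conductance <- function(neuron, target, proto = clamp_protocol(),
                                  rect = list(V_half = -50, k = 10,
                                              f_min = 0.4),
                                  tol_pA = 0.1) {
  if (abs(target) == 0)
    return(list(G_tonic = 0, current = 0, residual = 0))
  tc <- tonic_conductance(1, E_GABA = proto$E_GABA, V_half = rect$V_half,
                          k = rect$k, f_min = rect$f_min)
  area_tot <- sum(neuron$area_cm2) * 1e6
  G0 <- abs(target) /
    (tonic_rectification(proto$V_hold, tc) *
       abs(proto$V_hold - proto$E_GABA) * area_tot)
  f <- function(G) run_voltage_clamp(neuron, G, proto, rect) - target
  lo <- 0; hi <- 10 * G0
  if (f(lo) * f(hi) > 0)
    stop(sprintf(
      "target %.2f pA unreachable in bracket: currents %.2f to %.2f pA",
      target, f(lo) + target, f(hi) + target))
  r <- stats::uniroot(f, lower = lo, upper = hi, tol = G0 * 1e-8)
  cur <- run_voltage_clamp(neuron, r$root, proto, rect)
  if (abs(cur - target) > tol_pA)
    stop("clamp fit did not converge below the residual tolerance")
  list(G_tonic = r$root, current = cur, residual = cur - target)
}

#' Fit the apical PAM modulation factor
#'
#' Given the baseline fitted conductance, finds the apical-only
#' multiplicative factor such that the relative clamp current equals
#' `target_ratio` times the baseline current.  In the single-compartment
#' limit the factor equals the current ratio exactly; with finite
#' somato-apical coupling the dendritic voltage change attenuates the
#' somatically measured current, so the fitted factor exceeds the ratio.
#'
#' @inheritParams run_voltage_clamp
#' @param G_baseline baseline tonic conductance density (mS/cm^2).
#' @param target_ratio target current-magnitude ratio (> 1); default the
#'   1.52 per-cell paired increase (the ratio of printed mean currents,
#'   95.3/65.9 = 1.446, is also supported; both are documented).
#' @param tol relative residual tolerance.
#' @return list with `factor`, `current`, `baseline_current`, `ratio`.
#' @export
fit_pam_factor <- function(neuron, G_baseline,
                           target_ratio = 1.52,
                           proto = clamp_protocol(),
                           rect = list(V_half = -50, k = 10, f_min = 0.4),
                           tol = 1e-3) {
  if (target_ratio < 1)
    stop("PAM must increase the current magnitude (ratio >= 1)")
  base <- run_voltage_clamp(neuron, G_baseline, proto, rect)
  if (neuron$n_comp == 1L) {
    # current is linear in the (single) conductance at fixed V_hold
    fac <- target_ratio
    cur <- base * target_ratio
    return(list(factor = fac, current = cur, baseline_current = base,
                ratio = cur / base))
  }
  f <- function(fac)
    run_voltage_clamp(neuron, G_baseline, proto, rect,
                      apical_scale = fac) - target_ratio * base
  hi <- 20 * target_ratio
  if (f(1) * f(hi) > 0)
    stop("target ratio unreachable with apical-only scaling")
  r <- stats::uniroot(f, lower = 1, upper = hi, tol = 1e-9)
  cur <- run_voltage_clamp(neuron, G_baseline, proto, rect,
                           apical_scale = r$root)
  if (abs(cur / base - target_ratio) > tol * target_ratio)
    stop("PAM factor fit did not converge")
  list(factor = r$root, current = cur, baseline_current = base,
       ratio = cur / base)
}
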