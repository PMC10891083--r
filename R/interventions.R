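#' Depression transform: 40% loss of SST-mediated inhibition
#'
#' Scales every SST synaptic conductance (onto all cell types) by 0.6,
#' scales the Pyr apical tonic conductance by 0.6, and reduces each
#' interneuron's tonic conductance by 40% of its configured SST-contribution
#' fraction.  Applying the transform twice is an error.
#'
#' @param circuit a healthy [build_circuit()] result.
#' @return the transformed circuit, condition `"mdd"`.
#' @export
apply_depression <- function(circuit) {
  stopifnot(inherits(circuit, "circuit"))
  if ("depression" %in% circuit$interventions)
    stop("depression transform already applied")
  for (i in seq_along(circuit$classes)) {
    if (circuit$classes[[i]]$pre == "SST")
      circuit$classes[[i]]$g_syn <- circuit$classes[[i]]$g_syn * 0.6
  }
  circuit$tonic_scale$Pyr[2] <- circuit$tonic_scale$Pyr[2] * 0.6
  fr <- circuit$config$sst_tonic_frac
  for (ty in c("SST", "PV", "VIP"))
    circuit$tonic_scale[[ty]] <- circuit$tonic_scale[[ty]] * (1 - 0.4 * fr)
  circuit$interventions <- c(circuit$interventions, "depression")
  circuit$condition <- "mdd"
  circuit
}

#' Alpha5-selective PAM transform
#'
#' Boosts the targets of alpha5-containing GABA-A receptors only: the Pyr
#' apical tonic conductance and the SST to Pyr synaptic conductance, both by
#' `1 + dose * m` where `m = 0.6` is the modulation estimated for the
#' reference dose.  Nothing else is touched (alpha5 expression in
#' interneurons is negligible).  Composes only after [apply_depression()]
#' or on a healthy circuit; applying it twice is an error.
#'
#' @param circuit a circuit.
#' @param dose dose as a fraction of the reference dose (`1` = reference;
#'   the dose-response experiments sweep 0.25 to 1.5).
#' @param m reference modulation (fractional conductance increase).
#' @return the transformed circuit.
#' @export
apply_a5pam <- function(circuit, dose = 1, m = 0.6) {
  stopifnot(inherits(circuit, "circuit"))
  if (dose < 0) stop("dose must be non-negative")
  if (any(grepl("pam", circuit$interventions)))
    stop("a PAM transform was already applied")
  f <- 1 + dose * m
  for (i in seq_along(circuit$classes)) {
    cl <- circuit$classes[[i]]
    if (cl$pre == "SST" && cl$post == "Pyr")
      circuit$classes[[i]]$g_syn <- cl$g_syn * f
  }
  circuit$tonic_scale$Pyr[2] <- circuit$tonic_scale$Pyr[2] * f
  circuit$interventions <- c(circuit$interventions,
                             sprintf("a5pam:%g", dose))
  circuit$condition <- if ("depression" %in% circuit$interventions)
    sprintf("mdd+a5pam:%g%%", dose * 100) else
    sprintf("a5pam:%g%%", dose * 100)
  circuit
}

#' Non-selective PAM transform
#'
#' Benzodiazepine-like modulation: every inhibitory synaptic conductance and
#' every tonic conductance in the circuit is scaled by `1 + m` (60% boost at
#' the estimated reference modulation).  Excitatory conductances are
#' untouched.
#'
#' @inheritParams apply_a5pam
#' @return the transformed circuit.
#' @export
apply_nonselective_pam <- function(circuit, m = 0.6) {
  stopifnot(inherits(circuit, "circuit"))
  if (any(grepl("pam", circuit$interventions)))
    stop("a PAM transform was already applied")
  f <- 1 + m
  for (i in seq_along(circuit$classes)) {
    if (circuit$classes[[i]]$E_syn < circuit$config$neurons$Pyr$V_th)
      circuit$classes[[i]]$g_syn <- circuit$classes[[i]]$g_syn * f
  }
  for (ty in names(circuit$tonic_scale))
    circuit$tonic_scale[[ty]] <- circuit$tonic_scale[[ty]] * f
  circuit$interventions <- c(circuit$interventions, "nspam")
  circuit$condition <- if ("depression" %in% circuit$interventions)
    "mdd+nspam" else "nspam"
  circuit
}

#' Apply a named condition to a healthy circuit
#'
#' Parses condition labels of the form `healthy`, `mdd`,
#' `mdd+a5pam:<dose%>` or `mdd+nspam` and applies the corresponding
#' transform chain (depression first, then the PAM).
#'
#' @param circuit a healthy circuit.
#' @param condition condition label.
#' @return the transformed circuit.
#' @export
apply_condition <- function(circuit, condition) {
  if (condition == "healthy") return(circuit)
  if (condition == "mdd") return(apply_depression(circuit))
  if (condition == "mdd+nspam")
    return(apply_nonselective_pam(apply_depression(circuit)))
  m <- regmatches(condition,
                  regexec("^mdd\\+a5pam:([0-9.]+)%?$", condition))[[1]]
  if (length(m) == 2)
    return(apply_a5pam(apply_depression(circuit),
                       dose = as.numeric(m[2]) / 100))
  stop("unknown condition label: ", condition)
}

#' Total inhibitory synaptic conductance bookkeeping
#'
#' Sum over all inhibitory connection classes of `g_syn` times the realized
#' edge count; used to audit the intervention arithmetic.
#'
#' @param circuit a circuit.
#' @return total inhibitory peak conductance (nS).
#' @export
total_inhibitory_conductance <- function(circuit) {
  tot <- 0
  for (cl in circuit$classes)
    if (cl$E_syn < circuit$config$neurons$Pyr$V_th)
      tot <- tot + cl$g_syn * length(cl$pre_edges)
  tot
}
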