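#' Default connection-class table
#'
#' Connection probabilities and peak conductances for the reduced circuit.
#' These are calibration-based defaults (chosen so the healthy baseline Pyr
#' rate falls in the 0.5-1 Hz band with interneurons firing faster), all
#' overridable through [circuit_config()].  Targets encode the dendritic
#' logic the interventions rely on: SST inhibits Pyr apically, PV
#' perisomatically, recurrent excitation contacts both trees.
#'
#' @return data.frame with columns `pre`, `post`, `target`, `p`, `g_syn`,
#'   `tau_r`, `tau_d`, `E_syn`.
#' @export
default_connectivity <- function() {
  tab <- rbind(
    data.frame(pre = "Pyr", post = c("Pyr", "SST", "PV", "VIP"),
               target = c("both", "somatic", "somatic", "somatic"),
               p = c(0.15, 0.30, 0.30, 0.30),
               g_syn = c(0.4, 0.6, 0.6, 0.6),
               tau_r = 0.5, tau_d = 3, E_syn = 0),
    data.frame(pre = "SST", post = c("Pyr", "PV", "VIP"),
               target = c("apical", "somatic", "somatic"),
               p = c(0.30, 0.25, 0.25),
               g_syn = c(1.5, 2.0, 1.5),
               tau_r = 1, tau_d = c(10, 10, 10), E_syn = -80),
    data.frame(pre = "PV", post = c("Pyr", "PV"),
               target = "somatic", p = c(0.35, 0.30),
               g_syn = c(1.4, 4.0), tau_r = 0.5, tau_d = 8, E_syn = -80),
    data.frame(pre = "VIP", post = c("SST", "PV"),
               target = "somatic", p = c(0.45, 0.20),
               g_syn = c(1.5, 1.5), tau_r = 1, tau_d = 10, E_syn = -80))
  rownames(tab) <- NULL
  tab
}

#' Circuit configuration
#'
#' Collects everything needed to build and run a reduced microcircuit:
#' population sizes (1000 neurons at full scale, 80% Pyr, 5% SST, 7% PV,
#' 8% VIP), connection classes, tonic-conductance map, background-drive
#' magnitudes and the integration settings.  The desk-scale default is
#' `s = 0.2` (200 neurons); the full scale remains available with `s = 1`.
#'
#' @param N_total nominal neuron count at full scale.
#' @param s scale factor in (0, 1]; counts are `round(fraction * N_total * s)`.
#' @param fractions named population fractions summing to 1.
#' @param connectivity connection-class table, see [default_connectivity()].
#' @param g_ou named per-population base OU conductance magnitude g (nS);
#'   the per-process mean and SD are `g * exp(X_relative)`.
#' @param m_ou background multiplier applied to the Pyr drive (1, 3 or 6 in
#'   the activity-state experiments).
#' @param tau_ou OU correlation time (ms).
#' @param E_exc excitatory reversal of the OU drive (mV).
#' @param G_tonic tonic conductance density (mS/cm^2) applied to every
#'   compartment of every population; `NULL` fits it to the voltage-clamp
#'   current target via [fit_tonic_conductance()] (see vignette).
#' @param E_GABA_tonic physiological tonic reversal in the circuit (mV).
#' @param rect rectification parameters, list with `V_half`, `k`, `f_min`.
#' @param sst_tonic_frac assumed SST contribution to interneuron tonic
#'   inhibition (fraction), used by the depression transform.
#' @param duration,dt simulation length and step (ms).
#' @param volume_um tissue volume (x, y, z extent in um) used for neuron
#'   positions (dipole-orientation bookkeeping only).
#' @param neurons optional list of neuron parameter overrides per population.
#' @return object of class `circuit_config`.
#' @export
circuit_config <- function(N_total = 1000, s = 0.2,
                           fractions = c(Pyr = 0.80, SST = 0.05, PV = 0.07,
                                         VIP = 0.08),
                           connectivity = default_connectivity(),
                           g_ou = c(Pyr = 0.420, SST = 1.050, PV = 1.512,
                                    VIP = 0.765),
                           m_ou = 1, tau_ou = 3, E_exc = 0,
                           G_tonic = NULL, E_GABA_tonic = -75,
                           rect = list(V_half = -50, k = 10, f_min = 0.4),
                           sst_tonic_frac = 0.15,
                           duration = 4500, dt = 0.1,
                           volume_um = c(500, 500, 950),
                           neurons = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("population fractions must sum to 1")
  if (s <= 0 || s > 1) stop("scale factor s must lie in (0, 1]")
  if (any(connectivity$p < 0 | connectivity$p > 1))
    stop("connection probabilities must lie in [0, 1]")
  if (m_ou <= 0) stop("m_ou must be positive")
  pars <- list(
    Pyr = pyr_params(),
    SST = interneuron_params("SST"),
    PV = interneuron_params("PV"),
    VIP = interneuron_params("VIP"))
  if (!is.null(neurons))
    for (nm in names(neurons)) pars[[nm]] <- neurons[[nm]]
  if (is.null(G_tonic))
    G_tonic <- fit_tonic_conductance(pars$Pyr, target = -65.9,
                                     proto = clamp_protocol(),
                                     rect = rect)$G_tonic
  structure(list(N_total = N_total, s = s, fractions = fractions,
                 connectivity = connectivity, g_ou = g_ou, m_ou = m_ou,
                 tau_ou = tau_ou, E_exc = E_exc, G_tonic = G_tonic,
                 E_GABA_tonic = E_GABA_tonic, rect = rect,
                 sst_tonic_frac = sst_tonic_frac, duration = duration,
                 dt = dt, volume_um = volume_um, neurons = pars),
            class = "circuit_config")
}

#' Population counts for a configuration
#'
#' @param cfg a [circuit_config()].
#' @return named integer vector of neuron counts per population.
#' @export
population_counts <- function(cfg) {
  n <- round(cfg$fractions * cfg$N_total * cfg$s)
  storage.mode(n) <- "integer"
  n
}

#' Distance scaling of the background drive
#'
#' Mean and SD of the excitatory Ornstein-Uhlenbeck conductance both equal
#' `g * exp(X_relative)`, increasing with relative distance from the soma.
#' The inhibitory OU conductance is zero throughout.
#'
#' @param g base magnitude (nS), non-negative.
#' @param X_relative relative distance from soma in `[0, 1]`.
#' @return list with `mean` and `sd` (nS).
#' @export
ou_params <- function(g, X_relative) {
  if (any(g < 0)) stop("g must be non-negative")
  if (any(X_relative < 0 | X_relative > 1))
    stop("X_relative must lie in [0, 1]")
  v <- g * exp(X_relative)
  list(mean = v, sd = v)
}

#' Background-process placement for one neuron type
#'
#' One OU process sits at the midway point of each dendritic compartment;
#' pyramidal apical dendrites additionally receive five processes at
#' relative distances 0.1, 0.3, 0.5, 0.7 and 0.9.  In the two-compartment
#' reduction the apical set is folded into a single effective process whose
#' mean is the sum of the per-process means and whose variance is the sum of
#' the per-process variances (sum of independent OU processes with a common
#' correlation time is again OU).
#'
#' @param type population name.
#' @param g base OU magnitude (nS).
#' @return data.frame with columns `compartment`, `X`, `mean`, `sd` listing
#'   the individual processes before folding.
#' @export
place_ou_processes <- function(type, g) {
  if (type == "Pyr") {
    X <- c(0.5, 0.5, 0.1, 0.3, 0.5, 0.7, 0.9)
    comp <- c("somatic", rep("apical", 6))
  } else {
    X <- 0.5
    comp <- "somatic"
  }
  op <- ou_params(g, X)
  data.frame(compartment = comp, X = X, mean = op$mean, sd = op$sd)
}

fold_ou <- function(proc, compartment) {
  sub <- proc[proc$compartment == compartment, , drop = FALSE]
  if (nrow(sub) == 0) return(list(mean = 0, sd = 0))
  list(mean = sum(sub$mean), sd = sqrt(sum(sub$sd^2)))
}

#' Build a reduced microcircuit
#'
#' Samples Bernoulli connectivity per connection class, neuron positions in
#' the configured volume, folds the tonic-conductance map into absolute
#' conductances and attaches the background drive.  Deterministic given
#' `(cfg, seed)`.
#'
#' @param cfg a [circuit_config()].
#' @param seed integer RNG seed.
#' @return object of class `circuit`.
#' @export
build_circuit <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "circuit_config"))
  set.seed(seed)
  counts <- population_counts(cfg)
  types <- rep(names(counts), counts)
  n <- length(types)
  pos <- cbind(x = stats::runif(n, 0, cfg$volume_um[1]),
               y = stats::runif(n, 0, cfg$volume_um[2]),
               z = stats::runif(n, 0, cfg$volume_um[3]))
  neurons <- data.frame(id = seq_len(n), type = types, pos)

  # split "both"-target classes into somatic and apical halves sharing the
  # same adjacency draw
  classes <- list()
  for (r in seq_len(nrow(cfg$connectivity))) {
    row <- cfg$connectivity[r, ]
    pre_ids <- which(types == row$pre)
    post_ids <- which(types == row$post)
    if (length(pre_ids) == 0 || length(post_ids) == 0) next
    npair <- length(pre_ids) * length(post_ids)
    hit <- stats::runif(npair) < row$p
    pre_e <- rep(pre_ids, each = length(post_ids))[hit]
    post_e <- rep(post_ids, times = length(pre_ids))[hit]
    keep <- pre_e != post_e
    pre_e <- pre_e[keep]; post_e <- post_e[keep]
    mk <- function(target, w) {
      comp <- if (target == "apical") 1L else 0L
      list(pre = row$pre, post = row$post, target = target,
           g_syn = w, tau_r = row$tau_r, tau_d = row$tau_d,
           E_syn = row$E_syn, pre_edges = pre_e, post_edges = post_e,
           comp = comp)
    }
    if (row$target == "both") {
      # recurrent contacts are dendrite-dominant: 3/4 of the peak
      # conductance lands apically, 1/4 on the somatic-basal compartment
      classes <- c(classes, list(mk("somatic", row$g_syn * 0.25),
                                 mk("apical", row$g_syn * 0.75)))
    } else {
      classes <- c(classes, list(mk(row$target, row$g_syn)))
    }
  }

  # tonic map: absolute nS per neuron/compartment, same density everywhere
  tonic <- list()
  for (ty in names(counts)) {
    p <- cfg$neurons[[ty]]
    g_abs <- cfg$G_tonic * p$area_cm2 * 1e6  # mS/cm2 * cm2 -> nS
    tonic[[ty]] <- g_abs
  }

  # background drive (folded per compartment)
  ou <- list()
  for (ty in names(counts)) {
    g <- cfg$g_ou[[ty]]
    if (ty == "Pyr") g <- g * cfg$m_ou
    proc <- place_ou_processes(ty, g)
    ou[[ty]] <- list(somatic = fold_ou(proc, "somatic"),
                     apical = fold_ou(proc, "apical"))
  }

  structure(list(config = cfg, seed = seed, neurons = neurons,
                 counts = counts, classes = classes, tonic = tonic,
                 ou = ou, stimulus = NULL, condition = "healthy",
                 tonic_scale = lapply(tonic, function(x) x * 0 + 1),
                 interventions = character(0)),
            class = "circuit")
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", sum(x$counts), " neurons (",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "), condition: ", x$condition, "\n", sep = "")
  invisible(x)
}

#' Stimulus protocol
#'
#' Brief afferent volley reproducing the response protocol: excitatory
#' synapses delivered to subsets of Pyr (basal or apical target), PV and
#' two VIP groups, with uniform delays inside per-group windows.  Counts
#' refer to the full-scale circuit and are scaled by `s` (rounding half-up,
#' minimum 1) when attached.
#'
#' @param target `"basal"` (55 Pyr on the somatic-basal compartment) or
#'   `"apical"` (85 Pyr on the apical compartment).
#' @param onset stimulus onset time (ms).
#' @param g_stim stimulus synapse kinetics: excitatory, with a slow
#'   NMDA-like decay so one afferent volley drives the response window.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target = c("basal", "apical"), onset = 4000,
                              g_stim = list(tau_r = 1, tau_d = 6,
                                            E_syn = 0)) {
  target <- match.arg(target)
  pyr <- if (target == "basal")
    data.frame(pop = "Pyr", comp = "somatic", count = 55, d_lo = 2,
               d_hi = 4, g = 4)
  else
    data.frame(pop = "Pyr", comp = "apical", count = 85, d_lo = 2,
               d_hi = 4, g = 4)
  groups <- rbind(
    pyr,
    data.frame(pop = "PV", comp = "somatic", count = 35, d_lo = 2,
               d_hi = 2.5, g = 2),
    data.frame(pop = "VIP", comp = "somatic", count = 65, d_lo = 0.5,
               d_hi = 4.5, g = 2.8),
    data.frame(pop = "VIP", comp = "somatic", count = 80, d_lo = 7,
               d_hi = 12, g = 2.2))
  if (any(groups$d_hi < groups$d_lo)) stop("empty delay window")
  structure(list(target = target, onset = onset, groups = groups,
                 g_stim = g_stim),
            class = "stimulus_protocol")
}

#' Attach a stimulus to a circuit
#'
#' Each stimulated group receives one stimulus synapse per sampled neuron
#' (without replacement within a group), with delay drawn uniformly from the
#' group's window.  Counts scale with the circuit's scale factor.
#'
#' @param circuit a [build_circuit()] result.
#' @param proto a [stimulus_protocol()].
#' @param seed RNG seed for the stimulated-subset draw.
#' @return the circuit with a `stimulus` table attached.
#' @export
attach_stimulus <- function(circuit, proto, seed = 1) {
  stopifnot(inherits(circuit, "circuit"),
            inherits(proto, "stimulus_protocol"))
  set.seed(seed)
  s <- circuit$config$s
  rows <- list()
  for (g in seq_len(nrow(proto$groups))) {
    gr <- proto$groups[g, ]
    cnt <- max(1L, as.integer(floor(gr$count * s + 0.5)))
    ids <- circuit$neurons$id[circuit$neurons$type == gr$pop]
    if (cnt > length(ids))
      stop("stimulated count exceeds population size for ", gr$pop)
    chosen <- sample(ids, cnt)
    delay <- stats::runif(cnt, gr$d_lo, gr$d_hi)
    rows[[g]] <- data.frame(neuron = chosen, comp = gr$comp,
                            time = proto$onset + delay, w = gr$g)
  }
  stimtab <- do.call(rbind, rows)
  stimtab <- stimtab[order(stimtab$time), ]
  circuit$stimulus <- stimtab
  circuit$stim_onset <- proto$onset
  circuit$stim_kinetics <- proto$g_stim
  circuit
}

# assemble the flat argument list consumed by the compiled engine
build_engine_net <- function(circuit) {
  cfg <- circuit$config
  types <- circuit$neurons$type
  n <- nrow(circuit$neurons)
  getp <- function(field, comp) {
    vapply(types, function(ty) {
      p <- cfg$neurons[[ty]]
      v <- p[[field]]
      if (length(v) == 2) v[comp] else if (comp == 1) v else 0
    }, numeric(1))
  }
  two_comp <- types == "Pyr"
  Gt_s <- numeric(n); Gt_a <- numeric(n)
  for (i in seq_len(n)) {
    g <- circuit$tonic[[types[i]]] * circuit$tonic_scale[[types[i]]]
    Gt_s[i] <- g[1]
    Gt_a[i] <- if (length(g) == 2) g[2] else 0
  }
  ou_ms <- numeric(n); ou_ss <- numeric(n)
  ou_ma <- numeric(n); ou_sa <- numeric(n)
  for (i in seq_len(n)) {
    o <- circuit$ou[[types[i]]]
    ou_ms[i] <- o$somatic$mean; ou_ss[i] <- o$somatic$sd
    ou_ma[i] <- o$apical$mean; ou_sa[i] <- o$apical$sd
  }
  classes <- lapply(circuit$classes, function(cl) {
    o <- order(cl$pre_edges)
    pre <- cl$pre_edges[o] - 1L
    tgt <- cl$post_edges[o] - 1L
    ptr <- c(0L, cumsum(tabulate(pre + 1L, nbins = n)))
    list(ptr = as.integer(ptr), tgt = as.integer(tgt), w = cl$g_syn,
         tau_r = cl$tau_r, tau_d = cl$tau_d, E_syn = cl$E_syn,
         comp = cl$comp)
  })
  if (is.null(circuit$stimulus)) {
    stim <- list(neuron = integer(0), comp = integer(0), time = numeric(0),
                 w = numeric(0), tau_r = 0.5, tau_d = 3, E_syn = 0)
  } else {
    st <- circuit$stimulus
    stim <- list(neuron = as.integer(st$neuron - 1L),
                 comp = as.integer(st$comp == "apical"),
                 time = st$time, w = st$w,
                 tau_r = circuit$stim_kinetics$tau_r,
                 tau_d = circuit$stim_kinetics$tau_d,
                 E_syn = circuit$stim_kinetics$E_syn)
  }
  list(n = n, type = match(types, c("Pyr", "SST", "PV", "VIP")) - 1L,
       two_comp = two_comp,
       Cm_s = getp("C_m", 1), Cm_a = getp("C_m", 2),
       gL_s = getp("g_L", 1), gL_a = getp("g_L", 2),
       EL = getp("E_L", 1), Vth = getp("V_th", 1),
       Vreset = getp("V_reset", 1), tref = getp("t_ref", 1),
       gc = getp("g_c", 1),
       w_adapt = getp("w_adapt", 1), tau_adapt = getp("tau_adapt", 1),
       bap_g = vapply(types, function(ty) {
         v <- cfg$neurons[[ty]]$bap_g
         if (is.null(v)) 0 else v
       }, numeric(1)),
       bap_tau = vapply(types, function(ty) {
         v <- cfg$neurons[[ty]]$bap_tau
         if (is.null(v)) 1 else v
       }, numeric(1)),
       Gt_s = Gt_s, Gt_a = Gt_a,
       E_gaba = cfg$E_GABA_tonic, V_half = cfg$rect$V_half,
       k_rect = cfg$rect$k, f_min = cfg$rect$f_min,
       ou_mean_s = ou_ms, ou_sd_s = ou_ss,
       ou_mean_a = ou_ma, ou_sd_a = ou_sa,
       tau_ou = cfg$tau_ou, E_exc = cfg$E_exc,
       classes = classes, stim = stim,
       pyr_idx = as.integer(which(two_comp) - 1L))
}

#' Simulate a circuit
#'
#' Runs the compiled fixed-step exponential-Euler engine and returns spikes
#' plus, optionally, the somato-apical coupling (axial) current of the Pyr
#' population for dipole construction.  Deterministic given `seed`.
#'
#' @param circuit a built circuit (optionally with stimulus attached).
#' @param duration,dt simulated time and step (ms); default from the config.
#' @param seed RNG seed for background noise.
#' @param record_axial `"none"`, `"sum"` (population-summed axial current)
#'   or `"matrix"` (one row per Pyr neuron; memory-hungry, small runs only).
#' @param downsample keep every `downsample`-th axial sample.
#' @return object of class `spike_data`: list with `spikes` (data.frame
#'   `neuron_id`, `type`, `time_ms`), `duration`, `dt`, `onset`, `counts`,
#'   `condition`, and (if recorded) `axial` with sampling rate `fs` (Hz).
#' @export
simulate_circuit <- function(circuit, duration = NULL, dt = NULL, seed = 1,
                             record_axial = c("none", "sum", "matrix"),
                             downsample = 1L) {
  stopifnot(inherits(circuit, "circuit"))
  record_axial <- match.arg(record_axial)
  cfg <- circuit$config
  if (is.null(duration)) duration <- cfg$duration
  if (is.null(dt)) dt <- cfg$dt
  if (duration <= 0) stop("duration must be positive")
  net <- build_engine_net(circuit)
  mode <- match(record_axial, c("none", "sum", "matrix")) - 1L
  set.seed(seed)
  res <- .sim_engine(net, duration, dt, mode, as.integer(downsample))
  ord <- order(res$spike_t, res$spike_id)
  spikes <- data.frame(neuron_id = res$spike_id[ord],
                       type = circuit$neurons$type[res$spike_id[ord]],
                       time_ms = res$spike_t[ord])
  out <- list(spikes = spikes, duration = duration, dt = dt,
              onset = circuit$stim_onset, counts = circuit$counts,
              condition = circuit$condition, seed = seed)
  if (record_axial != "none") {
    out$axial <- res$axial
    out$fs <- 1000 / (dt * downsample)
  }
  structure(out, class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat("<spike_data> ", nrow(x$spikes), " spikes, ", x$duration,
      " ms, condition: ", x$condition, "\n", sep = "")
  invisible(x)
}

#' Population firing rate from spike data
#'
#' @param sd a `spike_data` object.
#' @param population population name.
#' @param interval time interval `c(lo, hi)` in ms; defaults to the full run.
#' @return mean rate in Hz per neuron.
#' @export
population_rate <- function(sd, population = "Pyr", interval = NULL) {
  if (is.null(interval)) interval <- c(0, sd$duration)
  sp <- sd$spikes
  k <- sum(sp$type == population & sp$time_ms > interval[1] &
             sp$time_ms <= interval[2])
  k / (sd$counts[[population]] * diff(interval) / 1000)
}

#' Write / read spike data (CSV plus JSON sidecar)
#'
#' @param sd a `spike_data` object.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `write_spike_data` returns `path` invisibly; `read_spike_data`
#'   returns a `spike_data` object.
#' @export
write_spike_data <- function(sd, path) {
  utils::write.csv(sd$spikes, path, row.names = FALSE)
  meta <- list(duration = sd$duration, dt = sd$dt, onset = sd$onset,
               counts = as.list(sd$counts), condition = sd$condition,
               seed = sd$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(path) {
  spikes <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(spikes = spikes, duration = meta$duration, dt = meta$dt,
                 onset = meta$onset, counts = unlist(meta$counts),
                 condition = meta$condition, seed = meta$seed),
            class = "spike_data")
}

#' Write / read a circuit configuration as YAML
#'
#' Serializes the scalar fields and the connectivity table; neuron parameter
#' objects are reconstructed from defaults plus stored overrides.
#'
#' @param cfg a [circuit_config()].
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  out <- list(N_total = cfg$N_total, s = cfg$s,
              fractions = as.list(cfg$fractions),
              connectivity = cfg$connectivity,
              g_ou = as.list(cfg$g_ou), m_ou = cfg$m_ou,
              tau_ou = cfg$tau_ou, E_exc = cfg$E_exc,
              G_tonic = cfg$G_tonic, E_GABA_tonic = cfg$E_GABA_tonic,
              rect = cfg$rect, sst_tonic_frac = cfg$sst_tonic_frac,
              duration = cfg$duration, dt = cfg$dt,
              volume_um = cfg$volume_um)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  circuit_config(N_total = y$N_total, s = y$s,
                 fractions = unlist(y$fractions),
                 connectivity = as.data.frame(y$connectivity),
                 g_ou = unlist(y$g_ou), m_ou = y$m_ou, tau_ou = y$tau_ou,
                 E_exc = y$E_exc, G_tonic = y$G_tonic,
                 E_GABA_tonic = y$E_GABA_tonic, rect = y$rect,
                 sst_tonic_frac = y$sst_tonic_frac, duration = y$duration,
                 dt = y$dt, volume_um = y$volume_um)
}
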