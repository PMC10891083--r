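#' Cohen's d (pooled-SD formula)
#'
#' \deqn{d = (\bar{x} - \bar{y}) / \sqrt{((N_x-1)\sigma_x^2 +
#'   (N_y-1)\sigma_y^2) / (N_x+N_y-2)}}
#' Sign convention: first group minus second group.
#'
#' @param x,y samples.
#' @return effect size d.  Infinite (with a warning) when the pooled SD is
#'   zero but the means differ; zero when both are identical.
#' @export
cohens_d <- function(x, y) {
  cohens_d_summary(mean(x), mean(y), stats::sd(x), stats::sd(y),
                   length(x), length(y))
}

#' @rdname cohens_d
#' @param mx,my group means.
#' @param sx,sy group standard deviations.
#' @param nx,ny group sizes (each at least 2).
#' @export
cohens_d_summary <- function(mx, my, sx, sy, nx, ny) {
  if (nx + ny <= 2) stop("need N_x + N_y > 2")
  sp <- sqrt(((nx - 1) * sx^2 + (ny - 1) * sy^2) / (nx + ny - 2))
  if (sp == 0) {
    if (mx == my) return(0)
    warning("zero pooled SD with unequal means; returning signed infinity")
    return(sign(mx - my) * Inf)
  }
  (mx - my) / sp
}

#' Paired-sample t-test
#'
#' Thin wrapper over [stats::t.test()] (paired); two-sided by default, with
#' the one-sided variants available for directional comparisons.
#'
#' @param x,y paired samples of equal length (>= 2).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (stats::sd(x - y) == 0 && !all(x == y))
    stop("zero-variance differences")
  if (all(x == y))
    return(list(t = 0, df = length(x) - 1,
                p = if (alternative == "two.sided") 1 else 0.5))
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Dose-response curve fitting
#'
#' Least-squares fits of linear (`a + b x`), exponential
#' (`a + b exp(c x)`) and sigmoid (`a + b / (1 + exp(-(x - x0)/s))`)
#' models, with sums of squared errors, relative SSE improvements over the
#' linear fit, and the two-sided Pearson correlation of the linear
#' relation.  Non-convergent nonlinear fits are flagged (`NA` SSE); the
#' linear fit is always returned.
#'
#' @param doses dose values (fraction of the reference dose).
#' @param values metric values, same length (>= 3; >= 4 for the sigmoid).
#' @return object of class `dose_response`.
#' @export
fit_dose_response <- function(doses, values) {
  if (length(doses) != length(values) || length(doses) < 3)
    stop("need >= 3 (dose, value) points")
  if (stats::sd(values) == 0)
    stop("constant values: correlation undefined")
  lin <- stats::lm(values ~ doses)
  sse_lin <- sum(stats::resid(lin)^2)
  ct <- stats::cor.test(doses, values, alternative = "two.sided")

  fit_try <- function(expr) tryCatch(expr, error = function(e) NULL)
  b0 <- unname(stats::coef(lin)[2])
  expf <- fit_try(minpack.lm::nlsLM(
    values ~ a + b * exp(cc * doses),
    start = list(a = min(values), b = max(b0, 1e-6), cc = 0.5),
    control = minpack.lm::nls.lm.control(maxiter = 200)))
  if (is.null(expf))
    expf <- fit_try(minpack.lm::nlsLM(
      values ~ a + b * exp(cc * doses),
      start = list(a = max(values), b = min(b0, -1e-6), cc = 0.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)))
  sig <- NULL
  if (length(doses) >= 4)
    sig <- fit_try(minpack.lm::nlsLM(
      values ~ a + b / (1 + exp(-(doses - x0) / s)),
      start = list(a = min(values), b = diff(range(values)),
                   x0 = stats::median(doses),
                   s = diff(range(doses)) / 4),
      lower = c(-Inf, -Inf, min(doses) - 1, 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 300)))
  sse_exp <- if (is.null(expf)) NA_real_ else
    sum(stats::resid(expf)^2)
  sse_sig <- if (is.null(sig)) NA_real_ else sum(stats::resid(sig)^2)
  structure(list(
    linear = lin, exponential = expf, sigmoid = sig,
    sse = c(linear = sse_lin, exponential = sse_exp, sigmoid = sse_sig),
    improvement = c(exponential = 1 - sse_exp / sse_lin,
                    sigmoid = 1 - sse_sig / sse_lin),
    pearson_r = unname(ct$estimate), pearson_p = ct$p.value),
    class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> Pearson r = %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_p))
  print(round(x$sse, 6))
  invisible(x)
}

# deterministic child seed for (condition independent) seed index
child_seed <- function(master, idx) {
  (as.integer(master) * 1009L + idx * 7919L) %% 2147480000L
}

#' Run a condition sweep over randomized circuits
#'
#' For each seed index a healthy circuit structure is built (shared across
#' conditions, so conditions are paired by seed), each condition's
#' conductance transform is applied, and the circuit is simulated.  Rate,
#' detection, correlation and (optionally) EEG/spectral metrics are
#' collected into a tidy table.
#'
#' Detection metrics follow the pooled protocol of [detection_analysis()]
#' and are computed per condition across the sweep's seeds.  EEG metrics
#' come from separate resting (stimulus-free) simulations with the axial
#' current recorded.
#'
#' @param cfg a [circuit_config()].
#' @param conditions character vector of condition labels
#'   (`healthy`, `mdd`, `mdd+a5pam:<dose>%`, `mdd+nspam`).
#' @param n_seeds paired seeds per condition.
#' @param seed master seed; per-index child seeds are derived by a fixed
#'   splitting rule.
#' @param metrics subset of `c("rates", "detection", "correlation",
#'   "eeg")`.
#' @param proto stimulus protocol for the response simulations.
#' @param eeg_duration duration of the resting EEG simulations (ms).
#' @param eeg_fs sampling rate of the recorded dipole (Hz).
#' @param model four-sphere model for the EEG forward step.
#' @return list with `results` (condition, seed, metric, value),
#'   `errors` (per-stage failures, if any), and `conditions`.
#' @export
run_condition_sweep <- function(cfg, conditions, n_seeds = 20, seed = 1,
                                metrics = c("rates", "detection"),
                                proto = stimulus_protocol("basal"),
                                eeg_duration = 10000, eeg_fs = 1000,
                                model = four_sphere_model()) {
  rows <- list(); errs <- list()
  addrow <- function(cond, sd, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(
      condition = cond, seed = sd, metric = metric, value = value)
  need_stim <- any(c("rates", "detection") %in% metrics)
  for (cond in conditions) {
    sims <- list()
    for (i in seq_len(n_seeds)) {
      cs <- child_seed(seed, i)
      res <- tryCatch({
        circ <- build_circuit(cfg, seed = cs)
        circ <- apply_condition(circ, cond)
        if (need_stim) circ <- attach_stimulus(circ, proto, seed = cs)
        sim <- simulate_circuit(circ, seed = cs)
        sims[[length(sims) + 1]] <- sim
        if ("rates" %in% metrics) {
          on <- sim$onset
          pre_lo <- max(0, on - 3000)
          addrow(cond, cs, "baseline_rate",
                 population_rate(sim, "Pyr", c(pre_lo, on)))
          addrow(cond, cs, "post_rate",
                 population_rate(sim, "Pyr", on + c(5, 55)))
          for (ty in c("SST", "PV", "VIP"))
            addrow(cond, cs, paste0("baseline_rate_", ty),
                   population_rate(sim, ty, c(pre_lo, on)))
        }
        if ("correlation" %in% metrics) {
          on <- sim$onset
          mc <- mean_pairwise_correlation(sim, bin = 1,
                                          interval = c(max(0, on - 3000),
                                                       on))
          addrow(cond, cs, "spike_correlation", mc$mean_r)
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        errs[[length(errs) + 1]] <- data.frame(condition = cond,
                                               seed = cs, error = res)
    }
    if ("detection" %in% metrics && length(sims) >= 2) {
      det <- tryCatch(detection_analysis(sims), error = function(e) NULL)
      if (!is.null(det)) {
        pc <- det$per_circuit
        for (r in seq_len(nrow(pc))) {
          addrow(cond, pc$seed[r], "p_failed", pc$P_failed[r])
          addrow(cond, pc$seed[r], "p_false", pc$P_false[r])
          addrow(cond, pc$seed[r], "snr", pc$SNR[r])
        }
      } else {
        errs[[length(errs) + 1]] <- data.frame(
          condition = cond, seed = NA, error = "detection stage failed")
      }
    }
    if ("eeg" %in% metrics) {
      for (i in seq_len(n_seeds)) {
        cs <- child_seed(seed, i)
        res <- tryCatch({
          circ <- build_circuit(cfg, seed = cs)
          circ <- apply_condition(circ, cond)
          sim <- simulate_circuit(circ, duration = eeg_duration,
                                  seed = cs, record_axial = "sum",
                                  downsample = round(1000 / cfg$dt /
                                                       eeg_fs))
          dip <- compute_dipole(sim$axial)
          eeg <- foursphere_potential(dip, model)
          psd <- welch_psd(eeg, sim$fs)
          addrow(cond, cs, "theta_power", band_power(psd, c(4, 8)))
          addrow(cond, cs, "alpha_power", band_power(psd, c(8, 12)))
          addrow(cond, cs, "beta_power", band_power(psd, c(12, 21)))
          fit <- fit_spectrum(psd$freq, psd$power)
          addrow(cond, cs, "aperiodic_exponent", fit$exponent)
          addrow(cond, cs, "aperiodic_auc", aperiodic_auc(fit))
          addrow(cond, cs, "periodic_theta",
                 periodic_band_power(fit, c(4, 8)))
          addrow(cond, cs, "periodic_beta",
                 periodic_band_power(fit, c(12, 21)))
          NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(res))
          errs[[length(errs) + 1]] <- data.frame(condition = cond,
                                                 seed = cs, error = res)
      }
    }
  }
  list(results = do.call(rbind, rows),
       errors = if (length(errs)) do.call(rbind, errs) else NULL,
       conditions = conditions)
}

#' Summarize a condition sweep
#'
#' Mean, SD and N per (condition, metric), plus Cohen's d of each condition
#' against the `healthy` and `mdd` reference conditions where present.
#'
#' @param sweep a [run_condition_sweep()] result (or its `results` table).
#' @return data.frame with one row per (condition, metric).
#' @export
summarize_sweep <- function(sweep) {
  res <- if (is.data.frame(sweep)) sweep else sweep$results
  out <- list()
  for (m in unique(res$metric)) {
    sub <- res[res$metric == m, ]
    for (cond in unique(sub$condition)) {
      v <- sub$value[sub$condition == cond]
      row <- data.frame(condition = cond, metric = m, mean = mean(v),
                        sd = stats::sd(v), n = length(v),
                        d_vs_healthy = NA_real_, d_vs_mdd = NA_real_)
      for (ref in c("healthy", "mdd")) {
        if (cond == ref) next
        vr <- sub$value[sub$condition == ref]
        if (length(vr) >= 2 && length(v) >= 2) {
          d <- cohens_d(v, vr)
          if (ref == "healthy") row$d_vs_healthy <- d else
            row$d_vs_mdd <- d
        }
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
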