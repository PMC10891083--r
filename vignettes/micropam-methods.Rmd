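---
title: "Simulating GABAergic modulation of a reduced human cortical microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GABAergic modulation of a reduced human cortical microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`micropam` implements, at desk scale, an in-silico pharmacology pipeline for
layer 2/3 of human cortex: a reduced spiking microcircuit with somatostatin-
(SST), parvalbumin- (PV) and VIP-expressing interneurons, tonic and synaptic
GABA-A inhibition, depression and positive-allosteric-modulator (PAM)
interventions, and the downstream biomarker analyses (signal-detection
metrics on firing-rate distributions, a four-sphere EEG forward model, Welch
spectra, aperiodic/periodic spectral parameterization, wavelet
oscillation-event detection, effect sizes and dose-response fits).

This vignette documents the model, its assumptions, the choices made where
the design was genuinely open, and what the synthetic test fixtures do and do
not establish about real data.

## The reduced circuit

The full-scale circuit has 1000 neurons (80% pyramidal, 5% SST, 7% PV,
8% VIP); the package default is a proportional desk-scale reduction to
`s = 0.2` (200 neurons), which preserves the excitatory-inhibitory balance.
Pyramidal cells are adaptive leaky integrate-and-fire neurons with two
electrically coupled compartments — somatic-basal and apical — because the
pharmacology is compartment-specific: SST synapses and alpha5-sensitive tonic
inhibition live on the apical tree, PV synapses perisomatically, recurrent
excitation on both (three quarters of the recurrent peak conductance is
placed apically, reflecting dendrite-dominant innervation). Interneurons are
single-compartment. Morphologically detailed dynamics, active dendritic
conductances and multi-objective electrophysiology fitting are out of scope.

Each neuron receives an independent excitatory Ornstein-Uhlenbeck (OU)
conductance at the midway point of each dendritic arbor; pyramidal apical
trees receive five additional processes at 10-90% of the apical length.
Process mean and SD both equal `g * exp(X_relative)`; the inhibitory OU
conductance is zero. In the two-compartment reduction the apical set is
folded into one effective OU process with the summed mean and variance (a
sum of independent OU processes with a common correlation time is again OU).
The correlation time defaults to 3 ms, a standard value for point-conductance
background; conductances are clipped at zero during integration.

Tonic GABA-A inhibition is outwardly rectifying,
`r(V) = f_min + (1 - f_min) / (1 + exp(-(V - V_half)/k))`, with defaults
`V_half = -50` mV, `k = 10` mV, `f_min = 0.4`. Only the scalar `r(V_hold)`
matters at a fixed clamp voltage, so the clamp fits are well defined whatever
the curve's exact shape. The circuit's tonic reversal is -75 mV
(physiological chloride); the clamp protocol uses -5 mV (high-chloride
internal solution).

A spike triggers, besides reset and adaptation, a brief excitatory
conductance on the apical compartment (default 200 nS decaying with 2 ms)
that stands in for the back-propagating action potential. In a
two-compartment cell this is the textbook Pinsky-Rinzel device for
regenerative dendritic events; here its load-bearing role is that every
spike deposits a stereotyped somato-apical dipole signature, so the summed
dipole tracks pyramidal spiking and its correlations. Without it the
simulated EEG is dominated by shared inhibitory synaptic currents and the
depression condition would *lower* EEG power, which is the opposite of the
elevation this class of models produces through increased, more correlated
firing.

Integration is fixed-step exponential Euler at `dt = 0.1` ms in compiled
code, with all randomness drawn from R's RNG so runs are bit-reproducible
given a seed.

## Calibration

Connection probabilities, synaptic weights and drive magnitudes are not
published for this circuit family; the shipped defaults were calibrated once,
with the following targets, and are not meant to be re-tuned per analysis:

* healthy baseline pyramidal rate in the 0.5-1 Hz band (~0.75 Hz),
  interneurons faster (SST ~5, PV ~8, VIP ~8 Hz);
* stimulus responses clearly above baseline but overlapping enough for
  detection errors in the percent range;
* the intervention phenomenology below.

The OU base magnitudes are `g = (Pyr 0.420, SST 1.050, PV 1.512,
VIP 0.765)` nS. Membrane areas (used only to fold tonic conductance
densities into nanosiemens) are 0.25e-4 / 1.5e-4 cm^2 for the pyramidal
somatic-basal / apical compartments and 3e-4, 4e-4, 2e-4 cm^2 for SST, PV,
VIP. The circuit's default tonic density is the value fitted by the clamp
module on the reduced neuron itself (~0.017 mS/cm^2), keeping the clamp
protocol and the circuit self-consistent; the published density for the
morphologically detailed model is an order of magnitude larger because it
folds a much larger membrane area and a different rectification curve.

## Interventions

All interventions are multiplicative conductance transforms on a built
circuit, recorded in the circuit's condition label:

* **Depression**: all SST synaptic conductances (onto every cell type)
  x0.6; pyramidal apical tonic conductance x0.6; each interneuron's tonic
  conductance reduced by 40% of its SST-contribution fraction. That
  fraction is not published; the package default is 0.15. (Larger values
  give the depression transform so much interneuron tonic relief that the
  non-selective PAM can no longer leave the baseline rate elevated, which is
  a qualitative result this model family produces.)
* **alpha5-PAM at dose fraction d**: apical tonic and SST->Pyr synaptic
  conductance x`(1 + 0.6 d)`; nothing else (alpha5 subunits are negligible
  in interneurons). The reference modulation 0.6 is the clamp-derived 60%
  conductance increase.
* **Non-selective PAM**: every inhibitory synaptic conductance and every
  tonic conductance x1.6.

Transforms compose only as depression-then-PAM and refuse to be applied
twice.

The stimulus protocol delivers one excitatory synapse to 55 pyramidal cells
(basal; 85 apical in the apical variant), 35 PV and two VIP groups (65
early, 80 late), with published delays and peak conductances; counts scale
with `s` (round half-up, minimum one). The stimulus synapse decays with
6 ms — an effective AMPA+NMDA mixture — so the afferent volley spans the
5-55 ms response window.

## Detection metrics

Pre-stimulus pyramidal population rates are computed in 50 ms windows
sliding by 1 ms over the 3 s before stimulus onset (2951 samples per
circuit) and fitted per circuit with a maximum-likelihood skew-normal. The
post-stimulus distribution pools the single 5-55 ms window across circuits
and is fitted once per condition (skew-normal, falling back to a normal when
the small-sample MLE degenerates at the optimizer's shape bound). The
decision threshold is the density intersection between the two fitted
distributions (optimal decision theory); failed/false detection rates are
the post mass below and the pre mass above it. SNR is defined as
`(mean(post) - mean(pre)) / sd(pre)`; the mean-ratio variant is available.
Pairwise spike correlations use 1 ms binary bins, skipping and counting
zero-variance trains.

## EEG and spectra

The equivalent dipole is the population sum of somato-apical coupling
currents times a 400 um separation, oriented along the depth axis. The
scalp potential comes from the quasi-static four-sphere model (grey matter,
CSF, skull, scalp; radii 79/80/85/90 mm, conductivities
0.047/1.71/0.02/0.41 S/m), solved per spherical-harmonic order by the
boundary linear system and truncated at 100 terms or a 1e-12 relative tail.
The dipole sits at 78 mm depth beneath a scalp-apex electrode by default
(positions are not published; both are configurable). Welch spectra use
3.5 s Hann segments with 50% overlap and per-segment mean removal, so the
~0.286 Hz resolution is preserved at any sampling rate; band powers are
trapezoidal integrals (theta 4-8, alpha 8-12, lower beta 12-21 Hz).

The spectral parameterization fits, in log-power space over 3-30 Hz, a 1/f
aperiodic component plus at most three Gaussian peaks (bandwidths clipped to
2-6 Hz, relative peak threshold 2 SD, minimum height 0): robust initial
aperiodic fit (refit on the 40% of points closest below the line, since
peaks only push residuals up), iterative peak extraction, joint Gaussian
refinement, aperiodic re-fit on the peak-subtracted spectrum. The periodic
band integral is taken in log-residual space (the convention is not
published; it is documented here and configurable in the sense that the raw
peak parameters are returned).

Oscillation events come from a Morlet spectrogram (7 cycles, 1-100 Hz in
0.5 Hz steps, 24 s analysis windows). Each frequency row is normalized by
its own median; local maxima above 4x median seed events; the bounding box
grows until the normalized power falls below half the peak or back to the
threshold level, whichever is reached first (the published example features
— a 10-cycle burst yielding roughly its cycle count — require the box to
extend beyond the half-power width for strong events, hence the second
clause); seeds inside an accepted box join that event, and boxes
overlapping an accepted box by more than 0.5 are discarded in favour of the
stronger peak. Band labels use the half-open table delta 0.5-4, theta 4-9,
alpha 9-15, beta 15-29, low gamma 30-40, gamma 40-80 Hz; the printed
29-30 Hz gap is preserved, with gap peaks mapped to the nearer band and
flagged. Note that with an exponentially distributed background the 4x
median threshold is exceeded by noise a few percent of the time, so a
stationary noise signal yields a nonzero event rate by design; analyses
should compare event features, not raw counts, across conditions.

## Statistics and the experiment runner

Effect sizes use the pooled-SD Cohen's d exactly as published, alongside
paired-sample t-tests. Dose-response fits
compare linear, exponential and sigmoid least squares with their SSEs and
the two-sided Pearson correlation. `run_condition_sweep()` shares the
circuit-structure seed across conditions within a seed index, so conditions
are paired, and derives child seeds from a master seed by a fixed splitting
rule; deterministic stages reproduce bit-for-bit.

## Problem sizes and what the tests show

The test-suite sweeps use 20 paired seeds per condition at `s = 0.2`
(4.5 s simulations; 12 s resting runs for EEG across 10 seeds), and the
acceptance script uses 12 (8 for EEG). At these sizes the qualitative
phenomenology is stable: depression elevates the baseline pyramidal rate
(d >> 1), the reference alpha5-PAM dose restores baseline, SNR and
detection-error rates while leaving the post-stimulus response unchanged,
the dose-rate relation is strongly negative-linear (r < -0.9), and
depression raises EEG power across 4-21 Hz with alpha5-PAM restoring all
three band powers.

Two published outcomes are known not to reproduce in this reduction and are
reported rather than asserted. First, the non-selective PAM worsens failed
detection in the full-scale model, but here it improves it: its
interneuron suppression restores the baseline while the stimulus volley
stays intact, and the wide, synchrony-broadened pre-stimulus distributions
that plausibly degrade detection under benzodiazepine-like modulation are a
collective regime this 200-neuron two-compartment model does not enter.
Second, the aperiodic exponent's depression shift depends on
morphology-dependent filtering that the reduction flattens.

The synthetic fixtures (Poisson populations with optional common
modulation, power-law spectra with injected Gaussian peaks, colored-noise
burst traces, piecewise-constant clamp traces) emulate the statistical
structure each stage assumes and make every analysis stage testable without
simulation; passing those tests validates the estimators, not the realism
of any particular circuit. Numerical edge cases are handled explicitly:
degenerate (zero-variance) rate samples are an error, small-sample
skew-normal fits fall back to normal at the shape bound, density
intersections are bracketed between the distribution modes with ties broken
toward the candidates' midpoint, and non-convergent nonlinear dose fits are
flagged while the linear fit is always returned.
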