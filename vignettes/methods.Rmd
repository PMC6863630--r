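---
title: "Models and methods behind optopallidum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optopallidum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optopallidum)
```

# Scope

optopallidum analyses optogenetic circuit-mapping experiments in the
basal ganglia: whole-cell recordings from globus pallidus (GP), striatal
and subthalamic (STN) neurons while ChR2-expressing cortical terminals
are photostimulated. It covers four analysis stages -- optically evoked
EPSC (oEPSC) detection and kinetics, intrinsic membrane-property
extraction, axonal bouton-density normalization, and cell-type
connection-probability statistics -- plus a synthetic-data generator
with known ground truth, so that every stage can be validated without
access to raw recordings.

# oEPSC detection and measurement

Recordings are voltage-clamp sweeps at 20 kHz, one sweep per
photostimulation train (10 pulses of 5 ms at 10 Hz by default, repeated
10-15 times). The pipeline in `measure_oepsc_train()`:

1. **Averaging.** Repeated trains are averaged pointwise
   (`average_aligned()`); since all sweeps share a protocol, alignment
   on each pulse onset is a pointwise mean.
2. **Baseline.** For each pulse, the mean and sample SD of the *raw*
   averaged trace over the 50 ms preceding the onset
   (`baseline_stats()`). Computing the SD before smoothing matters: it
   estimates the recording's true noise amplitude, which is what the
   3-SD detection criterion is meant to count in units of.
3. **Smoothing.** A trailing 4-point (0.2 ms) boxcar
   (`smooth_trace()`), edge-padded by holding the first value so length
   and interior mass are preserved.
4. **Detection.** The peak is the inward (negative) extremum of the
   smoothed average within the search window -- from the pulse onset to
   the next onset or 90 ms, whichever is first. A deflection is an
   oEPSC when its baseline-to-peak magnitude strictly exceeds 3
   baseline SDs; the amplitude is that magnitude, read from the
   smoothed trace. Detection is scale-equivariant by construction.
5. **Onset and latency.** A least-squares line through the rising phase
   between its 20% and 80% amplitude crossings (first crossing of each
   level before the peak) is extrapolated to the baseline; the
   intersection is the oEPSC onset and the latency is onset minus light
   onset. Fewer than 3 rise samples fall back to the first
   threshold-crossing time, flagged.
6. **Kinetics.** The 20-80% rise time uses linearly interpolated level
   crossings. The decay constant is a least-squares single-exponential
   fit from the peak to 10% of the peak, initialized by log-linear
   regression and refined by `nls()`; a failed refinement keeps the
   log-linear value and flags the row, never errors.
7. **Trains.** Each pulse is measured against its own immediately
   pre-pulse baseline; the paired-pulse ratio is the second/first
   amplitude, defined only when the first pulse is detected.

Numerical consequences worth knowing: the boxcar flattens the peak by
well under 1% for realistic kinetics (rise 0.8 ms at 20 kHz); the
linear extrapolation of a convex kernel foot biases the onset *early*
by roughly 0.1 ms for a 0.8 ms rise constant, which is why latency
recovery is asserted to 0.15 ms rather than one sample; and because
the detection threshold is 3 raw-baseline SDs while the extremum is
taken on the smoothed trace (whose noise SD is halved by the 4-point
boxcar), the false-positive rate of the extremum search over a 90 ms
window is negligible rather than the tens of percent a 3-SD criterion
on the smoothed noise would produce. No light-artifact blanking is
applied by default (synthetic data has no artifact); a real-data
blanking window is exposed as `detection_config(artifact_blank = )`.

# The synthetic-data generator

## Synaptic model

`simulate_vc_train()` adds, per pulse, an inward kernel
`-A_k * g(t - onset_k - latency_k)` to Gaussian baseline noise, where
`g` is the difference of exponentials with rise and decay constants
normalized by its analytic maximum, so the configured amplitude *is*
the true baseline-to-peak value (this makes amplitude recovery exactly
testable). Short-term plasticity is a per-pulse multiplicative gain,
transmission failures are per-pulse Bernoulli, and latency is jittered
per pulse. Defaults: rise 0.8 ms, decay 8 ms, latency 3 +/- 0.3 ms,
noise SD 2 pA. The kinetics are typical monosynaptic values; the
source recordings print distributions only, so these are the package's
own choices, not published numbers.

## Membrane model

`simulate_cc_steps()` and friends integrate a leaky integrate-and-fire
cell by exponential-Euler at the sampling interval (exact for the
linear subthreshold core), extended with:

- a **sag current** `I_sag = k * s`, where the activation `s` relaxes
  toward `max(E_rest - V, 0)` with a 300 ms time constant --
  hyperpolarization-activated, slowly developing, producing the
  characteristic sag and rebound;
- two **spike-triggered after-currents**: a fast decaying exponential
  (fAHP) and a slow alpha-like difference of exponentials (sAHP),
  incremented at each spike;
- a **tonic pacemaker drive**, and
- a stereotyped **spike stamp**: a symmetric triangle from threshold
  whose full width at half height equals the configured spike width,
  followed by a short ramp to the reset potential. The stamp starts
  exactly at the threshold-crossing sample, so a dV/dt-based threshold
  estimator reads back the configured threshold.

A conductance-based model is deliberately out of scope: the published
phenotype (input resistance, time constant, sag, rates, spike shape)
constrains features, not channel kinetics, and the LIF variant is the
simplest model whose features the extraction stage can recover.

Two calibration details make the phenotype self-consistent:

- **Input resistance under sag.** The published input resistance of
  sag-bearing neurons is the *measured* steady-state slope, which the
  sag current partly shunts. `membrane_params()` therefore derives the
  internal leak resistance from the requested measured `R_in` and sag
  amplitude (at the -100 pA reference step), so the extractor's V-I
  slope reproduces `R_in` rather than the bare leak.
- **Pacemaker drive.** `calibrate_pacemaker()` root-finds the tonic
  current whose noiseless simulated rate matches the target, starting
  from the closed-form passive-LIF period. The realized rate of fast
  pacemakers lands within a few percent of target; for slow-firing
  presets (~5 Hz) the rate is extremely sensitive to the drive and the
  realized value can deviate by ~20% -- the simulator's actual spike
  times are always stored as ground truth, and all rate checks compare
  extraction against that truth.

Presets for the four recorded cell classes (`membrane_preset()`) take
their measured phenotypes from the published population means
(prototypic `GP_STN` and striatum-projecting `GP_CPu` pallidal
neurons) and from the printed MSN/STN values; quantities never printed
(MSN spike shape, STN time constant, all AHP current magnitudes) are
plausible fill-ins. After-current amplitudes are kept modest: a
tonic-drive pacemaker with large AHP charge would need a drive so
strong that moderate hyperpolarizing steps no longer silence the cell,
which would make passive-property measurement meaningless. A side
effect is that the fast and slow AHP troughs of simulated spikes can
nearly coincide, unlike the well-separated troughs of real pallidal
neurons -- the extractor's two AHP windows are still exercised, but
the sAHP delay phenotype is not reproduced.

Passive properties of pacemaking presets are measured under a
hyperpolarizing bias (`holding_pa = -pacemaker_current`), the standard
silencing practice; without it a -50 pA step does not silence a 20 Hz
cell and its time-constant fit is ill-posed.

## Cohorts and bouton fields

`simulate_cohort()` draws a Bernoulli innervation flag per cell with
the published responder fractions as defaults (M1->GP_CPu 28/35,
M2->GP_CPu 23/27, M1->GP_STN 17/51, M2->GP_STN 36/75), log-normal
oEPSC amplitudes for innervated cells (median 40 pA for GP_STN, 90 pA
for GP_CPu, larger for MSN -- scales chosen by the package, as only
distributions are published), an optional two-component mixture for
GP_CPu emulating its apparently bimodal amplitudes, and simulated
voltage-clamp trains for every cell (noise-only for non-innervated
ones) so the detection pipeline runs blind to the truth.

`generate_bouton_counts()` draws Poisson ROI counts from Gaussian
mediolateral density profiles per region (default magnitudes follow
the published maxima in GP, striatum and STN), with a log-normal
per-animal scaling that emulates variable tracer-labeling efficacy --
the reason the published analysis normalizes within animal.

# Intrinsic-property extraction

- `input_resistance()`: least-squares slope of steady-state deflection
  (final 200 ms of the 1 s step, minus pre-step baseline) against
  current over the -20 to -100 pA family.
- `time_constant()`: single-exponential fit to the -50 pA onset over
  the first 5 tau-hat, iterated once; a non-monotonic (strong-sag)
  onset restricts the fit to 50 ms and flags it.
- `sag_amplitude()`: peak hyperpolarization in the first 300 ms minus
  the final-200 ms steady state, on the -100 pA step by default.
- `detect_spikes()`: onset where dV/dt first exceeds 10 mV/ms with the
  voltage subsequently exceeding -20 mV; 2 ms merge window. The
  10 mV/ms criterion is fixed common practice -- the source tables
  never define "spike threshold".
- `spike_features()`: threshold-to-peak height; full width at half
  height with interpolated crossings; fAHP = most negative V within
  5 ms of the peak; sAHP = most negative V between the fAHP trough and
  70 ms (covering the largest published sAHP delay), truncated at the
  next spike. AHP amplitudes are measured relative to threshold --
  a schema decision, as the source does not say.
- `f_i_metrics()`: spike count during the 1 s step; ties in the
  maximum go to the smaller current.
- `rheobase()`: ascending 5 pA grid of 5 ms pulses, first amplitude
  with a spike; the grid resolution matches the smallest published
  rheobase (5 pA). For the passive model this equals the analytic bound
  `(V_thr - E_rest) / (R_in (1 - exp(-T / tau_m)))` rounded up to the
  grid.
- `flag_putative_cholinergic()`: advisory flag (rate < 3 Hz on-cell
  and width > 1.5x the prototypic preset) mirroring the exclusion of
  large, silent, wide-spiking cells from projection-type analyses.

# Bouton-density normalization

Densities are counts per 100 x 100 um^2 (`count * 1e4 / roi_area`; the
source ROIs are 233 x 173 um). Because labeling efficacy varies across
animals, the per-animal maximum GP density is divided by the same
animal's maximum striatal or STN density
(`normalized_ratio_summary()`); the group summary is the mean and
(n-1) SD of those ratios, with the integer percentage rounded half-up.
The packaged `reference_bouton_counts()` table stores the published
per-animal maxima as counts over 100 x 100 um ROIs so density equals
the printed value; the original ROI tiling is unknown, so tiling is
data, not code. Recomputing the M1 STN-normalized summary from that
table gives 0.471 +/- 0.091 (47%); the source's running text prints
0.496 +/- 0.12 for this quantity while its own table and abstract
match the recomputation -- the table-derived value is the one this
package treats as ground truth.

# Cohort statistics

Standard tests are delegated to R's `stats` primitives behind thin
tidy wrappers: Fisher's exact test (two-sided by the point-probability
rule), Wilcoxon rank-sum (exact for combined n <= 20 without ties),
Kruskal-Wallis, one-way ANOVA + Tukey-HSD, two-sample
Kolmogorov-Smirnov, and a signed-rank test against a reference value
(zero differences dropped *before* the exact null is formed, so small
samples stay exact). Two wrappers go beyond `stats`:

- `kruskal_wallis()` reports the exact permutation p-value (own
  enumeration over rank assignments) when the combined n is at most 10
  without ties, because the chi-square reference is visibly wrong at
  the n = 4 + 4 sizes typical of per-animal ratio comparisons; larger
  samples use the chi-square reference.
- `connection_table_analysis()` fixes the planned-comparison family:
  GP_CPu vs GP_STN within each cortical source and M1 vs M2 within
  each projection class -- four Fisher tests under a Bonferroni family
  of 4, with stars at 0.05/4, 0.01/4 and 0.001/4. The family of 4 is
  reverse-engineered from those published star levels; the source
  never lists the family explicitly.

`tukey_hsd()` after `kruskal_wallis()` (exposed together in
`compare_density_groups()`) mirrors the published analysis even though
the combination is statistically unconventional; both outputs are
returned so users can prefer either.

# What the tests show, and what they do not

All validation is against synthetic data. The generator emulates:
double-exponential oEPSCs with jittered latency, failures and
short-term plasticity on Gaussian noise; LIF-with-sag step responses
and pacemaking; Bernoulli innervation at the published fractions;
Poisson ROI counts with per-animal labeling noise. It does *not*
emulate light artifacts, series-resistance and space-clamp errors,
baseline drift during a recording (a linear drift term exists but
defaults to 0), polysynaptic contamination, or the delay-stability
criterion the source applied qualitatively (no such filter is
implemented). Passing tests therefore demonstrate internal consistency
of generator and extractors and correctness of the arithmetic on the
published tables -- not robustness to every pathology of real
recordings.

Problem sizes used by the test-suite and acceptance checks are chosen
to keep statistical bands meaningful at desk scale: 10-train averages
for single-cell measurements, a 100-seed amplitude-recovery grid at
SNR >= 10, cohorts of 500 cells per group (binomial 3-SD bands of
about +/- 5 percentage points) with a shortened 1-pulse, 2-train
protocol, and full enumeration oracles up to total n = 12 for the
exact tests.

# Reporting conventions

Inward currents are negative deflections at -60 mV holding; amplitudes
are reported as magnitudes. Voltages are mV, currents pA, resistances
MOhm, times s at the interface and ms inside measurement outputs
(column names carry units). All window-to-sample conversions round to
the nearest sample through one function (`ms_to_samples()`). A
recording passes the series-resistance gate only strictly below
25 MOhm, estimated from the peak capacitive transient of the -10 mV /
10 ms test pulse (the estimator is the package's choice; only the
criterion is published).
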