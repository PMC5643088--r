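---
title: "Methods: quantifying synaptically driven spike patterning in dopaminergic pacemaker neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synaptically driven spike patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paceburst)
```

## Scope

`paceburst` implements the quantification chain used in slice
electrophysiology studies of how brainstem (pedunculopontine, PPN)
glutamatergic synapses pattern the firing of substantia nigra pars
compacta (SNc) dopaminergic pacemaker neurons:

1. voltage-clamp EPSC measurement (paired-pulse ratio, AMPA:NMDA ratio,
   current-voltage relations, drug-effect percent change, access-resistance
   QC);
2. subcellular optogenetic mapping (sCRACM) of synapse locations along
   dendrites, expressed as a response-frequency versus path-distance curve;
3. current-clamp and loose-seal spike analysis (threshold detection by a
   dV/dt criterion, phase plots, phase-resolved evoked-spike comparison,
   pacemaker resetting, stimulus-train following, soma-axon matching);
4. line-scan calcium imaging (background-subtracted dF/F0, transient area);
5. the associated non-parametric statistical layer;
6. a fully seeded synthetic-data generator that produces every input
   modality with known ground truth.

The package analyzes recordings; it does not model the biophysics of the
neurons beyond what the generator needs to emulate realistic inputs.

## Conventions

* Time is in seconds; epoch time axes place 0 at the stimulus onset; all
  analysis windows are half-open `[start, end)` except integration windows,
  which are closed.
* Currents are in pA (inward negative), potentials in mV, distances in
  micrometres.
* Junction-potential correction subtracts the internal-solution-specific
  value (cesium 5.9 mV, potassium 7 mV, perforated 5.1 mV) from commanded
  or measured potentials: corrected = recorded − JP, i.e. true potentials
  are more negative than nominal. The correction is applied exactly once
  per recording and both raw and corrected values can be carried by keeping
  the uncorrected object. Holding potentials in examples are nominal
  (pre-correction) values.
* Quantiles use R's default linear-interpolation rule (type 7); summary
  tables report mean, SD (n−1), median, quartiles and the 10th/90th
  percentiles (box-plot whiskers).

## EPSC measurement

The baseline is the mean over the 20 ms before the stimulus; the peak is
the signed extremum of the baseline-subtracted trace inside a search
window of 2–50 ms after the pulse. The window start skips the 1 ms
photostimulation artifact; the end accommodates the slow NMDA rise. An
optional boxcar smoother (0.5 ms) is available and off by default so that
noiseless fixtures measure exactly; on noisy sweeps it should be enabled,
because the raw extremum of ~500 noise samples is biased by roughly three
noise SDs.

**Paired-pulse ratio.** `compute_ppr` is the plain ratio of the second to
the first peak; it is invariant to baseline offsets and gain. At a 50 ms
inter-pulse interval, the first response's decay overlaps the second
baseline window; with fast AMPA kinetics (5 ms decay) this limits the
agreement between the measured PPR and the generative release fraction to
about 0.1%, which is why the loop-closure test asserts equality at 2e-3
rather than machine precision. Decay-corrected train measurements beyond
two pulses are out of scope for this version.

**AMPA:NMDA ratio.** The AMPA component is the inward peak at −70 mV; its
peak time t\* fixes the NMDA measurement point at t\* + 40 ms on the
+40 mV sweep (a fixed-latency read, not the +40 mV extremum). The ratio is
|AMPA| / |NMDA|; when the NMDA read does not exceed 3 baseline-noise SDs
the result is flagged unreliable rather than raised as an error, since a
missing NMDA component is itself a finding.

**Drug effects.** The effect of a drug on an isolated current is the
percent change of the response magnitude, `100·(|post| − |pre|)/|pre|`,
with at least three stable sweeps per condition. By default the peak
latency is located once on the pooled (pre + post) average trace with a
2 ms boxcar and per-sweep amplitudes are read at that fixed latency. This
choice matters: taking each sweep's own extremum inflates both magnitudes
by the expected noise extremum (~7% at 2 pA noise on a 60 pA current) and
biases the ratio; reading at a fixed latency is unbiased and is the
package default, with the per-sweep-extremum variant available as
`method = "per_sweep_peak"`.

**Access-resistance QC.** Baseline Ra is the mean of the first three
sweeps; any sweep deviating more than 20% marks the cell for discard.

## sCRACM mapping

Stimulation spots are registered to the reconstructed morphology (SWC) by
snapping to the nearest dendritic segment within 3 µm — roughly the ~1 µm
laser spot plus registration error — and distance is measured **along the
tree** from the soma root, with the Euclidean distance emitted alongside.

A spot "responds" when (a) the magnitude of the mean per-repeat inward
peak exceeds 3× the baseline noise SD and (b) at least half of the repeats
individually exceed 2×. Peaks here are taken from the 0.5 ms
boxcar-smoothed trace *by default*: with a 48 ms search window at 10 kHz
the raw noise extremum is ~3 SDs, so an unsmoothed rule would fire on
noise almost always, whereas the smoothed rule keeps the false-positive
rate well below 1% (verified by simulation at 1000 trials). Thresholds are
configurable and reported in the output metadata.

The population curve is the fraction of cells responding per 10 µm
distance bin: the numerator counts cells with ≥1 responding spot in the
bin, the denominator cells with ≥1 tested spot; untested bins are omitted.

## Spike analysis

**Detection.** dV/dt is a central difference on raw samples (minimum
10 kHz). An event starts at the first sample at or above 5 V/s after at
least 2 ms of continuously sub-criterion samples; the threshold is the
(t, V) pair at that sample and the peak is the maximum V within 5 ms.
Truncated spikes count as spikes everywhere — evoked axon-initial-segment
spikelets that fail to fully invade the soma are precisely the phenomenon
of interest, and they still propagate down the axon. The detector is
tested for exact agreement (event count and threshold sample index)
against an exhaustive per-sample scan oracle.

**Evoked classification.** A spike is evoked iff its threshold falls
within 10 ms after a pulse, at most one spike per stimulus
(earliest-wins). The 10 ms window reflects the short latencies of
proximally driven spikes and is configurable. Note that while pacemaking
continues, a spontaneous spike occasionally lands in a post-stimulus
window by chance (~1.25% per stimulus at a 1.25 Hz pacemaker); tests
therefore bound chance labels binomially rather than asserting a literal
zero under AMPAR blockade.

**Phase.** The oscillation phase of a stimulus is the time from the last
preceding spike divided by the mean inter-spike interval over the 4 s
before the stimulus (requiring ≥2 spikes). Phase-resolved comparisons
report the evoked−preceding-spontaneous threshold and peak differences and
the resetting index — the interval from the evoked spike to the next
spontaneous one over the mean ISI; 1 means full resetting.

**Trains.** The intra-stimulus window runs from the first onset to one
median inter-stimulus interval past the last onset, so the final evoked
spike is counted; the rate is spikes in the window over its duration, and
a variable-interval burst's "frequency" is (n−1)/(last−first). With a
spike per stimulus this equals the stimulus frequency exactly.

**Soma–axon matching.** Greedy nearest-neighbour matching on absolute time
difference within 3 ms, each event used once (symmetric under exchanging
trains). Instantaneous rates are 1/ISI to the previous event (backward),
with the forward version emitted alongside.

## Calcium line scans

Per line, the fluorescence is the structure-pixel mean minus the
background-pixel mean; F0 is the mean over a user window preceding the
stimulus (default 0.5 s); dF/F0 = (F − F_bg − F0)/F0. Shutter-gated lines
are linearly interpolated, flagged, excluded from F0, and the flag
propagates to any area computed over a window containing them. The
transient area is the signed trapezoidal integral over a closed window,
default stimulus onset to 2 s after (the integration window is not part of
the upstream convention and is configurable). The implementation converges
quadratically in the line period; the suite verifies that halving the 6 ms
period at least halves the error against a closed-form alpha-function
integral.

## Statistical layer

Between-subject comparisons use the Mann-Whitney U test, within-subject
the Wilcoxon signed-rank test, both two-tailed by default. Exact
distributions are used for small samples (n ≤ 20 per group / n ≤ 25
non-zero differences, covering every comparison size in practice, where
p-values like 0.0313 at n = 6 arise), falling back to the tie-corrected
normal approximation; zero differences are dropped (the classic
procedure; a Pratt-style variant is kept behind a flag). The exact
branches are verified against full enumeration of all group assignments /
sign patterns for n ≤ 8. Multiple comparisons use Holm-Bonferroni
step-down adjustment, and reported p-values are the adjusted ones.
Quadratic fits with pointwise 95% confidence bands (`polyfit2_ci`) use
ordinary least squares under homoscedastic Gaussian errors.

## The synthetic generator

The generator exists to give every analysis a controllable ground truth;
it is deliberately phenomenological rather than conductance-based, since
the package's claims concern measurement procedures, not biophysics.
All randomness flows from the seed in `sim_config`; identical
configurations reproduce bit-identical datasets.

**EPSCs.** Per pulse k the conductance is `g_ampa · rf^(k−1)` (vesicle
depletion with second-release fraction rf, default 0.83) plus
`g_nmda · B(V)`, each shaped by a unit-peak biexponential (AMPA 1 ms rise
/ 5 ms decay; NMDA 5 ms / 100 ms); the current is conductance times
driving force plus Gaussian noise (2 pA). The Mg block is the standard
Boltzmann `B(V) = 1/(1 + ([Mg]/K0)·e^(−V/Vc))` with K0 = 3.57 mM,
Vc = 16.13 mV; reduced Mg sensitivity (GluN2D-like receptors) is a
parameter setting, not a separate model. Defaults (`g_ampa` 0.63 nS,
`g_nmda` 1 nS) put the fixed-latency AMPA:NMDA value near 1.43. Drug
effects are conductance scalings.

**Pacemaker.** Spontaneous spikes come from a sawtooth oscillator with
lognormal ISIs (mean 0.8 s, CV 5% — a regular ~1.25 Hz SNc pacemaker);
spikes are piecewise-linear templates whose knots are snapped to the
sample grid so that detection recovers thresholds to within recording
noise (0.1 mV). Each stimulus evokes a spike at ~2 ms latency with
probability 1 − `failure_p`; under "nbqx" no spikes are evoked, and
"cpp" is the identity on spiking by construction, encoding
AMPAR-dependence as a testable null. The evoked somatic waveform
interpolates linearly with phase between a truncated spikelet with a
−10 mV threshold shift at phase 0 and the full spontaneous waveform at
phase 1 (the magnitudes are chosen to match the qualitative range of the
phenomenon; no published coefficients exist for them). After an evoked
spike the oscillator resets, or, in the apamin-like "delay" mode,
restarts with its first interval stretched by `delay_factor` (1.5).
A stimulus arriving within one refractory period (4 ms) after a scheduled
spontaneous spike captures that cycle — the synaptic drive triggers the
imminent spike — which is what makes faithful 1:1 following exact at
`failure_p = 0`. Every somatic spike emits an axonal event 1 ms later on
a loose-seal trace.

Two simulator facts shape the test design and deserve emphasis. First,
stimulus timing must be jittered (the suite uses ~4.3–5.7 s intervals):
because evoked spikes reset the oscillator, fixed-interval stimulation
samples an almost deterministic phase rather than the full cycle. Second,
the "null" configuration for phase-independence checks uses a shallow
subthreshold oscillation (trough −45 mV instead of −65 mV): with the full
oscillation, a phase-*independent* somatic threshold is dynamically
unreachable early in the cycle — the approach from the trough would have
to travel at 4–5 V/s, riding the detection criterion — which is exactly
the physical reason evoked spikes *do* look different at early phases.
The shallow null makes "no phase dependence" realizable at every phase so
that the statistical chain can be tested against a true zero.

**sCRACM.** Spots on a morphology (default a straight 160 µm dendrite,
10 µm spacing) are responsive everywhere ("uniform", the
subthalamic/uncaging-like control) or only within 80 µm of path distance
("ppn_like"); responsive spots produce inward EPSCs with lognormal
amplitude (median 30 pA), others pure noise.

**Line scans.** 512-pixel lines at 6 ms with structure and background
bands, Poisson photon noise plus Gaussian read noise, an optional
shutter-mask gap, and a single-exponential transient whose integral is
known in closed form.

What the generator does *not* emulate: dendritic cable filtering,
stochastic channel gating, opsin photocycle kinetics, electrode artifacts,
drift, and correlated noise. Passing tests therefore demonstrate that the
analysis chain recovers known ground truth under realistic noise levels —
not that it is robust to every pathology of real recordings.

## Problem sizes

The validation suite runs at desk scale: 100 two-second traces for the
detection-oracle check, 10-pulse trains at 5–50 Hz, ~200 evoked events
(14 runs of 15 jittered stimuli) for the phase-dependence recovery, 100
runs for the null-coverage check, 20 cells per sCRACM profile, 1000
simulations for the type-I-error and false-positive-rate checks. These
sizes were chosen so each property is measured with comfortable Monte
Carlo margins while the whole suite completes in about a minute.

## Known limitations

* The per-cell container is a plain-text directory (JSON metadata + CSV
  sweeps); vendor formats and NWB/HDF5 readers are not included in this
  version.
* PPR for long trains (residual-decay correction) is not implemented.
* No automatic dendrite segmentation for line scans: structure and
  background pixel ranges are user-supplied.
* The exact Mann-Whitney branch requires tie-free data; with ties the
  tie-corrected normal approximation is used even at small n (when the two
  differ materially both can be obtained by toggling `exact_max`).
* `reproduce_tables` infers the test design (paired vs unpaired) from cell
  id overlap between two conditions; panels with more than two conditions
  are summarized but not tested.
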