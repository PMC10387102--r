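---
title: "Methods: spike-train analysis for compartmentalized MEA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train analysis for compartmentalized MEA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neuronal cultures grown on a microelectrode array (MEA) under a PDMS
microfluidic chip are physically organized: cell bodies are confined to a
large somatic chamber, neurites grow through narrow microchannels aligned
with the electrode columns, mix in a central "synaptic" chamber, and long
axonal microchannels carry signals toward an empty output chamber. The
geometry makes the *direction* of signal flow a testable prediction:
activity recorded in a microchannel column should be a delayed copy of
somatic activity upstream of it.

`mfnet` implements the analysis chain such recordings call for:

1. **Geometry** — an 8 x 8, 200 µm-pitch, 60-electrode grid (four corners
   absent), with microfluidic compartments assigned to electrode columns
   and two reference channels assigned by column group.
2. **Preprocessing** — re-referencing of each column group against the
   reference electrode nearest its chamber, then a 4th-order Bessel
   bandpass (200–3500 Hz).
3. **Spike detection** — per-electrode ±5 MAD threshold with polarity
   selection and a 3 ms dead time; electrodes with mean rate ≥ 0.1 Hz are
   "active".
4. **Burst detection** — maximal runs of spikes with interspike intervals
   ≤ 100 ms.
5. **Correlation** — spike trains binned at 5 ms; for every electrode pair
   the central-bin coefficient and the maximum-bin coefficient with its
   signed lag are extracted, with significance from jitter surrogates.
6. **Connectivity graphs** — significant pairs whose maximum sits in the
   central bin (|delay| ≤ 2.5 ms) form the undirected *short-term* map;
   pairs peaking at 5–25 ms form the *delayed* map, directed from the
   leading electrode. Somatic electrodes with only outgoing (incoming)
   delayed edges are *efferent* (*afferent*) nodes.

Because no public recordings accompany this class of experiment, the
package ships a synthetic-recording generator with complete ground truth;
every stage is validated against it.

## The synthetic recording generator

`simulate_recording()` renders per-channel voltage as i.i.d. Gaussian
noise plus biphasic spike templates. A *source* is a point process — a
Poisson background superposed with burst trains (Poisson burst onsets,
4–7 spikes per burst at a fixed intra-burst interval with 10%
multiplicative jitter) — rendered at its home electrode. A *propagation
edge* copies each source event to a target electrode after a fixed delay,
thinned by a transmission probability and rescaled in amplitude. This is
the simplest generative model exhibiting the phenomenology the analysis
assumes: compartment-dependent amplitude (microchannel sealing amplifies
spikes, so microchannel templates default to ~-100 µV against ~-40 to
-60 µV at somatic sites), stereotyped axonal waveforms versus mixed
somatic ones, burst dynamics, and millisecond-scale directional delays.

Deliberate simplifications, and what they imply for test coverage: noise
is white and Gaussian per channel (no 50 Hz interference or drift — both
sit outside the analysis band by design); templates are fixed shapes (no
bursting amplitude adaptation); propagation delays are constant per edge
(no conduction jitter); sources are uncorrelated unless connected (no
common background modulation). Passing tests therefore demonstrate the
correctness and calibration of the *analysis*, not robustness to every
artifact of real recordings.

Design choices worth recording:

* **Sampling rate** defaults to 10 kHz — typical for the commercial
  60-channel amplifier class and ≥ 10× the inverse template width.
* **RNG streams.** Every source consumes its own RNG stream keyed by its
  id, and noise a separate stream, all derived from one master seed.
  Consequently simulations are reproducible, independent of source
  ordering, and *exactly* linear: the multi-source trace equals the sum of
  single-source traces at zero noise. The test suite asserts this
  identity.
* **Template.** A difference of Gaussians with a sharp negative phase
  (s.d. = width/5, i.e. ~0.5 ms negative phase for the default 1 ms
  template). Slower shapes lose half their peak to the 200 Hz corner and,
  worse, re-cross the threshold after the dead time via the highpass
  undershoot, producing echo detections; the default shape passes the
  filter with a single threshold crossing per event.
* **Canned scenario.** `scenario_dual_compartment()` wires one somatic
  electrode driving two pathways (a straight chain with cumulative delays
  6–20 ms through short microchannel, synaptic chamber and two
  long-microchannel sites; and an arbor spreading synchronously over the
  synaptic chamber), three synaptic-chamber sources feeding somatic
  electrodes back at 8 ms, a zero-delay common-drive triplet, and an
  unconnected control block. The programmed ground truth is one efferent
  and three afferent somatic nodes; all pairwise delay differences are
  either < 2.5 ms (short-term window) or 6–20 ms (delayed window), so the
  5 ms binning can resolve every true edge.

## Numerical and statistical choices

**Bessel filter design.** The analog low-pass prototype is built from the
roots of the reverse Bessel polynomial, rescaled to the −3 dB magnitude
normalization, then transformed to a bandpass with frequency pre-warping
and mapped by the bilinear transform (the same route `signal::butter`
takes). The test suite pins the resulting coefficients against an
independently designed reference filter. Application is single-pass causal
by default: a zero-phase (forward–backward) pass would smear spike energy
*backwards* in time, which is fatal for an analysis whose conclusions rest
on delay signs. The cost of causal filtering — a fraction-of-a-millisecond
group delay common to all channels — cancels in every pairwise delay. The
first 100 ms are excluded from detection to absorb the startup transient.

**Noise scale for thresholding.** The package's default `mad_type =
"normalized"` is the scaled median absolute deviation (`stats::mad`,
1.4826 × median |x − median|), the robust Gaussian-σ estimate standard in
extracellular spike detection; ±5 of it is a ±5σ threshold. The unscaled
median absolute deviation (`"median"`) and the mean absolute deviation
(`"mean"`) are available as options, but as *defaults* they are
self-defeating: for band-limited Gaussian noise, 5 × unscaled MAD is a
3.4σ threshold, which by Rice's crossing-rate formula fires several times
per second per channel on pure noise — every silent electrode would count
as active. At 5σ the expected noise yield is ~0.4 events per channel per
50 s, which is what makes the 0.1 Hz active gate a meaningful
false-positive control (the suite verifies that 20/20 noise-only
recordings produce zero active electrodes).

**Timestamp and boundary conventions.** A spike's timestamp is the first
sample beyond the threshold (not the extremum); a crossing during the dead
time neither registers nor extends the dead time. The burst ISI ceiling is
inclusive (an exact 100 ms gap continues a burst), and the minimum burst
size defaults to 2 spikes — the weakest reading of "a succession of
spikes". Binning is half-open, `[k·5, (k+1)·5)` ms, with an event exactly
at the recording end clamped into the last bin so counts are conserved.

**Correlation coefficient.** Pearson correlation of binned counts,
normalized over the overlapping region at each lag (coefficients of
silent/degenerate overlaps are defined as 0 and flagged). Pearson is the
only reading consistent with reporting values "close to 1" for strong
propagation; a covariance correlogram has arbitrary scale. The lag window
is ±5 bins (±25 ms), covering both analysis windows. Ties in the maximum
are broken toward the smallest |lag| and then toward the positive lag of
the canonical ordering, and the swapped ordering is defined by negation —
this keeps delay antisymmetry, delay(a,b) = −delay(b,a), an exact
invariant.

**Significance.** The published workflow confirmed correlations by visual
inspection; `mfnet` replaces that with a reproducible surrogate null:
spike times of one train are jittered uniformly by ±50 ms (wrapping
circularly at the recording boundaries, which preserves the train's rate
and marginal law) and the maximum-bin coefficient is recomputed. Jitter of
±50 ms destroys structure at the ≤ 25 ms lags under test while preserving
slow rate fluctuations, so the null is matched for bursty trains too.
p-values are sequential Monte-Carlo estimates (Besag–Clifford early
stopping at 50 exceedances), which cuts the cost of clearly
non-significant pairs by an order of magnitude without affecting decisions
at any level below 50/n. The suite calibrates the test on 1000 independent
Poisson pairs: the type-I error at α = 0.05 must land in [0.03, 0.07].

**Multiplicity.** Per published practice no multiple-testing correction is
applied by default (α applies per pair). For *graph-level* analyses of the
canned scenario, where ~400 pairs are tested simultaneously, the
documented analysis uses 2000 surrogates and a per-pair α = 5 × 10⁻⁴:
at α = 0.01 one expects ~4 spurious edges per map, which would
contaminate the afferent/efferent node classification; at 5 × 10⁻⁴ the
expected number of spurious edges per map is ~0.2. True edges in the
scenario carry maximum coefficients far above the surrogate null, so the
stricter level costs no power there.

**Window partition.** With 5 ms bins, "|delay| ≤ 2.5 ms" is exactly the
central bin and "5–25 ms" exactly lag bins 1–5, so the short-term and
delayed maps partition the significant pairs by construction; a pair can
never appear in both.

## Problem sizes used in validation

The canned scenario is analyzed at its native size (50 s × 60 channels ×
10 kHz). Detection equivalence against the exhaustive per-sample reference
uses 100 random traces of 10⁴ samples; the correlation kernel is checked
against brute force on 500 random pairs to 10⁻¹²; surrogate calibration
uses 1000 independent pairs of 10 s trains; the burst grouper is checked
against a quadratic reference on 1000 random trains; the noise-only
false-positive control uses 20 independent 50 s recordings. Rate
convergence of the generator is verified at 500 s (events only, no
voltage rendering).

## Known limitations

* Threshold crossings are multi-unit activity; no spike sorting into
  single units is attempted (waveform cutouts and their amplitude CV are
  provided as a summary of per-electrode waveform heterogeneity instead).
* Network-wide "collective bursts" spanning electrodes have no agreed
  detection rule and are deliberately not inferred.
* The delayed map reads a positive delay as propagation from the leading
  electrode, possibly through hidden nodes; it does not attempt pathway
  reconstruction or synaptic-versus-axonal attribution.
* Bidirectional significant pairs are kept as two directed edges; they are
  not merged.
* The recording container is plain CSV with a metadata header; vendor
  acquisition formats must be converted to a channels × samples array
  upstream.
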