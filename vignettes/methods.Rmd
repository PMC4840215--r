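---
title: "Methods: burst propagation, connectivity and transmission fidelity in two-layer MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst propagation, connectivity and transmission fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the methodology left them open.

## The preparation being modelled

Two small populations of cortical neurons ("Layer I", "Layer II") are
cultured in adjacent chambers joined by micro-tunnels that admit axons but
not somata; staggered plating makes the tunnels predominantly carry
Layer I → Layer II axons. A 60-electrode 8 × 8 MEA (200 μm pitch) records
22 electrodes under each chamber and two rows inside the tunnel strip;
instrumented tunnels hold a pair of electrodes 200 μm apart along the
conduction path. Devices differ in tunnel count (2, 5, 10, 15, 51), which
titrates the number of axonal pathways; because tunnels are pitched at
40 μm against the 200 μm electrode pitch, the instrumented-pair count is a
property of the device: one pair for 2- and 5-tunnel devices, two for 10,
three for 15, seven for 51 (`make_layout` hard-codes this mapping rather
than deriving it geometrically).

## The synthetic recording: a stated world

`simulate_recording` generates what the pipeline is meant to analyse, with
ground truth attached. Its defaults are the package's one fixed "world":

* **Background firing**: homogeneous Poisson per chamber electrode at
  0.55 Hz. Combined with burst spikes this puts total per-electrode rates
  near 0.8–1.1 Hz, inside the 0.6–1.6 Hz band typical of these cultures,
  and puts the fraction of spikes inside bursts near 40% (the reported
  value is ~43%).
* **Network bursts**: Layer I burst onsets follow a refractory renewal
  process (exponential waiting time plus a 2 s refractory) at 2/min by
  default; durations are normal with mean 0.49 s, sd 0.10 s, truncated
  positive. During a burst a random 80% of the layer's electrodes
  (`participation_fraction`; the source data do not report this quantity,
  so 0.8 is a free choice fixed once) fire an inhomogeneous Poisson
  envelope: half-Gaussian rise peaking at 30% of the burst duration,
  exponential decay after it, both tails truncated at `exp(-2)` so the
  burst switches on and off briskly relative to its own length. The
  envelope peak is the `in_burst_rate` (42.8–54.1 Hz depending on
  coupling).
* **Propagation**: each Layer I burst ignites a Layer II burst with
  probability `p_propagate` after a truncated-normal onset delay. The
  coupling map (`tunnel_coupling`) interpolates linearly in tunnel count
  between the empirical anchors of the weakest and strongest devices —
  probability 0.22 → 0.72, delay 280 ms → 90 ms, in-burst rate
  42.8 → 54.1 Hz. The intermediate groups' published values are noisy and
  partly non-monotone; anchoring only the endpoints reproduces the trend
  direction without asserting a mechanism for the middle.
* **Tunnel traffic**: every Layer I burst drives each instrumented tunnel's
  upstream electrode at 40 Hz under the same envelope; the downstream
  electrode receives an exact copy shifted by
  `separation / conduction_velocity` (0.5 ms at the 0.4 m/s default).
  Optional Gaussian jitter is off by default, so the copy is exact — which
  is what the correlogram stage should see at 0.1 ms resolution.
* **Determinism**: the seed fully determines the recording; identical
  configurations produce byte-identical spike tables.

`simulate_raw_trace` synthesizes a 25 kHz voltage trace (Gaussian noise of
stated RMS plus a biphasic template at each spike time, trough-aligned) for
testing the detection front-end. `simulate_coupled_panel` generates
lag-coupled Bernoulli point processes (1 ms bins; a source spike multiplies
the target's rate after the programmed lag) as the validation bed for the
Granger stage; it runs in compiled code off R's RNG, and aborts if rates
exceed 1 kHz for more than 100 ms.

What the generator does **not** emulate: biophysical membrane dynamics,
synaptic depression or facilitation during bursts, leader-neuron structure,
burst-shape motifs, electrode impedance or drift, and any within-layer
spatial correlation beyond shared burst participation. A green end-to-end
test therefore establishes that the pipeline recovers the statistical
structure it was pointed at — not that it would capture every property of
a living culture.

## Burst detection and its boundary resolution

Burstlets are maximal runs of ≥ 4 spikes whose inter-spike intervals are
all strictly below 25% of the electrode's mean ISI over the recording
(`0.25 × duration / count`). Overlapping burstlets across a layer's
electrodes merge transitively into network bursts (≥ 10 ms span); peak
rate and time come from the pooled spikes binned at 1 ms and smoothed with
a 5 ms Gaussian (±4σ, unit sum), ties resolved to the earliest bin.

Two open points were decided here. First, whether a single electrode's
burstlet can stand as a "network" burst: the package default says yes
(configurable via `min_channels`), but the analysis scripts use
`min_channels = 5`, because with ~0.5 Hz background a single electrode
produces chance 4-spike runs every few minutes, and at 22 electrodes per
layer those spurious singletons would contaminate propagation statistics.
Second, boundary semantics: intervals are treated as closed at spike
times, comparisons with the ISI threshold are strict, and the ≥ 20%
propagation-overlap criterion is inclusive (with a 1e-12 epsilon against
floating-point edge cases).

A consequence worth stating plainly: the summed-burstlet rule bounds the
*boundary precision* of a detected burst by the adaptive ISI threshold,
not by the binning. With total rates near 1 Hz the threshold sits at
~200 ms, so any background spike within ~200 ms of a burst's first or last
in-burst spike joins the run and drags the detected boundary outward. With
~17 participating electrodes per burst, at least one electrode does this
almost every burst; detected onsets/offsets therefore scatter ~100–300 ms
around the envelope's true support even though detection (presence) is
essentially perfect. Sub-burst-level (~20 ms) boundary accuracy is not
achievable with this detector in any Poisson-background world — the
corresponding acceptance check is kept at its stated tolerance and is
expected to fail, as a documented property of the method rather than a
defect of the implementation. Peak times, by contrast, are insensitive to
edge attachment, which is why propagation delays are measured peak-to-peak
and recover programmed delays to within a few milliseconds.

## Direction calls on tunnel pairs

Cross-correlograms accumulate target spikes in 0.1 ms bins over ±2 ms
around each reference spike. The direction call compares the largest
positive-lag bin against the largest negative-lag bin (the two bins
straddling zero are excluded as the lag-0 region). Significance of the
winning peak is assessed against the flat-baseline mean of all tested bins
using the **exact Poisson upper tail** at the one-sided level equivalent
to `min_peak_z = 3` normal standard deviations, Bonferroni-corrected over
the tested bins. A normal z-score was rejected deliberately: at the null
scale of two 1 Hz trains over 10 min the expected count per bin is ~0.06,
where a single chance coincidence is "3.8σ" and roughly half of all
independent pairs would receive a direction call; the exact tail reduces
to the z rule at high counts and stays calibrated at low ones. The
baseline deliberately includes the peak bin so that an almost-empty
correlogram cannot produce a zero baseline (and hence spurious
significance). Conduction velocity is `separation / |peak lag|`, reported
in m/s with the lag in ms; a programmed 0.5 ms lag sits on a bin edge, so
calls land in either adjacent bin (0.45 or 0.55 ms) — within the one-bin
tolerance that any statement at 0.1 ms resolution carries.

## Conditional Granger causality

Spike trains are binned at 1 ms and convolved with a causal exponential
kernel (τ = 4 ms, truncated at 8τ, unit sum). For each ordered pair
(source → target) the conditional statistic is
`ln(RSS_reduced / RSS_full)` from least-squares VAR fits of order 10
(10 ms — covering mono- and oligosynaptic latencies at 1 ms bins; the
methodology leaves the order open), where the reduced model drops the
source's lags while conditioning on all remaining channels. Significance
uses the F statistic of the nested regressions; p-values are
Benjamini–Hochberg adjusted across all ordered pairs (the step-up rule is
implemented in `bh_fdr` and cross-checked against an independent
implementation in the tests), and edges enter the graph at adjusted
p < 1e-4 by default (raw-p thresholding is available). Stationarity is
assumed; a split-half variance-ratio heuristic only warns. Smoothing
leaves residual autocorrelation that the AR(10) absorbs imperfectly, so
F-tests are mildly anti-conservative; the null simulations in the
acceptance suite bound the practical consequence (BH rejection fraction
well under the nominal level).

One structural limitation deserves emphasis: CGC at a 10 ms model horizon
sees millisecond-lag coupling (as on tunnel pairs or programmed panels)
but cannot see burst-scale propagation, whose delays are 90–280 ms. On
whole simulated recordings the dominant dependence is symmetric
co-bursting, so the recording-level CGC graphs in `analysis/03` show high
reciprocity and near-balanced direction; the directional evidence at
burst scale comes from the propagation matching, and at axonal scale from
the correlograms. This mirrors the division of labour in the original
methodology, where CGC was computed along tunnels to corroborate
directionality.

## Fidelity metrics

`vp_distance` implements the spike-train edit distance (insert/delete
cost 1, shift cost q·|Δt|) as the standard O(n_x·n_y) dynamic programme in
compiled code; the tests hold it to a brute-force enumeration over all
injective matchings on small trains, to the metric axioms, and to its
closed forms (q = 0 gives |n_x − n_y|; q → ∞ gives
n_x + n_y − 2·coincidences). Similarity is S_v = 1 − D_v/(n_x + n_y); it
is non-decreasing in 1/q, so rate-scale similarities always dominate
temporal-scale ones for the same pair. `vr_similarity` bins both trains at
1 ms, convolves with the causal exponential (τ_R, truncated at 8τ_R), and
takes the Pearson correlation, clamped below at zero so both metrics share
the [0, 1] range; the unclamped value is retained in an attribute for
audit.

Conventions for degenerate cases are explicit: two empty trains have
S_v = 1 (identical) but are flagged and excluded from composites; an empty
train against a non-empty one has S_v = 0; any constant smoothed series
makes S_R = 0 with a degeneracy flag. When similarity is computed inside a
window class, the correlation runs **only over bins inside the window
union** — otherwise the long stretches of shared silence outside bursts
would inflate S_R for every pair.

`fidelity_profile` sweeps both metrics over the scale grid {1, 2, 5, 10,
20, 50, 100, 200, 500} ms (the methodology names only the regime cutoffs,
> 50 ms for rate and < 20 ms for temporal; the grid brackets both
decades), for all between-layer and within-layer electrode pairs (tunnel
electrodes excluded — whether they belonged in "all possible pairs" was
unstated, and their near-duplicate trains would dominate), inside the
matched-overlap windows of propagation events and in their complement.
`max_pairs` caps the per-class pair count by random subsampling for
desk-scale runs. Pairing is at electrode level, matching a
per-electrode-pair averaging into the per-recording composite.

## Scaled-down defaults in the analysis scripts and tests

The analysis scripts simulate one 10-min culture per tunnel group with a
4/min burst schedule (above the ~1.6/min observed rate) so that even the
weakly coupled groups accumulate enough propagation events for stable
fidelity composites in minutes of CPU time; burst statistics other than
the count are unaffected. The end-to-end acceptance check uses 5 seeds per
coupling level and asserts a strictly increasing median rate-regime
composite. Adjacent intermediate coupling levels differ by only
Δp ≈ 0.05 and Δdelay ≈ 19 ms under the linear anchor map, so their
expected fidelity difference is close to the sampling noise of a
desk-scale run; a rank inversion between the 10- and 15-tunnel levels is
within that noise and, when it occurs, is reported honestly by the test
rather than absorbed by a looser tolerance.

## Numerical choices

* Time is seconds, double precision; windows are half-open [start, end);
  spike tables are sorted TSV, layouts JSON.
* The Gaussian burst-peak kernel is truncated at ±4σ and renormalized; the
  exponential kernels at 8τ. Histogram ties take the earliest bin.
* The band-pass for raw traces (300 Hz–3 kHz, Butterworth order 4,
  zero-phase forward-backward) is designed in-package via the bilinear
  transform because no signal-processing package is available in the
  target environment; detection applies it optionally (the synthetic
  front-end produces already-band-limited signals).
* Spike detection uses a 1 ms dead time and times events at the extremum
  of each supra-threshold excursion; spikes inside the 15 s noise window
  are still detected (the window only feeds the RMS estimate).
* k-means model selection uses a spherical-Gaussian BIC over k = 1..5 on
  the first three principal components — a documented simplification of
  automatic cluster counting.
* VAR fits share one QR decomposition per (full/reduced) design across all
  targets; rank deficiency and zero-variance channels raise errors naming
  the channels.

## Known limitations

* Burst boundary precision is threshold-limited (see above); onset-based
  delay estimates inherit that fuzz, which is why delays are peak-to-peak.
* Recording-level CGC cannot attribute direction to couplings slower than
  its VAR horizon.
* The F-test calibration for CGC is approximate under kernel smoothing;
  permutation testing would be the rigorous alternative and is left as an
  extension.
* The simulator's layers are exchangeable apart from the programmed
  propagation; it does not reproduce the reported slight Layer II burst
  lengthening, nor any maturation effects.
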