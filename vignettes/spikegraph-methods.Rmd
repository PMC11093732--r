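---
title: "spikegraph: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spikegraph: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

spikegraph is a spike-sorting pipeline for extracellular multichannel
recordings: it turns a flat binary voltage file plus a probe geometry into a
set of units (clusters of spikes attributed to putative single neurons),
with Phy-compatible output for manual inspection. This vignette explains the
models behind each stage, the parameters that matter, and the design
decisions taken where more than one reasonable implementation exists. The
worked examples in the README show the code entry points; here the focus is
on the science.

## Preprocessing model

Raw extracellular voltage is dominated by slow field potentials and shared
artifacts, neither of which carries single-unit information. Three linear
operations are applied per batch, strictly in this order:

1. **Common average referencing (CAR).** Each channel's temporal mean over
   the batch is removed, then the cross-channel median at every sample.
   The median cancels signals common to all channels (room noise,
   optogenetic transients). CAR must precede filtering so that large
   artifacts are cancelled before they can ring through the filter.
2. **High-pass filtering at 300 Hz.** The reference filter is a causal
   order-3 Butterworth (order and direction are configuration knobs;
   nothing in the method depends on them beyond common practice). To apply
   it as a batched convolution, the recursive filter's impulse response is
   materialized by filtering a unit impulse placed at the center of a
   zero vector of one batch length, and the resulting FIR kernel is applied
   in FFT space. The impulse response decays below 1e-13 of its peak within
   a few hundred samples, so the convolution is computed at a padded
   power-of-two length with no circular wrap; the batch padding absorbs all
   edge effects and the payload equals the recursive filter's output to
   round-off (this equality is regression-tested).
3. **Local ZCA whitening.** Channel covariance is estimated from CAR-ed,
   filtered batches subsampled evenly across the recording (25 batches by
   default; the estimator is the biased 1/T form). For each channel the
   covariance of its 32 nearest channels is eigendecomposed and the ZCA
   transform `U (S + eps I)^{-1/2} U'` built; only the row belonging to the
   center channel is kept, embedded in a sparse full-size matrix. Keeping
   32 coefficients per channel rather than `n_chan` prevents overfitting on
   large probes. `eps` defaults to `1e-6 * mean(S)` — small enough to be
   inert on well-conditioned neighborhoods, nonzero to keep degenerate
   neighborhoods finite. The 32-channel neighborhood corresponds to a
   ~160 µm span on a four-column Neuropixels layout; test configurations
   on the 16-channel single-column probe use 8 channels, the same physical
   span, because widening the neighborhood to the whole (short) probe
   turns local whitening into a global transform fitted on
   spike-containing covariance, which smears strong units across
   channels.

Drift alignment (below) is also a channel-space linear map, so the
whitening matrix and the per-batch alignment operator are multiplied into a
single matrix before touching the data.

Batches are `N_T = 60,000` samples with `n_t = 61` samples of padding on
each side. The first batch's left pad repeats the first sample; a short
final batch is padded with its last value; interior pads are true data.
Concatenating payloads reproduces the recording exactly.

## Drift model

Probe motion shifts every waveform along the probe axis. The estimator
works on detections from the *simple template* bank (below): in 2-s time
bins, a depth-by-amplitude histogram of detections (5-µm depth bins, 20
log-spaced amplitude bins) is registered against the element-wise median
histogram by maximizing cross-correlation over integer shifts, with
parabolic sub-bin refinement; nonrigid mode refines the rigid estimate in
depth blocks (6 by default). Three numerical details matter. The reference
falls back from the element-wise median to the mean when histograms are
sparse (the median of mostly-zero counts is identically zero and cannot be
registered against). The reference is then rebuilt three times from
back-shifted histograms and the registration repeated — a single-pass
reference is smeared by the very drift being estimated. And the final
trace is reported around the recording's mean position: registration only
defines shifts up to the reference's arbitrary phase, so the gauge is
fixed explicitly. This estimator is a deliberate simplification of full
iterative registration pipelines; the pieces this package commits to are
(a) detection with sign-inverted template pairs so both polarities
register, (b) 2-s bins, and (c) linear interpolation of the block traces
to every channel with constant extrapolation.

Correction resamples each channel at its position plus the estimated drift
using Gaussian-kernel kriging, `K(x_nom, x_shift) (K(x_shift, x_shift) +
lambda I)^{-1}` with sigma = 20 µm and lambda = 0.01 — the same kernel
family and values used to interpolate waveforms across depth in the
simulator, which keeps one consistent spatial smoothness assumption
throughout. Because the estimated trace is the apparent motion of the
units, the shift matrix is built from the negated per-channel trace.

## Detection and template deconvolution

**Simple templates.** Detection templates are all combinations of a 2-D
position (channel grid upsampled 2x per dimension), one of six unit-norm
single-channel waveform shapes, and one of five isotropic Gaussian spatial
envelopes (s.d. 0.5-3x the vertical pitch). Shapes and footprints are
separately unit-normalized, so a template's variance explained is the
squared projection `(W'D)^2`. By default the six shapes are packaged
parametric prototypes (biphasic, zero-mean because detection operates on
high-passed data); optionally they are learned from threshold-crossing
snippets by k-means (`shapes_from_data = TRUE`), falling back to the
prototypes below 500 snippets. Peaks must be local maxima over ±20 samples
and the 100 nearest positions and exceed threshold 9 (in template-norm
units). The large suppression neighborhood intentionally under-detects
overlapping spikes — template learning only needs a representative sample,
not every spike.

**Learned templates.** Detections are assigned 40-µm vertical sections by
their center-of-mass position; each section's spikes are embedded as PC
features (6 temporal PCs, 10 nearest channels, zero-padded to the union
channel set) and clustered with the graph clusterer using the bimodality
criterion only. Centroids map back to channels-by-time waveforms, are
temporally aligned to the prototype shapes by maximal correlation, and
near-duplicates merge when lagged correlation exceeds 0.9 and the aligned
relative difference of the norm-scaled waveforms is below 0.25 (the two
thresholds must be checked on aligned, scaled waveforms — at zero lag a
correlation of 0.9 already implies a relative difference of 0.45, and the
rule would never fire). Each template keeps its average spike norm `x_W`,
a rank-3 spatial-temporal factorization (truncated SVD; the top three
components capture essentially all waveform variance for smooth spike
shapes), and the table of pairwise cross products at all time lags.

**Matching pursuit.** Spikes are matched at the template's fixed average
norm: `V = 2 x_W W'D - x_W^2`. Each round computes every template's
correlation with the residual convolutionally through the rank-3 factors,
accepts peaks that are local maxima over ±`n_t` samples across all
templates and above threshold 8 (norm units), and subtracts `x_W W` at
every accepted spike. The first round computes correlations in full;
subsequent rounds update them only near subtracted spikes using the
precomputed lagged cross products, which makes later rounds nearly free.
Rounds stop at 50 or when no peak clears threshold. Because each
subtraction removes a positive amount of explained variance, the residual
norm never increases, and data = sum of accepted spikes + residual holds
to round-off.

**Features.** Each spike's features are the PC projection of the residual
patch on its template's ten nearest channels, plus the precomputed
PC-space contribution of its own template at `x_W`. Overlapping spikes
were subtracted with their own templates, so they do not contaminate the
features; the `do_feature_deconv = FALSE` ablation reverts to raw-patch
projections.

## Graph clustering

Spike features in each section are clustered by bipartite modularity. All
points are "left" nodes; a uniform subsample of at most 25,000 landmarks
("right" nodes) receives edges from every point to its k = 10 exact nearest
landmarks. k is not dictated by the method; 10 keeps small clusters
connected without bridging distinct ones, and it is a configuration knob.
The bipartite modularity

H = (1/2m) * sum_c [ e_c - gamma * K_c_left * K_c_right / (2m) ]

decomposes over left nodes given right labels (and vice versa), so all
labels on one side are reassigned *in parallel* by the argmax rule; sweeps
alternate sides until no label changes (cap 30). Ties take the lowest
cluster id, making runs bit-reproducible under fixed seeds. Initialization
is k-means++ with 200 seeds. Each parallel sweep maximizes H exactly over
that side's labels, so H is non-decreasing — the converged partition is a
local minimum that is characteristically *oversplit*, never under-merged,
which is the property the merging tree relies on.

## Merging tree and curation

Aggregating the graph by cluster gives edge counts `K_ij` and degrees
`k_i`; the pair with the largest merge resolution `gamma_hat = 2 m K_ij /
(k_i k_j)` merges first, re-aggregating until one root remains. `gamma_hat`
is non-increasing toward the root (this is asserted against a naive
re-scan), so the tree is well defined.

Traversal goes top-down; a kept merge prunes its subtree. At each node:

* merges with `gamma_hat` below 0.2 are rejected outright (split always
  accepted) — at the working resolution gamma = 1, such a pair is far from
  merge-favorable, and this backstop prevents pathological top-level
  merges. In practice it fires only for nearly disconnected pairs;
* otherwise, a refractory cross-correlogram keeps the node merged: when
  one neuron's spikes are divided between two clusters, the cross-pairs
  inherit the absolute refractory gap, so a refractory CCG is positive
  evidence of identity (the same rule drives the global merge stage);
* otherwise the node splits if and only if the regression-axis projection
  is bimodal (`bimod > 0.5`; the score itself is defined by the
  trough-to-peak density ratio of the 400-bin, Gaussian-smoothed histogram
  of projections on the size-weighted least-squares axis). The smoothing
  uses mirror-reflected edges so histogram mass is conserved exactly, and
  densities below 1e-9 of the total mass are treated as empty so that
  degenerate, single-spike-cloud projections score as unimodal rather than
  dividing 0 by 0.

Correlogram refractoriness uses 1-ms bins over ±0.5 s; `R12` is the
minimum over central windows k = 0..10 of observed versus expected
coincidences at the shoulder rate (maximum of the left/right mean over
|dt| of 50-500 ms), `Q12` the minimum Gaussian-approximated Poisson lower
tail. A CCG is refractory when `R12 < 0.25` and `Q12 < 0.05`; an ACG when
`R12 < 0.1` and `Q12 < 0.2`.

One subtlety is specific to *deconvolved* spike trains: matching pursuit
cannot accept two spikes of similar templates closer than its ±`n_t`
exclusion window (2.03 ms at 30 kHz), so the central correlogram bins of
extracted trains are structurally empty whether or not the underlying
neurons are related. Left uncorrected, this makes any pair of co-located
units look refractory (gluing distinct neurons at the merge stages) and
any multi-unit cluster's ACG look contamination-free. The pipeline
therefore censors the fully-dead central bins (`ccg_censor_bins = 2`,
i.e. |dt| ≤ 2.5 ms) when judging its own output and evaluates the
refractory statistics on the observable window only — a genuine 3-ms
refractory period still shows its dip in the 2.5-3.5 ms bin and beyond.
The raw (uncensored) definitions remain the default for
`compute_correlograms()` on arbitrary trains.

Units are labeled `good` when their ACG contamination `R12` is below 0.2,
with two power guards: the shoulder must predict at least `min_expected =
5` null coincidences in the widest window (a near-empty correlogram
provides no evidence of isolation), and the censored window is used for
the pipeline's own trains as above.

Global merges run after all sections: units in decreasing spike count,
candidates above 0.5 lagged waveform correlation in decreasing similarity,
merge on refractory CCG, retest after every merge, remove completed units.
This stage — not the tree — is what rejoins same-neuron pieces that ended
in different sections or became disconnected in feature space (for
example after a step drift).

## The simulator

The simulator renders drifting ground-truth recordings in the same binary
format the sorter reads. Its defaults are the study conditions the rest of
the package is tested under:

* **Waveform bank.** Units are parametric stand-ins for a recording-derived
  bank (which cannot be redistributed): biphasic-to-triphasic temporal
  shapes (skewed troughs of 0.08-0.3 ms, trough-to-peak 0.2-1 ms,
  rebounds up to 0.45 of the trough, optional positive pre-deflections —
  the diversity matters: a too-narrow waveform family makes distinct
  units' templates nearly collinear, and matching pursuit cannot separate
  collinear waveforms that fire together) times Gaussian spatial
  footprints of s.d.
  20-40 µm (wider footprints would cover most of a short test probe and
  defeat the cross-channel median reference — a geometry constraint of
  scaled-down probes, not of real recordings), sampled at 20 depth bins of 2 µm with small depth-dependent
  shape perturbations. The processing applied to them is the real one:
  top-3 PC denoising across depths, average-norm normalization, removal of
  units whose -20 µm waveform differs from the +20 µm waveform shifted by
  40 µm by more than 0.25, and kriging depth-upsampling x100 (sigma 20 µm,
  lambda 0.01). A user-supplied bank passes through the same code path.
* **Drift profiles.** `none`, `medium`, `high`, `fast`, `step`,
  `step_aligned`, each constructed from Gaussian noise smoothed in time
  (sigma = 100 s) and across the nine probe positions (sigma = 2
  positions), with per-profile scale factors (0.4 / 0.26 / 0.58) and exact
  affine rescaling to the stated extremes (±7, ±18.5, ±4 µm), a 30-µm
  midpoint offset for the step profiles, and 300 fast events (10 µm,
  difference-of-exponentials with 80 ms rise and 200 ms decay) on a 200-ms
  grid for `fast`. Smoothing uses mirror reflection at the edges — the
  default of the standard scientific-stack Gaussian filter; the edge
  convention measurably moves the drift-range statistic, and alternatives
  (zero padding, edge replication) were examined and rejected as either
  equivalent or clearly distorting.
* **Spike trains and norms.** Single units shuffle the inter-spike
  intervals of a reference set (synthetic gamma ISIs with a refractory
  floor and ~12.6 Hz mean rate standing in for a recorded library), which
  preserves the ISI multiset and hence the refractory period; multi-units
  are Poisson. Norms: single = 10 + Exponential(mean 7), multi =
  Uniform(4, 10).
* **Rendering.** Spikes are added at the depth given by the drift at their
  time (trains in three interleaved parts so collisions superpose
  exactly), then per-channel noise with a flat spectrum to 300 Hz at s.d.
  0.76, "unwhitening" by the square root of an AR(1) channel-correlation
  matrix (rho = 0.5), scaling by 200, clipping, int16. Identical seeds
  give bit-identical files.

What the simulator does *not* capture about real recordings: waveform
nonstationarity beyond smooth drift (bursting amplitude decrement,
electrode charging), non-Gaussian artifact statistics, and a realistic
density of background neurons — the background here is the stated noise
model plus whatever multi-units are requested. Passing tests on these
simulations therefore demonstrates the pipeline's mechanics (detection,
deconvolution, clustering, curation, scoring) under controlled truth, not
performance on any particular real dataset.

## Benchmarking

Each ground-truth unit is compared against the 40 detected units closest
by best channel; spikes match greedily one-to-one within 0.2 ms; the
candidate maximizing `score = 1 - FP - FN` wins. Units are `good` below
0.2 ACG contamination, and good units matching no ground-truth unit count
as false-positive units. The drift-range summary is the 5th-to-95th
percentile span of the median trace across positions.

## Problem sizes used in the test-suite

The suite exercises the full pipeline at reduced scale: 16-channel
single-column probes, 2-5 minute recordings at 30 kHz, 6-12 single units
with norms at or above 12 over a multi-unit background, and clustering
fixtures up to 50,800 points in six dimensions. These sizes were chosen so
every property of interest (drift recovery, collision resolution,
unbalanced-cluster recovery, oversplit repair) is measurable with stable
statistics on a single CPU; none of the algorithms carry assumptions tied
to probe size, and all scale parameters are configuration values.

## Known limitations

* The drift estimator is a single-pass histogram registration; very large
  or very fast motion (beyond ±40 µm or faster than the 2-s bin) will
  alias. The `fast` profile exists to generate such data, not to promise
  recovery.
* Matching pursuit fixes each template's amplitude at `x_W`; strongly
  amplitude-modulated neurons (bursting) leave structured residual and may
  split by amplitude before the tree re-merges them via their CCG.
* Single-channel probes cannot support the cross-channel median reference
  or spatial whitening; both degrade gracefully but the pipeline is
  designed for multichannel probes.
* The bipartite clusterer's local minimum depends on the k-means++ seed;
  runs are reproducible under a fixed seed but not invariant across seeds
  (the curation stages absorb most of the variation).
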