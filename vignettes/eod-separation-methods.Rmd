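---
title: "Separating electric organ discharges of paired pulse-type electric fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating electric organ discharges of paired pulse-type electric fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eodsep)
```

## The problem

Mormyrid fish such as *Gnathonemus petersii* emit brief biphasic electric
organ discharges (EODs), roughly 200–400 µs long, whose timing carries
behavioral and social information. When two free-swimming fish share a tank
instrumented with a pair of carbon electrodes, both animals' pulses appear
superimposed on the same two voltage channels, at rates that can exceed
100 Hz. Attributing each detected pulse to the individual that emitted it is
the bottleneck for any downstream analysis of discharge interactions, and
manual assignment does not scale to the ~10^5 events of a typical session.

`eodsep` implements a fully unsupervised separation for the dyad case:

1. **Detection.** Per channel, the signal isoline estimated by a running
   median is subtracted; the residual is squared (polarity depends on the
   fish's orientation relative to the electrodes, the square does not); peaks
   above a fixed threshold (5 mV in original amplitude units, i.e. 25e-6 V²
   on the squared trace) with a 400 µs minimum spacing are kept; detections
   coincident across channels are merged into one event on the
   higher-amplitude channel.
2. **Extraction.** 300 µs before and after the absolute-maximum sample are
   cut out — 31 samples at 50 kHz — normalized by the absolute peak, and
   polarity-flipped when the extremum is negative, so waveform shape is
   compared independent of amplitude and orientation.
3. **Features.** Each waveform is zero-padded (15 zeros per side) and
   transformed with an analytic generalized Morse wavelet (γ = 3, P² = 60,
   so β = P²/γ = 20) on a logarithmic grid of 12 voices per octave; the
   magnitude scalogram is cropped back to 31 columns, normalized by its
   maximum coefficient, and flattened into one feature vector.
4. **Embedding and clustering.** t-SNE maps the feature vectors to 2-D at
   perplexity 50; average-linkage hierarchical clustering with Euclidean
   distance cuts the embedding into exactly two clusters.
5. **Identity.** Each cluster's mean signed peak amplitude per channel
   summarizes where, and with which orientation, its fish sat relative to the
   electrode pair; clusters are mapped to fish A/B by (dominant channel,
   polarity), with identical signatures flagged ambiguous rather than
   silently resolved.

Two supervised baselines are included for comparison: Pearson correlation
against per-fish mean scalogram templates built from solo recordings, and an
RBF-kernel SVM trained on the highest-SNR solo EODs. Cluster quality is
quantified by the average silhouette score and the CDbw (composed density
between and within clusters) index, which tolerates the non-spherical
cluster shapes t-SNE tends to produce.

## The synthetic dyad simulator

No packaged data can stand in for a tank recording, so the package ships a
generator whose defaults encode the study conditions the method assumes:

* **Waveforms** are two raised-cosine lobes — a positive phase of width τ₁
  followed by a negative phase of width τ₂ scaled by a ratio in
  (−0.9, −0.25) — with total duration constrained to the physiological
  200–400 µs range and an asymmetry (time-warp) parameter. This reproduces
  the shape diversity the classifier exploits without modelling electrocyte
  physiology.
* **Individuality**: `make_fish(seed, divergence)` places a fish's shape
  parameters at a fixed distance `divergence` from the population centre in
  a seed-determined random direction, so `divergence = 0` yields identical
  fish (the honest-failure control) and larger values scale
  inter-individual distinctness monotonically.
* **Discharge timing** is a gamma renewal process (shape 3, mean IPI 125 ms
  by default, i.e. ~8 Hz). The gamma family nests the exponential and
  near-regular trains and gives the refractory-like regularity of real
  discharge sequences; collisions between the two fish within 400 µs occur
  with positive probability and are flagged in the ground truth, never
  forbidden.
* **Position and orientation**: each fish's channel-0 amplitude share
  follows a smooth logistic-transformed random walk in (0.2, 0.8) (the two
  electrodes sit at opposite corners, so channel 1 receives the
  complement), and a second walk's sign models orientation reversals that
  flip pulse polarity. This is a deliberate stand-in: no quantitative model
  of EOD amplitude versus position is available, and only the existence of
  a stable per-fish amplitude/polarity signature matters to identity
  assignment.
* **Noise and drift**: additive white noise at 0.2 mV RMS (the noise floor
  estimated from experimental recordings) plus a slow sinusoidal baseline
  drift (1 mV, 0.2 Hz by default) that the running-median step must remove.

What the simulator does *not* emulate: echo-response interactions between
the fish, hydrodynamics or realistic field geometry, electrode artefacts,
and session-scale waveform drift (exposed separately via `perturb_fish()`
for the cross-session robustness checks). Passing tests on synthetic dyads
therefore demonstrate the pipeline's correctness and its behavior under the
stated statistical structure — not performance on any particular tank,
which should be validated against real labeled recordings.

## Numerical and design choices

* **Threshold semantics.** The 5 mV detection threshold is interpreted in
  original amplitude units and applied as its square on the squared trace;
  squaring is peak enhancement, not a change of threshold scale.
* **Median kernel.** 5 ms (251 samples at 50 kHz): an order of magnitude
  above the 400 µs maximum pulse width (so pulses pass through) yet fast
  enough to track sub-hertz drift. A kernel below 3 pulse widths is
  rejected because it would erase the pulses themselves.
* **Scale grid.** The Morse scalogram band defaults to 1–25 kHz (56 scales
  at 12 voices/octave), spanning the energy of 200–400 µs biphasic pulses
  up to Nyquist at 50 kHz. The exact grid is configurable
  (`morse_params()`), and no result in this package depends on individual
  coefficient values — only on normalized-scalogram properties and
  downstream classification.
* **t-SNE.** Exact O(n²) gradient (compiled), 750 iterations, early
  exaggeration 12 for 250 iterations, momentum 0.5 → 0.8, adaptive gains,
  learning rate n/12. Initialization is the first two principal components
  scaled to SD 1e-4 plus a seeded jitter of SD 1e-6: deterministic for a
  fixed seed, which is the property tests and users need; embeddings are
  not reproducible across seeds, as with any t-SNE. Inputs are reduced to
  50 principal components first. At the ~2,000 events of a 2-minute dyad
  an exact gradient runs in seconds, so no approximate (tree- or
  interpolation-based) repulsion is needed at this scale.
* **Clustering determinism.** `hclust` average linkage; labels renamed by
  cluster size (0 = larger, ties to the cluster holding the lowest point
  index). Above 30,000 events a seeded uniform subsample is clustered and
  the rest inherit nearest-neighbour labels, bounding the O(n²) linkage
  memory; the embedding, not the feature matrix, is what gets clustered.
* **CDbw.** Implemented after Halkidi & Vazirgiannis (2008): 10
  farthest-point boundary representatives per cluster, shrink factors
  0.1–0.8 in steps of 0.1. Point densities use a Gaussian kernel at the
  cluster's RMS radius rather than a hard count, which keeps the index
  strictly positive and leaves its ranking of candidate labelings invariant
  under global rescaling of the embedding.
* **Weak-separation flag.** A separation is flagged when the two-cluster
  silhouette falls below 0.45 or the two clusters' amplitude/polarity
  signatures are indistinguishable. Calibrated on synthetic solo-fish
  versus dyad runs (solo recordings reliably trigger the ambiguity
  condition); the flag is advisory and never alters the returned labels.
* **SVM hyperparameters.** "Bayesian optimization" is realized as a
  sequential search: a coarse log-spaced (C, γ) grid over C ∈ [1e-2, 1e3],
  γ ∈ [1e-6, 1e1] scored by seeded 10-fold cross-validation, then one local
  zoom around the best cell, within a configurable evaluation budget. Only
  a well-tuned model matters for the comparison, not the search mechanism.
  Column standardization uses the plain training mean/SD — classes are
  balanced by construction, so weights are uniform.
* **Rate smoothing (sonification).** The instantaneous rate is the
  piecewise 1/IPI signal smoothed by a causal exponential window
  (τ = 0.25 s default). A step change in rate therefore reaches ~95% of its
  target after 3τ and ~99% after 5τ, per the closed-form step response;
  audio is forced silent 2 s after the last event. FM pitch mapping is
  exponential (octaves per unit relative rate change) so equal rate ratios
  sound as equal musical intervals.
* **Perplexity selection.** `select_perplexity()` sweeps a grid restricted
  to [30, 120], scores each value by median MCC (ties: accuracy, then
  runtime) over labeled dyad feature sets, and returns the score table
  along with the winner, so the choice is auditable.
* **Silhouette labeling modes.** For unlabeled dyads the silhouette is
  computed on the two predicted clusters; when known identities exist
  (e.g. the 24-individual analog), `silhouette_score()` accepts those
  labels directly — both usages appear in the tests.

## Problem sizes used in validation

The packaged validation suite runs 10 synthetic dyads of 120 s at 50 kHz
(~8 Hz per fish, ~2,000 EODs per dyad, divergence 0.7–0.9, 0.2 mV noise)
for the headline accuracy/MCC medians; a 24-individual, 960-EOD analog for
the representation-ordering check; and 30 s dyads at divergence 0 for the
honest-failure control. These sizes were chosen so the full pipeline —
simulation through clustering — exercises every code path at realistic
event counts while a complete run stays comfortably on a laptop.

## Known limitations

* Two fish only: the tree is always cut at k = 2, and triads or groups are
  out of scope by design.
* Offline only: detection and embedding are batch algorithms.
* Identity assignment presumes the amplitude/polarity signature is stable
  within a session; fish that swap positions mid-recording can defeat it
  (the flag, and the exported embedding, are the diagnostic).
* Divergence-0 dyads (identical waveform parameters) are not separable by
  construction, and the package's tests assert that accuracy then sits at
  chance rather than pretending otherwise.
* The silhouette threshold of the weak-separation flag and all sonification
  parameters are conventions, exposed in configuration objects, not
  quantities estimated from data.
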