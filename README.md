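# eodsep

Unsupervised separation of electric organ discharges (EODs) from paired
pulse-type weakly electric fish.

## What this is for

Mormyrids like *Gnathonemus petersii* probe and communicate with brief
(~200–400 µs) biphasic electric pulses. Recording two free-swimming fish on
one pair of tank electrodes superimposes both animals' discharges on two
voltage channels at combined rates that can exceed 100 Hz, and every
downstream question — discharge interactions, synchrony, behavioral
pharmacology — first needs each pulse attributed to the fish that emitted
it. `eodsep` does this without any training data:

```
detect (median-baseline removal, squared-signal threshold 5 mV,
        400 µs refractory, cross-channel merge)
  → extract (±300 µs around the peak → 31 samples @ 50 kHz,
             peak-normalized, polarity-canonicalized)
  → featurize (analytic Morse-wavelet scalogram, γ = 3, P² = 60,
               12 voices/octave, max-normalized, flattened)
  → embed (t-SNE, perplexity 50)
  → cluster (average-linkage hierarchical, Euclidean, k = 2)
  → identify (per-cluster channel-amplitude/polarity signature → fish A/B)
```

Cluster quality is reported as the average silhouette score and the CDbw
index; supervised baselines (scalogram-template Pearson correlation and an
RBF-SVM trained on high-SNR solo EODs) are included for comparison, along
with accuracy/MCC evaluation utilities, two sonification schemes
(pulse-wise bursts and IPI-driven FM melodies), and a ground-truth-labelled
synthetic dyad simulator used throughout the tests.

## Worked example

```r
library(eodsep)

# two synthetic fish with well-separated waveform parameters, 30 s dyad
fishA <- make_fish(seed = 1, divergence = 0.8)
fishB <- make_fish(seed = 2, divergence = 0.8)
sim   <- simulate_dyad(fishA, fishB, dyad_sim_config(duration_s = 30, seed = 3))

res <- separate(sim$recording, config = separation_config(perplexity = 50, seed = 3))
print(res)
#> <eod_separation> 483 EODs -> clusters of 250 / 233 (timefreq features)
#>   silhouette 0.862, CDbw 8.142
#>   identity: 0 -> B, 1 -> A

evaluate_run(res$events, sim$truth, tol_s = 1 / sim$recording$fs)
#> <eod_eval> ACC 0.9979, MCC 0.9959, 482 matched EODs
```

483 detected EODs split into two clusters; the silhouette of 0.86 says the
two waveform populations are well separated in the embedding; the identity
map assigns each cluster to a fish from its channel-amplitude/polarity
signature; and against the simulator's ground truth 481 of 482 matched
events are attributed correctly (one residual error is a pulse collision —
both fish discharging within 400 µs collapse to a single detected event).
`plot(res)` draws the labeled embedding; `res$events` is a plain data frame
(`t_s, channel, peak_amp_V, label, truth`) ready for CSV export via
`write_events_csv()`.

A command-line front end over the same functions lives at
`inst/cli/eodsep.R` (subcommands `simulate`, `detect`, `separate`,
`baseline`, `evaluate`, `sonify`, `bench`).

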