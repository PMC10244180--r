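# ovipost

Quantitative analysis of the *Drosophila melanogaster* egg-laying
behavioral sequence. Gravid females deposit each egg through an ordered
sequence of component actions — proboscis extension (`pe`) and walking
during exploration, then abdominal bending, rhythmic ovipositor burrowing
and completed egg expulsion (`egg_out`), followed by detachment, grooming
and a stationary reset phase. `ovipost` provides the statistical machinery
to quantify this sequence from frame-wise behavior annotations,
pose-estimation keypoint tracks and paired calcium-imaging recordings, for
behavioral neuroscientists studying how sensory feedback gates the
transitions between components.

## What it computes

**Transition structure.** Behavior onsets form a *start-to-start* sequence
(per-event ordered onsets, with proboscis-extension spacing and co-activity
filters, and bend scored once per sustained bend). The pooled transition
matrix is

P(i -> j) = N(i -> j) / sum_k N(i -> k),

with self-transitions counted. Each cell is tested against a one-sided
permutation null that shuffles the label order independently within each
sequence; p = (1 + #{P\*(i->j) >= P(i->j)}) / (1 + n_perm), with cells below
a probability floor (0.04) never flagged. First-occurrence ordering,
egg-out-aligned behavior time courses, and per-fly progression
probabilities (bend -> burrow; burrow -> egg_out, with minimum-bout
filters) round out the ethogram analytics.

**Burrow substructure and egg metrics.** Burrowing episodes are segmented
from the ethogram, carry their annotated cycle counts and an
abort/expel outcome, and yield per-fly cycle statistics and the
cycle-count/duration Pearson correlation. Egg records (depth scored
0 / 0.5 / 1, wall location, spontaneous drops) are summarized per fly.
Photostimulation trials are classified advance/revert by a 65-s
burrow-free reset rule, plus a 4-s expelled-after-stimulation flag.

**Pose features and behavior mapping.** From 13 tracked keypoints the
package builds the 17-channel frame-wise feature matrix
(`vel, pe, ba, velba, T1..T3, Pegg, w1ovi, w2ovi, cwt1..cwt7`): scutellum
speed over a 500-ms lag, a 0.29 mm/s walking classifier with 1-s
smoothing, z-scored abdominal bend angle and angular velocity, and
continuous Morlet wavelet band magnitudes (0.8–1.3 and 1.3–2.3 Hz of the
ovipositor ROI intensity; seven log-spaced bands 0.5–10 Hz of A5-stripe
movement). Frames are embedded in 2-D by t-SNE, segmented by watershed on
the embedding density, and clusters are tested for egg-out-locked
expression with a circular-shift null.

**Calcium pipeline.** dF/F0 with a median baseline excluding ±20 s around
ovipositor extrusions; tracked distances normalized to the median
T6–analia unit; event detection by zero-phase 0.001-Hz high-pass
filtering, exact 1-D total-variation regularization and threshold
crossings at one-fifth of the regularized maximum; 3-s response integrals
min–max normalized to context-specific anchors; event-triggered averages.

**Synthetic data.** Seeded generators with exact ground truth for every
stage: semi-Markov ethograms (gamma dwell times, burrow cycles, overlap
rules), keypoint tracks with behavioral kinematic signatures, transient +
step fluorescence/distance recordings, motif feature matrices, and egg
depth cohorts across substrate firmness.

## Worked example

```r
library(ovipost)

sim  <- simulate_ethogram(n_events = 200, seed = 1)
seqs <- lapply(sim$ethograms, extract_start_sequence, min_pe_spacing = 0)
tm   <- estimate_transitions(seqs, phase = "all")
max(abs(tm$probs - sim$ground_truth$transition_matrix))
#> [1] 0.0333927
round(tm$probs["burrow", ], 3)
#>     pe   walk   bend burrow egg_out detach  groom
#>  0.052  0.086  0.203  0.457   0.201  0.000  0.000
tm <- permutation_test(tm, seqs, n_perm = 9999, alpha = 0.001, seed = 1)

ep <- do.call(rbind, lapply(sim$ethograms, segment_burrow_episodes))
burrow_cycle_stats(ep)$r_cycles_duration
#> [1] 0.9300747
```

The recovered pooled matrix sits within 0.034 of the generating matrix
(200 events), the burrow row shows the self-transition loop and the
burrow -> egg_out exit, and episode cycle counts correlate at r = 0.93
with episode duration.

A thin command-line wrapper over the same functions is included:

```sh
Rscript inst/cli/ovipost.R simulate 20 --seed 1 --out events/
Rscript inst/cli/ovipost.R transitions events/ --n-perm 999 --seed 1 --out matrix.json
Rscript inst/cli/ovipost.R validate events/event001.csv
```

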