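---
title: "Methods: quantifying the egg-laying behavioral sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the egg-laying behavioral sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ovipost` quantifies the *Drosophila* egg-laying sequence from three data
streams: frame-wise multi-label behavior annotations (ethograms),
pose-estimation keypoint tracks, and paired two-channel fluorescence
recordings with tracked distances. This vignette explains the models and
procedures, the parameters that matter, the numerical choices, and what
the synthetic-data generators do and do not emulate.

## The ethogram representation

An ethogram is a frames x 7 boolean activity matrix over
`pe, walk, bend, burrow, egg_out, detach, groom` at a fixed frame rate
(default 20 Hz). The representation is deliberately multi-label: abdominal
bending is maintained throughout burrowing, egg expulsion and detachment,
so `bend` may be co-active with those three labels, while `walk` may never
be co-active with `burrow`. `egg_out` is a point-like label (one frame
natively; expansion to three frames happens only in the agreement module).
Frames are 0-based and bouts are half-open `[start, end)`; durations are
frames divided by the frame rate. Downstream consumers that need a single
stream derive the ordered onset ("start-event") sequence rather than
flattening the matrix.

## Start-to-start transitions

Consecutive behavior onsets form the unit of sequence analysis. Three
filters, applied at extraction, mirror how onsets are scored by an
annotator: proboscis-extension onsets count only at locations at least
0.5 mm from the previously counted one (skipped with a warning when no
location track exists); pe onsets on frames where any other behavior is
active are omitted; and a sustained bend contributes one onset even when
burrowing aborts and restarts inside it (this falls out of the run-length
bout encoding). Simultaneous same-frame onsets are ordered by a fixed
priority (egg_out > burrow > bend > detach > groom > pe > walk); such ties
are rare in annotated data and absent from the simulator's output.

Counts are pooled across events and flies before row normalization,
yielding one population matrix; per-fly matrices can be obtained by
calling the estimator on per-fly subsets. Pre- and post-expulsion phases
are tallied separately, with the egg_out item serving as the shared
boundary: the transition into egg_out is a pre-phase pair and the
transition out of it a post-phase pair.

The permutation null shuffles the label *order* independently and
uniformly within each sequence, phase-respecting. This preserves every
sequence's label multiset and length — each fly keeps its behavioral
repertoire under the null, and only the ordering is exchangeable. The
per-cell statistic is the pooled transition probability (not the count),
and the one-sided p-value uses the add-one estimator
p = (1 + #{null >= observed}) / (1 + n_perm), which cannot return zero.
Defaults follow the analysis conventions of the field: 10,000 shuffles,
alpha 0.001, and a probability floor of 0.04 below which cells are never
flagged significant. The same seed always reproduces the same p-values.

## Episode metrics and outcome classification

A burrowing episode is one maximal burrow bout; annotated cycle frames are
partitioned into episodes (a cycle outside every burrow bout is a
validation error), and an episode expels iff completed egg expulsion falls
within it. Cycle statistics are reported per fly and outcome with a
minimum of 2 episodes per (fly, outcome); the cycle-count/duration
association uses the Pearson correlation (the estimator is not otherwise
specified in common practice, and cycle counts scale linearly with
duration under a near-constant cycle rate).

"Dropped" eggs are operationalized as expulsion with no burrowing in the
preceding 5 s (configurable); depth scores are the standard 0 / 0.5 / 1
categories averaged per fly for flies with at least one egg, wall and
drop fractions use per-figure minimum egg counts (3 and 4 by default).

Post-expulsion classification is deterministic: the fly *advances* to the
reset phase when no burrow onset occurs within 65 s of the expelling
episode's end; otherwise it *reverts*, and the reset is anchored at the
onset of the last burrowing episode that precedes a 65-s burrow-free
window. The burrow-stop time is the expelling episode's end — a proxy for
the separately annotated ovipositor detachment onset, documented as a
convention. Frame-exact ties between burrow stop and light offset are
binned as "stopped at offset". The expelled-after-stimulation flag is true
when expulsion occurs no later than 4 s after the last pulse offset.

## The 17-channel feature matrix

Channels, in fixed order: `vel` (scutellum displacement across a 10-frame
/ 500-ms lag, px/s; convert to mm/s via the pixel calibration), `pe`
(per-frame displacement of the proboscis tip relative to the ocellus),
`ba` (per-recording z-score of the signed angle between the abdominal
line stripe-A2 to stripe-A6 and the body axis ocellus to scutellum),
`velba` (per-frame difference of the unnormalized angle, z-scored),
`T1`-`T3` (per-frame leg-joint displacements), `Pegg` (egg-tip tracking
confidence, passed through raw), `w1ovi`/`w2ovi` (linear Morlet band
magnitudes, 0.8-1.3 and 1.3-2.3 Hz, of the ovipositor-ROI mean intensity),
and `cwt1`-`cwt7` (log Morlet magnitudes of A5-stripe movement at seven
log-spaced center frequencies from 0.5 to 10 Hz). Movement channels are
per-frame Euclidean displacements, not velocity-smoothed. Z-scoring is per
recording (per fly), so `ba` is comparable across postures within a fly
but not in absolute degrees across flies.

Choices where the convention was open: the Morlet mother wavelet uses a
center-frequency parameter of 6 cycles (the standard admissibility
trade-off); the seven A5 bands are log-spaced because behavioral rhythms
concentrate at low frequencies; band channels average the magnitude over
five log-spaced frequencies inside the band; log outputs are floored at
1e-6. The ROI intensity trace is an input (video pixel extraction is out
of scope); without it the per-frame displacement of the ovipositor
keypoint stands in, and the matrix is flagged accordingly. The top A5 band
sits exactly at the 10-Hz Nyquist frequency of 20-Hz video; band edges
strictly above Nyquist are rejected. Tracker gaps below the confidence
threshold are repaired by linear interpolation with end values held;
repaired spans are recorded as provenance.

The walking classifier thresholds the 1-s centered moving average of the
speed channel at 0.29 mm/s, with shrinking windows at the recording edges;
it agrees frame-for-frame with a naive sliding-window implementation.

The CWT itself is implemented in the package by FFT convolution with the
analytic Morlet wavelet (no installed R package provides a continuous
wavelet transform); magnitudes are amplitude-normalized so a unit sinusoid
at a band's center yields magnitude near 1, and a constant signal
transforms to exactly zero.

## Behavior mapping

Features are z-scored, a Barnes-Hut t-SNE (perplexity 30, theta 0.5) is
trained on a random subsample (default 30,000 frames), and all remaining
frames are placed at the embedding coordinate of their nearest training
neighbor in feature space — the lightweight variant of re-embedding;
duplicated frames therefore map to identical coordinates, and a fixed seed
reproduces the map exactly.

The embedding density is estimated with a Gaussian KDE (normal-reference
bandwidth per axis, 512 x 512 grid) and segmented by a watershed transform
on the density surface. Shallow maxima within 5% of the normalized density
are absorbed (sampling ripple on a smooth mode would otherwise split it),
and basins holding under 0.5% of frames are merged into the nearest
retained basin.

Cluster significance uses a circular-shift null: within each event the
cluster label sequence is rotated by an independent uniform offset, which
preserves the labels' autocorrelation while destroying their alignment to
egg expulsion. The statistic is the peak of the egg-out-aligned occupancy
time course over a ±60-s window, after a 0.5-s moving-average smoothing
applied identically to observed and null time courses — without it the
peak lives on a coarse k/n_events grid and heavy ties make the test
needlessly conservative. A cluster enters the significant set when
p < 0.05 *and* its occupancy peaks within ±20 s of egg out. This null is a
stated substitute for the original analysis' unspecified chance test, not
a claim of equivalence.

## Calcium pipeline

dF/F0 uses a per-ROI median baseline over the window from recording onset
to 20 s before completed expulsion, excluding ±20 s around ovipositor
extrusion events; a constant trace maps to exactly zero, and scaling F by
a positive constant leaves dF/F0 unchanged. Three-point moving-average
smoothing exists only as a display helper, never in analysis paths.
Distances are normalized by the median T6-analia distance (set to 1).

Event detection: zero-phase first-order Butterworth high-pass at 0.001 Hz
(the DC component is removed before filtering, since at cutoff periods far
longer than the trace the forward-backward edge transient would leak a
mean-proportional ramp; the filtered trace is then centered at its median,
the baseline of a sparse-event trace), exact 1-D total-variation
regularization, and upward crossings of one-fifth of the regularized
maximum. The TV solver is a direct O(n) taut-string sweep whose output
satisfies the optimality conditions exactly (the tests verify the dual
certificate). The regularization weight defaults to the discrepancy
principle — the residual standard deviation is matched to a noise estimate
from the median absolute first difference (target inflated by 5% so pure
noise flattens completely). Crossings are snapped to the dominant upward
jump of the regularized signal within ±2 s (noise sub-steps can pre-cross
the threshold by a few frames), merged under a 1-s refractory rule, and no
events are returned (with a warning) when the regularized maximum stays
within 3 noise standard deviations. Upward crossings are the default
because the tracked distances increase as the egg or ovipositor advances;
the direction is configurable.

Response integrals are trapezoidal over t = 0..3 s after each onset,
min-max normalized per ROI so that a context-specific baseline anchor maps
to 0 and the maximum 3-s integral observed anywhere in the recording maps
to 1 (per-ROI, matching per-neuron display rows). In the expulsion design
the 0-anchor is the median sliding 3-s integral over the first contiguous
60-s stretch before complete expulsion avoiding ±20 s around expulsion
events (if no such stretch exists the longest valid run is used, with a
warning), and a post-expulsion value (median over t = 10..20 s after egg
out) is also reported; in the extrusion design the 0-anchor is the median
over the first 60 s worth of valid frames, possibly non-contiguous,
starting 10 s after expulsion. Out-of-range normalized values are
meaningful and never clipped; multi-event ROIs are reduced by the mean.
Sliding integrals step at every frame.

## Agreement

Frame-wise precision, recall and F1 per behavior, with
F1 = 2 * precision * recall / (precision + recall) and the 0/0 case scored
0. Point-like labels (`pe`, `egg_out`) are first dilated from one to three
frames (clipped at bounds) so one-frame timing offsets are not scored as
disagreement. The combined score is micro-averaged from pooled counts —
the natural reading of an "all behaviors combined" score — with the macro
average also reported.

## Synthetic data: what it emulates, and what it does not

`simulate_ethogram` draws per-event onset sequences from a semi-Markov
chain: labels from a 7 x 7 start-transition matrix, onset-to-onset gaps
from per-label gamma laws (positive, flexible coefficient of variation).
The default matrix mirrors the qualitative arrow structure of the
sequence — a pe/walk exploration loop with intermittent grooming,
walk -> bend, bend -> burrow, a burrow self-loop with abort routes, a
burrow -> egg_out exit, and a deterministic egg_out -> detach -> groom
reset — with free parameters chosen once; no numeric equality with any
empirically estimated matrix is claimed. Burrow gaps equal the bout's
cycle count over the cycle rate (1.5 cycles/s) plus a pause, so episode
duration and cycle count are intrinsically correlated as in real
burrowing. Each event carries one egg expulsion; after the reset
components the observation window closes geometrically (and immediately
upon a newly initiated bend), stopping rules that depend only on emitted
history so that row-wise transition estimates remain unbiased. Painting
rules guarantee exact recoverability: every chain item produces exactly
one bout onset (a restarting label closes its previous bout one frame
early), bend persists through burrow/egg_out/detach, and burrow closes
just after egg out.

Cohort sizes in the packaged benchmarks (200 events for matrix recovery;
500 null datasets of 18 x 25 items for calibration; 100 traces x 10 events
for detection; 5,000-frame embedding subsamples; 48 flies per firmness
level) were chosen so that each estimator's sampling error is comfortably
below the tolerance being checked while the full suite runs in minutes on
one CPU.

`simulate_keypoints` renders walking as whole-body translation, bending as
an abdominal-line angle ramp, burrowing as an ovipositor-intensity and
A5 oscillation whose frequency sweeps downward across the episode (as the
egg incrementally emerges), and egg emergence as a confidence ramp, plus
Gaussian keypoint jitter. `simulate_fluorescence` renders double-
exponential calcium transients (kernel normalized on the sample grid so
the peak equals the stated amplitude exactly), shared slow drift, an
anatomical channel without transients, and distance steps that are
instantaneous at the sample rate — a tracked egg advance spans less than
one frame at 10 Hz. `simulate_egg_depths` draws depth categories so that
twice the depth score is Binomial(2, p), giving the pooled mean depth an
exact binomial sampling law against which recovery is checked.

None of the generators emulate tracking failures beyond confidence-flagged
gaps, annotator disagreement, optics or motion artifacts, nonstationary
noise, or the full kinematic richness of real flies. Passing tests
therefore demonstrate the correctness and calibration of the estimators
under the stated generative assumptions — not performance on real video,
which depends on annotation and tracking quality upstream of this
package.

## Known limitations

- The spacing filter for proboscis extension requires a location track;
  without one it is skipped (with provenance), which can overcount pe
  onsets in location-free data.
- Whether transitions should be pooled across flies or averaged per fly is
  a genuine modeling choice; pooling is the default, and per-fly matrices
  must be built by the caller.
- The circular-shift cluster null and the nearest-neighbor out-of-sample
  embedding placement are standard lightweight variants, documented above,
  not re-implementations of any specific prior pipeline.
- Automatic burrow-cycle detection from the wavelet channels is not
  attempted; cycles enter as annotations or simulator ground truth.
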