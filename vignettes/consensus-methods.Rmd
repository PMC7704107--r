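---
title: "Agreement, consensus and quality metrics for spike sorting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement, consensus and quality metrics for spike sorting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikematch)
```

This vignette documents the models and estimators `spikematch` implements,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic benchmark does and does not emulate.

## The agreement model

A sorting is a set of units, each a strictly increasing train of integer
sample frames (0-based; seconds are a derived view). Storing frames rather
than seconds keeps matching exact and format-independent. Duplicate frames
within a unit are rejected rather than silently dropped, because downstream
matching must be deterministic; unsorted input files are sorted on read with
a warning.

Two spikes from different trains are **matched** when they occur within a
tolerance window of each other, $|t_1 - t_2| \le \Delta$ (inclusive). The
window is 0.4 ms by default and is converted to frames as
$\mathrm{round}(\Delta \cdot f_s / 1000)$. Matching is a maximum one-to-one
pairing: a spike can absorb at most one partner. On sorted trains this
optimum is attained by a greedy two-pointer sweep (pair the earliest
mutually compatible spikes, else advance the earlier train) — a standard
exchange argument shows no alternative pairing can do better for interval
adjacency on a line, and the test suite verifies equality with an
independent augmenting-path maximum-matching oracle on thousands of random
train pairs. Ties between equidistant candidates resolve toward the earlier
spike. The sweep is implemented in C++ because multi-sorter comparisons
evaluate it for every unit pair.

The **agreement score** of two trains is the matched count over the union
size,
$$ s = \frac{n_\text{match}}{n_1 + n_2 - n_\text{match}} \in [0, 1], $$
symmetric, 1 only for perfectly matching trains, and defined as 0 when both
trains are empty (an empty unit carries no evidence of agreement).

**Unit assignment.** The units of two sortings are matched one-to-one by
maximizing total agreement (the Hungarian problem). We solve it as a
maximum-weight bipartite matching (`igraph`); with non-negative scores the
two have the same optimum, and zero-score pairs — the only place they can
differ — are discarded afterwards anyway. Pairs below `min_score` (default
0.5) are reported unmatched; the threshold is applied *after* optimization.
The exhaustive-permutation oracle in the tests checks optimality on random
matrices up to 6×6. A thresholded `best_match()` mode (no injectivity)
exists for failure analysis, where an oversplit unit legitimately matches
several partners.

**Ground-truth evaluation.** Against a ground-truth sorting, matched spikes
are labelled tp, unpaired ground-truth spikes fn, unpaired tested spikes fp,
and summarized as accuracy $tp/(tp+fn+fp)$, recall $tp/(tp+fn)$, precision
$tp/(tp+fp)$, miss rate $fn/(tp+fn)$ and false discovery rate $fp/(tp+fp)$.
Tested units are classified by agreement, with rules applied in a fixed
precedence order (the rules overlap, so an order had to be chosen; checking
overmerge first prevents a unit that blends two cells from being called
well-detected):

1. **overmerged** — agreement > 0.2 with two or more ground-truth units;
2. **well-detected** — the assigned partner of a ground-truth unit, with
   agreement > 0.8;
3. **redundant** — agreement > 0.2 with exactly one ground-truth unit but
   not that unit's best-matched tested unit (oversplit or duplicate);
4. **false positive** — unmatched, or matched below 0.2;
5. **weak match** — everything else (intermediate agreement).

Both thresholds (0.8, 0.2) are user-adjustable parameters. A useful exact
consequence worth knowing: a clean even split of a unit scores exactly 0.5
against it ($n_m = n/2$, $n_1+n_2-n_m = n$), so at the default match
threshold the better half stays matched (a weak match) and the other half is
redundant.

## Multi-sorter consensus

All sorter pairs are compared; Hungarian matches with agreement ≥
`min_match_score` (default 0.5) become the edges of an undirected graph over
(sorter, unit) nodes. A node's **agreement count** $k$ is 1 plus the number
of *distinct other sorters* it is directly matched with. We deliberately do
not inherit $k$ from connected-component membership: transitive chains
(A≈B, B≈C, but A̸≈C) would otherwise inflate agreement.

Counting "units on which $k$ sorters agree" is ambiguous — a group of
matched units can be counted once, or once per member — so
`agreement_counts()` reports both tables explicitly: a group-level table
(connected components, with a group's $k$ the number of distinct sorters in
it) and a per-sorter node-level table.

Consensus is exposed in two forms, because both are useful in practice:

- `consensus_curation()` — per sorter, retain only units with $k \ge$
  `min_k` (default 2). Non-destructive: each output is a `CuratedSorting`
  with an exclusion log citing the removed unit's $k$.
- `build_consensus_sorting()` — per retained agreement group, emit one new
  unit: the union of the spike trains of the group's two closest-matching
  units (its strongest edge), with spikes matched within the window counted
  once (the earlier frame of a matched pair is kept). Exactly two donor
  trains are used per unit, and the donors are recorded in the provenance.

Threshold-based curation over any quality metric works the same way and
chains: exclusion predicates are independent, so curation order does not
change the result. `NaN` metric values (a metric undefined for a unit) fail
every threshold by default — a conservative rule, overridable with
`nan_policy = "keep"`.

## Quality metrics: estimator choices

The metric definitions are standard in the extracellular literature; where a
definition leaves an estimator open, the choices are:

- **SNR**: maximum absolute template amplitude on the unit's best channel
  (largest peak-to-peak) over that channel's noise, estimated as the median
  absolute deviation scaled by $1/0.6745$ (Gaussian consistency) on seeded
  random 1-s chunks.
- **ISI violation ratio** (contamination proxy): with $n_v$ inter-spike
  intervals shorter than $t_r$ (default 1.5 ms) among $N$ spikes over $T$
  seconds,
  $$ \rho = \frac{n_v / (2 N (t_r - t_{min}))}{N / T}. $$
  Note the calibration of this classical estimator: for a homogeneous
  Poisson train $E[n_v] \approx N r t_r$, so $\rho \to 0.5$ at chance, not
  1 — a clean refractory unit scores 0 and values approaching ~0.5 indicate
  Poisson-like contamination. The Monte-Carlo tests assert this 0.5
  calibration.
- **Amplitude cutoff** (missed-spike estimate): histogram of spike
  amplitudes (500 bins, Gaussian-smoothed with σ = 3 bins, reflect
  padding), assumed truncated on the weak side. The height of the
  lowest-amplitude bin marks the truncation level; by symmetry, the mass
  beyond the mirrored point on the strong side of the peak estimates the
  mass cut off. If that mirrored tail is $t$ relative to the observed mass,
  the missing fraction of the full distribution is $t/(1+t)$ — without this
  correction the estimator is biased upward by $\sim M/(1-M)$. Capped at
  0.5; NaN below 50 spikes. Negative-going amplitudes are negated
  internally so "weak" is always the left tail.
- **Drift**: per spike, depth is the centre of mass of the first
  principal-component energy across channels (probe y-coordinate = depth);
  per 60-s interval (≥ 10 spikes), the median depth; max drift is the range
  of interval medians and cumulative drift the summed absolute successive
  differences. NaN below two valid intervals.
- **Isolation distance**: squared Mahalanobis distance (cluster mean and
  covariance) of the $N$-th closest non-member, $N$ the cluster size; NaN
  when non-members are fewer than members or the covariance is singular.
- **L-ratio**: $\sum_{\text{non-members}} (1 - F_{\chi^2_d}(D^2)) / N$ with
  $d$ the feature dimension.
- **d′**: member vs. all-other spikes projected on the Fisher discriminant
  axis (pooled within-class covariance); $d' = |\mu_1 - \mu_2| /
  \sqrt{(\sigma_1^2 + \sigma_2^2)/2}$.
- **Nearest-neighbour hit/miss rates**: the average *fraction* of member
  spikes among each spike's 4 nearest neighbours (members for the hit rate,
  non-members for the miss rate). The fraction — rather than a majority
  vote — is used so that fully interleaved equal clusters sit at 0.5 (a
  majority vote over an even neighbour count is biased off 0.5 by ties).
- **Silhouette**: the standard $(b-a)/\max(a,b)$ per member spike against
  the nearest other cluster, averaged.

PCA features are fitted per channel on spikes pooled across units (3
components per channel by default) and concatenated across channels for the
cluster metrics. Pooling is required by every cross-unit metric; a per-unit
basis would make Mahalanobis distances between units incomparable. Every
constant above is surfaced as a parameter and recorded in the metric table's
parameter block, and every stochastic step (waveform subsampling, PCA fit
subsampling, noise chunks, neighbour subsampling) is driven by one seed, so
a metric table is bit-reproducible.

## Preprocessing and postprocessing

Preprocessing stages are lazy: a stage is itself a `Recording`, computation
happens only when traces are requested, and constructing a chain reads no
trace bytes (the tests instrument a counting trace source to prove it).
Filters are zero-phase (forward–backward) Butterworth IIR of order 3 before
doubling — zero phase so spike times are not shifted, which would corrupt
matching. The notch is a 2nd-order biquad (centre frequency and quality
factor) run through the same zero-phase filter. Chunked lazy reads fetch a
1024-frame margin on each side so they agree with an eager full-trace
filter to well below 1e-6 µV away from recording edges; note that a very
narrow notch (bandwidth ≪ fs/1024) has an impulse response longer than the
margin, so its chunked output near chunk boundaries is approximate.
Common referencing subtracts the per-frame median (or mean) across *all*
channels, whatever channel subset is requested. Removing every channel is an
error rather than an empty recording.

Waveforms are cut as `round(ms_before·fs/1000) + round(ms_after·fs/1000)`
samples (defaults 1 and 2 ms, 500 spikes per unit, seeded subsampling
without replacement); spikes whose window crosses a recording edge are
skipped and counted, while per-spike amplitudes use a truncated window
instead so every spike gets an amplitude. The template trough is the
extremum of larger absolute amplitude, ties toward negative, so
positive-going units are handled by the same logic mirrored.

## The synthetic benchmark

The generators emulate a simulated ground-truth benchmark at desk scale:

- `generate_gt_sorting()` — independent Poisson units (default 5 Hz, 300 s,
  30 kHz) thinned to enforce a refractory period (default 2 ms; the later
  spike of a violating pair is deleted). Thinning was chosen over a renewal
  process because it is simpler and the resulting ISIs above the dead time
  remain exponential to good approximation (KS-tested in the suite).
- `synthesize_recording()` — a grid probe (default 4×2, 25 µm pitch); each
  unit gets a biphasic template (Gaussian trough plus delayed repolarization
  bump, normalized so the trough equals the stated amplitude exactly) at a
  random location, scaled per channel by $e^{-d/30\,\mu m}$, plus white
  Gaussian noise of 10 µV by default.
- `corrupt_sorting()` — sorter failure modes with known rates: i.i.d. spike
  misses, Gaussian timing jitter rounded to integer frames (collisions
  nudged +1 frame to preserve strict ordering), uniform false-positive
  insertions, unit splits (alternating spikes), merges, and appended
  pure-noise units.
- `generate_comparison_scenario()` — the consensus test bed: 6
  pseudo-sorters each detect a seeded 80% subset of 40 ground-truth units,
  reproduce them with 10% misses and 0.1 ms jitter, and add 10 private
  noise units; the planted truth table records every unit's origin and its
  expected agreement count.

All generators are pure functions of their parameters including the seed,
and restoring a dumped provenance record regenerates them exactly.

What this emulates — and what it does not: the synthetic recordings have
stationary units, white uncorrelated noise, parametric templates and no
electrode drift or spike collisions across units' waveforms. Tests passing
on them demonstrate the correctness and calibration of the comparison and
metric machinery, not sorter performance on real tissue; real recordings
have correlated noise, bursting, drift and template overlap that this
benchmark deliberately omits. Problem sizes in the test suite (seconds to
minutes of simulated data, tens of units) were chosen as the smallest scales
at which the Monte-Carlo tolerances are stable.

## Provenance, formats, determinism

Every `Recording`/`Sorting` carries a provenance record — source (file path
or synthetic generator with full parameters and seed), ordered operation
list, schema version — serializable to JSON; `restore_provenance()` rebuilds
the object exactly, and unknown schema versions are rejected explicitly.
Native formats are deliberately minimal: sorting CSV (`unit_id,frame` plus a
sampling-frequency comment line) and NPZ (`unit_ids`, `spike_frames`,
CSR-style `unit_index_ptr`, scalar `sampling_frequency`; int64 frames,
numpy-compatible, written as stored zip entries with zeroed timestamps so
output is byte-stable), and flat little-endian frame-major binary recordings
with a JSON sidecar and a `channel_id,x,y` probe CSV. CLI runs write a
`run_log.json` with the fully resolved configuration; `replay_run()`
re-executes it byte-identically.

## Known limitations

- The Hill-style ISI violation ratio saturates: it cannot distinguish
  contamination beyond its ~0.5 chance level, and its absolute scale should
  be read against that calibration.
- The amplitude-cutoff estimator assumes a unimodal, symmetric amplitude
  distribution; bimodal inputs hit the 0.5 cap by design.
- Isolation distance, L-ratio and d′ need a non-singular member covariance;
  with `n_comp` components on `C` channels the feature dimension is
  `n_comp·C`, so small clusters on high-channel-count probes yield NaN (use
  fewer components or channels).
- Chunked lazy filtering is exact only away from recording edges and for
  impulse responses shorter than the 1024-frame margin.
- The consensus unit uses exactly two donor trains (the group's strongest
  edge); spikes found only by a third sorter in the group are not added.
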