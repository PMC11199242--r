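---
title: "Microstate segmentation, ERN scoring, and the synthetic world: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

EEG microstate analysis treats the multichannel scalp potential as a
sequence of brief (~50–150 ms) quasi-stable topographies. At each time
point the average-referenced potential vector $x_t$ is modeled as
$x_t \approx g_t \, s_t \, a_{L_t}$, where $a_k$ is one of $K$ unit-norm,
zero-mean template maps, $g_t > 0$ is the global field power (GFP, the
spatial SD of $x_t$), $s_t \in \{-1, +1\}$ an ignorable polarity (for
resting data; oscillatory generators flip sign without changing
configuration), and $L_t$ a piecewise-constant label sequence. The analysis
estimates the templates, the labels, and per-state temporal statistics.

Because topographies at GFP peaks have the best signal-to-noise ratio,
templates are estimated from peak topographies only; backfitting then labels
*every* sample.

## Clustering and the number of states

`modified_kmeans()` alternates assignment and template update. In
polarity-invariant mode the assignment maximizes the squared spatial
correlation and the update is the principal eigenvector of the members'
outer-product sum — the maximizer of explained variance under sign
ambiguity. In polarity-variant mode (task data) assignment uses the signed
correlation and the update is the normalized mean. Restarts use
k-means++-style seeding (new seeds drawn proportionally to unexplained
variance), and on small instances ($n \cdot k \le 240$) a Hartigan-style
single-point relocation polish follows convergence — alternating
minimization alone has many shallow basins on tiny inputs, and the polish
makes 20 restarts reliably reach the global optimum (verified against
exhaustive partition enumeration in the acceptance suite). Empty clusters
are re-seeded from the worst-fit sample; assignment ties break to the lowest
template index; convergence is declared at label stability or a relative
objective change below 1e-6 (cap 1000 iterations). These determinism-first
tie-break rules are deliberate: reproducibility over elegance.

The number of states is chosen by `meta_criterion()`: seven cluster-validity
criteria each vote for their best k and the *lower median* of the votes wins
(ties resolve toward fewer states, the conservative choice). The criterion
set — Silhouette, Davies–Bouldin (negated), Dunn, point-biserial,
Calinski–Harabasz, Krzanowski–Lai, and the closed-form cross-validation
criterion (negated) — is this package's documented substitute for an
unpublished aggregate used by existing microstate software; the aggregation
structure (seven independent criteria, one vote each) is preserved. The
cross-validation criterion is the classic closed form
$\hat\sigma^2 \cdot ((C-1)/(C-1-k))^2$ rather than a held-out-split
estimate, because it is deterministic; this was the one open design point we
resolved differently from the obvious reading, precisely to avoid a second
RNG stream inside model selection. Distances between topographies are
$1 - r^2$ (invariant) or $1 - r$ (variant), matching the assignment rule.
Criteria undefined at a given k abstain; k = 1 never receives votes;
criteria that are numerically constant across candidates (relative range
below 1e-10) abstain, and solutions whose converged assignment uses fewer
than k clusters are disqualified at that k — on noiseless, perfectly
separable data every extra cluster collapses onto a duplicate template, and
without the disqualification rule the vote would be decided by float noise.

Stage structure mirrors the study design: per participant, 50 epochs of 833
randomly subsampled peak maps are clustered at k 1–12 and each epoch keeps
its meta-criterion winner; group level pools all winners' maps, resamples
100 epochs of 1000 sets at k 1–15, and a final clustering of the stage-2
winners yields the group templates. All stages are seeded and bit-for-bit
reproducible.

## Backfitting and temporal statistics

`backfit()` labels each sample with the best-correlated template, subject to
a minimum-correlation gate: 0.50 on |r| for resting data, 0.25 on signed r
(restricted to the state's own window) for task data. Sub-gate samples stay
unassigned — the gate is a hard constraint, never revisited by smoothing.
`smooth_labels()` minimizes, per sample,
$(1 - \mathrm{fit}_{t,k}) - \frac{\beta}{2w} N_{t,k}$ with $\beta$ the Besag
factor (default 10), $w$ the half-window in samples (32 ms), and $N_{t,k}$
the count of same-label assigned neighbors within $\pm w$ (self excluded).
The $2w$ normalizer makes the penalty scale-stable across sampling rates and
reduces exactly to unpenalized labeling at $\beta = 0$. Updates are
synchronous passes to a label fixed point (cap 100). Unassigned samples are
frozen and never counted as neighbors.

`enforce_min_segment()` removes runs shorter than 32 ms shortest-first with
re-scanning: the first $\lfloor \ell/2 \rfloor$ samples join the preceding
run, the rest the following run (odd samples favor the following run — an
arbitrary, documented convention); edge runs merge wholly into their single
neighbor. Unassigned runs are ordinary runs here: they can absorb halves and
be divided.

`temporal_stats()` computes GEV as GFP-weighted squared correlation with the
*final* label's template (recomputed after smoothing — a deliberate choice
where assignment-time and post-smoothing correlations could differ slightly),
normalized by total squared GFP over the analyzed range (the window only,
for windowed task backfitting, so GEV reads "fraction of within-window
variance explained"). Runs touching the analyzed-range edges are censored:
excluded from occurrence and mean duration (a truncated dwell biases the
mean) but included in coverage and GEV, which are pointwise.

## ERN pipeline

Condition averages are response-locked (−500…800 ms, baseline −500…−300 ms,
both windows closed) after RT filtering (keep 100–2000 ms, closed interval)
and epoch rejection; quality gates require ≥ 21 correct go and ≥ 6 error
no-go trials. The grand-average nogo−go difference wave is segmented in one
polarity-variant stage over all non-baseline timepoints (k 1–20, 300
restarts by default), labeled sequentially without a gate, smoothed, and
min-segment-cleaned. The error-related microstate is identified
deterministically as the labeled run containing t = 0 (most samples in
[−100, 150] ms on ties) — a reproducible stand-in for the visual inspection
a human analyst would perform, with a CLI override. Its channel pool (ROI)
is the template's negative pole: channels below (mean − 1 SD) of the
template — a thresholding stand-in for "channels surrounding the vertex",
also overridable. Scores are the mean over window × ROI per condition;
residualized ERN is the OLS residual of no-go on go scores.

## The synthetic world

The generator emulates what the pipeline needs to be tested against, not
biophysics. Defaults state the world once:

* montage: 32 channels quasi-uniform on the upper unit sphere (104 mirrors
  the study's retained high-density net; 32 keeps tests fast);
* resting: 157 s at 250 Hz (the study's trim and rate), mean dwell 100 ms
  with truncated-normal jitter (SD 40% of the mean, floor 40 ms — microstate
  dwell times are typically below ~150 ms), per-segment random polarity,
  GFP envelope = rectified smoothed Gaussian noise (many local maxima, so
  GFP peaks exist at realistic density), base GFP 10 µV, SNR 10 (mean signal
  GFP over noise GFP; spatially white sensor noise);
* task: epochs −500…800 ms, 120 go / 80 no-go, shared background microstate
  activity, error trials carrying a −5 µV central-negative component over
  −64…108 ms (scaled so its negative-pole mean equals the stated amplitude),
  RTs uniform 300–900 ms with a 5% out-of-range fraction;
* cohort: latent error-processing strength with linear couplings (default
  r = 0.5) to residualized ERN, error-state GEV, and one resting-state GEV,
  plus age/sex covariates and questionnaire totals.

What the generator does **not** emulate: volume-conducted spatial noise
correlations (available as an option but off by default), non-stationarity,
artifacts other than what the rejection tests construct explicitly, realistic
ERP components other than the planted one, and any lead-field physics. A
green recovery test therefore establishes the *algorithms* invert the stated
generative model at the stated SNR — not that the pipeline's numbers match
any particular laboratory's cohort.

## Numerical and scope notes

* All seeded code paths route through one seed argument; derived seeds stay
  below 2^31.
* The statistics module calibrates the F-change test without the MCD screen
  (the criterion targets the test itself); with the screen on, removals are
  reported per model and the focal-effect sign is stable on the synthetic
  cohorts.
* MCD uses support fraction 0.75 and flags at the χ²(0.975) quantile —
  conventional defaults, configurable; the robust scatter must be
  non-singular (smallest eigenvalue above 1e-12 of the largest).
* The spatial filter (min/max-trimmed mean over self + 6 nearest neighbors,
  then re-reference) and the per-epoch channel repair (same operator,
  neighbors only) are deterministic stand-ins for unpublished smoothing and
  spherical-spline interpolation operators; repairs are flagged in the
  rejection report so users can substitute their own.
* Backfitting recovery tests feed the planted templates directly rather than
  spatially filtering first: the filter is a fixed smoothing operator, and on
  coarse montages it shifts topographies away from templates that were not
  themselves derived from filtered data. In the full pipeline templates come
  from filtered data, so the two sides agree.
* EDF round trips are exact only to int16 quantization; BrainVision to
  float32; the package's own TSV format round-trips doubles exactly (%.17g).

## Known limitations

Single-CPU; no AAHC or hierarchical clustering variants; no
transition-syntax/Markov statistics; no source localization. The
meta-criterion's seven-criterion set matches the cited aggregate's structure
but not necessarily its exact members, so selected k values can differ from
other software on the same data.
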