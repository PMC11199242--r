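# microstatr

EEG microstate analysis for resting-state and response-locked (go/no-go)
data, with a microstate-guided scoring of the error-related negativity (ERN)
and the association statistics that link the two — plus a seeded
synthetic-EEG generator with full ground truth, so the entire pipeline is
testable without any recordings.

## Who this is for

Researchers analyzing multichannel scalp EEG who want a scriptable,
reproducible implementation of the classical microstate workflow:

1. **Preprocess** — average reference, spatial (outlier-trimmed neighborhood)
   filtering, amplitude / peak-to-peak / joint-probability epoch rejection
   with per-epoch channel repair, trimming, GFP-median normalization.
2. **Cluster** — topographies at global field power (GFP) peaks are clustered
   with the polarity-invariant *modified k-means* (for task data, a
   polarity-variant variant), at every candidate k; the number of microstate
   classes is chosen by a **meta-criterion**: the median vote of seven
   cluster-validity criteria (Silhouette, Davies–Bouldin, Dunn,
   point-biserial, Calinski–Harabasz, Krzanowski–Lai, cross-validation).
   A two-stage resampling scheme (epochs of subsampled maps per participant,
   then pooled sets across participants) yields group-level templates.
3. **Backfit** — each sample is labeled with the template of highest spatial
   correlation (|r| ≥ 0.50 at rest; signed r ≥ 0.25 within the identified
   window for task data), followed by Besag-penalized temporal smoothing
   (half-window 32 ms, factor 10) and removal of segments shorter than 32 ms.
   Per-state temporal statistics: GEV, coverage, occurrence, mean duration.
4. **ERN** — response-locked condition averages (−500…800 ms, baseline
   −500…−300 ms), nogo−go difference wave, single-stage polarity-variant
   segmentation of the grand average, identification of the error-related
   microstate (the labeled run containing t = 0), and mean-amplitude scoring
   over that window and the template's negative pole; scores are
   residualized (no-go regressed on go).
5. **Statistics** — MCD multivariate outlier screening, hierarchical OLS
   regression with ΔAdj-R² / F-change, and Benjamini–Hochberg correction
   across models.

## The statistics at the core

For an average-referenced topography $v \in \mathbb{R}^{C}$,
$\mathrm{GFP}(v) = \sqrt{\tfrac{1}{C}\sum_c v_c^2}$. The spatial correlation
between two zero-mean topographies is their cosine similarity; the modified
k-means maximizes, over templates $a_k$ (unit norm) and assignments, the
explained variance $\sum_t (a_{k(t)}^{\top} x_t)^2 / \lVert x_t \rVert^2$,
updating each template as the principal eigenvector of its members' outer
products (polarity-invariant) or their normalized mean (polarity-variant).
The GEV of state $k$ over an analyzed range is
$\sum_{t:\,L_t=k} \big(\mathrm{GFP}_t \cdot r_t\big)^2 \,/\, \sum_t \mathrm{GFP}_t^2$
with $r_t$ the correlation of sample $t$ with its assigned template.

## Worked example

```r
library(microstatr)

states <- make_template_maps(n_channels = 32, K = 4, seed = 1)
sim <- simulate_resting(states, duration_s = 60, snr = 10,
                        coverage = c(0.4, 0.3, 0.2, 0.1), seed = 2)
peaks <- extract_gfp_peaks(sim$recording)
sel <- select_k(peaks$maps, k_range = c(1, 8), polarity = "invariant",
                n_restarts = 10, seed = 3)
sel$profile
#> <criterion_profile: k in [1, 8], meta_k = 4>
#>           silhouette   neg_davies_bouldin                 dunn
#>                    4                    4                    4
#>       point_biserial    calinski_harabasz       krzanowski_lai
#>                    4                    4                    4
#> neg_cross_validation
#>                    4

seg <- backfit(normalize_gfp_median(sim$recording), sel$best, min_corr = 0.5)
seg <- enforce_min_segment(smooth_labels(seg, window_half_size = 32, besag = 10), 32)
temporal_stats(seg)
#>  state       gev  coverage occurrence mean_duration_ms
#>      1 0.3734242 0.3876000   2.383333        161.28671
#>      2 0.3270179 0.3211333   2.583333        123.04516
#>      3 0.1751016 0.1792000   2.183333         82.07634
#>      4 0.1173422 0.1120667   2.416667         46.37241
#> unassigned fraction: 0.000, total GEV: 0.993

round(sim$truth$coverage, 3)
#> [1] 0.388 0.321 0.179 0.112
```

All seven validity criteria vote for the planted K = 4, and the estimated
coverages (0.388/0.321/0.179/0.112 realized ground truth) are recovered to
three decimals. Occurrence is per second; durations in ms.

## Command line

A thin CLI wraps the same functions (`exec/mstate`, or `mstate_cli()` from
R): `mstate simulate {rest,gonogo,cohort}`, `mstate preprocess`,
`mstate segment`, `mstate backfit`, `mstate ern`, `mstate stats` — every
seeded invocation is bit-for-bit reproducible.

## File formats

Plain-matrix TSV (channels × samples, with a YAML sidecar for rate/montage;
exact round trip), template-map TSV, segmentation TSV, temporal-statistics
JSON, ERN-score CSV — plus readers/writers for EDF and BrainVision
(`.vhdr/.vmrk/.eeg`) continuous recordings.
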