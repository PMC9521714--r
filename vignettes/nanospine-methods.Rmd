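---
title: "Methods: nanoscale organization analyses for postsynaptic scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale organization analyses for postsynaptic scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nanospine implements three quantitative analyses of scaffold-protein
organization in dendritic spines — SMLM high-density-region (HDR)
detection against a randomization null, immunogold particle geometry on
annotated membrane contours, and a multi-state diffusion hidden Markov
model (HMM) for single-molecule tracking — together with seeded generators
that produce each input modality with ground truth. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, and what the validation on synthetic data does and does not show.

## 1. HDR detection in localization maps

**Model.** A localization field is a set of 2D points (nm) inside an ROI
polygon (the synaptic region analyzed). The local density of localization
$i$ is the number of other localizations within a fixed radius $r$,
$n_i(r)$, self excluded and boundary inclusive. The null hypothesis is
spatial uniformity: each of `n_reps` replicates re-draws the same number of
points uniformly over the ROI and recomputes the counts. HDR membership
requires $n_i(r) > \mu_0 + 2.5\,\sigma_0$ where $\mu_0,\sigma_0$ are the
mean and SD of the pooled null counts. Supra-cutoff points are linked into
connected components by single linkage at `link_radius`; components with at
least `min_points` members are HDRs. The effective diameter is the
diameter of the circle with the same area as the convex hull of the
member points.

**Parameters.**

| parameter | default | rationale |
|---|---|---|
| density radius `radius` | 50 nm | half the ~100 nm scale of the nanoclusters of interest; small enough to resolve 100–300 nm regions, large enough for stable counts |
| `n_reps` | 100 | pooled null of ~10^5 counts for a typical field; SD stable to a few percent |
| `sd_multiplier` | 2.5 | the published density cutoff |
| `link_radius` | = `radius` | supra-cutoff points closer than the counting scale belong to one region |
| `min_points` | 10 | suppresses chance pairs/triples of supra-cutoff points |
| `peri_band` | 100 nm | matches the 100 nm zone depth used throughout the EM analyses |

The local density is a fixed-radius count rather than a k-nearest-neighbor
or kernel estimate; the alternatives would change the null in the same way
as the data, but fixed-radius counting is the simplest statistic whose
null is exactly simulable. The cutoff is computed per field, not pooled
across synapses. No edge correction is applied to the counts: the same
uncorrected statistic is used for data and null, so the ROI-edge deficit
cancels in the comparison. Localization blinking is not corrected;
repeated localizations of one emitter inflate both the data counts and the
apparent cluster weight, which is a known caveat of density-based SMLM
cluster analysis.

**PSD outline.** The PSD-marker channel is outlined by thresholding its
own density distribution at mean + 2 SD, keeping the largest connected
component, and taking its convex hull. Two deliberate choices: (i) a
convex hull rather than a concave one — PSD outlines at this scale are
near-convex, and a concave hull would introduce an arbitrary concavity
parameter; (ii) the hull is dilated radially by `radius / 2` because a
localization at the edge of a dense region has about half its counting
disc outside it, so the supra-cutoff set is eroded by roughly half the
counting radius. On generated discs this compensation recovers the disc
area to within a few percent. The self-thresholding scheme requires the
dense region to hold a minority (below roughly 20%) of the channel's
localizations — equivalently, a visible off-PSD background — otherwise the
dense mode inflates the mean and SD past its own density. The generator's
PSD channel therefore includes a scattered background population
(default twice the scaffold-channel background), which also reflects real
PSD-marker channels, where a substantial fraction of the protein sits
outside the PSD.

**HDR position classes.** An HDR centroid inside the PSD polygon is
`psd-overlapping`; within `peri_band` of its boundary, `peri-synaptic`;
otherwise `distal`.

## 2. Immunogold geometry on membrane contours

**Distances.** Particle-to-membrane distance is the minimum Euclidean
distance to any contour segment (point-to-segment, not vertex-only); a
brute-force oracle that resamples the contour at 0.1 nm steps agrees to
within 0.1 nm in the tests.

**Zones.** The synaptic zone extends from the postsynaptic membrane
associated with the PSD to 100 nm into the cytoplasm; the extrasynaptic
zone is the region within 100 nm of the remaining spine membrane (the
analogous region of a dendrite-shaft contour is `nonsynaptic-shaft`).
A particle is assigned by its nearest contour point: on the PSD arc and
within the depth, `synaptic`; off the arc and within the depth,
`extrasynaptic`; deeper than 100 nm, `cytoplasm`; outside the contour,
`outside`. The "vertical distance" of the zone definition is implemented
as the minimum distance to the contour, which equals the perpendicular
distance wherever the membrane is locally flat relative to the 100 nm
depth; the PSD's lateral extent is delimited by the
nearest-point-on-arc rule with no outward extrapolation of the PSD
edges. All geometry is 2D (image plane / projection); silver-enhancement
label displacement (~10–20 nm) is not modeled — distances are to particle
centers as annotated.

**Statistics.** Distance summaries use the n−1 SD, linear-interpolation
quantiles, and CV = SD/mean; report tables round half-up at the printed
precision (base R's round-half-even would turn 35.52% into 35 rather than
36). Group comparisons use the two-sided Wilcoxon rank-sum test (exact
when sample sizes permit), Kruskal-Wallis with pairwise Wilcoxon post hoc
(Holm-adjusted; base R provides no Dunn test), or one-way ANOVA with Tukey
HSD; no correction is applied beyond the within-family adjustment. Gold
clusters are single-linkage components at `link_distance` 60 nm (about
twice the ~30 nm minimum nearest-neighbor spacing observed for membrane
labels) with at least 4 members; their diameter is the maximum pairwise
member distance. Nearest-neighbor analyses pool particles per compartment,
with a subset selector for per-structure analyses.

**Conformation calls.** With N- and C-terminus distance summaries, the
classifier calls `vertical-extended` when mean_C/mean_N >= 1.5 and a Welch
test from the summaries gives p < 0.01; `parallel-or-compact` when the
ratio is within 1.25-fold or p >= 0.05; otherwise `indeterminate`. The
1.5 threshold sits halfway between the published PSD case (ratio ~1.8) and
the equality band; the band of 1.25 allows the few-nm asymmetries seen at
the extrasynaptic membrane.

## 3. Diffusion HMM for pooled short trajectories

**Model.** Tracks are positions at fixed dt (default 0.022 s). In state
$k$ the single-step displacement is 2D Gaussian with per-coordinate
variance $2 D_k \Delta\tau$, so its magnitude is Rayleigh with
$\langle r^2 \rangle = 4 D_k \Delta\tau$; the state evolves by a
row-stochastic per-time-step matrix $A$. Fitting is maximum-likelihood EM
(Baum-Welch) with per-track forward-backward passes; the initial-state
distribution is a free parameter (keeping the EM ascent exact), while the
reported occupancies are the stationary vector of $\hat A$. The number of
states is selected by BIC over K = 1..3; the cap at 3 prevents
over-fitting the short, photobleaching-limited tracks. States are labeled
by ascending D, so state 1 is the bound/immobile state; dwell times are
$\Delta\tau/(1 - A_{kk})$.

This is a maximum-likelihood replacement for the variational treatment of
the same displacement HMM used in the original tracking analysis; with the
state count capped at 3 both approaches estimate the same parameter set.
Localization error is excluded from the default emission variance
(matching that analysis); an optional `loc_error` adds $4\sigma^2$ to the
emission mean square.

**Numerics.** Emissions are computed in log space and normalized per jump
before the scaled forward-backward recursions, so jumps far into a state's
tail cannot underflow. The forward-backward pass is vectorized across
tracks by step index (all tracks' step-t updates are one matrix
operation), which makes thousands of short tracks cheap. EM stops when the
relative log-likelihood gain drops below `tol` (1e-8) or at `max_iter`
(1000), returning `converged = FALSE` in the latter case. Restarts
(default 10) draw initial D log-uniformly over
[0.5 × the 10% jump-scale quantile, 2 × the 90% quantile], with the first
restart log-spaced deterministically; A starts at 0.8 on the diagonal.
Estimated D is floored just above zero so a state emptied by the E step
cannot produce a degenerate emission.

**Reference-model completion.** The WT and CS reference models
(`reference_hmm()`) carry the published diffusion coefficients and
occupancies for AKAP79 in spines. Only some transition entries are
reported (bound→slow, bound↔fast at 0.05 or less, fast→slow) along with
the bound-state dwell times; the remaining entries are completed by
detailed balance ($\pi_i A_{ij} = \pi_j A_{ji}$) against the renormalized
occupancies (the reported WT occupancies sum to 1.01). The completed
matrices reproduce every reported entry and the reported bound dwell
times (0.022/0.15 ≈ 0.15 s WT, 0.022/0.29 ≈ 0.08 s CS); they are a
documented model completion, not themselves reported quantities. The CS
bound-state D is not reported separately and is set to the WT value, as
the per-state coefficients are very similar between variants.

## 4. Synthetic-data generators

Every generator takes a mandatory seed and returns ground truth. They
emulate the statistical structure the analyses assume, not the microscopy:
no PSF/camera simulation, no 3D.

- **SMLM synapse** (`simulate_smlm_synapse()`): PSD-marker channel =
  uniform disc (default radius 150 nm, 3000 localizations/μm²) over a
  scattered background; scaffold channel = uniform Poisson background
  (default 300/μm² over a 2×2 μm ROI) plus isotropic Gaussian nanoclusters
  (default 3 clusters, σ 40 nm, 200 localizations) placed just outside the
  PSD disc within 100 nm of its boundary (peripheral placement). Emitter
  re-blinking is modeled as 1 + Poisson(blink_factor − 1) copies with
  localization jitter; the default blink_factor 1 disables it, since the
  upstream analysis applies no blink correction either. Cluster sizes and
  densities follow the ~70–300 nm nanocluster scale of PSD scaffolds.
- **EM spine** (`simulate_em_spine()`): an elliptical spine-head contour
  (default 600 × 500 nm, 200 vertices) with a PSD arc (default 300 nm);
  particles are placed at inward-normal offsets drawn from per-zone
  truncated normals — defaults are the wild-type synaptic model
  (34 ± 18 nm truncated to [0, 100]) and extrasynaptic model (13 ± 5 nm) —
  laterally uniform along each zone's arc, with an optional hard-core
  minimum spacing. Organelles carry Bernoulli labeled flags (default
  labeling probability 0.86, the wild-type endosome-label fraction).
- **Tracks** (`simulate_tracks()`): initial state from the stationary
  distribution of A, per-step switching by A, Gaussian displacements,
  optional additive localization error and an optional reflecting circular
  confinement (off by default — spine confinement at the published jump
  scale is secondary to state structure). Track lengths are geometric —
  each track has 1 + Geometric jumps with mean `mean_track_len` (default 6,
  chosen so that ~7300 tracks yield the published ~39,000 jumps, matching
  photobleaching-limited track statistics) — with a minimum of two
  positions. Whether the original trajectories were corrected for
  localization error or blink-induced splitting is not stated; both appear
  as explicit parameters instead of baked-in guesses.

**What passing tests show.** Recovery on these generators validates the
estimators under the stated models: uniformity nulls, Gaussian clusters,
truncated-normal offsets, memoryless switching diffusion. Real data
violate these in known ways — blinking-correlated localizations, non-Gaussian
cluster shapes, annotation digitization error, state-dependent
bleaching — so passing tests bound implementation correctness, not
biological validity.

## 5. Validation problem sizes

The test suite exercises: exact equivalence of the neighbor counts with an
all-pairs brute force (2,000 points); 0.1 nm agreement of contour
distances with a densified oracle; specificity (mean false-HDR count over
100 uniform fields ≤ 0.1) and sensitivity (≥ 90% recovery of clusters
planted at 5× peak-to-background contrast); HMM recovery of the WT
reference model from 3,000 tracks across 5 seeds (D within 20%,
occupancies within 0.05, bound dwell within 30%); BIC state-count
selection on 1-state and well-separated 3-state data; and the exact
label-fraction, dwell-time, and conformation arithmetic. Jump statistics
are cross-checked against the closed-form Rayleigh-mixture CDF
(`mixture_cdf()`), with the simulated empirical CDF within KS distance
0.01 at 10^5 jumps.

## 6. Interfaces and units

Localization and EM coordinates are nanometres; track coordinates are
micrometres (each community's convention); units are embedded in the
column names (`x_nm`, `x_um`). CSV files are UTF-8 with headers and "."
decimals; JSON schemas are versioned. The ThunderSTORM export header
(`"x [nm]"`, `"y [nm]"`, `"uncertainty [nm]"`) is accepted on input.
Rendered-image pixel size is irrelevant to coordinate analysis and
ignored. The package is an R library: the reader/writer functions and
`run_pipeline()` (stages: simulate-smlm, hdr, simulate-em, em-dist,
simulate-tracks, jumps, hmm) are the orchestration surface; no shell
wrapper is shipped.

## 7. Known limitations

- No blink/overcounting correction in density analysis; HDR counts and
  sizes are biased by fluorophore photophysics exactly as in the upstream
  method.
- The extrasynaptic "vertical distance" is a minimum distance; for highly
  curved or invaginated membranes it can underestimate the
  along-normal distance.
- The HMM assumes memoryless switching and state-independent track
  termination; state-dependent bleaching would bias occupancies.
- Whether reported occupancies should be stationary or posterior-weighted
  fractions is a convention choice; stationary occupancies are reported,
  and posterior fractions are available from `predict()`.
- 2D throughout; tomographic projections are analyzed in the image plane.
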