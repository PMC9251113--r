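---
title: "Mapping and decoding cortical hue domains from intrinsic signal imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and decoding cortical hue domains from intrinsic signal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(huedomains)
```

## The problem

Intrinsic signal optical imaging (ISOI) records stimulus-evoked changes in
cortical light reflectance under red illumination. Neural activation raises
local deoxyhemoglobin and darkens the tissue, so an activated patch appears
as a *negative* fractional reflectance change on the order of
$\Delta R/R \sim 10^{-3}$. When the stimuli are isoluminant gratings whose
hue moves around the cone-opponent (DKL) color plane, small cortical patches
— *hue domains* — respond preferentially to particular hues, and domains of
neighboring hues overlap and chain into *hue clusters*. This package
implements the full analysis path from trial-wise image stacks to thresholded
hue domains, cluster morphometrics, and multivariate decoding of hue
identity, together with a synthetic-data generator that plants known ground
truth so that every stage is testable without access to raw imaging data.

## Stimulus geometry

Hues live in the isoluminant plane of DKL space. Hue angle 0° is the +L−M
direction, 90° is +S, 180° is +M−L, 270° is −S; the experiment samples every
45°. `dkl_cone_contrast()` maps an angle to Weber cone contrasts: the locus
is scaled so the maxima are 7% for the L cone (along L−M) and 70% for the S
cone (along S), and the M-cone contrast is set so the weighted L+M luminance
sum stays constant. The luminance weights default to a 2:1 L:M ratio and are
configurable, because they depend on the cone fundamentals chosen; every
choice keeps the isoluminance invariant $w_L c_L + w_M c_M = 0$ exactly,
which is what the tests assert. RGB rendering of stimuli is out of scope —
the analysis consumes only the condition labels.

A canonical run has 10 conditions (`make_condition_set()`): eight hue
gratings at 10% luminance contrast, one achromatic grating, one blank.

## From stacks to maps

A trial is an 18-frame stack (4 frames/s × 4.5 s), with stimulus onset at
1.0 s; frame $k$ (1-based) covers $[(k-1)/4, k/4)$ s. `compute_dRR()`
averages the frames whose bin centers fall in the pre-stimulus window
$[-1, 0)$ s and the response window $[1, 3.5)$ s relative to onset (frames
1–4 and 9–18) and forms $(R_1 - R_0)/R_0$ per pixel. Pixels with a
non-positive baseline are flagged `NA` and stay `NA` through every
downstream operation.

Two running-median filters shape the maps ("median filter" here means a
running median, the robust standard in ISOI, not a convolution):

* `highpass()` subtracts a 1.0 mm × 1.0 mm median, removing the global
  signal (non-specific fluctuations spanning several millimeters or more);
* `smooth_map()` applies a 160 µm × 160 µm median to suppress
  high-spatial-frequency noise before statistics.

Kernel sizes are `round(size/pixel_pitch)` forced odd, with reflected border
padding; both choices make results deterministic and borders unbiased. The
implementation delegates to EBImage's constant-time median filter after an
affine rescale of the data into its `[0, 1]` working range; the 16-bit
internal quantization puts the filter within $2\,(\max-\min)/65535$ of an
exact running median, which the tests verify against a brute-force oracle.

`single_condition_map()` (condition mean minus blank mean),
`subtraction_map()` (condition A minus condition B; darker = stronger for A)
and `hue_vector_map()` complete the map set. The vector-sum map places each
hue's single-condition response at its hue angle and sums vectors per pixel.
Since activation is a darkening, responses are rectified as
$r_h = \max(0, -v_h)$ by default; negative response magnitudes have no
meaning in a polar sum. The signed variant (`rectify = FALSE`) exists for
sensitivity checks, as the rectification convention is not uniquely
determined by common practice.

## Statistics: vessels, pixel tests, cluster extents

**Vessel exclusion.** Pixels on or near large vessels fluctuate strongly
from trial to trial even without stimulation. `vessel_mask()` computes the
per-pixel SD of blank-condition maps across trials and excludes pixels whose
variance exceeds the upper limit of the one-sided 95% chi-square interval,
$\hat\sigma^2 \chi^2_{1-\alpha,\nu}/\nu$ with $\nu = n-1$. The reference
$\hat\sigma^2$ is the across-pixel *median* of the per-pixel variances
(robust to vessel contamination), rescaled by $\nu/\chi^2_{0.5,\nu}$ so that
under homogeneous noise the expected exclusion fraction is exactly
$\alpha$ — without that rescaling the median's small-sample bias (~2% at
$\nu = 39$) would push the null exclusion rate visibly above $\alpha$. The
pipeline feeds this rule high-passed but *unsmoothed* blank maps: high-pass
removes the shared global signal (blanks carry no evoked response, so the
filter is unbiased there), while smoothing would smear vessel variance into
halos around every vessel.

**Pixel-wise tests.** `pixelwise_ttest()` (two-tailed two-sample, pooled
variance by default) and `pixelwise_anova()` (one-way, or balanced two-way
main effects for hue × orientation) run vectorized across all pixels and are
cross-checked in the tests against `t.test()` / `aov()` pixel by pixel.
Pixels with zero within-group variance are flagged invalid rather than
granted $p = 0$.

**Ordering decision.** The statistical path is $\Delta R/R \rightarrow$
160 µm smooth $\rightarrow$ test. The high-pass is *not* applied before the
tests, on purpose. A running-median subtraction is slightly biased wherever
a window contains a genuinely dark patch: the median of the surround shifts
by roughly $\varepsilon\sigma\sqrt{2\pi}/2$, where $\varepsilon$ is the
fraction of window pixels inside responding domains. That bias is tiny
(~$10^{-5}$) but it is a *mean* shift, so after smoothing — which cuts
independent pixel noise by an order of magnitude — it becomes a ~2-standard-
error artifact that surrounds every true domain with spuriously significant
halo at realistic trial counts. Because hue and achromatic conditions carry
different domain responses, the halos do not cancel in the contrast. Keeping
the tests on smoothed raw maps avoids the artifact; the global signal that
the high-pass would have removed is common-mode between the compared
conditions and only costs power, which the trial counts easily absorb.
High-pass filtering is retained where it belongs: display maps,
vector-sum maps, decoding features, and the vessel rule.

**Cluster-extent thresholding.** `cluster_extent_threshold()` implements the
multiple-comparison rule: keep 8-connected components of $p < 0.05$ pixels
that span at least 200 contiguous pixels, contain a peak $p < 0.001$, and
overlap (≥ 1 pixel) a component passing the same size/peak rule in an
independent session. The 200-pixel extent is defined at the reference pitch
of 8 µm/pixel (≈ 12,900 µm², equivalent diameter ≈ 128 µm) and rescales as
$(8/\text{pitch})^2$ on other grids so the physical minimum is invariant.
"Reproduced in another session" is operationalized as one-pixel overlap
because no stricter overlap rule is canonical; the choice is recorded and
trivially configurable at the call site by pre-filtering regions. Note the
detection floor this rule implies: domains smaller than ~128 µm equivalent
diameter cannot pass it at 8 µm pitch, so the smallest (V1-scale, ~84 µm)
domains are intrinsically below the floor — one reason measured domain areas
are method-dependent and should be used for relative comparisons only.

## Domains, clusters, morphometrics

`extract_domains()` turns each surviving region into a hue domain (area =
pixel count × pitch², equivalent diameter $2\sqrt{A/\pi}$, peak = minimum-p
pixel with ties broken by larger |statistic| then row-major order) and drops
domains touching vessel-masked pixels. `build_clusters()` forms the domain
overlap graph (edge = ≥ 1 shared pixel) and keeps connected components with
at least 4 distinct hues; a cluster with all 8 is *complete*. Components
that chain more domains than hues (merged clusters sharing domains) are kept
whole and flagged by their `n_domains` — no splitting rule is attempted
because none is well defined. `normalized_domain_area()` (domain area over
cluster union area), `completeness_summary()` (percentage of incomplete
clusters, one decimal) and `arrangement_path()` (peaks ordered by hue angle)
provide the morphometrics used to compare areas and hues.

## Decoding

`bin_map()` reduces maps by non-overlapping block means (default 10 × 10
pixels → 80 µm bins; a 1308 × 1080 frame becomes 131 × 108), keeping partial
edge blocks and ignoring invalid pixels inside a block.
`make_features()` flattens the ROI bins of every trial map into a feature
matrix and z-normalizes per feature. The default scheme standardizes with
the mean and SD pooled over *all* trials: the per-stimulus variant
(normalizing within each condition) is also implemented, but taken
literally it removes the class means and with them the linearly decodable
signal, so it exists for comparison rather than as the default.
`balance_trials()` equalizes per-condition counts by seeded downsampling,
and `subsample_features()` equalizes feature counts across areas for fair
comparisons.

`cv_accuracy()` runs stratified 10-fold cross-validation of a linear
max-margin classifier (LIBSVM via e1071, linear kernel, cost 1, one-vs-one
multiclass reduction — the mature linear-SVM implementation available;
the decision family is linear either way). `bootstrap_accuracy()` resamples
the training set with replacement 1000 times, refits, evaluates on the
intact test split, and reports the mean, the 2.5/97.5 percentile interval,
and $p = \max(1/B, \Pr(\text{acc} \le \text{chance}))$ — the p-value is
floored at $10^{-3}$ for $B = 1000$ by construction. The bootstrap is run on
a single stratified 90/10 split rather than inside every CV fold; nothing
in the procedure's definition forces the latter and the single split keeps
the resampling distribution interpretable. `compare_areas()` declares two
accuracy distributions different when the 2.5th percentile of the higher one
exceeds the 97.5th percentile of the lower one (97.5% non-overlap).

## The synthetic generator

`make_layout()` plants clusters of circular hue domains on a ring: each
domain sits at its own hue angle (plus a random per-cluster rotation), so
adjacent-hue domains overlap partially and the cluster is a chain arranged
circularly in hue order — the geometry the arrangement analysis expects.
Defaults: a 256 × 256 px field at 8 µm/pixel (≈ 2 × 2 mm — a desk-scale
field; all physical kernel sizes are honored through the pitch), four
clusters, three complete and one missing hues 45° and 90° (emulating
under-represented +S hues), domain diameter 250 µm jittered ±10%
(log-normal, truncated at 2 SD). The 250 µm default lies within the range
reported for higher visual areas and deliberately clears *both* size floors
the detection method imposes: the cluster rule's 200-pixel extent
(equivalent diameter ≈ 128 µm at 8 µm pitch) and — less obviously — the
160 µm median smoothing itself. A running median erases objects whose area
is comparable to half its window: a 190 µm disk (≈ 345 px) barely exceeds
half the 21 × 21 px window (441 px), so its noise-free smoothed support
covers only ~half of its pixels and detection fragments below the extent
threshold. Domains must exceed roughly 200 µm before their smoothed support
is robust. A V1-like 84 µm preset exercises the geometry but cannot be
recovered through this pipeline — a property of the published method's
filters, not a bug. Hue tuning of a planted domain is a circular raised cosine with
compact support, $\cos^2(\pi d / 2w)$ for circular distance $d < w$; the
default half-width $w = 45°$ makes each domain respond to exactly one of the
eight hues (crisp ground truth), while wider settings give graded responses
for tuning-curve tests.

`simulate_trial()` composes, per frame: baseline counts; the evoked
darkening (peak $\Delta R/R = -10^{-3}$) ramping linearly to plateau over
1 s after onset; a global signal (one spatial cosine of 10 mm wavelength —
global fluctuations span the imaged field, so the 1 mm high-pass removes
them almost exactly — with a per-trial Gaussian amplitude, SD
$5\times10^{-4}$); a spatially correlated *vasomotion* component; shot noise
(iid per pixel and frame), tripled in SD on vessel pixels; and 16-bit
digitization to integer counts. Vessel lines are sampled to stay clear of
the planted clusters: the screening rule drops vessel-contaminated domains,
so planting truth under a vessel would make the ground truth unreachable by
design; experimenters similarly select analyzable, vessel-free patches.

The noise budget deserves a note. The per-trial map noise SD is
$2\times10^{-4}$ — one fifth of the response peak — split between white shot
noise ($1.6\times10^{-4}$ at the map level) and vasomotion
($1.2\times10^{-4}$, correlation length 150 µm, implemented as coarse white
noise bilinearly upsampled with a random grid offset per trial so the field
is stationary). Both the split and the correlation length matter. Median
smoothing cuts *white* noise by ~17× but passes correlated fluctuation, so
a generator with only white noise would hand the cluster rule an
unrealistically tiny noise floor, and every domain would be detected with a
wide penumbra; the correlated share sets the effective detection floor and
keeps recovered footprints close to the planted disks. The correlation
length in turn sets the size of null clusters in the smoothed t maps: at
several hundred µm the 2 × 2 mm desk field holds only a handful of
independent patches, and chance suprathreshold blobs grow to thousands of
pixels, attach to true domains and merge clusters across the field. At
150 µm — the scale of fine parenchymal vasculature, and comparable to the
smoothing kernel — null blobs stay near the extent threshold and the
cluster rule behaves as designed.

What the generator does *not* emulate: real vascular geometry (vessels are
straight lines), hemodynamic nonlinearities and undershoots, eye- or
orientation-specific maps (only an optional binary orientation gain),
breathing/heartbeat harmonics, and slow session drifts. Passing the
recovery suite therefore shows the pipeline is correct under the stated
noise model, not that it is robust to every artifact of a physiology rig.

## Problem sizes and numerical choices

The packaged test and acceptance runs use the desk-scale defaults: 256 × 256
fields, 40 trials per condition per session, two sessions (800 stacks), and
smaller fields (64–128 px) for law-of-large-numbers and monotonicity
checks — sizes chosen so the whole suite completes in minutes while keeping
every rule at its paper-scale parameters (200-pixel extents, 160 µm and
1 mm kernels, 10 × 10 binning, $B = 1000$ bootstrap in the acceptance run).
Ties in peak selection are broken deterministically; all randomness flows
from a single seed through per-stage derived streams; maps are stored in
image coordinates (row 1 = top) and physical units enter only via
`pixel_pitch`. Stacks are written as 16-bit integer TIFF (lossless for
camera counts); dR/R maps as 32-bit-quantized TIFF with affine scale and
validity mask in a JSON sidecar, which reproduces values to better than
single precision over the data range.

## Known limitations

* The cluster-extent rule's false-positive behavior is calibrated under
  independent-pixel nulls; after 160 µm smoothing, null clusters are larger
  and the cross-session reproduction requirement is the effective guard. A
  noise blob that touches a true domain's component inherits that
  component's credentials and inflates its footprint — visible occasionally
  as one oversized domain in a recovery run.
* Domain areas are method-dependent (filter sizes, trial counts); they are
  meant for relative comparisons.
* The one-vs-one multiclass reduction differs from one-vs-rest used with
  LIBLINEAR-style solvers; accuracies on separable or near-chance data are
  indistinguishable, but per-class error patterns can differ slightly.
* With fewer than ~10 blank trials the chi-square vessel rule is weak; the
  generator defaults provide 40 per session.
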