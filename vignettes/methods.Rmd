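---
title: "Methods: social ensemble detection from calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social ensemble detection from calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(socens)
```

# Overview

`socens` identifies social-behavior-tuned neurons in two-photon calcium
imaging of a mouse performing a three-stage exploration assay. The recorded
quantities are a fluorescence video (e.g. 512×512 px at 9.76 Hz, field of
view 420 μm, so 420/512 μm per pixel) and a 30 Hz head trajectory; the
derived quantities are per-neuron ΔF/F traces, binary behavior vectors, and
a cascade of statistics built on the contrast between exploration (E) and
nonexploration (NE) frames.

This vignette documents the model assumptions, the tunable parameters, the
numerical choices made where the underlying procedure admitted several
readings, and what the synthetic-data generator does and does not establish.

# Behavior

The head trajectory is smoothed with a coordinatewise running median
(default window 5 behavior frames ≈ 167 ms; endpoints use shrinking
windows). A direct-exploration epoch of event type `E` is a maximal run of
frames whose Euclidean head-to-target distance is below a threshold
(default 3 cm) lasting at least `min_duration` (default 0.5 s). Both values
are configuration keys rather than constants because direct exploration is
operationally "mouth-to-mouth contact", a criterion that was verified
manually in the original workflow; an automated distance proxy must be
tunable, and a manual epoch-override file can replace detected epochs
entirely. No gap merging is performed: one above-threshold frame splits an
epoch in two.

Behavior (30 Hz) and imaging (9.76 Hz) clocks are aligned by giving each
imaging frame the label of its nearest behavior timestamp; the alignment
error is at most half a behavior frame (16.7 ms) for overlapping uniform
clocks and is reported as mean ± SD. Epochs shorter than one imaging frame
can vanish in this resampling; this is accepted and tested rather than
special-cased.

Conventions used everywhere: imaging frames are 0-based; epochs are
half-open `[start, end)` in both frames and seconds; `B_NE` is 1 exactly
where no event vector is 1 (a frame-exact partition).

# ΔF/F extraction (ARS)

Per neuron, with `F_raw` the mean soma intensity, `F_ring` the mean
intensity of an annulus around it and `F_b` the per-frame minimum pixel of
the video:

```
F_ROI = F_raw - F_b
F_con = F_ring - F_b
F_sig = F_ROI - alpha * F_con        (alpha = 1 by default)
dF/F  = F_sig / F_0,   F_0 = mean(F_ROI)
```

Two ambiguities are resolved as follows and kept configurable:

* **Baseline convention.** `F_sig / F_0` as written has baseline near 1.
  `ars_dff(..., convention = "relative")` returns `(F_sig - F_0)/F_0`
  (baseline near 0). All downstream statistics that compare trace values
  against noise levels (engagement, EAN detection) assume the baseline-0
  convention, which is what the pipeline uses; the ratio form is the
  default of `ars_dff()` itself so the formula chain is reproducible as
  stated.
* **Background.** "Concatenated minima of the stack" is read as a per-frame
  minimum trace (one value per frame); a global scalar minimum is available
  via `per_frame = FALSE`. Note that with α = 1 the background cancels out
  of `F_sig` entirely and only rescales `F_0`.

The annulus takes pixels whose distance to the nearest soma pixel lies in
`(gap, gap + width]` px (defaults gap 2, width 4 — the source procedure
never states the geometry), excluding pixels of *any* soma so a neighbor's
signal never leaks into the ring. An empty ring after exclusions is an
error for that neuron, not a silent zero.

Segmentation is a simplified stand-in for the original detection framework:
the feature image is the per-pixel mean of squared positive z-scores over
time (our definition of "normalized power enhancement": it amplifies
transient-active pixels over static background), seeds come from a
Laplacian-of-Gaussian blob detector at soma scale (σ = 3 px), the mask from
an adaptive threshold (median + 3·MAD), and candidates are kept by area
range and a robust trace-SNR test. Blob detection replaces the cited
tubular-structure detector because somata in this preparation are
blob-like. Motion correction is out of scope; input is assumed registered.

Cross-day matching declares two neurons identical iff, after applying the
supplied displacement field, centroid distance < 3 μm *and* mask overlap
(defined as Jaccard, intersection over union — "overlap rate" is not
otherwise specified) > 0.75, with greedy smallest-distance-first one-to-one
assignment.

# SAN / SIN classification

The similarity between the binary social vector `B` and a trace `C_i` is

```
S_i = (B . C_i) / (|B|^2 + |C_i|^2)
```

Each neuron's `S_i` is compared to `k = 1000` similarities computed after
fully re-permuting `B` (norms are permutation invariant, so only the dot
product is resampled; for binary `B` with `m` ones this is an O(k·m)
sampling problem, implemented in C++ against R's RNG). A neuron is SAN if
`S_i` strictly exceeds the 99.17th percentile of its null, SIN if strictly
below the 0.83rd percentile (≈ 1/120 per tail; the choice is inherited as
given), otherwise Other — ties are Other by the strict inequalities.
Percentiles interpolate linearly between order statistics (R quantile
type 7), configurable.

A full random shuffle ignores the autocorrelation of behavior; that is the
procedure as stated, and it is what the calibration targets certify: on
traces independent of `B`, the fraction not labeled SAN is ≈ 99.17% and the
fraction labeled SIN ≈ 0.83% within binomial error. A block/circular-shift
null could be added by permuting epoch labels instead, but it is
deliberately not the default because it would change those calibration
semantics.

No multiple-testing correction is applied across neurons (none is applied
in the source procedure); the number of tests equals the number of neurons
and is recorded in the outputs.

# Event averages, noise, engagement

Peri-event averages use 8 s windows: 4 s of clean NE before an onset and
4 s inside the event (mirrored for offsets); traces are smoothed with a
span-5 centered moving average ("low-pass filter with a span of 5" read in
its common source-environment meaning) before alignment, fragments are
averaged per neuron and then across the ensemble. The *relative* variant
subtracts the neuron's mean ΔF/F over NE frames first, so its NE half is
zero-mean up to noise.

Noise levels are the SD of the trace after a 50th-order FIR high-pass at
1 Hz cutoff (9.76 Hz sampling). The named order and cutoff do not fix a
design, so the filter is a Hamming-windowed sinc low-pass converted by
spectral inversion, applied forward only, with the first 50 (unfilled)
samples dropped. On white noise this passes (Nyquist − 1)/Nyquist ≈ 80% of
the variance, i.e. reads ≈ 0.89 σ; tests therefore use a 15% tolerance.

A neuron is *engaged* in an event iff at least `n = 10` samples inside the
event exceed 3× its noise level (noise from the whole trace, per the stated
definition — contrast with EAN noise below, which is NE-only). Events
shorter than 10 frames can never be engaged; this degenerate case is
documented and tested rather than rescaled.

# EAN and cue-preferred detection

For each event type `E`, `c_E` is the mean ΔF/F over `E` frames and `c_NE`
the mean over NE frames, where the angle-bracket mean `<B_E · C_i>` is read
as the *conditional* mean over active frames (dividing the masked sum by
the full trace length would conflate tuning with event frequency; the other
reading is available via `normalize = "full"`). The NE contrast is
stage-specific: cage is tested against habituation NE, object/mouse against
sociability NE, new/old against novelty NE — the three-stage structure
implies this pairing although it is nowhere stated outright. `noise_NE` is
the high-pass SD of the concatenated NE frames of that stage.

`E`-association is the strict test `c_E − c_NE > β · noise_NE` with
β = 0.5; the EAN set is monotonically shrinking in β (a tested invariant).
Cue preference is pure set logic: NewPN iff NewN and none of
CageN/ON/MN/OldN; OldPN symmetric; mutually exclusive by construction and
verified against brute-force set evaluation on all 32 flag patterns.

The behavioral correlation matrix correlates per-state response profiles
per neuron and averages over the ensemble. "ΔF/F segments during different
states" could mean concatenated raw segments or per-state event averages;
the event-average profile (onset-aligned, 8 s) is the default because it is
length-matched across states by construction, and the segment reading
(truncated to the shortest state) is selectable.

# Epoch kinetics

A social epoch is *discarded* if it lasts under 4 s or if the
exploration-free gap before it is under 4 s ("social or presocial
exploration times shorter than 4 s" is read as a constraint on the gap
immediately preceding the epoch — the stated purpose is preventing
cross-talk from adjacent events, which the gap reading achieves). Otherwise
the peak is the maximum of the trace over `[start − 4 s, start + 4 s]`; the
epoch is *activated* iff the peak falls strictly after the start (a peak at
`t = 0` counts as nonactivated; ties across frames take the earliest
frame). `P_up` is activated / (activated + nonactivated); rise time is peak
time − start and amplitude is peak − (minimum over the 4 s pre-window),
both averaged over activated epochs.

# Signed networks

ΔF/F traces are spliced by state (social or nonsocial frames concatenated
in time order — a linear correlation is used precisely because splicing
breaks temporal continuity), correlated pairwise (Pearson), and the matrix
is split into positive and negative parts. The "generalized clustering
coefficient" is not given as a formula; we adopt the Zhang–Horvath weighted
form computed on cube-rooted weights,

```
C_u = sum_{v,w} (w_uv w_vw w_wu)^(1/3)
      / [ (sum_v w_uv^(1/3))^2 - sum_v w_uv^(2/3) ]
```

because it reduces exactly to the unweighted clustering coefficient on
binary graphs (verified exhaustively up to 6 nodes) and keeps coefficients
in [0, 1]. Scaling all weights by λ scales coefficients by λ^(1/3) — this
behavior is documented and tested, not hidden. An Onnela-style variant is
selectable. Isolated nodes (zero denominator) get coefficient 0 and are
flagged. No correlation thresholding is applied by default. Whether social
and nonsocial coefficients should be computed on matched frame counts is
exposed as a user decision (splice the longer state down yourself); the
package does not silently equalize.

# The synthetic generator: what it emulates, what it does not

`simulate_behavior()` reproduces the paradigm's structure: three stages
(default 300 s each — 5-minute sessions), cage epochs only in habituation,
object/mouse in sociability, new/old in novelty, epochs placed sequentially
with drawn durations (default 2–8 s, 2 epochs/min per type, ≥ 1 s apart)
and a 30 Hz Ornstein–Uhlenbeck trajectory snapped to within contact radius
of the active target during each epoch. Requests that cannot fit the stage
raise an explicit error.

`simulate_dff()` plants one class per neuron. Responsive classes emit, with
per-epoch probability 0.7, a transient `gain × k(t)` where `k` is a
double-exponential kernel with 0.2 s rise and 1.8 s decay — typical
GCaMP6s-like kinetics, chosen because the indicator's kinetics are not
reported for this preparation; both are configurable. The kernel is
evaluated from the behavioral onset on the imaging grid (so rise-time
estimates are meaningful to one frame). The per-epoch Bernoulli response
exists precisely so activation-probability statistics have nontrivial
ground truth. SINs carry an elevated tonic level (1.0 vs 0.2) suppressed by
a kernel-smoothed step during social epochs. Defaults gain 1.0 and noise SD
0.2 give the 5:1 response-to-noise regime the recovery criteria are stated
at; no SNR figures exist for the real recordings, so these are stated
defaults, not inferences.

`render_video()` draws disk somata (radius 4 px) on a jittered grid, a
smooth cosine neuropil field with a slow shared temporal trace, a camera
offset and white pixel noise, clamped nonnegative; 16-bit TIFF output.
Overlapping somata are rejected so ground truth stays identifiable.

What the generator does **not** emulate: brain motion, photobleaching,
correlated (pink) noise, soma shape irregularity, overlapping or
out-of-focus cells, or the animal-tracking problem itself. A green
planted-recovery test therefore establishes that the detectors implement
their definitions correctly and are calibrated under their stated null — it
does not establish performance on real recordings, and the package makes no
claim about reproducing the original study's empirical counts, which
require the original data.

# Reproducibility

Every stochastic step consumes R's RNG under a single top-level seed that
fans out to per-module child seeds (`behavior = 1, dff = 2, video = 3,
classification = 4`) via a fixed affine map modulo a < 2³¹ prime, so any
module can be re-run in isolation bit-identically. `run_pipeline()` writes
a manifest (package version, seed, full config, config MD5) sufficient to
re-run. Identical seeds give identical CSVs; this is a tested contract.

# Known limitations

* The permutation null ignores trace and behavior autocorrelation by
  design (see above); its calibration statements are about exchangeable
  nulls.
* Segmentation is intentionally simple and tuned for blob-like somata at
  the default scale; dense or overlapping fields need the area/σ/SNR
  parameters adjusted.
* The high-pass noise estimate under-reads white noise by ≈ 11% (energy
  below cutoff); thresholds expressed in noise units inherit that bias
  consistently, so comparisons across neurons are unaffected.
* TIFF support covers the plain dialect the package writes (uncompressed
  16-bit little-endian grayscale); HDF5 export needs the optional `rhdf5`
  package.
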