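---
title: "Simulating and quantifying multiplexed FLASH-PAINT proximity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying multiplexed FLASH-PAINT proximity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashpaint)
```

## What is being modelled

FLASH-PAINT images many protein species sequentially in one sample: each
species carries a distinct DNA docking strand (via an antibody or
nanobody), a transient adapter recruits the dye-labeled imager to one
species at a time, and an eraser strand silences that species before the
next round. Each round is an ordinary DNA-PAINT acquisition — tens of
thousands of camera frames in which individual docking sites blink as
imagers bind and unbind — and yields a super-resolved point cloud. Across
rounds the clouds share one coordinate frame, so distances *between*
species are meaningful at nanometre scale.

The package's generator reproduces this acquisition over a parameterised
Golgi-ribbon phantom with full ground truth, and the analysis half
re-implements the downstream processing: localization, drift correction,
round alignment, and the median cross-target distance statistic under a
500 nm neighbour cutoff.

## The geometry phantom

The Golgi stack is represented in 2-D, as a ribbon backbone polyline with
each species' layer displaced along the local stack normal (cis → trans)
and optionally along the ribbon tangent. A 2-D model is appropriate
because the acquisition this emulates is near-TIRF and the published
quantification operates on projected coordinates; axial structure appears
as in-plane layer offsets.

Two presets cover the needs of testing and exploration:

* `two_layer` — two straight parallel ribbons separated by `delta`
  (default 60 nm): the minimal configuration in which a layer separation
  must be recovered.
* `golgi7` — seven species with default offsets GM130 0, GRASP65 10,
  VPS13B 30, Giantin 80, Golgin97 190, TGN46 210 nm, and the COPI coat
  marker (beta-COP) placed off-stack on the cis side (−80 nm) and
  laterally displaced by 300 nm. These defaults reproduce the *qualitative*
  cis→trans ordering of the markers; they are configurable placeholders,
  not measured ultrastructure — the true axial offsets between these
  proteins are unknown, which is precisely why the ranking analysis
  estimates them. The beta-COP axial position is the package's own choice
  (only its lateral displacement is conventionally described); placing it
  off-stack matches its role at the cis-Golgi/ERGIC interface.

Docking sites are laid along each layer as a 1-D Poisson process with the
species' linear density (default 150–200 sites/µm, i.e. ~5–7 nm spacing,
representative of a well-labeled membrane protein), thinned by the
labeling efficiency, and displaced per coordinate by Gaussian noise of
sd √(jitter² + linkage²). The membrane jitter (default 5 nm for `golgi7`)
models epitope spread around the ideal layer; the linkage term models the
antibody/nanobody arm (≈6 nm for a primary/secondary antibody stack,
smaller for nanobodies).

## Blinking, erasure, photons

Kinetics are discretised at frame resolution: dark gaps are geometric with
mean `mean_dark_frames` (default 500 frames), bright dwells geometric
(support ≥ 1 frame) with mean `mean_bright_frames` (default 3 frames at
the default 25 ms exposure). Sub-frame kinetics are deliberately not
modelled: the analysis consumes frame-stamped localizations, and at 25 ms
exposure the discretisation error is irrelevant to distance statistics.
Event photon counts are Poisson with mean `n_frames × photons_per_frame`.

Erasure is modelled by a single residual fraction ε (`eraser_residual`):
in round *r*, each site of an earlier species *s* < *r* is active
independently with probability ε^(r−s), compounding geometrically over
successive erasures; species later than *r* have not yet received their
adapter and are never active. This is the simplest model consistent with
the eraser mechanism; hybridisation kinetics of the eraser itself
(concentration, incubation time) are out of scope. ε = 0 gives perfect
round purity; ε = 1 is rejected.

Two fidelity levels exist on purpose. *List mode* shortcuts the camera:
one localization per blink event at the true site position plus drift at
the event's middle frame plus isotropic Gaussian error of sd
σ = `psf_sigma`/√photons. It makes the proximity stage testable in
seconds. *Frame mode* renders 16-bit camera frames (integrated Gaussian
PSF, Poisson pixel noise, uniform Poisson background) and exercises the
full localization path.

## Localization (frame mode)

Candidates are local maxima of the 3×3 box-smoothed frame above
median + k·MAD (default k = 5), merged within 2·⌈σ/a⌉ pixels keeping the
brighter. Each candidate ROI (half-size ⌈2σ/a⌉+1 pixels, capturing >95%
of the PSF mass) is fit by maximum likelihood with an integrated symmetric
2-D Gaussian plus constant background under Poisson noise — the
Poisson-correct choice at low photon counts — using L-BFGS-B with an
analytic gradient, an iteration budget of 50, and the fitted PSF sd
constrained to [0.5, 3]× nominal. Non-converged fits fall back to a
background-subtracted centroid and are dropped (counted) by
`localize_movie()`.

The reported per-axis precision uses the standard closed form
σ_loc = √((σ² + a²/12)/N · (16/9 + 8πσ²b/(Na²))) with the fitted photon
count N, background b and PSF sd σ. That formula describes least-squares
estimation; the MLE meets it with margin (measured RMSE ≈ 0.65–0.9× the
formula at N = 1000, b = 10), so it is a conservative per-localization
error bar.

Because one binding event spans several frames, per-frame localizations
are merged (`link_blinks()`) when they fall within `max_dist` of a chain's
running position in consecutive frames (≤ `max_gap` dark frames), using
inverse-variance weighting. Without this step, long events would weight
the distance medians by event duration.

## Drift correction and round alignment

Within each round, drift is estimated by redundant cross-correlation:
frames are split into `n_segments` equal blocks (default 10), each block
is rendered as a 5 nm histogram blurred by 10 nm (blurring stabilises the
correlation peak on sparse point data), all pairwise block shifts are
measured by FFT cross-correlation with 3-point quadratic sub-bin
interpolation, and the overdetermined shift system is solved by least
squares with block 0 anchored. Block displacements are interpolated
linearly (with linear extrapolation at the ends) to per-frame drift and
re-anchored to zero at the round's first frame.

RCC is blind to a constant per-round offset. Two mechanisms are provided:

* **Drift-continuity chaining** (`chain_rounds = TRUE`, default): the
  extrapolated end of round r−1 seeds the start of round r, appropriate
  when the stage drifts continuously through on-stage buffer exchanges.
* **Structural alignment** (`align_rounds()`): cross-correlating each
  round's rendering against a reference round and applying the negated
  peak shift as a rigid translation (translation only — same instrument
  and field across rounds, the standard assumption in exchange-style
  multiplexing). A normalised-correlation floor and a maximum plausible
  shift (default 500 nm) guard against aligning rounds that share no
  structure; circular correlation would otherwise always "find" a shift.

A degeneracy deserves emphasis, because it changed the pipeline's default.
When different rounds image *different* layers of the same smooth
structure, translation alignment is only identifiable up to the true
inter-layer offset: aligning a straight 60 nm-shifted ribbon onto its
reference collapses the very separation the analysis is meant to measure
(verified on the two-layer phantom: cross-layer medians fall from ~50 nm
to ~2 nm). Real specimens mitigate this with shared structural features or
fiducials, but the failure mode persists in attenuated form. The pipeline
therefore defaults to `registration.align = FALSE` and relies on
drift-continuity chaining; structural alignment remains available (and
correct) when rounds share structure, and is what the alignment tests
exercise.

## The proximity statistic

For an ordered pair (A → B), `"nn"` mode takes, for each localization of
A, the distance to its nearest localization of B, retaining values ≤
`r_max` (500 nm, *inclusive* — the cutoff phrasing in published legends is
"closer than", but an inclusive bound differs only on a measure-zero
event and is exactly testable). `"all_pairs"` mode keeps every cross
distance within the cutoff; both are reported because figure legends
rarely state the convention. On the diagonal, only the identical record is
excluded — co-site records remain, so the diagonal reads out the repeat-
localization floor rather than zero. The accelerated neighbour search
(sorted-sweep in C++, compiled with floating-point contraction disabled)
is bit-identical to an exhaustive scan, and the tests assert exact
equality against a brute-force oracle.

The nn-median is a biased estimator of layer separation: with site spacing
*s* and effective point noise σ, the nearest neighbour in the other layer
is found at an oblique distance, so the median sits below √(Δ²) and above
the Δ = 0 noise floor. The package treats this bias as a property to
quantify (the test suite pins the Δ = 0 floor and the Δ = 60 nm value
against a generative Monte-Carlo oracle) rather than something to correct:
ordering and monotonicity in Δ — the quantities the ranking analysis
uses — are unaffected.

### Confidence intervals

Record-level bootstrap resampling of the query species is substantially
anti-conservative for this statistic (measured ~70% coverage at nominal
95%): nn distances are positively correlated through repeat blink events
of the same site and through the shared local target realization.
Resampling *sites* of the target side is worse still — duplicating points
of a spatial point process thins its effective density and biases nn
distances upward. `distance_matrix()` therefore uses a spatial block
bootstrap: per-query distances are grouped by the `boot_block_nm` grid
cell of the query localization (grid anchored at the data minimum so thin
structures are not split by a coincidental block boundary), blocks are
resampled with replacement, and percentile intervals of the resampled
medians are reported. The default block edge of 100 nm exceeds the
measured correlation length (CI width grows steeply up to ~50 nm blocks,
then plateaus) and gives ~92% empirical coverage at nominal 95% on the
two-layer phantom — the residual undercoverage is typical of block
bootstraps with moderate block counts.

## Determinism and numerical choices

Every stochastic operation takes an explicit seed; `run_pipeline()` fans a
master seed out to per-stage seeds (one `sample.int` draw per stage in
fixed order, recorded in the manifest) so stages can be re-run in
isolation. Identical configuration and seed give byte-identical outputs.
Other fixed choices: coordinates in nm with origin at the field's
top-left (x right, y down), frames and rounds 0-based, round *r* images
species *r*; localization tables are serialized as CSV with a `# key:
value` header and 17-significant-digit coordinates so text round trips are
bit-exact (a pixel-unit export is provided for interoperability but nm is
the only internal unit); cross-correlation peaks are interpolated by a
3-point quadratic fit per axis (adequate at 5 nm bins); ties in detection
merging and nearest-neighbour searches break deterministically (brighter
first, then smaller row/column; lower record index).

## Problem sizes

The test suite and the acceptance script run deliberately reduced
problems: 3,000-frame rounds (rather than 30,000), ribbons of 2–4 µm,
hundreds of sites per species, and a frame-mode field of ~10 µm at 108 nm
pixels with 3 × 2,000 frames. These sizes give the statistics enough
support (thousands of localizations per species, single-nanometre
standard errors on medians) while keeping a full run in minutes on one
CPU; all densities and kinetic parameters are the same as at full scale,
so no stage behaves qualitatively differently.

## What passing tests do and do not show

The generator emulates: layered geometry with configurable offsets,
Poisson site placement with labeling efficiency, linkage error, two-state
blinking, Poisson photons, imperfect erasure, continuous stage drift, and
(in frame mode) the camera's integrated PSF, shot noise and uniform
background. It does not emulate: photobleaching of docking strands or
imager depletion, 3-D/astigmatic PSFs, sCMOS pixel-dependent noise,
structured background (out-of-focus haze, cytosolic signal), non-rigid
sample deformation between rounds, or eraser kinetics beyond the residual
fraction. Passing tests therefore demonstrate that the analysis correctly
recovers what this generative model produces — separations, orderings,
drift, alignment — not that real Golgi data meets the model's
assumptions. The ordering-recovery rate in particular is conditional on
the phantom's offsets and densities; on real data the corresponding
guarantee is only qualitative.

## Known limitations

* Translation-only round alignment; no affine or non-rigid registration,
  no fiducial tracking.
* Single-emitter fitting only: overlapping active sites within ~2 PSF
  widths in the same frame are merged or dropped, so frame mode
  undercounts at high activity (keep duty cycle low, as in real
  DNA-PAINT).
* The all-pairs bootstrap resamples per-query pair groups; for very dense
  data its intervals are approximate.
* The diagonal of the distance matrix is a repeat-localization floor, not
  a biological quantity.
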