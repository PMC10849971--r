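---
title: "Methods: compartment geometry, perimeter polarity and marker-list statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment geometry, perimeter polarity and marker-list statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoquant)
```

This vignette is the package's own account of the quantification it
implements: the measurement model behind each stage, the parameters that
matter, the numerical choices that were genuinely open and how they were
fixed, and what validation on synthetic scenes does and does not show
about real microscopy data.

## The measurement problem

In extended-culture human embryo models, wild-type (epiblast-like) cells
form disc-shaped compartments surrounded by induced GATA6⁺ extra-embryonic
cells. Three imaging questions recur. First, *geometry*: how many
compartments are there, how large, how round, how far apart, and how much
of each is overlain by the EGFP⁺ extra-embryonic layer? Second,
*perimeter polarity*: anterior (CER1) and posterior (TBXT/Brachyury)
markers concentrate in angular domains around the compartment perimeter;
whether those domains sit opposite each other (anti-polar, the
embryo-like configuration), together (syn-polar), or neither, is the
readout of axis formation. Third, *haematopoiesis*: in later cultures,
blood-island-like foci of CD43⁺/marker⁺ cells, haemoglobin isoform ratios,
CD34⁺ vasculature and the apical-basal layering of FOXA2/CD34/Desmin
quantify yolk-sac-like development. A separate, non-imaging stage compares
single-cell cluster marker lists across datasets with overlap statistics.

## Compartment segmentation

Compartments are detected by thresholding a designated high-signal channel
(nuclear dye, F-actin or a constitutive fluorophore). The threshold
default is Otsu's method on that channel; a fixed value can be supplied
(`threshold =`). Connected components use 8-connectivity, computed by a
run-based union-find written in-package so the connectivity convention is
explicit and bit-reproducible.

Small components near single-cell size are removed by the size rule

$$\text{lower size limit} = \frac{A_{max}}{10^{(A_{max}-A_{cell})/2}},$$

with both areas *manually defined* inputs (there are no defaults: they are
judgement calls about the culture). The formula is implemented exactly as
stated, in whatever working unit the user supplies. Note its scale
behaviour: for areas in the thousands of µm² the exponent is enormous and
the limit vanishingly small, so the filter only bites when the two areas
are within a few units of each other. Because that makes the formula
awkward for some unit conventions, `detect_compartments()` also accepts an
absolute `min_area` as a practical alternative; the formula remains the
documented default path.

Per-compartment features: area is the pixel count times `pixel_size²`;
the centroid is the pixel-centre mean; the equivalent radius is
$\sqrt{A/\pi}$ exactly. The perimeter is the length of the closed polygon
through the Moore-traced boundary pixel centres after a circular 5-point
moving average. The smoothing matters: raw chain-code or marching-squares
lengths overestimate digitized smooth contours by 5–6 % (the staircase
effect), which would push a digital disc's circularity $4\pi A/P^2$ down
to ≈ 0.89–0.91; the smoothed polygon gives ≈ 0.99–1.03 for discs of radius
25–50 px while keeping a 100-px square within 2 % of its true π/4.
Digitization can therefore push circularity slightly above 1; values up to
≈ 1.1 are normal for small discs. Masks with fewer than 8 boundary points
fall back to counting exposed pixel edges.

Nearest-compartment distance is centroid-to-centroid (the natural default
when compartments are near-circular); a single compartment reports a
missing value. Coverage is the fraction of mask pixels whose EGFP
intensity exceeds the coverage threshold, and `covered` is *strictly*
greater than 0.5 — a compartment exactly half-covered is not counted.

## Radial profiling

From every border point, a straight line is drawn toward the compartment
centroid and each channel is sampled at 1-pixel steps with bilinear
interpolation over a user-chosen depth (µm). The depth is a required
parameter — it trades perimeter locality against noise averaging; it must
be smaller than the equivalent radius. If any sample along a line falls
outside the mask (concave shapes, image edges), the whole line is skipped
and that border position carries a missing value — skipped is never zero,
and skipped positions are excluded from every downstream mean.

Per-position profiles (mean over depth) are aligned by circularly shifting
each compartment so the CER1 maximum sits at position 1 (ties break to the
lowest index, for determinism), then resampled by linear interpolation on
the circular index to a common length, by default the longest border
recorded. Linear interpolation was chosen over higher-order kernels
because it is monotone (no overshoot near the aligned peak) and pinned in
tests; missing positions are interpolated across at this stage, since the
aligned profiles feed visualization and cohort averaging rather than the
polarity calls (which run on the unaligned profiles and keep their
missing-value semantics).

## Polarity classification

CER1 and TBXT per-position profiles are divided pointwise by the F-actin
profile — a cell-density normalization that cancels local variation in how
much tissue each line crosses — with a small `epsilon` (default 1e-6)
guarding empty positions. The normalized profile is smoothed with a
circular rolling average including every position whose arc distance is at
most one-eighth of the disc radius on either side (window boundaries
inclusive). With `L` equally spaced border positions spanning a
circumference of $2\pi R$, that half-window is $\lfloor L/(16\pi)\rfloor$
indices, independent of `R`; a window covering the whole circle returns
the global mean (not an error). Smoothing is a contraction: the smoothed
range never exceeds the raw range.

A marker is **polar** when max − min of its smoothed profile strictly
exceeds 0.1 (normalized intensity, a.u.); a range of exactly 0.1 is not
polar. The 0.1 value is the field's working threshold on the
F-actin-normalized scale and is exposed as a parameter (`threshold`). The
peak is the argmax (lowest index on ties), reported as the border angle.
With both markers polar, the axis class follows the circular difference
`d = (TBXT − CER1) mod 360`: anti-polar on the closed interval
`135° ≤ d ≤ 225°`, syn-polar when the minimal separation is ≤ 45°,
otherwise unrelated. The windows are treated as closed because the
boundary language ("between", "within") does not fix open versus closed;
closed was chosen and is pinned in tests. Under a uniform random TBXT
peak both anti- and syn-polar windows capture 90/360 = 25 % of
compartments, a useful null to keep in mind when reading cohort fractions.

Compartments with several poles are excluded
(`axis_class = "excluded_multi_pole"`), automating what is otherwise a
by-eye verification. A pole is a local maximum of the smoothed profile
exceeding `min + threshold`; two maxima are distinct poles only when
separated by more than the rolling half-window *and* by a dip of at least
`threshold` below the weaker maximum. The prominence condition is the
substantive choice here: without it, noise ripples on the flank of one
genuine pole register as extra poles and healthy compartments are
discarded wholesale (on the package's noisy benchmark cohort, exclusion
errors alone would cap accuracy near 86 %). The screen can be switched
off (`exclude_multi_pole = FALSE`).

## Haematopoietic quantification

Cell objects are threshold + 8-connected components + a minimum-area gate
on one marker channel; each object contributes its centroid and mean
intensity in *every* channel, so CD43 object counts and per-cell
scatterplot quantities come from one pass. Wild-type compartment regions
are removed beforehand by setting their pixels to missing
(`exclude_wt_regions()`), which keeps them out of thresholds, objects and
positive-area counts while leaving the image geometry intact — the CD34
area fraction divides the suprathreshold area *outside* the WT mask by
the *total* image area, matching how coverage percentages are read.

Haemoglobin quantification normalizes per-cell ε and γ mean intensities by
the coverslip-wide mean pan-haemoglobin object intensity (a per-coverslip
staining control), and forms the per-cell ε/γ ratio; cells with zero γ get
a missing ratio rather than being dropped. The population median of the
ratio recovers a generating log-ratio to within a few percent at n = 1000,
which is the package's parameter-recovery check for the developmental
ε-to-γ switch.

Focus classification is deliberately split from focus *grouping*: the
grouping of cells into a candidate focus is provided either externally (as
done by eye in practice) or by single-linkage spatial clustering with a
link radius. The rules then are: a focus must have strictly more than 20
cells; it is uni-lineage for marker m if fewer than 3 member cells lack m
and no cell is positive for the pan-haematopoietic progenitor marker
(CD43) while negative for m; it is multi-lineage if at least 3 cells are
positive for each of two or more assessed markers. The progenitor marker
is never itself a lineage. When several markers satisfy the uni rule
simultaneously (focus-wide co-expression), the call falls through to
multi-lineage — the uni rule is meant to identify a *single* dominant
lineage. The multi rule is assumed unaffected by CD43-only cells, since
the stated exception concerns only the uni case.

Z-stacks: each channel's per-slice mean intensity is computed, the stack
bottom is the lowest slice whose mean exceeds a configurable noise floor
(standing in for an unstated in-focus criterion), slices below it are
discarded, and each channel is expressed as percent of its own maximum —
so the maximum is exactly 100 % whenever the channel has signal, and the
profile is invariant to global intensity scaling. Replicate stacks are
aligned at their bottoms, their percentage profiles averaged index-wise
(shorter stacks simply stop contributing), and the average renormalized.

Relative qPCR expression uses the standard
$2^{-\Delta\Delta C_T}$ form against an endogenous control gene and a
calibrator sample, with a tidy-table wrapper that averages replicate Ct
values first.

## Marker-list statistics

The overlap of two gene lists of sizes $|A|, |B|$ from a universe of $N$
genes is tested with the upper-tail hypergeometric probability
$P(X \ge k)$, computed in log space (`phyper(log.p = TRUE)`) so that
extreme tails keep full precision; the implementation is verified against
exhaustive enumeration of binomial-coefficient ratios for every universe
up to $N = 30$ at relative error below $10^{-10}$. The universe size is a
required, explicit parameter: whether it should be the full genome or the
detected genes is a genuine analytical decision that the package refuses
to make silently. Families of tests share one Benjamini–Hochberg
correction (`stats::p.adjust`), applied across an entire query × reference
comparison matrix at once.

The Jaccard-difference statistic asks whether a query cluster C is more
similar to reference E than to reference D. "Unique overlap" is read as
*exclusive* overlap — $A = (C\cap D)\setminus E$,
$B = (C\cap E)\setminus D$ — because otherwise the adjective adds nothing;
this is the module's main interpretive risk, is surfaced here, and a
`overlap = "plain"` switch computes the non-exclusive version for
sensitivity analysis. With $j_1 = |A|/|C\cup D|$, $j_2 = |B|/|C\cup E|$,
significance of $\Delta = j_2 - j_1$ comes from R draws of three
size-matched gene sets sampled uniformly without replacement from the
genome. The empirical p-value uses the add-one estimator
$(1 + \#\{\Delta_{null} \ge \Delta_{obs}\})/(R+1)$ with ties counted
toward the tail: p is never zero, $-\log_{10}(P)$ is finite, and the
estimate is conservative. One consequence is worth knowing: $\Delta$ is a
difference of ratios of small integers, so with short lists (tens of
genes) its null distribution has large atoms, tie-inflation is
non-negligible, and the empirical p becomes visibly super-uniform. The
package's null-calibration check therefore runs at cluster-marker scale —
lists of 300 genes against a 4 000-gene universe — where the statistic's
granularity is fine and 500 replicate p-values pass Kolmogorov–Smirnov
uniformity comfortably; with 25-gene lists in a 300-gene universe the same
check fails by design of the estimator, not by error.

## The synthetic-scene generator

The generator emulates exactly the structure downstream stages assume:
disc/ellipse/crescent compartments with per-channel baselines; polar
domains as wrapped-Gaussian bumps in perimeter angle (any smooth unimodal
bump would do — the wrapped Gaussian was chosen because its peak is
differentiable, making peak-recovery tests sharp); an EGFP layer covering
a controlled area fraction; a uniform F-actin density channel; additive
Gaussian noise clipped at zero (the weakest noise model that still
exercises thresholding — real microscopy noise is neither Gaussian nor
additive, see limitations). Coordinates are 0-based (row, col) pixels,
physical micrometres via `pixel_size`, angles in degrees counter-clockwise
from the +x axis. One seed governs a scene; sub-generators draw from
seed-derived streams so adding a compartment never perturbs earlier ones,
and identical specs are pixel-identical. Every true parameter — masks,
areas, peak angles, the implied axis class, per-slice means, positivity
labels, overlap counts — is recorded in a JSON-serializable manifest that
independent pixel-counting or set-arithmetic oracles can reproduce with
zero discrepancy at zero noise.

Scenes write to 16-bit multi-page TIFF with a JSON channel map recording
the intensity scale (the field has no canonical bit depth for
arbitrary-unit fluorescence; quantization error is one part in 65 535).

## Validation scale and study conditions

The packaged benchmarks run at desk scale, chosen once: a 200-compartment
polarity cohort (radii 25–40 µm on 121-px scenes, domain amplitude 1.0 =
10× the polarity threshold, noise SD 0.1 = 10 % of amplitude, true
separations cycling {0°, 30°, 90°, 180°}), on which axis-class recovery
is 100 % and noiseless peak-angle error stays below one border step;
two-disc segmentation scenes at noise 5 % of contrast, recovering masks
exactly and areas to well under 2 %; the 500-replicate × R = 199 null
calibration described above; and the exhaustive blood-island rule table
over focus sizes 15–30. `scripts/acceptance.R --seed <int> --out <path>`
recomputes all of it from scratch.

## Known limitations

Passing these checks shows the *rules* are implemented faithfully and
recoverable under the generator's assumptions — flat-field, well-separated,
convex-ish compartments with additive Gaussian noise. It does not show
robustness to the things real coverslips do: uneven illumination, touching
or overlapping compartments (no watershed splitting is attempted),
out-of-focus light, non-Gaussian camera noise, or genuinely ambiguous
multi-pole biology. Threshold choice (Otsu versus fixed) remains the
largest practical sensitivity in segmentation, and the 0.1 polarity
threshold is only meaningful on the F-actin-normalized intensity scale.
Lumen/cavity scoring, differential-expression calling and 3D
reconstruction are out of scope.
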