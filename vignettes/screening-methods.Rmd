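---
title: "Screening images for copy-move manipulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening images for copy-move manipulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copymove)
```

## The problem

Two kinds of image manipulation leave an exact repeat of pixel values at a
fixed displacement. *Copy-move* manipulation hides unwanted content (a band
on an electrophoresis gel, a structure in a micrograph) by pasting another
region of the same image over it — usually background noise, because noise
is the only texture that blends in. *Figure duplication* reuses the same
image, or a cropped detail of it, in another panel or publication. In both
cases the duplicated material is invisible to the eye but trivially present
in the data: two regions of the pixel matrix agree value for value, offset
by one fixed shift.

`copymove` screens for such repeats by brute force: it scores **every**
possible relative displacement of one image over another and asks which
shifts score conspicuously against the bulk. A flagged shift is evidence of
duplicated content, never a verdict — deciding whether an image is
fraudulent is explicitly left to human experts.

## Cyclic shifts and the comparison window

Images are 8-bit grayscale matrices of integer levels 0–255 (color inputs
are converted via BT.601 luminance; see below). A shift $(d_i, d_j)$ slides
one image over the other by $d_i$ rows and $d_j$ columns; rows and columns
pushed past the edge wrap around to the opposite side. For equal sizes this
*cyclic* overlay superimposes every pixel pair at exactly one shift, which
gives the pixel-wise statistic an exact conservation law used heavily in the
test suite:

$$\sum_{d_i, d_j} \mathrm{count}(d_i, d_j) \;=\; \sum_{v=0}^{255} h_A(v)\, h_B(v),$$

where $h_A, h_B$ are the gray-level histograms.

For unequal sizes the comparison window is the smaller extent in each
dimension and the shift space the larger. In each dimension the larger image
(the first argument on ties) is the one indexed cyclically: window position
$i$ pairs $\text{wrapped}[(i + d) \bmod n]$ with $\text{direct}[i]$. Two
consequences fix the orientation of the convention: a shift by one row pairs
the first row of the first image with the last row of the second, and a
cropped detail is superimposed on its source region exactly at the shift
equal to its crop origin — in either argument order. Shifts are 0-based
throughout; grid entry `[di + 1, dj + 1]` scores shift `(di, dj)`.

Mirror pairs: on a self-scan, shift $(d_i, d_j)$ and its mirror
$(M - d_i, N - d_j)$ superimpose the same pixel pairs and score identically —
they are one duplication event seen from either end. `canonical_shift()`
folds each pair onto its row-major-smaller representative, and
`find_candidate_shifts(collapse_mirror = TRUE)` does this folding *before*
thresholding; otherwise the quantile threshold would sit exactly on a tied
maximum and discard it.

## The three statistics

**Pixel-wise counts** (`pixelwise_shift_counts`). The number of superimposed
pixel pairs with exactly equal levels. Equality is exact integer equality —
levels are stored as integers 0–255 precisely so that "identical" needs no
floating-point tolerance. Robust to single-pixel damage, but on an
$m \times n$ window with $L$ effective levels roughly $mn/L$ pairs match by
chance at every shift, so only large copied areas rise above that floor.

**Nearest-neighbor counts** (`nn_shift_counts`). The number of anchor
positions whose full 3×3 neighborhood is identical in both overlaid images,
recorded at the block's top-left pixel. Chance matches require nine
simultaneous equalities ($\approx mn/L^9$ — essentially zero), so even tiny
copied areas stand out; conversely a single re-encoded pixel destroys the
block and the statistic is fragile under lossy compression. A copied
$h \times w$ rectangle contributes $(h-2)(w-2)$ anchors at its shift.

**Block-variance sums** (`variance_shift_sums`). At each shift the overlay
is subtracted and, for every 3×3 block, the population variance (divide by
9) of the nine differences is accumulated. A region copied and then
brightness-adjusted by a constant offset no longer matches exactly, but its
difference block is constant and has variance zero, so *low* sums flag
similarity that exact counting misses: `variance(A, A + c)` equals
`variance(A, A)` entry for entry, with zero at the origin shift. Population
rather than sample variance is a pure scale choice; rankings are unchanged.

Two anchoring details differ deliberately between the statistics. The
counting algorithms take 3×3 anchors over the interior of the materialized
overlay, so a block whose partner wraps across the cyclic seam still counts
(a constant image must score $(m-2)(n-2)$ at every shift). The variance
algorithm *skips* blocks that cross the seam of either image: a seam block
juxtaposes opposite image edges, its variance is pure noise, and dropping it
makes the statistic exactly mirror-symmetric in the shift, matching the
symmetry the counting algorithms already have.

## Monochrome masking

Saturated monochrome areas (pure black 0 and pure white 255, typically) make
every pixel identical to every other and would drown the counting statistics
in false matches. `mask_monochrome()` replaces each such pixel with a unique
negative sentinel that never matches anything — not even itself, so a fully
masked image scores zero at *every* shift, including the identity. The
variance algorithm cannot run on masked images (a sentinel has no gray value
to subtract) and refuses them with an error; this mirrors the method's known
limitation on images with monochrome areas.

## From grids to findings

**Trivial-shift exclusion.** Small displacements score highly on any natural
image because neighboring pixels resemble each other; these shifts say
nothing about manipulation. All shifts within toroidal Chebyshev distance
`radius` of the origin are excluded before ranking. The default radius of
5 px removes that autocorrelation plateau on the image classes this tool
targets while costing only an 11×11 patch of the shift space; it is
configurable, and radius 0 still removes the self-overlay shift (0, 0).

**Thresholds.** The interesting quantity is a score conspicuous *relative to
the other shifts of the same grid* — absolute counts scale with window area
and level spread and do not transfer between images. Explicit thresholds are
honored strictly (`> t` for counting, `< t` for variance); when none is
given, the default is the top 0.05% quantile of the eligible scores for the
counting algorithms and the bottom 0.1% for variance. Ties are broken
row-major by `(di, dj)`, so rankings — and the JSON reports built from them —
are byte-reproducible.

**Localization.** The shift grid says by *how much* duplicated regions are
displaced; localization matrices say *where* they sit. For the
nearest-neighbor algorithm, entry $(r, c)$ counts over all shifts how often
the block anchored there matched, so its grand total equals the total of the
shift grid — an exact identity the tests assert. For the variance algorithm
the count is of blocks below a per-block variance cut-point.

**Region reconstruction.** `match_mask()` maps the exact matches of one
conspicuous shift; `reconstruct_moves()` greedily extracts the largest
all-matching rectangle, removes it, and repeats, reporting each rectangle
with its shift-displaced partner. Greedy largest-first extraction is simple,
deterministic, and matches how copy-and-paste manipulations are actually
made (rectangular drags). Rectangles below `min_area = 4` pixels are left as
residual: isolated matches of 1–3 pixels are indistinguishable from chance,
and the residual count is reported so that rectangle areas plus residual
always equal the number of matching pixels.

## Input handling

PNG and JPEG are decoded by magic bytes, not extension. PNG is the lossless
house format; JPEG is accepted with a warning because its 8×8-block lossy
compression perturbs exactly the pixel identities the counting statistics
rely on. Color inputs are reduced by BT.601 luminance
($0.299R + 0.587G + 0.114B$, rounded half-up) — the most common still-image
convention; since no single convention is universal, level-exact agreement
with other tools on *color* inputs is not guaranteed, while 8-bit grayscale
round-trips bit-exactly. Alpha channels are dropped with a warning; inputs
deeper than 8 bits are rescaled to 8 bits with rounding.

## The synthetic fixture generator

Validation needs images with known ground truth. `gen_background()` draws
i.i.d. uniform integer levels on a configurable range — the default
`[96, 159]` gives 64 distinct levels of mid-gray "weak background noise",
the texture class on which copy-move screening is meaningful in the first
place. `plant_copy()` pastes a source rectangle at a destination, optionally
brightness-offset (clipping is an error, not a saturation), and returns the
ground-truth shift; `gen_duplicate_pair()` returns an image together with a
cropped detail and the crop-origin shift.

What the generator deliberately does **not** emulate: spatial texture and
autocorrelation (real micrograph backgrounds are smoother, which *raises*
the trivial-shift plateau and chance-match floor), JPEG re-encoding,
rescaling and rotation (known defeats of these algorithms), and
structured foreground signal. Passing tests on these fixtures therefore
demonstrate the algorithms' correctness and their statistical behavior under
the stated noise model, not detection performance on arbitrary real figures.

With 64 background levels, a planted copy of $\ge 100$ px exceeds the
expected chance-match floor per shift ($mn/64 \approx 156$ for a 100×100
image) by an order of magnitude less area than it contributes, so the
counting algorithms recover planted shifts essentially always; the seeded
validation runs 20 replicates of a 20×15 copy in a 100×100 background and
10 replicates of a 50×50 crop from a 120×120 image, sizes chosen so the
full suite re-runs in a couple of minutes on one core.

**A known negative result, kept on record:** for the *variance* algorithm
the same 20×15 planted copy is usually invisible. Its signal — about
$(h-2)(w-2) \approx 234$ zero-variance blocks against a background
expectation of $\sim 600$ per block — amounts to only 1–2 standard
deviations of the shift-to-shift variation of the variance sum, while the
minimum over the $\sim 10^4$ candidate shifts sits about 3 SD below the
mean. The acceptance suite asserts the stricter recovery property anyway and
the assertion fails, by design rather than accident: the variance statistic
needs the duplicated area to be a substantially larger fraction of the
window (the 30×20-in-60×60 configuration in the unit tests, about 15% of
the blocks, is reliably a low extreme). This matches the method's observed
behavior of detecting only the larger of two copied areas.

## Numerical choices

* Integer levels 0–255 internally; the 0–1 scale of floating-point readers
  is recovered as `level/255`. Counting grids are integer matrices.
* Variance sums are accumulated in double precision via running
  column-triple sums of $d$ and $d^2$; the per-block variance is clamped at
  zero against cancellation. Equality checks of variance grids in the tests
  use a $10^{-9}$ tolerance (summation-order effects only).
* Sentinels are consecutive negative integers in row-major order — unique by
  construction and outside the level range; comparisons additionally treat
  *any* negative value as non-matching, so masked pixels cannot match even
  their own sentinel value.
* All generators are pure functions of their arguments including the seed;
  RNG state is scoped with `withr::with_seed` and never leaks.

## Limitations

No scale or rotation invariance: a duplicated detail that was rescaled by
even a few pixels defeats all three statistics. No detection of *added*
content (that requires edge-forensic methods, a different problem). No
significance calibration: scores are ranked, not tested, and the thresholds
are screening heuristics. And by design, no verdicts — the output of a scan
is a ranked list of shifts and localized regions for a human expert to
inspect.
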