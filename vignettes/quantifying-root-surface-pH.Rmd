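---
title: "Quantifying root-surface pH from dual-excitation ratio images"
author: "rhizopH maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying root-surface pH from dual-excitation ratio images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A membrane-impermeant, pH-sensitive dye of the fluorescein family is
dissolved in the solid growth medium. It stains the medium and the
root surface but does not enter the root tissue, so in the image the
root is a dark object embedded in bright medium. The dye is excited
sequentially at 488 nm and 405 nm with a shared emission band; the
excitation ratio

$$ R = \frac{I_{488} - b_{488}}{I_{405} - b_{405}} $$

rises monotonically with pH across the dye's response range and, being
a ratio of two signals from the same fluorophore pool, cancels dye
concentration, medium thickness, and any multiplicative illumination
field shared by the channels. Ratios are reported as *relative* pH by
default; an absolute pH column is only emitted against an explicit
per-session calibration, because absolute intensities depend on medium
preparation and optics.

What the package measures is the pH of the rhizosphere a few microns
off the root surface, resolved along the root's longitudinal axis —
enough to see the alkaline transition-zone domain, the acidic tip and
maturation domains, their response to hormone treatments and mutants,
and their fast rearrangement during gravitropic bending.

## The pipeline and its parameters

1. **Segmentation** (`segmentRoot`). The two channels are summed (the
   ratio is undefined at the low counts inside the root) and
   Otsu-thresholded; the largest dark component is kept, closed with a
   3 px disc, hole-filled, and components under `minAreaPx` (200 px)
   are dropped. Degenerate scenes error explicitly: no dark component
   (`NoRootFound`), or more than 80 % of the image dark
   (staining failure).
2. **Midline** (`extractMidline`). Zhang–Suen thinning, pruned to the
   longest endpoint-to-endpoint geodesic of the skeleton graph (this
   removes spur branches), smoothed with a 7-point moving average, and
   extended at both ends along the local direction by the interior
   distance-transform value — thinning retreats about one local radius
   from each end, and the extension restores the midline to the mask
   boundary. Arc length is cumulative Euclidean length times the pixel
   size.
3. **Tip** (`detectTip`). The endpoint not on an image border (the
   root enters the field shootward); ties resolved by the largest
   projection on the gravity vector. The tip tangent is the principal
   direction of up to 60 midline points (~40 µm) nearest the tip.
   The nominal choice of 25 points proved biased by up to 5° on
   phantoms when the root lies at a shallow angle to the pixel grid —
   a thinned skeleton staircases — while 60 points average the
   staircase down to ≤ 2.2° without feeling root curvature at these
   scales; roots shorter than 25 midline points are rejected as too
   short.
4. **Surface band** (`extractSurfaceBand`). Medium pixels whose exact
   Euclidean distance to the mask lies in `[bandMinPx, bandMaxPx]`
   (10–25 px). Each pixel carries the arc length of its nearest
   midline point (its longitudinal coordinate *s*), a left/right label
   from the sign of the cross product of the local shootward tangent
   with the midline-to-pixel displacement, and background-subtracted
   intensities (negative values clamped to zero and counted). The
   distance transform was verified exactly against an all-pairs
   brute-force computation.
5. **Binning** (`binProfile`). Pixels are pooled per side and per
   half-open bin of `binLengthPx` (20 px) of arc length — with the
   15 px band width this gives the 15 × 20 px bins of the established
   convention — and the bin ratio is **Σ I488 / Σ I405**. Summing
   before dividing avoids the noise amplification and low-count bias
   of averaging per-pixel ratios. Bins with fewer than `nMinPixels`
   (30) pixels, with a vanishing 405 sum, or not fully covered by the
   midline extent (the last, border-mixed bin) are marked invalid.
   Profiles are truncated at `maxDistUm` (1000 µm).
6. **Calibration** (`fitCalibration`). Default: a monotone Hyman
   spline through the (pH, ratio) standards; ratio→pH queries invert
   the spline by bisection so both round trips close to 1e-6. A
   4-parameter logistic (`sigmoid`) is offered since
   fluorescein-family dyes follow a single-pKa titration; it needs
   standards that bracket the midpoint. Out-of-range queries clamp to
   the boundary and are flagged, never extrapolated — the dye
   saturates outside its response range. Bin *ratios* are calibrated;
   calibrated pH is never re-averaged across bins, because calibration
   and aggregation do not commute.

### Kinetics

`trackRoot` segments each frame independently, guards tip
correspondence with a 100 µm jump limit, tolerates up to two
consecutive failed frames (interpolated in derived series), and
aborts beyond that. Derived series:

- **Elongation rate** — midline length increment between first and
  last frame over elapsed minutes; the midline's shootward end sits on
  the field border, which acts as the fixed anchor.
- **Tip angle** — unsigned angle between tip tangent and gravity,
  optionally median-smoothed over 3 frames. After a 90° rotation the
  series starts near 90° and falls toward 0° as the root realigns.
- **Flank asymmetry** (`flankRatioSeries`) — band pixels 200–500 µm
  from the tip (the transition-zone window; the window is configurable
  and echoed in outputs since no canonical value exists) are split
  into lower/upper by the sign of their midline displacement projected
  on gravity; the lower/upper ratio of flank means is reported per
  frame. Onset (`flankOnset`) is the first post-baseline frame
  exceeding 1 + 3·SD(pre-stimulus) for 2 consecutive frames; baseline
  frames themselves are not eligible.
- **Oscillations** (`oscillationTrace`) — for fast acquisitions
  (≥ 64 frames) the first frame's band is reused (the root is
  quasi-static over minutes), the windowed ratio is linearly
  detrended, and the dominant period comes from the periodogram peak.

### Statistics

Two-group profile comparison uses the **Brunner–Munzel** rank test per
position on per-root bin values: the relative effect
P(X < Y) + ½ P(X = Y) via midranks, a Satterthwaite-type t
approximation, and a permutation lower bound 2/C(n₁+n₂, n₁) when the
rank variance degenerates (complete separation). It tolerates ties
and unequal variances. Per-position flags at α are the default
(mirroring per-position significance bars over profile figures); Holm
adjustment across positions is available, and many-to-one comparisons
Holm-adjust across groups per position. The test's type-I error was
verified at 0.05 ± 0.01 by simulation, and the relative effect against
exhaustive enumeration.

The **alkalinization factor** is the ratio of group mean profiles per
position (the alternative — difference of calibrated pH — is not the
default; the definition is recorded in the output), with a bootstrap
confidence band over roots. **Alkaline-domain descriptors** detect the
peak on a 5-bin-smoothed profile against a baseline through the
flanking minima — smoothing keeps a flat noisy profile from ever
presenting a spurious 3σ domain — then measure position, amplitude and
FWHM on the raw bins; a bump truncated by the search window is
reported one-sided and flagged `boundaryLimited`; an absent domain is
explicit (`present = FALSE`, NA descriptors). **Penetration
efficiency** normalizes each variant's fraction of roots crossing the
mesh to the reference variant within the same replicate; the reference
itself is normalized to its across-replicate mean, so it averages to
1 by construction.

## The phantom generator

`makePhantom` renders everything the pipeline consumes, with ground
truth: a tapered dark root (radius `rootRadiusPx`·√(s/`taperPx`),
defaults 25 px and 60 px) stamped along a straight or
bending centerline; a programmed surface pH field — baseline 5.2 with
a Gaussian alkaline halo (center 350 µm, amplitude +0.5 pH, σ 60 µm)
over medium at pH 5.7, matching the zonation the dye reveals on
vertically grown roots and the pH of the unbuffered imaging medium;
forward optics through a logistic ratio curve (midpoint pKa 6.4,
ratios 0.3–4.0, a ~4-fold ratio change over pH 4.5–6.0); per-channel
gains of 300 mean counts with the channel split chosen so total
emission is pH-independent; an optional smooth multiplicative
illumination field shared by both channels; and Poisson shot noise
plus Gaussian read noise (σ = 3 counts), matching an sCMOS camera
qualitatively. Intensities are snapped to the float32 grid so saved
stacks round-trip bit-identically, and a seed fixes every draw.

Radially, the surface pH holds at the programmed pH(s) out to the
outer band edge (25 px) and decays exponentially (30 px) to the medium
pH beyond. This makes the sampled band read the programmed profile
directly — the closure property "calibrated profile equals programmed
pH(s) within 0.05 pH wherever the band exists" holds by construction
and is verified end-to-end — while the image still shows a decaying
halo. Time series add growth (px/frame appended at the tip), bending
(rotation of the distal segment about a fixed elongation-zone pivot),
a lower-flank pH offset stepping in at a programmed onset, and
sinusoidal halo-amplitude modulation.

Dynamics defaults follow the imaging protocols this pipeline targets:
vertical growth every 10 min for 30 min (4 frames), gravistimulation
every 2 min for 42 min (22 frames, initial angle 90°), oscillation
imaging every 5 s.

What the phantoms do *not* emulate: root hairs and surface texture,
multiple roots per field, PSF blur (optional smoothing only),
proton diffusion/reaction in the gel, dye response to cations or
redox state, and focus drift. Passing tests therefore demonstrate the
correctness of the geometry, photometry and statistics of the
pipeline, not robustness to every real-world artifact; on real data
the segmentation and band parameters remain the user's
responsibility.

## Numerical choices and edge cases

- Pixel centers sit at integer coordinates, x = column, y = row
  increasing downward; gravity defaults to (0, 1). Bins are half-open
  `[kΔ, (k+1)Δ)`.
- Channels are identified by explicit order (sidecar or argument),
  never by intensity heuristics: acquisition order varies between
  instruments.
- Stacks are written as multi-page 32-bit *float* TIFF (written by the
  package, read by the standard TIFF reader; the installed writer only
  supports lossy integer samples) with a JSON sidecar for pixel size,
  frame interval, channel order and gravity. A missing pixel size
  falls back to 1 µm/px with a warning rather than failing, keeping
  ratio profiles computable (positions then effectively in px).
- Nearest-midline assignment uses a stride-4 coarse search refined
  exactly within ±4 points; on smooth midlines this equals the exact
  nearest neighbor, and a worst-case s error of a few px is far below
  the 13 µm bin.
- The band's assignment of s and side is a pure function of the mask;
  rotating the image with a co-rotated gravity vector leaves profiles
  unchanged within discretization, and mirroring swaps flanks exactly.
- Problem sizes in the tests and the acceptance script (image fields
  of 512–1024 px, 4–22 frame series, 10 roots per comparison group)
  were chosen as the smallest at which every programmed effect is
  comfortably resolved by the geometry — e.g. a halo at 350 µm needs
  roots longer than ~600 µm of band.
- Group comparison in the acceptance run uses Holm across positions:
  with ~20 true-null positions per profile, per-position α flags would
  mark ~1 position outside the programmed window on every run by
  design; family-wise control makes "no flags outside the window" the
  expected outcome. The package default remains per-position flags.

## Known limitations

Single focal plane and single root per field; no registration across
sessions; the tip-angle estimator is transparent but simple (no
subpixel contour fitting), with ~2° accuracy on phantoms; absolute pH
depends entirely on the user's calibration standards and is clamped at
their range; the Brunner–Munzel t approximation is slightly liberal
below ~10 samples per group.
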