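---
title: "Validating camera image-quality metrics against synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating camera image-quality metrics against synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapqc)
```

## Why this package exists

Manufacturing a surgical camera (for example a low-cost laparoscope)
requires verifying four optical properties on every unit: the limit of
resolution, depth of field (DOF), colour accuracy, and geometric
distortion. In practice these are measured semi-automatically from
photographs of standard test charts: an operator draws a line or clicks
landmark points, and an algorithm does the arithmetic. `lapqc`
implements those four analyses as a tested R library plus a `lapqc`
command-line tool, and pairs them with a synthetic chart generator so
that every algorithm can be validated against *known* ground truth
without any captured images or laboratory hardware.

All pixel coordinates in the package are 0-based `(row, col)` with
pixel centers at integer coordinates.

## The four analyses

### Limit of resolution (USAF-1951 bar target)

A USAF-1951 chart arranges bar triplets in *groups* and *elements*;
element E of group G has spatial frequency

$$f = 2^{G + (E-1)/6} \ \text{lp/mm}, \qquad \text{line width} = 500/f \ \mu m .$$

The operator draws a line through all elements of a group. The package
samples the intensity profile along that line (bilinear interpolation
at ~1 px arc-length steps, the classic "plot profile" operation),
extracts alternating peaks (white gaps) and troughs (dark bars), and
assigns each element its three dark-bar troughs in order. An element
*passes* when its peak level is at least twice its trough level (the
2:1 contrast criterion); the limit of resolution is the finest element
of the leading all-pass run, reported in lp/mm and µm.

Design choices that were genuinely open:

* **Aggregation within an element.** Manual practice reads individual
  line pairs; we aggregate an element's peaks and troughs by their
  means (default) because single-pair readings are noise-sensitive. A
  `worst_pair` strategy (lowest peak over highest trough) is available
  for conservative QA.
* **First-failure truncation.** Once an element fails, finer elements
  cannot define the limit even if they nominally pass — near the
  sampling limit aliasing can produce spurious high-contrast readings.
  Such passes are reported but flagged as anomalies.
* **Finite ratios.** Troughs are floored at 1 gray level so the
  pass/fail ratio stays finite on fully black bars; a run with no
  detectable trough (saturated) passes with an infinite-ratio flag.

### Depth of field (5 lp/mm ladder)

The DOF target presents horizontal line pairs at 5 lp/mm along a tilted
surface, so distance along the chart maps to working distance. The
operator draws a line down the ladder. The rule implemented:

1. the *initial range* is the first full peak minus its adjacent
   trough; the *range check* is half of it;
2. scan successive peak/trough pairs; the first pair whose difference
   falls below the range check is a candidate failure;
3. the candidate is confirmed only if the following 20 pairs are also
   below the range check — a single depressed pair with recovery is an
   anomaly and scanning continues;
4. DOF in mm = number of peaks before the failure ÷ 5.

Open points we had to resolve: when fewer than 20 pairs remain after a
candidate, all remaining pairs below threshold confirms it (the rule is
otherwise undefined at the sequence tail); the failing pair's own peak
is not counted; each peak pairs with the trough immediately after it
and a trailing unpaired peak is ignored. A "first full peak" must rise
by at least the prominence floor above what precedes it, which excludes
a peak clipped by the start of the line; if no qualifying peak exists
among the first three extrema the analysis refuses and asks for the
line to be redrawn.

### Colour accuracy (CIE76)

Patch means are taken over the centered inner 50 % of each patch ROI
(avoiding border bleed), decoded from sRGB to CIELAB (IEC 61966-2-1
transfer, D65 white, 2° observer, via `grDevices::convertColor`), and
compared with a reference table:

$$\Delta E^*_{ab} = \sqrt{(\Delta L^*)^2 + (\Delta a^*)^2 + (\Delta b^*)^2},
\qquad
\Delta C^*_{ab} = \sqrt{(\Delta a^*)^2 + (\Delta b^*)^2}.$$

Means are reported over the colour patches; white-balance squares are
summarized separately so either convention can be compared. No
chromatic-adaptation transform is applied — reports assume the chart
was lit near D65, and comparisons across illuminants should account for
that. Two editable CSV presets ship with the package; both carry
nominal (not batch-measured) values and say so in their headers.

### Geometric distortion (SMIA TV)

From six user-selected landmarks — the left, middle and right points of
the outer top and bottom grid lines — the vertical extents $A_1$ (left),
$B$ (middle), $A_2$ (right) are Euclidean pixel distances, and

$$A = (A_1 + A_2)/2, \qquad \%\,\text{distortion} = 100\,(A - B)/B .$$

The output is signed: negative for barrel (outer sides pulled toward
the center), positive for pincushion; the magnitude is also reported
for comparison with tools that drop the sign. An optional `snap` step
refines each clicked point to the sub-pixel line center: each
coordinate is re-estimated as the darkness-weighted centroid along its
axis while ignoring a band around the crossing line, which keeps
corner and T-junction landmarks unbiased. Snapping is off by default —
the semi-automated workflow treats clicks as authoritative user data.

## The synthetic generator and what it does (not) show

`render_chart()` rasterizes idealized charts with 4× supersampled
anti-aliasing and returns a machine-readable ground-truth record:
exact bar positions and contrasts, the six ideal landmark coordinates,
per-patch CIELAB aims, or the analytic contrast-failure position.
`apply_degradation()` applies, in a fixed order, Gaussian blur →
one-term Brown–Conrady radial distortion → uniform CIELAB offset →
seeded additive Gaussian noise, and updates the ground truth
analytically (landmarks are forward-mapped through
$r \mapsto r(1 + k_1 r^2)$, normalized by half the image diagonal;
effective patch Labs include the offset).

Generator conventions worth knowing:

* **USAF charts** render each element as three horizontal dark bars of
  exact width $500/f$ µm at the stated scale, with per-element contrast
  configurable, so charts with a *constructed* limit of resolution can
  be produced (e.g. finer elements at 1.9:1, coarser at 2.5:1).
  Frequencies beyond the Nyquist limit of the pixel grid are rejected.
* **DOF ladders** place a quarter-period dark lead-in before the first
  light band so the first peak is an interior extremum of any profile
  drawn from row 0, and support a linear contrast gradient whose
  pairwise contrast provably halves at a chosen position — the ground
  truth for DOF recovery is closed-form, not simulated. Blur gradients
  (sigma varying linearly along the ladder) are also supported; they
  have no closed-form failure position and are used for monotonicity
  checks only.
* **Grid charts** extend every line slightly past the outer
  intersections, as printed grid targets do, so all six landmarks sit
  on symmetric crosses and sub-pixel snapping is unbiased.
* **Colour charts** are rendered through the same sRGB pipeline the
  analysis decodes. Note that some standard reference colours (notably
  the classic chart's cyan) lie outside the sRGB gamut and render with
  a clipping error of several ΔE; properties that should not be
  confounded by gamut clipping are validated on mid-range tables.

What passing these tests shows: the arithmetic, conventions and edge
rules of all four engines are correct, stable under endpoint jitter,
scale changes and mild noise, and deterministic under a seed. What they
do *not* show: behaviour on real captures — the generator does not
model lens PSFs, vignetting, demosaicing, illumination non-uniformity,
glare, or chart printing defects. Real-image agreement between this
implementation and commercial tools must be established on captured
images, exactly as one would validate any new analysis app.

## Numerical choices

* Profile sampling uses an endpoint-inclusive grid with step
  `len/round(len)` — exactly 1 px on integer-length lines (so
  axis-aligned width-1 profiles reproduce raw pixels bit-for-bit) and
  within 0.5 % of 1 px otherwise, which makes reversing the line
  reverse the samples exactly.
* Extrema detection handles plateaus (a flat run contributes its
  center sample) and prunes swings below `min_prominence` (default 5
  gray levels, configurable) by repeatedly removing the smallest
  adjacent pair, which guarantees strict peak/trough alternation. The
  default suppresses 8-bit noise ripple while keeping any feature a 2:1
  criterion could care about.
* Perpendicular profile averaging width defaults to 1 px (the common
  plot-profile default); widths > 1 average across parallel offsets.
* The radial warp inverts the distortion model per pixel by 12 Newton
  iterations (ample for $|k_1| \le 0.3$ at unit normalized radius);
  landmark updates use the exact forward map, so oracle comparisons are
  analytic, not resampled.
* Degraded images are re-quantized to 8 bits, because that is what the
  analyses will face; ground-truth recovery tolerances (e.g. mean
  ΔE ≤ 1 on an undegraded chart) budget for this quantization.
* Validation problem sizes: USAF sweeps use group 2 rendered at
  72 px/mm, chosen so that at the largest tested blur (σ = 4 px) the
  finest element still produces detectable extrema and fails the 2:1
  criterion rather than merging; DOF ladders use 40 px/mm (8 px per
  period); grids are 8 × 8 cells at 30 px/mm. Each render is a few
  hundred pixels square and the whole validation suite runs in seconds
  on one CPU.

## Known limitations

* Chart registration is deliberately manual: lines, layouts and
  landmark points are user inputs, echoed into every report. There is
  no automatic chart detection.
* ΔE2000/ΔE94 are not implemented; the colour engines compute exactly
  the CIE76 quantities above.
* The distortion simulator is a single-coefficient radial model about
  the image center; it is sufficient to exercise the SMIA TV statistic
  but is not a full lens model.
* BMP input is not supported (PNG and TIFF are); 10-bit-and-deeper
  pipelines are out of scope — everything is 8-bit.
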