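---
title: "Measuring root hair growth zones from single root-tip images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring root hair growth zones from single root-tip images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhsizer)
```

## The problem

Root hairs (RHs) are tubular outgrowths of root epidermal cells. Along a
growing root they form a developmental gradient: no hairs near the tip
(cells are still dividing and elongating), emerging hairs in the early
differentiation zone, and fully grown hairs further back. Measuring hairs
one by one is slow and, in densely haired species such as *Medicago
truncatula*, practically impossible at scale. This package measures an RH
length *profile* — RH length as a function of distance from the root tip —
from a single focused brightfield image, and condenses it into a handful of
biologically meaningful parameters.

## The measurement pipeline

1. **Segmentation.** The image (dark structures on a bright background) is
   binarized twice with local adaptive thresholds: Bernsen's min/max
   midgrey rule with a small radius captures the root *with* its hairs;
   Phansalkar's mean/standard-deviation rule with a radius on the order of
   the root width captures structures generally, and a morphological
   opening larger than a hair diameter then strips the hairs, leaving the
   root body. The hairs-only mask is the set difference. Hole filling is
   restricted to holes below an area cap: on densely haired roots, bent
   hairs can touch their neighbours and enclose background channels that an
   unconditional fill would flood.
2. **Root median line (RML).** The root-body mask is thinned to a skeleton
   (Zhang-Suen) and the longest geodesic path between skeleton endpoints
   (steps weighted 1 orthogonally, sqrt(2) diagonally) becomes the root
   axis. The tip end is identified automatically as the endpoint with the
   least hair area around it — root tips are bald.
3. **Straightening.** The hairs-only mask is resampled along the RML: one
   column per pixel of arc length, rows covering a band of signed normal
   offsets. Nearest-neighbour sampling is used and the result re-binarized;
   for a binary mask this is equivalent to grey straightening followed by
   renormalisation.
4. **Profile scan.** A rectangular window of width $w$ (default 8 µm,
   roughly half a hair diameter) slides along the straightened root in
   steps of its own width. Per window and root side, the thresholded area
   $A$ gives the length estimate $L = A / w$: because the window is
   narrower than a hair, a hair crossing it contributes area equal to its
   length times the window width, regardless of how bent it is.
5. **Max filter.** Within every block of $k$ consecutive windows (default
   10) only the largest $L$ survives, with the distance of its window.
   Windows that fall on bald spots, or on hairs leaving the focal plane,
   underestimate length; the best-positioned hair in each interval does
   not.

## The model

The profile is fitted with a symmetric four-parameter logistic curve

$$f(d) = L_{noise} + \frac{L_{max} - L_{noise}}{1 + e^{(d_{50} - d)/\delta}}$$

where $d$ is distance from the root tip, $L_{max}$ the mature hair length,
$L_{noise}$ the lower asymptote (segmentation noise in the hairless zone —
ideally zero), $d_{50}$ the inflection point and $\delta$ the slope factor.
The tangent at the inflection point intersects the asymptotes at
$d_{50} \pm 2\delta$; those two abscissae are taken as the positions of RH
initiation and growth arrest, so the RH growth region has width $4\delta$,
and the segment from the tip to $d_{50} - 2\delta$ approximates the
division-plus-elongation zone. Because cells in the growth region no longer
elongate, the quasi-linear central part of the sigmoid can be read as a
growth trajectory in disguise: if the root grows at a known rate, hairs
pass through the region at that speed and elongate by $L_{max} - L_{noise}$
over a span of $4\delta$, giving

$$\mathrm{rate}_{RH} = \frac{L_{max} - L_{noise}}{4\,\delta}\times\mathrm{rate}_{root}.$$

Fitting is unweighted least squares (Levenberg-Marquardt, relative
tolerance $10^{-8}$ on the residual sum of squares, at most 1000
iterations) with data-driven starts: $L_{noise}^0$ and $L_{max}^0$ are the
extremes of the measured lengths, $d_{50}^0$ is the first distance whose
length reaches half the maximum, and $\delta^0$ the first distance whose
length reaches 5% of the maximum (falling back to a tenth of the fitted
range when that rule degenerates, which also serves as a retry start when
the solver reports a singular start). Bounds are enforced by clipping:
a negative fitted $L_{noise}$ triggers a refit with $L_{noise}$ pinned to
zero, and a non-positive $\delta$ after a sign-flipped retry is an error.
The fit is performed twice: a first pass over a user-chosen range (0–6000
µm works well for roots whose plateau lies within the scan) supplies
$d_{50,1}$ and $\delta_1$, and the definitive fit uses only data in
$d_{50,1} \pm 5\delta_1$, clipped to the data extent (the clipped and
requested ranges are both reported). The second pass makes the result
insensitive to how much hairless tip or saturated plateau the first range
happened to include.

## A worked example on synthetic data

```{r example, eval = FALSE}
spec <- synth_spec(seed = 1)          # L_max 600, d50 2500, delta 500 um
syn <- generate_root_image(spec)
masks <- build_masks(syn$image, segmentation_config_for(spec$px_size_um))
rml <- extract_rml(masks$root_body, tip_rule = "auto",
                   hairs_only = masks$hairs_only)
sm <- straighten(masks$hairs_only, rml, band_halfwidth_px = 600)
prof <- measure_profile(sm, w_um = 8, interval_k = 10, range_um = c(0, 6000))
fit <- two_step_fit(prof, first_range_um = c(0, 6000))
fit$fit2
derive_parameters(fit$fit2, root_growth_rate_um_h = 300)
```

On this scene the second fit recovers `L_max` within about 5% of the truth
and `d50` within about 3%, with r² ≈ 0.95.

## What the synthetic generator emulates — and what it does not

`generate_root_image` renders a brightfield-like scene: a dark, gently
curved root body (default width 120 µm, bend radius 50 mm) on a bright
background (structure ≈ 60/255 on background ≈ 200/255), with perpendicular
hairs every 25 µm per side whose true lengths follow the sigmoid
(`L_max` 600 µm, `d50` 2500 µm, `delta` 500 µm by default) with 10%
lognormal length jitter. A fifth of the hair sites are bald and a fifth of
the hairs kink mid-length by 20–35°. Gaussian blur (σ = 1 px) and additive
intensity noise are applied last. The noise σ defaults to 2 grey levels:
the workflow's Bernsen contrast threshold of 15 presupposes background
peak-to-peak local contrast below 15, i.e. noise σ of about 2.5 or less,
which is what sum projection of a 5-slice stack followed by 8-bit
conversion delivers in practice. The default pixel size is 1.5 µm — at
this sampling neighbouring hairs (13 µm gaps) remain separable after
thresholding, which is also what real acquisitions at sub-micron
resolution provide.

The generator does not emulate: out-of-focus hairs, intensity texture
inside the root, touching neighbouring roots, lateral roots, mosaic
stitching seams, or optical vignetting. Passing the recovery tests
therefore shows that the geometry and statistics of the method are
implemented correctly — not that segmentation will survive every real
acquisition artefact; the annotation/exclusion mechanism exists for those.

## Parameter choices that matter

* **Window width `w_um` (8 µm).** Should be ½–⅔ of a hair diameter; wider
  windows mix hairs with background and bias $L$ downward.
* **Interval `interval_k` (10 windows).** The max filter can only bridge a
  bald stretch shorter than its interval. With hairs every 25 µm, an 80 µm
  interval holds ~3 hair sites — adequate for mildly bald roots (20% of
  sites) but not for extreme ones: at 50% bald sites, ~11% of intervals are
  empty and the plateau of the fit collapses. The published alternative
  settings (2, 10, 50, 250) exist for exactly this trade-off; interval 50
  keeps the estimate stable even at 50% baldness, at the cost of a coarser
  profile. Larger intervals also raise the estimate slightly (order of the
  length jitter) because they select the maximum of more hairs.
* **Segmentation scales.** The published radii and iteration counts are
  pixel quantities tied to the acquisition resolution;
  `segmentation_config_for(px_size_um, ...)` re-derives them from physical
  scales (Bernsen radius ≈ one hair diameter; Phansalkar radius ≈ one root
  width; body opening > hair diameter plus the ~2 px edge widening the
  threshold adds; closing kept below the inter-hair gap; hole filling
  capped at (3 × hair diameter)²).
* **Straightening band `band_halfwidth_px`.** Must exceed the longest hair
  plus half the root width; a warning is raised when foreground touches the
  band edge.
* **First fit range.** Should cover the sigmoid's rise and some plateau;
  the second pass then standardises the effective range to
  $d_{50,1} \pm 5\delta_1$.

## Numerical and design notes

* **Polarity.** `dark_objects` flips which side of the local threshold is
  foreground while the statistics are computed on the original intensities
  (the behaviour of the ImageJ implementations of both methods). For
  Bernsen this is exactly equivalent to inverting the image; Phansalkar's
  formula is not inversion-symmetric, so for it the flip is the method's
  dark-object semantics rather than a mirror image.
* **Hole filling** is a 4-connected background flood from the border;
  everything not reached and not larger than the cap is filled.
* **Morphology.** n iterations of the 3×3 box dilation/erosion are applied
  as a single (2n+1) box pass (an exact identity); windows shrink at image
  borders, so erosion does not eat the frame.
* **Skeleton.** Zhang-Suen thinning; the longest path is resolved on the
  8-connected pixel graph with exact 1/√2 step weights. Thinning shortens
  a shape's ends by roughly half its local width — arc positions carry
  that uncertainty near the extreme tip.
* **Tip finding** compares hair area in a window (default 150 px half-size)
  around the two skeleton endpoints; ties go to the first endpoint. A
  named border rule is available when both ends are bald.
* **Distances** are assigned at window centres; annotation intervals are
  closed; max-filter ties break toward the tip.
* **Degenerate inputs.** Fits require ≥ 8 usable points spanning ≥ 4
  distinct distances and non-constant lengths; empty root-body masks,
  multi-component masks, and skeletons without two endpoints are errors
  rather than silent results.
* **Problem sizes.** The validation suite runs the full pipeline on
  6.2 mm synthetic roots at 1.5 µm/px (≈ 4300 × 1700 px) across five seeds,
  and smaller scenes for module-level checks; these sizes exercise every
  code path at realistic hair counts (~400 hairs per root) while keeping a
  complete run of the suite under ten minutes on a single CPU.

## Known limitations

* One root per image; lateral roots would contribute skeleton branches and
  are only handled insofar as the longest path ignores them.
* The symmetric sigmoid cannot represent profiles whose hair length
  declines again far from the tip (senescence); restrict the scan range
  instead.
* $L_{noise}$ absorbs segmentation debris; it is reported, not subtracted
  from per-window values.
* The RH growth-rate estimate inherits the assumptions of steady-state
  root growth and uniform hair growth within the linear zone; it is an
  estimate, not a kinematic measurement.
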