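---
title: "Wall-mask guided retinal vessel detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall-mask guided retinal vessel detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vesselmask)
```

## The problem and the two-stage idea

Retinal blood vessels appear in fundus photographs as dark, elongated,
tube-like structures against a brighter, unevenly illuminated background.
The classical detector convolves the whole image with a bank of oriented,
multi-scale matched filters (MF) and takes the per-pixel maximum response —
a maximum-intensity-projection (MIP) over orientations and scales. That
works, but it spends almost all of its time convolving pixels that are
obviously not vessels.

`vesselmask` implements a two-stage alternative. A *coarse* stage builds a
binary **vessel wall pixel** (VWP) mask from cheap gradient features:
vessel walls are the loci of locally maximal grey-level gradient, and every
true wall pixel has a partner on the opposite wall whose gradient points
the other way. The surviving wall pixels occupy one to two percent of the
field of view. The *fine* stage then evaluates the matched-filter bank only
at sites designated by the mask — one convolution site per wall-pixel pair,
at its midpoint — and infers the vessel interior between paired walls by
interpolation instead of convolution. On a 605×700 frame this reduces the
convolution workload from the full FOV (~3.3×10^5 pixels) to roughly a
thousand sites, two orders of magnitude, while the pair geometry delivers
the centerline and a per-location width estimate for free.

## The coarse stage, step by step

**Preprocessing.** Gaussian smoothing (window 8 px up to 32 px; we read a
window size `s` as a discrete Gaussian with sigma `s/4` truncated at the
next odd window). Illumination correction subtracts a large-scale
background estimate — Gaussian smoothing with a window at least four times
the widest expected vessel (default 200 px for 50 px vessels) — re-centres
on the original mean, and clips bright peaks beyond three global standard
deviations. The clip is one-sided by design: vessels are the dark tail of
the grey-level distribution, and a symmetric clip was measured to erase
them on sparse scenes. All statistics are restricted to the elliptical
field of view, and the gradient is declared undefined wherever its stencil
touches non-FOV pixels; otherwise the FOV rim masquerades as the strongest
edge in the image.

**Gradient frame and features.** Central differences give the gradient;
its normalised direction is the across-vessel axis and its +90° rotation
the local orientation. Three feature families support wall selection:

* *gradient strength* `s = A exp(-||g||^2 / (2 sigma^2))` with `sigma` the
  global gradient SD and `A` the local gradient maximum over a 9×9
  neighbourhood. As printed this peaks at flat pixels, so candidate
  selection uses the raw magnitude jointly with it; a `deviation_form`
  switch replaces the exponent with the squared deviation from the mean
  magnitude.
* *orientation scope*: the largest radius over which the windowed gradient
  SD keeps the homogeneity score `exp(-var_local/var_global)` above a
  threshold (default 0.5). The score is 1 on homogeneous neighbourhoods
  and `e^{-1} ≈ 0.37` where local spread matches the global spread, so 0.5
  separates coherent structure from noise.
* *local homogeneity maps*: 8×8 block variances of gradient magnitude,
  orientation (circular, on the doubled angle — orientation is axial), and
  a curvature proxy (directional derivative of the orientation angle along
  the vessel axis).

**Candidates and pairing.** A wall candidate must exceed the
`percentile_thr` quantile (default 0.75) of gradient magnitudes in its
32×32 tile, exceed the FOV-mean magnitude, and be a 1-D local maximum
along its own gradient (non-maximum suppression), giving thin ridges.
Each candidate then marches against its gradient — from the bright side
into the dark lumen — and accepts the first candidate within the 5–50 px
width range whose gradient is antiparallel within 20° and whose
orientation agrees within 20°. The ray samples at unit steps and probes
the 8-neighbourhood of each sample: a one-pixel ridge crossed obliquely
would otherwise slip between samples. Matching is made mutual one-to-one
(nearest first); because greedy conflicts cascade, unmatched pixels
re-march against the remaining free candidates for up to three rounds.

**Inclusion and pruning.** Paired pixels are graded against their accepted
neighbours within 15 px on four features — gradient magnitude, orientation,
grey level, and local contrast (GL range over the 8×8 block) — by Gaussian
similarity `exp(-(x-mu)^2/(2 sigma^2))`, combined by product, with a hard
gate at two local standard deviations per feature. (At exactly 2σ the
factor is `exp(-2) ≈ 0.135`.) Finally a sparse-pixel brush removes noise:
4-connected components, optionally grown up to ten constrained dilation
steps within the candidate support (padded by one pixel, since thin
diagonal ridges are never 4-connected), lose all their pixels if they
recruited fewer than `min_size = 10`. A limited-range Hough alternative
keeps only pixels voting for line peaks in 64×64 windows.

**Width estimates.** A single pair distance carries the localisation
jitter of two noise-perturbed ridges, so the per-pair width estimate is
the median distance over neighbouring pairs running in the same direction
(midpoints within 7 px, axis within 30°) — the same homogeneity forcing
the inclusion stage applies to wall features. On twenty seeded scenes with
widths spanning 5–50 px and the default noise, this estimator's mean
absolute error is just under 2 px; the raw distances alone are nearer 3 px
because non-maximum suppression on the broad gradient maxima of wide
Gaussian-bell profiles localises to only a few pixels under noise.

## SGLD texture and the displacement scan

The spatial grey-level difference (co-occurrence) matrix is the joint
probability of grey-level pairs at a fixed displacement, estimated over
pairs with both ends inside the FOV; scalar features are energy, marginal
mean/variance, correlation, entropy, and the mean absolute grey-level
difference. For width estimation we scan displacement magnitudes 2–30 px
along the normal of the dominant orientation and score each by the
near-diagonal co-occurrence mass restricted to the wall region, weighted
by the fraction of region pixels whose displaced partner is also in the
region: at the true width one wall maps onto the opposite wall and like
tissue is re-encountered. Scores are only meaningful for a region with a
coherent orientation; on scenes mixing many vessel directions the global
scan is uninformative, which the snapping low-confidence flag detects.
The pipeline therefore narrows the filter bank to SGLD-estimated widths
only when a confident estimate exists, and otherwise uses the configured
candidate set (16/32/64 by default, configurable to a dense 5–50 grid; the
coarse triple and the pairing range intentionally coexist, the former
being the bank's default scale grid and the latter the pairing gate).

## The matched filter

The kernel is an amplitude-modulated, spatially modulated two-variable
Gaussian on the rotated frame (u along the vessel, v across):

    K(u,v) = (2 pi (s_u s_v)^{3/2})^{-1} (u^2 - a_u^2)(v^2 - a_v^2)
             exp(-((u-a_u)^2/(2 s_u^2) + (v-a_v)^2/(2 s_v^2)))

inside the disk `(u-a_u)^2 + (v-a_v)^2 <= D^2` and zero outside. The
modulation offsets place exact zero crossings at `|u| = a_u`, `|v| = a_v`.
Dual-mode kernels compose two mirrored copies offset across the vessel;
single-sided kernels keep one sign lobe. Production kernels are
mean-subtracted over their support (zero DC: flat background yields a null
response) and normalised to unit L2 energy; `zero_dc = FALSE` exposes the
raw analytic form, and `as_printed = TRUE` reproduces a sigma-centred
exponent variant.

Three bank-construction choices matter and were each settled by
measurement on noiseless rendered profiles:

* `sigma_v = 0.75 w` per scale: the central negative lobe of this kernel
  shape ends near `0.8 sigma_v`, so this tying puts the zero crossing on
  the lumen boundary and makes the kernel respond most to the width it was
  built for (a `w/4` tying, natural for a pure-Gaussian kernel, loses
  selectivity entirely for this shape);
* a fixed along-vessel `sigma_u = 4` px for all scales: with unit-energy
  kernels, a longer kernel always wins on an elongated structure
  regardless of its cross-profile, so the integration length must not vary
  across the bank;
* unit L2 normalisation, without which the largest kernel dominates the
  max-over-bank for trivial amplitude reasons.

The default bank is 12 angles over the full circle × 4 scales geometric
over the candidate widths. The angle grid is redundant for double-sided
even kernels (θ and θ+π coincide), which is why arg-max identities are
only defined up to such ties.

## Guided detection, interiors, baseline

Guided detection convolves the bank at the distinct pair midpoints only.
A pair is accepted when its midpoint response exceeds `th_mfr` times the
mean response over the evaluated sites (default 0.5 — the guided site
population is vessels-only, so its mean sits high in the response
distribution) and the midpoint grey level falls inside the adaptive
interval `[0.5 mu_L, 2.5 mu_L]`. The reference level `mu_L` is the local
grey-level mean in a disk whose radius follows the local GL standard
deviation, floored at 3 px and capped at `r_L` (≤ 25 px; the raw rule can
give a degenerate zero radius), and it is anchored *at the wall seeds*:
there the window straddles lumen and background and its mean separates the
two, whereas deep inside a wide lumen it would just re-measure the lumen.

Interior vessel pixels are inferred, not convolved: each accepted pair
contributes its connecting chord (endpoints pulled 1 px inward — the wall
ridge is the outer inflection of the profile), and the cross-sections
between neighbouring accepted pairs (midpoints within `gap_max = 5` px)
are interpolated between the corresponding wall endpoints. A chord is
rejected as a false pairing when more than `max_bad_fraction = 0.25` of
its pixels fail the interval test or fail to be at least one grey level
darker than the wall-anchored reference — a chord across background has
about half its pixels on the bright side, a chord through a bright blob
most of them. Centerline pixels are the rounded pair midpoints carrying
the consensus width, with gaps up to 5 px bridged by linear interpolation.

The full-scan baseline evaluates the bank at every FOV pixel by FFT
correlation, takes the per-pixel maximum (MIP), and applies the same
thresholding with the FOV-wide mean response. The site-restricted and
dense paths agree to 10^-9 at shared sites (both use zero-padded
boundaries), which the test suite asserts.

## Evaluation

Pixel confusion counts are FOV-restricted; SE = TP/(TP+FN) and
SP = TN/(FP+TN). ROC curves sweep the parameter pairs `(r_L, th_mfr)`.
The reliability summary is the area between the achieved SE = f(SP) curve
and the chance diagonal: trapezoidal AUC minus one half, with the curve
extended to the conventional endpoints (SE = 1 at SP = 0 — labelling
everything vessel is always available — and SE = 0 at SP = 1) where they
were not measured. A perfect detector scores 0.5, a chance detector 0.

## The synthetic scene generator

The generator emulates what the coarse stage relies on: dark tubes with
smooth cross-sections whose steepest transition sits at the geometric
wall, a bright background with a smooth illumination ramp, bright
drusen-like blobs as distractors, and i.i.d. Gaussian noise, inside an
elliptical FOV. Centerlines are bounded-curvature heading walks (an AR(1)
turn process capped at 0.02 rad/px) rather than splines through random
waypoints: the walk gives a hard per-pixel curvature bound, which the
locally-quasi-linear assumption of pairing requires. Cross-sections:
a Gaussian bell with sigma = w/2 (inflection at w/2), a dual-mode wall-
accentuated profile, or a sigmoid-walled plateau. The ground-truth tube is
all pixels within w/2 of the centerline; the wall mask is its outer 1.2 px
ring; the width map stores w at centerline pixels.

Default study conditions (fundus scale): 605×700 frame, 15 vessels,
widths uniform in 5–50 px, segment lengths 150–250 px, lumen contrast 60
grey levels on a background of 150 with a 25-GL illumination ramp, 8
drusen of radius 4–12 px and +25 GL (the source material never quantifies
drusen; these are fixed realistic choices), noise SD 5.

What the generator does *not* emulate: branching topology, calibre
tapering, central light reflexes, colour, lesions beyond drusen-like
blobs, and the sharp-walled profiles of real large vessels. The last
point matters for interpretation: a Gaussian bell spreads a fixed contrast
over the width, so the wall gradient of a 50 px synthetic vessel is ~5×
weaker than a 10 px one, and wall recall on wide faint vessels is
correspondingly low — a scene-physics property, not an implementation one.
Passing tests therefore demonstrate the guided pipeline's search-space,
geometry and agreement claims, not clinical-grade sensitivity on real
fundus images.

## Numerical choices and degenerate inputs

Box statistics use exact integral images, not FFT. Constant images:
gradient undefined everywhere, strength defined as `A` with a warning.
Zero local sigma in the inclusion stage accepts a zero deviation and
rejects a non-zero one with a degenerate-stats flag; pixels with fewer
than 5 accepted neighbours are deferred (kept ungated). Empty wall maps
warn and yield empty vessel maps with zero evaluated sites. Duplicate
convolution sites are collapsed; out-of-bounds sites are skipped and
counted. Problem sizes in the test suite — 160–300 px scenes for module
tests, the 605×700 reference scene and a 20-scene battery at 260×260 for
the end-to-end checks — were chosen to exercise the fundus-scale regime
the method targets while keeping the default test run comfortable on a
laptop.

## Known limitations

* Pairing recall on wide, faint (Gaussian-bell) vessels is the dominant
  sensitivity limiter; the guided detector cannot recover a vessel whose
  walls never enter the candidate set.
* Tube end caps are unpairable by construction (no antiparallel partner),
  so a short segment loses proportionally more of its area.
* The SGLD displacement scan assumes one dominant orientation in its
  region; use it regionally, not globally.
* The `2.5 mu_L` upper bound of the acceptance interval is generous for
  bright-background fundus polarity; it mainly guards against saturated
  pixels rather than discriminating vessels.
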