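---
title: "Drift-free estimation of pennate muscle geometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-free estimation of pennate muscle geometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

B-mode ultrasound of pennate muscle (vastus lateralis, gastrocnemius, ...)
shows two bright, roughly horizontal sheets — the superficial and deep
aponeuroses — with thin oblique fascicle stripes between them. From a single
frame one wants muscle thickness $T$, the superficial aponeurosis angle
$\beta$, the fascicle angle $\alpha$, the pennation angle $\varphi$ and the
fascicle length $L_\mathrm{fas}$. The widely used optic-flow trackers
estimate frame-to-frame *changes* and integrate them, so errors accumulate
over long sequences (integration drift) and an initial manual tracing is
needed. `pennatrack` instead detects the geometry independently in every
frame: no state is carried between frames, so errors cannot accumulate with
sequence length, which is what the drift test in the acceptance suite
verifies on a long cyclic phantom sequence.

## Pipeline

Per frame:

1. **Vesselness filtering.** A single-scale Frangi-type Hessian filter
   enhances bright line-like structures, run twice: at the fascicle scale
   `sigma_fas_px` and at the aponeurosis scale `sigma_apo_px`. The Hessian is
   computed with scale-normalised ($\sigma^2$) Gaussian-derivative kernels
   and replicate borders; for eigenvalues $|\lambda_1|\le|\lambda_2|$ the
   response is $e^{-R_B^2/2\beta^2}(1-e^{-S^2/2c^2})$ with
   $R_B=\lambda_1/\lambda_2$, $S=\sqrt{\lambda_1^2+\lambda_2^2}$, zero where
   $\lambda_2\ge 0$ (bright ridges only), max-normalised per image.
2. **Aponeurosis detection.** Within each user-specified relative depth
   region, either (a) *Hough*: the dominant straight line of the thresholded
   image (de-biased accumulator, see below) is sampled at `n_apox` abscissae
   and each sample is traced vertically toward the muscle interior to the
   last bright pixel — the inner edge, where fascicles insert; or (b)
   *object*: the best 8-connected component (longest by major-axis length,
   ties by length-ratio `l_ratio_max` resolved on mean masked intensity)
   provides per-column inner edges, shifted `sigma_apo_px/4` away from the
   fascicles to undo the dilation added by the filter chain's Gaussian
   smoothing. Inner-edge points are then fitted by polynomials $S(x)$,
   $D(x)$ of orders `o_super`, `o_deep` under slope constraints
   $|p'(x)|\le\tan(\max|\text{angle range}|)$, solved exactly as a small
   quadratic program (primal active set).
3. **Fascicle angle.** Inside an elliptic region spanning the image width
   and the gap between $S$ and $D$, the Hough transform of the binary
   fascicle image is de-biased, corrected for the ellipse chord length per
   angle, and $\alpha$ is the weighted median of the `k_peaks` strongest
   peaks (weights = corrected accumulator values). The median resists
   outlier sub-populations that capture the single tallest peak.
4. **Geometry.** $\varphi=\alpha-\beta$ with $\beta$ the angle of $S$ at the
   right border; $T=|S(x)-D(x)|\cos\beta$ at a user-chosen abscissa
   (`x_eval_rel`, default mid-image); $L_\mathrm{fas}=T/\sin\varphi$.
   Optionally, the fascicle through the mid-gap midpoint is intersected with
   the polynomial extensions of $S$ and $D$ (extrapolation mode), which by
   construction spreads any beyond-frame extension evenly left and right;
   the extrapolated fraction is always reported and flagged above
   `extrap_warn_fraction`.

Per sequence (optional, in this order): time-interpolation of occluded
frames (brightness below `brightness_threshold_rel` of the time-average),
then zero-phase low-pass filtering of $\alpha$, $\beta$ and $T$ with
$\varphi$ and $L$ recomputed, so the trigonometric identities hold on every
output row.

## Conventions

Pixel grid is (row, col) with row 1 the most superficial tissue; x runs
rightward in columns, depth downward in rows. All angles are
counter-clockwise-positive w.r.t. the horizontal with "up" toward the
superficial side, i.e. $\theta=\arctan(-\Delta\text{row}/\Delta\text{col})$;
fascicles are assumed to rise to the right (first quadrant,
`theta_fas_range_deg` $\subset(0°,90°)$ — flip the image horizontally
otherwise). A consequence worth noting: a superficial aponeurosis sloping
*deeper* toward the right has negative $\beta$. Hough lines are
parameterised by this visual angle and the signed distance
$\rho=x\sin\theta+y\cos\theta$ at 1-px resolution.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `sigma_fas_px`, `sigma_apo_px` | 2, 8 | px | vesselness scales; a structure of thickness about equal to sigma responds strongly, and the aponeurosis smoothing SD is `sigma_apo/2` — half a structure thickness |
| `t_fas`, `t_apo` | 0.2 | — | thresholds on max-normalised responses (and raw grayscale for the aponeurosis mask), hence device-independent |
| `d_superficial`, `d_deep` | [0, .35], [.55, 1] | height fraction | the only per-dataset inputs; set once per acquisition protocol |
| `theta_fas_range_deg`, resolutions | [5, 80], 0.5 | deg | eligible fascicle angles and accumulator granularity; 0.5 deg bounds the quantisation of $\alpha$ |
| `n_apox`, `x_margin_px` | 20, 10 | —, px | inner-edge sampling density and lateral crop against edge effects |
| `l_ratio_max` | 0.5 | — | object disambiguation: below it the longest object wins outright |
| `beta_range_deg`, `gamma_range_deg` | ±20 | deg | plausible aponeurosis slopes; bound both the Hough search and the fit slopes |
| `k_peaks` | 10 | — | peaks entering the weighted median |
| `rotation_delta_deg` | 5 | deg | de-biasing rotation; any value off the 45-degree lattice works, 5 keeps interpolation loss small |

## Hough de-biasing

On a square lattice, exactly horizontal/vertical/diagonal lines concentrate
votes (all pixels of an image row share one $\rho$ bin), so the accumulator
is biased at $\theta\in\{0°,\pm45°,90°\}$. Where those angles occur on the
axis, the counts are replaced by those measured on the image rotated by
`rotation_delta_deg` (bilinear, enlarged zero-padded canvas, re-binarised at
0.5): the same physical line then sits at $\theta+\delta$, off the lattice,
and its distance maps exactly through
$\rho' = \rho - c\cdot n(\theta) + c'\cdot n(\theta+\delta)$ for the
rotation about the image centre (nearest-bin assignment). Only the biased
columns are touched.

## Chord correction

Within an elliptic ROI with semi-axes $a,b$, a line at angle $\theta$ can
collect at most $L(\theta)=2ab/\sqrt{b^2\cos^2\theta+a^2\sin^2\theta}$
votes. Each accumulator column is divided by $L(\theta)/\max_\theta L$, so
orientations are compared per unit of available chord rather than raw
count; normalising by the maximum keeps weights comparable across frames.
Whether to divide or multiply is not *a priori* obvious; division
(penalising orientations with longer possible chords) is implemented and
isolated in `chord_correction()` so the alternative is a one-line change.

## The phantom generator

`phantom_spec()`/`render_phantom()` draw two bright bands on polynomial
centre lines, oblique stripes at the true fascicle angle strictly between
the bands' inner edges (so the ground-truth insertion geometry is exact),
multiplicative mean-one log-normal speckle (a standard B-mode
approximation), optional per-frame brightness scaling for occlusion, and an
optional second stripe population for estimator-robustness experiments.
Defaults: band thickness = `sigma_apo_px` (8 px) and stripe thickness =
`sigma_fas_px` (2 px), the 1:1 thickness-to-scale pairing under which the
object method's `sigma_apo/4` edge trim exactly compensates the smoothing
dilation; intensities background 0.08 / stripes 0.65 / bands 0.9;
`cm_per_px = 0.01` (a ~5 cm probe at ~500 px width).

What the phantom does **not** emulate: depth-dependent attenuation and
focus, anisotropic point-spread functions, curved fascicles, out-of-plane
motion, or vendor post-processing. Passing the recovery tests therefore
demonstrates correctness of the detection and geometry chain under the
stated image model, not clinical accuracy on arbitrary hardware.

## Numerical choices

* Gaussian kernels are truncated at 4 SD; the second-derivative kernel is
  mean-subtracted so a constant image yields an exactly zero Hessian
  response despite truncation.
* Frangi constants: $\beta=0.5$; $c$ defaults to half the maximum Hessian
  norm of each image (both overridable).
* Accumulator ties break deterministically toward smaller $|\theta|$, then
  smaller $|\rho|$; peak picking suppresses a 3×3 cell neighbourhood per
  peak.
* The constrained polynomial fit solves the exact KKT systems of a primal
  active-set QP; duplicate constraint rows (order-1 fits make the slope
  constraint identical at every abscissa) are removed first. A zero
  polynomial is always feasible, so the program cannot be infeasible for a
  positive slope bound.
* Extrapolation intersections are bracketed outward from the midpoint in
  half-width steps up to five image widths, then refined with `uniroot`;
  in non-extrapolated mode an out-of-reach intersection only voids the
  extrapolated-fraction diagnostic (`NA`), never the frame.
* The zero-phase low-pass (2nd-order Butterworth, forward-backward) filters
  mean-removed series, so constant inputs pass through exactly.
* Occlusion interpolation uses the *time-mean* brightness as reference,
  linear interpolation between nearest valid frames and nearest-valid
  extension at the boundaries; it also fills rows whose detection failed,
  and is idempotent. Interpolation and filtering act on the independent
  features ($\alpha$, $\beta$, $T$) and recompute $\varphi$ and $L$.
* Frames whose detection fails yield a flagged row rather than aborting the
  sequence; `per_sequence` ellipse mode seeds its cached ROI from the first
  frame that succeeds.

## Validation problem sizes

The test suite and the acceptance script work at desk scale: randomized
Hough-oracle equality on 200 binary images up to 64×64; 1,000 random
geometry triples for the closed-form identities; 25 noise-free phantoms
spanning $\alpha\in[15°,40°]$ and $T\in[1,3]$ cm for both aponeurosis
methods; 20 phantoms at speckle log-SD 0.3; and cyclic sequences of 120–200
frames (speckle 0.15, a modest level typical of decent-quality recordings)
for the drift check, comparing the first and last cycle's mean fascicle
length.

## Known limitations

Fascicles are assumed straight; aponeuroses are modelled by low-order
polynomials only. Heavy speckle can let a sub-population dominate the
accumulator; the weighted median mitigates but does not remove this. The
angle estimate is quantised to `theta_fas_res_deg`. Extrapolation assumes
the fitted geometry continues beyond the frame and should be sanity-checked
against panoramic imaging where available. Calibration is a single
isotropic `cm_per_px`; anisotropic pixel spacing is out of scope.
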