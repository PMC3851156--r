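---
title: "Estimating muscle fiber orientation in B-mode ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle fiber orientation in B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mfodetect)
```

## The problem

Longitudinal B-mode sonograms of pennate muscle show fascicles and
aponeuroses as bright, roughly straight bands on a darker, speckled
background. The orientation of those bands -- the muscle fiber orientation
(MFO) -- underlies pennation-angle and fiber-length analyses of muscle
function, and tracking it across a contraction requires processing hundreds
of frames. Exhaustive voting methods (Hough or Radon transforms over the
whole image) are accurate but slow; `mfodetect` implements a shape-aware
pipeline that reserves voting for the rare cases that need it.

The pipeline has three stages:

1. **Enhancement.** Multiscale vessel-enhancement filtering (MVEF) based on
   the eigenvalues of the scale-normalized Hessian boosts bright tubular
   structures and suppresses speckle.
2. **Segmentation.** Otsu's threshold on the enhanced image yields a binary
   candidate map; 8-connected components are described by their
   moment-equivalent ellipse (major axis $L$, minor axis $\omega$, aspect
   ratio $A_r = L/\omega$, orientation $\phi$).
3. **Detection.** Regions are consumed longest-first. A long, thin region
   ($A_r > T_1$ and $\omega < T_2$) is a single fiber trace and its angle is
   read directly from $\phi$ -- an $O(n)$ moment computation. Anything else
   (branched or blob-like) falls back to a Hough transform restricted to that
   region's own pixels. After each detection a strip around the line is
   cleared map-wide and the loop repeats until $N$ lines are found or region
   length drops below $T_3 \cdot L^1$.

## The vesselness model

At scale $\sigma$ the image is correlated with sampled Gaussian-derivative
kernels to form the Hessian; eigenvalues are ordered
$|\lambda_1| \le |\lambda_2|$ and scale-normalized by $\sigma^2$. For bright
structures on a dark background the response is

$$
V_\sigma =
\begin{cases}
0 & \lambda_2 \ge 0,\\[4pt]
\exp\!\left(-\dfrac{R_B^2}{2\beta^2}\right)
\left(1 - \exp\!\left(-\dfrac{S^2}{2c^2}\right)\right) & \lambda_2 < 0,
\end{cases}
\qquad
R_B = \frac{\lambda_1}{\lambda_2},\quad
S = \sqrt{\lambda_1^2 + \lambda_2^2},
$$

and the enhanced image is $\max_\sigma V_\sigma$. The blobness term rejects
isotropic structures; the structureness term rejects low-contrast noise.

Parameter choices, all overridable through `vesselness_params()`:

* **Scales** $\sigma \in \{1,\dots,5\}$ px. Fascicle bands in clinical
  sonograms are a few pixels to roughly ten pixels across; a ridge of width
  $w$ responds most strongly near $\sigma \approx w/2$.
* **$\beta = 0.5$**, the customary blobness sensitivity for this family of
  filters.
* **$c$ = `"auto"`**: half the maximum Frobenius norm of the
  scale-normalized Hessian at each scale. This adapts the structureness term
  to image contrast; combined with min-max normalization of the input it
  makes the filter invariant to the intensity scale of the source data.
* Kernels are truncated at $4\sigma$ with mirror-reflected boundaries, which
  avoids spurious ridges at frame edges. The second-derivative kernel is
  re-centred to sum exactly to zero, so constant and linear intensity fields
  are annihilated to machine precision rather than to discretization error.

## Shape descriptors and the angle convention

Region moments carry the standard $1/12$ unit-square pixel correction on the
diagonal, so a single pixel has the ellipse of a unit square
($L = \omega = 4\sqrt{1/12}$) and the aspect ratio of a $l \times w$
rectangle is exactly $l/w$. This matches the usual "ellipse with the same
normalized second central moments" definition and keeps thin-bar aspect
ratios finite.

All angles are reported in the NIH-Image convention: degrees from the
downward image vertical (the vector from the top-left to the bottom-left
corner), folded into $[0, 180)$, with positive rotation toward the upper
right. Under the Hough normal form
$\rho = x\cos\theta + y\sin\theta$ (x = column, y = row) this convention
makes the map from the winning $\theta$ to the reported angle the identity,
and it is shared by the moment orientation $\phi$ and by the synthetic
generator's ground truth, so the ellipse path, the voting path, and the
truth tables are mutually consistent. Isotropic regions
($e_{\max} = e_{\min}$), which can never be classified as fiber traces, get
$\phi = 0$ as a deterministic tie-break.

## Detector parameters

| parameter | default | meaning |
|---|---|---|
| `T1` | 5 | aspect-ratio threshold; the ellipse path requires $A_r > T_1$ (strict) |
| `T2` | 30 px | width threshold; the ellipse path requires $\omega < T_2$ (strict) |
| `T3` | 10% | stop when $L^n < T_3 \cdot L^1$ |
| `N` | 7 | maximum lines per frame (7 covers skin, bone, both aponeuroses and the fascicles between them; use 4 for reduced-architecture imaging) |
| `removal_width` | 17 px | strip cleared around each detected line, 8 px to each side |
| `theta_step`, `rho_step` | 1°, 1 px | Hough accumulator resolution |

Raising `T1` or lowering `T2` routes more regions through the Hough path
(slower, but safer when merged fibers are common); the defaults classify the
overwhelming majority of clinical regions as single traces. The removal
strip is applied by perpendicular distance to the infinite detected line
across the *whole* map: that clears noise along the line and also consumes
collinear fragments of the same broken fiber, so a fiber imaged in pieces is
not counted twice. The line that triggers the $T_3$ stop is recorded (the
stop check happens after detection); `drop_terminal_short_line = TRUE`
discards it instead.

Ambiguities resolved as deliberate choices: accumulator ties break toward
the smallest $\theta$, then the smallest $\rho$; "longest region" ties break
toward larger area, then smaller label; components are 8-connected
(diagonal fascicle traces fragment under 4-connectivity); binarization is
strict (`intensity > threshold`); Otsu uses 256 uniform bins over the
enhanced image's range with the smallest tying level returned.

## What the synthetic generator does and does not emulate

`render_scene()` draws anti-aliased rotated rectangles (soft 1-px edges, so
the noiseless moment orientation matches the nominal angle to well under a
degree), composites them over a uniform background, blurs with a Gaussian
(default $\sigma = 1$ px, a stand-in for the finite beam width), and applies
per-pixel multiplicative speckle $s \sim \mathrm{Gamma}(k, k)$ (unit mean;
default shape $k = 4$, a strongly speckled but readable appearance).
`render_crossing()` builds the branched two-fiber pattern and verifies the
two bars form one connected component in the noiseless binarization;
`render_sequence()` sweeps bar angles along a per-frame trajectory with
per-frame seeds derived from the base seed.

Real sonograms differ in ways the generator does not model: log-compressed
spatially correlated speckle rather than i.i.d. gamma factors, depth
attenuation and shadowing, curved fascicles, intensity banding from the
probe, and annotation overlays. Passing recovery tests therefore demonstrate
the geometry and plumbing of the method -- angle conventions, ordering,
removal, termination -- under a credible noise surrogate, not clinical
accuracy; validation on real frames needs operator-annotated data.

## Problem sizes and numerical behaviour

The test-suite and acceptance fixtures use 150--300 px frames, 50-fixture
angle-recovery suites, and a 50-frame tracking sequence -- sizes at which
one frame enhances and detects in well under a second, and the package's own
recomputation script finishes in well under a minute. On those conditions
single-fiber recovery is accurate to a few hundredths of a degree on
average (worst case about a third of a degree), no single-fiber frame ever
routes through the Hough path, and tracking correlation with the generated
truth exceeds 0.999.

## Known limitations

* **Junction suppression.** The blobness term drives the vesselness of a
  fiber crossing toward $e^{-2}$ of the arm response, so a strongly
  contrasted perpendicular crossing can split into separate arms after
  thresholding -- most visibly on noiseless renders, occasionally under
  heavy speckle. The branched-region Hough fallback then simply sees the
  arms as single traces; both angles are still recovered, but the method tag
  is `ellipse` rather than `hough`. Shallow-angle adherent fibers, the
  common clinical merge, are less affected because their junction stays
  elongated.
* One line is extracted per branched region per iteration (the global
  accumulator maximum); remaining branches survive the removal strip and are
  picked up in later iterations.
* Otsu assumes a bimodal enhanced histogram. A frame with no tubular
  structure yields a constant (all-zero) enhanced image; the pipeline warns
  and returns an empty line table instead of failing.
* Angles are attributes of straight lines; curvature is outside the model.
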