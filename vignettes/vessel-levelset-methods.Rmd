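---
title: "Methods: spatially coupled Bayesian energy and its level set minimizer"
author: "vesselseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially coupled Bayesian energy and its level set minimizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselseg)
```

## The model

A fundus image is treated as a two-class labeling problem: every pixel is
either vessel or background, and each class is modeled as Gaussian around a
mean intensity $\mu_k$. Plain pixel-independent maximum likelihood ignores
that vessels are connected, thin structures; this package instead couples
each pixel's likelihood to its spatial neighborhood. The conditional
probability of pixel $i$ is a $\lambda$-weighted mixture over the
class-conditional densities of its neighbors $j \in \mathcal{N}_i$, with
mixing weights

$$\lambda_{ij} = \frac{h_{ij}}{\sum_{j \in \mathcal{N}_i} h_{ij}},
\qquad h_{ij} = \exp\!\left(-\frac{\|u_i - u_j\|^2}{2\sigma_g^2}\right),$$

a purely geometric (Gaussian-in-distance) closeness. `mixingWeights()`
exposes these; note they are constants of the model, so after taking the
negative log-likelihood and assuming a common class variance they drop out,
leaving the energy

$$\mathcal{F}(\mu) = \sum_k \sum_{j \in \Omega_k} e_k(x_j), \qquad
e_k(x_j) = c(j)\,(x_j - \mu_k)^2,$$

where $c(j)$ counts how many pixels' windows contain $j$ — the full window
size $(2r+1)^2$ in the interior, fewer at image borders, where out-of-domain
pixels simply do not exist (`neighborCount()` uses zero padding for exactly
this reason). The neighborhood coupling therefore survives only as this
count weighting plus the interpretation of the model; per-class variances
are deliberately out of scope, since the minimization algorithm is derived
from the common-variance functional only.

## Level set formulation

The two regions are encoded by the sign of a level set function $\varphi$:
$\Omega_1 = \{\varphi > 0\}$, $\Omega_2 = \{\varphi < 0\}$. With the
regularized Heaviside and Dirac pair

$$H_\epsilon(z) = \tfrac12\left[1 + \tfrac{2}{\pi}\arctan(z/\epsilon)\right],
\qquad \delta_\epsilon(z) = \frac{1}{\pi}\frac{\epsilon}{\epsilon^2 + z^2},$$

the total energy is

$$\mathcal{F}(\varphi, \mu) = \sum_j e_1 H_\epsilon(\varphi_j)
 + \sum_j e_2 (1 - H_\epsilon(\varphi_j))
 + \alpha \sum_i \delta_\epsilon(\varphi_i)\,|\nabla\varphi_i|
 + \beta \sum_i \tfrac12 (|\nabla\varphi_i| - 1)^2 .$$

The $\alpha$ term is the contour length (smoothness of the vessel
boundary); the $\beta$ term penalizes deviation of $\varphi$ from a signed
distance function, so no reinitialization is ever performed. Minimization
alternates the closed-form mean update

$$\mu_1 = \frac{\sum_j c(j)\, x_j\, H(\varphi_j)}{\sum_j c(j)\, H(\varphi_j)}$$

(and symmetrically for $\mu_2$) with gradient descent on $\varphi$:

$$\partial_t \varphi = \delta_\epsilon(\varphi)(e_2 - e_1)
 + \alpha\,\delta_\epsilon(\varphi)\,\mathrm{div}\!\left(\frac{\nabla\varphi}{|\nabla\varphi|}\right)
 + \beta\,\mathrm{div}\!\left(\left(1 - \frac{1}{|\nabla\varphi|}\right)\nabla\varphi\right).$$

Because $\delta_\epsilon$ has unbounded support, region forces act on every
pixel regardless of the current contour position, which is why the result
is insensitive to the initialization (a property the test suite checks on
three different starts).

## Numerical scheme

Discretization is deliberately plain: central differences with replicated
(Neumann) borders, gradient magnitudes floored at $10^{-10}$ in
denominators, and the regularization divergence expanded as
$\Delta\varphi - \mathrm{div}(\nabla\varphi/|\nabla\varphi|)$ so that it
shares the curvature operator.

Two stabilizations matter, and both were chosen from first principles
rather than tuned per image:

1. **Substepped regularization.** With intensities on the 0–255 scale the
   calibrated weight is $\beta = 0.001 \cdot 255^2 \approx 65$, so the
   explicit diffusion number $\beta\,\Delta t \approx 6.5$ is far beyond
   the $\approx 1/8$ two-dimensional stability limit; a single explicit
   step amplifies checkerboard modes by a factor of tens per iteration and
   diverges within a handful of iterations. The regularization flow is
   therefore integrated with $m = \lceil 8\beta\Delta t\rceil$ substeps per
   iteration, each individually stable; this integrates the same ODE over
   the same time $\Delta t$, it does not change the model.

2. **Capped updates.** The data force $\delta_\epsilon(\varphi)(e_2-e_1)$
   has magnitude up to $\sim 10^4$ in level set units — squared 0–255
   intensities times the window count — which no explicit step size can
   absorb. Per iteration, the data + curvature update is capped at
   $\pm 5$ level set units per pixel and the total regularization
   displacement at $\pm 2$ (split evenly across substeps). This is CFL-type
   rate limiting: it preserves fixed points and descent directions while
   bounding front speed (a few pixels per iteration). The asymmetry of the
   caps is essential for thin structures: if the regularizer may move
   $\varphi$ exactly as fast as the data term, its smoothing flow refills a
   freshly carved one- to three-pixel vessel groove at the same rate the
   data term digs it, and the two stall in a tie; with the data cap larger,
   the data term wins every such race and vessels of the minimum
   (two-pixel) caliber survive. With these caps the evolution converges in
   well under ten iterations on all fixtures in the suite.

**Mean updates use the ideal Heaviside.** The closed-form minimizer above is
derived with the exact step function; the smooth $H_\epsilon$ is needed only
to differentiate the energy in $\varphi$. Using $H_\epsilon$ in the mean
update leaks $O(\epsilon/|\varphi|)$ of each class into the other mean — at
the typical converged amplitude $|\varphi| \sim 40$ on a 0–255 image that
is a bias of more than one intensity unit, which would visibly shift the
decision boundary. `updateMeans()` offers both (`hard = TRUE/FALSE`); the
solver uses the hard form. An empty class (denominator below $10^{-12}$)
returns NA and the solver keeps the previous mean.

**Stopping.** The partition is declared stationary when the fraction of
pixels whose sign of $\varphi$ changed in one iteration falls below the
tolerance ($10^{-4}$) *and* both class means moved by less than
$10^{-4}$ times the intensity range, with a minimum of three iterations.
The sign-change test alone is not sufficient: from a symmetric start (for
example the centered circle on the two-block image) the two class means
begin equal, all forces are near zero, and a pure sign-change test fires
immediately on a configuration that is not a minimum. A degenerate
one-class image (no contrast) satisfies both tests at once and returns a
trivial partition without error.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\alpha$ | 1.0 | energy | contour-length weight |
| $\beta$ | $0.001 \cdot 255^2$ | energy | distance-regularization weight, calibrated to 0–255 intensities; rescale to 0.001 for \[0,1\] images (`--normalize`) |
| $\Delta t$ | 0.1 | time | gradient-flow step |
| $\epsilon$ | 1.0 | level set units | Heaviside/Dirac width; not a data-scale quantity, so it is kept at the standard 1 |
| $\sigma_g^2$ | 10 | px² | closeness-kernel variance |
| $r$ | 1 | px | neighborhood radius (3×3 window) |
| caps | 5 / 2 | level set units | per-iteration update limits, data vs regularization (see above) |
| tolerance | $10^{-4}$ | — | stationarity threshold on the sign-change fraction |
| max iterations | 500 | — | generous: fixtures converge in <10 |

The working channel for RGB fundus images is green (highest vessel
contrast); the converged class with the *lower* mean is labeled vessel,
since vessels are dark in the green channel. Both rules are configurable.

## The phantom generator

`vesselPhantom()` produces ground-truthed samples matching the model's own
assumptions: a bright disk (the FOV) of mean 180, dark vessel trees of mean
80, i.i.d. Gaussian noise of sd 10, clipped to \[0, 255\], zero outside the
disk as in a real fundus photograph. Trees are random walks from the disk
center — heading perturbed by $N(0, 0.15^2)$ radians per unit step — dilated
to a linearly tapering width of 5 down to 2 pixels, one daughter branch per
trunk. Those defaults put the class separation at 10 noise standard
deviations, which is the regime the intensity model assumes; everything is
reproducible from a single seed, and the generator restores the caller's
RNG state.

What the phantom does *not* emulate: intensity inhomogeneity and vignetting,
the central light reflex of arteries, contrast that decays with caliber,
pathologies, or the JPEG-like artifacts of real databases. Passing on
phantoms therefore validates the estimator and the minimizer under the
stated model, not clinical performance; for the latter the CLI can run the
full DRIVE/STARE experiment when those databases are supplied by the user.

```{r example}
ph <- vesselPhantom(shape = c(128, 128), seed = 2)
res <- segmentVessels(ph)
res
scoreSegmentation(res, truthMap(ph), fovMask(ph))
```

## Problem sizes and runtime

The test suite exercises oracle equivalence on fields up to 16×16 (scalar
loop references), parameter recovery on the 64×64 two-block fixture, and
full segmentation on 256² phantoms; a 256² segmentation takes a couple of
seconds on one core. These sizes were chosen because every claimed property
is already decidable at them — the method is resolution-independent, and
565×584 DRIVE frames run in well under a minute through the CLI.

## Known limitations

- Two phases only; the multi-phase extension is out of scope.
- A global mean per class: slow illumination drift across the FOV is not
  modeled and will bias the threshold between classes.
- The common-variance assumption removes $\sigma_k$ from the minimization;
  classes with very different spreads are not represented.
- Hard segmentation output: no soft vesselness score, hence no ROC/AUC.
- No GIF decoder (DRIVE masks must be converted to PNG once).
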