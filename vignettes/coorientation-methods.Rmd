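---
title: "Quantifying co-orientation in two-color localization microscopy"
author: "coorient package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-orientation in two-color localization microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coorient)
```

## The problem

Cytoskeletal networks - actin, microtubules, intermediate filaments - are
extended, oriented structures. Classical co-localization analysis asks only
whether molecules of two species occupy the same places; it ignores that the
molecules sit on filaments whose *orientations* carry additional evidence
about interaction. Two filament systems that run close together *and*
parallel are much stronger candidates for physical coupling than two systems
that merely cross. `coorient` quantifies this *co-orientation* - the
simultaneous co-localization and orientational alignment of structures in
two color channels of single-molecule localization microscopy (SMLM) data -
and attaches a calibrated significance statement to it.

## The model, step by step

### From localizations to orientation space

Each channel's localization table is binned into a 2D histogram image
$I_l(\vec x)$ with 10 nm bins by default. Pixelation at this size is benign
as long as the bin is smaller than about 1.5 times the localization
precision; `binLocalizations()` warns when that guard is violated.

Local orientation is measured by convolving $I_l$ with a bank of
orientation-selective band-pass filters defined in the Fourier domain:

$$\hat\Phi(\vec q;\phi_k) = 2\,
  \exp\!\Big(-\frac{(\phi_q-\phi_k)^2}{2 w_\phi^2}\Big)\,
  (q s_o)^{1/(w_q^2 s_o^2)}
  \exp\!\Big(-\frac{q^2 s_o^2 - 1}{2 w_q^2 s_o^2}\Big),$$

where $\phi_q$ denotes the orientation of the structure a wavevector
evidences (perpendicular to the wavevector itself), $s_o$ is the
*orientation scale*, $w_q = 0.8/s_o$ the radial bandwidth, and
$w_\phi = \pi/n_o$ the angular bandwidth for $n_o$ orientation channels
($n_o = 41$ by default, an angular resolution of about 77 mrad). The radial
exponent is written here in the form under which the radial profile peaks at
$q = 1/s_o$ with value 1, so the filter's maximum modulus over the frequency
plane is exactly the prefactor 2; this is the only reading consistent with a
scale-selective filter centered on $1/s_o$. The DC response is identically
zero. A single angular lobe is used (no Hermitian mirror), so spatial
responses are complex; only their modulus enters the analysis, which makes
the lobe convention immaterial.

The raw responses $I_l(\vec x, \phi_k)$ are converted to a normalized
orientation-space density

$$\tilde I_l(\vec x,\phi_k) = \frac{|I_l(\vec x,\phi_k)| - m(\vec x)}
  {\Delta\phi \sum_k |I_l(\vec x,\phi_k)| - \pi\, m(\vec x)}\; I_l(\vec x),
  \qquad m(\vec x) = \min_k |I_l(\vec x,\phi_k)|,$$

interpretable as the expected density of localizations per unit angle
belonging to structures of orientation $\phi_k$ at $\vec x$. Subtracting the
per-pixel minimum removes the filters' unavoidable response at orientations
not present at that location. By construction
$\Delta\phi \sum_k \tilde I = I$ at every occupied pixel. Two degenerate
cases need a convention the construction itself does not fix: pixels with no
localizations are zero everywhere, and pixels with a perfectly isotropic
response (vanishing denominator) are assigned the uniform density $I/\pi$,
which preserves the angular-integral identity.

### The generalized cross-correlation

Co-orientation is measured by the cross-correlation of the two channels'
orientation densities over spatial lag *and* orientation difference,

$$c(\Delta\vec x, \Delta\phi) = \pi\,\Delta\phi_{\mathrm{bin}}
  \frac{\sum_{\vec x,k} W \tilde I_1(\vec x,\phi_k)\,
        W \tilde I_2(\vec x+\Delta\vec x,\phi_k+\Delta\phi)}
       {\langle I_1\rangle \langle I_2\rangle\; (W\!\star\!W)(\Delta\vec x)},$$

with $W$ a binary region-of-interest mask and $\langle I_l\rangle$ the mean
localization count per pixel over the ROI (the mean, not the RMS: an RMS
normalization would react to noise level, labeling density and localization
precision rather than to structure). The orientation average is an integral
over $\phi$ ($\Delta\phi_{\mathrm{bin}} = \pi/n_o$), which together with the
$\pi$ prefactor calibrates $c$ so that statistically independent channels
give exactly $c = 1$: for an isotropic, independent pair,
$E[\tilde I_l] = \langle I_l\rangle/\pi$ per unit angle, and the factors
cancel. The implementation evaluates the sums with 3D FFTs; the spatial axes
are zero-padded (linear correlation, so a lag never wraps around the field)
while the orientation axis is genuinely circular with period $\pi$. Lags
whose mask overlap $W\!\star\!W$ falls below $10^{-3}$ of the ROI size carry
too little support and are flagged invalid rather than zero-filled. The
radial reduction $c(r, \Delta\phi)$ averages valid lags over annuli one bin
wide centered on multiples of the bin, so structure at radius $r$ reports in
the annulus labeled $r$.

### The anisotropic Ripley's K statistic

The co-orientation strength within a distance $R$ is summarized by

$$K_\parallel(R) = \frac{1}{\pi R^2}\,\frac{2}{\pi}
  \int_{|\Delta\vec x|\le R}\int_{-\pi/2}^{\pi/2}
  c(\Delta\vec x,\Delta\phi)\cos(2\Delta\phi)\,
  d^2\Delta x\, d\Delta\phi.$$

The $\cos(2\Delta\phi)$ weight extracts the second Fourier coefficient of
$c$ in the orientation difference: the first-order tendency of filaments to
be *aligned* (positive) or *perpendicular* (negative) when they are near
each other, with any orientation-independent (pure co-localization) part
integrating to exactly zero. The prefactor is fixed by the calibration that
a unit-amplitude modulation $c = 1 + \cos(2\Delta\phi)$ over the disc gives
$K_\parallel = 1$; in the discrete sums, $\pi R^2$ is realized as the summed
area of the included lag pixels, which makes that calibration exact on the
grid rather than only in the continuum limit. Absolute $K$ values reported
by any implementation depend on this prefactor convention, so comparisons
should always use a single convention throughout. A $\cos^2(\Delta\phi) =
(1+\cos 2\Delta\phi)/2$ weight is also available; it additionally retains
the co-localization term (it does *not* vanish for constant $c$), which is
useful for display but conflates proximity with alignment.

### Significance: the rotation null

Under the null hypothesis that the two channels are independent,
$E[K_\parallel] = 0$, but its variance is analytically intractable - the
localizations are heavily dependent (many per fluorophore, many per
filament). The package therefore estimates the null variance from the data:
channel 2's *localization coordinates* are rotated about the center of a
circular ROI over $n_\theta$ equally spaced angles $\theta_j = 2\pi
j/n_\theta$ (default 49), re-binned and re-filtered (so the orientation
content rotates consistently with the data - a shortcut that only shifts the
$\phi$ axis would not land on the orientation grid), and $K_\parallel(R;
\theta)$ is recomputed for each rotation. The ROI must be circular so the
channel sums are rotation-invariant. The variance estimate is

$$\sigma_K^2 = \Big(\frac{1}{n_\theta}\sum_\theta K(R;\theta)\Big)^2
  + \frac{1}{2 n_\theta}\sum_\theta \big(K(R;\theta)-K(R;-\theta)\big)^2,$$

with $K(R;-\theta)$ read off the same grid, and the one-sided p-value is the
upper Gaussian tail $p = \tfrac12\,\mathrm{erfc}\big(K/(\sigma_K\sqrt
2)\big)$, i.e. small for large positive $K$ - the direction in which the
test must reject. Whether the $\theta = 0$ term belongs in the sums is not
determined by the estimator's derivation; the default includes it (the
formula as stated), and `estimateSigma(..., includeZero = FALSE)` drops it
for users worried about contamination when a real signal is present (the
estimate is in any case only meaningful under the null). The estimator
carries a relative error of order tens of percent, which makes the test
mildly anticonservative near 0.05; a stricter reporting threshold (0.01) is
the package default in summaries.

Internally each rotation costs one binning, one orientation filtering and an
inner product: because $K$ is a linear functional of the masked channel-2
stack, the fixed channel-1 side, the disc geometry, the angular weight and
the per-lag overlap normalization are folded into a single precomputed
kernel by one 3D convolution. This is algebraically identical to running the
full cross-correlation per rotation (the test suite verifies the identity to
$10^{-8}$), just cheaper.

### Local co-orientation maps

To see *where* in an image co-orientation lives, $K_\parallel(R)$ is
evaluated in square subregions of side $3R$ displaced by multiples of $R$
(two-thirds overlap between neighbors), always with the *global* channel
means in the denominator so values are comparable across subregions. Only
fully interior subregions are evaluated; values are assigned to subregion
centers and bilinearly interpolated to full resolution, with the border
strip clamped to the nearest center. The overlay rendering puts the two data
channels in red and green and the map in blue, with negative map values set
to zero, the brightest 3% of pixels clipped and the rest scaled linearly. A
faster approximate map replaces the per-subregion correlation by
convolutions: $\tilde I_1$ is convolved with $\cos(2\Delta\phi)\,O(\vec
x/R)$ (disc kernel $O$), multiplied by $\tilde I_2$, summed over $\phi$ and
smoothed with a normalized disc $O(\vec x/3R)$; its scale constant
$2\Delta\phi^2/(N_R \langle I_1\rangle\langle I_2\rangle)$ follows in closed
form from the exact map's formula when the per-lag overlap correction is
replaced by a constant. Because the smoothing geometry differs (disc of
radius $3R$ versus square subregions of side $3R$), the fast map is treated
as a *rank-level* approximation; the suite enforces a Spearman correlation
bound against the exact map frozen from a reference calibration.

## The synthetic-data generator

Validation uses a generative model of two-channel filament SMLM data whose
defaults are the package's study conditions:

* **Filaments.** 2D wormlike chains (Kratky-Porod) of $10^4$ segments of
  1 nm; per-step turn angles are $N(0, \sqrt{\ell/\xi})$ for segment length
  $\ell$ and persistence length $\xi$ - the discretization whose tangent
  correlations decay as $e^{-s/2\xi}$ in 2D. Chains grow symmetrically from
  a central segment whose midpoint is uniform in a disc of radius
  $\mathrm{FOV}/\sqrt2 + L/2$ about the field center (the circumradius of
  the square field plus half the contour length - the smallest disc that
  guarantees homogeneous, isotropic coverage) and whose orientation is
  uniform in $(-\pi,\pi]$.
* **Channel 2** is derived per filament: displaced a fixed distance $d$
  along the local normal (`parallel`); displaced by $d_{\max}\sin(2\pi
  s/\mathrm{period} + \varphi_0)$ with contour distance $s$ and a random
  phase per filament (`twisted`); or simulated afresh with its own $\xi$
  (`independent`).
* **Labeling.** Filament vertices are rendered to a 5 nm density image,
  blurred with a 5 nm FWHM Gaussian (finite filament width); a Poisson
  number of fluorophores is sampled proportional to that density and
  jittered by a 5 nm FWHM Gaussian (antibody linker).
* **Blinking and precision.** Each fluorophore is localized
  $M = \min(M_{\mathrm{Pois}(25)}, M_{\mathrm{Geom}(11)})$ times (geometric
  on $\{1,2,\dots\}$, so the mean is exactly 11; a fluorophore can draw
  $M_{\mathrm{Pois}} = 0$ and never be seen). Each localization draws
  photons $n_{ph} \sim$ Geometric with mean 2000 on $\{1,2,\dots\}$,
  background $b$ as the mean of $9\times9$ Poisson(1) pixels and a PSF
  width $\sigma_a \sim N(1.38, 2\%)$ camera pixels (100 nm pixels). The
  localization precision is the maximum-likelihood expression for a
  pixelated Gaussian PSF without excess noise,
  $$\sigma^2 = \frac{\sigma_a'^2}{n_{ph}}\Big(\frac{16}{9} +
    \frac{8\pi \sigma_a'^2 b}{n_{ph} a^2}\Big),\qquad
    \sigma_a'^2 = \sigma_a^2 a^2 + a^2/12,$$
  and the recorded position is the fluorophore position plus $N(0,\sigma)$
  per axis. Blink trains occupy consecutive frames from a random start, so
  the frame-based grouping rule is exercisable on simulated data.

What the generator does *not* emulate: detailed on/off photokinetics and
multiple blink trains per fluorophore, camera-frame image formation (spot
fitting is upstream of this package), drift, chromatic aberration beyond
what the affine registration module corrects, and autofluorescent
background structure. Passing the suite therefore demonstrates correctness
of the *analysis* given the coordinate-based data model, and realistic
sensitivity under idealized labeling; on real data, localization error
additionally blurs and shifts the co-orientation peak and lowers its
magnitude, and background lowers contrast.

## Numerical choices

* FFT grids are padded to sizes with only small prime factors; images are
  zero-padded by $\max(3 s_o, 3/w_q)$ before filtering to suppress kernel
  wrap-around, and by the maximal lag before correlation (linear spatial
  correlation); the orientation axis is exactly circular.
* The orientation grid is $\phi_k = -\pi/2 + k\pi/n_o$, spanning
  $[-\pi/2,\pi/2)$; everything downstream treats orientation as
  $\pi$-periodic.
* The isotropic-pixel fallback triggers when the normalization denominator
  is below $10^{-9}$ of its scale.
* Disc membership (for $K$ and the kernels) is by pixel-center radius -
  simple and unbiased at 10 nm bins.
* Degenerate significance cases: $\sigma_K^2 = 0$ yields $p \in \{0, 0.5,
  1\}$ by the sign of $K$, with a warning.
* Radial annuli are centered on multiples of the lag spacing. One practical
  consequence, visible in the parallel-companion simulation: for two
  parallel curves a fixed distance $d$ apart, the radial profile of the
  correlation does not peak exactly at $r = d$ but slightly above it - the
  annulus at $r$ crosses the companion ridge at an angle, and localization
  error, label jitter and pixelation push the maximum a few nanometres
  outward - so at 10 nm resolution the peak annulus for $d = 50$ nm is the
  50 nm or the 60 nm one.

## Problem sizes used in validation

The test suite runs on one CPU within minutes by scaling the study designs
while keeping their structure: the independence baseline uses the full
$4\,\mu$m/$10^4$-point design over 20 seeds; the parallel-companion
reproduction runs at half field size (100 filaments, $2\,\mu$m, 5000
fluorophores) for the in-suite check, and full size in
`scripts/acceptance.R`; the twisted-companion reproduction runs at full
size; the null-calibration study runs 50 replicates of a reduced design (50
independent filaments per channel, $2\,\mu$m field, 2500 fluorophores per
channel, $n_\theta = 25$, $n_o = 21$) - the same generative recipe as the
full 500-replicate design, scaled for a desk run, with the p-value
uniformity, the fraction below 0.05, the normality of $K$ and the
$\sigma_K$ accuracy band all asserted on that batch.

## Known limitations

* Strong co-localization *without* orientational alignment violates the
  rotation-invariance assumption of the null model; p-values are then
  unreliable (use the `cossq` map to recognize the situation).
* $\sigma_K^2$ is estimated with tens-of-percent relative error, so
  p-values near a threshold should be read conservatively; between-condition
  comparisons should use sets of $K$ values and a rank test
  (e.g. `wilcox.test`), never $\sigma_K$.
* $K_\parallel$ decreases when the density of co-oriented filaments
  increases (the normalization divides by total density), so comparisons
  across samples with very different filament densities need care.
* The analysis is 2D; orientation in 3D stacks is out of scope.

## A worked example

```{r example, eval = FALSE}
library(coorient)
sim <- simulateDataset("parallel", seed = 1, nFilaments = 100L,
                       nFluorophores = 5000, fov = 2000)
ext <- c(0, 2000, 0, 2000)
oa1 <- orientationAnalysis(sim$locs1, binSize = 10, extent = ext, so = 200)
oa2 <- orientationAnalysis(sim$locs2, binSize = 10, extent = ext, so = 200,
                           bank = oa1$bank)
map <- crossCorrelate(oa1$stack, oa2$stack, lagMax = 600)
plotCoorientation(map, rMax = 600)

test <- significanceTest(sim$locs1, sim$locs2,
                         circleROI(c(1000, 1000), 1000), ext,
                         R = 200, nTheta = 49)
test
```
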