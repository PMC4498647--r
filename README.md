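# coorient

Co-orientation analysis for two-color single-molecule localization
microscopy (SMLM).

## What it does, and for whom

Cytoskeletal filament systems (microtubules, actin, intermediate filaments
such as vimentin or keratin) are extended, oriented structures. When two of
them are imaged in different color channels, the interesting question is
rarely just "do the molecules co-localize?" but "do the *filaments* run
close together *and* parallel?" — co-localization plus orientational
alignment, here called **co-orientation**. `coorient` is for microscopists
and image analysts working with coordinate-based SMLM data (localization
tables with per-point precision) who want a quantitative, calibrated answer
to that question.

The analysis core:

1. **Orientation space.** Each channel's localizations are binned to a
   10 nm histogram image and filtered with a bank of scale- and
   orientation-selective Fourier filters (orientation scale `s_o`, `n_o =
   41` orientations, angular bandwidth `w_phi = pi/n_o`, radial bandwidth
   `w_q = 0.8/s_o`). The normalized response `Ĩ_l(x, phi)` is the expected
   density of localizations at `x` on structures of orientation `phi`.
2. **Generalized cross-correlation.** The channels are cross-correlated
   over spatial lag and orientation difference,
   `c(Δx, Δphi) = pi * <Ĩ1(x, phi) Ĩ2(x+Δx, phi+Δphi)> / (<I1><I2>)`,
   normalized so that independent channels give `c = 1`. Its radial
   reduction `c(r, Δphi)` is the *co-orientation plot*.
3. **Anisotropic Ripley's K.** `K∥(R) = (1/(πR²))(2/π) ∫∫ c(Δx, Δphi)
   cos(2Δphi) d²Δx dΔphi` summarizes co-orientation within distance `R`:
   zero under independence, positive for nearby aligned filaments,
   negative for perpendicular crossings.
4. **Rotation-null significance.** Channel 2 is rotated about a circular
   ROI's center over `n_theta = 49` angles and K recomputed, yielding a
   variance estimate
   `σ_K² = (mean_θ K)² + (1/(2 n_θ)) Σ_θ (K(θ) − K(−θ))²` and the
   one-sided p-value `p = erfc(K/(σ_K √2))/2`.
5. **Local maps.** K evaluated in overlapping `3R` subregions, rendered as
   a blue overlay on the two-channel image; plus a fast convolutional
   approximation.
6. **Simulator.** Two-channel wormlike-chain filament data with a full
   SMLM localization model (blinking, photon statistics,
   maximum-likelihood localization precision) and known ground truth —
   parallel companions, independent channels, or twisted companions.

Utilities: localization CSV I/O, blink-event grouping (3×(σi+σj)
consecutive-frame rule), affine two-channel registration with
leave-one-recording-out target registration error, a YAML-configured
pipeline (`runPipeline()`), and a CLI front end
(`inst/scripts/cofilament.R`).

## Worked example

```r
library(coorient)

# simulate: 100 filaments (xi = 5 um) in a 2 um field, each with a
# companion filament 50 nm away in the other channel
sim <- simulateDataset("parallel", seed = 1, nFilaments = 100L,
                       nFluorophores = 5000, fov = 2000)
ext <- c(0, 2000, 0, 2000)

oa1 <- orientationAnalysis(sim$locs1, binSize = 10, extent = ext, so = 200)
oa2 <- orientationAnalysis(sim$locs2, binSize = 10, extent = ext, so = 200,
                           bank = oa1$bank)
map <- crossCorrelate(oa1$stack, oa2$stack, lagMax = 600)
prof <- radialProfile(map)
pk <- which(prof$profile == max(prof$profile, na.rm = TRUE), arr.ind = TRUE)
c(r = prof$r[pk[1]], dphi_deg = prof$dphi[pk[2]] * 180 / pi)
#>        r dphi_deg
#>       60        0

test <- significanceTest(sim$locs1, sim$locs2,
                         circleROI(c(1000, 1000), 1000), ext,
                         R = 200, nTheta = 49)
test
#> NullProfile: K(R = 200 nm) = 0.209813 over 49 rotations
#>   sigma_K = 0.0413974, one-sided p = 2.007e-07
```

The co-orientation plot peaks at the companion distance with zero
orientation difference, and the rotation-null test reports the
co-orientation as strongly significant; an `"independent"` preset dataset
instead gives `c ≈ 1` everywhere, `K ≈ 0`, and a uniform p-value. (Exact
numbers above are from the stated seed; different seeds vary within
sampling error. The peak annulus for a 50 nm offset reports at 50 or
60 nm — the radial estimator sits a few nanometres above the true offset
because the annulus crosses the companion ridge at an angle and
localization error pushes the maximum outward; see the methods vignette.)

Between-condition comparisons (e.g. two cell types) should compare *sets*
of K values with a rank test such as `wilcox.test`; `σ_K` is a null-model
quantity and is not valid for that purpose.

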