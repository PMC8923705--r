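---
title: "Measurement-driven optical fluence normalization for 3D breast optoacoustic tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-driven optical fluence normalization for 3D breast optoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A reconstructed 3D optoacoustic tomography (OAT) volume estimates the
initial pressure `p0 = Gamma * mu_a * phi`: the product of the tissue's
optical absorption `mu_a` and the optical fluence `phi` that reached it
(`Gamma`, the Grueneisen coefficient, is treated as a constant absorbed into
units). In breast imaging the fluence is far from uniform. Two effects
dominate:

1. **Nonuniform incident fluence.** Illumination is delivered in a radially
   symmetric pattern, so the fluence arriving at the breast surface varies
   with the polar angle `theta` (measured from the upward z axis through the
   cup centre; the chest wall sits at 90 degrees, the nipple pole at 180).
   Regions near the chest wall receive less light and appear dim.
2. **Depth-dependent attenuation.** Inside tissue the fluence decays
   approximately as Beer-Lambert, `phi(d) = phi0 * exp(-mu_eff * d)`, with
   `d` the depth below the breast surface and `mu_eff` an effective
   attenuation coefficient around 1 cm^-1 in breast — and, crucially,
   wavelength-dependent ("spectral coloring").

Spectral linear unmixing treats per-wavelength `p0` volumes as surrogates of
`mu_a` and solves, per voxel, for deoxy- and oxyhemoglobin concentrations
through the pseudoinverse of the molar extinction matrix. Any
wavelength-*independent* gain cancels in the oxygen-saturation ratio
`sO2 = C_HbO2 / (C_Hb + C_HbO2)`, but the wavelength-*dependent* decay does
not: uncorrected, it biases sO2 increasingly with depth. The package
implements a measurement-data-driven normalization that estimates both
effects from the image itself and divides them out, then unmixes, detects
vessels, and scores the result.

## The normalization pipeline

The pipeline runs in a fixed order, because the surface cannot be found
reliably before the incident fluence is evened out:

1. **Incident-fluence compensation** (`angular_mvbp()`,
   `fit_incident_profile()`, `compensate_incident()`). Subdermal blood
   vessels are assumed present at every polar angle and to absorb far more
   than other tissue, so the brightest voxel in each 1-degree polar bin
   traces the incident fluence profile. A degree-L polynomial (L = 1 or 2
   in practice) is fitted over 90-160 degrees — the nipple/areola cone
   above 160 degrees is excluded because pigment violates the
   vessels-are-brightest assumption — normalised to peak 1, floored at 0.05
   of peak, and divided out with angles clamped to the fit range. The floor
   and clamp are this package's guards: the fitted polynomial may approach
   zero or go negative outside its support, and the division must stay
   finite.
2. **Surface and depth estimation** (`estimate_surface()`). The compensated
   volume is median-filtered (3x3x3, a true volumetric filter) and squared,
   Otsu-thresholded to extract bright subdermal vessel voxels, and each
   z-slice's maximum cylindrical radius is recorded. A rotationally
   symmetric spheroid `(z - zc)^2/a^2 + rho^2/b^2 = 1` is fitted to those
   radii by algebraic least squares (plain nonlinear least squares on the
   algebraic residual; a geometric point-to-curve fit would need an inner
   root-find and adds nothing at these noise levels). The spheroid yields
   the breast mask and a per-voxel depth map.
3. **Attenuation compensation** (`depth_binned_max()`,
   `fit_beer_lambert()`, `compensate_attenuation()`). The maximum in-mask
   brightness per one-voxel-wide depth bin traces the decay;
   `c * exp(-mu_eff * d)` is fitted by nonlinear least squares (log-linear
   initialisation, `mu_eff >= 0`), and each in-mask voxel is divided by the
   decay normalised to 1 at the surface. Out-of-mask voxels are set to
   exactly 0.

For multiwavelength data the surface is estimated once, from the first
wavelength's compensated volume (the breast is held static by the
stabilizer cup), while the incident profile and the attenuation fit are per
wavelength — `mu_eff` is wavelength-dependent by design; removing that
dependence is what mitigates spectral coloring.

### Numerical choices

* **Point-to-spheroid depth.** Rotational symmetry reduces depth to
  point-to-ellipse distance in the (rho, z) half-plane. The ellipse's mirror
  symmetries fold any query into the first quadrant with ordered semi-axes,
  where the stationarity condition of the squared distance becomes a single
  strictly decreasing root function with a closed-form bracket. We run
  Newton's method on that root function, safeguarded by the bracket
  (bisection step whenever Newton would leave it), with closed forms on the
  axes, including the inside-the-evolute case where the nearest surface
  point is off-axis. An earlier formulation — Newton on the surface angle
  initialised along the ray from the centre — was rejected because it can
  converge to the wrong stationary branch for eccentric spheroids; the
  property test against a dense-sampling oracle caught exactly that.
* **Otsu threshold.** 256 uniform bins over the value range; between-class
  variance maximised over all cuts. When well-separated classes leave an
  empty gap in the histogram, every cut in the gap ties; the threshold takes
  the middle of the maximal plateau.
* **Beer-Lambert fit window.** Bins deeper than 30 mm are excluded by
  default (`fit_depth_range_mm`). At depth the per-bin maximum is the upper
  tail of amplified noise rather than vessel signal; including those bins
  flattens the fitted decay. This is also why the recovered `mu_eff` runs a
  few percent low on noisy phantoms: the noise floor props up the deepest
  bins that remain in the window.
* **Gain cap.** The attenuation divisor is floored at its value at 35 mm
  (`depth_cap_mm`), bounding noise amplification at depth.
* **Frangi vesselness.** No parameters are published for the motivating
  study; we use the filter's canonical defaults (alpha = beta = 0.5) with
  the structureness cutoff set per scale to half the maximum Hessian
  Frobenius norm, which makes the response invariant to global intensity
  rescaling. A tube of width `w` voxels responds maximally near
  `sigma = w/2`, hence the width-to-scale mapping; default widths 1-5
  voxels.
* **CLAHE baseline.** Tile grid 8x8x4, clip limit 0.01 of the tile voxel
  count, 256 bins, trilinear interpolation of tile mappings. The published
  comparison gives no CLAHE parameters, so ours are recorded in every
  report; the baseline's role is directional, not numeric.
* **PSNR/SSIM between different units.** Comparing a brightness estimate
  with a true absorption map has no shared scale; both volumes are
  independently min-max rescaled to [0, 255] and compared with MAX = 255
  (Gaussian SSIM window, sigma 1.5, 11^3 support). The rescale convention
  is a package convention, recorded in the report.

## The synthetic phantom

`generate_phantom()` builds the study conditions end to end: a
hemispherical breast of radius 60 mm (z < 0) with a 1.5 mm skin shell and a
glandular core; a subdermal vessel net constructed as a spherical spiral at
mid-shell depth so that *every* 1-degree polar bin in [90, 160] contains a
vessel voxel within the 0.5-3 mm subdermal shell (the assumption the
incident-fluence estimate rests on, and auditable via
`audit_subdermal_coverage()`); and random piecewise-linear deep vessel
segments with radii of 1-5 voxels labelled artery or vein. Arteries carry
97% oxygenation and veins 70%, so the classification threshold — the
arithmetic mean — is 83.5%. Vessel absorption at each wavelength is derived
from the bundled hemoglobin extinction table at those saturations and a
whole-blood hemoglobin concentration, making the phantom exactly consistent
with the unmixing model; background tissues get small configured
absorptions. The subdermal net is uniformly venous: anatomically the
subdermal plexus visible in breast OAT is predominantly venous, and a
spectrally mixed net would make the per-angle maximum alternate between
tissues of different spectra, which the method's vessels-are-alike
assumption excludes.

The fluence is analytic: `phi = g(theta) * exp(-mu_eff(lambda) * d)` with a
quadratic `g` weakest at the chest wall and peaking near 160 degrees, and
`mu_eff` of 1.1 / 1.0 / 0.9 cm^-1 at 757 / 800 / 850 nm — the ~1 cm^-1
scale measured in vivo, with mild wavelength dependence to produce
coloring. `p0 = mu_a * phi` plus Gaussian noise with standard deviation 1%
of the maximum signal. The phantom deliberately realises the model class
the method assumes (radially symmetric illumination, single-exponential
depth decay, additive noise): Monte-Carlo photon transport, acoustic
propagation and reconstruction artifacts are out of scope, so passing
tests demonstrate correctness of the normalization given its assumptions,
not robustness to reconstruction physics.

Problem sizes used by the checks: unit tests run 2 mm phantoms; the
task-metric and surface-recovery checks run the 1 mm fixture; attenuation
recovery and the coloring-isolation check run at the native 0.5 mm voxel
size (240^3 grid). These sizes were chosen so each property is measured at
the coarsest resolution at which it is meaningful.

## What the evaluation computes

`run_functional()` unmixes, masks sO2 where total hemoglobin falls below a
robust floor, enhances the total-hemoglobin map with multiscale Frangi
filtering, detects vessels by Otsu within the breast mask, classifies
detected voxels at 83.5%, and — when ground truth is supplied — reports:
detectability DET (fraction of true vessel voxels detected);
known-structure classification rates TAR/TVR/ACC (every true vessel voxel
scored on its sO2 class); detection-classification rates DTAR/DTVR/DACC
(only detected-and-correct voxels count); and the same indices in five
10-mm depth bins. On the fixture phantom the three processing arms order
as expected: no normalization < CLAHE < fluence normalization for both DET
and DACC.

## Known limitations

* A single global `mu_eff` per wavelength; spatial variation of optical
  properties biases the compensation (the same limitation the underlying
  method has).
* Axisymmetric surfaces only; the spheroid model cannot follow a breast
  that the cup does not keep rotationally symmetric.
* Compensation amplifies noise and artifacts along with signal at depth;
  the gain cap bounds but does not remove this.
* Concentrations are in arbitrary units unless inputs are calibrated
  absorption maps; sO2, a ratio, is the interpretable output.
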