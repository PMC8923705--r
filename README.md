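# oatnorm

Measurement-data-driven normalization of the optical fluence distribution
in reconstructed 3D optoacoustic tomography (OAT / photoacoustic CT)
volumes of the breast, and the functional analysis that depends on it.

## The problem

A reconstructed OAT volume estimates the initial pressure
`p0 = Γ · μa · φ`. The absorption `μa` is the quantity of interest, but the
optical fluence `φ` is strongly nonuniform: the radially symmetric
illumination deposits less light near the chest wall (a polar-angle effect)
and the fluence decays with depth as Beer–Lambert,
`φ(d, λ) = φ0 · exp(−μeff(λ) · d)`, with `μeff ≈ 1 cm⁻¹` in breast and
wavelength-dependent. Direct spectral unmixing of multiwavelength `p0`
volumes into deoxy-/oxyhemoglobin (via the pseudoinverse of the extinction
matrix) therefore misestimates oxygen saturation
`sO2 = C_HbO2/(C_Hb + C_HbO2) × 100%` — the "spectral coloring" effect —
and buries deep vessels below the detection threshold.

`oatnorm` estimates both effects **from the image itself**, with no prior
knowledge of tissue optics or the illumination system:

1. the incident profile from the per-polar-angle maximum voxel brightness
   of subdermal vessels (polynomial fit over 90°–160°, divided out);
2. the breast surface as a rotationally symmetric spheroid
   `(z−z_C)²/a² + ρ²/b² = 1` fitted to per-slice maximal vessel radii
   (median filter → square → Otsu), giving a mask and per-voxel depth;
3. the depth decay `c·exp(−μeff·d)` fitted to depth-binned maximum vessel
   brightness, divided out per wavelength.

It also provides spectral unmixing and sO2 maps, 3D multiscale Frangi
vessel enhancement with Otsu detection, artery/vein classification at the
83.5% threshold (the mean of arterial 97% and venous 70% oxygenation), a
3D CLAHE contrast baseline, physical (PSNR/SSIM) and task-based
(DET, TAR/TVR/ACC, DTAR/DTVR/DACC, 10-mm depth-binned) image-quality
metrics, and a hemispherical numerical breast phantom with full ground
truth for validation.

## Worked example

```r
library(oatnorm)

# a 60 mm hemispherical breast phantom at 1 mm voxels, three wavelengths
spec <- phantom_spec(voxel_size_mm = 1, seed = 11)
gt   <- generate_phantom(spec)

# normalization: incident profile, surface + depth, Beer-Lambert, per λ
norm <- run_normalize(gt$p0, oat_config())
unlist(norm$surface$model)
#>      a_mm      b_mm     zc_mm
#> 61.256507 59.509481  1.649333     (truth: 60, 60, 0)
sapply(norm$attenuation, mu_eff_cm)
#>      757      800      850
#> 1.012954 0.891474 0.799894        (truth: 1.1, 1.0, 0.9 cm^-1)

# unmix, detect on total hemoglobin, classify at 83.5%, score vs truth
ext <- hb_extinction(spec$wavelengths_nm)
fun <- run_functional(norm$normalized, ext, oat_config(),
                      mask = norm$surface$mask, truth = gt)
fun$metrics$det; fun$metrics$dacc
#> [1] 64.42
#> [1] 61.28
```

The surface comes back within a voxel or two of truth, the recovered
effective attenuation sits at the in-vivo ~1 cm⁻¹ scale a few percent low
(the noise floor props up the deepest depth bins), and detectability more
than doubles relative to running the same detection on the raw volumes
(DET 26.6 → 64.4 on this fixture; CLAHE reaches 32.7).

A thin command-line wrapper for shell use lives at
`inst/cli/oatnorm-cli.R` (`simulate`, `normalize`, `unmix` subcommands;
NIfTI in/out).

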