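---
title: "Calibrating intraoperative hyperspectral imaging setups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating intraoperative hyperspectral imaging setups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsical)
```

## The problem

Hyperspectral imaging records a reflectance spectrum in every pixel, and in
surgery that spectrum carries diagnostic information: oxygenated and
deoxygenated blood, nerve, gland, muscle and connective tissue differ in
their optical behaviour across the visible and near-infrared range. Two very
different instruments can acquire such data intraoperatively. A *filter-wheel
microscope* selects the wavelength on the illumination side: a xenon source
is filtered into 19 narrow bands (400–700 nm in 20 nm steps at FWHM 10 nm,
plus 750/800/850 nm at FWHM 25 nm) and a panchromatic sensor captures one
frame per band. A *snapshot-camera rig* selects the wavelength on the sensor
side: multispectral filter arrays with a 4×4 (16 bands, 463–638 nm) or 5×5
(25 bands, 693–966 nm) periodic mosaic capture all bands in one exposure at
reduced spatial resolution. Raw counts from either system mix the quantity
of interest — tissue reflectance — with lens vignetting, dark current,
filter-response overlap, exposure and illumination differences, and
instrument-specific scale shifts. The calibration chain in this package
removes those effects so that data from both setups land on the same
physical scale.

## The chain, step by step

**(a) Flat-field.** Lens vignetting and aperture falloff are corrected by a
band-specific multiplicative gain `I_ref / I_meas`, where `I_ref` is the
band's mean intensity in a ±10-pixel window at the sensor center and
`I_meas` is a dark-subtracted frame of a spatially uniform target (the white
calibration board). The gain is estimated once (`estimate_flat_field()`) and
applied to dark-subtracted counts (`apply_flat_field()`). Applying a
multiplicative gain *before* dark subtraction would inject a
`dark · (1/v − 1)` bias toward the corners, so the package subtracts the
dark mean first; `to_reflectance()` accepts `dark = NULL` for cubes marked
as already dark-subtracted.

**(b, c) Denoising and conversion to reflectance.** The dark-frame series is
temporally averaged (`average_dark()`); its per-pixel SD is the noise scale
in `SNR = A_signal / σ_noise` (`compute_snr()`, per band via the spatial
median — the spatial reduction is our choice, the definition leaves it
open). The one-point white calibration is implemented literally:

```
I_res = (I_raw − I_dark|ε_raw) / (I_white − I_dark|ε_white) · (ε_white / ε_raw)
```

Note that the formula normalizes against the white *board*, whose true
reflectance is 0.95, not 1.0; the literal form therefore over-estimates
reflectance by 1/0.95. We reproduce the literal formula by default (the
residual factor is absorbed by step (f), which is exactly what the scalar
correction exists for) and expose `apply_board_reflectance = TRUE` as the
physically strict option. Negative values (noise below dark) are kept and
flagged rather than clipped — clipping would bias tile means upward. Pixels
with a non-positive white denominator are masked `NA`.

**(d) Spectral correction (snapshot path only).** A mosaic pixel's band
response is not an ideal narrow filter: responses overlap, and some bands of
the NIR camera show a secondary response peak ~150 nm below the primary. The
correction matrix `C` applied as `I_cor = I_res · C` is fitted by
Tikhonov-regularized least squares mapping the measured response curves to
ideal unit-area Gaussian targets at the tabulated centers/FWHMs. Two
numerical choices matter:

* The fit is performed on responses *projected onto a basis of smooth
  spectra* (Gaussians of σ = 15 nm spaced every 10 nm) rather than
  pointwise in wavelength. Narrow neighboring bands cannot reproduce a
  wider secondary lobe sample-by-sample, but they can reproduce its action
  on any smooth spectrum, which is the quantity that matters; the
  basis-projected fit suppresses monochromatic secondary-peak contamination
  to a few percent where the pointwise fit leaves ~45 %.
* Because `C` acts on white-normalized reflectance — where a spectrally flat
  scene reads 1.0 in every band — responses and targets are row-normalized
  to unit sum (optionally weighted by the illumination spectrum) and the
  columns of `C` are rescaled so a flat input maps to a flat output. Any
  residual global scale is absorbed by α in step (f).

The default ridge (1e-4, relative to the mean Gram diagonal) is flat over a
wide range on noiseless responses and stabilizes the solution when the
manufacturer curves are noisy. `ridge = 0` requests the exact
normal-equation solution and fails with advice when the band-overlap Gram
matrix is singular.

**(e) Registration and assembly.** Alignment uses integer translation with
normalized cross-correlation as cost, searched exhaustively over
`(2·max_shift + 1)²` candidates and scored only on the valid overlap (no
zero padding); ties break toward the smallest shift. Sub-pixel, rotational
or perspective alignment is out of scope — the clinical answer to the
two-camera parallax was expert annotation of matching regions, and we keep
that limitation. One design point deviates from the obvious reading of
"register every band to a common reference": NCC between spectrally distant
bands is unreliable, because scene content decorrelates across wavelength
(we observed systematic misregistration between, e.g., a 531 nm and a
900 nm chart rendering). `assemble_hypercube()` therefore estimates one
rigid shift per cube, anchored on the *spectrally closest* pair of bands
between the cubes, and offers `per_band = TRUE` for sequentially acquired
stacks whose frames may drift individually. The merged hypercube holds
16 + 25 = 41 bands sorted by center wavelength with per-band source tags.

**(f) Intensity correction.** Residual systematic scale shifts —
underexposure from frame-rate constraints, working-distance differences,
the 0.95 board factor — are absorbed by one scalar per setup,
`I_final = α · I_res`. α is fitted by least squares through the origin,
`α = Σ m·r / Σ m²`, pooled over all 24 chart tiles (the single tabulated
scalar per setup implies pooling). Wavelengths above 850 nm are excluded:
there the SNR collapses and the reference SD grows to ~0.11, making the
samples uninformative. The injection-recovery tests show the fit recovers
factors between 1.00 and 2.01 to 1e-6 noiselessly and to 1 % at band
SNR 50.

**Validation.** `validate_against_chart()` compares per-tile spatial mean
spectra at the band centers with the chart resampled to those centers,
reporting the difference `d`, a within-SD flag (reference SD plus measured
spatial SD), and RMSE split at 680 and 850 nm — the wavelengths where
reference uncertainty and SNR change regime.

## The synthetic world

`scene_simulator` replays the physical acquisition in silico so every stage
has ground truth. What it emulates, and the defaults chosen where the
instruments' descriptions leave gaps:

* **Reference chart** (`make_reference_chart()`): 18 colored tiles as random
  smooth mixtures of 2–4 Gaussian bumps scaled into [0.03, 0.95]; 6 gray
  tiles at the classic neutral levels 0.90/0.59/0.36/0.19/0.09/0.03
  (seed-independent); an SD envelope rising smoothly from 0.002 in the
  visible to 0.11 in the NIR. Tile-by-tile SDs of the real chart are not
  published, so a single envelope stands in for them.
* **Illumination**: xenon = flat from 400 nm with narrow peaks between 810
  and 845 nm; surgical LED = 460 nm peak, 525–680 nm plateau, rapid decay
  above 680 nm, scaled ×130 relative to xenon because the LED's much higher
  flux is what forces the ~100× shorter tabulated exposures. Both clip below
  400 nm (UV avoidance).
* **Sensor responses**: Gaussian primaries at the tabulated center/FWHM;
  peak heights 0.2 for the 16-band camera (one band at 0.1 — we place the
  documented low band at sorted index 3, 489 nm, since the vendor's band
  numeration is not the sorted order), 0.1 for the 25-band camera; by
  default two NIR bands (900, 940 nm) carry a secondary peak at −150 nm,
  30 % of the primary.
* **References**: the dark series is 20 frames by default; the white board
  is rendered 20 times and averaged — the board is uniform and static, and
  without temporal averaging the near-zero white denominator of the LED/NIR
  configuration turns the reflectance conversion into a heavy-tailed ratio
  (we observed the α fit attenuated to ~0.7 from single-frame whites).
  Chart tiles span 8 × 8 pixels at cube resolution; real tiles span
  thousands, so desk-scale region means are noisier than the instrument's.
* **Noise and optics**: radial quartic vignetting (strength 0.2 — any smooth
  radial model suffices since step (a) corrects it empirically), 12-bit full
  well (4095), dark offset 100 counts, Gaussian read noise SD 2, optional
  Poisson shot noise, saturation clipping. The sensor gain (3 counts per
  ms·radiance·nm) is set once so the brightest band at the tabulated optimal
  exposures (42/65/0.5/110/7.5 ms) sits near but below full well — the same
  rule the real exposure tables encode.

What the simulator does *not* model: optical blur, chromatic aberration,
thermal drift and scattered light (explicitly outside the calibration's
scope), and any real tissue optics. A green end-to-end test therefore
establishes that the chain inverts its own forward model exactly where that
model holds — not that a real camera meets the same numbers.

## Visualization choices

RGB rendering samples the CIE 1931 2° color matching functions at the band
centers (bands are ≤ 25 nm FWHM, narrow relative to the CMFs) with
trapezoid weights over the uneven band spacing and an equal-energy
illuminant — the cube is already reflectance, so neutral rendering is the
faithful choice. We use the published multi-lobe Gaussian analytic fits of
the CMFs (accurate to ~1 %) because no colour-science library is available,
and white-balance the linear RGB so a unit-reflectance pixel is exactly
neutral before gamma encoding; the clip fraction is reported.

The PCA enhancement evaluates the minor-component reconstruction
`W Σ_{i>m} γ_i A_i` per pixel; the weighted residual spectrum is summed over
bands to a scalar map (the equation produces a spectrum per pixel; a single
channel receives it, so a scalar reduction is required — band summation is
ours) and min-max normalized to [0, 1] before blending into the blue
channel with an exposed `blend` factor. For `m` the package offers an
automatic rule (smallest m explaining ≥ 95 % variance) but the two-tissue
analyses in the tests fix `m = 1`: the synthetic scene has exactly one
dominant common mode (albedo/shading along the base spectrum), and the
variance rule can otherwise swallow the faint contrast component itself.
When the 460–480 nm contrast is 0.05 reflectance at noise SD 0.01, the map
separates the regions with AUROC > 0.95.

## Degenerate inputs and numerical edges

* `resample_curve()` refuses extrapolation; curves must be strictly
  increasing in wavelength with nonnegative values.
* A single dark frame yields SD 0 and is flagged (`sd_degenerate`);
  `compute_snr()` errors on σ = 0 rather than returning infinity.
* Flat-field gains at near-zero pixels are masked, with a warning above 5 %
  masked fraction; the center-window mean gain is renormalized to exactly 1.
* `fit_alpha()` errors when fewer than two usable points survive the cutoff
  or when the fitted scalar is non-positive.
* Registration requires ≥ 16×16 px of overlap at the maximal shift and
  errors on constant images (undefined NCC).
* The cube text container stores doubles at %.17g, so write/read round
  trips are bit-exact.

## Known limitations

Translation-only integer registration; no estimation of sensor responses
from measurements (manufacturer curves are inputs); the measured SNR tables
of the real instruments are not reproducible from a desk (they need the
hardware) and are not attempted; the synthetic chart is a structural
stand-in, not a spectral library of the physical ColorChecker.
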