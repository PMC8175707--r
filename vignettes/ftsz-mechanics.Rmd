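---
title: "Methods: quantifying FtsZ-driven membrane mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying FtsZ-driven membrane mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ftszmech)
```

## The system and the measurement chain

FtsZ, the bacterial tubulin homolog at the core of the cytokinetic Z ring,
self-organizes on membranes into treadmilling vortices and ring-like units.
When membrane-bound FtsZ decorates a soft lipid tube pulled from a deflated
giant unilamellar vesicle (GUV) by an optically trapped bead, the tube is
actively wound into a spring-like helix; GTP hydrolysis compresses the helix
from a relaxed pitch (λ > 3 µm) to λ ≈ 1.6 µm. This package implements the
full quantification chain for such experiments:

1. **kymo** — circular-ROI kymographs of treadmilling vortices and
   tangential-velocity estimation (tens of nm/s);
2. **tubegeom** — tube diameter, membrane tension, arclength, protein
   density and helical pitch from two-channel (protein/lipid) image stacks;
3. **rings** — single-ring brightness and diameter photometry, and
   brightness-based counting of ring units on a tube;
4. **tweezers** — optical-trap calibration (position response, trap
   stiffness from the power spectrum) and oscillation-mode spring constants;
5. **rodmech** — elastic-rod closed forms linking spring constants to
   flexural rigidity and Young's moduli, and the GTPase force estimate;
6. **report** — bimodal pitch statistics, morphology tables, and pipeline
   orchestration;
7. **synthgen** — synthetic generators for every input, with stored ground
   truth.

Raw data of the original experiments are not publicly deposited, so the
synthetic module is first-class: every estimator is validated against
generated inputs whose ground truth is known exactly.

## Models and closed forms

**Membrane tube.** A tube pulled from a vesicle equilibrates at diameter
$d = \sqrt{2\kappa/\sigma}$, with $\kappa$ the lipid bending modulus and
$\sigma$ the membrane tension; `tension_from_diameter()` inverts this to use
the measured diameter as an in-situ tension gauge. With
$\kappa = 20\,k_BT$ and $d = 0.47$ µm, $\sigma \approx 0.74$ pN/µm
($7.4\times10^{-7}$ N/m), a typical deflated-GUV tension.

**Oscillation-mode spring constant.** The stage (and with it the GUV)
oscillates as $x_p(t) = A\sin(2\pi f t)$ with $A = 3$ µm, $f = 1$ Hz, while
the bead is held by a trap of stiffness $k_{trap}$ (74.4 pN/µm at the
operating power; 1.66 V/µm detector response). The QPD record (10 kHz,
60 s) is Fourier transformed; the single-sided amplitude at $f$ is converted
to displacement, then force ($F = k_{trap}\,x_{amp}$), and
$k = F_{amp}/A$. Because trap and tube springs act in series, this estimator
carries a factor $k_{trap}/(k_{trap}+k)$ (≈ 0.988 for $k = 0.9$ pN/µm);
it is **documented, not corrected**, to mirror the assay's own estimator —
the closed-form series value is what the tests assert.

**Trap stiffness.** From an undriven trace, the positional power spectrum is
Lorentzian, $S(f) = D/(2\pi^2(f_c^2+f^2))$, and
$k_{trap} = 2\pi\gamma f_c$ with Stokes drag $\gamma = 6\pi\eta r$
(bead Ø 1.71 µm). At 10 kHz sampling the corner (~735 Hz) is a sizeable
fraction of Nyquist, so the fitted model sums the aliased spectral copies,
and the fit minimizes squared log-residuals (insensitive to the skewed
periodogram noise). A plain unweighted Lorentzian fit is biased high by
5–10% under these conditions; the chosen estimator is within ~1–3%.
`equipartition_stiffness()` ($k = k_BT/\mathrm{var}(x)$) is the independent
cross-check.

**Elastic rod.** $K = l_p\,k_BT$ converts persistence length to flexural
rigidity; with $l_p = 0.39$ µm and $T = 295$ K, $K = 1.59\times10^{-27}$
N m². $K = EI$ with $I = \pi r^4/4$ ($r = 2.5$ nm) gives
$E \approx 51.8$ MPa. For a spring, $E = k\,l_0/S$; treating the lipid
bilayer and the FtsZ monolayer as independent thin shells of ~5 nm wall with
nearly equal $l_0/S$, the modulus ratio should match the stiffness ratio:
$k_{FtsZ}/k_l = 0.59/0.34 = 1.74$ against $E_{FtsZ}/E_l = 51.8/22.9 = 2.26$.
The lipid modulus 22.9 MPa is carried as a given reference constant, not
re-derived from $\kappa$ (the plate-to-modulus conversion is not part of
this package's scope).

**GTPase force estimate.** The pitch difference between active and
hydrolysis-dead filaments (Δλ ≈ 2 µm) at the mean spring constant
(≈ 0.9 pN/µm) and ring density (≈ 1 ring/µm) yields a per-ring force.
`gtpase_force_estimate()` uses Δλ/2 as the effective per-ring displacement
— the unique simple convention that reproduces ≈ 0.9 pN from those working
values; the full-Δλ alternative (1.8 pN) is exposed via `full_delta = TRUE`.
This is a documented reconstruction: the original arithmetic path from the
working values to the printed force is not stated.

## Key tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| temperature | 295 | K | reproduces $K = 1.59\times10^{-27}$ N m² from $l_p = 0.39$ µm to 3 s.f. |
| pixel size | 0.11 | µm | typical 100×/EMCCD spinning-disk sampling; not stated by the source experiments |
| PSF sigma | 0.25 | µm | diffraction-limited confocal blur at ~500–650 nm |
| tube diameter (FWHM) | 0.47 | µm | the assay's mean pulled-tube diameter |
| helix radius | 0.4 | µm | consistent with ~0.5 µm cone cross-sections and sub-µm ring radii |
| drive amplitude / frequency | 3 / 1 | µm / Hz | the oscillation protocol |
| QPD rate / duration | 10⁴ / 60 | Hz / s | the acquisition protocol |
| trap stiffness | 74.4 | pN/µm | operating stiffness at 200 mW |
| Welch segment | 1 | s | resolves f ≥ 1 Hz; ~119 averaged segments in 60 s |
| pitch smoothing | 1 | px | mild anti-shot-noise filter; kernel size not stated upstream |
| peak prominence / separation | 10% of range / 3 px | — | robust defaults; upstream peak picking was manual |
| ridge threshold (kymo) | median + 3 MAD | — | robust to the mostly-empty kymograph background |

## The pitch procedure and its numerical choices

`measure_pitch()` follows the up/center/down recipe: Gaussian-filter the
lipid frame, integrate intensity perpendicular to the (PCA-aligned) tube
axis, normalize the profile to 1, take the profile maximum row as *center*
and the rows where the profile is nearest 0.3 on each flank as *up*/*down*
(sub-pixel, linear interpolation between the bracketing pixels). Axial
profiles at the three rows are peak-detected; pitch values are successive
peak spacings, reported per trace and pooled into a mean.

One geometric subtlety is handled explicitly: when the perpendicular
profile peaks on the helix axis, the *center* trace crosses the axis twice
per turn, so its raw spacing is λ/2. A center trace whose median spacing is
below 0.65 of the flank-trace reference is therefore doubled
(`center_doubled` flag); center spacings still inconsistent with the flank
reference afterwards (outside 0.7–1.4 × reference) are dropped
(`center_dropped` count). These flags replace the manual per-experiment
inspection of the original workflow. The flank traces anchor the reference
because they cannot, geometrically, be crossing traces.

"Half-width of the Gaussian" for the tube diameter is read as **full width
at half maximum** ($2\sqrt{2\ln 2}\,\sigma$): it reproduces sub-µm
diameters for optically imaged tubes, and the HWHM alternative would halve
every diameter. The fit quality flag (`fit_rsq < 0.8`) marks unusable
profiles rather than failing.

## What the synthetic world does and does not emulate

The helix generator renders the 2-d projection of a 3-d helical tube:
photons are deposited uniformly per unit of 3-d arclength, so turning
points are brighter than crossings, as in real projections; the tube
cross-section is an isotropic Gaussian (FWHM = nominal diameter) convolved
with the PSF; Poisson shot noise is applied. The vortex generator rotates
Gaussian spots on a circle; the ring generator draws annular Gaussian rims
with prescribed integrated brightness; the trace generator integrates the
overdamped Langevin equation (Euler–Maruyama, sub-stepped so the discrete
stationary-variance bias stays ~1%, C++ inner loop, R RNG for seeded
reproducibility).

Not emulated: supercoiled/plectonemic tube regions, membrane fluctuations
and tether-force fluctuations, detector nonlinearity and low-frequency
drift, protein photobleaching, out-of-focus light, and xy cross-talk of the
QPD. A green test therefore establishes estimator correctness under
idealized optics and Brownian statistics — not robustness to every
instrumental artifact of a real trap.

**A resolution limit worth knowing.** With FWHM ≈ 0.75 µm observed tube
width (0.47 µm tube ⊗ 0.25 µm PSF), the strands of adjacent helix turns
overlap within the PSF once the pitch falls below roughly four times the
observed width. The apparent cross-sectional width at *any* section of such
a compressed helix is then physically inflated by 10–30%; no estimator can
undo this, and three independent ones (full-column fit, windowed fit at
turning points, two-level outer-flank crossings) were verified to agree on
the inflation. `tube_diameter_at_turns()` — the automated stand-in for
choosing a "representative tube section" — is therefore validated to 10%
only at λ ≥ 3 µm; at λ ≤ 2 µm tests assert only the inflation direction.
Pitch recovery is unaffected (validated to 10% at λ = 1.5–4 µm).

## Other design choices made where the design was open

- **Angular sampling** of kymographs: one-pixel arc length at the fitted
  radius (n_bins = round(2πr)); bilinear interpolation off-grid; the
  circular ROI is averaged over radii r−1, r, r+1 px.
- **Direction convention**: angle increasing in y-down image coordinates
  (anticlockwise on screen) maps to positive kymograph slope; no sign
  convention was fixed upstream.
- **Velocity extraction**: per-frame ridge maxima linked into tracks by
  nearest angle with circular unwrapping, then linear regression per track;
  a track drifting less than one angular bin has no defined direction.
- **Binarization** for arclength: global Otsu after a 1 px Gaussian filter
  (the filter prevents shot-noise jitter of per-column centroids from
  inflating the arclength); blurred end caps are trimmed where the column
  support drops below half its median.
- **Position calibration**: within the |response| < 70%-of-saturation core,
  an odd cubic is fit and its linear coefficient reported — the tangent
  slope at the s-curve centre. A plain line over the same core is biased
  several percent low by the onset of saturation.
- **Lipid baseline**: protein spring constants inside the [min, max] range
  of the lipid-only set are discarded (the membrane reservoir dominated
  those vesicles); the protein-only constant is mean(kept) − mean(lipid).
- **Ring brightness reference**: median of accepted (non-overlapping)
  single rings; a reference from fewer than 10 rings is flagged.
- **Pitch-state statistics**: a two-component Gaussian mixture by EM
  (quantile initialization, σ floored, 500-iteration cap with a flagged
  single-component fallback) operationalizes "two pitch states"; means are
  reported sorted, and bimodality requires mode separation above the pooled
  within-component σ.
- **Percentage display**: truncation to integers (80.8% → "80", matching
  the reference counts' display style); full precision is kept in JSON.
- **Serialization**: image stacks and traces are written as plain-text CSV
  with JSON sidecars rather than TIFF — no TIFF package is available in the
  supported dependency set, and text fixtures remain reviewable.

## Worked demonstration

```{r demo}
report <- run_pipeline(seed = 1, fast = TRUE)
report$trap$k_spring_pn_um        # ~0.92 pN/um (series value 0.889)
report$tube$mean_pitch_um         # ~1.59 um (true 1.6)
report$mech$E_mpa                 # 51.77 MPa
```

All numbers printed by the pipeline are computed at run time from synthetic
inputs; nothing is looked up.

## Known limitations

- Velocity estimation assumes quasi-linear streaks; strongly accelerating
  or merging filament trajectories are split into separate tracks.
- The pitch procedure presumes a single tube roughly aligned with one image
  axis after PCA rotation; branching or folded tubes should be cropped
  first.
- The spring-constant estimator inherits the series-spring bias by design;
  for stiff samples (k approaching k_trap) the reported value
  underestimates the true stiffness substantially.
- Sub-stepping keeps the Langevin integration accurate for the parameter
  ranges of this assay; pathological configurations (corner frequency near
  Nyquist) are rejected rather than silently aliased.
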