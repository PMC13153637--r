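---
title: "Marker-less target tracking with orthogonal kV imaging: models and methods"
author: "orthoTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-less target tracking with orthogonal kV imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoTrack)
```

## The problem

Robotic stereotactic radiotherapy of the pancreas tracks the tumour in real
time on a pair of kilovoltage imagers mounted at &plusmn;45&deg; from vertical.
Conventionally the target is localized through implanted gold fiducial
markers, whose surgical placement carries a complication risk. This package
implements a marker-less alternative: the treatment images are registered to
digitally reconstructed radiographs (DRRs) of the planning CT, and a linear
motion model converts the resulting image-space shifts into a 3D target
position. Because no public imaging data exist for this problem, the package
also provides a digital abdomen phantom that generates complete synthetic
cohorts with known ground truth, which every claim in the test suite is
evaluated against.

## Stereo geometry

Both imagers see the patient's superior--inferior (SI) axis along the image
rows, so an SI target shift moves both images together by $J_{AB}$, while
left--right and antero-posterior shifts mix into the two lateral image axes.
With $R = \sqrt{2}/2$,

$$x = R(I_A + I_B), \qquad y = R(I_B - I_A), \qquad z = -J_{AB}.$$

`backprojectShift()` applies this relation, `projectOffset()` its exact
algebraic inverse; the round trip is identity to machine precision. Signs
follow the convention that $x$ is positive toward patient left, $y$ anterior,
$z$ superior, image columns increase with $I$, and rows increase downward
(toward inferior), which makes $z = -J_{AB}$ literal. The detector row
direction is not dictated by the hardware description; this inferior-down
choice is the one that keeps the back-projection formula sign-free.

## Image formation

DRRs are ray-traced with parallel rays at &plusmn;45&deg; in the axial plane
(the real cone beam's divergence is ignored, consistent with the parallel
back-projection relation above). Each pixel holds the attenuation-style line
integral $\mu \int \rho\, dl$ with $\mu = 0.0171\ \mathrm{mm}^{-1}$ at
120 kV, so dense anatomy is bright. Before tracing, voxels with density
above $1.869\ \mathrm{g\,cm^{-3}}$ are reassigned to 1.0, which hides
implanted fiducials on the DRR while leaving them visible on treatment
images. Both views are integrated on a common rotated grid whose
integration axis extends to the full in-plane diagonal of the volume, so a
detector field narrower than the body still sees complete ray paths.

## Preprocessing

Three conditioning steps precede registration:

* **Bandpass sharpening** multiplies the 2D spectrum by a radial gain
  $1 + gf$ up to half the Nyquist frequency ($g = 0.02$, $f$ in
  discrete-transform bin units, $f_{max}$ = half the image size). For the
  upper band we use the continuous complement $1 + g(f_{max} - f)$, which
  joins the first branch at its peak ($2.6$ for a 320-pixel image) and
  returns to unity at Nyquist; the discontinuous textbook-verbatim variant
  is available behind `literal = TRUE`. Frequency-bin units matter: in
  cycles/pixel the same gradient would give a peak gain of 1.005 and the
  filter would do nothing. The DC gain is exactly 1, so the image mean is
  preserved.
* **Fiducial removal** selects the brightest 0.5% of pixels within the
  central region (0.25--0.75 of the image span) and overwrites each
  selected pixel and its 8 neighbours with the mean of the four pixels
  10 px left, right, above and below. The selection count is
  `ceiling(fraction * central pixels)` with raster-order tie-breaking;
  offsets are clamped at the image border.
* **Equalization** rescales the DRR's interquartile range to the treatment
  image's, smoothly: 25th/75th percentiles are computed in the four corner
  regions of a 5&times;5 partition, interpolated bilinearly between the
  corner-region centres (clamped outside the anchor rectangle --- the
  source text specifies only "bilinear interpolation", so anchor placement
  and clamping are our choices), and each pixel is mapped as
  $D^{eq} = (D - d_{min})s + t_{min}$ with
  $s = (t_{max}-t_{min})/(d_{max}-d_{min})$. A non-positive DRR
  interquartile range in any corner raises an error naming the region.
  This step assumes the corner regions are anatomy-filled; on images with
  air corners the percentile anchors become unstable, which is why the
  synthetic cohort's default field of view (160 mm at 1.25 mm/px) keeps
  the abdomen filling the frame.

## Registration

Every candidate shift is scored by $\gamma = \mathrm{NMS} \times
\mathrm{NMI}$:

$$\mathrm{NMS} = 1 - \frac{1}{Nn}\sum_{ij}\bigl(T(i+I, j+J) -
D(i,j)\bigr)^2, \qquad N = \bigl[\max(D_{max}-T_{min},\,
T_{max}-D_{min})\bigr]^2,$$

with treatment pixels falling outside the image excluded and $n$ reduced
accordingly, and NMI $= (\Psi(D)+\Psi(T))/\Psi(M)$ computed from 128-bin
histograms with $\Psi = -\sum p \ln p$. The histogram range is fixed at the
search's start shift and held constant across candidates so the bin edges
are stable during optimization; a zero joint entropy (both regions
constant) is treated as a degenerate perfect match with NMI = 2. The NMS
term carries the spatial information; the NMI term tolerates residual
intensity mismatch.

The search proceeds in three stages:

1. **Coupled whole-image search**: one shared $J_{AB}$ scanned in an outer
   loop; for each $J$, $I_A$ and $I_B$ maximized independently and the
   per-view $\gamma$ values summed. Two passes: &plusmn;20 px step 4, then
   &plusmn;2 px step 1 around the coarse optimum. Ties break to the
   smallest shift norm, then candidate order, making results
   deterministic.
2. **Subregion refinement**: 25 overlapping regions per image (width
   $\lfloor 2 \cdot \mathrm{size}/6 \rfloor$, five start positions evenly
   spaced so adjacent regions overlap by about half), each searched
   independently in 2D (&plusmn;10 px step 2, then &plusmn;1 px step 1)
   seeded at the global shift. Each image is refined separately; only the
   global and PTV stages couple $J$ across views.
3. **PTV-region search**: one further coupled search restricted to the
   rectangle around the PTV's beam's-eye-view projection plus a 20 mm
   margin (converted to pixels at the target plane), with the subregion
   pass schedule, and no adjustment afterwards.

The 25 grid shifts plus the PTV shift of both images, each an (I, J) pair
in mm, stack into the 104-component registration vector in a fixed
documented order (image A grid row-major, then its PTV slot, then image B
likewise).

## Motion model

Observations are split into inter- and intra-fraction parts by per-fraction
averaging: $v_{mn} = v_m + v'_{mn}$ and likewise for the position $r$.
Each part is fitted as a linear system $Ax = b$ with $A$ the $n \times
105$ design (104 components plus intercept) solved by SVD,
$x = V W^{-1} U^T b$, where reciprocals of singular values below
$w_{max}/R$ are zeroed ($R = 1.2$ inter, $R = 7.0$ intra). We read the
cutoff rule as the standard truncated-SVD convention --- discarding the
*smallest* singular values, the ones that contribute negligibly or drive
over-fitting; the verbatim alternative (thresholding the reciprocals
themselves, which would delete the largest values) contradicts that
purpose but is available behind `literal = TRUE` for comparison. The
intercept is fitted in both models; the intra model's is close to zero by
construction (residuals are mean-centred) and retained for symmetry.
Columns are not standardized: all components are in mm, so scales are
commensurate.

Two scenarios are evaluated. Without daily volumetric imaging (DVI), the
fraction mean position must itself be predicted from the images:
$\hat r_{mn} = f_{inter}(v_m) + f_{intra}(v_{mn} - v_m)$. With DVI, a
pre-fraction volumetric image supplies the true mean, and only the
intra-fraction deviations are predicted: $\hat r_{mn} = r_m +
f_{intra}(v_{mn} - v_m)$ --- an idealization that assumes the daily image
localizes the mean position exactly. `loocvEvaluate()` holds each patient
out in turn, fits both models on the rest, and reports min/quartile/median/
max errors per patient and pooled; pooled rows aggregate per-image errors
across patients, not medians of medians. Quartiles use linear interpolation
between order statistics (type 7).

## The synthetic phantom cohort

The phantom partitions an elliptical body cylinder into three components:
a static spine cylinder; lung-density tissue above a spherical diaphragm
dome, which follows respiration in $z$ only; and the abdominal
soft-tissue block below the dome, which carries the full 3D target motion
--- the target sphere (CTV), a denser visceral block around it, randomly
placed texture blobs standing in for bowel and vascular structure, and
optional fiducial markers. Bowel-gas pockets are **redrawn each fraction**:
day-to-day bowel change is the mechanism that makes the per-fraction mean
registration state an imperfect predictor of the baseline position, which
is exactly why daily volumetric imaging helps. Treatment images are
synthesized by shifting the component projections in the image plane
(exact for rigid translations under parallel rays; components are
projected on a padded canvas so shifts slide real anatomy, not zero fill,
into the field of view), then degraded by a smooth multiplicative
polynomial field and additive Gaussian noise.

Study conditions (the generator defaults): per-fraction baseline offsets
i.i.d. Gaussian with 5 mm per-axis sigma; respiratory half peak-to-peak
amplitudes drawn per patient within the clinical pancreas ranges
(left--right 3.5--14 mm, antero-posterior 3.75--11 mm, supero-inferior
7--17 mm, i.e. peak-to-peak up to ~28/22/34 mm); a $\cos^4$ waveform with
end-exhale dwell (a pure cosine is available); period 3.2--5 s; noise at
2% of the DRR intensity range and a 5% intensity field --- values chosen
once as representative of processed kV image quality, since no noise
statistics are published for the real system. The default study size is
4 patients &times; 3 fractions &times; 6 image pairs at 128 px / 1.25 mm
with a 128&sup3; &times; 2 mm phantom and a 16-beam plan; these sizes were
chosen as the package's desk-scale study and are what the acceptance
script runs. What passing tests on this cohort do **not** show: robustness
to scatter, beam hardening, detector artifacts, deformable organ motion or
out-of-plane rotation --- none of which the phantom emulates.

## Dosimetric accumulation

A synthetic multi-beam plan stands in for a clinical dose engine: each of
`nBeams` beams (quasi-uniform directions over the superior/anterior
sphere) contributes an anisotropic Gaussian-falloff dose conformal to the
PTV --- flat lateral falloff sigma 4 mm, long axial sigma 30 mm --- with a
25% central boost reproducing the stereotactic convention of prescribing
to a peripheral (~80% of maximum) isodose. The sum is normalized so the
PTV's $D_{95\%}$ equals the prescription (35 Gy in 5 fractions).

Residual tracking errors (predicted minus reference) are accumulated
stochastically: for each repeat, fraction and beam, a residual is drawn
uniformly from the patient's series and the beam's per-fraction dose is
rigidly shifted by it; 10 repeats give a DVH band, and the expectation
dose (every shift applied to the whole plan) gives the infinite-delivery
limit. Shift indices are drawn independently per fraction; duplicated
shift vectors are pooled before resampling, which leaves the statistics
unchanged and makes the zero-residual case reproduce the planned dose
bit-exactly. Doses are resampled trilinearly; out-of-grid samples are
zero, with a &ge;25 mm zero-dose pad built into the synthetic grids so the
fill never clips a structure DVH. $D_{95\%}$ and $D_{0.5cc}$ are read off
the exact sorted voxel list with linear interpolation on the cumulative
volume curve, not the binned DVH (0.1 Gy bins, reporting only).

## Numerical choices and edge cases

* Grid searches are exhaustive within each pass; no interpolation below
  1 px (the finest step), no subpixel estimates.
* Argmax ties: smallest shift norm, then raster order.
* Empty search overlap, empty masks or fractions, misaligned grids,
  non-finite inputs and sub-0.5 cm&sup3; structures for $D_{0.5cc}$ all
  raise informative errors rather than propagating garbage.
* All randomness flows from named integer seeds (cohort master seed
  &rarr; per-patient &rarr; per-fraction/per-image); generators restore
  the ambient RNG state, so package calls do not perturb a session's
  random stream.
* Images on disk are 32-bit float TIFF normalized to [0, 1] with a JSON
  scale sidecar (exact to float precision); volumes are NIfTI with an
  origin sidecar; models are full-precision JSON.

## Known limitations

The phantom's motion is rigid per component; real pancreatic motion
deforms. The inter-fraction model sees an idealized linear image response,
so its heavy truncation at $R = 1.2$ is exercised but not stressed by
realistic anatomy variability across patients. The DVI scenario assumes a
perfect daily mean-position measurement. Cone-beam divergence, imager
calibration and rotational tracking are out of scope, as is any clinical
dose engine: the dosimetry module validates the *accumulation* arithmetic,
not absolute dose.

```{r example, eval = FALSE}
# a miniature end-to-end run (about a minute)
cfg <- defaultRunConfig(seed = 21)
cfg$cohort$n_patients <- 2; cfg$cohort$n_fractions <- 2
cfg$cohort$n_images <- 3
cfg$geometry <- list(image_size = 64, pixel_spacing_mm = 2.5)
cfg$dose$n_beams <- 4; cfg$dose$repeats <- 2
out <- runPipeline(cfg)
out$summary$pooled_median_error_noDVI_mm
out$summary$pooled_median_error_DVI_mm
```
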