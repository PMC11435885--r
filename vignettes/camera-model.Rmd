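---
title: "Camera model, reconstruction chain and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera model, reconstruction chain and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lasipcam)
```

`lasipcam` studies how the pixel size, shape and noise of a large
SiPM-based gamma camera affect its energy and intrinsic spatial
resolution.  The camera is a NaI(Tl) slab read out by 6 x 6 mm2 silicon
photomultipliers whose analog currents are summed in groups — large-area
SiPM pixels (LASiPs) — to keep the channel count of a full-body SPECT
head manageable.  Everything here runs at desk scale: the instrumented
region is the central 225 x 225 mm of the crystal, and all inputs are
simulated by the package itself.

## Geometry

SiPMs sit on a lattice of pitch 6.25 mm (6 mm cell + 0.25 mm gap), either
on a square grid (1296 cells in the region) or on a "honeycomb" grid:
horizontal rows at the same vertical pitch with odd rows shifted by half a
pitch.  With square cells a true equilateral packing is impossible; the
row-offset realisation is the simplest one in which every interior cell
(and every interior pixel built on the lattice) has six lattice
neighbours, which is the property the comb pixels exploit.  The honeycomb
region holds 1278 cells because offset rows lose one cell at the boundary.

Eight pixel groupings are studied.  Models 1-4 are square blocks of
3x3 ... 6x6 SiPMs.  Model 5 ("flower") groups 24 SiPMs of the square grid
into a 4-fold-symmetric octagon with row lengths (2,4,6,6,4,2); it tiles
the plane by pure translations with lattice {(6,0),(3,4)} (in cell
units).  Models 6-8 ("combs") are hexagon-like clusters on the offset
lattice with row patterns (2,3,2), (3,4,5,4,3) and (4,5,6,5,4) — the
unique symmetric patterns summing to 7, 19 and 24 — and all three tile by
translations in axial coordinates.  Groups clipped by the region boundary
are kept but flagged `partial`; all metrics use interior pixels only.
The exact flower and comb shapes admit more than one reading; the
templates above are this package's definition, kept in one place
(`R/geometry.R`) and serialised with every tiling so any alternative can
be swapped in.

## Synthetic light transport

A full optical Monte Carlo is replaced by a parametric model with two
spatial knobs:

* a **solid-angle kernel**: a scintillation at (x, y) illuminates each
  cell with the solid-angle fraction it subtends from an effective
  emission point at height `h_eff = crystal/2 + glass = 5.5 mm` above the
  photodetector plane (`K(r; h) = h / (4 pi (r^2 + h^2)^(3/2))`, integrated
  analytically over each cell);
* a **diffuse term**: a fraction `diffuse_fraction = 0.15` of the
  detected light is spread uniformly over the instrumented area, standing
  in for reflector light.

The number of detected photoelectrons per 140 keV event is Poisson with
mean `E * Y * collection_eff * pde * (1 - exp(-T_int / tau))` =
140 keV x 38 ph/keV x 0.6 x 0.5 x 0.926 ~ 1478; `collection_eff` absorbs
the overall geometric and reflector losses, so the kernel weights are
renormalised over the instrumented cells before the multinomial split.
The NaI(Tl) decay constant is taken as 230 ns (the standard value) and
the 600 ns integration window then accepts 92.6% of the light.  A
multiplicative Gaussian of width `intrinsic_sigma`, truncated at zero and
applied to the event total before the split, models the scintillator
intrinsic resolution; `calibrate_intrinsic()` bisects it (common random
numbers, fixed seed, +-0.1 percentage point tolerance) until the no-dark
energy resolution of the 9-SiPM pixel at the optimal pixel count equals
the 8.1% anchor.  Typical calibrated values are ~0.016.  Interaction
depth is folded into the single `h_eff`; no per-event depth, no Compton
tail (the photopeak window is still exercised by noise), no wavelength
dependence.

## SiPM noise

Dark counts are Poisson per SiPM with mean `DCR x 36 mm2 x 600 ns`
(presets: cooled 0.015, room 0.050, hot 0.150 MHz/mm2; "none" keeps
crosstalk only).  Every primary avalanche — photon or dark — is
multiplied by a Borel branching cascade with `lambda = -ln(1 - p_ct)`, so
the probability of at least one secondary is exactly the crosstalk
probability (25%) and the mean multiplicity is `1/(1 - lambda)`.
Crosstalk is applied to dark primaries as well.  Summing more SiPMs into
one channel also degrades the electronic SNR; with no validated
functional form built in, that effect is exposed only as the optional
`elec_sigma_coeff` (p.e. per sqrt of summed SiPMs, default 0).  Gains are
identical across SiPMs.

## Charge and energy

The event charge is the sum over the M pixels with the highest individual
charge (ties by pixel id).  When dark counts are present the expected
dark charge of each pixel — `n_members x dark rate x window /
(1 - lambda)`, a deterministic baseline fixed by the noise configuration —
is subtracted before ranking and summing.  Without this baseline
subtraction the fitted photopeak position would inflate linearly with M
while its width grows only with sqrt(M), the FWHM/position ratio would
improve as noise is added, and the pixel-count optimum would not exist;
with it, dark counts enter only through their fluctuations, which is what
an AC-coupled or pedestal-corrected readout measures.  The photopeak is
found with a two-pass Gaussian fit (Freedman-Diaconis binning, +-2 sigma
refit window around the mode — the refit window is our choice, as is the
central +-60 mm flat field used for energy measurements so light
collection is uniform), events within +-15% of the peak are kept, and the
energy resolution is 100 x FWHM / position.  `optimize_M()` scans M and
reports the curve and its argmin, with the equivalent-SiPM axis
`M x SiPMs-per-pixel`.

## Light-response functions and positioning

LRFs are sampled on a 21 x 21 grid of beam positions with 6.5 mm spacing
(span +-65 mm): the mean normalised charge `q_ij / Q_j` per pixel and
node, fitted per pixel with the radially symmetric generalised bell
`f(x,y) = a / (1 + (((x-d)^2 + (y-e)^2)/b^2)^c)` by weighted
Levenberg-Marquardt with perturbed restarts; of the bell-family variants
we use the radially symmetric one, whose five parameters are amplitude,
scale, shape exponent and the two peak coordinates.  Calibration data are
noiseless (the LRF is a detector
property; noise robustness enters through the likelihood), samples below
10^-3 are excluded, and pixels whose centroid lies more than half a pixel
pitch outside the calibration span are flagged unusable — their peak is
never sampled, so a fit there would be an unconstrained extrapolation.
We fit the node means directly (weighted by their standard errors) rather
than interpolating a 2-D histogram first; the two are equivalent here
because the fit consumes exactly the per-node means.  The bell is a
deliberate smoothing of the true response, which is flat-topped (the
pixel integrates the kernel over its aperture) with heavier-than-bell
tails: held-out calibration nodes reproduce to ~15-25% relative accuracy,
and a relative-error weighting that chases the tails makes both the fits
and the reconstruction markedly worse.  The likelihood only consumes
ratios of LRFs across neighbouring pixels, which is why positioning
remains accurate despite this smoothing.

Positions maximise the Poisson likelihood of the charges over the
maximum-charge pixel and its 20 nearest neighbours (`M_rec = 21`), with
rates `lam_i = f_i(x,y) * sum(q) / sum(f)` — the standard Poisson
negative log likelihood up to charge-only constants, with the
M_rec-pixel sums used for both the charge and the LRF normalisation.
The search is a bounded 2-D Nelder-Mead (simplex tolerance 10^-3 mm,
restarts from four perturbed seeds, charge-centroid fallback flagged on
non-convergence) constrained to a 40 mm radius around the seed-pixel
centre; the constraint is implemented as a radius, the more permissive
of the two readings of that bound.  Raw charges (not baseline-
subtracted) feed the likelihood: dark counts then blur positions exactly
as they do in the physical camera.

## Corrections and metrics

The calibration grid is reconstructed to build a displacement map
(bilinear between nodes, nearest-edge outside); linearity correction
subtracts the interpolated displacement event-wise.  A reconstructed,
linearity-corrected flat field over the fiducial area (calibration span
minus one lattice spacing, +-58.5 mm) is binned at 6.5 mm, normalised,
floor-clamped at 10% of the mean and inverted to give the multiplicative
uniformity map; it errors only when mean statistics per bin are too low
(< 5 events), because deeply empty bins are a real feature of
large-pixel raw reconstructions, not a statistics problem.

Spatial resolution follows the capillary procedure: vertical line
sources through interior pixel-centre columns (the conservative
d-hat = 0 choice), y bands of half-width 1.25 mm centred on pixel-centre
rows, x projections in 0.5 mm bins weighted by the uniformity map, cubic
spline (natural) through the profile, FWHM from the half-maximum
crossings bracketing the peak.  The mean of the band FWHM distribution is
the resolution, its SD the error.  d-hat normalises the capillary-to-
pixel-centre distance by half the pixel pitch, where the pitch is the
median nearest-neighbour centroid distance of interior pixels (for
staggered honeycomb rows each band carries its own d-hat).  The Derenzo
pattern puts one diameter class (1, 2, 3, 4, 6, 8 mm, centre spacing 2d)
in each of six 60-degree sectors of a 45 mm-radius disc — the sector
arrangement is our choice — and a class is "resolved" when the mean
intensity at valley midpoints between adjacent circles falls below 60% of
the mean at the circle centres.

## Problem sizes

The package's own default study sizes are: 200 events per calibration
node for LRFs (the samples are means, so their errors shrink as
1/sqrt(n)), 20 per node for the linearity map, 2-4 x 10^4 flat-field
events for the uniformity map, ~10^4 events per energy-resolution
measurement and ~3 x 10^3 events per capillary position; the bundled
tests run the same pipeline at one-half to one-quarter of these sizes.

## What the generator does and does not emulate

Passing tests show that the reconstruction chain — truncated charge,
bell-fitted LRFs, Poisson MLE, linearity and uniformity corrections,
spline FWHM — behaves correctly on a camera whose light spread is the
solid-angle kernel plus a uniform diffuse term.  Two caveats matter when
comparing with a physically transported camera:

* The kernel's heavy tails carry more positional information to
  neighbouring pixels than diffusive reflector transport does, so
  absolute spatial resolutions come out better (smaller) than in a
  camera with diffusive optical transport, increasingly so for large
  pixels; the largest square
  pixel even collapses onto discrete likelihood attractors instead of
  dispersing.  Orderings among the smaller pixels and between noise
  levels are preserved; absolute FWHMs are not transferable.
* Because the kernel concentrates light and the diffuse term carries no
  gradient, far pixels buy less signal per unit dark noise than diffusive
  transport would provide, and the room-noise pixel-count optimum lands at
  ~400-550 equivalent SiPMs rather than ~700.  The optimum is shallow
  (< 0.1 percentage point over that span), so the energy resolutions at
  the optimum are barely affected.

Energy-resolution quantities are insensitive to the kernel shape (they
depend on counting statistics, crosstalk overdispersion and the dark
budget) and transfer well.

## Known limitations

No depth-of-interaction, no afterpulsing, no gain dispersion, no
collimator, no Compton continuum, no energy-dependent corrections.  The
comb/flower templates are one of several defensible shape choices.  Reconstruction quality degrades outside the calibration span;
all quoted metrics use the fiducial area.
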