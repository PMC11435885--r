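# lasipcam

Simulation and reconstruction study for large gamma cameras read out by
**large-area SiPM pixels (LASiPs)** — groups of 6 x 6 mm2 silicon
photomultipliers summed into single channels.  Full-body SPECT heads need
thousands of SiPMs if each is read out alone; summing them into larger
pixels cuts the channel count, but bigger pixels collect more dark counts
and give the positioning algorithm less information.  This package
quantifies that trade-off: it simulates 140 keV scintillation events on a
pixelated NaI(Tl) camera, injects SiPM dark counts and optical crosstalk,
reconstructs event energy and position, and reports the photopeak energy
resolution and the intrinsic spatial resolution for eight pixel
configurations (square 3x3 to 6x6 blocks, a 24-SiPM "flower" on the
square grid, and 7/19/24-SiPM "comb" clusters on a honeycomb grid) under
four noise levels (none, cooled, room, hot).

It is aimed at detector physicists exploring readout granularity for
Anger-type cameras, and at anyone who wants a compact, fully synthetic
testbed for Poisson maximum-likelihood positioning with light-response
functions.

## Model and methods

* **Light generation** — an event at (x, y) produces
  `N ~ Poisson(E Y c_eff PDE (1 - e^{-T/tau}))` ~ 1478 photoelectrons
  (140 keV, 38 ph/keV, 50% PDE, 600 ns window, 230 ns decay), smeared by a
  calibrated multiplicative Gaussian (scintillator intrinsic resolution)
  and split over cells by a multinomial whose weights combine the
  solid-angle kernel `K(r; h) = h / (4 pi (r^2 + h^2)^{3/2})` at
  `h = 5.5 mm` with a 15% uniform diffuse term.
* **Noise** — per-SiPM Poisson dark counts (0.015 / 0.050 / 0.150
  MHz/mm2) and Borel-branching crosstalk with
  `lambda = -ln(1 - 0.25)`, applied to every primary avalanche.
* **Energy** — truncated sum `Q = sum_i^M q_i` over the M highest-charge
  pixels (expected dark baseline subtracted), two-pass Gaussian photopeak
  fit, `ER = 100 FWHM / Q_140`, with M optimised per configuration.
* **Position** — per-pixel light-response functions
  `f(x,y) = a / (1 + (((x-d)^2 + (y-e)^2)/b^2)^c)` fitted on a 21 x 21
  calibration grid (6.5 mm spacing), then Poisson maximum likelihood
  `min_x,y sum_i [lam_i - q_i ln lam_i]`, `lam_i = f_i sum(q) / sum(f)`,
  over the max-charge pixel and its 20 nearest neighbours within a 40 mm
  search radius.
* **Corrections & metrics** — event-wise spatial-linearity correction
  from the calibration grid; bin-wise uniformity correction from an
  inverted flat-field image; intrinsic spatial resolution as the mean
  spline FWHM of capillary-source projections; Derenzo-pattern
  valley-contrast resolvability.

## Worked example

```r
library(lasipcam)
set.seed(1)

lay <- build_grid("square", c(225, 225), 6, 0.25)   # 1296 SiPMs
tl  <- group_pixels(lay, 1)                          # 144 9-SiPM pixels

cfg <- optics_config()
cfg$intrinsic_sigma <- calibrate_intrinsic(cfg, tl, target_er = 8.1,
                                           n_events = 3000, seed = 1)

er <- measure_er(cfg, tl, noise_config("room"), n_events = 6000)
cat(sprintf("room-noise ER: %.2f%% at %d equivalent SiPMs\n",
            er$er_opt, er$equiv_opt))

pl <- build_pipeline(cfg, 1, noise_config("room"),
                     n_cal = 150, n_lin = 20, n_ffi = 20000)
sr <- measure_spatial_resolution(pl, n_cap = 3000)
cat(sprintf("intrinsic spatial resolution: %.2f +- %.2f mm\n",
            sr$mean, sr$sd))
```

On one run with these sizes this prints

```
room-noise ER: 8.48% at 432 equivalent SiPMs
intrinsic spatial resolution: 1.36 +- 0.28 mm
```

i.e. dark counts at room temperature degrade the calibrated 8.1%
no-noise resolution to ~8.5% at the optimal pixel count, and a line
source through a pixel centre reconstructs with a ~1.4 mm FWHM.

The `analysis/` directory holds the numbered study drivers
(`01_geometry.R` ... `05_derenzo.R`); each writes its tables under
`results/`.

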