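---
title: "Network spikes and pixel-level local fields in plate-reader calcium movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network spikes and pixel-level local fields in plate-reader calcium movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfca)
```

## The measurement problem

Cocultures of human induced glutamatergic neurons (GLUT iN) on primary
astrocytes (pA) develop synchronized network activity within about four weeks.
On a kinetic plate reader, each well's GCaMP6f fluorescence is recorded as a
grayscale movie (5–8 frames/s); the well-average trace shows large,
synchronized *network spikes*, and the spike frequency and amplitude are the
standard assay endpoints for neuroactive compounds.

Well averaging, however, erases everything that is not synchronized. `lfca`
additionally analyzes the movie at *pixel resolution*: each pixel of the
well's growth area covers on the order of a hundred neurons and acts as a
sensor for local-field calcium activity, analogous to an electrode of a
multi-electrode array. This reveals local spikes that never appear in the
well average, and allows asking whether a perturbation (inhibitory GABAergic
neurons, GABA~A~ blockade) acts on synchronized activity, on local activity,
or on both.

## Spike detection

All detection is based on **topographic prominence**: the height of a local
maximum above the highest contour line enclosing no higher peak. Prominence is
insensitive to baseline offsets and, unlike absolute peak height, gives a
single threshold that works across wells with different resting fluorescence.
`detect_spikes()` reports, per event, the prominence (used as the spike
*amplitude* throughout), the peak value and time, and the full width at half
maximum (FWHM) measured at half the prominence below the peak with linear
interpolation, clamped to the peak's prominence bases. Plateau maxima resolve
to their leftmost sample. The implementation is checked in the test suite
against a naive brute-force scanner and against an independent
implementation of the same definition in another language's signal library.

The plate-wide detection threshold for well traces comes from the instrument
background: for every *empty* (dry) well at the plate edge the maximal peak
prominence of its well-average trace is measured, and the threshold is their
mean plus three standard deviations (`global_threshold()`). One consequence,
visible in simulations with known ground truth, is that coincidences of
several independent local events can occasionally exceed this background-only
threshold and register as small network spikes; their prominence (~5% of a
real network spike) makes them easy to inspect, and they are included in the
package's recovery error rather than hidden.

Pixel traces are min-max normalized to [0, 1] before detection, because the
pixel-level thresholds are defined on a bounded scale: 0.4 for standard
local-field detection, 0.1 as the sweep floor "close to noise". On this scale
a threshold sweep from 0.10 to 1.00 in 0.01 steps (`threshold_sweep()`)
reports, per class, the fraction of spikes retained relative to the floor;
since prominences do not depend on the detection threshold, detection runs
once at the floor and higher thresholds filter, making the curves monotone by
construction.

## IN and OUT spikes, phases, and synchrony

Each network spike of the well trace defines a participation window: the
half-prominence interval padded by one frame on each side, with overlapping
windows merged (`network_windows()`). A pixel spike whose peak time falls
inside any window is an **IN spike** (local activity participating in the
network event); outside, an **OUT spike**. The same windows, applied to frame
midpoints, partition the recording into IN phases and OUT phases
(`phase_masks()`), and Pearson correlation of pixel-trace pairs can be
computed on the full recording or restricted to either phase
(`pairwise_correlation()`), with distances from the pixel pitch for
correlation-versus-distance curves. The window rule (peak time, closed
intervals, 1-frame pad) is the simplest well-defined choice; the padding
matters only for spikes within one frame of a window edge.

## Zone masks

Well tiles on the image are larger than the physical growth surface. Per
well, the temporal mean brightness of each pixel is clustered into three
classes mapped by ascending brightness to *outside*, *border* and *growth*
zones; only growth pixels enter any analysis. The three centers are
initialized deterministically by splitting the sorted brightness values at
the two largest gaps and refined by standard k-means iterations. (A simpler
min/median/max initialization fails systematically here: most tile pixels are
bright growth pixels, so the median coincides with the bright plateau and two
centers split it, halving the growth count. The gap split lands one center on
each plateau and the refinement then converges to the plateau means;
everything is deterministic, so masks are reproducible.) With default
geometry a 96-format well yields 400 growth pixels and a 384-format well 132,
matching the coverage for which the analysis constants (top-400 active
pixels, 130 for 384) were designed.

## The simulator

`simulate_plate()` renders full plate movies with known ground truth so every
stage is testable without instrument data. Per well: network events are a
homogeneous Poisson process; each growth pixel participates in each event
independently with `participation_prob`, adding a difference-of-exponentials
transient `exp(-t/0.6) - exp(-t/0.1)` (unit peak; rise/decay in seconds
chosen so a GCaMP6f-like transient spans several frames at 8 fps — the
kinetics are a modeling choice, as the assay itself reports none) with
lognormal amplitude and Gaussian timing jitter (50 ms). OUT spikes are an
independent Poisson process per pixel — modeling them as cell-autonomous,
isolated events — and overlapping transients sum linearly (no indicator
saturation). Acute drug effects scale rate and amplitude from the addition
time onward; dose-response wells scale the network rate by a four-parameter
Hill term. Frames are quantized to integer counts in [0, 65535] like a
16-bit detector, which also makes TIFF round trips exactly lossless. One RNG
stream per well is derived from the seed, so single wells can be
re-simulated independently.

Defaults describe a control 96-format coculture: 3.3 network spikes/min,
participation 0.9, OUT rate 2.6/min/pixel (injected per-pixel rate ≈
5.6/min), IN amplitude 300 counts (cv 0.2) versus OUT 250 (cv 0.25) over a
3000-count growth baseline, and noise of 40 counts — approximately shot
noise at that baseline, which also puts high-intensity noise just under a
prominence of 0.1 on the normalized pixel scale, consistent with using 0.1
as the sweep floor. On the normalized scale these amplitudes put typical IN
spikes near 0.55 and OUT spikes near 0.45, both detectable at 0.4 with IN >
OUT. An "inhibitory-like" condition is expressed as higher network rate,
lower participation and lower IN amplitude with OUT parameters untouched.

What the simulator does *not* emulate: photobleaching, cell motion or focus
drift, indicator saturation, bursting substructure within a network spike,
spatially structured connectivity (participation is spatially uniform unless
configured otherwise), and optical crosstalk between neighboring pixels.
Passing tests therefore demonstrate that the analysis recovers what the model
generates under realistic rates, amplitudes and noise — not that it is robust
to every artifact of real recordings.

## Dose-response, culture metrics and statistics

`fit_dose_response()` fits the standard 4-parameter logistic in log-IC50 by
Levenberg–Marquardt with data-derived starts; flat or non-monotone data are
returned flagged as poor fits rather than silently accepted. Culture metrics
are deterministic arithmetic on nuclei-count tables: survival percent
(`100 · density · area / seeded`), neuron-to-astrocyte ratio, total survival
rate and cells-per-pixel; because the mean of per-well ratios differs from
the ratio of group means, both conventions are available and should be
labeled explicitly. Marker specificity is `1 −` the base-2 Jensen–Shannon
divergence between a gene's cluster-expression distribution and the one-hot
distribution of a perfectly specific gene; base 2 bounds the score in [0, 1]
(the logarithm base is a convention choice).

Group comparisons follow the assay's conventions: unpaired Student t-tests
across wells, paired t-tests for within-well drug-versus-baseline (a 10 s
guard interval after compound addition skips the dispense artifact; the
length is a pragmatic choice, not a measured artifact duration), and two-way
ANOVA with type-II sums of squares (types coincide on the balanced designs
used in tests) with Tukey HSD post-hoc comparisons and Bonferroni correction
available for families of t-tests. The test suite calibrates all three on
null simulations (1,000 replicates, nominal 5% within ±2 points).

## Numerical choices and limitations

* Minimum peak separation is 2 frames; strict local maxima already satisfy
  this, so it only suppresses plateau-derived doublets.
* Zero-range pixels under min-max normalization become flagged all-zero
  traces; zero-variance pixels are excluded (and listed) from correlation
  matrices.
* Empty spike sets yield flagged `NA` amplitudes, not errors.
* The empty-well threshold floor is machine epsilon when the plate is
  noise-free, so any positive-prominence peak passes.
* Problem sizes in the tests and the acceptance script: one full-scale
  96-format plate (400 growth pixels/well, 300 s at 8 fps) for recovery, a
  two-well control-versus-inhibitory plate for direction checks, 1,000
  random traces for oracle equivalence, and 1,000 null replicates for
  calibration — sizes at which the relevant Poisson/binomial error is well
  inside the asserted margins.
* Well-level frequency recovery carries two structural biases documented
  above: near-coincident network events merge into one detected peak, and
  coincident local events occasionally cross the background threshold. At
  control rates both stay within a few percent.

## A worked example

```{r example, eval = FALSE}
library(lfca)

wells <- list(B02 = well_spec(),
              B03 = well_spec(network_rate = 5.4, participation_prob = 0.6,
                              in_amplitude_mean = 200))
cfg <- sim_config(wells = wells, plate_format = 96, frame_rate = 8,
                  duration = 300, rng_seed = 7)
sim <- simulate_plate(cfg)

mask <- build_zone_mask(sim$movie)
thr  <- global_threshold(sim$movie, mask)$threshold

wt  <- extract_well_trace(sim$movie, mask, "B02")
ss  <- detect_spikes(wt, thr)
spike_frequency(ss); mean_spike_amplitude(ss)

pt  <- extract_pixel_traces(sim$movie, mask, "B02", "minmax")
win <- network_windows(ss)
tab <- classify_in_out(detect_pixel_spikes(pt, 0.4), win)
summarize_local_fields(tab)

sweep <- threshold_sweep(pt, win)
masks <- phase_masks(win, nrow(pt$traces), pt$frame_rate)
pairwise_correlation(pt, masks$in_mask, phase = "in_phases")$mean_r
pairwise_correlation(pt, masks$out_mask, phase = "out_phases")$mean_r
```
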