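---
title: "Models and methods behind rad51kin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rad51kin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad51kin)
```

# The system being modelled

In dual-trap optical-tweezers assays of homologous recombination, a
single-stranded lambda DNA molecule (48,502 nt) is held between two beads,
coated with fluorescent RPA, and exposed to RAD-51 recombinase with or
without mediator proteins.  RAD-51 polymerizes into helical nucleoprotein
filaments, each protomer occluding 3 nt; filament assembly displaces RPA
(dark wedges appear in the RPA-eGFP kymograph channel) and relaxes the
force between the traps from roughly 15 pN on bare RPA-coated ssDNA to
roughly 1 pN at full coverage.  Two mediator classes act differently:
a BRCA2-class mediator mainly stimulates nucleation, while a RAD-51
paralog complex acts as a transient "chaperone" that binds the 5' end of
nascent filaments, suppresses burst dissociation there, and thereby
roughly doubles net growth in the 3'-to-5' direction.

`rad51kin` implements (i) a kinetic Monte Carlo simulator of this system
that provides exact ground truth, (ii) renderers that turn simulated
event logs into realistic kymographs, force traces and photobleaching
traces, and (iii) the full quantification pipeline used on such data.
Every analysis stage can therefore be validated against a simulation in
which the true answer is known.

# The simulator (`sim_core`)

## State and events

The exposed ssDNA is a 1-D lattice of `lattice_length_nt` nucleotides,
0-based, with position 0 at the strand's 5' end.  A filament with `p`
protomers starting at `s` occupies the half-open interval
`[s, s + 3 p)`.  The edge at the lower coordinate faces the ssDNA 5'
side; growth there extends the filament 3'-to-5', and it is the end the
mediator caps.  Five event kinds are simulated with the exact
(next-event, Gillespie) algorithm, so all waiting times are exponential
by construction:

* **nucleation** — deposits a monomer or dimer on an uncovered stretch
  at least one footprint long (uniformly over allowed start positions);
* **addition** — one protomer joins an exposed filament end (rates
  `add_rate_5p`, `add_rate_3p` per end per minute; the end must have at
  least 3 free nt);
* **burst dissociation** — an end loses a geometrically distributed
  number of protomers (mean `burst_mean_protomers`, truncated at the
  filament length), at `off_attempt_rate` per uncapped end per minute;
* **cap bind / release** — the mediator occupies an uncapped 5' end at
  `cap_on_rate` per minute and releases after an exponential dwell of
  mean `cap_dwell_tau_s`.  A capped 5' end cannot burst; with
  `cap_blocks_addition = TRUE` (Walker-box-mutant mode) it cannot grow
  either.

## The nucleation mixture and its calibration

Single-round dipping experiments show a non-integer apparent nucleation
exponent (about 1.6) and photobleaching shows nucleating clusters to be
a mixture of monomers and dimers.  The simulator realizes this with two
nucleation channels: per free site, monomers deposit at
`J f (c / c_ref)` and dimers at `J (1 - f) (c / c_ref)^2` per minute,
with `f = monomer_nucleation_fraction = 0.4` the monomer share of events
at the reference concentration `c_ref`.  The concentration dependence of
the mixture then interpolates between exponent 1 and 2.  Calibration was
done once, before any recovery test was run: with `f` fixed at 0.4, the
apparent exponent of the *expected* counts over 50–800 nM, fitted by
raw-scale nonlinear least squares (the convention used for such data),
equals 1.6 when `c_ref = 470` nM.  Both constants are frozen at those
values.  A corollary, documented rather than hidden: at dipping
concentrations well below `c_ref` the simulated cluster population is
majority-monomer, while the mixture is 40/60 only at `c_ref` itself.

## Default rates ("paper scale")

The remaining defaults were set from the published magnitudes, using the
package's nm-per-nt constant (next section) to convert:

* `add_rate_5p = add_rate_3p = 27.4` protomers/min: a fully capped 5'
  end then advances at 82 nt/min = 38 nm/min;
* `off_attempt_rate = 3.6`/min with mean burst size 4: an uncapped end
  nets 38.6 nt/min = 18 nm/min, so wild-type capping roughly doubles the
  3'-to-5' rate — the published contrast;
* `cap_dwell_tau_s = 11.3` s (ATP); the Walker-box-mutant preset uses a
  20-fold longer dwell and blocks addition; the slowly-hydrolysable-ATP
  condition lies in between (28.3 s);
* `nucleation_rate_const_J = 1.2e-3` per nt per min at `c_ref`, with an
  implicit RPA competition factor of 0.1 on coated ssDNA, which gives
  recombinase alone a coverage half-time of roughly 10 min on a full
  lambda lattice at 500 nM;
* condition presets scale these: the BRCA2-class preset multiplies
  nucleation by 4 and growth by 1.4; the paralog preset turns on capping
  (`cap_on_rate = 50`/min, occupancy about 0.9); `"combined"` applies
  both.  The presets reproduce the published *ordering* of overall
  assembly rates (combined > either single mediator > none), which is
  what the tests assert; the absolute fitted rates depend on lattice
  size and observation window and are not claimed.

RPA is modelled implicitly (a scalar suppression of nucleation), because
none of the analyses resolve individual RPA molecules.  Burst-size law
and the end-specificity of the BRCA2-class growth effect are
parameterized, not asserted: the literature states only "bursts of
multiple protomers", so the geometric law with mean 4 is a modelling
choice.

# Rendering (`sim_render`)

Kymographs use the published imaging geometry: 100 nm pixels, 0.1 ms
per-pixel scan dwell, 1.5 s inter-frame wait (so the frame interval is
`n_px * 1e-4 + 1.5` s).  The blue channel is proportional to uncovered
ssDNA per pixel, the green channel carries one fluorophore per labeled
protomer (binned at the protomer center), and the red channel renders
caps as diffraction-limited spots.  A 1-D Gaussian PSF (sigma 150 nm,
approximately confocal at 488 nm — the instrument value is not
published) is applied along position, then Poisson shot noise plus
Gaussian read noise.  Photon budgets default to a single-fluorophore
SNR of about 5 (30 photons, read noise SD 3).  Green-channel
photobleaching uses a mean-field `exp(-rate t)` factor rather than
per-protomer bleach times; `render_bleach_trace()` does track individual
fluorophores, because step counting depends on that discreteness.

The red channel can also include transient nonspecific mediator spots
(`red_nonspecific_per_frame`, Poisson per frame, uniform over the
lattice).  This exists because scored mediator binding events in the
real experiment include off-end events — roughly 29% in the published
scoring (71% at borders) — and the end-binding classifier should be
exercised against that composition.  The default rate is 0; the
acceptance test uses 0.37 spots/frame against a cap occupancy of about
0.9, i.e. the published 29/71 ratio, fixed a priori.

Force is mapped linearly in coverage from 15 pN (bare) to 1 pN (full
coverage); the published data constrain only the endpoints.

# Polymer mechanics (`mechanics`)

Duplex DNA follows the Marko-Siggia worm-like chain interpolation with
persistence length 50 nm and thermal energy 4.11 pN nm; ssDNA follows
the extensible freely-jointed chain (Kuhn length 1.5 nm, contour
0.56 nm/nt, stretch modulus 800 pN).  A gapped molecule is the series
combination.  Fits use only 2–30 pN, below the overstretching
transition, which is not modelled.  `fit_polymer()` fits WLC curves in
force residuals and FJC/series curves in extension residuals; the series
model frees both contour lengths, and `gap_length()` converts the
contour-length increase over the intact duplex reference into
nucleotides via `g = dLc / (0.56 - 0.34)` nm.

The conversion between kymograph distances and nucleotides is the single
constant 0.464 nm/nt.  The published work prints four nm/min-to-nt/min
growth-rate pairs without stating the conversion basis; 0.464 nm/nt
reproduces all four within 2%, and it coincides with the FJC extension
per nucleotide at the 15 pN imaging force under the defaults above,
which is almost certainly its physical origin.

# Kymograph analysis (`kymo_analysis`)

`quantify_displacement()` sums the RPA channel per frame, normalizes to
the mean of the first three frames, and fits
`y = (1 - b) exp(-k t) + b` with a floating baseline (noisy renders
never reach zero).  Half-time is defined as `ln 2 / k`; note that the
published half-time for recombinase alone (10.16 min) is not exactly
`ln 2 / 0.07`, so the two published quantities were evidently estimated
separately — this package defines them consistently and documents the
discrepancy rather than matching both.  Two numerical details: because
the trace is normalized to the first-3-frame mean, the t = 0 value
slightly exceeds 1 and `k` carries a bias of order 1% under this model;
and when the fitted amplitude is negligible (trace essentially flat) the
(k, b) pair is unidentifiable, so the fit falls back to `b = 0`, where a
flat trace honestly yields `k ~ 0`.

`count_filaments_over_time()` reproduces the published nucleation-
counting image pipeline step for step: contrast normalization (1st/99th
percentiles — the original states only that contrast was increased),
25-frame running median along time, inversion, 5-pixel boxcar smoothing
along position then time (the original names a "signal convolution
function" with a 5-pixel window; a boxcar is the simplest such kernel),
per-frame peak detection, and a saturating exponential fit
`y = A_max (1 - exp(-k t))`.  Peak detection uses prominence >= 20% of
the frame's dynamic range with 3 px minimum separation (the original
gives no threshold), plus a detectability floor so that a filament-free
noise image yields zero counts.  Edges are reflect-padded.

`measure_growth_rates()` localizes each dark-region edge per frame at
the half-depth crossing of the smoothed profile (subpixel, linear
interpolation: the original's "border of displaced signal" is not
operationally defined), fits a line over time, and converts nm/min to
nt/min.  Edge-direction labels follow the construct orientation
metadata; a metamorphic test checks that flipping the orientation flips
the labels.  Accurate recovery needs the filament wider than the PSF and
a total edge excursion of a few pixels; the recovery suite spans
10–50 nm/min with observation windows chosen to move each edge at least
3 px, matching how such slopes are measured in practice.

`downsample_force()` is non-overlapping block means to 3 Hz (the
conventional plotting rate), trailing partial block dropped.

# Photobleaching steps (`step_counting`)

`find_steps()` performs greedy binary segmentation under a Gaussian
likelihood: repeatedly split the segment whose best split most reduces
the residual sum of squares, recording the RSS path, then select the
number of change points minimizing
`N log(RSS/N) + penalty_mult * n_cp * log N`.  Two deliberate choices:

* *Selection over the whole greedy path*, not a stop-at-first-failure
  rule — on non-monotone staircases the best *first* split can be weak
  even when deeper splits recover everything, and a sequential
  acceptance rule then finds nothing.
* *`penalty_mult = 3` rather than the textbook BIC's 1 per change
  point.*  The split position is optimized within every segment, so the
  best spurious reduction behaves like the maximum of many correlated
  chi-squared variates (about `2 log log N` above scale), and the plain
  BIC over-segments badly (fewer than 40% of 4-step staircases at
  step/sigma = 3 were counted correctly; with the stricter penalty about
  94%, with essentially no false steps on flat traces).

The published analysis names maximum-likelihood step estimation without
stating penalty or search strategy, so only the criterion family is
reproduced; the stricter penalty is this package's choice.

`calibrate_unit()` bins step magnitudes (Freedman-Diaconis) and fits a
double Gaussian with the second mean constrained to twice the first.
Component weights are computed from each component's predicted counts
over the observed bins, not from raw amplitudes: a component centered
beyond the data support has an unidentifiable amplitude, and comparing
amplitudes directly misclassifies pure single-component data.  If the
second component carries under 2% of the predicted counts, the
calibration falls back to a single Gaussian and flags it.
`count_protomers()` rounds intensity over the unit, floored at one
protomer for a detected cluster; `detect_growth()` applies the published
definition (an increase of at least one protomer between consecutive
occupied frames) and reports the growing fraction per molecule.

# Dwell times and nucleation kinetics (`kinetics`)

Dwells are maximal runs of consecutive detected frames at one genomic
position (drift tolerance 1 px); a run touching the final frame is
censored.  A single detected frame counts one 30 s interval.
`fit_dwell_exponential()` bins dwell times at the frame interval
(keeping empty bins) and fits `A exp(-t/tau)` — the histogram
convention used for such figures; the maximum-likelihood estimate (the
sample mean) is available as a cross-check.  For frame-count data the
histogram estimator is essentially unbiased (the geometric bin ratio
equals `exp(-dt/tau)`); its sampling SD at n = 87 is about 15%, which is
why recovery tests judge the median error over seeds.  Censored records
are excluded from fits by default (they are lower bounds) but retained
in survival curves; a test asserts the resulting bias direction.

`median_with_ci()` uses order-statistic (binomial) intervals.  Only a
discrete set of confidence levels is achievable for a given n, which is
exactly why published medians of this kind carry odd levels like 96% or
97.6%; the achievable level nearest (and at least) the request is
reported alongside.  The published preconditions suggest five records,
but the printed worked example has three, so the implementation accepts
n >= 3.

`fit_power_law()` fits `k = J c^n` by raw-scale nonlinear least squares
(the GraphPad convention), started from the log-log slope; data lying
exactly on a power law short-circuit to the log-log solution because a
zero-residual start breaks the optimizer.

# Localization (`localization`)

`locate_filament()` fits a Gaussian to the inverted RPA profile; the
center is the fitted mean and the edges sit at the half-width at half
maximum, following the published "reversed eGFP intensity" procedure
whose "peak's width" is not otherwise defined.  For wide, flat-bottomed
filaments the Gaussian HWHM slightly underestimates the physical
half-width; the 200 nm (2 px) classification tolerance absorbs this.
`classify_binding()` labels a spot 5'/3'-end if within tolerance of the
corresponding edge (nearer edge wins, exact ties flagged), internal if
strictly inside beyond tolerance, RPA/ssDNA otherwise; the published
"proximity" is never quantified, so the 2 px tolerance is this package's
choice, validated by a confusion-matrix test (diagonal >= 0.9).
`colocalization_fraction()` uses one PSF sigma as the colocalization
radius and reports per molecule, with no-spot molecules NA rather
than 0.

# What a green test does and does not establish

The synthetic world is deliberately simple: no sequence dependence, no
explicit RPA molecules, no dsDNA binding, no filament merging
resolution, mean-field kymograph bleaching, a linear coverage-to-force
map, and Gaussian PSF/noise models with declared (not measured)
brightness.  Green recovery tests therefore establish that the analysis
code is correct *given* this generative model at the published
magnitudes — they do not re-derive the published biology from raw data,
which at single-molecule scale is not reproducible on a desktop.  The
only quantities asserted against published numbers are those that are
analytically recomputable (the nm/nt conversion pairs, `ln 2 / k`
half-time consistency) or that the calibrated simulator should
reproduce as stated (the apparent nucleation exponent 1.6 +/- 0.2, the
orderings across mediator conditions, the border-binding fraction with
the published event composition).

# Known limitations

* Growth-rate recovery degrades for filaments narrower than about twice
  the PSF, where half-depth edges are not resolved; the simulator seeds
  resolvable filaments for those tests, as the original analysis selects
  resolvable growth events.
* The displacement decay of the lattice model is only approximately
  exponential (nucleation-plus-growth coverage is Avrami-like), matching
  the empirical character of the published exponential fits.
* Cluster tracking in `simulate_dipping()` is by simulator identity, not
  by positional re-detection; the detection-based path is exercised
  separately through `extract_dwells()`.
* The CLI covers the documented verbs with plain-text formats only;
  vendor HDF5 ingestion is out of scope, and kymographs use a documented
  JSON layout because no TIFF/HDF5 reader is available in the supported
  dependency set.
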