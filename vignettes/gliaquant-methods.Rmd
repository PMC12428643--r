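---
title: "Quantitative methods in gliaquant: stereology, calcium events, and minimal stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods in gliaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

gliaquant packages the three quantitative arms of a hippocampal
astrocyte study — design-based stereology of immunolabelled cell
populations, somatic Ca²⁺ event analysis around a chemogenetic
(DREADD/CNO) stimulus, and minimal-stimulation synaptic physiology — as
reusable, tested estimators. Each arm ships with a seeded synthetic-data
generator carrying ground truth, so every estimator is validated by
parameter recovery rather than by eyeballing real micrographs or sweeps.
This vignette is the package's own account of the models, the defaults
and why they were chosen, and what the validation does and does not show.

## 1. Design-based stereology

### Reference volumes (Cavalieri)

A region's reference volume is estimated from equally spaced parallel
sections as

$$V = T \cdot a(p) \cdot \sum P,$$

where $T$ is the spacing between sampled sections, $a(p)$ the grid area
per point, and $\sum P$ the total count of grid points hitting the
region of interest (`cavalieri_volume()`). The point grid
(`point_grid()`) is a square lattice with a uniformly random phase
within one period, which makes $a(p)\,E[P]$ equal to the section area
exactly; fewer than 200 total points triggers a precision warning, the
conventional minimum for a reliable estimate.

**Boundary rule.** A probe point exactly on the ROI boundary counts on
the top/right boundary only. This mirrors the counting frame's
inclusion-line convention and guarantees that a tiling of probes counts
each point exactly once; it leaves the estimator unbiased because
boundaries have measure zero under the random phase.

### Numerical densities (optical disector)

Cells are counted in 3D counting frames of area $a$ (one corner point,
$p = 1$) and disector height $h$. A cell is counted once, by its unique
counting point, iff that point lies strictly inside the frame laterally
or on the right/upper *inclusion* borders — never on the left/lower
*exclusion* borders — and its depth lies in $(0, h]$ below the top
focus plane (`disector_count()`). The density estimator is the
thickness-corrected form

$$N_v = \frac{\bar{t}_{Q^-}}{BA} \cdot
  \frac{\sum Q^-}{h \cdot (a/p) \cdot \sum P},$$

with $\bar t_{Q^-}$ the number-weighted mean measured section thickness
(`number_weighted_mean_thickness()`), $BA$ the block advance set on the
cutting device, and $\sum P$ the number of frame corner points hitting
reference tissue. The ratio $\bar t_{Q^-}/BA$ compensates z shrinkage
after fixation: sections cut at $BA$ but measured at
$t = s \cdot BA$ hold their cells in a compressed depth, so the raw
in-section density overestimates the tissue density by $BA/t$. Total
numbers follow as $N = V_{ref} \cdot N_v$ (`total_number()`).

Frames whose corner point misses the ROI contribute no corner point
(and hence no reference area) but keep their in-ROI cell counts; frames
are placed on a systematic grid with random phase, 24 per region by
default (within the 21–24 frames-per-region design range; counts
outside that range warn).

**Counting point.** In the synthetic tissue the unique counting point
of a cell is the top of its nucleus, modelled as a point at the soma
centre. A point nucleus keeps the counting points uniformly distributed
in the block — cells near the top face would otherwise carry counting
points outside the sectioned volume — which makes the partition
property ("every counting point in exactly one section") and the
density ground truth exact.

**Guard zones.** No top guard zone is applied by default: the disector
band starts at the plane where the first cell comes into focus
(configurable via `guard_top` in `disector_count()`). Whether the
original protocol used one is not stated; the default follows its
zero-position convention.

### Soma volumes and intensities

A soma delineated on consecutive optical planes spaced $T$ µm apart has
the Cavalieri volume $\sum_i A_i \cdot T$ (`soma_volume()`, mode
`"standard"`). A `"paper_literal"` mode computing
$\sum_i A_i \cdot n \cdot T$ is retained for compatibility with reports
that state the formula with an explicit plane-count factor; since
$\sum A_i$ already sums over planes, that form scales the true volume
by $n$ and the standard mode is the default. Mean soma intensities are
background-subtracted per image and clamped at zero with a warning
(`soma_intensity()`).

### What the stereology validation shows

On synthetic slabs (500 × 500 × 1200 µm, density $10^{-4}$ cells/µm³,
40 µm sections, every 6th kept, shrinkage 0.75) the Cavalieri mean over
random grid phases recovers the analytic slab volume within a fraction
of a percent, and the full chain — sectioning, frame placement,
disector counts, thickness correction, $N = V \cdot N_v$ — recovers the
true cell count within sampling error (tests run 200 replicates; the
suite-internal spot check uses 40). The synthetic tissue has no
staining gradients, no lost caps, no over-projection and no lateral
shrinkage, so these tests certify the estimators and counting rules,
not robustness to histological artefacts.

## 2. Calcium events

### Model and normalization

Somatic GCaMP traces are sampled at 1 Hz for 150 s with a CNO puff at
118 s; activity before 120 s is basal, from 120 s on post-stimulus.
The generator (`simulate_ca_traces()`) draws event onsets as a Poisson
process (basal rate before the stimulus, a higher rate after), gives
each transient an instantaneous rise and exponential decay, sums
overlaps linearly, and renders
$F(t) = \text{background} + F_0(1 + \sum \text{transients} + \text{noise})$.
Onsets are snapped to the 1 Hz acquisition grid so that the recorded
frame maximum equals the true amplitude; with off-grid onsets the
sampled peak of an exponentially decaying transient is systematically
below the true amplitude and no detector could report it.

`compute_dff()` subtracts the background, estimates $F_0$ as a robust
mean of the 0–20 s window (samples more than 2 MAD above the window
median are treated as transient contamination and dropped), and returns
$\Delta F/F_0 = (F - \text{background} - F_0)/F_0$. A non-positive
baseline is an error, not a silent NaN.

### Event detection

An event is a signal maximum exceeding the previous steady signal by
more than $k$ of its standard deviations (default $k = 2$).
`detect_events()` implements this as:

1. **Candidates** — local maxima with a strict rise, which also persist
   (one of the next two frames stays above half the peak). A transient
   decaying with a multi-second time constant remains elevated at 1 Hz;
   a single-frame noise spike does not.
2. **Grouping** — neighbouring maxima whose intervening valley stays
   above half the smaller peak are one event (wiggles on a decay are
   not new events).
3. **Threshold** — a candidate is accepted when its peak exceeds
   `median + k * SD` of the trailing steady window (default 20 s)
   before its onset, with the SD estimated robustly (MAD of first
   differences / $\sqrt2$) so sparse transients inside the window do
   not inflate it.

Steps 1–2 do not depend on $k$, so the event count is non-increasing in
$k$ on every trace — a property a sequential open/close threshold
detector does not have (raising $k$ can split one excursion into two).
That monotonicity, together with exact recall and precision on
noise-free traces, is what the tests pin down. Masked frames (movement
artefacts) split the trace into independent runs: statistics never
cross a gap and gaps never spawn events. An onset needs at least five
preceding unmasked samples, so events in the first five frames of a run
are outside the detector's domain and excluded from recall accounting.

At $k = 2$ the detector is deliberately permissive: pure-noise traces
yield a small positive false-event rate which falls monotonically as
$k$ grows (measured over 500 seeded noise traces in the tests).

### Summaries and group statistics

`summarize_cell()` reports per-cell event frequencies (events/min and
Hz — the display unit is events/min) and mean amplitudes per window,
using effective durations with masked time subtracted. Cells with no
events anywhere are flagged non-oscillating, logged with a
machine-parseable reason code, and excluded from group means.
`group_compare()` runs the factorial genotype × treatment ANOVA with
Tukey HSD, gated by Shapiro–Wilk (residual normality) and Bartlett
(variance homogeneity); when a gate fails, the rank-based fallback
(Kruskal–Wallis with pairwise Wilcoxon, Holm-adjusted) is the reported
primary result.

### Generator defaults

The study protocol fixes the recording geometry (1 Hz, 150 s, stimulus
at 118 s) but not spontaneous rates or amplitudes; those defaults are
free parameters chosen once at field-typical values: basal rate
0.02 s⁻¹ (1.2 events/min), post-stimulus rate 0.1 s⁻¹, amplitudes
lognormal with median 0.8 ΔF/F₀, decay constant 6 s, trace noise SD
0.05 ΔF/F₀, 10% silent cells. They emulate sparse somatic astrocyte
transients with a clear CNO response; they do not emulate microdomain
events, photobleaching drift, or correlated network activity.

## 3. Minimal-stimulation synaptic analysis

### Parameters

With stimulation intensity calibrated near 50% failures / 50%
successes, each trial is summarized by its EPSC peak (stored as a
positive magnitude; the holding potential is −70 mV) and a success
call — peak above 3× the baseline noise SD by default
(`call_success()`; the criterion is configurable, and the generator's
ground-truth labels let the tests measure its accuracy, >99% at
potency 20 pA / noise 2 pA). `synaptic_params()` computes synaptic
efficacy (mean peak of all trials, failures included), potency (mean
peak of successes; undefined and flagged with zero successes), and
probability of release Pr (successes / trials). With failure peaks
exactly zero, efficacy $=$ Pr × potency identically; for real data
failures contribute their measured noise peak by default
(`failure_mode = "measured"`), and both modes are exposed.

### Stability and outcomes

`stability_qc()` marks a recording stable when series resistance,
input resistance, resting potential and stimulus-artifact duration all
stay within ±20% of their initial values — *more than* 20% fails, so
the boundary itself is stable. Unstable sessions are excluded from
outcome classification with a logged reason.

`classify_outcome()` compares five 1-min bins of basal efficacy
against the first five post-stimulus minutes (of the ten recorded) in
a paired t-test at $\alpha = 0.05$; a significant increase is
`potentiated`, a significant decrease `depressed`, otherwise
`unchanged`. Copied windows give differences of exactly zero, which is
reported as `unchanged` with $p = 1$ rather than a degenerate test
statistic. The per-synapse criterion is not stated in the source
protocol; a paired comparison over the stated statistical windows is
the package's design choice, and its operating characteristics are
measured, not assumed: across 200 simulated null sessions ≥90% are
called unchanged, and with release probability stepping 0.5 → 0.2 at
constant potency >90% are called depressed.

`efficacy_timecourse()` normalizes per-bin efficacy by the basal mean
(basal maps to 1; half-open bins, so a trial at exactly 60 s is in
bin 2), and `cohort_summary()` tallies outcome proportions as exact
fractions at two decimals — 7 of 13 is 53.85%, 6 of 14 is 42.86%.

### Generator defaults

0.5 Hz stimulation, 5 min basal / 10 min post (150 + 300 trials),
success peaks lognormal with median 20 pA, measurement noise 2 pA,
peaks clamped at zero. A warning (not an error) flags configurations
whose mean potency is within 3 noise SDs — formally valid but not an
identifiable success/failure regime. An optional multiplicative drift
exists solely to exercise the stability QC.

## 4. Numerical and design choices

- **Determinism.** Every generator takes a seed and restores the
  caller's RNG state; pipeline stages derive their seeds from one
  global seed, so identical seed + config reproduces simulation
  outputs bit-identically.
- **Coordinates.** Continuous µm; z increases downward from the
  preparation top; sections are half-open $[z_{top}, z_{top} + t)$;
  shrinkage acts along z only.
- **Degenerate inputs.** Zero density gives an empty field; an all-zero
  disector tally gives $N_v = 0$, while zero corner points is an error
  (undefined density); empty input files fail before any output is
  written.
- **Problem sizes.** Validation uses 200-replicate Monte-Carlo checks
  for unbiasedness and recovery and 500 traces for false-positive
  rates; these sizes put 3-standard-error bands well inside the effect
  sizes under test while keeping the whole suite under a minute of
  compute.

## 5. Known limitations

- The synthetic tissue and traces omit optics (PSF, depth attenuation),
  neuropil background, biophysical Ca²⁺ dynamics and conductance-based
  synapses — deliberately: ground truth must be exact for the
  estimators to be testable.
- $F_0$ estimated from the 0–20 s window is biased upward when a large
  transient occupies most of that window; the robust clip bounds but
  does not eliminate this, and detected amplitudes on such cells are
  correspondingly compressed.
- Event detection at 1 Hz cannot resolve transients closer than a few
  samples; overlapping events merge, and the fidelity tests therefore
  use resolvable (well-separated) events.
- Outcome classification with five bin pairs has limited power for
  small efficacy changes; it is calibrated for the step sizes the
  protocol targets.
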