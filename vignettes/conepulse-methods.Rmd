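---
title: "Methods: simulating and analysing Taylor-cone pulsation against MS ion current"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Taylor-cone pulsation against MS ion current}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

In a pulsating electrospray the liquid meniscus at the emitter tip forms and
collapses a Taylor cone at roughly 1--2 kHz, and charged droplets are emitted
only while the cone is present. If a mass spectrometer could register that
structure, cone-resolved gating should raise sensitivity. `conepulse`
implements the complete measurement and analysis pipeline for the question
"does Taylor-cone presence correlate with the recorded MS ion current?" as an
executable model: a synthetic-data generator that plays the role of the
high-speed camera, Faraday plate and mass spectrometer, the image classifier,
the correlation and frequency analyses, and a forward model of the
ion path whose carryover and duty-cycle parameters explain why the measured
correlation can be null even though emission is strictly cone-locked.

# The generative model

## Emission

All signals derive from one continuous-time emission process per run
(`generate_emission_train()`). In the pulsating regime the phase
$\phi(t) = f t$ advances at the preset pulsation frequency $f$; cycle $i$
has the cone present for a fraction $d_i$ of its period and emits flux

$$ q(t) = 2 A_i \sin^2\!\left(\pi\, \mathrm{frac}(\phi)/d_i\right), \qquad
   \mathrm{frac}(\phi) < d_i, $$

so that the cycle-averaged flux is $A_i d_i$ and flux is strictly zero while
the cone is absent. Duty and amplitude are jittered cycle-to-cycle
($d_i \sim N(0.5, 0.15^2)$ clipped to $[0.05, 0.95]$;
$A_i \sim N(1, 0.2^2)$ clipped at 0). These two dispersions are the
generator's realism knobs: they were fixed once, at design time, to produce
the per-bin occupancy spread seen in real pulsating sprays (roughly 30--70%
within 4 ms bins) while keeping per-bin emitted charge an imperfect rank
proxy of occupancy -- real sprays vary in droplet size and charge, so equal
cone time does not imply equal delivered charge. Because the cycle tables
are drawn once per run, the train is an analytic function of time and can be
re-sampled exactly at camera or oscilloscope timestamps; identical seeds give
bit-identical data.

The voltage map (`make_preset()`) follows the classical mode ladder: below
the 2.22 kV onset threshold nothing sprays; between threshold and 3 kV the
source is in burst mode, modelled as Poisson-random isolated discharges
(default 20 s$^{-1}$, 1 ms wide, 50% amplitude jitter, peak flux 20x the
pulsating amplitude -- an isolated burst releases charge accumulated between
events, which is what makes the recorded "sporadic spikes" spike); from
3 to 5 kV the pulsating regime uses a voltage-to-frequency table
(1.6--2.0 kHz, including the characteristic frequency drop between 3.5 and
4.0 kV attributed to the approaching cone-jet transition); above 5 kV the
model degenerates to a steady cone-jet. The reference-line offset is also
voltage-dependent (30--50 px, 40 px at 4.0 kV) because lower voltages
elongate the cone.

## Imaging and detection

`render_shadowgraph_stack()` draws each frame at its timestamp: a dark
capillary silhouette on a bright background and, when the cone is present,
an isoceles triangle of half-angle 49.3 degrees (the Taylor angle) whose
length exceeds the reference-line offset by 10 px, so a present cone always
crosses the line. Gaussian pixel noise (default sd 5 of 255) is seeded per
(frame, column), which makes lazily rendered sub-regions bit-identical to
fully rendered frames; a 30 s acquisition at 5000 fps (150,000 frames of
256 x 256 px, ~10 GB of pixels) is therefore never materialised -- the
classifier renders only the 120-px reference line, in chunks.

Detection (`analyze_stack()`) is deliberately primitive, mirroring what a
real-time loop can afford: extract the 120-row column at
`tip_x + offset`, count pixels strictly below the intensity threshold
(default 128), call the cone present when the count reaches the count
threshold (default 10; the boundary count classifies as present). Both
thresholds are explicit configuration -- the classifier never learns them
from data -- and raising either is monotone in the obvious direction, which
the test suite checks. The emitter-tip anchor is always explicit input;
`propose_tip()` can suggest one but is never applied silently.

## The signal chain

The path from emission to a recorded SIM intensity (`ms_chain` functions) is

1. **plume gate** (`apply_gate()`): transmission 1 when the RE3 electrode is
   de-energised, 0 when energised; the cone state is untouched because the
   gate is downstream of the emitter;
2. **transit + carryover** (`transit_mixing()`): a pure delay (default 1 ms,
   the droplet time-of-flight to the gate) followed by convolution with a
   causal exponential kernel of time constant $\tau$ (default 5 ms),
   normalised to unit area. The kernel is the simplest model of ion packets
   blending in the atmospheric interface and ion guides; $\tau = 5$ ms makes
   the blending span more than one acquisition event. Sinusoidal modulation
   at frequency $f$ is attenuated by $|1 + 2\pi i f \tau|^{-1}$ (about 60x
   at 1.92 kHz), which the tests verify against the closed form;
3. **SIM sampling** (`sample_sim_events()`): one intensity per 4 ms event,
   integrating arrival flux only over the first 0.8 ms (the dwell); the
   remaining 3.2 ms of each event is dead time. Gaussian detector noise
   (default sd 25 at gain $10^5$, i.e. roughly 60% of the mean single-event
   intensity) is added and intensities clip at zero. Sub-millisecond SIM
   events count few ions, so large relative noise is the realistic default,
   and it matters: it is one of the three legs (with carryover and duty
   cycle) on which the null result stands.

The implementation works on the train's 10 us grid; the recursive-filter
form of the exponential kernel conserves integrated flux exactly in the
interior and loses only the $(\text{delay} + \tau)$-sized edges.

# The analyses

**Occupancy and shift scan.** Presence is binned per 20 frames (4 ms at
5000 fps, matching the MS event period); trailing partial bins are
discarded. Spearman's rho is computed explicitly as the Pearson correlation
of average-ranked data so tie handling is visible; constant inputs yield a
flagged `NA`, never 0, so zero-signal voltages cannot fabricate
correlations. `shift_scan()` slides the occupancy series over -2..+10 ms in
0.2 ms steps (the step is the instrument convention; the range covers the
~1 ms transit plus instrument lag) and pairs each shifted bin with the
nearest MS event -- nearest-event matching rather than interpolation,
because intensities are event integrals, not samples of a smooth curve.
Consequently the scan resolves time offsets only to within half an event
(2 ms), which is as sharp as the data can support.

**Null result and mechanism.** `run_null_replicates()` repeats the full
gated 30 s experiment over the pulsating presets and nine seeds and reports
the maximum $|\rho|$ over all shifts per run; with the default chain every
run stays inside $(-0.2, 0.2)$. That this is a property of the chain and
not of the statistic is shown by the idealised counterpart
(`sample_arrival_continuous()`): with $\tau = 0$, no detector noise and
100% duty cycle, the same generator yields $\rho > 0.5$ at the
transit-delay shift. The mechanism check uses a transit delay of 8 ms --
a whole number of events -- so that the shift grid can align the two series
exactly; with the default fractional-event delay (1 ms) part of the
correlation is lost to bin misalignment rather than to the chain, which
would muddy the attribution. A three-point ladder (full duty/no mixing,
default dwell with $\tau$ = 5 ms, $\tau$ = 20 ms) verifies that growing
dead time and carryover monotonically erase $|\rho|$.

**Frequency agreement.** For the offline configuration (1 s at 50,000 fps
imaging plus 20 us current sampling, both driven by one train), spectra are
computed on mean-subtracted, Hann-windowed traces; the peak is searched
above 100 Hz to exclude drift, ties break toward lower frequency, and no
sub-bin interpolation is applied by default (published values carry "~", so
bin precision -- 1 Hz at these settings -- suffices). Peak location is
window-invariant for isolated peaks. When a peak lands within one bin of
Nyquist, or a channel's rate is below twice the preset frequency,
an undersampling warning fires: that is precisely why the online 5000 fps
data is binned into occupancy rather than Fourier-analysed (1.92 kHz is
within 25% of the 2.5 kHz Nyquist limit).

**RTC simulation.** `run_rtc_trial()` classifies frames in stream order and
opens the gate once, `set_delay + loop_latency (+ truncated Gaussian
jitter)` after the first frame satisfying the condition; the run yields a
single intensity, defined as the maximum event intensity among events
overlapping the gated packet's arrival window (gate opening + transit
through gate closure + transit + $5\tau$) -- the instrument's internal
packet bookkeeping is unpublished, and the maximum is robust to how the
packet straddles event boundaries. `calibrate_delay()` is ordinary least
squares of elapsed time on set delay; with zero jitter the fit is exact and
the intercept recovers the 0.44 ms loop latency identically.
`compare_conditions()` adds a percentile bootstrap interval for the
positive-negative mean difference, making "nearly identical intensities"
a testable statement rather than an error-bar impression. The gate-opening
latency (1.44 ms at the default 1 ms set delay) spans ~3 pulsation cycles,
so the cone phase at gate opening is fully scrambled and the model predicts
indistinguishable positive and negative intensities by construction.

# Numerical and design choices

* Time is seconds everywhere internally; ms/kHz appear only at interfaces.
  Pixel coordinates are 0-based, origin top-left, x along the spray axis.
* Emission grid 10 us; ratios event/dt and dwell/dt are integral, so event
  integrals are cumulative-sum differences with no quadrature error.
* The recursive exponential filter requires dt much smaller than $\tau$ and
  refuses to run otherwise; $\tau = 0$ degenerates to a pure delay.
* Degenerate inputs are defined, not accidental: zero-duration trains are
  empty, empty stacks give empty traces, constant series give flagged `NA`
  rho, all-closed gates zero the flux, sub-3-pair shifts are `NA`.
* Reference-line rows are the 120 rows centred on `tip_y` (from
  `tip_y - 60` to `tip_y + 59`); geometry that leaves the frame is an error
  carrying the frame index.
* RNG discipline: every public generator takes a seed; compound experiments
  derive sub-seeds (+1 pixel noise, +2 detector noise/jitter, +3 MS noise)
  so channels are independent but jointly reproducible.

# Problem sizes

The shipped checks run the experiment at its native scale where the claim
depends on it: the null-result and frame-accounting checks use full 30 s
acquisitions at 5000 fps (150,000 frames, 7,500 events) for five presets
and nine seeds; the frequency check uses 1 s at 50,000 fps. Unit and
property tests use 0.002--10 s acquisitions, which exercise identical code
paths thanks to the lazy renderer.

# What the generator does and does not emulate

It emulates the statistical structure the analyses assume: cone-locked
emission, voltage-dependent mode and frequency (including the 3.5 to 4.0 kV
frequency drop), shot-to-shot variability of duty and amplitude, shadowgraph
geometry with additive sensor noise, oscilloscope sampling, SIM dwell/event
timing, and gate scheduling. It does not model electrohydrodynamics (cone
shapes are a fixed triangle, not a solution of the field equations), droplet
fission or ionisation mechanisms, space-charge or ion-optical focusing
(treated as unit transmission), flicker in illumination, or motion blur
within an exposure. Passing tests therefore demonstrate that the analysis
chain behaves correctly and that the proposed carryover + duty-cycle +
noise mechanism suffices to produce the null on realistic inputs -- they do
not prove that mechanism is the one operating in any particular instrument.

# Known limitations

* The carryover kernel is a single exponential; real interfaces may need a
  mixture of time constants or a flow-dependent kernel.
* Spearman's rho on overlapping nearest-event pairs ignores serial
  correlation within each series; the scan is used for bounding and
  localisation, not for p-values.
* The RTC "single signal per run" convention (maximum event in the arrival
  window) is one of several defensible choices; sums over the window behave
  similarly but scale differently with $\tau$.
* `run_rtc_trial()` renders and classifies frames honestly but generates
  the emission train for the whole timeout window up front; extremely long
  timeouts cost memory proportional to their duration.
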