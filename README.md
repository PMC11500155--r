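# conepulse

Does Taylor-cone formation in a pulsating electrospray show up in the mass
spectrometer's ion current? In the pulsating regime an electrospray meniscus
forms and collapses its cone at ~1–2 kHz, and charged droplets leave only
while the cone is present — so one might expect per-event MS intensities to
track the fraction of time the cone was up. `conepulse` is an R package for
researchers in ESI-MS instrumentation who want to run, replicate, or stress
that analysis: it pairs high-speed shadowgraph image analysis with
selected-ion-monitoring (SIM) traces, and ships a synthetic-data generator
plus a forward model of the ion path that reproduces — and explains — the
counterintuitive null result.

## What it computes

* **Cone detection** — the reference-line classifier: extract a 120-px
  vertical line at a voltage-dependent offset (30–50 px; 40 px at 4.0 kV)
  in front of the emitter tip, count pixels darker than an intensity
  threshold, and call the cone present when the count reaches a count
  threshold. Runs lazily over 150,000-frame acquisitions.
* **Occupancy / intensity correlation** — presence binned per 20 frames
  (4 ms, matching the SIM event period) into occupancy percentages, then
  Spearman's

  ρ(s) = corr(rank occupancy(t), rank intensity(t + s))

  scanned over time shifts s = −2 … +10 ms in 0.2 ms steps, with ties
  average-ranked and constant series flagged `NA`.
* **Ion-path forward model** — plume gate (transmission 0/1), droplet
  transit delay (1 ms), carryover as a causal exponential kernel
  (τ = 5 ms; modulation at frequency f attenuated by |1 + 2πifτ|⁻¹), and
  SIM sampling that integrates only 0.8 ms of every 4 ms event, plus
  detector noise. With these defaults every shift scan stays inside
  |ρ| < 0.2; switch the chain off (τ = 0, full duty, no noise) and the same
  generated data gives ρ > 0.5 — the null belongs to the chain, not the
  statistic.
* **Real-time control (RTC) simulation** — stream-order classification
  triggers a 1 ms gate opening after a set delay plus the 0.44 ms loop
  latency; OLS of elapsed time on set delay recovers the latency as the
  intercept, and a bootstrap interval tests whether cone-positive and
  cone-negative gating give distinguishable intensities (they do not).
* **Frequency agreement** — FFT peak of the per-frame black-pixel trace
  (1 s at 50,000 fps) versus the spray-current trace (20 µs sampling):
  both channels peak at the preset pulsation frequency (~1.92 kHz at
  4.0 kV) within one FFT bin.

Real acquisitions enter through `read_frame_stack()` (PNG sequence,
multi-page TIFF, raw 8-bit + sidecar, including the 100-frames-per-merged-
image camera convention) and `read_trace_csv()` (oscilloscope exports).

## Worked example

```r
library(conepulse)

preset <- make_preset(4.0)
preset
#> <spray_preset> 4 kV, mode = pulsating
#>   pulsation: 1.92 kHz, duty 0.5 (jitter sd 0.15)
#>   reference-line offset: 40 px; emission amplitude: 1

# emission -> shadowgraph frames -> classifier -> occupancy,
# and emission -> gate -> carryover -> SIM events, from one train
exp <- run_gated_experiment(preset, duration = 2, seed = 1)
exp
#> <gated_experiment> 4 kV, 2 s at 5000 fps
#>   500 occupancy bins / 500 MS events

shift_scan(exp$occupancy, exp$ms)
#> <shift_scan> 61 shifts (-2 .. 10 ms)
#>   max |rho| = 0.0966 at shift 2.2 ms (n = 499)

# coupled offline dataset: images at 50 kfps + current at 20 us
ds <- generate_offline_dataset(preset, duration = 1, seed = 1)
compare_channels(ds$cone_trace, ds$current, preset = preset)
#> <channel_comparison> image 1.92 kHz vs current 1.92 kHz; |delta f| = 1.92e-09 Hz (agree)
```

The shift scan says: even at the best time alignment, occupancy explains
essentially none of the event-to-event intensity ranking (|ρ| < 0.1 here,
never reaching 0.2 at any shift or voltage in the full replicate set) —
while the frequency comparison confirms the two channels are locked to the
same ~1.92 kHz oscillation, i.e. the imaging really does watch the process
that drives the current. Carryover smears sub-millisecond structure across
events, the 20% detection duty cycle discards most of each event, and
detector noise buries what remains.

A thin CLI wraps the same pipelines:

```sh
Rscript inst/cli/conepulse.R full-null-experiment --voltage 4.0 --seed 1 --out results/
Rscript inst/cli/conepulse.R spectra --voltage 4.0 --duration 1 --seed 1 --out results/
```

Every command writes its resolved config and seed next to its outputs.

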