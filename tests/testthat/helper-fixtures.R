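# Shared fixtures: small, built in code at test time.

preset4 <- make_preset(4.0)

default_geom <- function(offset = 40, ...) {
  detection_geometry(tip_x = 100, tip_y = 128, horizontal_offset = offset,
                     ...)
}

# Short synthetic acquisition; in-memory stack unless force_lazy.
small_stack <- function(duration = 0.05, seed = 3, noise_sd = 0,
                        frame_rate = 5000, force_lazy = FALSE) {
  train <- generate_emission_train(preset4, duration, seed = seed)
  settings <- acquisition_settings(frame_rate = frame_rate,
                                   duration = duration)
  stack <- render_shadowgraph_stack(
    train, settings, preset4, seed = seed + 1L, noise_sd = noise_sd,
    max_pixels_in_memory = if (force_lazy) 0 else 2e7)
  list(train = train, stack = stack, settings = settings)
}

# Plain frame with a dark emitter bar and optional cone column band.
flat_frame <- function(height = 256, width = 256, value = 255) {
  matrix(value, height, width)
}

# Ladder of RTC trials over set delays 0.2 .. 2.0 ms.
delay_ladder <- function(jitter_sd, reps, seed0 = 100) {
  trials <- list()
  for (d in seq(0.2e-3, 2e-3, by = 0.2e-3)) {
    for (r in seq_len(reps)) {
      trials[[length(trials) + 1]] <- run_rtc_trial(
        preset4,
        config = rtc_config("positive", set_delay = d,
                            latency_jitter_sd = jitter_sd, timeout = 0.5),
        seed = seed0 + length(trials))
    }
  }
  trials
}
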