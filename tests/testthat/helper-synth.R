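# Shared synthetic fixtures, generated once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

# 10-min two-channel recording with the default study conditions.
shared_synth <- function() {
  memo("synth", function() generate_recording(synth_spec(seed = 1)))
}

# Full pipeline run with fixed bands over S2 + SWS.
shared_run_fixed <- function() {
  memo("run_fixed", function() {
    g <- shared_synth()
    run_detection(g$recording, g$hypnogram,
                  spindle_config(band_mode = "fixed",
                                 stages = c("S2", "SWS")))
  })
}

# Full pipeline run with individually adjusted bands.
shared_run_auto <- function() {
  memo("run_auto", function() {
    g <- shared_synth()
    run_detection(g$recording, g$hypnogram,
                  spindle_config(band_mode = "auto",
                                 stages = c("S2", "SWS")))
  })
}

# Null-simulation of the genetic variance test (2000 replicates at the
# published group sizes), memoized because two suites assert on it.
shared_gva_type1 <- function() {
  memo("gva_type1", function() {
    rej <- 0L; done <- 0L
    for (r in 1:2000) {
      d <- generate_twin_dataset(twin_sim_spec(
        32, 14, var_genetic = 0, var_shared = 0.3, var_unique = 0.7,
        night_noise_sd = 0.1, seed = 10000 + r))
      g <- gva(d)
      if (g$prerequisites$passed) {
        done <- done + 1L
        if (g$genetic_p < 0.05) rej <- rej + 1L
      }
    }
    list(rate = rej / done, performed = done)
  })
}

# Background sigma-band SD under the default study conditions,
# measured on a spindle-free regeneration of the same background.
shared_sigma_sd <- function() {
  memo("sigma_sd", function() {
    g0 <- generate_recording(synth_spec(seed = 1, spindle_trains = list(),
                                        emg_bursts = list(band = c(20, 45),
                                                          sd = 15,
                                                          length = 2,
                                                          rate = 0)))
    bg <- resample_100hz(g0$recording)
    filt <- fir_design(c(10, 16), 100, "pass", 201)
    stats::sd(fir_apply(bg$data[1, ], filt))
  })
}
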