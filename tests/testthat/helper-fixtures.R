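# Shared fixtures. The small pipeline objects are memoised so several test
# files can reuse one generation/training run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Seconds-scale pipeline: 24x24 grid, 4 antennas, 2 frequencies, 120
# scenarios, 4 epochs.
small_pipeline <- function() {
  memo("small_pipeline", function() {
    cfg <- preset_config("fixture", seed = 42)
    cfg$n_samples <- 120L
    cfg$epochs <- 4L
    run_pipeline(cfg)
  })
}

# Desk-scale pipeline under the documented desk conditions (24x24 grid, 4
# antennas, 4 frequencies, 2,000 scenarios, 15 epochs, 40 dB). Built once
# and shared by the acceptance tests.
desk_pipeline <- function() {
  memo("desk_pipeline", function() {
    run_pipeline(preset_config("desk", seed = 42))
  })
}
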