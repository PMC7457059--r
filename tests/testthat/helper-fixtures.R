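# Shared fixtures, memoized so expensive solves run once per test session.

.fixtures <- new.env(parent = emptyenv())

canonical_lm <- function() {
  if (is.null(.fixtures$lm)) .fixtures$lm <- make_canonical_pelvis()
  .fixtures$lm
}

canonical_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_model(canonical_lm())
  .fixtures$model
}

# default battery on the canonical model (8 equilibrium solves)
canonical_battery <- function() {
  if (is.null(.fixtures$battery)) {
    .fixtures$battery <- run_battery(canonical_model())
  }
  .fixtures$battery
}

# three identical zero-operator-noise trials of the full battery
zero_noise_trials <- function() {
  if (is.null(.fixtures$zero_trials)) {
    .fixtures$zero_trials <- run_trials(
      canonical_lm(), operator_noise(sd = 0, seed = 1), n_trials = 3)
  }
  .fixtures$zero_trials
}

canonical_phantom <- function() {
  if (is.null(.fixtures$ct)) .fixtures$ct <- render_ct(canonical_lm())
  .fixtures$ct
}

canonical_segmentation <- function() {
  if (is.null(.fixtures$seg)) .fixtures$seg <- threshold_segment(canonical_phantom())
  .fixtures$seg
}
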