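# shared noise-free pipeline runs, computed once per test session
.pipeline_cache <- new.env(parent = emptyenv())
.validation_cache <- new.env(parent = emptyenv())

cached_validation <- function() {
  if (is.null(.validation_cache$rep)) .validation_cache$rep <- run_validation()
  .validation_cache$rep
}

cached_run <- function(name) {
  if (is.null(.pipeline_cache[[name]])) {
    sc <- builtin_scenarios()[[name]]
    run <- run_scenario(sc)
    est <- estimate_pressures(run$envelope, sc$cuff)
    .pipeline_cache[[name]] <- list(scenario = sc,
                                    recording = run$recording,
                                    envelope = run$envelope,
                                    estimate = est)
  }
  .pipeline_cache[[name]]
}

# envelope synthesised from the closed-form predicted amplitude
synth_envelope <- function(SBP, DBP, a, b, P = seq(40, 145, by = 1)) {
  P <- sort(P, decreasing = TRUE)              # deflation order
  envelope_from_beats(P, predicted_envelope(P, SBP, DBP, a, b))
}
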