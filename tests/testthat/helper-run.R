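# One trained end-to-end run shared by the tests that need a fitted deep
# survival pipeline (training takes a few minutes, so it is built once per
# test session and cached).

.run_cache <- new.env(parent = emptyenv())

get_trained_run <- function() {
  if (is.null(.run_cache$run)) {
    .run_cache$run <- run_pipeline(run_config(seed = 101), verbose = FALSE)
  }
  .run_cache$run
}
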