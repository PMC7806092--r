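# The end-to-end classification experiment is shared by several acceptance
# checks; run it once per test session.
.experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function() {
  if (!exists("res", envir = .experiment_cache)) {
    assign("res", classification_experiment(n_cycles = 50, seed = 4242),
           envir = .experiment_cache)
  }
  get("res", envir = .experiment_cache)
}
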