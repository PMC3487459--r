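# The standard-parameter screen over all four-locus topographies with 0-6
# LFGs is used by several acceptance checks; compute it once per test run.
.screen_cache <- new.env(parent = emptyenv())

standard_screen_0_6 <- function() {
  if (is.null(.screen_cache$screen)) {
    reps <- orbit_representatives(4, 0:6)
    .screen_cache$reps <- reps
    .screen_cache$screen <- screen_deterministic(
      reps$topographies, standard_param_grid(), weights = reps$sizes)
  }
  list(reps = .screen_cache$reps, screen = .screen_cache$screen)
}
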