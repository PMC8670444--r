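# share expensive press simulations across test files
.press_cache <- new.env(parent = emptyenv())

cached_press <- function(mu, ...) {
  key <- paste0("mu_", mu)
  if (is.null(.press_cache[[key]])) {
    p <- finger_params(mu = mu, ...)
    .press_cache[[key]] <- simulate_press(p)
  }
  .press_cache[[key]]
}

# small, fast synthetic trial configuration used by the pipeline tests
small_trial_config <- function(seed, alpha_um = 1e-3, ...) {
  args <- utils::modifyList(
    list(seed = seed, alpha_um = alpha_um, size_px = 96,
         pixel_resolution_mm = 0.05, frame_rate_hz = 8,
         peak_force_N = 4.5, duration_s = 1.2, force_rate_N_s = 4,
         force_rate_hz = 200),
    list(...))
  do.call(synth_config, args)
}
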