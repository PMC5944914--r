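# Shared fixtures: reduced parameters at the reference point of the phase
# diagram, and memoised Gillespie runs reused across test files.

red_marker <- function(f_ind = 0.23, eps = 0) {
  rescaled_params(n = 0.8, g = 0.1, f_ind = f_ind, eps = eps, k_c = 1)
}

.sim_cache <- new.env(parent = emptyenv())

cached_run_1d <- function(scheme, T = 2500, seed = 100 + scheme, ...) {
  key <- paste("s", scheme, T, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_cargo_1d(
      scheme, table1_params(paste0("process", scheme)), T = T, seed = seed, ...)
  }
  .sim_cache[[key]]
}

cached_run_2d <- function(r, T = 1500, seed = 7) {
  key <- paste("r", r, T, seed, sep = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_cargo_2d(r, T = T, seed = seed)
  .sim_cache[[key]]
}

# independent transcription of the acceleration field used as an
# arithmetic oracle (kept deliberately separate from q_eval)
q_oracle <- function(x, v, n, g, f_ind, k_c, eps) {
  s <- if (eps > 0) tanh(x / eps) else sign(x)
  base <- k_c * (n * sinh(v / f_ind) - 2 * (v + g * s) * cosh(v / f_ind))
  if (eps > 0) base - v * (g / eps) * (1 / cosh(x / eps))^2 else base
}
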