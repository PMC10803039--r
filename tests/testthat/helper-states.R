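# deterministic pseudo-random states for property-style tests
random_state <- function(params, seed) {
  set.seed(seed)
  g <- params$geometry
  st <- initial_state(params)
  st$pools[] <- runif(6, 0, 0.4)
  st$fields[] <- matrix(runif(g$n_cells * 8, 0, 0.3), g$n_cells, 8)
  st
}

tiny_params <- function(...) {
  default_params(n_cells = 12, pole_width = 0.5, ...)
}
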