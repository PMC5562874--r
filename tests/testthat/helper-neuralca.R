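# shared fixtures: the standard Mexican-hat kernel and parameter sets
std_spec <- function(...) kernel_spec(...)

det_params <- function(kappa = 30, h = 1, spec = std_spec()) {
  model_params(kappa = kappa, beta = Inf, h = h, p = 1, kernel = spec)
}

# random three-state configuration
random_state <- function(N, L = pi) {
  lattice_state(sample(c(-1L, 0L, 1L), N, replace = TRUE), L)
}
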