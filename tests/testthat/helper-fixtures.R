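# Small builders shared across the test files. Everything is generated in
# code; no stored fixtures.

# single uncoupled oscillator with excitability eta (no noise)
single_neuron_state <- function(eta, params = NULL) {
  if (is.null(params))
    params <- network_params(N = 1L, n_exc = 1L, n_hebb = 0L, n_anti = 0L,
                             noise_sigma = 0)
  st <- init_network(params, "zero", seed = 1)
  st$eta <- eta
  st$V <- params$Vr
  st
}

# raster data frame from vectors
make_raster <- function(time, neuron) data.frame(time = time, neuron = neuron)

# deterministic two-neuron network with decoupled dynamics (g = 0) but
# plastic weights, for replaying spikes through the R plasticity path
two_neuron_params <- function() {
  network_params(N = 2L, n_exc = 2L, n_hebb = 0L, n_anti = 0L,
                 ge = 0, ghi = 0, gai = 0, noise_sigma = 0)
}

default_assignment <- function(M = 2) {
  population_assignment(network_params(), M)
}
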