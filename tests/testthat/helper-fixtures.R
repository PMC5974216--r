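# Shared fixtures: the standard microcircuit neuron parameters and a few
# canned inputs.  Everything is generated in code; no data files.

std_params <- function() neuron_params()

# fixed Poisson input realization on the 0.1 ms grid
fixed_input <- function(rate = 8000, h = 0.1, duration = 1000, seed = 7) {
  generate_grid_poisson(rate, h, duration, seed)
}

# a tiny two-population network spec for engine-level tests
tiny_net_spec <- function(drive = "poisson", N = 40L) {
  pops <- list(
    population_spec("E", N,
                    nu_ext = if (drive == "poisson") 9000 else NULL,
                    I_DC = if (drive == "dc") 0.45 else NULL),
    population_spec("I", N %/% 2L,
                    nu_ext = if (drive == "poisson") 9000 else NULL,
                    I_DC = if (drive == "dc") 0.45 else NULL))
  proj <- list(
    projection_spec("E", "E", p = 0.1, weight_mean = 0.0878,
                    weight_sd = 0.00878, sign = "excitatory",
                    delay_mean = 1.5, delay_sd = 0.75),
    projection_spec("E", "I", p = 0.1, weight_mean = 0.0878,
                    weight_sd = 0.00878, sign = "excitatory",
                    delay_mean = 1.5, delay_sd = 0.75),
    projection_spec("I", "E", p = 0.2, weight_mean = 0.3512,
                    weight_sd = 0.03521, sign = "inhibitory",
                    delay_mean = 0.75, delay_sd = 0.375),
    projection_spec("I", "I", p = 0.2, weight_mean = 0.3512,
                    weight_sd = 0.03521, sign = "inhibitory",
                    delay_mean = 0.75, delay_sd = 0.375))
  network_spec(pops, proj)
}
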