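# small-network parameter/protocol fixtures used across test files

small_params <- function(...) {
  network_params(N_e = 60L, N_i = 20L, ...)
}

short_protocol <- function(t_total = 400, t_step = 200, seed = 1L, ...) {
  protocol(t_total = t_total, t_step = t_step, burn_in = 100,
           measure_window = min(200, t_total - t_step), seed = seed, ...)
}

# hand-built raster: spikes is a list of step-index vectors per E cell
toy_raster <- function(spikes_e, spikes_i = list(), n_steps = 1000, dt = 1) {
  eistim:::new_spike_raster(e = spikes_e, i = spikes_i,
                            n_steps = n_steps, dt = dt)
}

# decoupled network (all weights zero) for single-cell oracles
decoupled_params <- function(D, N = 50L, ...) {
  network_params(N_e = N, N_i = N, w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0,
                 I_e = 0, I_i = 0, D = D, ...)
}
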