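#' Simulate the stochastic E-I spiking network
#'
#' Euler-Maruyama integration of the coupled membrane equations with per-step
#' Bernoulli spiking. Each step of size `dt` (converted to seconds once)
#' updates, per cell,
#'
#' `u <- u + (a dt) (-u + syn + I + I_o(t) + S(t)) + sqrt(2 D (a dt)) z`
#'
#' where `z` is an independent standard normal per cell per step, `syn` is the
#' population-normalized weighted spike count of the previous step
#' (`w_ee/N_e * n_E + w_ie/N_i * n_I` for excitatory cells, analogously with
#' `w_ei`, `w_ii` for inhibitory cells; the inhibitory weights carry their
#' sign), the tonic terms `I_e + I_o(t)` enter the excitatory equation only,
#' `I_i` the inhibitory one, and the global stimulus `S(t)` enters both. A
#' spike is then emitted with probability `f[u]` (the sharp sigmoid) and
#' contributes exactly 1 to the next step's synaptic count, so that the
#' time-average of a cell's spike train equals the time-average of `f[u]`
#' (diffusion approximation). The noise increment is scaled so that a
#' decoupled cell's stationary membrane variance equals `D` in both
#' populations (deviations per membrane time constant; see the vignette).
#'
#' Initial membrane values are drawn from the stationary deviation law
#' N(0, D). Runs are bitwise reproducible for a fixed protocol seed.
#'
#' @param params a [network_params()] object.
#' @param protocol a [protocol()] object; its seed drives all randomness
#'   (cells and, unless the spec carries its own seed, the stimulus).
#' @param stim a [stimulus_spec()]; default none.
#' @param keep_cell_traces logical; retain per-cell membrane traces (memory
#'   permitting, see `max_trace_mb`). Population means are always retained.
#' @param max_trace_mb cap (MiB) on the estimated size of per-cell traces.
#' @param u0 optional initial membrane value(s), recycled over all cells of
#'   both populations; by default cells start from the stationary deviation
#'   law N(0, D).
#' @return An object of class `sim_result` with elements `u_e_mean`,
#'   `u_i_mean` (per-step population means), `counts_e`, `counts_i` (per-step
#'   spike counts), `raster` (a `spike_raster`), `stimulus` (the compiled
#'   `stimulus_trace`), `params`, `protocol`, `seed`, and optionally `u_e`,
#'   `u_i` (cells x steps matrices).
#' @examples
#' p <- network_params(N_e = 40L, N_i = 10L)
#' r <- simulate_network(p, protocol(t_total = 300, t_step = 150, burn_in = 50,
#'                                   measure_window = 100, seed = 1))
#' mean_firing_rate(r$raster, "e", c(150, 300))
#' @export
simulate_network <- function(params, protocol, stim = stimulus_spec("none"),
                             keep_cell_traces = FALSE, max_trace_mb = 512,
                             u0 = NULL) {
  validate_network_params(params)
  dt_ms <- params$dt
  dt <- dt_ms / 1000
  if (dt * max(params$a_e, params$a_i) >= 1)
    stop("explicit scheme unstable: need dt * a < 1")
  n_steps <- round(protocol$t_total / dt_ms)
  Ne <- params$N_e; Ni <- params$N_i

  if (keep_cell_traces) {
    est_mb <- (Ne + Ni) * n_steps * 8 / 2^20
    if (est_mb > max_trace_mb)
      stop(sprintf("per-cell traces would need ~%.0f MiB (cap %g); population means are always kept",
                   est_mb, max_trace_mb))
  }

  stim_seed <- if (!is.null(stim$seed)) stim$seed else protocol$seed + 1000003L
  strace <- compile_stimulus(stim, n_steps, dt_ms, rng_seed = stim_seed)
  S <- strace$values

  set.seed(protocol$seed)
  he <- params$a_e * dt
  hi <- params$a_i * dt
  noise_e <- sqrt(2 * params$D * he)
  noise_i <- sqrt(2 * params$D * hi)
  if (is.null(u0)) {
    u_e <- stats::rnorm(Ne, 0, sqrt(params$D))
    u_i <- stats::rnorm(Ni, 0, sqrt(params$D))
  } else {
    u_e <- rep_len(u0, Ne)
    u_i <- rep_len(u0, Ni)
  }

  step_idx <- ceiling(protocol$t_step / dt_ms)  # first step at/after t_step
  io_vec <- ifelse((seq_len(n_steps) - 1) * dt_ms >= protocol$t_step,
                   protocol$Io_post, protocol$Io_pre)

  u_e_mean <- numeric(n_steps); u_i_mean <- numeric(n_steps)
  counts_e <- integer(n_steps); counts_i <- integer(n_steps)
  rast_e <- matrix(FALSE, Ne, n_steps)
  rast_i <- matrix(FALSE, Ni, n_steps)
  if (keep_cell_traces) {
    tr_e <- matrix(0, Ne, n_steps); tr_i <- matrix(0, Ni, n_steps)
  }
  n_spk_e <- 0L; n_spk_i <- 0L

  for (k in seq_len(n_steps)) {
    syn_e <- params$w_ee * n_spk_e / Ne + params$w_ie * n_spk_i / Ni
    syn_i <- params$w_ei * n_spk_e / Ne + params$w_ii * n_spk_i / Ni
    u_e <- u_e + he * (-u_e + syn_e + params$I_e + io_vec[k] + S[k]) +
      noise_e * stats::rnorm(Ne)
    u_i <- u_i + hi * (-u_i + syn_i + params$I_i + S[k]) +
      noise_i * stats::rnorm(Ni)
    sp_e <- stats::runif(Ne) < firing_prob(u_e, params)
    sp_i <- stats::runif(Ni) < firing_prob(u_i, params)
    n_spk_e <- sum(sp_e); n_spk_i <- sum(sp_i)
    counts_e[k] <- n_spk_e; counts_i[k] <- n_spk_i
    u_e_mean[k] <- mean(u_e); u_i_mean[k] <- mean(u_i)
    rast_e[, k] <- sp_e; rast_i[, k] <- sp_i
    if (keep_cell_traces) { tr_e[, k] <- u_e; tr_i[, k] <- u_i }
  }

  raster <- new_spike_raster(
    e = lapply(seq_len(Ne), function(j) which(rast_e[j, ])),
    i = lapply(seq_len(Ni), function(j) which(rast_i[j, ])),
    n_steps = n_steps, dt = dt_ms)

  out <- list(u_e_mean = u_e_mean, u_i_mean = u_i_mean,
              counts_e = counts_e, counts_i = counts_i,
              raster = raster, stimulus = strace,
              params = params, protocol = protocol, seed = protocol$seed)
  if (keep_cell_traces) { out$u_e <- tr_e; out$u_i <- tr_i }
  structure(out, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  n <- x$raster$n_steps
  cat(sprintf("sim_result: %d E + %d I cells, %d steps of %g ms (seed %d)\n",
              x$params$N_e, x$params$N_i, n, x$raster$dt, x$seed))
  cat(sprintf("  total spikes: %d E, %d I; stimulus: %s\n",
              sum(x$counts_e), sum(x$counts_i), x$stimulus$spec$family))
  invisible(x)
}

new_spike_raster <- function(e, i, n_steps, dt) {
  structure(list(e = e, i = i, n_steps = n_steps, dt = dt),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d E cells (%d spikes), %d I cells (%d spikes), %d steps\n",
              length(x$e), sum(lengths(x$e)), length(x$i), sum(lengths(x$i)),
              x$n_steps))
  invisible(x)
}

# step indices covering the half-open time window [t0, t1) in ms
window_steps <- function(window, dt, n_steps) {
  if (length(window) != 2 || window[2] <= window[1]) stop("window must be (t0, t1) with t1 > t0")
  k0 <- max(1L, floor(window[1] / dt) + 1L)
  k1 <- min(n_steps, ceiling(window[2] / dt))
  if (k0 > k1) stop("window lies outside the simulation")
  seq.int(k0, k1)
}

#' Population- and time-averaged membrane activity
#'
#' Averages the per-step population-mean membrane traces over a time window,
#' giving the mean membrane activity of each population.
#'
#' @param result a `sim_result`.
#' @param window `(t0, t1)` in ms, inside the simulation.
#' @return Named vector `c(u_e = ..., u_i = ...)`.
#' @export
population_mean_traces <- function(result, window) {
  ks <- window_steps(window, result$raster$dt, result$raster$n_steps)
  c(u_e = mean(result$u_e_mean[ks]), u_i = mean(result$u_i_mean[ks]))
}

#' Export a spike raster as TSV
#'
#' Three columns: `cell_id`, `population`, `spike_time_ms`.
#'
#' @param raster a `spike_raster`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_raster_tsv <- function(raster, file) {
  rows <- rbind(
    data.frame(cell_id = rep(seq_along(raster$e), lengths(raster$e)),
               population = "e",
               spike_time_ms = (unlist(raster$e) - 1) * raster$dt),
    data.frame(cell_id = rep(seq_along(raster$i), lengths(raster$i)),
               population = "i",
               spike_time_ms = (unlist(raster$i) - 1) * raster$dt))
  utils::write.table(rows, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export population traces as CSV
#'
#' Columns `time_ms`, `u_e_mean`, `u_i_mean`, `stimulus`.
#'
#' @param result a `sim_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_traces_csv <- function(result, file) {
  utils::write.csv(data.frame(
    time_ms = (seq_along(result$u_e_mean) - 1) * result$raster$dt,
    u_e_mean = result$u_e_mean,
    u_i_mean = result$u_i_mean,
    stimulus = result$stimulus$values), file, row.names = FALSE)
  invisible(file)
}
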