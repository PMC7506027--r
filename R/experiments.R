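#' Stimulation period grid (ms)
#'
#' The non-uniform period list used for frequency sweeps, sampling 1-200 Hz:
#' 1000, 500, 300 down to 100 by 25, 90 down to 50 by 10, 45 down to 30 by 5,
#' 28 down to 20 by 2, and 19 down to 5 by 1 ms.
#'
#' @return Numeric vector of periods (ms), decreasing.
#' @export
methods_period_grid <- function() {
  c(1000, 500, seq(300, 100, by = -25), seq(90, 50, by = -10),
    seq(45, 30, by = -5), seq(28, 20, by = -2), seq(19, 5, by = -1))
}

# derived per-run seed; kept well below 2^31
derive_seed <- function(base_seed, ...) {
  idx <- c(...)
  s <- as.double(base_seed) %% 1e6
  for (j in seq_along(idx)) s <- (s * 131 + idx[j] * 7919) %% 2147483629
  as.integer(s) + 1L
}

#' Run a transition experiment
#'
#' Simulates the network while the tonic excitatory drive steps from
#' `Io_pre` to `Io_post` at `t_step`, with an optional stimulation waveform
#' applied continuously before and after the step, and reports pre/post spike
#' coherence, pre/post population firing rates and mean membrane activities.
#' The pre window is `[burn_in, t_step)`; the post window is the final
#' `measure_window` ms of the run.
#'
#' @param params a [network_params()] object.
#' @param protocol a [protocol()] object.
#' @param stim a [stimulus_spec()].
#' @param coh a [coherence_config()].
#' @return List with `sim` (the `sim_result`) and `metrics` (a one-row data
#'   frame: `coh_pre`, `coh_post`, `rate_e_pre`, `rate_e_post`, `rate_i_pre`,
#'   `rate_i_post`, `u_e_post`, `u_i_post`, `seed`).
#' @export
run_transition <- function(params, protocol, stim = stimulus_spec("none"),
                           coh = coherence_config()) {
  sim <- simulate_network(params, protocol, stim)
  pre <- c(protocol$burn_in, protocol$t_step)
  post <- c(protocol$t_total - protocol$measure_window, protocol$t_total)
  m <- data.frame(
    coh_pre = spike_coherence(sim$raster, coh, pre),
    coh_post = spike_coherence(sim$raster, coh, post),
    rate_e_pre = mean_firing_rate(sim$raster, "e", pre),
    rate_e_post = mean_firing_rate(sim$raster, "e", post),
    rate_i_pre = mean_firing_rate(sim$raster, "i", pre),
    rate_i_post = mean_firing_rate(sim$raster, "i", post),
    u_e_post = population_mean_traces(sim, post)[["u_e"]],
    u_i_post = population_mean_traces(sim, post)[["u_i"]],
    seed = protocol$seed)
  list(sim = sim, metrics = m)
}

#' Sweep the intrinsic noise variance
#'
#' Repeats the transition experiment over a set of intrinsic noise variances
#' `D` and replicate seeds, reporting replicate-level metrics and a summary of
#' the post-step coherence and rate jump against `D`. Optionally pairs each
#' `D` with its mean-field multistable interval.
#'
#' @param params a [network_params()] object (its `D` is overridden).
#' @param protocol a [protocol()] object (its seed is the base seed).
#' @param D_values intrinsic noise variances to test.
#' @param n_reps replicates per noise level.
#' @param coh a [coherence_config()].
#' @param meanfield also compute the multistable interval per `D`.
#' @param drive_grid drive grid for the mean-field pairing.
#' @return List with `replicates` (data frame) and `summary` (one row per
#'   `D`: mean post coherence, mean rate jumps, interval width).
#' @export
run_noise_sweep <- function(params, protocol,
                            D_values = c(0.005, 0.010, 0.025, 0.05),
                            n_reps = 3, coh = coherence_config(),
                            meanfield = TRUE,
                            drive_grid = seq(0, 0.12, by = 0.002)) {
  rows <- list()
  for (di in seq_along(D_values)) {
    p <- params; p$D <- D_values[di]
    for (rep in seq_len(n_reps)) {
      pr <- protocol
      pr$seed <- derive_seed(protocol$seed, di, rep)
      m <- run_transition(p, pr, coh = coherence_config(coh$bin_ms, coh$n_pairs,
                                                        derive_seed(coh$seed, di, rep)))$metrics
      m$D <- D_values[di]; m$rep <- rep
      rows[[length(rows) + 1L]] <- m
    }
  }
  reps <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(D_values, function(D) {
    sub <- reps[reps$D == D, ]
    data.frame(D = D,
               coh_post = mean(sub$coh_post),
               coh_post_se = stats::sd(sub$coh_post) / sqrt(nrow(sub)),
               rate_e_jump = mean(sub$rate_e_post - sub$rate_e_pre),
               rate_i_jump = mean(sub$rate_i_post - sub$rate_i_pre))
  }))
  if (meanfield) {
    sm$interval_width <- vapply(D_values, function(D) {
      p <- params; p$D <- D
      iv <- multistable_interval(bifurcation_sweep(p, drive_grid))
      if (is.null(iv)) 0 else diff(iv)
    }, numeric(1))
  }
  list(replicates = reps, summary = sm)
}

#' Stimulation amplitude-frequency heatmap
#'
#' For each (amplitude, frequency) cell, runs `n_reps` transition experiments
#' with distinct derived seeds and records the post-step spike coherence and
#' the post-step excitatory and inhibitory firing rates. Frequencies come from
#' a period list (rounded to whole steps; the realized frequency
#' `1000/round(period)` is stored). Periods shorter than one step are recorded
#' as missing cells. For the `ou_noise` family the amplitude axis is the
#' stimulus noise variance `D_s` and the frequency axis is the cutoff `f_c`.
#'
#' @param params a [network_params()] object.
#' @param protocol a [protocol()] object (its seed is the base seed).
#' @param family waveform family (`"pulse"`, `"biphasic"`, `"sinusoid"`,
#'   `"ou_noise"`).
#' @param amplitudes amplitude grid (`S0`, or `D_s` for `ou_noise`).
#' @param periods_ms period grid (ms; converted to Hz), or for `ou_noise` a
#'   vector of cutoff frequencies in Hz.
#' @param n_reps replicates per cell (10 for the full protocol; use fewer at
#'   desk scale).
#' @param coh a [coherence_config()].
#' @return An object of class `heatmap_result`: `coherence`, `rate_e`,
#'   `rate_i` matrices (amplitude x frequency, replicate means), the
#'   per-replicate arrays, the realized `frequencies` (Hz), `amplitudes`,
#'   `n_reps`, `family` and the seed table.
#' @export
run_stim_heatmap <- function(params, protocol, family = "biphasic",
                             amplitudes = c(0.5, 1.0, 1.75, 2.5),
                             periods_ms = methods_period_grid(),
                             n_reps = 3, coh = coherence_config()) {
  if (family == "ou_noise") {
    freqs <- periods_ms  # interpreted directly as cutoff frequencies (Hz)
  } else {
    freqs <- 1000 / round(periods_ms / params$dt) / params$dt
    freqs[round(periods_ms / params$dt) < 1] <- NA
  }
  nA <- length(amplitudes); nF <- length(freqs)
  arr <- function() array(NA_real_, dim = c(nA, nF, n_reps))
  coh_r <- arr(); re_r <- arr(); ri_r <- arr()
  seeds <- array(NA_integer_, dim = c(nA, nF, n_reps))
  for (ai in seq_len(nA)) for (fi in seq_len(nF)) {
    if (is.na(freqs[fi])) next
    for (rep in seq_len(n_reps)) {
      seed <- derive_seed(protocol$seed, ai, fi, rep)
      spec <- if (family == "ou_noise")
        stimulus_spec("ou_noise", D_s = amplitudes[ai], f_c = freqs[fi],
                      seed = seed + 7L)
      else if (amplitudes[ai] == 0)
        stimulus_spec("none")
      else
        stimulus_spec(family, S0 = amplitudes[ai], f_s = freqs[fi])
      pr <- protocol; pr$seed <- seed
      m <- run_transition(params, pr, spec,
                          coherence_config(coh$bin_ms, coh$n_pairs, seed))$metrics
      coh_r[ai, fi, rep] <- m$coh_post
      re_r[ai, fi, rep] <- m$rate_e_post
      ri_r[ai, fi, rep] <- m$rate_i_post
      seeds[ai, fi, rep] <- seed
    }
  }
  structure(list(
    coherence = apply(coh_r, c(1, 2), mean),
    rate_e = apply(re_r, c(1, 2), mean),
    rate_i = apply(ri_r, c(1, 2), mean),
    coherence_reps = coh_r, rate_e_reps = re_r, rate_i_reps = ri_r,
    amplitudes = amplitudes, frequencies = freqs,
    n_reps = n_reps, family = family, seeds = seeds,
    base_seed = protocol$seed),
    class = "heatmap_result")
}

#' @export
print.heatmap_result <- function(x, ...) {
  cat(sprintf("heatmap (%s): %d amplitudes x %d frequencies, %d reps\n",
              x$family, length(x$amplitudes), length(x$frequencies), x$n_reps))
  cat("mean post-step coherence:\n")
  m <- round(x$coherence, 3)
  dimnames(m) <- list(paste0("A=", x$amplitudes),
                      paste0(signif(x$frequencies, 3), "Hz"))
  print(m)
  invisible(x)
}

#' Single-cell power-spectrum comparison across waveform families
#'
#' Evaluates the analytic excitatory and inhibitory spectra for the biphasic,
#' pulse, sinusoidal and filtered-noise (white-limit) stimulation families at
#' a common parameter set, plus an empirical periodogram cross-check from a
#' simulated decoupled cell driven by intrinsic noise only.
#'
#' @param a_e,a_i rate constants.
#' @param D intrinsic noise spectral density.
#' @param D_s stimulus noise spectral density (noise family).
#' @param S0 stimulus amplitude (from the squared amplitude of the protocol).
#' @param f_s stimulation frequency (Hz).
#' @param T observation length (s).
#' @param empirical_T duration of the decoupled-cell simulation (s).
#' @param seed RNG seed for the empirical cross-check.
#' @return List with one `spectrum_result` per family (`biphasic`, `pulse`,
#'   `sinusoid`, `ou_noise`) and `empirical` (list of `e` and `i`
#'   periodograms).
#' @export
run_psd_comparison <- function(a_e = 100, a_i = 200, D = 200, D_s = 50,
                               S0 = sqrt(0.5), f_s = 50, T = 2,
                               empirical_T = 80, seed = 1L) {
  fams <- list(
    biphasic = stimulus_spec("biphasic", S0 = S0, f_s = f_s),
    pulse = stimulus_spec("pulse", S0 = S0, f_s = f_s),
    sinusoid = stimulus_spec("sinusoid", S0 = S0, f_s = f_s),
    ou_noise = stimulus_spec("ou_noise", D_s = D_s, f_c = 100, seed = seed))
  spectra <- lapply(fams, psd_analytic, a_e = a_e, a_i = a_i, D = D, T = T)
  emp <- lapply(c(e = a_e, i = a_i), function(a) {
    tr <- simulate_decoupled_cell(a, D, T = empirical_T, dt_ms = 0.1, seed = seed)
    psd_empirical(tr, dt_ms = 0.1, n_segments = max(1, round(empirical_T / T)))
  })
  c(spectra, list(empirical = emp))
}

#' Write a run manifest
#'
#' JSON record of the full configuration (parameters, protocol, stimulus
#' specification and realized seed) sufficient to reproduce a run bitwise.
#'
#' @param result a `sim_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(result, file) {
  jsonlite::write_json(list(params = unclass(result$params),
                            protocol = unclass(result$protocol),
                            stimulus = unclass(result$stimulus$spec),
                            seed = result$seed,
                            package_version = as.character(utils::packageVersion("eistim"))),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
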