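#' Coherence estimation settings
#'
#' @param bin_ms bin width (ms), default 20.
#' @param n_pairs number of random excitatory pairs averaged.
#' @param seed pair-sampling seed.
#' @return An object of class `coherence_config`.
#' @export
coherence_config <- function(bin_ms = 20, n_pairs = 100, seed = 1L) {
  if (bin_ms <= 0) stop("bin_ms must be positive")
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  structure(list(bin_ms = bin_ms, n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed)),
            class = "coherence_config")
}

#' Bin spike times into indicator bins
#'
#' One indicator per bin `[k dt, (k+1) dt)` within `[t0, t1)`; a bin is 1 if
#' at least one spike fell into it (indicator, not count). A trailing partial
#' bin is dropped.
#'
#' @param spike_times spike times (ms).
#' @param bin_ms bin width (ms).
#' @param t0,t1 window bounds (ms), `t1 > t0`.
#' @return Integer vector of 0/1 indicators.
#' @export
bin_spikes <- function(spike_times, bin_ms, t0, t1) {
  if (t1 <= t0) stop("need t1 > t0")
  if (bin_ms <= 0) stop("bin_ms must be positive")
  n_bins <- floor((t1 - t0) / bin_ms)
  out <- integer(n_bins)
  if (n_bins == 0) return(out)
  st <- spike_times[spike_times >= t0 & spike_times < t0 + n_bins * bin_ms]
  if (length(st)) out[unique(floor((st - t0) / bin_ms)) + 1L] <- 1L
  out
}

#' Coherence of two binned spike trains
#'
#' Normalized binned cross-correlation
#' `C = sum(x y) / sqrt(sum(x^2) sum(y^2))`, so identical nonempty trains give
#' 1 and bin-disjoint trains give 0. Returns 0 if either train is empty.
#'
#' @param x,y equal-length 0/1 indicator vectors.
#' @return Value in \[0, 1\].
#' @export
binned_coherence <- function(x, y) {
  if (length(x) != length(y)) stop("trains must have equal length")
  d <- sqrt(sum(x^2) * sum(y^2))
  if (d == 0) return(0)
  sum(x * y) / d
}

#' Pairwise spike coherence of the excitatory population
#'
#' Randomly samples `n_pairs` pairs of excitatory cells, bins each train into
#' `bin_ms` indicators over the window, and averages the pairwise normalized
#' cross-correlations. Pairs in which either train is empty are resampled (up
#' to a fixed budget); if no excitatory cell fires in the window the coherence
#' is 0. Deterministic given the config seed.
#'
#' @param raster a `spike_raster`.
#' @param config a [coherence_config()].
#' @param window `(t0, t1)` in ms; must span at least 2 bins.
#' @return Mean pairwise coherence in \[0, 1\].
#' @export
spike_coherence <- function(raster, config = coherence_config(), window) {
  if (diff(window) < 2 * config$bin_ms) stop("window must span at least 2 bins")
  n_cells <- length(raster$e)
  if (n_cells < 2) stop("need at least 2 excitatory cells")
  times <- lapply(raster$e, function(idx) (idx - 1) * raster$dt)
  binned <- lapply(times, bin_spikes, bin_ms = config$bin_ms,
                   t0 = window[1], t1 = window[2])
  occupied <- vapply(binned, function(b) any(b > 0), logical(1))
  if (!any(occupied)) return(0)
  set.seed(config$seed)
  vals <- numeric(config$n_pairs)
  for (p in seq_len(config$n_pairs)) {
    for (attempt in 1:100) {
      ij <- sample.int(n_cells, 2)
      if (occupied[ij[1]] && occupied[ij[2]]) break
    }
    vals[p] <- binned_coherence(binned[[ij[1]]], binned[[ij[2]]])
  }
  mean(vals)
}

#' Population mean firing rate
#'
#' Total spikes of a population in the window divided by (cell count x window
#' length), in Hz.
#'
#' @param raster a `spike_raster`.
#' @param population `"e"` or `"i"`.
#' @param window `(t0, t1)` in ms.
#' @return Rate in spikes per cell per second.
#' @export
mean_firing_rate <- function(raster, population = c("e", "i"), window) {
  population <- match.arg(population)
  cells <- raster[[population]]
  if (!length(cells)) stop("empty population")
  if (diff(window) <= 0) stop("window length must be positive")
  ks <- window_steps(window, raster$dt, raster$n_steps)
  k0 <- ks[1]; k1 <- ks[length(ks)]
  n_spk <- sum(vapply(cells, function(idx) sum(idx >= k0 & idx <= k1), numeric(1)))
  n_spk / (length(cells) * (length(ks) * raster$dt / 1000))
}

lorentzian <- function(a, omega) a^2 / (a^2 + omega^2)

#' Analytic single-cell power spectral density
#'
#' Closed-form power spectra of a decoupled cell with rate constant `a_e`
#' (excitatory) or `a_i` (inhibitory) driven by intrinsic white noise of
#' spectral density `D` plus a global stimulus, on the discrete grid
#' `omega_n = 2 pi n / T`. All families share the Lorentzian low-pass envelope
#' `a^2 / (a^2 + omega^2)` multiplying `D` plus a family-specific stimulus
#' term:
#' * `ou_noise` (white-noise limit): flat `D + D_s`;
#' * `pulse`: an equidistant comb at multiples of the repetition frequency;
#' * `biphasic`: the comb weighted by `n^2` (zero-width pulse-pair
#'   idealization, growing with harmonic order);
#' * `sinusoid`: a single line at the stimulation frequency.
#'
#' Comb families require the stimulation frequency to be a multiple of `1/T`
#' so the spectral lines land on grid points.
#'
#' @param spec a [stimulus_spec()].
#' @param a_e,a_i rate constants (their numeric units set the frequency units
#'   of the spectrum grid).
#' @param D intrinsic noise spectral density.
#' @param T observation length (s).
#' @param f_max highest frequency on the grid (Hz).
#' @param biphasic_offset pulse-pair separation (s) for the biphasic family.
#' @return An object of class `spectrum_result`: `omega` (rad/s), `freq_hz`,
#'   `power_e`, `power_i`, noise-only envelope closures, `spec`, `T`.
#' @export
psd_analytic <- function(spec, a_e = 100, a_i = 200, D = 0.01, T = 2,
                         f_max = 400, biphasic_offset = 0.002) {
  n <- 0:ceiling(f_max * T)
  omega <- 2 * pi * n / T
  stim_term <- switch(spec$family,
    none = rep(0, length(n)),
    ou_noise = rep(spec$D_s, length(n)),
    sinusoid = {
      k <- spec$f_s * T
      check_on_grid(k, "sinusoid")
      ifelse(n == round(k), T * spec$S0^2 / 4 * 2, 0)  # delta_{n,k} + delta_{-n,k} at n > 0
    },
    pulse = {
      k <- spec$f_s * T
      check_on_grid(k, "pulse")
      comb <- n %% round(k) == 0
      base <- 1 / T + ifelse(comb, 2 * (2 * pi * spec$f_s) / (4 * pi), 0)
      T * spec$S0^2 * base^2
    },
    biphasic = {
      k <- spec$f_s * T
      check_on_grid(k, "biphasic")
      comb <- n %% round(k) == 0 & n > 0
      ws <- 2 * pi * spec$f_s
      ifelse(comb, spec$S0^2 * ws^2 * biphasic_offset^2 * n^2 / (4 * T) * 2, 0)
    },
    stop("unsupported stimulus family for the analytic PSD"))
  env_e <- function(w) lorentzian(a_e, w) * (D + if (spec$family == "ou_noise") spec$D_s else 0)
  env_i <- function(w) lorentzian(a_i, w) * (D + if (spec$family == "ou_noise") spec$D_s else 0)
  structure(list(omega = omega, freq_hz = omega / (2 * pi),
                 power_e = lorentzian(a_e, omega) * (D + stim_term),
                 power_i = lorentzian(a_i, omega) * (D + stim_term),
                 envelope_e = env_e, envelope_i = env_i,
                 a_e = a_e, a_i = a_i, spec = spec, T = T),
            class = "spectrum_result")
}

check_on_grid <- function(k, family) {
  if (abs(k - round(k)) > 1e-8)
    stop(sprintf("%s frequency must be a multiple of 1/T so spectral lines land on the grid", family))
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum: %d frequencies up to %.1f Hz (T = %g s, family %s)\n",
              length(x$omega), max(x$freq_hz), x$T,
              if (!is.null(x$spec)) x$spec$family else "empirical"))
  invisible(x)
}

#' Empirical power spectral density (periodogram)
#'
#' Two-sided periodogram `P(omega_n) = |dt sum x_k exp(-i omega_n t_k)|^2 / T`
#' on the grid `omega_n = 2 pi n / T`, optionally averaged over contiguous
#' segments for variance reduction (the grid then uses the segment length).
#' The mean is removed per segment. Parseval: `sum over the full two-sided
#' grid of P / T` equals the mean square of the (centered) trace; with the
#' one-sided grid returned here, `(P_0 + 2 sum_{n>0} P_n) / T` (adjusting the
#' Nyquist term for even lengths) recovers the variance.
#'
#' @param trace numeric trace (e.g. a membrane or stimulus trace).
#' @param dt_ms step (ms).
#' @param n_segments number of equal segments to average.
#' @return A `spectrum_result` with `omega`, `freq_hz` and `power`.
#' @export
psd_empirical <- function(trace, dt_ms, n_segments = 1) {
  if (length(trace) < 2) stop("trace too short")
  dt <- dt_ms / 1000
  seg_len <- floor(length(trace) / n_segments)
  half <- floor(seg_len / 2)
  acc <- numeric(half + 1)
  for (s in seq_len(n_segments)) {
    x <- trace[((s - 1) * seg_len + 1):(s * seg_len)]
    x <- x - mean(x)
    P <- (abs(stats::fft(x))^2) * dt / seg_len
    acc <- acc + P[1:(half + 1)]
  }
  T_seg <- seg_len * dt
  omega <- 2 * pi * (0:half) / T_seg
  structure(list(omega = omega, freq_hz = omega / (2 * pi),
                 power = acc / n_segments, T = T_seg, n_segments = n_segments,
                 seg_len = seg_len, spec = NULL),
            class = "spectrum_result")
}

#' Simulate a decoupled linear cell (for spectrum cross-checks)
#'
#' Integrates `a^-1 du/dt = -u + eta(t)` where `eta` is intrinsic white noise
#' of spectral density `D` plus an optional stimulus trace, matching the
#' convention of the analytic single-cell spectra.
#'
#' @param a rate constant (1/s).
#' @param D intrinsic noise spectral density.
#' @param T duration (s).
#' @param dt_ms step (ms).
#' @param stim optional stimulus values (length `T/dt`), added to `eta`.
#' @param seed RNG seed.
#' @return Numeric membrane trace.
#' @export
simulate_decoupled_cell <- function(a, D, T, dt_ms = 1, stim = NULL, seed = 1L) {
  dt <- dt_ms / 1000
  n <- round(T / dt)
  if (is.null(stim)) stim <- numeric(n)
  if (length(stim) != n) stop("stimulus length must match the step count")
  set.seed(seed)
  z <- stats::rnorm(n)
  h <- a * dt
  if (h >= 1) stop("explicit scheme unstable: need a * dt < 1")
  amp <- a * sqrt(D * dt)
  as.numeric(stats::filter(h * stim + amp * z, 1 - h,
                           method = "recursive", init = 0))
}

#' Half-power cutoff frequency of a noise-only spectrum
#'
#' Numerically solves `S^2(omega_c) / S^2(0) = 1/2` on the smooth
#' (stimulus-line-free) spectral envelope. For the Lorentzian envelope of a
#' cell with rate constant `a` the solution is `omega_c = a`, returned in the
#' same numeric units as the rate constant. Analytic spectra carry their
#' noise-only envelope closure and are solved to root-finder precision;
#' empirical spectra are interpolated, and a non-monotone (comb) spectrum is
#' rejected.
#'
#' @param spectrum a `spectrum_result`.
#' @param population `"e"` or `"i"` for analytic spectra (ignored for
#'   empirical ones).
#' @return The half-power frequency.
#' @export
half_power_frequency <- function(spectrum, population = c("e", "i")) {
  population <- match.arg(population)
  if (!is.null(spectrum$envelope_e)) {
    env <- if (population == "e") spectrum$envelope_e else spectrum$envelope_i
    a <- if (population == "e") spectrum$a_e else spectrum$a_i
    s0 <- env(0)
    if (!is.finite(s0) || s0 <= 0) stop("envelope has no finite positive zero-frequency value")
    f <- function(w) env(w) / s0 - 0.5
    upper <- 10 * a
    while (f(upper) > 0) upper <- upper * 10
    return(stats::uniroot(f, c(0, upper), tol = 1e-12)$root)
  }
  p <- spectrum$power
  if (is.null(p)) stop("spectrum carries neither an envelope nor empirical power")
  run_mean <- stats::filter(p, rep(1 / 9, 9), sides = 2)
  sm <- as.numeric(run_mean); sm[is.na(sm)] <- p[is.na(sm)]
  if (stats::cor(seq_along(sm), sm, method = "spearman") > -0.5)
    stop("empirical spectrum is not a monotone envelope; call on the noise-only envelope")
  ratio <- sm / sm[1]
  idx <- which(ratio <= 0.5)[1]
  if (is.na(idx)) stop("half-power point beyond the frequency grid")
  w1 <- spectrum$omega[idx - 1]; w2 <- spectrum$omega[idx]
  r1 <- ratio[idx - 1]; r2 <- ratio[idx]
  w1 + (0.5 - r1) * (w2 - w1) / (r2 - r1)
}
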