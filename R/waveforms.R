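#' Stimulation waveform specification
#'
#' Describes the global stimulus S(t) injected identically into every cell.
#' Families:
#' \describe{
#'   \item{none}{identically zero trace.}
#'   \item{pulse}{brief pulses of amplitude `S0` (one integration step long)
#'     repeated at `f_s` Hz; `S0 < 0` is the inhibitory pulse train.}
#'   \item{biphasic}{paired +`S0` / -`S0` pulses (net zero mean); the negative
#'     pulse trails the positive one by 2 ms.}
#'   \item{sinusoid}{`S0 * sin(2 pi f_s t)`.}
#'   \item{ou_noise}{low-pass-filtered Gaussian noise (an Ornstein-Uhlenbeck
#'     process) with zero mean, noise-variance parameter `D_s` and cutoff
#'     frequency `f_c = 1/tau` Hz. Its stationary variance is
#'     `D_s * f_c / a_ref`, with the rate nondimensionalization `a_ref`
#'     matching the network's excitatory rate constant (see the vignette).}
#' }
#'
#' @param family one of `"none"`, `"ou_noise"`, `"pulse"`, `"biphasic"`,
#'   `"sinusoid"`.
#' @param S0 amplitude (membrane units, signed).
#' @param f_s repetition / oscillation frequency (Hz).
#' @param D_s stimulus noise variance (ou_noise only).
#' @param f_c low-pass cutoff frequency (Hz; ou_noise only).
#' @param seed RNG seed (ou_noise only).
#' @param a_ref rate constant used to nondimensionalize the ou_noise variance
#'   (Hz; defaults to the excitatory membrane rate of the reference network).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(family = c("none", "ou_noise", "pulse", "biphasic", "sinusoid"),
                          S0 = 0, f_s = NULL, D_s = NULL, f_c = NULL,
                          seed = NULL, a_ref = 100) {
  family <- match.arg(family)
  if (family %in% c("pulse", "biphasic", "sinusoid")) {
    if (is.null(f_s) || f_s <= 0) stop("f_s > 0 required for periodic families")
  }
  if (family == "ou_noise") {
    if (is.null(D_s) || D_s < 0) stop("D_s >= 0 required for ou_noise")
    if (is.null(f_c) || f_c <= 0) stop("f_c > 0 required for ou_noise")
  }
  structure(list(family = family, S0 = S0, f_s = f_s, D_s = D_s, f_c = f_c,
                 seed = seed, a_ref = a_ref),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  desc <- switch(x$family,
    none = "none",
    pulse = sprintf("pulse train, S0 = %g, %g Hz", x$S0, x$f_s),
    biphasic = sprintf("biphasic train, +/-%g, %g Hz", abs(x$S0), x$f_s),
    sinusoid = sprintf("sinusoid, S0 = %g, %g Hz", x$S0, x$f_s),
    ou_noise = sprintf("filtered noise, D_s = %g, f_c = %g Hz", x$D_s, x$f_c))
  cat("stimulus:", desc, "\n")
  invisible(x)
}

new_stimulus_trace <- function(values, dt, spec) {
  structure(list(values = values, dt = dt, spec = spec),
            class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("stimulus trace: %d steps of %g ms, mean %.4g\n",
              length(x$values), x$dt, mean(x$values)))
  invisible(x)
}

period_steps <- function(f_s, dt) {
  ps <- round((1000 / f_s) / dt)
  if (ps < 1) stop(sprintf("period 1/f_s = %g ms is below one step (%g ms)", 1000 / f_s, dt))
  ps
}

#' Pulse train stimulus
#'
#' Amplitude `S0` held for exactly one integration step at the start of each
#' period `1/f_s` (periods rounded to an integer number of steps), zero
#' elsewhere.
#'
#' @param spec a [stimulus_spec()] with `family = "pulse"`.
#' @param n_steps trace length (steps).
#' @param dt step (ms).
#' @return A `stimulus_trace`.
#' @export
make_pulse_train <- function(spec, n_steps, dt) {
  stopifnot(spec$family == "pulse")
  ps <- period_steps(spec$f_s, dt)
  v <- numeric(n_steps)
  v[seq.int(1L, n_steps, by = ps)] <- spec$S0
  new_stimulus_trace(v, dt, spec)
}

#' Biphasic pulse train stimulus
#'
#' `+S0` at each period start and `-S0` exactly 2 ms later, zero elsewhere;
#' the trace has zero mean over whole periods. The period must be long enough
#' to host both pulses.
#'
#' @param spec a [stimulus_spec()] with `family = "biphasic"`.
#' @inheritParams make_pulse_train
#' @return A `stimulus_trace`.
#' @export
make_biphasic_train <- function(spec, n_steps, dt) {
  stopifnot(spec$family == "biphasic")
  ps <- period_steps(spec$f_s, dt)
  off <- max(1L, round(2 / dt))
  if (ps < off + 1L)
    stop(sprintf("period of %d steps cannot host a +/- pulse pair %d steps apart", ps, off))
  v <- numeric(n_steps)
  pos <- seq.int(1L, n_steps, by = ps)
  v[pos] <- spec$S0
  neg <- pos + off
  v[neg[neg <= n_steps]] <- -spec$S0
  new_stimulus_trace(v, dt, spec)
}

#' Sinusoidal stimulus
#'
#' `S0 * sin(2 pi f_s t)` sampled at `t = (k - 1) * dt`.
#'
#' @param spec a [stimulus_spec()] with `family = "sinusoid"`.
#' @inheritParams make_pulse_train
#' @return A `stimulus_trace`.
#' @export
make_sinusoid <- function(spec, n_steps, dt) {
  stopifnot(spec$family == "sinusoid")
  t_s <- (seq_len(n_steps) - 1) * dt / 1000
  new_stimulus_trace(spec$S0 * sin(2 * pi * spec$f_s * t_s), dt, spec)
}

#' Low-pass-filtered (Ornstein-Uhlenbeck) noise stimulus
#'
#' Exact discretization of the OU process with correlation time
#' `tau = 1/f_c`: each step applies the decay factor `exp(-dt/tau)` and a
#' Gaussian increment with the exact transition variance, so the stationary
#' variance `D_s * f_c / a_ref` holds at any step size. The process starts
#' from a stationary draw; the trace has zero mean and is reproducible given
#' the spec's seed. A plain Euler-Maruyama variant is kept internally as a
#' cross-check.
#'
#' @param spec a [stimulus_spec()] with `family = "ou_noise"`.
#' @inheritParams make_pulse_train
#' @param rng_seed optional override of `spec$seed`.
#' @return A `stimulus_trace`.
#' @export
make_ou_noise <- function(spec, n_steps, dt, rng_seed = NULL) {
  stopifnot(spec$family == "ou_noise")
  tau_ms <- 1000 / spec$f_c
  if (dt >= tau_ms)
    stop(sprintf("dt = %g ms must be below the correlation time 1/f_c = %g ms", dt, tau_ms))
  seed <- if (!is.null(rng_seed)) rng_seed else spec$seed
  if (is.null(seed)) stop("ou_noise requires a seed (spec$seed or rng_seed)")
  var_s <- spec$D_s * spec$f_c / spec$a_ref
  v <- numeric(n_steps)
  if (var_s > 0) {
    set.seed(seed)
    decay <- exp(-dt / tau_ms)
    sd_inc <- sqrt(var_s * (1 - decay^2))
    x0 <- stats::rnorm(1, 0, sqrt(var_s))
    z <- stats::rnorm(n_steps)
    v <- as.numeric(stats::filter(sd_inc * z, decay, method = "recursive",
                                  init = x0))
  }
  new_stimulus_trace(v, dt, spec)
}

# Euler-Maruyama form of the OU update, used only as a numerical cross-check
# of the exact discretization (it carries an O(dt) bias in the variance).
ou_noise_euler <- function(spec, n_steps, dt, rng_seed = NULL) {
  tau_ms <- 1000 / spec$f_c
  seed <- if (!is.null(rng_seed)) rng_seed else spec$seed
  set.seed(seed)
  var_s <- spec$D_s * spec$f_c / spec$a_ref
  h <- dt / tau_ms
  x0 <- stats::rnorm(1, 0, sqrt(var_s))
  z <- stats::rnorm(n_steps)
  as.numeric(stats::filter(sqrt(2 * var_s * h) * z, 1 - h,
                           method = "recursive", init = x0))
}

#' Compile a stimulus specification into a discrete trace
#'
#' @param spec a [stimulus_spec()].
#' @inheritParams make_pulse_train
#' @param rng_seed seed for stochastic families (overrides `spec$seed`).
#' @return A `stimulus_trace` of length `n_steps`.
#' @export
compile_stimulus <- function(spec, n_steps, dt, rng_seed = NULL) {
  switch(spec$family,
    none = new_stimulus_trace(numeric(n_steps), dt, spec),
    pulse = make_pulse_train(spec, n_steps, dt),
    biphasic = make_biphasic_train(spec, n_steps, dt),
    sinusoid = make_sinusoid(spec, n_steps, dt),
    ou_noise = make_ou_noise(spec, n_steps, dt, rng_seed))
}

#' Time-average of a stimulus trace
#'
#' The mean drive a waveform adds to the population equations; zero for
#' biphasic and sinusoidal waveforms over whole periods.
#'
#' @param trace a `stimulus_trace`.
#' @return The arithmetic time-average of the trace values.
#' @export
waveform_mean <- function(trace) {
  if (!length(trace$values)) stop("empty stimulus trace")
  mean(trace$values)
}

#' Export a stimulus trace as two-column CSV
#'
#' Columns `time_ms` and `value`.
#'
#' @param trace a `stimulus_trace`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_stimulus_csv <- function(trace, file) {
  utils::write.csv(data.frame(time_ms = (seq_along(trace$values) - 1) * trace$dt,
                              value = trace$values),
                   file, row.names = FALSE)
  invisible(file)
}
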