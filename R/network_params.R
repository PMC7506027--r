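#' Network parameters for the stochastic E-I spiking network
#'
#' Constructs the parameter set shared by the spiking simulator and the
#' mean-field analysis. Defaults are the reference cortical parameter set:
#' 800 excitatory and 200 inhibitory cells, a sharp sigmoidal firing-rate
#' nonlinearity (gain 300, threshold 0), membrane rate constants of 100 Hz
#' (excitatory) and 200 Hz (inhibitory), mean synaptic weights
#' (w_ee, w_ei, w_ie, w_ii) = (1.60, 3.00, -4.70, -0.13), baseline drives
#' (I_e, I_i) = (-0.25, -0.50) and a 1 ms integration step.
#'
#' Inhibitory weights carry their sign in the value: the simulator adds
#' weighted spike counts without extra negation. Weights are homogeneous
#' all-to-all (self-connections included); the mean-field reduction uses the
#' same values as population-mean weights.
#'
#' The intrinsic noise variance `D` is expressed per membrane time constant of
#' each population, so that the stationary variance of a decoupled cell's
#' membrane deviations equals `D` for both populations (see the package
#' vignette for why this nondimensionalization is the one under which the
#' mean-field bifurcation structure is reproduced).
#'
#' @param N_e,N_i number of excitatory / inhibitory cells.
#' @param beta sigmoid gain (dimensionless).
#' @param h sigmoid threshold (membrane units).
#' @param a_e,a_i membrane rate constants (Hz).
#' @param w_ee,w_ei,w_ie,w_ii mean synaptic weights (signed, dimensionless).
#' @param I_e,I_i baseline drives (membrane units).
#' @param D intrinsic noise variance (membrane units squared, per membrane
#'   time constant).
#' @param dt integration step (ms).
#' @return An object of class `network_params` (a named list).
#' @examples
#' p <- network_params()
#' firing_prob(0, p) # 0.5 at threshold
#' @export
network_params <- function(N_e = 800L, N_i = 200L, beta = 300, h = 0,
                           a_e = 100, a_i = 200,
                           w_ee = 1.60, w_ei = 3.00, w_ie = -4.70, w_ii = -0.13,
                           I_e = -0.25, I_i = -0.50,
                           D = 0.01, dt = 1) {
  p <- list(N_e = as.integer(N_e), N_i = as.integer(N_i), beta = beta, h = h,
            a_e = a_e, a_i = a_i,
            w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
            I_e = I_e, I_i = I_i, D = D, dt = dt)
  validate_network_params(p)
  structure(p, class = "network_params")
}

validate_network_params <- function(p) {
  num <- unlist(p[setdiff(names(p), c("N_e", "N_i"))])
  if (any(!is.finite(num))) stop("network parameters must be finite")
  if (p$N_e <= 0 || p$N_i <= 0) stop("N_e and N_i must be positive")
  if (p$a_e <= 0 || p$a_i <= 0) stop("a_e and a_i must be positive")
  if (p$beta <= 0) stop("beta must be positive")
  if (p$dt <= 0) stop("dt must be positive")
  if (p$D < 0) stop("D must be nonnegative")
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("E-I network parameters\n")
  cat(sprintf("  cells: %d excitatory + %d inhibitory\n", x$N_e, x$N_i))
  cat(sprintf("  rates: a_e = %g Hz, a_i = %g Hz; dt = %g ms\n", x$a_e, x$a_i, x$dt))
  cat(sprintf("  sigmoid: gain %g, threshold %g\n", x$beta, x$h))
  cat(sprintf("  weights: w_ee %g, w_ei %g, w_ie %g, w_ii %g\n",
              x$w_ee, x$w_ei, x$w_ie, x$w_ii))
  cat(sprintf("  drives: I_e %g, I_i %g; noise variance D = %g\n", x$I_e, x$I_i, x$D))
  invisible(x)
}

#' Instantaneous firing probability
#'
#' The sharp sigmoid `f[u] = (1 + exp(-beta (u - h)))^-1` mapping a membrane
#' value to a per-step spiking probability. Numerically saturates to 0/1
#' without overflow.
#'
#' @param u membrane value(s).
#' @param params a [network_params()] object.
#' @return Value(s) in (0, 1).
#' @export
firing_prob <- function(u, params) {
  stats::plogis(params$beta * (u - params$h))
}

#' Derivative of the firing probability
#'
#' Analytic slope `beta * f * (1 - f)` of [firing_prob()].
#'
#' @inheritParams firing_prob
#' @return Nonnegative value(s); `beta/4` at the threshold.
#' @export
firing_prob_slope <- function(u, params) {
  f <- firing_prob(u, params)
  params$beta * f * (1 - f)
}

#' Simulation protocol
#'
#' Describes a transition run: total length, the time at which the tonic
#' excitatory drive steps from `Io_pre` to `Io_post`, the burn-in discarded
#' before any measurement, and the post-step window used for metrics (the
#' final `measure_window` ms of the run).
#'
#' @param t_total simulation length (ms).
#' @param t_step time of the drive change (ms).
#' @param Io_pre,Io_post tonic excitatory drive before / after the step
#'   (membrane units).
#' @param burn_in discarded initial interval (ms); must precede `t_step`.
#' @param measure_window length of the post-step metric window (ms); at most
#'   `t_total - t_step`.
#' @param seed base RNG seed for the run.
#' @return An object of class `protocol`.
#' @export
protocol <- function(t_total = 2000, t_step = 1000, Io_pre = 0, Io_post = 0.1,
                     burn_in = 500, measure_window = 800, seed = 1L) {
  if (t_step < 0 || t_step > t_total) stop("need 0 <= t_step <= t_total")
  if (burn_in >= t_step) stop("burn_in must be smaller than t_step")
  if (measure_window > t_total - t_step)
    stop("measure_window must be at most t_total - t_step")
  structure(list(t_total = t_total, t_step = t_step,
                 Io_pre = Io_pre, Io_post = Io_post,
                 burn_in = burn_in, measure_window = measure_window,
                 seed = as.integer(seed)),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("protocol: %g ms, drive %g -> %g at %g ms (burn-in %g ms, window %g ms, seed %d)\n",
              x$t_total, x$Io_pre, x$Io_post, x$t_step, x$burn_in,
              x$measure_window, x$seed))
  invisible(x)
}

#' Save / load network parameters as a flat YAML config
#'
#' Keys are the parameter symbol names; the round trip is lossless.
#'
#' @param params a [network_params()] object.
#' @param file path to a YAML file.
#' @return `read_network_params` returns a [network_params()] object;
#'   `write_network_params` returns `file` invisibly.
#' @export
write_network_params <- function(params, file) {
  yaml::write_yaml(unclass(params), file, precision = 15L)
  invisible(file)
}

#' @rdname write_network_params
#' @export
read_network_params <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(network_params, vals)
}
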