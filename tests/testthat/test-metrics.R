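test_that("spike binning produces per-bin indicators over whole bins", {
  expect_equal(bin_spikes(c(5, 25, 45), 20, 0, 60), c(1L, 1L, 1L))
  expect_equal(bin_spikes(numeric(0), 20, 0, 60), c(0L, 0L, 0L))
  # indicator, not count: two spikes in one bin still read 1
  expect_equal(bin_spikes(c(3, 7), 20, 0, 60), c(1L, 0L, 0L))
  # trailing partial bin dropped; window is half-open
  expect_equal(bin_spikes(c(65), 20, 0, 70), c(0L, 0L, 0L))
  expect_equal(bin_spikes(c(20), 20, 0, 40), c(0L, 1L))
  expect_error(bin_spikes(1, 20, 10, 10), "t1 > t0")
})

test_that("binned coherence is calibrated at 0, 1/2 and 1", {
  x <- bin_spikes(seq(5, 995, by = 100), 20, 0, 1000)
  expect_identical(binned_coherence(x, x), 1)
  odd <- rep(c(1L, 0L), 25)
  even <- rep(c(0L, 1L), 25)
  expect_identical(binned_coherence(odd, even), 0)
  # overlap example: bins {1,2} vs {2,3} -> 1 / sqrt(2 * 2)
  expect_equal(binned_coherence(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_equal(binned_coherence(rep(0L, 10), rep(0L, 10)), 0)
})

test_that("coherence is symmetric, bounded and concentrates at the firing probability for independent trains", {
  set.seed(31)
  for (rep in 1:20) {
    x <- rbinom(200, 1, runif(1, 0.05, 0.9))
    y <- rbinom(200, 1, runif(1, 0.05, 0.9))
    c1 <- binned_coherence(x, y)
    expect_identical(c1, binned_coherence(y, x))
    expect_gte(c1, 0); expect_lte(c1, 1)
  }
  p <- 0.3
  x <- rbinom(20000, 1, p); y <- rbinom(20000, 1, p)
  expect_equal(binned_coherence(x, y), p, tolerance = 0.05)
})

test_that("population coherence averages resampled pairs deterministically", {
  # two synchronous cells and one silent cell: silent trains are resampled away
  sync <- seq(1, 1000, by = 50)
  raster <- toy_raster(list(sync, sync, integer(0)))
  cfg <- coherence_config(bin_ms = 20, n_pairs = 10, seed = 4)
  expect_equal(spike_coherence(raster, cfg, c(0, 1000)), 1)
  expect_identical(spike_coherence(raster, cfg, c(0, 1000)),
                   spike_coherence(raster, cfg, c(0, 1000)))
  # fully silent population
  empty <- toy_raster(list(integer(0), integer(0)))
  expect_equal(spike_coherence(empty, cfg, c(0, 1000)), 0)
  expect_error(spike_coherence(raster, cfg, c(0, 30)), "2 bins")
})

test_that("mean firing rate counts spikes per cell per second", {
  # 200 cells, 10 spikes each over 1 s -> 10 Hz
  spikes <- replicate(200, seq(50, 950, by = 100), simplify = FALSE)
  raster <- toy_raster(spikes)
  expect_equal(mean_firing_rate(raster, "e", c(0, 1000)), 10)
  # empty raster -> 0 Hz
  expect_equal(mean_firing_rate(toy_raster(list(integer(0))), "e", c(0, 1000)), 0)
  # additive over disjoint windows (weighted by length)
  r1 <- mean_firing_rate(raster, "e", c(0, 400))
  r2 <- mean_firing_rate(raster, "e", c(400, 1000))
  expect_equal(0.4 * r1 + 0.6 * r2, mean_firing_rate(raster, "e", c(0, 1000)))
})

test_that("a cell pinned far above threshold fires once per step", {
  p <- decoupled_params(D = 1e-6, N = 5L)
  p$I_e <- 1  # holds u near 1, f ~ 1
  pr <- protocol(t_total = 2000, t_step = 1000, Io_pre = 0, Io_post = 0,
                 burn_in = 500, measure_window = 1000, seed = 2)
  r <- simulate_network(p, pr, u0 = 1)
  expect_equal(mean_firing_rate(r$raster, "e", c(500, 2000)), 1000, tolerance = 0.01)
})

test_that("analytic spectra are Lorentzian-enveloped with family-specific lines", {
  D <- 200
  specs <- list(
    noise = stimulus_spec("ou_noise", D_s = 50, f_c = 100, seed = 1),
    pulse = stimulus_spec("pulse", S0 = sqrt(0.5), f_s = 50),
    biphasic = stimulus_spec("biphasic", S0 = sqrt(0.5), f_s = 50),
    sinusoid = stimulus_spec("sinusoid", S0 = sqrt(0.5), f_s = 50))
  for (nm in names(specs)) {
    s <- psd_analytic(specs[[nm]], D = D, T = 2)
    expect_true(all(s$power_e >= 0))
    # inhibitory cells respond more strongly at every nonzero frequency
    # (a_i > a_e flattens the Lorentzian); the spectra coincide only at 0
    expect_true(all(s$power_i[-1] > s$power_e[-1]))
    expect_equal(s$power_i[1], s$power_e[1])
  }
  # sinusoid: exactly one off-zero line, at n = f_s T
  s <- psd_analytic(specs$sinusoid, D = 0, T = 2)
  lines <- which(s$power_e > 0) - 1
  expect_equal(lines, 50 * 2)
  # pulse: lines at multiples of the repetition frequency
  sp <- psd_analytic(specs$pulse, D = 0, T = 2)
  big <- which(sp$power_e > max(sp$power_e) * 1e-3) - 1
  expect_true(all(big %% 100 == 0))
  # biphasic comb weight grows with harmonic order before the envelope wins
  sb <- psd_analytic(specs$biphasic, D = 0, T = 2)
  comb <- which(sb$power_e > 0)
  expect_gt(sb$power_e[comb[2]] / eistim:::lorentzian(100, sb$omega[comb[2]]),
            sb$power_e[comb[1]] / eistim:::lorentzian(100, sb$omega[comb[1]]))
  # with the stimulus terms removed every family reduces to the bare Lorentzian
  s0 <- psd_analytic(stimulus_spec("pulse", S0 = 0, f_s = 50), D = D, T = 2)
  expect_equal(s0$power_e, eistim:::lorentzian(100, s0$omega) * D)
  sn0 <- psd_analytic(stimulus_spec("ou_noise", D_s = 0, f_c = 100, seed = 1), D = D, T = 2)
  expect_equal(sn0$power_e, eistim:::lorentzian(100, sn0$omega) * D)
  # off-grid line frequencies are rejected rather than smeared
  expect_error(psd_analytic(stimulus_spec("sinusoid", S0 = 1, f_s = 50.3), T = 2),
               "multiple of 1/T")
})

test_that("half-power frequency of the noise envelope equals the rate constant", {
  s <- psd_analytic(stimulus_spec("ou_noise", D_s = 50, f_c = 100, seed = 1),
                    a_e = 100, a_i = 200, D = 200, T = 2)
  expect_equal(half_power_frequency(s, "e"), 100, tolerance = 1e-6)
  expect_equal(half_power_frequency(s, "i"), 200, tolerance = 1e-6)
  # doubling the rate doubles the cutoff
  s2 <- psd_analytic(stimulus_spec("none"), a_e = 50, a_i = 400, D = 1, T = 2)
  expect_equal(half_power_frequency(s2, "e"), 50, tolerance = 1e-6)
  expect_equal(half_power_frequency(s2, "i"), 400, tolerance = 1e-6)
})

test_that("periodogram satisfies Parseval and recovers the Lorentzian of a decoupled cell", {
  set.seed(13)
  x <- rnorm(4096)
  ps <- psd_empirical(x, dt_ms = 1)
  n <- length(x)
  total <- (ps$power[1] + ps$power[length(ps$power)] +
              2 * sum(ps$power[2:(length(ps$power) - 1)])) / ps$T
  expect_equal(total, mean((x - mean(x))^2), tolerance = 0.01)

  u <- simulate_decoupled_cell(a = 100, D = 0.01, T = 40, dt_ms = 0.1, seed = 21)
  ps <- psd_empirical(u, dt_ms = 0.1, n_segments = 40)
  keep <- ps$omega > 0 & ps$freq_hz < 400
  analytic <- eistim:::lorentzian(100, ps$omega[keep]) * 0.01
  rms_log <- sqrt(mean((log10(ps$power[keep]) - log10(analytic))^2))
  expect_lt(rms_log, 0.1)
  # high-frequency slope of the Lorentzian tail approaches -2
  tail <- ps$omega > 2000 & ps$omega < 3000
  fit <- lm(log10(ps$power[tail]) ~ log10(ps$omega[tail]))
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.3)

  # a pure sinusoid with no noise shows a single dominant line at f_s
  tr <- make_sinusoid(stimulus_spec("sinusoid", S0 = 1, f_s = 50), 2000, 1)
  pss <- psd_empirical(tr$values, dt_ms = 1)
  expect_equal(pss$freq_hz[which.max(pss$power)], 50)
  expect_error(half_power_frequency(pss), "monotone")
})
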