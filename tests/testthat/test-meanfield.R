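test_that("effective noise variance follows the filter composition formula", {
  expect_equal(effective_noise_variance(100, 0.01, 0.08, 400),
               100 * 0.01 + 100 * 0.08 * 400 / 500)
  expect_equal(effective_noise_variance(100, 0.01, 0.08, 400), 7.4)
  # white-noise limit is the maximum; zero cutoff removes the stimulus
  expect_equal(effective_noise_variance(100, 0.01, 0.08, Inf), 100 * 0.09)
  expect_equal(effective_noise_variance(100, 0.01, 0.08, 0), 1)
  expect_equal(effective_noise_variance(200, 0.02), 4)
})

test_that("network effective variances are positive, intrinsic-only without a stimulus, and larger for inhibition under stimulation", {
  p <- network_params(D = 0.01)
  nv <- effective_noise(p)
  expect_equal(nv$Dbar_e, 0.01)
  expect_equal(nv$Dbar_i, 0.01)
  ns <- effective_noise(p, D_s = 0.08, f_c = 400)
  var_s <- 0.08 * 400 / p$a_e
  expect_equal(ns$Dbar_e, 0.01 + var_s * 100 / 500)
  expect_equal(ns$Dbar_i, 0.01 + var_s * 200 / 600)
  expect_gt(ns$Dbar_i, ns$Dbar_e)
  expect_gt(ns$Dbar_e, nv$Dbar_e)
})

test_that("closed-form smoothed transfer agrees with direct quadrature of the convolution", {
  u <- seq(-2, 2, length.out = 81)
  for (Dbar in c(0.5, 1.0)) {
    closed <- effective_transfer(u, Dbar)
    quad <- effective_transfer_quad(u, Dbar, beta = 300)
    expect_lt(max(abs(closed - quad)), 2e-3)
  }
  # at the network's operating variance the finite-gain correction stays small
  u2 <- seq(-0.5, 0.5, length.out = 81)
  expect_lt(max(abs(effective_transfer(u2, 0.005) -
                    effective_transfer_quad(u2, 0.005, beta = 300))), 5e-3)
})

test_that("smoothed transfer is a strictly increasing map onto (0, 1) with matching slope", {
  expect_equal(effective_transfer(0, 0.3), 0.5)
  u <- sort(runif(50, -3, 3))
  f <- effective_transfer(u, 0.7)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  eps <- 1e-6
  fd <- (effective_transfer(u + eps, 0.7) - effective_transfer(u - eps, 0.7)) / (2 * eps)
  expect_equal(effective_transfer_slope(u, 0.7), fd, tolerance = 1e-6)
  expect_error(effective_transfer(0, 0), "positive")
})

test_that("with couplings removed the unique equilibrium is the drive itself", {
  p <- network_params(w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0, D = 0.01)
  eq <- find_equilibria(p, 0.07)
  expect_equal(nrow(eq), 1L)
  expect_equal(eq$u_e, p$I_e + 0.07, tolerance = 1e-10)
  expect_equal(eq$u_i, p$I_i, tolerance = 1e-10)
  expect_true(eq$stable)
})

test_that("every returned equilibrium satisfies the steady-state equations to 1e-10", {
  set.seed(99)
  for (rep in 1:40) {
    p <- network_params(w_ee = runif(1, 0, 2.5), w_ei = runif(1, 0.5, 3.5),
                        w_ie = runif(1, -5, 0), w_ii = runif(1, -1, 0),
                        I_e = runif(1, -0.5, 0.2), I_i = runif(1, -0.7, 0.2),
                        D = runif(1, 0.003, 0.08))
    io <- runif(1, -0.05, 0.15)
    eq <- find_equilibria(p, io)
    nv <- effective_noise(p)
    for (r in seq_len(nrow(eq))) {
      res <- eistim:::mf_residuals(eq$u_e[r], eq$u_i[r], p, io, nv)
      expect_lt(max(abs(res)), 1e-10)
    }
  }
})

test_that("low intrinsic noise yields three equilibria with an unstable middle branch; high noise yields one", {
  p <- network_params(D = 0.005)
  eq <- find_equilibria(p, 0.05)
  expect_equal(nrow(eq), 3L)
  expect_true(eq$stable[1])        # low-activity node
  expect_gt(eq$damping[2], 0)      # middle saddle branch is unstable
  p5 <- network_params(D = 0.05)
  for (io in seq(0, 0.1, by = 0.02))
    expect_equal(nrow(find_equilibria(p5, io)), 1L)
})

test_that("decoupled linearization recovers the bare relaxation rates", {
  p <- network_params(w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0, D = 0.01)
  st <- linear_stability(p, -0.25, -0.5)
  expect_equal(sort(Re(st$lambda)), c(-200, -100))
  expect_equal(st$eigfreq, 0)
  expect_true(st$stable)
  expect_equal(st$damping, -100)
})

test_that("closed-form eigenvalues match the numeric eigendecomposition over random draws", {
  set.seed(7)
  for (rep in 1:1000) {
    p <- network_params(w_ee = runif(1, -2, 3), w_ei = runif(1, -2, 4),
                        w_ie = runif(1, -6, 2), w_ii = runif(1, -2, 1),
                        a_e = runif(1, 20, 300), a_i = runif(1, 20, 400),
                        D = runif(1, 0.002, 0.1))
    nv <- effective_noise(p)
    ue <- runif(1, -0.6, 0.4); ui <- runif(1, -0.8, 0.4)
    st <- linear_stability(p, ue, ui, nv)  # hard-errors on >1e-9 mismatch
    # trace identity against an independently built Jacobian
    Re_ <- effective_transfer_slope(ue, nv$Dbar_e)
    Ri <- effective_transfer_slope(ui, nv$Dbar_i)
    J <- rbind(c(p$a_e * (-1 + p$w_ee * Re_), p$a_e * p$w_ie * Ri),
               c(p$a_i * p$w_ei * Re_, p$a_i * (-1 + p$w_ii * Ri)))
    expect_equal(sum(Re(st$lambda)), sum(diag(J)), tolerance = 1e-9)
  }
})

test_that("bifurcation sweep locates, shrinks and loses the multistable interval as noise grows", {
  grid <- seq(0, 0.12, by = 0.002)
  widths <- numeric(4)
  Ds <- c(0.005, 0.010, 0.025, 0.05)
  for (di in seq_along(Ds)) {
    bd <- bifurcation_sweep(network_params(D = Ds[di]), grid)
    iv <- multistable_interval(bd)
    widths[di] <- if (is.null(iv)) 0 else diff(iv)
    if (di == 1) {
      expect_false(is.null(iv))
      expect_true(iv[1] < 0.05 && 0.05 < iv[2])  # spans drives near 0.05
    }
  }
  expect_true(all(diff(widths) <= 0))
  expect_equal(widths[4], 0)
})

test_that("equilibria shift to lower excitatory potential as noise grows (outside the interval)", {
  Ds <- c(0.005, 0.010, 0.025, 0.05)
  for (io in c(0.09, 0.1, 0.12)) {  # drives beyond every multistable interval
    ue <- sapply(Ds, function(D) max(find_equilibria(network_params(D = D), io)$u_e))
    expect_true(all(diff(ue) < 0))
  }
})

test_that("refined interval endpoints behave as saddle-node points", {
  p <- network_params(D = 0.005)
  bd <- bifurcation_sweep(p, seq(0, 0.12, by = 0.002))
  iv <- multistable_interval(bd)
  nv <- effective_noise(p)
  eps <- 5e-4
  expect_equal(eistim:::n_equilibria(p, iv[1] - eps, nv), 1L)
  expect_equal(eistim:::n_equilibria(p, iv[1] + eps, nv), 3L)
  expect_equal(eistim:::n_equilibria(p, iv[2] - eps, nv), 3L)
  expect_equal(eistim:::n_equilibria(p, iv[2] + eps, nv), 1L)
  # at a saddle-node the two merging equilibria are within O(sqrt(eps))
  eq <- find_equilibria(p, iv[1] + eps)
  d <- sort(abs(diff(eq$u_e)))
  expect_lt(d[1], 0.05)
})

test_that("bifurcation diagrams serialize to CSV plus a JSON summary", {
  bd <- bifurcation_sweep(network_params(D = 0.05), seq(0, 0.1, by = 0.02))
  fc <- withr::local_tempfile(fileext = ".csv")
  fj <- withr::local_tempfile(fileext = ".json")
  s <- write_bifurcation(bd, fc, fj)
  d <- read.csv(fc)
  expect_equal(names(d), c("I_o", "branch", "u_e", "u_i", "damping", "eigfreq_hz", "stable"))
  j <- jsonlite::read_json(fj)
  expect_null(j$multistable_interval)
  expect_equal(j$Dbar_e, 0.05)
})
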