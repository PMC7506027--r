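#' Effective deviation variance under intrinsic plus filtered-noise stimulation
#'
#' Generic first-order-filter composition: a cell with rate constant `a`
#' receiving intrinsic white noise of variance `D` and a low-pass-filtered
#' noise stimulus (variance parameter `D_s`, cutoff `f_c`) has membrane
#' deviations of variance `a D + a D_s f_c / (a + f_c)`. The white-noise limit
#' `f_c -> Inf` gives the maximum `a (D + D_s)`; `f_c -> 0` leaves only the
#' intrinsic term `a D`.
#'
#' @param a rate constant.
#' @param D intrinsic noise variance.
#' @param D_s stimulus noise variance (0 for no stimulation).
#' @param f_c low-pass cutoff frequency (same units as `a`).
#' @return The effective variance.
#' @export
effective_noise_variance <- function(a, D, D_s = 0, f_c = 0) {
  stopifnot(a > 0, D >= 0, D_s >= 0, f_c >= 0)
  extr <- if (D_s == 0) 0 else if (is.infinite(f_c)) a * D_s else a * D_s * f_c / (a + f_c)
  a * D + extr
}

#' Effective noise variances of the E-I network
#'
#' Computes the per-population deviation variances `Dbar_e`, `Dbar_i` that
#' enter the noise-smoothed transfer functions. Without stimulation both equal
#' the intrinsic variance `D` (deviations per membrane time constant). A
#' filtered-noise stimulus of stationary variance `D_s f_c / a_e` adds, by
#' linear filter theory, `Var_S * a / (a + f_c)` to the population with
#' physical rate `a` — so the faster inhibitory population always picks up
#' more of the stimulus than the excitatory one.
#'
#' @param params a [network_params()] object.
#' @param D_s stimulus noise variance (0 for no stimulation).
#' @param f_c stimulus cutoff frequency (Hz).
#' @param D intrinsic noise variance; defaults to `params$D`.
#' @return List with `Dbar_e` and `Dbar_i` (both > 0 whenever `D > 0`).
#' @export
effective_noise <- function(params, D_s = 0, f_c = 0, D = params$D) {
  var_s <- if (D_s == 0 || f_c == 0) 0 else D_s * f_c / params$a_e
  extr <- function(a) {
    if (var_s == 0) 0
    else if (is.infinite(f_c)) var_s
    else var_s * a / (a + f_c)
  }
  list(Dbar_e = D + extr(params$a_e), Dbar_i = D + extr(params$a_i))
}

#' Noise-smoothed (effective) transfer function and its slope
#'
#' The single-cell sigmoid convolved with the stationary Gaussian law of the
#' membrane deviations. For the sharp sigmoid the convolution is the Gaussian
#' CDF: `F[u] = Phi(u / sqrt(Dbar)) = (1 + erf(u / sqrt(2 Dbar))) / 2`, with
#' slope `R[u] = ` the normal density with variance `Dbar` at `u`.
#' [effective_transfer_quad()] evaluates the convolution directly by
#' Gauss-Hermite quadrature at finite sigmoid gain and must agree with the
#' closed form in the infinite-gain limit.
#'
#' @param u membrane value(s).
#' @param Dbar effective deviation variance (> 0).
#' @return `effective_transfer`: values in (0, 1), strictly increasing;
#'   `effective_transfer_slope`: nonnegative slope values.
#' @export
effective_transfer <- function(u, Dbar) {
  if (Dbar <= 0) stop("Dbar must be positive")
  stats::pnorm(u / sqrt(Dbar))
}

#' @rdname effective_transfer
#' @export
effective_transfer_slope <- function(u, Dbar) {
  if (Dbar <= 0) stop("Dbar must be positive")
  stats::dnorm(u, sd = sqrt(Dbar))
}

#' @rdname effective_transfer
#' @param beta sigmoid gain used in the quadrature.
#' @param h sigmoid threshold.
#' @param n_nodes number of Gauss-Hermite nodes for `method = "hermite"`.
#' @param method `"adaptive"` (default) splits the integral at the sigmoid's
#'   transition point and uses adaptive Gauss-Kronrod quadrature on each half,
#'   which resolves the near-step integrand at any gain; `"hermite"` is a
#'   fixed Gauss-Hermite rule, adequate only when `1/beta` is comparable to
#'   `sqrt(Dbar)` (the sharp-sigmoid transition falls between Hermite nodes
#'   otherwise).
#' @export
effective_transfer_quad <- function(u, Dbar, beta = 300, h = 0, n_nodes = 200,
                                    method = c("adaptive", "hermite")) {
  if (Dbar <= 0) stop("Dbar must be positive")
  method <- match.arg(method)
  if (method == "hermite") {
    gh <- pracma::gaussHermite(n_nodes)
    # int f(u + v) N(0, Dbar)(v) dv with v = sqrt(2 Dbar) x
    return(vapply(u, function(ui) {
      sum(gh$w * stats::plogis(beta * (ui + sqrt(2 * Dbar) * gh$x - h))) / sqrt(pi)
    }, numeric(1)))
  }
  sd <- sqrt(Dbar)
  vapply(u, function(ui) {
    g <- function(v) stats::plogis(beta * (ui + v - h)) * stats::dnorm(v, 0, sd)
    v0 <- max(min(h - ui, 9 * sd), -9 * sd)  # sigmoid transition, kept in the mass
    stats::integrate(g, -Inf, v0, rel.tol = 1e-11, abs.tol = 1e-13)$value +
      stats::integrate(g, v0, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }, numeric(1))
}

# Steady-state residuals of the two-population mean-field map.
mf_residuals <- function(u_e, u_i, params, I_o, noise) {
  Fe <- effective_transfer(u_e, noise$Dbar_e)
  Fi <- effective_transfer(u_i, noise$Dbar_i)
  c(params$w_ee * Fe + params$w_ie * Fi + params$I_e + I_o - u_e,
    params$w_ei * Fe + params$w_ii * Fi + params$I_i - u_i)
}

# Newton polish of an equilibrium from a starting point; returns c(u_e, u_i)
# or NULL if it fails to reach the residual tolerance.
mf_newton <- function(u_e, u_i, params, I_o, noise, tol = 1e-12, max_iter = 60) {
  for (it in seq_len(max_iter)) {
    g <- mf_residuals(u_e, u_i, params, I_o, noise)
    if (max(abs(g)) < tol) return(c(u_e, u_i))
    Re_ <- effective_transfer_slope(u_e, noise$Dbar_e)
    Ri <- effective_transfer_slope(u_i, noise$Dbar_i)
    J <- matrix(c(params$w_ee * Re_ - 1, params$w_ie * Ri,
                  params$w_ei * Re_, params$w_ii * Ri - 1), 2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damp large steps to stay on the transfer's responsive range
    sc <- max(1, max(abs(step)) / 0.5)
    u_e <- u_e - step[1] / sc
    u_i <- u_i - step[2] / sc
  }
  g <- mf_residuals(u_e, u_i, params, I_o, noise)
  if (max(abs(g)) < tol) c(u_e, u_i) else NULL
}

# Vectorized scan of the equilibrium curve parameterized by u_i:
# from the inhibitory steady-state equation, F_e = (u_i - w_ii F_i - I_i)/w_ei
# determines u_e = sqrt(Dbar_e) qnorm(F_e); sign changes of the excitatory
# residual along the curve bracket every equilibrium (unique u_i branch since
# w_ii <= 0 makes the inhibitory equation monotone in u_i).
mf_scan <- function(params, I_o, noise, n_grid = 6000) {
  if (params$w_ii > 0 &&
      params$w_ii * effective_transfer_slope(0, noise$Dbar_i) >= 1)
    stop("self-excitatory inhibitory coupling strong enough for multiple u_i branches is not supported")
  if (params$w_ei != 0) {
    # the inhibitory equation confines equilibria to g(u_i) = u_i - w_ii F_i(u_i)
    # in (I_i, I_i + w_ei); g is monotone for w_ii <= 0, so invert its ends
    g_inv <- function(cv) stats::uniroot(function(ui)
      ui - params$w_ii * effective_transfer(ui, noise$Dbar_i) - cv,
      interval = cv + c(-abs(params$w_ii) - 1, abs(params$w_ii) + 1),
      tol = 1e-13)$root
    ui_f0 <- g_inv(params$I_i)                 # u_i branch end where F_e = 0
    ui_f1 <- g_inv(params$I_i + params$w_ei)   # ... and where F_e = 1
    ends <- sort(c(ui_f0, ui_f1))
    pad <- 1e-7 * max(1, diff(ends))
    ui <- seq(ends[1] + pad, ends[2] - pad, length.out = n_grid)
    Fi <- effective_transfer(ui, noise$Dbar_i)
    Fe <- (ui - params$w_ii * Fi - params$I_i) / params$w_ei
    ok <- Fe > 1e-14 & Fe < 1 - 1e-14
    uio <- ui[ok]; Fio <- Fi[ok]; Feo <- Fe[ok]
    ue <- sqrt(noise$Dbar_e) * stats::qnorm(Feo)
    res <- params$w_ee * Feo + params$w_ie * Fio + params$I_e + I_o - ue
    flips <- which(res[-1] * res[-length(res)] <= 0 & res[-length(res)] != 0)
    starts <- cbind(ue = (ue[flips] + ue[flips + 1]) / 2,
                    ui = (uio[flips] + uio[flips + 1]) / 2)
    # equilibria deep in the saturated tails (F_e numerically 0 or 1) fall
    # outside the qnorm-parameterized stretch; add them as direct candidates
    sd_e <- sqrt(noise$Dbar_e)
    lo_tail <- params$w_ie * effective_transfer(ui_f0, noise$Dbar_i) +
      params$I_e + I_o
    if (stats::pnorm(lo_tail / sd_e) < 1e-6)
      starts <- rbind(starts, c(lo_tail, ui_f0))
    hi_tail <- params$w_ee + params$w_ie * effective_transfer(ui_f1, noise$Dbar_i) +
      params$I_e + I_o
    if (stats::pnorm(hi_tail / sd_e) > 1 - 1e-6)
      starts <- rbind(starts, c(hi_tail, ui_f1))
    if (!nrow(starts))
      stop(sprintf("no equilibrium bracketed at I_o = %g; widen the scan grid", I_o))
  } else {
    # inhibitory equation decouples: solve u_i once, then 1-D scan in u_e
    ui_star <- stats::uniroot(function(ui)
      ui - params$w_ii * effective_transfer(ui, noise$Dbar_i) - params$I_i,
      interval = params$I_i + c(min(0, params$w_ii) - 1, max(0, params$w_ii) + 1),
      tol = 1e-14)$root
    base <- params$w_ie * effective_transfer(ui_star, noise$Dbar_i) + params$I_e + I_o
    pad <- 6 * sqrt(noise$Dbar_e) + 1
    ue <- seq(base + min(0, params$w_ee) - pad, base + max(0, params$w_ee) + pad,
              length.out = n_grid)
    res <- params$w_ee * effective_transfer(ue, noise$Dbar_e) + base - ue
    flips <- which(res[-1] * res[-length(res)] <= 0 & res[-length(res)] != 0)
    starts <- cbind(ue = (ue[flips] + ue[flips + 1]) / 2, ui = ui_star)
  }
  starts
}

#' Find all mean-field equilibria at a given drive
#'
#' Solves the coupled steady-state equations
#' `u_e = w_ee F_e[u_e] + w_ie F_i[u_i] + I_e + I_o` and
#' `u_i = w_ei F_e[u_e] + w_ii F_i[u_i] + I_i`
#' with the noise-smoothed transfer functions, returning every real solution.
#' The equilibrium curve is scanned in a fully vectorized parameterization and
#' each bracketed root is polished by Newton iteration to residuals below
#' 1e-12; duplicates within 1e-6 are merged. Each equilibrium is annotated
#' with its linear stability (see [linear_stability()]).
#'
#' @param params a [network_params()] object.
#' @param I_o tonic excitatory drive.
#' @param noise effective variances from [effective_noise()]; defaults to the
#'   intrinsic-only case.
#' @param n_grid scan resolution.
#' @return A data frame of class `equilibria` with columns `u_e`, `u_i`,
#'   `I_o`, `damping` (1/s), `eigfreq` (rad/s), `eigfreq_hz`, `stable`.
#' @export
find_equilibria <- function(params, I_o, noise = effective_noise(params),
                            n_grid = 6000) {
  starts <- mf_scan(params, I_o, noise, n_grid)
  sols <- list()
  for (r in seq_len(nrow(starts))) {
    s <- mf_newton(starts[r, 1], starts[r, 2], params, I_o, noise)
    if (!is.null(s)) sols[[length(sols) + 1L]] <- s
  }
  if (!length(sols)) stop(sprintf("no equilibria converged at I_o = %g", I_o))
  m <- do.call(rbind, sols)
  keep <- rep(TRUE, nrow(m))
  for (r in seq_len(nrow(m))[-1]) {
    if (any(vapply(which(keep[seq_len(r - 1)]), function(q)
      max(abs(m[r, ] - m[q, ])) < 1e-6, logical(1)))) keep[r] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  stab <- lapply(seq_len(nrow(m)), function(r)
    linear_stability(params, m[r, 1], m[r, 2], noise))
  out <- data.frame(u_e = m[, 1], u_i = m[, 2], I_o = I_o,
                    damping = vapply(stab, `[[`, numeric(1), "damping"),
                    eigfreq = vapply(stab, `[[`, numeric(1), "eigfreq"),
                    eigfreq_hz = vapply(stab, `[[`, numeric(1), "eigfreq") / (2 * pi),
                    stable = vapply(stab, `[[`, logical(1), "stable"))
  class(out) <- c("equilibria", "data.frame")
  out
}

#' Linear stochastic stability of a mean-field equilibrium
#'
#' Linearizes the population equations about `(u_e, u_i)` using the slopes
#' `R_e`, `R_i` of the noise-smoothed transfers and evaluates the eigenvalues
#' of the rate-scaled Jacobian
#' `J = [[a_e (-1 + w_ee R_e), a_e w_ie R_i], [a_i w_ei R_e, a_i (-1 + w_ii R_i)]]`
#' by two independent routes — direct eigendecomposition and the closed form
#' `lambda = (G ± sqrt(H))/2` with `G = tr J` and `H = (tr J)^2 - 4 det J`
#' written out in the weight/slope terms. Disagreement beyond 1e-9 relative is
#' a hard error (an implementation-bug trap, not a user condition).
#'
#' @param params a [network_params()] object.
#' @param u_e,u_i equilibrium membrane values.
#' @param noise effective variances from [effective_noise()].
#' @return List with `damping` (Re lambda of the leading eigenvalue, 1/s),
#'   `eigfreq` (|Im lambda|, rad/s), `eigfreq_hz`, `stable` (damping < 0) and
#'   `lambda` (both eigenvalues, complex).
#' @export
linear_stability <- function(params, u_e, u_i, noise = effective_noise(params)) {
  Re_ <- effective_transfer_slope(u_e, noise$Dbar_e)
  Ri <- effective_transfer_slope(u_i, noise$Dbar_i)
  a_e <- params$a_e; a_i <- params$a_i
  wee <- params$w_ee; wei <- params$w_ei; wie <- params$w_ie; wii <- params$w_ii

  J <- matrix(c(a_e * (-1 + wee * Re_), a_e * wie * Ri,
                a_i * wei * Re_, a_i * (-1 + wii * Ri)), 2, 2, byrow = TRUE)
  ev <- eigen(J, only.values = TRUE)$values

  G <- wee * Re_ * a_e + wii * Ri * a_i - (a_e + a_i)
  H <- (wee * Re_ * a_e)^2 + (wii * Ri * a_i)^2 -
    2 * a_e * a_i * Re_ * Ri * wee * wii +
    4 * a_e * a_i * Re_ * Ri * wei * wie -
    2 * a_e^2 * Re_ * wee + 2 * a_e * a_i * Re_ * wee +
    2 * a_e * a_i * Ri * wii - 2 * a_i^2 * Ri * wii -
    2 * a_e * a_i + a_i^2 + a_e^2
  lam <- (G + c(1, -1) * sqrt(as.complex(H))) / 2

  scale <- max(abs(lam), abs(ev), 1e-12)
  mismatch <- min(max(abs(sort_complex(lam) - sort_complex(ev))),
                  max(abs(sort_complex(lam) - sort_complex(rev(ev))))) / scale
  if (mismatch > 1e-9)
    stop("closed-form and numerical eigenvalues disagree: internal error")

  lead <- lam[which.max(Re(lam))]
  list(damping = Re(lead), eigfreq = abs(Im(lead)),
       eigfreq_hz = abs(Im(lead)) / (2 * pi),
       stable = Re(lead) < 0, lambda = lam)
}

sort_complex <- function(z) z[order(Re(z), Im(z))]

# number of distinct polished equilibria at a drive
n_equilibria <- function(params, I_o, noise, n_grid = 6000) {
  nrow(find_equilibria(params, I_o, noise, n_grid))
}

#' Bifurcation sweep over the tonic drive
#'
#' Runs [find_equilibria()] at every grid drive and annotates the multistable
#' interval — the extent of drives with three or more coexisting equilibria,
#' bounded by two saddle-node points — refining its endpoints by bisection.
#'
#' @param params a [network_params()] object.
#' @param drive_grid sorted vector of `I_o` values.
#' @param noise effective variances from [effective_noise()].
#' @param refine_tol bisection tolerance for the interval endpoints.
#' @return An object of class `bifurcation_diagram`: list with `branches` (a
#'   data frame of equilibria across the grid, with a `branch` index per
#'   drive), `multistable_interval` (`c(lo, hi)` or `NULL`), `noise`, and
#'   `drive_grid`.
#' @export
bifurcation_sweep <- function(params, drive_grid, noise = effective_noise(params),
                              refine_tol = 1e-4) {
  if (is.unsorted(drive_grid)) stop("drive_grid must be sorted")
  eqs <- lapply(drive_grid, function(io) {
    e <- find_equilibria(params, io, noise)
    e$branch <- seq_len(nrow(e))
    e
  })
  branches <- do.call(rbind, eqs)
  counts <- vapply(eqs, nrow, integer(1))
  multi <- counts >= 3
  interval <- NULL
  if (any(multi)) {
    i_lo <- which(multi)[1]
    i_hi <- which(multi)[sum(multi)]
    nfun <- function(io) n_equilibria(params, io, noise)
    lo <- if (i_lo == 1) drive_grid[1] else
      bisect_edge(nfun, drive_grid[i_lo - 1], drive_grid[i_lo], refine_tol, rising = TRUE)
    hi <- if (i_hi == length(drive_grid)) drive_grid[length(drive_grid)] else
      bisect_edge(nfun, drive_grid[i_hi], drive_grid[i_hi + 1], refine_tol, rising = FALSE)
    interval <- c(lo, hi)
  }
  structure(list(branches = branches, multistable_interval = interval,
                 noise = noise, drive_grid = drive_grid, params = params),
            class = "bifurcation_diagram")
}

# locate the drive at which the equilibrium count crosses 3, by bisection;
# rising = TRUE means counts go 1 -> 3 across [a, b]
bisect_edge <- function(nfun, a, b, tol, rising) {
  while (b - a > tol) {
    m <- (a + b) / 2
    inside <- nfun(m) >= 3
    if (inside == rising) b <- m else a <- m
  }
  (a + b) / 2
}

#' Multistable drive interval of a bifurcation diagram
#'
#' @param diagram a `bifurcation_diagram`.
#' @return `c(lo, hi)` in drive units, or `NULL` when no grid point has three
#'   coexisting equilibria.
#' @export
multistable_interval <- function(diagram) diagram$multistable_interval

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("bifurcation diagram over I_o in [%g, %g] (%d drives)\n",
              min(x$drive_grid), max(x$drive_grid), length(x$drive_grid)))
  iv <- x$multistable_interval
  if (is.null(iv)) cat("  no multistable interval\n")
  else cat(sprintf("  multistable for I_o in [%.4f, %.4f] (midpoint %.4f)\n",
                   iv[1], iv[2], mean(iv)))
  invisible(x)
}

#' Serialize a bifurcation diagram
#'
#' Writes the branch table as CSV (`I_o, branch, u_e, u_i, damping,
#' eigfreq_hz, stable`) and a JSON summary with the interval endpoints and
#' effective variances.
#'
#' @param diagram a `bifurcation_diagram`.
#' @param csv_file,json_file output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_bifurcation <- function(diagram, csv_file = NULL, json_file = NULL) {
  if (!is.null(csv_file)) {
    b <- diagram$branches
    utils::write.csv(b[, c("I_o", "branch", "u_e", "u_i", "damping",
                           "eigfreq_hz", "stable")], csv_file, row.names = FALSE)
  }
  summary <- list(multistable_interval = diagram$multistable_interval,
                  Dbar_e = diagram$noise$Dbar_e, Dbar_i = diagram$noise$Dbar_i,
                  n_drives = length(diagram$drive_grid))
  if (!is.null(json_file))
    jsonlite::write_json(summary, json_file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}
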