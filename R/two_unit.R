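#' Fixed point of the reduced two-unit model
#'
#' With no spatial coupling the network reduces to two units whose
#' equilibrium solves `r_a = phi(u_a)` with
#' `u_a = W_ae r_e + W_ai r_i + mu_a`. The solver runs damped Newton
#' iterations from a coarse grid scan over `[0, 10]^2` and returns the
#' solution with residual below `1e-10`.
#'
#' @param params A [field_params()] object (only weights, drives and time
#'   constants are used).
#' @param grid_n Number of scan points per axis.
#' @return An object of class `two_unit_fp` with equilibrium rates `r_e`,
#'   `r_i`, equilibrium inputs `u_e`, `u_i` and the residual.
#' @export
two_unit_fixed_point <- function(params, grid_n = 41) {
  stopifnot(inherits(params, "field_params"))
  W <- matrix(c(params$W_ee, params$W_ie, params$W_ei, params$W_ii), 2, 2)
  mu <- c(params$mu_e, params$mu_i)
  Ffun <- function(r) -r + transfer(drop(W %*% r) + mu)
  newton <- function(r) {
    for (it in 1:200) {
      u <- drop(W %*% r) + mu
      F <- -r + transfer(u)
      if (max(abs(F)) < 1e-13) break
      L <- transfer_deriv(u)
      J <- diag(-1, 2) + L * W            # rows scaled by L_alpha
      step <- tryCatch(solve(J, F), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      # damped update: keep rates finite and make progress on the residual
      lam <- 1
      repeat {
        rn <- r - lam * step
        if (all(is.finite(rn)) &&
            (max(abs(Ffun(pmax(rn, 0)))) < max(abs(F)) || lam < 1e-4)) break
        lam <- lam / 2
      }
      r <- rn
    }
    r
  }
  best <- NULL
  scan <- seq(0, 10, length.out = grid_n)
  for (re0 in scan) {
    for (ri0 in scan) {
      r <- newton(c(re0, ri0))
      if (is.null(r)) next
      if (any(r < -1e-9) || max(abs(Ffun(r))) > 1e-10) next
      best <- pmax(r, 0)  # the model's fixed point is unique; first root wins
      break
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    stop("no fixed point with residual < 1e-10 found", call. = FALSE)
  u <- drop(W %*% best) + mu
  structure(list(r_e = best[1], r_i = best[2], u_e = u[1], u_i = u[2],
                 residual = max(abs(Ffun(best)))),
            class = "two_unit_fp")
}

#' @export
print.two_unit_fp <- function(x, ...) {
  cat(sprintf(
    "Two-unit fixed point: r_e=%.6g, r_i=%.6g (u_e*=%.6g, u_i*=%.6g)\n",
    x$r_e, x$r_i, x$u_e, x$u_i))
  invisible(x)
}

#' Jacobian of the two-unit model at a fixed point
#'
#' Returns the 2x2 matrix
#' `[[(-1 + L_e W_ee)/tau_e, L_e W_ei/tau_e],
#'   [L_i W_ie/tau_i, (-1 + L_i W_ii)/tau_i]]`
#' with gains `L_a = phi'(u_a*)` at the equilibrium inputs.
#'
#' @param params A [field_params()] object.
#' @param fp A fixed point from [two_unit_fixed_point()]; computed if
#'   omitted.
#' @return A 2x2 numeric matrix.
#' @export
two_unit_jacobian <- function(params, fp = NULL) {
  stopifnot(inherits(params, "field_params"))
  if (is.null(fp)) fp <- two_unit_fixed_point(params)
  L_e <- transfer_deriv(fp$u_e)
  L_i <- transfer_deriv(fp$u_i)
  matrix(c((-1 + L_e * params$W_ee) / params$tau_e,
           L_i * params$W_ie / params$tau_i,
           L_e * params$W_ei / params$tau_e,
           (-1 + L_i * params$W_ii) / params$tau_i), 2, 2)
}

#' Hopf bifurcation point in the inhibitory time constant
#'
#' Bisects `tau_i` for the zero crossing of the real part of the leading
#' Jacobian eigenvalue of the two-unit fixed point. The fixed point itself
#' does not depend on `tau_i`, so only the Jacobian is recomputed. The
#' crossing is flagged as a Hopf bifurcation when the eigenvalues there are
#' a complex pair.
#'
#' @param params A [field_params()] object (`tau_i` is ignored).
#' @param tau_range Search interval (ms) that must bracket the crossing.
#' @param tol Bisection tolerance (ms).
#' @return A list with `tau_hb` (ms), `omega` (imaginary part at the
#'   crossing, rad/ms) and `hopf` (logical).
#' @examples
#' hopf_point(field_params(tau_i = 8, sigma_i = 0.1, n_side = 16))$tau_hb
#' @export
hopf_point <- function(params, tau_range = c(4, 15), tol = 1e-8) {
  stopifnot(inherits(params, "field_params"), length(tau_range) == 2)
  fp <- two_unit_fixed_point(params)
  lead_re <- function(tau_i) {
    J <- two_unit_jacobian(update_params(params, tau_i = tau_i), fp)
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  lo <- min(tau_range); hi <- max(tau_range)
  f_lo <- lead_re(lo); f_hi <- lead_re(hi)
  if (f_lo * f_hi > 0)
    stop("leading eigenvalue real part does not change sign on tau_range",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (lead_re(mid) * f_lo <= 0) hi <- mid else lo <- mid
  }
  tau_hb <- (lo + hi) / 2
  ev <- eigen(two_unit_jacobian(update_params(params, tau_i = tau_hb), fp),
              only.values = TRUE)$values
  list(tau_hb = tau_hb, omega = max(abs(Im(ev))),
       hopf = max(abs(Im(ev))) > 1e-8)
}

#' Integrate the reduced two-unit model
#'
#' Classical RK4 on the two-unit ODEs (the no-spatial-coupling reduction).
#'
#' @param params A [field_params()] object.
#' @param init Length-2 numeric `(r_e, r_i)` initial rates.
#' @param duration Duration (ms).
#' @param dt Step (ms); defaults to `params$dt`.
#' @param record_stride Record every this many steps (0: final state only).
#' @return A list with `t`, `re`, `ri` (if recorded) and `final_re`,
#'   `final_ri`.
#' @export
two_unit_simulate <- function(params, init, duration, dt = params$dt,
                              record_stride = 1L) {
  stopifnot(inherits(params, "field_params"), length(init) == 2)
  n_steps <- as.integer(round(duration / dt))
  cpp_two_unit(init[1], init[2], unclass(params), dt, n_steps,
               as.integer(record_stride))
}

# upward mean-level crossing times of x(t) with local quadratic interpolation
crossing_times <- function(t, x, level) {
  s <- x - level
  idx <- which(s[-length(s)] < 0 & s[-1] >= 0)
  idx <- idx[idx > 1 & idx < length(s)]
  vapply(idx, function(j) {
    # quadratic through (t[j-1], t[j], t[j+1]) in shifted time
    tt <- t[(j - 1):(j + 1)] - t[j]
    yy <- s[(j - 1):(j + 1)]
    cf <- solve(cbind(1, tt, tt^2), yy)
    disc <- cf[2]^2 - 4 * cf[3] * cf[1]
    if (abs(cf[3]) < 1e-14 || disc < 0) {
      # fall back to the linear interpolant
      return(t[j] + (t[j + 1] - t[j]) * (-s[j]) / (s[j + 1] - s[j]))
    }
    roots <- (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
    root <- roots[which.min(abs(roots))]
    t[j] + root
  }, numeric(1))
}

#' Find a limit cycle of the two-unit model
#'
#' Integrates past a transient, then detects the oscillation period from
#' successive upward crossings of `r_e` through its mean (with quadratic
#' interpolation between samples, averaged over at least 10 cycles). When
#' the trajectory's oscillation amplitude has collapsed below `amp_tol` the
#' function reports convergence to the fixed point instead.
#'
#' @param params A [field_params()] object.
#' @param init Length-2 initial rates; default `(1, 1)`.
#' @param transient Transient discarded before detection (ms).
#' @param duration Recorded span used for detection (ms).
#' @param dt Integration step (ms).
#' @param amp_tol Oscillation amplitude below which the trajectory is
#'   declared stationary.
#' @return An object of class `limit_cycle` with the period `T` (ms), a
#'   densely sampled orbit (`t`, `r_e`, `r_i`, and equilibrium-input traces
#'   `u_e`, `u_i`) over one period, extrema of `r_e`, and `n_cycles` used;
#'   or an object of class `fixed_point_signal` if no oscillation persists.
#' @examples
#' p <- field_params(tau_i = 9, sigma_i = 0.1, n_side = 16)
#' lc <- find_limit_cycle(p)
#' lc$period
#' @export
find_limit_cycle <- function(params, init = c(1, 1), transient = 2000,
                             duration = 1000, dt = 0.01, amp_tol = 1e-4) {
  stopifnot(inherits(params, "field_params"))
  warm <- two_unit_simulate(params, init, transient, dt = dt,
                            record_stride = 0L)
  sim <- two_unit_simulate(params, c(warm$final_re, warm$final_ri),
                           duration, dt = dt, record_stride = 1L)
  amp <- max(sim$re) - min(sim$re)
  if (amp < amp_tol) {
    return(structure(list(r_e = mean(sim$re), r_i = mean(sim$ri),
                          amplitude = amp),
                     class = "fixed_point_signal"))
  }
  level <- mean(sim$re)
  tc <- crossing_times(sim$t, sim$re, level)
  if (length(tc) < 11) {
    # extend until enough cycles are available
    sim <- two_unit_simulate(params, c(warm$final_re, warm$final_ri),
                             duration * 10, dt = dt, record_stride = 1L)
    level <- mean(sim$re)
    tc <- crossing_times(sim$t, sim$re, level)
    if (length(tc) < 3)
      stop("trajectory is neither periodic nor stationary", call. = FALSE)
  }
  periods <- diff(tc)
  period <- mean(periods[pmax(1, length(periods) - 19):length(periods)])
  # one period of orbit samples starting at the last-but-one crossing
  t0 <- tc[length(tc) - 1]
  seg <- sim$t >= t0 - dt & sim$t <= t0 + period + dt
  ts <- sim$t[seg] - t0
  orbit_e <- sim$re[seg]
  orbit_i <- sim$ri[seg]
  tt <- seq(0, period, length.out = max(4000, 2 * ceiling(period / dt)))
  r_e <- splinefun(ts, orbit_e)(tt)
  r_i <- splinefun(ts, orbit_i)(tt)
  closure <- sqrt((r_e[1] - r_e[length(tt)])^2 +
                    (r_i[1] - r_i[length(tt)])^2)
  # enforce exact closure for downstream periodic interpolation
  r_e[length(tt)] <- r_e[1]
  r_i[length(tt)] <- r_i[1]
  structure(list(
    period = period, t = tt, r_e = r_e, r_i = r_i,
    u_e = params$W_ee * r_e + params$W_ei * r_i + params$mu_e,
    u_i = params$W_ie * r_e + params$W_ii * r_i + params$mu_i,
    r_e_max = max(orbit_e), r_e_min = min(orbit_e),
    n_cycles = length(periods), closure = closure, dt = dt,
    period_sd = sd(periods)),
    class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf(
    "Limit cycle: period %.4g ms, r_e in [%.4g, %.4g] (%d cycles, closure %.2g)\n",
    x$period, x$r_e_min, x$r_e_max, x$n_cycles, x$closure))
  invisible(x)
}

#' @export
print.fixed_point_signal <- function(x, ...) {
  cat(sprintf("Converged to fixed point: r_e=%.6g, r_i=%.6g (amplitude %.2g)\n",
              x$r_e, x$r_i, x$amplitude))
  invisible(x)
}

#' Bistability interval of the two-unit model
#'
#' The upper endpoint is the Hopf bifurcation from [hopf_point()]. The lower
#' endpoint is found by a hysteresis sweep: starting on the stable limit
#' cycle (default at `tau_i = 8` ms), `tau_i` is decreased in `step`
#' increments, each run re-seeded from the previous endpoint, until the
#' oscillation amplitude collapses below `amp_tol`; the last `tau_i` that
#' sustained the cycle is returned.
#'
#' @param params A [field_params()] object.
#' @param tau_start Starting `tau_i` (ms) inside the oscillatory regime.
#' @param step Sweep decrement (ms).
#' @param sim_time Integration time per sweep point (ms).
#' @param dt Integration step (ms).
#' @param amp_tol Amplitude collapse threshold.
#' @return A list with `tau_lo`, `tau_hb` (ms).
#' @export
bistability_interval <- function(params, tau_start = 8, step = 0.01,
                                 sim_time = 2000, dt = 0.05,
                                 amp_tol = 1e-4) {
  stopifnot(inherits(params, "field_params"))
  hb <- hopf_point(params)
  state <- c(1, 1)
  warm <- two_unit_simulate(update_params(params, tau_i = tau_start),
                            state, 2000, dt = dt, record_stride = 0L)
  state <- c(warm$final_re, warm$final_ri)
  tau <- tau_start
  tau_lo <- tau_start
  while (tau > tau_start - 2) {
    tau <- round(tau - step, 10)
    sim <- two_unit_simulate(update_params(params, tau_i = tau), state,
                             sim_time, dt = dt,
                             record_stride = max(1L, as.integer(1 / dt)))
    half <- sim$re[-seq_len(length(sim$re) %/% 2)]
    amp <- max(half) - min(half)
    if (amp < amp_tol) break
    tau_lo <- tau
    state <- c(sim$final_re, sim$final_ri)
  }
  list(tau_lo = tau_lo, tau_hb = hb$tau_hb)
}

#' Bifurcation diagram of the two-unit model over `tau_i`
#'
#' For each `tau_i`: the fixed point and its eigenvalue stability, and (when
#' an oscillation is found from the supplied or inherited initial condition)
#' the limit-cycle extrema, period, and its Floquet stability at spatial
#' mode 0.
#'
#' @param params A [field_params()] object.
#' @param tau_values Increasing `tau_i` samples (ms).
#' @param init Initial rates for the first limit-cycle search.
#' @return A data frame of class `bifurcation_diagram` with columns
#'   `tau_i`, `re_fp`, `ri_fp`, `fp_stable`, `lc_found`, `lc_remax`,
#'   `lc_remin`, `lc_period`, `lc_stable`.
#' @export
bifurcation_diagram <- function(params, tau_values, init = c(1, 1)) {
  stopifnot(inherits(params, "field_params"))
  fp <- two_unit_fixed_point(params)
  rows <- lapply(tau_values, function(tau) {
    p <- update_params(params, tau_i = tau)
    ev <- eigen(two_unit_jacobian(p, fp), only.values = TRUE)$values
    lc <- find_limit_cycle(p, init = init)
    found <- inherits(lc, "limit_cycle")
    lc_stable <- NA
    if (found) {
      M <- monodromy(p, lc, 0)
      mult <- abs(eigen(M, only.values = TRUE)$values)
      # one multiplier is the trivial unit (tangent) one
      lc_stable <- sort(mult)[1] <= 1 + 1e-3
    }
    data.frame(tau_i = tau, re_fp = fp$r_e, ri_fp = fp$r_i,
               fp_stable = max(Re(ev)) < 0, lc_found = found,
               lc_remax = if (found) lc$r_e_max else NA_real_,
               lc_remin = if (found) lc$r_e_min else NA_real_,
               lc_period = if (found) lc$period else NA_real_,
               lc_stable = lc_stable)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bifurcation_diagram", "data.frame")
  out
}

#' Export a bifurcation diagram to CSV
#'
#' @param diagram A [bifurcation_diagram()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bifurcation_csv <- function(diagram, path) {
  write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}
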