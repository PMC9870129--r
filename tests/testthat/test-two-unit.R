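test_that("fixed point solves the equilibrium conditions", {
  # decoupled network: r = phi(mu)
  p0 <- field_params(tau_i = 8, sigma_i = 0.1, W_ee = 0, W_ei = 0,
                     W_ie = 0, W_ii = 0, n_side = 16)
  fp0 <- two_unit_fixed_point(p0)
  expect_equal(fp0$r_e, 0.48^2, tolerance = 1e-10)
  expect_equal(fp0$r_i, 0.32^2, tolerance = 1e-10)
  # fully rectified network: zero rates
  pneg <- field_params(tau_i = 8, sigma_i = 0.1, W_ee = 0, W_ei = -10,
                       W_ie = 0, W_ii = -10, mu_e = -0.2, mu_i = -0.1,
                       n_side = 16)
  fpn <- two_unit_fixed_point(pneg)
  expect_equal(c(fpn$r_e, fpn$r_i), c(0, 0))
  # default parameters: agreement with a brute-force grid + polish oracle
  p <- tp(8, 0.1)
  fp <- two_unit_fixed_point(p)
  expect_lt(fp$residual, 1e-10)
  res <- function(r1, r2) {
    u1 <- p$W_ee * r1 + p$W_ei * r2 + p$mu_e
    u2 <- p$W_ie * r1 + p$W_ii * r2 + p$mu_i
    (-r1 + pmax(u1, 0)^2)^2 + (-r2 + pmax(u2, 0)^2)^2
  }
  # derivative-free oracle: 400^2 grid search with iterative refinement
  lo <- c(0, 0); hi <- c(0.4, 0.4)
  for (round in 1:8) {
    g1 <- seq(lo[1], hi[1], length.out = 400)
    g2 <- seq(lo[2], hi[2], length.out = 400)
    R <- outer(g1, g2, res)
    ij <- arrayInd(which.min(R), dim(R))
    ctr <- c(g1[ij[1]], g2[ij[2]])
    span <- (hi - lo) / 10   # keep ~80 grid cells of slack around the best
    lo <- pmax(ctr - span, 0); hi <- ctr + span
  }
  expect_equal(c(fp$r_e, fp$r_i), ctr, tolerance = 1e-5)
})

test_that("two-unit Jacobian has the gain-scaled structure", {
  p0 <- field_params(tau_i = 7, sigma_i = 0.1, W_ee = 0, W_ei = 0,
                     W_ie = 0, W_ii = 0, n_side = 16)
  expect_equal(two_unit_jacobian(p0), diag(c(-1 / 5, -1 / 7)))
  # both equilibrium inputs negative: zero gains
  pneg <- field_params(tau_i = 7, sigma_i = 0.1, W_ee = 0, W_ei = -10,
                       W_ie = 0, W_ii = -10, mu_e = -0.2, mu_i = -0.1,
                       n_side = 16)
  expect_equal(two_unit_jacobian(pneg), diag(c(-1 / 5, -1 / 7)))
  # default weights, small tau_i: stable spiral
  ev <- eigen(two_unit_jacobian(tp(5, 0.1)))$values
  expect_true(all(Re(ev) < 0))
})

test_that("Hopf point matches the analytic trace condition", {
  p <- tp(8, 0.1)
  hb <- hopf_point(p)
  # closed-form oracle: trace of the Jacobian vanishes at the Hopf point
  fp <- two_unit_fixed_point(p)
  L_e <- 2 * max(fp$u_e, 0)
  L_i <- 2 * max(fp$u_i, 0)
  tau_exact <- -(-1 + L_i * p$W_ii) * p$tau_e / (-1 + L_e * p$W_ee)
  expect_equal(hb$tau_hb, tau_exact, tolerance = 1e-6)
  expect_true(hb$hopf)
  # Hopf conditions: zero trace, positive determinant
  J <- two_unit_jacobian(update_params(p, tau_i = hb$tau_hb), fp)
  expect_lt(abs(sum(diag(J))), 1e-7)
  expect_gt(det(J), 0)
  # bracketing-interval invariance
  hb2 <- hopf_point(p, tau_range = c(6, 20))
  expect_equal(hb$tau_hb, hb2$tau_hb, tolerance = 1e-6)
  # no crossing: decoupled network
  p0 <- field_params(tau_i = 8, sigma_i = 0.1, W_ee = 0, W_ei = 0,
                     W_ie = 0, W_ii = 0, n_side = 16)
  expect_error(hopf_point(p0), "sign")
})

test_that("limit-cycle detection finds the oscillation and its period", {
  p9 <- tp(9, 0.1)
  lc <- find_limit_cycle(p9)
  expect_s3_class(lc, "limit_cycle")
  expect_lt(lc$closure, 1e-6)
  expect_gte(lc$n_cycles, 10)
  # independent period oracle: autocorrelation peak of a long run
  sim <- two_unit_simulate(p9, c(lc$r_e[1], lc$r_i[1]), 600, dt = 0.01)
  x <- sim$re - mean(sim$re)
  ac <- acf(x, lag.max = 5000, plot = FALSE)$acf
  pk <- which(diff(sign(diff(ac))) == -2) + 1
  per_ac <- pk[which.max(ac[pk])] * 0.01
  expect_lt(abs(lc$period - per_ac) / lc$period, 0.01)
  # small tau_i: stationary
  expect_s3_class(find_limit_cycle(tp(5, 0.1)), "fixed_point_signal")
})

test_that("the fixed point and the limit cycle coexist in the bistable
           window, selected by the initial condition", {
  p <- tp(7.5, 0.1)
  fp <- two_unit_fixed_point(p)
  near <- find_limit_cycle(p, init = c(fp$r_e * 1.01, fp$r_i * 1.01))
  expect_s3_class(near, "fixed_point_signal")
  far <- find_limit_cycle(p, init = c(1, 1))
  expect_s3_class(far, "limit_cycle")
})

test_that("hysteresis sweep brackets the cycle's fold", {
  p <- tp(8, 0.1)
  bi <- bistability_interval(p, step = 0.05, sim_time = 1000)
  expect_lt(bi$tau_lo, bi$tau_hb)
  expect_gt(bi$tau_lo, 7.0)
  expect_lt(bi$tau_lo, 7.4)
})

test_that("bifurcation diagram labels the branches", {
  p <- tp(8, 0.1)
  bd <- bifurcation_diagram(p, c(7.0, 7.5, 9.0))
  expect_equal(nrow(bd), 3)
  # below the fold: stable fixed point only
  expect_true(bd$fp_stable[1])
  expect_false(bd$lc_found[1])
  # bistable window: both attractors, both stable
  expect_true(bd$fp_stable[2])
  expect_true(bd$lc_found[2])
  expect_true(bd$lc_stable[2])
  # beyond the Hopf: unstable fixed point, stable cycle
  expect_false(bd$fp_stable[3])
  expect_true(bd$lc_found[3])
  expect_true(bd$lc_stable[3])
  expect_true(all(diff(bd$tau_i) > 0))
  f <- tempfile(fileext = ".csv")
  write_bifurcation_csv(bd, f)
  expect_true(all(c("tau_i", "lc_remax", "lc_period") %in%
                    names(read.csv(f))))
  unlink(f)
})
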