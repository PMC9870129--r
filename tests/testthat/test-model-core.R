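test_that("parameter constructor validates invariants", {
  p <- tp(8, 0.1)
  expect_s3_class(p, "field_params")
  expect_equal(p$W_ee, 80)
  expect_equal(p$W_ei, -160)
  expect_equal(p$mu_e, 0.48)
  expect_error(tp(-1, 0.1), "positive")
  expect_error(tp(8, 0), "positive")
  expect_error(tp(8, 0.1, n_side = 4), "n_side")
  expect_error(tp(8, 0.1, dt = 1), "dt")
  expect_error(field_params(tau_i = 8, sigma_i = 0.1, dim = 3), "dim")
})

test_that("drift vanishes at the uniform fixed point and reduces to the
           two-unit right-hand side on uniform states", {
  p <- tp(8, 0.1)
  st <- initial_state(p, "fixed_point")
  d <- drift(st, p)
  expect_lt(max(abs(d$dr_e)), 1e-10)
  expect_lt(max(abs(d$dr_i)), 1e-10)
  # uniform state: drift = two-unit RHS broadcast
  su <- initial_state(p, "uniform", amplitude = 0.7)
  d2 <- drift(su, p)
  u_e <- p$W_ee * 0.7 + p$W_ei * 0.7 + p$mu_e
  u_i <- p$W_ie * 0.7 + p$W_ii * 0.7 + p$mu_i
  expect_equal(unique(round(as.vector(d2$dr_e), 12)),
               round((-0.7 + transfer(u_e)) / p$tau_e, 12))
  expect_equal(unique(round(as.vector(d2$dr_i), 12)),
               round((-0.7 + transfer(u_i)) / p$tau_i, 12))
  # zero rates: excitatory drift is phi(mu_e)/tau_e
  s0 <- initial_state(p, "uniform", amplitude = 0)
  d0 <- drift(s0, p)
  expect_equal(unique(as.vector(d0$dr_e)), 0.48^2 / 5, tolerance = 1e-12)
})

test_that("initial states honor their contracts", {
  p <- tp(8, 0.1)
  fp <- initial_state(p, "fixed_point")
  pert0 <- initial_state(p, "perturbed", amplitude = 0, seed = 4)
  expect_equal(fp$r_e, pert0$r_e)
  a <- initial_state(p, "perturbed", amplitude = 0.05, seed = 9)
  b <- initial_state(p, "perturbed", amplitude = 0.05, seed = 9)
  expect_identical(a$r_e, b$r_e)
  expect_true(all(a$r_e >= 0))
  r <- initial_state(p, "random", amplitude = 0.3, seed = 2)
  expect_true(all(r$r_e >= 0 & r$r_e <= 0.3))
  expect_error(initial_state(p, "warped"), "arg")
  expect_error(initial_state(p, "perturbed", amplitude = -1), "amplitude")
})

test_that("uniform initial conditions reproduce the two-unit ODE solution", {
  p <- tp(8, 0.05, n_side = 12)
  init <- initial_state(p, "uniform", amplitude = 1)
  tr <- simulate_field(p, init, duration = 500, record = "units",
                       units = c(1, 77), seed = 1)
  tu <- two_unit_simulate(p, c(1, 1), 500, record_stride = 1L)
  expect_lt(max(abs(tr$unit_re[, 1] - tu$re)), 1e-8)
  expect_lt(max(abs(tr$unit_re[, 2] - tu$re)), 1e-8)
  # independent oracle: deSolve RK4 on the two-unit system
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) {
    u_e <- p$W_ee * y[1] + p$W_ei * y[2] + p$mu_e
    u_i <- p$W_ie * y[1] + p$W_ii * y[2] + p$mu_i
    list(c((-y[1] + max(u_e, 0)^2) / p$tau_e,
           (-y[2] + max(u_i, 0)^2) / p$tau_i))
  }
  sol <- deSolve::ode(c(1, 1), seq(0, 500, by = p$dt), rhs, NULL,
                      method = "rk4")
  expect_lt(max(abs(sol[, 2] - tu$re)), 1e-6)
})

test_that("trajectories remain nonnegative and deterministic under a seed", {
  for (seed in 1:3) {
    p <- tp(9 + seed, 0.08, n_side = 12, dim = 1)
    tr <- simulate_field(p, duration = 300, transient = 100, seed = seed,
                         record_ri = TRUE)
    expect_true(all(tr$re >= 0))
    expect_true(all(tr$ri >= 0))
    expect_true(all(is.finite(tr$re)))
  }
  p <- tp(12.8, 0.096, n_side = 12)
  a <- simulate_field(p, duration = 200, seed = 7)
  b <- simulate_field(p, duration = 200, seed = 7)
  expect_identical(a$re, b$re)
})

test_that("halving dt leaves regular trajectories unchanged to 1e-4", {
  p <- tp(8, 0.03, n_side = 16, dt = 0.025)
  init <- initial_state(p, "perturbed", seed = 3)
  e1 <- simulate_field(p, init, duration = 1000, record = "none")$state$r_e
  e2 <- simulate_field(update_params(p, dt = 0.0125), init,
                       duration = 1000, record = "none")$state$r_e
  expect_lt(max(abs(e1 - e2)) / max(abs(e1)), 1e-4)
})

test_that("numerical blow-up is caught and reported with the step", {
  # pure excitation with no inhibition diverges under the quadratic transfer
  p <- field_params(tau_i = 8, sigma_i = 0.1, W_ei = 0, W_ii = 0,
                    n_side = 12, dim = 1)
  init <- initial_state(p, "uniform", amplitude = 1)
  expect_error(simulate_field(p, init, duration = 100, record = "none"),
               "step")
})

test_that("trajectory containers round-trip and export", {
  p <- tp(8, 0.03, n_side = 12, dim = 1)
  tr <- simulate_field(p, duration = 50, seed = 1)
  f <- tempfile(fileext = ".rds")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_identical(tr$re, tr2$re)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), nrow(tr$re) * ncol(tr$re))
  expect_true(all(c("t", "unit", "r_e") %in% names(df)))
  m <- field_at(tr, 1)
  expect_length(m, p$n_side)
  unlink(f)
})

test_that("model parameters round-trip through YAML", {
  p <- tp(11, 0.07, n_side = 20)
  np <- noise_params(0.04, 0.5)
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(p, f, noise = np)
  back <- read_params_yaml(f)
  expect_equal(unclass(back$params), unclass(p))
  expect_equal(back$noise$sigma_n, 0.04)
  unlink(f)
})
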