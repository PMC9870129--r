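test_that("mode Jacobian interpolates between the two-unit Jacobian and
           pure decay", {
  p <- tp(8, 0.05)
  fp <- two_unit_fixed_point(p)
  mj0 <- mode_jacobian(p, 0, fp)
  expect_equal(mj0$J, two_unit_jacobian(p, fp))
  # far mode: coupling terms vanish
  mj <- mode_jacobian(p, 200, fp)
  expect_equal(mj$J, diag(c(-1 / p$tau_e, -1 / p$tau_i)), tolerance = 1e-10)
  # (1,0) and (0,1) give identical eigenvalues
  expect_equal(mode_jacobian(p, c(1, 0), fp)$eigenvalues,
               mode_jacobian(p, c(0, 1), fp)$eigenvalues)
})

test_that("fixed-point stability scan reproduces the phase-diagram
           geometry", {
  expect_true(fixed_point_stability(tp(5, 0.05))$stable)
  # narrow inhibition: instability sets in at zero wave number past the Hopf
  fs0 <- fixed_point_stability(tp(7.9, 0.05))
  expect_false(fs0$stable)
  expect_equal(fs0$crit_k, 0)
  # broad inhibition: instability at a nonzero wave number, below the Hopf
  fs1 <- fixed_point_stability(tp(7, 0.15))
  expect_false(fs1$stable)
  expect_gt(fs1$crit_k, 0)
  expect_gte(fs1$n_unstable, 1)
  # verdict invariant to the mode cutoff once the kernel has decayed
  fs2 <- fixed_point_stability(tp(7, 0.15), max_mode = 30)
  expect_equal(fs1$stable, fs2$stable)
  expect_equal(fs1$crit_k, fs2$crit_k)
})

test_that("the k = 0 instability threshold equals the two-unit Hopf point", {
  p <- tp(8, 0.05)
  fp <- two_unit_fixed_point(p)
  lead0 <- function(tau) {
    max(Re(mode_jacobian(update_params(p, tau_i = tau), 0, fp)$eigenvalues))
  }
  lo <- 5; hi <- 12
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (lead0(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, hopf_point(p)$tau_hb, tolerance = 1e-6)
})

test_that("monodromy matrix satisfies Floquet structure and limits", {
  p <- tp(8, 0.03)
  lc <- find_limit_cycle(p)
  # k = 0: one multiplier is 1 (tangent to the cycle)
  M0 <- monodromy(p, lc, 0)
  ev <- eigen(M0, only.values = TRUE)$values
  expect_lt(min(abs(ev - 1)), 1e-3)
  # large k: closed form exp(-T/tau) decay
  M <- monodromy(p, lc, 40)
  expect_equal(M, diag(c(exp(-lc$period / p$tau_e),
                         exp(-lc$period / p$tau_i))), tolerance = 1e-8)
})

test_that("monodromy agrees with a piecewise-constant matrix-exponential
           oracle", {
  skip_if_not_installed("Matrix")
  p <- tp(8, 0.03)
  lc <- find_limit_cycle(p)
  k <- 3
  ge <- gaussian_mode_coef(k, p$sigma_e)
  gi <- gaussian_mode_coef(k, p$sigma_i)
  npc <- 10000
  tgrid <- (seq_len(npc) - 0.5) * lc$period / npc
  ue <- splinefun(lc$t, lc$u_e, method = "periodic")(tgrid)
  ui <- splinefun(lc$t, lc$u_i, method = "periodic")(tgrid)
  M <- diag(2)
  h <- lc$period / npc
  for (i in seq_len(npc)) {
    L_e <- 2 * max(ue[i], 0); L_i <- 2 * max(ui[i], 0)
    J <- matrix(c((-1 + L_e * p$W_ee * ge) / p$tau_e,
                  L_i * p$W_ie * ge / p$tau_i,
                  L_e * p$W_ei * gi / p$tau_e,
                  (-1 + L_i * p$W_ii * gi) / p$tau_i), 2, 2)
    M <- as.matrix(Matrix::expm(J * h)) %*% M
  }
  ev_oracle <- sort(Mod(eigen(M, only.values = TRUE)$values))
  ev_rk <- sort(Mod(eigen(monodromy(p, lc, k), only.values = TRUE)$values))
  expect_equal(ev_rk, ev_oracle, tolerance = 1e-4)
})

test_that("bulk-oscillation stability reproduces both instability types", {
  # stable bulk oscillation: small sigma_i, intermediate tau_i
  bo <- bulk_oscillation_stability(tp(8, 0.03))
  expect_false(bo$no_cycle)
  expect_true(bo$stable)
  expect_equal(bo$n_unstable, 0)
  # increasing sigma_i: period doubling (a real multiplier below -1)
  bo_pd <- bulk_oscillation_stability(tp(8, 0.06))
  expect_false(bo_pd$stable)
  first <- bo_pd$class_by_mode[bo_pd$class_by_mode != "stable"][1]
  expect_equal(first, "lambda_lt_minus1")
  lead <- bo_pd$multipliers[[which(bo_pd$class_by_mode != "stable")[1]]]
  lead <- lead[which.max(Mod(lead))]
  expect_lt(Re(lead), -1)
  expect_lt(abs(Im(lead)), 1e-6)
  # increasing tau_i: same-period pattern formation (multiplier above 1)
  bo_pf <- bulk_oscillation_stability(tp(13, 0.03))
  expect_false(bo_pf$stable)
  first <- bo_pf$class_by_mode[bo_pf$class_by_mode != "stable"][1]
  expect_equal(first, "lambda_gt_1")
  # no cycle below the fold
  expect_true(bulk_oscillation_stability(tp(5, 0.03))$no_cycle)
})

test_that("phase diagram labels every cell and matches the two-unit Hopf
           at vanishing sigma_i", {
  p <- tp(8, 0.05)
  pd <- phase_diagram(p, sigma_values = c(0.01, 0.05),
                      tau_values = c(7.7, 7.9, 9), max_mode = 30)
  expect_equal(nrow(pd), 6)
  expect_true(all(!is.na(pd$fp_stable)))
  # sigma_i -> 0 boundary: stable below tau_HB ~ 7.80, unstable above
  expect_true(pd$fp_stable[pd$sigma_i == 0.01 & pd$tau_i == 7.7])
  expect_false(pd$fp_stable[pd$sigma_i == 0.01 & pd$tau_i == 7.9])
  # bulk oscillation exists and is classified where a cycle exists
  expect_true(all(pd$bo_exists[pd$tau_i == 9]))
  f <- tempfile(fileext = ".csv")
  write_phase_diagram_csv(pd, f)
  expect_true(all(c("sigma_i", "tau_i", "fp_stable", "bo_class") %in%
                    names(read.csv(f))))
  unlink(f)
})
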