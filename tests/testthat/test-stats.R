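test_that("spatial correlation is a normalized, symmetric displacement
           map", {
  tr <- chaos_traj()
  cm <- spatial_correlation(tr)
  expect_equal(correlation_at(cm, 0, 0), 1, tolerance = 1e-10)
  expect_true(all(abs(cm$C) <= 1 + 1e-12))
  # C(dx, dy) = C(-dx, -dy)
  expect_equal(correlation_at(cm, 0.125, 0.25),
               correlation_at(cm, -0.125, -0.25), tolerance = 1e-10)
  # chaotic activity decorrelates with distance
  expect_gt(correlation_at(cm, 1 / 32), 0.5)
  expect_lt(abs(correlation_at(cm, 0.5)), 0.1)
  expect_lt(correlation_at(cm, 0.5), correlation_at(cm, 0.125))
  expect_error(spatial_correlation(matrix_traj(matrix(1, 5, 256))),
               "window")
})

test_that("a spatially uniform oscillation is perfectly correlated at all
           displacements", {
  cm <- spatial_correlation(bulk_traj())
  expect_equal(max(abs(cm$C - 1)), 0, tolerance = 1e-6)
})

test_that("spectral displacement covariance equals the direct pair loop", {
  set.seed(5)
  n <- 12; Tn <- 40
  X <- matrix(rnorm(Tn * n * n), Tn, n * n)
  cm <- spatial_correlation(matrix_traj(X, n_side = n))
  Xc <- sweep(X, 2, colMeans(X))
  # direct oracle over displacements, periodic wrapping
  num <- matrix(0, n, n)
  arr <- array(t(Xc), c(n, n, Tn))
  for (dx in 0:(n - 1)) {
    for (dy in 0:(n - 1)) {
      s <- 0
      for (tt in 1:Tn) {
        A <- arr[, , tt]
        B <- A[c((1 + dx):n, seq_len(dx)), c((1 + dy):n, seq_len(dy)),
               drop = FALSE]
        s <- s + mean(A * B)
      }
      num[dx + 1, dy + 1] <- s / Tn
    }
  }
  Cd <- num / num[1, 1]
  for (dx in c(0, 1, 5)) {
    for (dy in c(0, 2, 7)) {
      expect_equal(correlation_at(cm, dx / n, dy / n),
                   Cd[dx + 1, dy + 1], tolerance = 1e-8)
    }
  }
})

test_that("power spectrum normalization, power-law fit and peak
           extraction", {
  # constant trajectory: zero spectrum
  spc <- power_spectrum(matrix_traj(matrix(2, 3000, 256)), segment = 1000)
  expect_true(all(spc$power == 0))
  # pure 30 Hz sinusoid units: peak at 30 Hz, exact Parseval
  tt <- seq_len(6000) / 1000
  X <- outer(sin(2 * pi * 30 * tt), runif(64, 0.5, 1.5))
  sp <- power_spectrum(matrix_traj(X, n_side = 8), segment = 2000)
  expect_lt(abs(sp$peak_hz - 30), 1)
  df <- sp$freq[2] - sp$freq[1]
  expect_equal(sum(sp$power) * df, mean(apply(X, 2, var)),
               tolerance = 1e-6)
  # smoothing invariance for a unimodal spectrum
  expect_lt(abs(spectral_peak(sp, 5) - spectral_peak(sp, 10)), 2)
  # synthetic exact power laws
  fake <- structure(list(freq = seq(1, 500, by = 0.5)), class =
                      "spectrum_result")
  fake$power <- fake$freq^-2
  expect_equal(powerlaw_exponent(fake, c(50, 200)), 2, tolerance = 1e-10)
  fake$power <- rep(3, length(fake$freq))
  expect_equal(powerlaw_exponent(fake, c(50, 200)), 0, tolerance = 1e-10)
  expect_error(powerlaw_exponent(fake, c(50, 51)), "bins")
  expect_error(power_spectrum(matrix_traj(matrix(1, 50, 256))), "short")
})

test_that("chaotic spectra satisfy the Parseval contract", {
  sp <- power_spectrum(chaos_traj())
  df <- sp$freq[2] - sp$freq[1]
  X <- sweep(chaos_traj()$re, 2, colMeans(chaos_traj()$re))
  expect_equal(sum(sp$power) * df, mean(apply(X, 2, var)),
               tolerance = 0.01)
  expect_gt(sp$peak_hz, 0)
})

test_that("PC variance spectra conserve variance and detect
           one-dimensional structure", {
  # common signal + tiny jitter: dimension 1 at every sample size
  set.seed(8)
  sig <- sin(seq_len(2000) / 30)
  X <- outer(sig, runif(256, 0.5, 2)) +
    matrix(rnorm(2000 * 256, sd = 1e-5), 2000, 256)
  tr1 <- matrix_traj(X)
  ev <- pca_variance_spectrum(tr1, n_sample = 100, seed = 1)
  expect_true(all(diff(ev) <= 1e-12))
  expect_gt(ev[1] / sum(ev), 0.999)
  d <- dimension_95(tr1, sample_sizes = c(50, 150), repeats = 3, seed = 1)
  expect_true(all(d$dims == 1))
  # trace conservation: summed PC variances equal the total variance
  ev_all <- pca_variance_spectrum(matrix_traj(X), n_sample = 256, seed = 2)
  expect_equal(sum(ev_all), sum(apply(X, 2, var)), tolerance = 1e-8)
  expect_error(pca_variance_spectrum(tr1, n_sample = 1000), "exceeds")
})

test_that("the 95% criterion is calibrated: white noise is
           full-dimensional", {
  set.seed(3)
  nu <- 60
  X <- matrix(rnorm(5000 * nu), 5000, nu)
  d <- dimension_95(matrix_traj(X, n_side = 16), sample_sizes = nu,
                    repeats = 3, seed = 2)
  expect_gt(d$summary$mean_dim, 0.9 * 0.95 * nu)
  expect_lte(d$summary$mean_dim, nu)
})

test_that("chaotic population activity is low dimensional and dimension
           grows with sample size", {
  d <- dimension_95(chaos_traj(), sample_sizes = c(100, 300, 600),
                    repeats = 5, seed = 4)
  expect_true(all(diff(d$summary$mean_dim) >= 0))
  expect_lt(d$summary$mean_dim[3], 50)
  expect_gte(min(d$dims), 1)
  # variance concentrates in the first few tens of components
  ev <- pca_variance_spectrum(chaos_traj(), n_sample = 600, seed = 4)
  expect_gt(sum(ev[1:40]) / sum(ev), 0.9)
})
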