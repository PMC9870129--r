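test_that("regime labels agree with theory and the published exemplars", {
  # stable fixed-point region
  pfp <- tp(5, 0.05, n_side = 16)
  trf <- simulate_field(pfp, duration = 300, transient = 1500, seed = 2)
  mlf <- max_lyapunov(pfp, n = 150, delta_t = 10, seed = 2, transient = 500)
  expect_equal(classify_regime(trf, mlf)$label, "fixed_point")
  # stable bulk-oscillation region
  pbo <- tp(8, 0.03, n_side = 16)
  mlb <- max_lyapunov(pbo, n = 400, delta_t = 10, seed = 2,
                      transient = 2000)
  expect_equal(classify_regime(bulk_traj(), mlb)$label, "bulk_oscillation")
  # chaotic exemplar
  regc <- classify_regime(chaos_traj(), chaos_mle())
  expect_equal(regc$label, "chaotic")
  expect_gt(regc$scores$mle, 0.005)
})

test_that("traveling waves and alternating bumps are recognized", {
  ptw <- tp(8, 0.1, n_side = 32)
  trw <- simulate_field(ptw, duration = 1200, transient = 3000, seed = 5)
  mlw <- max_lyapunov(ptw, n = 500, delta_t = 10, seed = 5,
                      transient = 3000)
  rw <- classify_regime(trw, mlw)
  expect_equal(rw$label, "traveling_wave")
  expect_gt(rw$scores$drift_r2, 0.99)
  pab <- tp(9, 0.06, n_side = 32)
  tab <- simulate_field(pab, duration = 1200, transient = 3000, seed = 5)
  mab <- max_lyapunov(pab, n = 500, delta_t = 10, seed = 5,
                      transient = 3000)
  ra <- classify_regime(tab, mab)
  expect_equal(ra$label, "alternating_bumps")
  expect_lt(ra$scores$alternation, -0.3)
  # evidence scores always accompany the label
  expect_true(all(c("mle", "acf_peak", "uniformity") %in%
                    names(ra$scores)))
})

test_that("transition sweep orders regular before chaotic dynamics with
           full provenance", {
  p <- tp(11, 0.06, n_side = 32)
  sw <- transition_sweep(p, sigma_values = c(0.06, 0.096), seed = 2,
                         duration = 1200, transient = 3000, mle_n = 400)
  expect_equal(nrow(sw$points), 2)
  expect_true(all(is.na(sw$points$error)))
  # periodic point: near-zero exponent, harmonic spectrum
  expect_lt(abs(sw$points$mle[1]), 0.002)
  expect_true(sw$points$regime[1] %in%
                c("alternating_bumps", "alternating_stripes",
                  "non_alternating_bumps", "bulk_oscillation"))
  # chaotic point: positive exponent, broadband spectrum, decorrelation
  expect_gt(sw$points$mle[2], 0.005)
  expect_true(sw$points$regime[2] %in% c("chaotic", "intermittent"))
  expect_lt(sw$points$corr_half[2], 0.5)
  expect_false(is.na(sw$config_hash))
  expect_length(unique(sw$points$seed), 2)
})

test_that("noise sweep: periodic networks stay regular without correlated
           noise and destabilize with it", {
  p <- tp(9, 0.06, n_side = 32)
  ns <- noise_sweep(p, sigma_n_values = c(0, 0.04), c_values = c(0, 1),
                    seed = 3, n = 300, delta_t = 10, transient = 1500)
  pts <- ns$points
  expect_equal(nrow(pts), 4)
  # sigma_n = 0 rows: periodic solution, MLE ~ 0
  expect_true(all(abs(pts$mle[pts$sigma_n == 0]) < 0.002))
  # independent noise leaves the exponent near zero
  mle_c0 <- pts$mle[pts$sigma_n == 0.04 & pts$c == 0]
  expect_lt(abs(mle_c0), 0.005)
  # correlated noise induces chaos
  mle_c1 <- pts$mle[pts$sigma_n == 0.04 & pts$c == 1]
  expect_gt(mle_c1, 0.005)
  expect_equal(pts$sigma_nc, pts$sigma_n * sqrt(pts$c))
})

test_that("configured runs execute, archive and reproduce", {
  cfg <- list(
    experiment = "simulate",
    model = list(tau_i = 8, sigma_i = 0.03, n_side = 12, dim = 1),
    integration = list(duration = 200, transient = 100))
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_config(cfg, out_dir = d1, seed = 5)
  r2 <- run_config(cfg, out_dir = d2, seed = 5)
  expect_true(file.exists(file.path(d1, "trajectory.rds")))
  expect_true(file.exists(file.path(d1, "config_resolved.yaml")))
  expect_true(file.exists(file.path(d1, "run.log")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$experiment, "simulate")
  expect_equal(man$seed, 5)
  # identical config + seed: identical numerical outputs and hashes
  expect_identical(read_trajectory(file.path(d1, "trajectory.rds"))$re,
                   read_trajectory(file.path(d2, "trajectory.rds"))$re)
  expect_equal(man$config_hash,
               jsonlite::read_json(file.path(d2,
                                             "manifest.json"))$config_hash)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("configuration schema rejects unknown keys by name", {
  cfg <- list(experiment = "simulate",
              model = list(tau_i = 8, sigma_i = 0.1, n_side = 12),
              banana = 1)
  expect_error(run_config(cfg), "banana")
  expect_error(run_config(list(model = list(tau_i = 8, sigma_i = 0.1))),
               "experiment")
  expect_error(run_config(list(experiment = "fly",
                               model = list(tau_i = 8, sigma_i = 0.1))),
               "unknown experiment")
  cfg2 <- list(experiment = "simulate",
               model = list(tau_i = 8, sigma_i = 0.1, n_side = 12),
               mle = list(n = 10, wrong_key = 2))
  expect_error(run_config(cfg2), "wrong_key")
})

test_that("stats and mle experiments write their tabular outputs", {
  d <- tempfile()
  cfg <- list(
    experiment = "stats",
    model = list(tau_i = 12.8, sigma_i = 0.096, n_side = 16),
    integration = list(duration = 3000, transient = 1500),
    stats = list(sample_sizes = c(50, 100), repeats = 3, segment = 1000))
  run_config(cfg, out_dir = d, seed = 2)
  expect_true(file.exists(file.path(d, "spectrum.csv")))
  expect_true(file.exists(file.path(d, "correlation.csv")))
  expect_true(file.exists(file.path(d, "dimension.csv")))
  spec <- read.csv(file.path(d, "spectrum.csv"))
  expect_true(all(spec$power >= 0))
  unlink(d, recursive = TRUE)
})
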