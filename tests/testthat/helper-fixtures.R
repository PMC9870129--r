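# Small parameter sets and lazily cached simulations shared across tests.

# compact constructor: landmark networks at test-scale grids
tp <- function(tau_i, sigma_i, n_side = 16, dim = 2, dt = 0.1, ...) {
  field_params(tau_i = tau_i, sigma_i = sigma_i, n_side = n_side,
               dim = dim, dt = dt, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# chaotic reference network at the published example parameters, scaled to a
# 32x32 grid (resolves all spatial modes with non-negligible kernel weight)
chaos_params <- function() tp(12.8, 0.096, n_side = 32)

chaos_traj <- function() cached("chaos_traj",
  simulate_field(chaos_params(), duration = 6000, transient = 2000,
                 seed = 1))

chaos_mle <- function() cached("chaos_mle",
  max_lyapunov(chaos_params(), n = 800, delta_t = 10, seed = 1,
               transient = 2000))

# spatially uniform bulk oscillation on a small grid
bulk_traj <- function() cached("bulk_traj",
  simulate_field(tp(8, 0.03, n_side = 16), duration = 500, transient = 2000,
                 seed = 2))

# wrap a plain time x units matrix as a minimal trajectory for the
# statistics functions
matrix_traj <- function(X, dt_ms = 1, n_side = NULL, dim = 2) {
  if (is.null(n_side)) n_side <- as.integer(sqrt(ncol(X)))
  structure(list(t = seq_len(nrow(X)) * dt_ms, re = X,
                 params = field_params(tau_i = 8, sigma_i = 0.1,
                                       n_side = n_side, dim = dim),
                 duration = nrow(X) * dt_ms, transient = 0, stride = dt_ms),
            class = "rate_trajectory")
}
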