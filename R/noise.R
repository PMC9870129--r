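#' One exact Ornstein-Uhlenbeck update
#'
#' Advances an OU process `tau_n * d eta = -eta dt + dW` by `dt` using the
#' exact discretization
#' `eta <- eta * exp(-dt/tau_n) + sqrt((1 - exp(-2 dt/tau_n)) * v) * z`,
#' which preserves the stationary law (variance `v = 1/(2 tau_n)`, or 1 when
#' `normalize = TRUE`).
#'
#' @param eta Current value(s).
#' @param tau_n Time constant (ms).
#' @param dt Step (ms), > 0.
#' @param draw Standard-normal draw(s), same shape as `eta`.
#' @param normalize Use the unit-variance scaling?
#' @return Updated value(s).
#' @examples
#' ou_step(1, tau_n = 5, dt = 5, draw = 0)  # exp(-1)
#' @export
ou_step <- function(eta, tau_n, dt, draw, normalize = FALSE) {
  stopifnot(dt > 0, tau_n > 0)
  rho <- exp(-dt / tau_n)
  v <- if (normalize) 1 else 1 / (2 * tau_n)
  eta * rho + sqrt((1 - rho^2) * v) * draw
}

#' Frozen Ornstein-Uhlenbeck noise paths
#'
#' Returns the exact noise paths the simulator uses: each path is a pure
#' function of `(seed, population, unit)` through counter-based stream
#' seeding, so the same seed always reproduces the same realization, and
#' the paths returned here are bitwise identical to those driving
#' [simulate_field()] with the same seed and step. Unit index 0 denotes the
#' population's common (shared) component.
#'
#' @param noise A [noise_params()] object.
#' @param n_steps Number of steps; the path has `n_steps + 1` samples at
#'   times `0, dt, ..., n_steps * dt`.
#' @param dt Step (ms).
#' @param seed Integer seed.
#' @param population `"e"` or `"i"`.
#' @param units Integer unit indices (0 = common component).
#' @return A `(n_steps + 1) x length(units)` matrix of OU samples.
#' @export
noise_paths <- function(noise, n_steps, dt, seed, population = c("e", "i"),
                        units = 0L) {
  stopifnot(inherits(noise, "noise_params"), n_steps >= 1, dt > 0)
  population <- match.arg(population)
  pop <- if (population == "e") 1L else 2L
  cpp_noise_paths(as.numeric(seed), pop, as.integer(units),
                  as.integer(n_steps), dt, noise$tau_n, noise$normalize)
}

#' Compose per-unit input currents from noise paths
#'
#' Implements the input model
#' `I_k = mu + sigma_n * (sqrt(1 - c) * eta_k + sqrt(c) * eta_c)`: at
#' `c = 1` every unit of a population receives the identical input, at
#' `c = 0` inputs are independent, and the pairwise correlation between the
#' inputs of two units equals `c`.
#'
#' @param noise A [noise_params()] object.
#' @param params A [field_params()] object (supplies the static drive).
#' @param eta_private Private-path values (vector or matrix over units, or
#'   a time x units matrix).
#' @param eta_common Common-path value(s) (scalar or time vector).
#' @param population `"e"` or `"i"`.
#' @return Input currents with the shape of `eta_private`.
#' @export
noise_input <- function(noise, params, eta_private, eta_common,
                        population = c("e", "i")) {
  stopifnot(inherits(noise, "noise_params"),
            inherits(params, "field_params"))
  population <- match.arg(population)
  mu <- if (population == "e") params$mu_e else params$mu_i
  mu + noise$sigma_n * (sqrt(1 - noise$c) * eta_private +
                          sqrt(noise$c) * eta_common)
}
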