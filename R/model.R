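#' Construct an initial rate field
#'
#' @param params A [field_params()] object.
#' @param mode One of `"uniform"` (constant field at `amplitude`),
#'   `"fixed_point"` (the spatially uniform fixed point of the reduced
#'   two-unit model), `"perturbed"` (fixed point plus seeded spatial white
#'   noise of standard deviation `amplitude`, clipped at 0), or `"random"`
#'   (seeded uniform draws on `[0, amplitude]`).
#' @param amplitude Nonnegative scalar; see `mode`.
#' @param seed Integer seed for the `"perturbed"` and `"random"` modes.
#' @return An object of class `rate_field` with matrices (2D) or vectors
#'   (1D) `r_e`, `r_i` and the time stamp `t = 0`.
#' @export
initial_state <- function(params, mode = c("perturbed", "fixed_point",
                                           "uniform", "random"),
                          amplitude = 0.01, seed = 1) {
  stopifnot(inherits(params, "field_params"))
  mode <- match.arg(mode)
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("amplitude must be nonnegative", call. = FALSE)
  n <- params$n_side
  shape <- if (params$dim == 2) c(n, n) else c(n, 1)
  nunits <- prod(shape)
  make <- function(v) {
    m <- matrix(v, shape[1], shape[2])
    if (params$dim == 1) drop(m) else m
  }
  fp <- NULL
  if (mode %in% c("fixed_point", "perturbed")) {
    fp <- two_unit_fixed_point(params)
  }
  fields <- switch(mode,
    uniform = list(r_e = make(amplitude), r_i = make(amplitude)),
    fixed_point = list(r_e = make(fp$r_e), r_i = make(fp$r_i)),
    perturbed = with_seed(seed, list(
      r_e = make(pmax(fp$r_e + rnorm(nunits, sd = amplitude), 0)),
      r_i = make(pmax(fp$r_i + rnorm(nunits, sd = amplitude), 0)))),
    random = with_seed(seed, list(
      r_e = make(runif(nunits, 0, amplitude)),
      r_i = make(runif(nunits, 0, amplitude))))
  )
  structure(c(fields, list(t = 0, dim = params$dim, n_side = n)),
            class = "rate_field")
}

#' Stripe-biased initial state
#'
#' The uniform fixed point plus a small single-mode cosine perturbation
#' (wave number `k` along one axis), with the inhibitory perturbation phase
#' shifted to break the standing/traveling symmetry. Pattern-formed
#' solutions such as traveling waves and stripes coexist with other
#' attractors, and their basins are hard to reach from spatially white
#' perturbations on moderate grids; this deterministic initial condition
#' converges reliably onto the pattern branch.
#'
#' @param params A [field_params()] object.
#' @param k Integer wave number of the seeded mode.
#' @param amplitude Perturbation amplitude.
#' @param phase Phase shift (radians) of the inhibitory perturbation.
#' @return A `rate_field`.
#' @export
stripe_state <- function(params, k = 1, amplitude = 0.01, phase = pi / 4) {
  stopifnot(inherits(params, "field_params"), amplitude >= 0)
  fp <- two_unit_fixed_point(params)
  n <- params$n_side
  x <- (0:(n - 1) + 0.5) / n
  pe <- cos(2 * pi * k * x)
  pi_ <- cos(2 * pi * k * x + phase)
  if (params$dim == 2) {
    pe <- outer(rep(1, n), pe)
    pi_ <- outer(rep(1, n), pi_)
  }
  structure(list(r_e = pmax(fp$r_e + amplitude * pe, 0),
                 r_i = pmax(fp$r_i + amplitude * pi_, 0),
                 t = 0, dim = params$dim, n_side = n),
            class = "rate_field")
}

#' @export
print.rate_field <- function(x, ...) {
  cat(sprintf("Rate field (%dD, n_side=%d) at t=%g ms\n",
              x$dim, x$n_side, x$t))
  cat(sprintf("  r_e in [%.4g, %.4g], r_i in [%.4g, %.4g]\n",
              min(x$r_e), max(x$r_e), min(x$r_i), max(x$r_i)))
  invisible(x)
}

#' Instantaneous drift of the rate field
#'
#' Evaluates the right-hand side of the model: for each population,
#' `(-r + phi(W_ee g_e * r_e + W_ei g_i * r_i + input)) / tau`, where `*` is
#' periodic spatial convolution with the wrapped-Gaussian kernel. With the
#' default inputs (the static drives) a state at the spatially uniform fixed
#' point has identically zero drift.
#'
#' @param state A `rate_field` (see [initial_state()]).
#' @param params A [field_params()] object.
#' @param input_e,input_i Total external current per population: a scalar or
#'   a field the shape of `r_e`. Defaults to the static drives `mu_e`,
#'   `mu_i`.
#' @return A list with fields `dr_e`, `dr_i` (rate derivatives, 1/ms).
#' @export
drift <- function(state, params, input_e = params$mu_e,
                  input_i = params$mu_i) {
  stopifnot(inherits(state, "rate_field"), inherits(params, "field_params"))
  if (!all(is.finite(state$r_e)) || !all(is.finite(state$r_i)))
    stop("non-finite state", call. = FALSE)
  ge <- spectral_kernel(params$n_side, params$sigma_e, params$dim)
  gi <- spectral_kernel(params$n_side, params$sigma_i, params$dim)
  u_e <- params$W_ee * apply_coupling(state$r_e, ge) +
    params$W_ei * apply_coupling(state$r_i, gi) + input_e
  u_i <- params$W_ie * apply_coupling(state$r_e, ge) +
    params$W_ii * apply_coupling(state$r_i, gi) + input_i
  list(dr_e = (-state$r_e + transfer(u_e)) / params$tau_e,
       dr_i = (-state$r_i + transfer(u_i)) / params$tau_i)
}

as_cpp_field <- function(x, params) {
  if (params$dim == 2) as.matrix(x) else matrix(x, params$n_side, 1)
}

#' Simulate the spatial rate network
#'
#' Fixed-step integration of the rate-field equations by classical
#' 4th-order Runge-Kutta. With input noise, the Ornstein-Uhlenbeck input
#' current is held constant over each step and updated by its exact
#' discretization at step boundaries (the input is a smooth random process
#' with `tau_n` much longer than `dt`, so the held-noise error is
#' negligible). The noise realization is frozen: it is a pure function of
#' `seed` and the noise parameters.
#'
#' @param params A [field_params()] object.
#' @param init A `rate_field` initial condition; default is a seeded
#'   perturbation of the uniform fixed point.
#' @param duration Recorded duration (ms) after the transient.
#' @param noise Optional [noise_params()].
#' @param record `"fields"` records full excitatory fields every `stride`
#'   ms; `"units"` records the units in `units` at every step; `"none"`
#'   records only the final state.
#' @param stride Recording stride (ms) for `record = "fields"`.
#' @param units Integer indices (into the flattened excitatory field) for
#'   `record = "units"`.
#' @param record_ri Also record the inhibitory fields?
#' @param seed Integer seed (noise realization and default initial state).
#' @param transient Initial span (ms) simulated but not recorded.
#' @return An object of class `rate_trajectory` with fields `t` (ms),
#'   `re` (time x units matrix of excitatory rates), optionally `ri`,
#'   optionally `unit_t`/`unit_re`, the final `state`, and the `params`,
#'   `noise`, `seed` that produced it.
#' @examples
#' p <- field_params(tau_i = 8, sigma_i = 0.03, n_side = 16, dim = 1)
#' tr <- simulate_field(p, duration = 200, transient = 500, seed = 2)
#' tr
#' @export
simulate_field <- function(params, init = NULL, duration,
                           noise = NULL,
                           record = c("fields", "units", "none"),
                           stride = 1, units = NULL, record_ri = FALSE,
                           seed = 1, transient = 0) {
  stopifnot(inherits(params, "field_params"), duration > 0, transient >= 0)
  record <- match.arg(record)
  if (is.null(init)) init <- initial_state(params, "perturbed", seed = seed)
  stopifnot(inherits(init, "rate_field"))
  if (init$n_side != params$n_side || init$dim != params$dim)
    stop("initial state grid does not match params", call. = FALSE)
  ge <- spectral_kernel(params$n_side, params$sigma_e, params$dim)
  gi <- spectral_kernel(params$n_side, params$sigma_i, params$dim)
  n_steps <- as.integer(round((transient + duration) / params$dt))
  rec_stride <- if (record == "fields") {
    max(1L, as.integer(round(stride / params$dt)))
  } else 0L
  rec_units <- if (record == "units") {
    if (is.null(units)) stop("record = 'units' needs unit indices")
    as.integer(units)
  } else integer(0)
  out <- cpp_simulate(as_cpp_field(init$r_e, params),
                      as_cpp_field(init$r_i, params),
                      unclass(params), ge$G, gi$G, params$dim == 2L,
                      n_steps, rec_stride, record_ri, rec_units,
                      noise_to_cpp(noise), as.numeric(seed), 0)
  traj <- list(params = params, noise = noise, seed = seed,
               transient = transient, duration = duration,
               record = record, stride = stride)
  if (record == "fields") {
    keep <- out$t >= transient - 1e-9
    traj$t <- as.numeric(out$t[keep])
    traj$re <- out$re[keep, , drop = FALSE]
    if (record_ri) traj$ri <- out$ri[keep, , drop = FALSE]
  }
  if (record == "units") {
    keep <- out$unit_t >= transient - 1e-9
    traj$unit_t <- as.numeric(out$unit_t[keep])
    traj$unit_re <- out$unit_re[keep, , drop = FALSE]
    traj$units <- rec_units
  }
  traj$state <- structure(
    list(r_e = if (params$dim == 2) out$final_re else drop(out$final_re),
         r_i = if (params$dim == 2) out$final_ri else drop(out$final_ri),
         t = n_steps * params$dt, dim = params$dim, n_side = params$n_side),
    class = "rate_field")
  structure(traj, class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("Rate trajectory (%dD, n_side=%d): %g ms recorded",
              x$params$dim, x$params$n_side, x$duration))
  if (x$transient > 0) cat(sprintf(" after %g ms transient", x$transient))
  cat("\n")
  if (!is.null(x$re))
    cat(sprintf("  fields: %d samples x %d units (stride %g ms)\n",
                nrow(x$re), ncol(x$re), x$stride))
  if (!is.null(x$unit_re))
    cat(sprintf("  units: %d samples x %d units (every step)\n",
                nrow(x$unit_re), ncol(x$unit_re)))
  if (!is.null(x$noise))
    cat(sprintf("  noise: sigma_n=%g, c=%g (seed %d)\n",
                x$noise$sigma_n, x$noise$c, x$seed))
  invisible(x)
}

#' Extract one recorded field as a spatial array
#'
#' @param traj A `rate_trajectory` with recorded fields.
#' @param i Time index into `traj$t`.
#' @param population `"e"` or `"i"`.
#' @return A vector (1D) or matrix (2D) of rates.
#' @export
field_at <- function(traj, i, population = c("e", "i")) {
  population <- match.arg(population)
  m <- if (population == "e") traj$re else traj$ri
  if (is.null(m)) stop("population not recorded", call. = FALSE)
  v <- m[i, ]
  if (traj$params$dim == 2) {
    matrix(v, traj$params$n_side, traj$params$n_side)
  } else v
}

#' Save or load a trajectory
#'
#' Trajectories (with full parameter and seed provenance) are archived as
#' RDS files; [as.data.frame.rate_trajectory()] gives a plain long-format
#' table for CSV export.
#'
#' @param traj A `rate_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rate_trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  stopifnot(inherits(traj, "rate_trajectory"))
  traj
}

#' @export
as.data.frame.rate_trajectory <- function(x, ...) {
  if (!is.null(x$re)) {
    data.frame(t = rep(x$t, ncol(x$re)),
               unit = rep(seq_len(ncol(x$re)), each = nrow(x$re)),
               r_e = as.vector(x$re))
  } else if (!is.null(x$unit_re)) {
    data.frame(t = rep(x$unit_t, ncol(x$unit_re)),
               unit = rep(x$units, each = nrow(x$unit_re)),
               r_e = as.vector(x$unit_re))
  } else {
    stop("trajectory has no recorded samples", call. = FALSE)
  }
}
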