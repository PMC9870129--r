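#' Model parameters for the spatial rate network
#'
#' Constructs and validates the parameter set of the two-population rate
#' model on the unit interval (1D ring) or unit square (2D torus). Defaults
#' are the reference cortical-network parameter set used throughout:
#' `W_ee = 80`, `W_ei = -160`, `W_ie = 80`, `W_ii = -150`, `tau_e = 5` ms,
#' `sigma_e = 0.1`, `mu_e = 0.48`, `mu_i = 0.32`. The inhibitory time
#' constant `tau_i` and projection width `sigma_i` are the swept variables
#' and must be supplied.
#'
#' @param tau_i Inhibitory time constant (ms).
#' @param sigma_i Inhibitory Gaussian projection width (fraction of the
#'   domain length).
#' @param W_ee,W_ei,W_ie,W_ii Dimensionless mean connection strengths
#'   (`W_ei`, `W_ii` are inhibitory and must be `<= 0`).
#' @param tau_e Excitatory time constant (ms).
#' @param sigma_e Excitatory projection width.
#' @param mu_e,mu_i Static external drive to each population.
#' @param dim Spatial dimension, 1 (ring) or 2 (torus).
#' @param n_side Number of units per spatial axis per population.
#' @param dt Integration step (ms); must satisfy `dt <= tau_e / 10`.
#' @return An object of class `field_params`.
#' @examples
#' p <- field_params(tau_i = 12.8, sigma_i = 0.096, n_side = 32)
#' p
#' @export
field_params <- function(tau_i, sigma_i,
                         W_ee = 80, W_ei = -160, W_ie = 80, W_ii = -150,
                         tau_e = 5, sigma_e = 0.1,
                         mu_e = 0.48, mu_i = 0.32,
                         dim = 2, n_side = 100, dt = 0.1) {
  p <- list(W_ee = W_ee, W_ei = W_ei, W_ie = W_ie, W_ii = W_ii,
            tau_e = tau_e, tau_i = tau_i, sigma_e = sigma_e,
            sigma_i = sigma_i, mu_e = mu_e, mu_i = mu_i,
            dim = as.integer(dim), n_side = as.integer(n_side), dt = dt)
  validate_field_params(p)
  structure(p, class = "field_params")
}

validate_field_params <- function(p) {
  num <- c("W_ee", "W_ei", "W_ie", "W_ii", "tau_e", "tau_i", "sigma_e",
           "sigma_i", "mu_e", "mu_i", "dt")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      stop("parameter '", f, "' must be a finite scalar", call. = FALSE)
  }
  if (p$tau_e <= 0 || p$tau_i <= 0)
    stop("time constants must be positive", call. = FALSE)
  if (p$sigma_e <= 0 || p$sigma_i <= 0)
    stop("projection widths must be positive", call. = FALSE)
  if (!p$dim %in% c(1L, 2L)) stop("dim must be 1 or 2", call. = FALSE)
  if (p$n_side < 8) stop("n_side must be at least 8", call. = FALSE)
  if (p$dt <= 0 || p$dt > p$tau_e / 10)
    stop("dt must be positive and at most tau_e/10", call. = FALSE)
  invisible(p)
}

#' @export
print.field_params <- function(x, ...) {
  cat("Spatial rate-network parameters\n")
  cat(sprintf("  weights: W_ee=%g W_ei=%g W_ie=%g W_ii=%g\n",
              x$W_ee, x$W_ei, x$W_ie, x$W_ii))
  cat(sprintf("  time constants (ms): tau_e=%g tau_i=%g\n", x$tau_e, x$tau_i))
  cat(sprintf("  projection widths: sigma_e=%g sigma_i=%g\n",
              x$sigma_e, x$sigma_i))
  cat(sprintf("  drive: mu_e=%g mu_i=%g\n", x$mu_e, x$mu_i))
  cat(sprintf("  grid: dim=%d, n_side=%d, dt=%g ms\n", x$dim, x$n_side, x$dt))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params A [field_params()] object.
#' @param ... Named fields to replace.
#' @return A `field_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "field_params"))
  p <- modifyList(unclass(params), list(...))
  p$dim <- as.integer(p$dim)
  p$n_side <- as.integer(p$n_side)
  validate_field_params(p)
  structure(p, class = "field_params")
}

#' Ornstein-Uhlenbeck input-noise parameters
#'
#' Parameters of the correlated-plus-private input noise: each unit receives
#' `mu + sigma_n * (sqrt(1-c) * eta_k + sqrt(c) * eta_c)` where `eta_k` is a
#' private OU process and `eta_c` is an OU process common to all units of the
#' population. With `normalize_unit_variance = TRUE` (default) the OU
#' processes are scaled to unit stationary variance so that `sigma_n` is the
#' standard deviation of the input current; with `FALSE` the OU equation
#' `tau_n * d eta = -eta dt + dW` is used literally (stationary variance
#' `1/(2 tau_n)`).
#'
#' @param sigma_n Noise amplitude (input-current units), `>= 0`.
#' @param c Correlation coefficient in `[0, 1]`.
#' @param tau_n Noise time constant (ms).
#' @param normalize_unit_variance Scale the OU paths to unit variance?
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma_n, c = 0.5, tau_n = 5,
                         normalize_unit_variance = TRUE) {
  stopifnot(is.numeric(sigma_n), length(sigma_n) == 1, sigma_n >= 0,
            is.numeric(c), length(c) == 1, c >= 0, c <= 1,
            is.numeric(tau_n), tau_n > 0)
  structure(list(sigma_n = sigma_n, c = c, tau_n = tau_n,
                 normalize = isTRUE(normalize_unit_variance)),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(
    "OU input noise: sigma_n=%g, c=%g, tau_n=%g ms (%s variance)\n",
    x$sigma_n, x$c, x$tau_n,
    if (x$normalize) "unit" else "1/(2 tau_n)"))
  invisible(x)
}

# noise list passed down to the C++ core (empty list = noiseless)
noise_to_cpp <- function(noise) {
  if (is.null(noise)) return(list())
  stopifnot(inherits(noise, "noise_params"))
  if (noise$sigma_n == 0) return(list())
  list(sigma_n = noise$sigma_n, c = noise$c, tau_n = noise$tau_n,
       normalize = noise$normalize)
}

#' Read or write model/noise parameters as YAML
#'
#' Serializes a parameter set under a `model:` block (and optionally a
#' `noise:` block) compatible with [run_config()] configuration files.
#'
#' @param params A [field_params()] object.
#' @param noise Optional [noise_params()] object.
#' @param path File to write to.
#' @return `write_params_yaml` returns `path` invisibly; `read_params_yaml`
#'   returns a list with elements `params` and (possibly `NULL`) `noise`.
#' @export
write_params_yaml <- function(params, path, noise = NULL) {
  stopifnot(inherits(params, "field_params"))
  block <- list(model = unclass(params))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_params"))
    nn <- unclass(noise)
    names(nn)[names(nn) == "normalize"] <- "normalize_unit_variance"
    block$noise <- nn
  }
  yaml::write_yaml(block, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  block <- yaml::read_yaml(path)
  if (is.null(block$model)) stop("YAML file has no 'model:' block")
  params <- do.call(field_params, block$model)
  noise <- NULL
  if (!is.null(block$noise)) noise <- do.call(noise_params, block$noise)
  list(params = params, noise = noise)
}
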