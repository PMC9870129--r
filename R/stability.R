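#' Jacobian of the fixed point at one spatial Fourier mode
#'
#' Linearizing the spatial model around its uniform fixed point in Fourier
#' space gives, at integer mode `n` with wave number `k = ||n||`, the 2x2
#' matrix whose coupling terms are scaled by the kernel coefficients
#' `g~(k, sigma_e)` and `g~(k, sigma_i)`. Stability depends only on `k`.
#'
#' @param params A [field_params()] object.
#' @param k Wave number (scalar `||n||`; an integer mode vector is also
#'   accepted).
#' @param fp A fixed point from [two_unit_fixed_point()]; computed if
#'   omitted.
#' @return An object of class `mode_jacobian`: list with `k`, the 2x2
#'   matrix `J` and its `eigenvalues`.
#' @export
mode_jacobian <- function(params, k, fp = NULL) {
  stopifnot(inherits(params, "field_params"))
  if (is.null(fp)) fp <- two_unit_fixed_point(params)
  k <- sqrt(sum(k^2))
  L_e <- transfer_deriv(fp$u_e)
  L_i <- transfer_deriv(fp$u_i)
  ge <- gaussian_mode_coef(k, params$sigma_e)
  gi <- gaussian_mode_coef(k, params$sigma_i)
  J <- matrix(c((-1 + L_e * params$W_ee * ge) / params$tau_e,
                L_i * params$W_ie * ge / params$tau_i,
                L_e * params$W_ei * gi / params$tau_e,
                (-1 + L_i * params$W_ii * gi) / params$tau_i), 2, 2)
  structure(list(k = k, J = J,
                 eigenvalues = eigen(J, only.values = TRUE)$values),
            class = "mode_jacobian")
}

#' Mode-wise linear stability of the uniform fixed point
#'
#' Scans integer wave numbers `k = 0..max_mode` and reports whether all
#' leading eigenvalue real parts are negative, the most unstable wave
#' number, its growth rate, and the number of unstable wave numbers.
#'
#' @param params A [field_params()] object.
#' @param max_mode Largest wave number scanned. The default 50 is past the
#'   point where the kernel coefficient underflows for all widths of
#'   interest, so verdicts are insensitive to it.
#' @return An object of class `fp_stability`: list with `stable`, `crit_k`,
#'   `growth_rate` (1/ms), `n_unstable` and the per-mode leading real parts
#'   `lead_re`.
#' @export
fixed_point_stability <- function(params, max_mode = 50) {
  stopifnot(inherits(params, "field_params"), max_mode >= 1)
  fp <- two_unit_fixed_point(params)
  ks <- 0:max_mode
  lead <- vapply(ks, function(k)
    max(Re(mode_jacobian(params, k, fp)$eigenvalues)), numeric(1))
  structure(list(stable = all(lead < 0), crit_k = ks[which.max(lead)],
                 growth_rate = max(lead), n_unstable = sum(lead > 0),
                 k = ks, lead_re = lead, fp = fp),
            class = "fp_stability")
}

#' @export
print.fp_stability <- function(x, ...) {
  cat(sprintf(
    "Fixed point %s: most unstable k=%d (growth %.4g/ms), %d unstable modes\n",
    if (x$stable) "STABLE" else "UNSTABLE", x$crit_k, x$growth_rate,
    x$n_unstable))
  invisible(x)
}

# Monodromy matrices for a set of wave numbers, integrating the periodic
# linear system X' = J(k; t) X over one period with RK4, vectorized over k.
# Gains L_alpha(t) come from periodic cubic splines of the equilibrium
# inputs along the cycle (phi' is piecewise linear, so interpolating u and
# then applying phi' preserves the kink).
monodromy_all <- function(params, cycle, ks, n_steps = NULL) {
  stopifnot(inherits(cycle, "limit_cycle"))
  if (length(cycle$t) < 2000)
    stop("orbit samples too coarse for monodromy integration", call. = FALSE)
  Tp <- cycle$period
  if (is.null(n_steps)) n_steps <- max(4000L, length(cycle$t))
  h <- Tp / n_steps
  ue_fun <- splinefun(cycle$t, cycle$u_e, method = "periodic")
  ui_fun <- splinefun(cycle$t, cycle$u_i, method = "periodic")
  # interpolation-error estimate: spline through every other sample,
  # evaluated at the left-out samples (error at spacing 2h ~ 16x that at h)
  odd <- seq(1, length(cycle$t), by = 2)
  even <- seq(2, length(cycle$t) - 1, by = 2)
  half_fun <- splinefun(cycle$t[odd], cycle$u_e[odd])
  err <- max(abs(half_fun(cycle$t[even]) - cycle$u_e[even])) / 16
  scale <- max(abs(cycle$u_e))
  if (!is.finite(err) || err > 1e-6 * max(1, scale))
    stop("orbit samples too coarse: interpolation error estimate too large",
         call. = FALSE)
  tfine <- seq(0, Tp, by = h / 2)
  Le <- transfer_deriv(ue_fun(tfine %% Tp))
  Li <- transfer_deriv(ui_fun(tfine %% Tp))
  ge <- vapply(ks, gaussian_mode_coef, numeric(1), sigma = params$sigma_e)
  gi <- vapply(ks, gaussian_mode_coef, numeric(1), sigma = params$sigma_i)
  K <- length(ks)
  # X entries per k
  x11 <- rep(1, K); x12 <- rep(0, K); x21 <- rep(0, K); x22 <- rep(1, K)
  jac <- function(idx) {
    le <- Le[idx]; li <- Li[idx]
    list(a = (-1 + le * params$W_ee * ge) / params$tau_e,
         b = le * params$W_ei * gi / params$tau_e,
         c = li * params$W_ie * ge / params$tau_i,
         d = (-1 + li * params$W_ii * gi) / params$tau_i)
  }
  mult <- function(J, y11, y12, y21, y22) {
    list(d11 = J$a * y11 + J$b * y21, d12 = J$a * y12 + J$b * y22,
         d21 = J$c * y11 + J$d * y21, d22 = J$c * y12 + J$d * y22)
  }
  for (s in seq_len(n_steps)) {
    i0 <- 2 * s - 1          # index of t in tfine
    J1 <- jac(i0); J2 <- jac(i0 + 1); J4 <- jac(i0 + 2)
    k1 <- mult(J1, x11, x12, x21, x22)
    k2 <- mult(J2, x11 + h / 2 * k1$d11, x12 + h / 2 * k1$d12,
               x21 + h / 2 * k1$d21, x22 + h / 2 * k1$d22)
    k3 <- mult(J2, x11 + h / 2 * k2$d11, x12 + h / 2 * k2$d12,
               x21 + h / 2 * k2$d21, x22 + h / 2 * k2$d22)
    k4 <- mult(J4, x11 + h * k3$d11, x12 + h * k3$d12,
               x21 + h * k3$d21, x22 + h * k3$d22)
    x11 <- x11 + h / 6 * (k1$d11 + 2 * k2$d11 + 2 * k3$d11 + k4$d11)
    x12 <- x12 + h / 6 * (k1$d12 + 2 * k2$d12 + 2 * k3$d12 + k4$d12)
    x21 <- x21 + h / 6 * (k1$d21 + 2 * k2$d21 + 2 * k3$d21 + k4$d21)
    x22 <- x22 + h / 6 * (k1$d22 + 2 * k2$d22 + 2 * k3$d22 + k4$d22)
  }
  lapply(seq_len(K), function(j)
    matrix(c(x11[j], x21[j], x12[j], x22[j]), 2, 2))
}

#' Monodromy matrix of the bulk oscillation at one spatial mode
#'
#' Integrates the periodic linear variational system `X' = J(k; t) X` with
#' `X(0) = I` over one period of the bulk oscillation (the spatial lift of
#' the two-unit limit cycle) and returns `M(k) = X(T)`. Its eigenvalues are
#' the Floquet multipliers of the bulk oscillation against perturbations at
#' wave number `k`; at `k = 0` one multiplier equals 1 (perturbations
#' tangent to the cycle).
#'
#' @param params A [field_params()] object.
#' @param cycle A [find_limit_cycle()] result (class `limit_cycle`).
#' @param k Wave number (or integer mode vector).
#' @return A 2x2 monodromy matrix.
#' @export
monodromy <- function(params, cycle, k) {
  stopifnot(inherits(params, "field_params"))
  k <- sqrt(sum(k^2))
  monodromy_all(params, cycle, k)[[1]]
}

classify_multipliers <- function(mult, tol = 1e-3) {
  mag <- abs(mult)
  if (all(mag <= 1 + tol)) return("stable")
  lead <- mult[which.max(mag)]
  if (abs(Im(lead)) < 1e-8 * max(1, abs(lead))) {
    if (Re(lead) < -1) "lambda_lt_minus1" else "lambda_gt_1"
  } else "complex_unstable"
}

#' Floquet stability of the bulk oscillation across spatial modes
#'
#' Computes the monodromy matrix at each wave number `k = 0..max_mode` and
#' classifies each mode: stable (all multipliers inside the unit circle, up
#' to tolerance), `lambda_lt_minus1` (a real multiplier below -1: a
#' period-doubling instability producing alternating patterns),
#' `lambda_gt_1` (a real multiplier above 1: pattern formation with the
#' oscillation period) or `complex_unstable`. If no bulk oscillation exists
#' at these parameters, a `no_cycle` signal is returned.
#'
#' @param params A [field_params()] object.
#' @param max_mode Largest wave number scanned.
#' @param cycle Optionally a precomputed [find_limit_cycle()] result.
#' @param tol Tolerance on the unit-circle test.
#' @return An object of class `floquet_result`: per-mode multipliers and
#'   classification, the count of unstable modes (`n_unstable`), overall
#'   `stable`, and the period used. Or a list with `no_cycle = TRUE`.
#' @export
bulk_oscillation_stability <- function(params, max_mode = 50, cycle = NULL,
                                       tol = 1e-3) {
  stopifnot(inherits(params, "field_params"))
  if (is.null(cycle)) cycle <- find_limit_cycle(params)
  if (inherits(cycle, "fixed_point_signal"))
    return(structure(list(no_cycle = TRUE, fp = cycle),
                     class = "floquet_result"))
  ks <- 0:max_mode
  Ms <- monodromy_all(params, cycle, ks)
  mult <- lapply(Ms, function(M) eigen(M, only.values = TRUE)$values)
  cls <- vapply(mult, classify_multipliers, character(1), tol = tol)
  structure(list(no_cycle = FALSE, k = ks, period = cycle$period,
                 monodromy = Ms, multipliers = mult, class_by_mode = cls,
                 n_unstable = sum(cls != "stable"),
                 stable = all(cls == "stable"), cycle = cycle),
            class = "floquet_result")
}

#' @export
print.floquet_result <- function(x, ...) {
  if (isTRUE(x$no_cycle)) {
    cat("No bulk oscillation at these parameters (fixed point reached)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Bulk oscillation (T=%.4g ms) %s: %d unstable modes",
    x$period, if (x$stable) "STABLE" else "UNSTABLE", x$n_unstable))
  if (!x$stable) {
    first <- x$k[x$class_by_mode != "stable"][1]
    cat(sprintf(" (first at k=%d, %s)",
                first, x$class_by_mode[x$k == first]))
  }
  cat("\n")
  invisible(x)
}

#' Phase diagram over inhibitory width and time constant
#'
#' Runs both mode-wise stability analyses at every grid cell and returns a
#' long-format table; per-cell failures are recorded as `NA` rows, not
#' fatal.
#'
#' @param params A [field_params()] object (its `sigma_i`, `tau_i` are
#'   overridden cell by cell).
#' @param sigma_values Grid of `sigma_i`.
#' @param tau_values Grid of `tau_i` (ms).
#' @param max_mode Largest wave number scanned.
#' @return A data frame of class `phase_diagram` with columns `sigma_i`,
#'   `tau_i`, `fp_stable`, `bo_exists`, `bo_stable`, `fp_crit_k`,
#'   `bo_class`, `n_unstable_fp`, `n_unstable_bo`.
#' @export
phase_diagram <- function(params, sigma_values, tau_values, max_mode = 50) {
  stopifnot(inherits(params, "field_params"),
            length(sigma_values) > 0, length(tau_values) > 0)
  grid <- expand.grid(sigma_i = sigma_values, tau_i = tau_values)
  cycles <- list()  # cache limit cycles per tau_i (independent of sigma_i)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    sig <- grid$sigma_i[j]; tau <- grid$tau_i[j]
    p <- update_params(params, sigma_i = sig, tau_i = tau)
    out <- tryCatch({
      fps <- fixed_point_stability(p, max_mode)
      key <- sprintf("%.10g", tau)
      if (is.null(cycles[[key]])) cycles[[key]] <<- find_limit_cycle(p)
      bos <- bulk_oscillation_stability(p, max_mode, cycle = cycles[[key]])
      no_cycle <- isTRUE(bos$no_cycle)
      bo_class <- if (no_cycle) {
        NA_character_
      } else if (bos$stable) "stable" else {
        first <- bos$k[bos$class_by_mode != "stable"][1]
        bos$class_by_mode[bos$k == first]
      }
      data.frame(sigma_i = sig, tau_i = tau, fp_stable = fps$stable,
                 bo_exists = !no_cycle,
                 bo_stable = if (no_cycle) NA else bos$stable,
                 fp_crit_k = fps$crit_k, bo_class = bo_class,
                 n_unstable_fp = fps$n_unstable,
                 n_unstable_bo = if (no_cycle) NA_integer_ else
                   bos$n_unstable)
    }, error = function(e) {
      data.frame(sigma_i = sig, tau_i = tau, fp_stable = NA, bo_exists = NA,
                 bo_stable = NA, fp_crit_k = NA_integer_,
                 bo_class = paste("error:", conditionMessage(e)),
                 n_unstable_fp = NA_integer_, n_unstable_bo = NA_integer_)
    })
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' Export a phase diagram to CSV
#'
#' @param diagram A [phase_diagram()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phase_diagram_csv <- function(diagram, path) {
  write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}
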