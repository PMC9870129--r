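#' Distance-dependent spatial correlation of excitatory activity
#'
#' For each displacement on the periodic grid, the Pearson correlation of
#' the time-centered excitatory rates averaged over all unit pairs at that
#' displacement (with periodic wrapping), normalized by the spatially
#' averaged temporal variance. Computed spectrally: the displacement
#' covariance is the inverse transform of the time-accumulated spatial
#' power, which equals the direct pair-loop average exactly.
#'
#' @param traj A `rate_trajectory` with recorded fields.
#' @param min_samples Minimum number of recorded frames required.
#' @return An object of class `correlation_map`: `C` (a centered
#'   displacement vector in 1D or matrix in 2D, displacement 0 at the
#'   center), the displacement axes `dx` (and `dy`), and the time window.
#' @export
spatial_correlation <- function(traj, min_samples = 10) {
  stopifnot(inherits(traj, "rate_trajectory"))
  if (is.null(traj$re) || nrow(traj$re) < min_samples)
    stop("trajectory window shorter than ", min_samples, " samples",
         call. = FALSE)
  n <- traj$params$n_side
  d2 <- traj$params$dim == 2
  X <- sweep(traj$re, 2, colMeans(traj$re))  # time-centered per unit
  Tn <- nrow(X)
  if (d2) {
    acc <- matrix(0, n, n)
    for (i in seq_len(Tn)) {
      f <- fft(matrix(X[i, ], n, n))
      acc <- acc + Re(f * Conj(f))
    }
    num <- Re(fft(acc, inverse = TRUE)) / (n * n)^2 / Tn
  } else {
    acc <- numeric(n)
    for (i in seq_len(Tn)) {
      f <- fft(X[i, ])
      acc <- acc + Re(f * Conj(f))
    }
    num <- Re(fft(acc, inverse = TRUE)) / n^2 / Tn
  }
  denom <- num[1]
  if (denom <= 0) stop("zero spatial variance; correlation undefined",
                       call. = FALSE)
  C <- num / denom
  # center displacement 0: axis runs -floor(n/2) .. ceil(n/2)-1 grid steps
  dgrid <- -floor(n / 2):(ceiling(n / 2) - 1)
  pos <- (dgrid %% n) + 1
  Cc <- if (d2) C[pos, pos] else C[pos]
  out <- list(C = Cc, dx = dgrid / n, n_side = n, dim = traj$params$dim,
              window = range(traj$t), n_samples = Tn)
  if (d2) out$dy <- dgrid / n
  structure(out, class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf(
    "Spatial correlation map (%dD, n=%d, %d frames over [%g, %g] ms)\n",
    x$dim, x$n_side, x$n_samples, x$window[1], x$window[2]))
  half <- x$C
  if (x$dim == 2) half <- half[, which(x$dy == 0)]
  mid <- which(x$dx == 0)
  cat(sprintf("  C at |dx| = 0, 0.25, 0.5: %.3f, %.3f, %.3f\n",
              half[mid], half[mid + floor(x$n_side / 4)][1],
              half[1]))
  invisible(x)
}

#' Correlation at a given displacement
#'
#' @param map A [spatial_correlation()] result.
#' @param dx,dy Displacements in domain units (multiples of `1/n_side`).
#' @return Correlation value(s).
#' @export
correlation_at <- function(map, dx, dy = 0) {
  n <- map$n_side
  wrap <- function(d) {
    g <- round(d * n) %% n
    ifelse(g >= ceiling(n / 2), g - n, g)  # map onto the centered axis
  }
  ix <- match(wrap(dx), round(map$dx * n))
  if (map$dim == 2) {
    iy <- match(wrap(dy), round(map$dy * n))
    map$C[cbind(ix, iy)]
  } else map$C[ix]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Population-averaged single-unit power spectrum
#'
#' Per unit, subtracts the time mean and estimates the power spectral
#' density with Welch's method (Hann window, 50% overlap), then averages
#' over units. The spectrum is normalized so that `sum(S) * df` equals the
#' mean single-unit temporal variance (Parseval convention). A power-law
#' exponent over `band` and the (lightly smoothed) spectral peak are
#' attached.
#'
#' @param traj A `rate_trajectory` with recorded fields, or a plain time x
#'   units matrix via `x`/`fs`.
#' @param segment Welch segment length (ms).
#' @param band Frequency band (Hz) for the power-law fit.
#' @param smoothing Bins of moving average for peak extraction.
#' @return An object of class `spectrum_result` with `freq` (Hz), `power`,
#'   `gamma`, `peak_hz`, and the estimation settings.
#' @export
power_spectrum <- function(traj, segment = 2000, band = c(50, 200),
                           smoothing = 5) {
  stopifnot(inherits(traj, "rate_trajectory"))
  if (is.null(traj$re)) stop("trajectory has no recorded fields")
  dt_s <- diff(traj$t[1:2]) / 1000            # sampling interval (s)
  fs <- 1 / dt_s
  X <- traj$re
  nseg <- as.integer(round(segment / 1000 * fs))
  if (nrow(X) < nseg)
    stop("trajectory too short for the requested segment length",
         call. = FALSE)
  spec <- welch_psd(X, fs, nseg)
  out <- structure(list(freq = spec$freq, power = spec$power, fs = fs,
                        segment = segment, n_units = ncol(X),
                        band = band, smoothing = smoothing),
                   class = "spectrum_result")
  out$gamma <- tryCatch(powerlaw_exponent(out, band), error = function(e)
    NA_real_)
  out$peak_hz <- spectral_peak(out, smoothing)
  out
}

# Welch PSD of the columns of X, averaged over columns; one-sided,
# rescaled to exact Parseval normalization against the mean column variance
welch_psd <- function(X, fs, nseg) {
  Tn <- nrow(X)
  X <- sweep(X, 2, colMeans(X))
  w <- hann_window(nseg)
  starts <- seq(1, Tn - nseg + 1, by = max(1, floor(nseg / 2)))
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- X[s:(s + nseg - 1), , drop = FALSE] * w
    F <- mvfft(seg)
    acc <- acc + rowMeans(Re(F * Conj(F))[1:nfreq, , drop = FALSE])
  }
  pw <- acc / length(starts) / (fs * sum(w^2))
  pw[2:(nfreq - 1)] <- 2 * pw[2:(nfreq - 1)]  # one-sided
  freq <- (0:(nfreq - 1)) * fs / nseg
  df <- fs / nseg
  target_var <- mean(apply(X, 2, var))
  total <- sum(pw) * df
  if (total > 0 && target_var > 0) pw <- pw * (target_var / total)
  list(freq = freq, power = pw)
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(
    "Power spectrum: %d units, %g Hz sampling, %d bins to %g Hz\n",
    x$n_units, x$fs, length(x$freq), max(x$freq)))
  cat(sprintf("  peak at %.3g Hz; 1/f^gamma exponent %.3g over [%g, %g] Hz\n",
              x$peak_hz, x$gamma, x$band[1], x$band[2]))
  invisible(x)
}

#' Power-law exponent of a spectrum
#'
#' Least-squares slope of `log S` against `log f` over `band`; returns
#' `gamma = -slope` of the `1/f^gamma` scaling.
#'
#' @param spec A [power_spectrum()] result.
#' @param band Frequency interval (Hz) within the spectrum's axis.
#' @return The exponent `gamma`.
#' @export
powerlaw_exponent <- function(spec, band = c(50, 200)) {
  stopifnot(inherits(spec, "spectrum_result"))
  sel <- spec$freq >= band[1] & spec$freq <= band[2] & spec$power > 0
  if (sum(sel) < 5)
    stop("fit band contains fewer than 5 frequency bins", call. = FALSE)
  fit <- lm(log(spec$power[sel]) ~ log(spec$freq[sel]))
  -unname(coef(fit)[2])
}

#' Peak frequency of a spectrum
#'
#' Frequency of the global maximum of the lightly smoothed spectrum,
#' excluding the zero-frequency bin.
#'
#' @param spec A [power_spectrum()] result.
#' @param smoothing Moving-average window (bins); values < 2 disable
#'   smoothing.
#' @return Peak frequency (Hz).
#' @export
spectral_peak <- function(spec, smoothing = 5) {
  stopifnot(inherits(spec, "spectrum_result"))
  p <- spec$power
  if (smoothing >= 2) {
    k <- rep(1 / smoothing, smoothing)
    p <- as.numeric(stats::filter(p, k, sides = 2))
  }
  p[1] <- NA  # exclude DC
  spec$freq[which.max(p)]
}

#' Principal-component variance spectrum of sampled units
#'
#' Uniformly samples `n_sample` recorded excitatory units without
#' replacement (seeded) and returns the eigenvalues of the across-time
#' covariance matrix of their rates, sorted descending. Covariance (not
#' correlation) eigenvalues are used: units are not variance-normalized.
#'
#' @param traj A `rate_trajectory` with recorded fields.
#' @param n_sample Number of units to sample.
#' @param seed Integer seed for the sampling.
#' @return Numeric vector of sorted PC variances.
#' @export
pca_variance_spectrum <- function(traj, n_sample = 1000, seed = 1) {
  stopifnot(inherits(traj, "rate_trajectory"))
  if (is.null(traj$re)) stop("trajectory has no recorded fields")
  if (nrow(traj$re) < 2) stop("need at least 2 time samples", call. = FALSE)
  if (n_sample > ncol(traj$re))
    stop("n_sample exceeds the number of recorded units", call. = FALSE)
  idx <- with_seed(seed, sample.int(ncol(traj$re), n_sample))
  X <- traj$re[, idx, drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  cv <- crossprod(X) / (nrow(X) - 1)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sort(pmax(ev, 0), decreasing = TRUE)
}

count_dim95 <- function(ev, threshold = 0.95) {
  total <- sum(ev)
  if (total <= 0) return(1L)
  as.integer(which(cumsum(ev) >= threshold * total)[1])
}

#' PCA dimensionality of population activity
#'
#' For each sample size and repeat, the dimension is the smallest number of
#' leading principal components whose cumulative variance reaches 95% of
#' the total. The full covariance of all recorded units is computed once
#' and subset per sample.
#'
#' @param traj A `rate_trajectory` with recorded fields.
#' @param sample_sizes Numbers of units to sample.
#' @param repeats Seeded repeats per sample size.
#' @param seed Master seed.
#' @param threshold Cumulative-variance criterion (default 0.95).
#' @return An object of class `dimension_result`: a data frame `summary`
#'   (`n_sample`, `mean_dim`, `sd_dim`), the per-repeat `dims` matrix, and
#'   the PC variance spectrum of the largest sample's first repeat.
#' @export
dimension_95 <- function(traj, sample_sizes = c(100, 300, 1000),
                         repeats = 10, seed = 1, threshold = 0.95) {
  stopifnot(inherits(traj, "rate_trajectory"), repeats >= 1)
  if (is.null(traj$re)) stop("trajectory has no recorded fields")
  if (nrow(traj$re) < 2) stop("need at least 2 time samples", call. = FALSE)
  n_units <- ncol(traj$re)
  if (max(sample_sizes) > n_units)
    stop("sample size exceeds the number of recorded units", call. = FALSE)
  X <- sweep(traj$re, 2, colMeans(traj$re))
  CV <- crossprod(X) / (nrow(X) - 1)
  dims <- matrix(NA_integer_, length(sample_sizes), repeats,
                 dimnames = list(sample_sizes, NULL))
  spectrum <- NULL
  for (a in seq_along(sample_sizes)) {
    for (r in seq_len(repeats)) {
      idx <- with_seed(derive_seed(seed, a * 1000 + r),
                       sample.int(n_units, sample_sizes[a]))
      ev <- eigen(CV[idx, idx], symmetric = TRUE, only.values = TRUE)$values
      ev <- sort(pmax(ev, 0), decreasing = TRUE)
      dims[a, r] <- count_dim95(ev, threshold)
      if (a == which.max(sample_sizes) && r == 1) spectrum <- ev
    }
  }
  summary <- data.frame(n_sample = sample_sizes,
                        mean_dim = rowMeans(dims),
                        sd_dim = apply(dims, 1, sd))
  structure(list(summary = summary, dims = dims, pc_variances = spectrum,
                 threshold = threshold, repeats = repeats, seed = seed),
            class = "dimension_result")
}

#' @export
print.dimension_result <- function(x, ...) {
  cat(sprintf("Population dimensionality (%d%% variance, %d repeats)\n",
              round(100 * x$threshold), x$repeats))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export a spectrum or dimension summary to CSV
#'
#' @param x A `spectrum_result` or `dimension_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(x, path) {
  df <- if (inherits(x, "spectrum_result")) {
    data.frame(freq = x$freq, power = x$power)
  } else if (inherits(x, "dimension_result")) {
    x$summary
  } else if (inherits(x, "correlation_map")) {
    if (x$dim == 2) {
      data.frame(dx = rep(x$dx, length(x$dy)),
                 dy = rep(x$dy, each = length(x$dx)),
                 C = as.vector(x$C))
    } else data.frame(dx = x$dx, C = x$C)
  } else stop("unsupported object")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
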