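#' Audio and envelope containers
#'
#' Lightweight S3 containers for the signal chain: `audio_signal()` holds a
#' mono waveform with its sampling rate, `envelope_signal()` a non-negative
#' amplitude envelope, and `theta_envelope()` a zero-mean band-limited
#' envelope together with its passband.
#'
#' @param samples,values numeric vector of samples.
#' @param rate sampling rate in Hz (> 0).
#' @param band length-2 numeric, passband edges in Hz.
#' @return An object of the corresponding class; all are lists with a
#'   `values` (or `samples`) element and a `rate` element.
#' @export
audio_signal <- function(samples, rate) {
  check_finite_numeric(samples, "samples")
  stopifnot(is.numeric(rate), length(rate) == 1, rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_signal")
}

#' @rdname audio_signal
#' @export
envelope_signal <- function(values, rate) {
  check_finite_numeric(values, "values")
  stopifnot(rate > 0)
  if (any(values < 0))
    stop("envelope values must be non-negative", call. = FALSE)
  structure(list(values = as.numeric(values), rate = rate),
            class = "envelope_signal")
}

#' @rdname audio_signal
#' @export
theta_envelope <- function(values, rate, band = c(4, 8)) {
  check_finite_numeric(values, "values")
  stopifnot(rate > 0, length(band) == 2, band[1] > 0, band[2] > band[1])
  structure(list(values = as.numeric(values), rate = rate, band = band),
            class = "theta_envelope")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %d samples @ %g Hz\n",
              length(x$values), x$rate))
  invisible(x)
}

#' @export
print.theta_envelope <- function(x, ...) {
  cat(sprintf("<theta_envelope> %d samples @ %g Hz, band [%g, %g] Hz\n",
              length(x$values), x$rate, x$band[1], x$band[2]))
  invisible(x)
}

# Imaginary part of the analytic signal (discrete Hilbert transform) via the
# FFT half-spectrum method. Convention: hilbert_im(cos) = sin.
hilbert_im <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Exact FFT-domain resampling for band-limited signals: the spectrum is
# truncated (or zero-padded) to the new Nyquist band.
fft_resample <- function(x, rate_in, rate_out) {
  if (rate_in == rate_out) return(x)
  n <- length(x)
  m <- max(2L, as.integer(round(n * rate_out / rate_in)))
  X <- stats::fft(x)
  Y <- complex(m)
  k <- min(n, m)
  half <- floor((k - 1) / 2)
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  if (k %% 2 == 0 && k > 1) {
    # split the Nyquist bin symmetrically when it exists
    ny <- X[k / 2 + 1]
    if (m > k) {
      Y[k / 2 + 1] <- ny / 2
      Y[m - k / 2 + 1] <- Conj(ny) / 2
    } else {
      Y[m / 2 + 1] <- ny
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Extract the amplitude envelope of an audio signal
#'
#' Computes the magnitude of the analytic signal (Hilbert envelope) of the
#' broadband audio. The envelope may optionally be resampled to a lower rate
#' (`out_rate`), which is recommended before theta-band filtering: the
#' subsequent 4-8 Hz bandpass makes the precise envelope estimator
#' non-critical, while filter design at very high sampling rates is
#' numerically fragile.
#'
#' @param audio an [audio_signal()].
#' @param out_rate optional output sampling rate in Hz; `NULL` keeps the
#'   input rate.
#' @return An [envelope_signal()].
#' @examples
#' t <- seq(0, 2, by = 1 / 1000)
#' a <- audio_signal(sin(2 * pi * 440 * t), 1000)
#' env <- extract_envelope(a)
#' @export
extract_envelope <- function(audio, out_rate = NULL) {
  stopifnot(inherits(audio, "audio_signal"))
  x <- audio$samples
  env <- sqrt(x^2 + hilbert_im(x)^2)
  rate <- audio$rate
  if (!is.null(out_rate) && out_rate != rate) {
    stopifnot(out_rate > 0)
    env <- fft_resample(env, rate, out_rate)
    env[env < 0] <- 0  # resampling ripple can dip marginally below zero
    rate <- out_rate
  }
  envelope_signal(env, rate)
}

# Design the zero-phase theta bandpass: a Butterworth bandpass of the stated
# order (an even order 2k is realized as butter(k, band)), applied
# forward-backward so the effective attenuation is the squared magnitude.
design_theta_filter <- function(rate, low = 4, high = 8, order = 6) {
  if (order <= 0 || order %% 2 != 0)
    stop("filter `order` must be a positive even integer", call. = FALSE)
  if (rate <= 2 * high)
    stop(sprintf("sampling rate %g Hz is too low for a %g Hz upper band edge",
                 rate, high), call. = FALSE)
  signal::butter(order / 2, c(low, high) / (rate / 2), type = "pass")
}

# Complex frequency response of a designed filter at frequency f (Hz); the
# zero-phase (forward-backward) gain is Mod(.)^2.
filter_response <- function(filt, f, rate) {
  w <- 2 * pi * f / rate
  num <- vapply(w, function(wi)
    sum(filt$b * exp(-1i * wi * (seq_along(filt$b) - 1))), complex(1))
  den <- vapply(w, function(wi)
    sum(filt$a * exp(-1i * wi * (seq_along(filt$a) - 1))), complex(1))
  num / den
}

#' Theta-band zero-phase filtering of a speech envelope
#'
#' Bandpass-filters an envelope in the theta range with a zero-phase
#' (forward-backward) Butterworth IIR filter. The design order refers to the
#' single-pass filter; the forward-backward application doubles the
#' effective attenuation and cancels the group delay, so features of the
#' filtered envelope stay temporally aligned with the acoustics.
#'
#' @param env an [envelope_signal()] (a plain numeric vector is also
#'   accepted together with `rate`).
#' @param low,high passband edges in Hz.
#' @param order single-pass filter order; must be even (default 6).
#' @param rate sampling rate, only needed when `env` is a bare vector.
#' @return A [theta_envelope()]; its values are zero-mean by construction
#'   (DC lies in the stopband).
#' @export
bandpass_theta <- function(env, low = 4, high = 8, order = 6, rate = NULL) {
  if (inherits(env, "envelope_signal")) {
    x <- env$values
    rate <- env$rate
  } else {
    check_finite_numeric(env, "env")
    if (is.null(rate)) stop("`rate` required for a bare numeric envelope",
                            call. = FALSE)
    x <- as.numeric(env)
  }
  if (length(x) < rate)
    stop("need at least 1 s of samples for well-posed filtering",
         call. = FALSE)
  filt <- design_theta_filter(rate, low, high, order)
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  n <- length(x)
  n_pad <- min(n - 1, 3 * round(rate))
  xp <- c(2 * x[1] - x[(n_pad + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - n_pad)])
  yp <- signal::filtfilt(filt, xp)
  y <- yp[(n_pad + 1):(n_pad + n)]
  theta_envelope(y, rate, band = c(low, high))
}

#' Correlation between pairs of speech envelopes
#'
#' Computes Pearson's correlation for each pair of envelopes, then the mean
#' and standard error of the per-pair correlations and a two-tailed
#' one-sample t test of the mean correlation against zero. This is the check
#' that target and distractor envelopes are statistically unrelated.
#'
#' Pairs of unequal length are truncated to the shorter member; the number
#' of truncated pairs is recorded in the result.
#'
#' @param pairs a list of length-2 lists of [envelope_signal()] objects (or
#'   bare numeric vectors).
#' @return A list of class `envelope_correlation` with elements `r`
#'   (per-pair correlations), `mean_r`, `sem_r`, `t`, `df`, `p`, and
#'   `n_truncated`.
#' @export
envelope_pair_correlation <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1)
  n_trunc <- 0L
  r <- vapply(pairs, function(p) {
    stopifnot(length(p) == 2)
    a <- if (inherits(p[[1]], "envelope_signal")) p[[1]]$values else p[[1]]
    b <- if (inherits(p[[2]], "envelope_signal")) p[[2]]$values else p[[2]]
    if (length(a) != length(b)) {
      n_trunc <<- n_trunc + 1L
      k <- min(length(a), length(b))
      a <- a[seq_len(k)]; b <- b[seq_len(k)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance envelope: correlation undefined", call. = FALSE)
    stats::cor(a, b)
  }, numeric(1))
  mean_r <- mean(r)
  if (length(r) > 1) {
    sem_r <- stats::sd(r) / sqrt(length(r))
    if (sem_r == 0) {
      # all pairs identical: the t test is undefined
      out <- list(r = r, mean_r = mean_r, sem_r = 0, t = NA_real_,
                  df = length(r) - 1, p = NA_real_, n_truncated = n_trunc)
    } else {
      tt <- stats::t.test(r, mu = 0, alternative = "two.sided")
      out <- list(r = r, mean_r = mean_r, sem_r = sem_r,
                  t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value, n_truncated = n_trunc)
    }
  } else {
    out <- list(r = r, mean_r = mean_r, sem_r = NA_real_, t = NA_real_,
                df = NA_real_, p = NA_real_, n_truncated = n_trunc)
  }
  structure(out, class = "envelope_correlation")
}

#' @export
print.envelope_correlation <- function(x, ...) {
  cat(sprintf("Envelope-pair correlation: mean r = %.4f +/- %.4f (SEM, %d pairs), p = %.3g\n",
              x$mean_r, x$sem_r, length(x$r), x$p))
  invisible(x)
}
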