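#' Stimulation waveform containers
#'
#' `normalized_waveform()` holds a unit-amplitude waveform in which every
#' interior local maximum equals +1 and every interior local minimum equals
#' -1 (within a tolerance); `stimulus_waveform()` holds a current waveform
#' in mA together with its phase shift and source label.
#'
#' @param values numeric samples.
#' @param rate sampling rate (Hz).
#' @param phase_deg phase shift in degrees, stored modulo 360.
#' @param source one of `"target"`, `"distractor"`, `"sham"`.
#' @param max_current maximum current magnitude in mA.
#' @export
normalized_waveform <- function(values, rate) {
  check_finite_numeric(values, "values")
  stopifnot(rate > 0)
  structure(list(values = as.numeric(values), rate = rate),
            class = "normalized_waveform")
}

#' @rdname normalized_waveform
#' @export
stimulus_waveform <- function(values, rate, phase_deg, source, max_current) {
  check_finite_numeric(values, "values")
  source <- match.arg(source, c("target", "distractor", "sham"))
  stopifnot(rate > 0, max_current > 0)
  if (max(abs(values)) > max_current * (1 + 1e-9))
    stop("waveform exceeds max_current", call. = FALSE)
  structure(list(values = as.numeric(values), rate = rate,
                 phase_deg = wrap_deg(phase_deg), source = source,
                 max_current = max_current),
            class = "stimulus_waveform")
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat(sprintf("<stimulus_waveform> %s, phase %g deg, peak %.3g mA, %d samples @ %g Hz\n",
              x$source, x$phase_deg, x$max_current, length(x$values), x$rate))
  invisible(x)
}

# Interior local extrema of a sampled signal, as a list of indices and a
# +1/-1 type marker. Plateaus are collapsed to their midpoint.
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2)
    return(list(idx = integer(0), type = integer(0)))
  idx <- integer(0); type <- integer(0)
  prev <- nz[1]
  for (k in nz[-1]) {
    if (s[k] != s[prev]) {
      # extremum between end of previous run and start of this one
      i <- as.integer(round((prev + 1 + k) / 2))
      idx <- c(idx, i)
      type <- c(type, if (s[prev] > 0) 1L else -1L)
    }
    prev <- k
  }
  list(idx = idx, type = type)
}

#' Equalize the extrema of a theta-band waveform
#'
#' Rescales a band-limited waveform so that all interior local maxima equal
#' +1 and all interior local minima equal -1. The rescaling divides the
#' signal by a piecewise-linear amplitude profile interpolated through the
#' magnitudes of the detected extrema (constant beyond the outermost
#' extrema), which is continuous, preserves zero crossings and keeps the
#' number and order of extrema. Because a time-varying amplitude profile
#' can shift extrema slightly, the rescaling is iterated to a fixed point
#' until every detected extremum lies within `tol` of +/-1.
#'
#' @param theta a [theta_envelope()], [normalized_waveform()] or numeric
#'   vector.
#' @param tol tolerance on extremum magnitudes (default `1e-6`).
#' @param max_iter maximum number of rescaling passes.
#' @param rate sampling rate, required for bare numeric input.
#' @return A [normalized_waveform()].
#' @export
equalize_extrema <- function(theta, tol = 1e-6, max_iter = 50, rate = NULL) {
  if (inherits(theta, "theta_envelope") ||
      inherits(theta, "normalized_waveform")) {
    x <- theta$values
    rate <- theta$rate
  } else {
    check_finite_numeric(theta, "theta")
    if (is.null(rate)) stop("`rate` required for bare numeric input",
                            call. = FALSE)
    x <- as.numeric(theta)
  }
  n <- length(x)
  for (iter in seq_len(max_iter)) {
    ext <- local_extrema(x)
    if (length(ext$idx) < 2)
      stop("fewer than 2 interior extrema: cannot equalize", call. = FALSE)
    v <- abs(x[ext$idx])
    if (any(v < 1e-12))
      stop("extremum with (near-)zero magnitude: cannot equalize",
           call. = FALSE)
    if (max(abs(v - 1)) <= tol) break
    amp <- stats::approx(ext$idx, v, xout = seq_len(n), rule = 2)$y
    x <- x / amp
  }
  normalized_waveform(x, rate)
}

#' Phase-shift a waveform by rotating its analytic signal
#'
#' Implements `y(t) = x(t) cos(theta) - H{x}(t) sin(theta)`, where `H` is
#' the Hilbert transform with the convention `H{sin} = -cos`. A positive
#' shift advances the phase (`sin` becomes `cos` at +90 degrees); a shift
#' of 180 degrees is an exact pointwise negation of the input, and the
#' instantaneous amplitude (analytic magnitude) is preserved for any shift.
#'
#' @param wave a [normalized_waveform()] or numeric vector.
#' @param degrees phase shift in degrees (any real value).
#' @param rate sampling rate, required for bare numeric input.
#' @return The shifted waveform, same class and length as the input.
#' @export
phase_shift <- function(wave, degrees, rate = NULL) {
  is_obj <- inherits(wave, "normalized_waveform")
  if (is_obj) {
    x <- wave$values
    rate <- wave$rate
  } else {
    check_finite_numeric(wave, "wave")
    x <- as.numeric(wave)
  }
  stopifnot(is.numeric(degrees), length(degrees) == 1, is.finite(degrees))
  # cospi/sinpi give exact values at multiples of 90 deg, so the 180-deg
  # case is bitwise negation
  ct <- cospi(degrees / 180)
  st <- sinpi(degrees / 180)
  y <- if (st == 0) x * ct else x * ct - hilbert_im(x) * st
  if (is_obj) normalized_waveform(y, rate) else y
}

#' Sham stimulation pulse
#'
#' A brief placebo current: a pulse of total duration `duration_ms` with
#' linear on/off ramps of `ramp_ms` and a flat plateau in between, at
#' amplitude `max_mA`. The pulse starts at sample 1; if `total_ms` exceeds
#' the pulse duration the remainder is zero-padded.
#'
#' @param rate sampling rate (Hz).
#' @param duration_ms pulse duration (default 500 ms).
#' @param ramp_ms ramp duration (default 100 ms); `0` gives a rectangular
#'   pulse.
#' @param max_mA pulse amplitude in mA.
#' @param total_ms optional total waveform duration (>= `duration_ms`).
#' @return A [stimulus_waveform()] with `source = "sham"`.
#' @export
make_sham <- function(rate, duration_ms = 500, ramp_ms = 100, max_mA = 0.67,
                      total_ms = duration_ms) {
  stopifnot(rate > 0, duration_ms > 0, ramp_ms >= 0, max_mA > 0,
            total_ms >= duration_ms)
  if (duration_ms <= 2 * ramp_ms)
    stop("duration_ms must exceed twice ramp_ms (plateau would be empty)",
         call. = FALSE)
  n <- round(rate * duration_ms / 1000)
  nr <- round(rate * ramp_ms / 1000)
  up <- if (nr > 0) seq_len(nr) / nr else numeric(0)
  plateau <- rep(1, n - 2 * nr)
  v <- c(up, plateau, rev(up)) * max_mA
  n_total <- round(rate * total_ms / 1000)
  if (n_total > length(v)) v <- c(v, numeric(n_total - length(v)))
  stimulus_waveform(v, rate, phase_deg = 0, source = "sham",
                    max_current = max_mA)
}

#' Scale a normalized waveform to a stimulation current
#'
#' Peak-referenced scaling: the output's maximum absolute value equals
#' `max_mA` and the waveform shape is unchanged up to that scalar. An
#' all-zero input stays all-zero.
#'
#' @param wave a [normalized_waveform()].
#' @param max_mA maximum current magnitude in mA (> 0; the study calibrated
#'   per subject in 0.1 mA steps between 0.1 and 1.5 mA, mean 0.67 mA).
#' @param source waveform source label.
#' @param phase_deg phase shift metadata carried into the result.
#' @return A [stimulus_waveform()].
#' @export
scale_current <- function(wave, max_mA, source = "target", phase_deg = 0) {
  stopifnot(inherits(wave, "normalized_waveform"))
  if (!is.numeric(max_mA) || length(max_mA) != 1 || !is.finite(max_mA) ||
      max_mA <= 0)
    stop("`max_mA` must be a positive number", call. = FALSE)
  pk <- max(abs(wave$values))
  v <- if (pk == 0) wave$values else wave$values * (max_mA / pk)
  stimulus_waveform(v, wave$rate, phase_deg = phase_deg, source = source,
                    max_current = max_mA)
}

#' Full audio-to-stimulus chain
#'
#' Composes the waveform pipeline in the fixed order: envelope extraction,
#' theta bandpass, extrema equalization, phase shift, current scaling.
#' Deterministic: identical inputs give bit-identical outputs.
#'
#' @param audio an [audio_signal()].
#' @param phase_deg phase shift in degrees.
#' @param max_mA maximum current (mA).
#' @param source `"target"` or `"distractor"`.
#' @param env_rate envelope sampling rate used for filtering (default
#'   250 Hz).
#' @param low,high,order theta bandpass parameters, see [bandpass_theta()].
#' @return A [stimulus_waveform()].
#' @export
make_stimulus <- function(audio, phase_deg = 0, max_mA = 0.67,
                          source = "target", env_rate = 250,
                          low = 4, high = 8, order = 6) {
  env <- extract_envelope(audio, out_rate = env_rate)
  th <- bandpass_theta(env, low = low, high = high, order = order)
  nw <- equalize_extrema(th)
  sh <- phase_shift(nw, phase_deg)
  scale_current(sh, max_mA, source = source, phase_deg = phase_deg)
}
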