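# Synthetic-data generation: cohort comprehension scores with a known
# ground-truth phase modulation, and surrogate theta-band envelope pairs.
# These emulate the study conditions (18 subjects; 26 sentences x 5
# keywords = 130 keywords per condition; scores near 50% at the SRT;
# sinusoidal phase modulation of ~3 percentage points peaking at 0 degrees
# for target-envelope stimulation and ~1.6 points peaking at 180 degrees
# for distractor-envelope stimulation; binomial keyword scoring noise).

#' Generate a synthetic comprehension-score cohort
#'
#' For each subject, source and phase, the number of correct keywords is
#' drawn as `binomial(n_keywords, p)` with
#' `p = (cs_mean + offset_s + A1 cos(phi - phi1)) / 100`, where `offset_s`
#' is a Gaussian between-subject offset. Sham scores are generated with no
#' phase modulation and carry `phase_deg = NA`.
#'
#' @param n_subjects number of subjects (default 18).
#' @param n_sentences,keywords_per_sentence per-condition sentence count
#'   and keywords per sentence (defaults 26 and 5, i.e. 130 keywords).
#' @param cs_mean population mean comprehension score in percent at the
#'   SRT (default 50).
#' @param a1_true named vector of true modulation amplitudes (percentage
#'   points) for `target` and `distractor`.
#' @param phi1_true_deg named vector of true best phases (degrees).
#' @param subject_sd SD of the between-subject offset (percentage points).
#' @param seed integer seed; the generator is a pure function of its
#'   parameters and seed.
#' @return A data frame of class `cohort_scores` with columns `subject`,
#'   `source`, `phase_deg`, `n_keywords`, `n_correct`, `cs`, and a
#'   `truth` attribute recording the generating parameters.
#' @export
generate_cohort <- function(n_subjects = 18, n_sentences = 26,
                            keywords_per_sentence = 5, cs_mean = 50,
                            a1_true = c(target = 3.0, distractor = 1.6),
                            phi1_true_deg = c(target = 0, distractor = 180),
                            subject_sd = 5, seed = NULL) {
  stopifnot(n_subjects >= 2, n_sentences >= 1, keywords_per_sentence >= 1,
            subject_sd >= 0)
  stopifnot(all(c("target", "distractor") %in% names(a1_true)),
            all(c("target", "distractor") %in% names(phi1_true_deg)))
  n_kw <- n_sentences * keywords_per_sentence
  phases <- c(0, 90, 180, 270)
  with_seed(seed, {
    offsets <- stats::rnorm(n_subjects, 0, subject_sd)
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (src in c("target", "distractor")) {
        mu <- cs_mean + offsets[s] +
          a1_true[[src]] * cos(deg2rad(phases - phi1_true_deg[[src]]))
        p <- mu / 100
        if (any(p <= 0.001) || any(p >= 0.999))
          stop("keyword probability out of range: reduce amplitudes or subject_sd",
               call. = FALSE)
        k <- stats::rbinom(length(phases), n_kw, p)
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("S%02d", s), source = src, phase_deg = phases,
          n_keywords = n_kw, n_correct = k, cs = 100 * k / n_kw)
      }
      p_sham <- (cs_mean + offsets[s]) / 100
      if (p_sham <= 0.001 || p_sham >= 0.999)
        stop("keyword probability out of range: reduce subject_sd",
             call. = FALSE)
      k <- stats::rbinom(1, n_kw, p_sham)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("S%02d", s), source = "sham", phase_deg = NA_real_,
        n_keywords = n_kw, n_correct = k, cs = 100 * k / n_kw)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("cohort_scores", "data.frame"),
              truth = list(cs_mean = cs_mean, a1_true = a1_true,
                           phi1_true_deg = phi1_true_deg,
                           subject_sd = subject_sd, n_keywords = n_kw,
                           seed = seed))
  })
}

# Broadband 1/f-shaped ("pink-ish") Gaussian noise via FFT spectral
# shaping; the realistic broadband content from which the theta band is
# extracted.
pink_noise <- function(n, rate) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)  # two-sided frequency axis
  w <- ifelse(f > 0, 1 / sqrt(pmax(f, 0.5)), 0)
  Re(stats::fft(X * w, inverse = TRUE)) / n
}

surrogate_envelope_one <- function(duration_s, rate, mod_band) {
  n <- round(duration_s * rate)
  x <- pink_noise(n, rate)
  th <- signal::filtfilt(design_theta_filter(rate, mod_band[1], mod_band[2]),
                         x)
  v <- th - min(th)  # offset to non-negativity
  envelope_signal(v, rate)
}

#' Generate a pair of independent surrogate speech envelopes
#'
#' Stands in for the envelopes of two unrelated sentences: each member is
#' theta-band-filtered 1/f-shaped noise, offset to non-negativity, so its
#' modulation spectrum is dominated by the 4-8 Hz band. The two members
#' are generated from distinct seeded substreams and are statistically
#' independent; `duplicate = TRUE` returns the same signal twice (the
#' degenerate fully-correlated case, for checks).
#'
#' @param duration_s duration in seconds (>= 2).
#' @param rate sampling rate in Hz (>= 64).
#' @param mod_band modulation band, default `c(4, 8)` Hz.
#' @param seed master integer seed; member substreams are derived from it.
#' @param seeds optional explicit length-2 seeds for the two members; they
#'   must differ (an identical pair would not be independent).
#' @param duplicate return the first member twice.
#' @return A list of two [envelope_signal()] objects.
#' @export
generate_envelope_pair <- function(duration_s = 3, rate = 250,
                                   mod_band = c(4, 8), seed = NULL,
                                   seeds = NULL, duplicate = FALSE) {
  stopifnot(duration_s >= 2, rate >= 64)
  if (!is.null(seeds)) {
    stopifnot(length(seeds) == 2)
    if (seeds[1] == seeds[2])
      stop("the two members of an envelope pair must use distinct seeds",
           call. = FALSE)
  } else if (!is.null(seed)) {
    seeds <- c(2L * as.integer(seed), 2L * as.integer(seed) + 1L)
  } else {
    seeds <- c(NULL, NULL)
  }
  a <- with_seed(if (length(seeds)) seeds[1] else NULL,
                 surrogate_envelope_one(duration_s, rate, mod_band))
  if (duplicate) return(list(a, a))
  b <- with_seed(if (length(seeds)) seeds[2] else NULL,
                 surrogate_envelope_one(duration_s, rate, mod_band))
  list(a, b)
}

#' Fraction of modulation power inside a frequency band
#'
#' Computes the periodogram of a (mean-removed) envelope and returns the
#' fraction of total power falling inside `band`. Used to verify that
#' surrogate envelopes carry their modulation energy in the theta range.
#'
#' @param env an [envelope_signal()] or numeric vector.
#' @param band length-2 band in Hz.
#' @param rate sampling rate for bare numeric input.
#' @return A single number in `[0, 1]`.
#' @export
band_power_fraction <- function(env, band = c(4, 8), rate = NULL) {
  if (inherits(env, c("envelope_signal", "theta_envelope"))) {
    x <- env$values; rate <- env$rate
  } else {
    check_finite_numeric(env, "env")
    if (is.null(rate)) stop("`rate` required", call. = FALSE)
    x <- as.numeric(env)
  }
  x <- x - mean(x)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)  # positive frequencies, DC excluded
  f <- (half - 1) * rate / n
  sum(pw[half][f >= band[1] & f <= band[2]]) / sum(pw[half])
}
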