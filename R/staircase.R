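# Simulation of the adaptive 1-up/1-down sentence-reception-threshold
# (SRT) procedure with virtual listeners. The real study ran this with
# human participants; the virtual listener is a logistic psychometric
# model used to validate the estimator.

#' Virtual listener with a logistic psychometric function
#'
#' The probability of understanding a keyword at a given SNR is
#' `p(snr) = guess + (1 - guess - lapse) * plogis(4 * slope * (snr - srt_true))`,
#' so with zero guess and lapse rates the keyword probability is 50% at
#' `srt_true` and the slope of `p` at threshold equals `slope`
#' (probability per dB).
#'
#' @param srt_true true 50%-keyword SNR in dB.
#' @param slope psychometric slope at threshold, probability/dB (> 0).
#' @param guess,lapse guess and lapse rates in `[0, 0.1]`.
#' @return A list of class `listener_model`.
#' @export
listener_model <- function(srt_true, slope = 0.2, guess = 0, lapse = 0) {
  stopifnot(is.finite(srt_true), slope > 0,
            guess >= 0, guess <= 0.1, lapse >= 0, lapse <= 0.1)
  structure(list(srt_true = srt_true, slope = slope, guess = guess,
                 lapse = lapse),
            class = "listener_model")
}

keyword_prob <- function(listener, snr) {
  span <- 1 - listener$guess - listener$lapse
  listener$guess +
    span * stats::plogis(4 * listener$slope / span *
                           (snr - listener$srt_true))
}

#' Simulate one sentence trial
#'
#' Draws the number of correctly understood keywords as a binomial with
#' the listener's keyword probability at the presented SNR.
#'
#' @param listener a [listener_model()].
#' @param snr presented SNR in dB.
#' @param n_keywords keywords per sentence (study: 5).
#' @param seed optional integer seed (for single reproducible trials;
#'   inside [run_staircase()] the run-level seed governs).
#' @return Integer count of correct keywords.
#' @export
simulate_trial <- function(listener, snr, n_keywords = 5, seed = NULL) {
  stopifnot(inherits(listener, "listener_model"), n_keywords >= 1)
  p <- keyword_prob(listener, snr)
  with_seed(seed, stats::rbinom(1, n_keywords, p))
}

#' Run one adaptive 1-up/1-down staircase
#'
#' The track starts at a random SNR drawn uniformly between -3 and 0 dB
#' (or at `start_snr` if given). After each sentence, the SNR increases by
#' 1 dB if at most two of the five keywords were understood, and decreases
#' by 1 dB otherwise. The run stops after seven reversals of the SNR
#' direction or after 17 trials, whichever comes first.
#'
#' @param listener a [listener_model()].
#' @param seed integer seed for the whole run.
#' @param start_snr starting SNR in dB; `NULL` draws uniform on
#'   `[-3, 0]` (continuous by default; `integer_start = TRUE` draws an
#'   integer).
#' @param step step size in dB (default 1).
#' @param up_max at most this many correct keywords triggers an SNR
#'   increase (default 2 of 5).
#' @param n_keywords keywords per sentence.
#' @param max_reversals,max_trials stopping rules (defaults 7 and 17).
#' @param integer_start draw an integer starting SNR.
#' @return A list of class `staircase_run` with `snr_track` (presented
#'   SNRs), `n_correct` per trial, `reversals` (trial indices), `n_trials`
#'   and `stopped_by`.
#' @export
run_staircase <- function(listener, seed = NULL, start_snr = NULL,
                          step = 1, up_max = 2, n_keywords = 5,
                          max_reversals = 7, max_trials = 17,
                          integer_start = FALSE) {
  stopifnot(inherits(listener, "listener_model"), step > 0)
  with_seed(seed, {
    snr <- start_snr %||% {
      s <- stats::runif(1, -3, 0)
      if (integer_start) round(s) else s
    }
    track <- numeric(0)
    ncorr <- integer(0)
    dirs <- integer(0)
    reversals <- integer(0)
    repeat {
      k <- stats::rbinom(1, n_keywords, keyword_prob(listener, snr))
      track <- c(track, snr)
      ncorr <- c(ncorr, k)
      d <- if (k <= up_max) 1L else -1L
      t_now <- length(track)
      if (t_now >= 2 && d != dirs[t_now - 1]) reversals <- c(reversals, t_now)
      dirs <- c(dirs, d)
      if (length(reversals) >= max_reversals) {
        stopped <- "reversals"; break
      }
      if (t_now >= max_trials) {
        stopped <- "max_trials"; break
      }
      snr <- snr + d * step
    }
    structure(list(snr_track = track, n_correct = ncorr,
                   reversals = reversals, n_trials = length(track),
                   stopped_by = stopped),
              class = "staircase_run")
  })
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("Staircase run: %d trials, %d reversals, stopped by %s; final SNRs: %s dB\n",
              x$n_trials, length(x$reversals), x$stopped_by,
              paste(round(utils::tail(x$snr_track, 3), 2), collapse = ", ")))
  invisible(x)
}

#' Estimate the 50% sentence reception threshold from four runs
#'
#' The procedure is run four times per listener; the SRT is taken from the
#' last three runs. Two readings of the estimator are provided:
#' `rule = "last3_mean"` (default) averages, within each of the last three
#' runs, that run's final three presented SNRs, then averages across runs;
#' `rule = "final_snr"` averages the single final SNR of each of the last
#' three runs.
#'
#' @param runs a list of exactly 4 [run_staircase()] results.
#' @param rule estimator reading, see Details.
#' @return A list of class `srt_estimate` with `srt_db`, the `rule` and
#'   the per-run summaries.
#' @export
estimate_srt <- function(runs, rule = c("last3_mean", "final_snr")) {
  rule <- match.arg(rule)
  if (!is.list(runs) || length(runs) != 4 ||
      !all(vapply(runs, inherits, logical(1), "staircase_run")))
    stop("`runs` must be a list of exactly 4 staircase runs", call. = FALSE)
  last3 <- runs[2:4]
  per_run <- vapply(last3, function(r) {
    tr <- r$snr_track
    if (rule == "last3_mean") mean(utils::tail(tr, 3))
    else utils::tail(tr, 1)
  }, numeric(1))
  structure(list(srt_db = mean(per_run), per_run = per_run, rule = rule,
                 runs = runs),
            class = "srt_estimate")
}

#' @export
print.srt_estimate <- function(x, ...) {
  cat(sprintf("SRT estimate: %.2f dB (rule %s; per-run %s)\n",
              x$srt_db, x$rule, paste(round(x$per_run, 2), collapse = ", ")))
  invisible(x)
}

#' Simulate SRT measurement for a virtual cohort
#'
#' Draws listeners with normally distributed true thresholds, runs the
#' full four-run staircase procedure for each, and returns true and
#' estimated SRTs. Default cohort parameters emulate the study population
#' (mean SRT -6.9 dB, SD 1.6 dB).
#'
#' @param n_listeners number of virtual listeners.
#' @param srt_mean,srt_sd population mean and SD of the true SRT (dB).
#' @param slope,guess,lapse psychometric parameters, see
#'   [listener_model()].
#' @param seed integer seed.
#' @param rule SRT estimator rule, see [estimate_srt()].
#' @return A data frame with `listener`, `srt_true` and `srt_est`.
#' @export
simulate_srt_cohort <- function(n_listeners = 18, srt_mean = -6.9,
                                srt_sd = 1.6, slope = 0.2, guess = 0,
                                lapse = 0, seed = NULL,
                                rule = "last3_mean") {
  with_seed(seed, {
    out <- lapply(seq_len(n_listeners), function(i) {
      lst <- listener_model(stats::rnorm(1, srt_mean, srt_sd), slope,
                            guess, lapse)
      runs <- lapply(1:4, function(j) run_staircase(lst))
      data.frame(listener = i, srt_true = lst$srt_true,
                 srt_est = estimate_srt(runs, rule = rule)$srt_db)
    })
    do.call(rbind, out)
  })
}
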