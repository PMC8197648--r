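#' Mean-center comprehension scores across stimulation phases
#'
#' For one stimulation source, computes each subject's mean comprehension
#' score over the four phase shifts (0, 90, 180, 270 degrees) and the
#' per-phase deviations from that mean. These deviations (`dcs`, in
#' percentage points) are what the harmonic model is fitted to; by
#' construction they sum to zero within each subject.
#'
#' @param scores a cohort scores data frame with columns `subject`,
#'   `source`, `phase_deg` and `cs` (percent correct); see
#'   [generate_cohort()] and [read_scores()].
#' @param source which stimulation source to analyse (`"target"` or
#'   `"distractor"`).
#' @return A data frame of class `centered_scores` with columns `subject`,
#'   `phase_deg`, `cs`, `cs_bar` and `dcs`, and a `source` attribute.
#' @export
center_scores <- function(scores, source = c("target", "distractor")) {
  source <- match.arg(source)
  stopifnot(is.data.frame(scores),
            all(c("subject", "source", "phase_deg", "cs") %in% names(scores)))
  d <- scores[scores$source == source, , drop = FALSE]
  if (nrow(d) == 0)
    stop(sprintf("no rows with source '%s'", source), call. = FALSE)
  phases <- c(0, 90, 180, 270)
  split_d <- split(d, d$subject)
  out <- do.call(rbind, lapply(split_d, function(ds) {
    if (!setequal(ds$phase_deg, phases) || nrow(ds) != 4)
      stop(sprintf("subject '%s' does not have exactly the four phases 0/90/180/270",
                   ds$subject[1]), call. = FALSE)
    ds <- ds[order(ds$phase_deg), ]
    cs_bar <- mean(ds$cs)
    data.frame(subject = ds$subject, phase_deg = ds$phase_deg,
               cs = ds$cs, cs_bar = cs_bar, dcs = ds$cs - cs_bar)
  }))
  rownames(out) <- NULL
  structure(out, class = c("centered_scores", "data.frame"),
            source = source, aligned = FALSE)
}

#' Discrete Fourier coefficients of a four-phase score profile
#'
#' Decomposes the centered score deviations at the four phases into the
#' discrete Fourier coefficients `a_k = (1/4) sum_n dcs(phi_n)
#' exp(-i k pi phi_n / 180)`, with `phi_n = n * 90` degrees. For real
#' scores, `a0` and `a2` are real and `a3 = Conj(a1)`. The harmonic-model
#' parameters follow as `A0 = a0`, `A1 = 2|a1|`, `A2 = a2` and
#' `phi1 = -Arg(a1)` (the sign convention under which
#' `dcs = A1 cos(phi - phi1)` holds).
#'
#' @param delta numeric length-4 vector of centered deviations, ordered by
#'   phase 0, 90, 180, 270 degrees.
#' @return A list of class `fourier_coefficients` with elements `a0`, `a1`,
#'   `a2`, `a3`, `A0`, `A1`, `A2`, `phi1_deg`, `B1`, `B2`.
#' @export
dft_coefficients <- function(delta) {
  check_finite_numeric(delta, "delta")
  if (length(delta) != 4)
    stop("`delta` must have exactly 4 values (phases 0/90/180/270)",
         call. = FALSE)
  a <- stats::fft(delta) / 4
  structure(list(
    a0 = Re(a[1]), a1 = a[2], a2 = Re(a[3]), a3 = a[4],
    A0 = Re(a[1]), A1 = 2 * Mod(a[2]), A2 = Re(a[3]),
    phi1_deg = if (Mod(a[2]) > 0) wrap_deg(-rad2deg(Arg(a[2]))) else 0,
    B1 = -2 * Im(a[2]), B2 = 2 * Re(a[2])),
    class = "fourier_coefficients")
}

#' Amplitude and phase of the 360-degree harmonic
#'
#' Converts the sine/cosine regression coefficients into the amplitude and
#' phase of the first harmonic: `A1 = sqrt(B1^2 + B2^2)` and
#' `phi1 = atan2(B1, B2)` (quadrant-correct, reduced to `[0, 360)`), so
#' that `B1 sin(phi) + B2 cos(phi) = A1 cos(phi - phi1)` identically.
#'
#' @param b1 coefficient of `sin(phi)`.
#' @param b2 coefficient of `cos(phi)`.
#' @return A list with `a1` (amplitude, same units as the coefficients) and
#'   `phi1_deg` (degrees in `[0, 360)`).
#' @export
amplitude_phase <- function(b1, b2) {
  stopifnot(is.finite(b1), is.finite(b2))
  a1 <- sqrt(b1^2 + b2^2)
  phi1 <- if (a1 > 0) wrap_deg(rad2deg(atan2(b1, b2))) else 0
  list(a1 = a1, phi1_deg = phi1)
}

# Weighted squared correlation between fitted and observed values. For the
# robust fit the final IRLS weights are used, so the fit quality is judged
# on the observations the estimator actually honors; with unit weights
# this reduces to the ordinary r^2, under which OLS is optimal by
# construction and no other estimator could ever score higher.
weighted_r2 <- function(fitted_vals, y, w = rep(1, length(y))) {
  sw <- sum(w)
  mx <- sum(w * fitted_vals) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (fitted_vals - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(1)
  (sum(w * (fitted_vals - mx) * (y - my)))^2 / (vx * vy)
}

harmonic_design <- function(phase_deg, aligned) {
  ph <- deg2rad(phase_deg)
  if (aligned) data.frame(sphi = sin(ph), cphi = cos(ph))
  else data.frame(sphi = sin(ph), cphi = cos(ph), c2phi = cos(2 * ph))
}

#' Fit the harmonic model of comprehension versus stimulation phase
#'
#' Fits `dcs = A0 + B1 sin(phi) + B2 cos(phi) + A2 cos(2 phi)` (the `A2`
#' term is dropped for best-phase-aligned data, which only has the three
#' relative phases 90/180/270) by pooled multiple linear regression over
#' all subject-by-phase observations. `method = "robust"` uses iteratively
#' reweighted least squares with Tukey's bisquare weights (tuning constant
#' 4.685, MAD scale, convergence `1e-8` or 200 iterations). Per-coefficient
#' p values are FDR-corrected (Benjamini-Hochberg) within the model.
#' The robust fit's `r^2` is the squared correlation between fitted and
#' observed values weighted by the final IRLS weights (see
#' [bootstrap_r2_compare()] for the rationale); for OLS it is the ordinary
#' coefficient of determination. The robust F statistic is derived from
#' that `r^2` through the usual identity.
#'
#' The derived first-harmonic amplitude `A1` and phase `phi1` are computed
#' with [amplitude_phase()]; the `A1` confidence interval uses a delta-method
#' standard error from the chosen coefficient covariance. `vcov = "model"`
#' uses the regression's own covariance (as in the classical analysis);
#' `vcov = "cluster"` uses a by-subject cluster-robust covariance
#' (recommended for inference on `A1`, because within-subject centering
#' correlates the residuals of a subject's four phases).
#'
#' @param centered a `centered_scores` data frame from [center_scores()] or
#'   [align_to_best_phase()].
#' @param method `"ols"` or `"robust"`.
#' @param aligned logical; `NULL` (default) takes the flag from `centered`.
#' @param vcov `"model"` or `"cluster"` (cluster is only available for
#'   `method = "ols"`).
#' @param conf_level confidence level for all intervals (default 0.95).
#' @return An object of class `harmonic_fit`: a list with a `coefficients`
#'   data frame (term, estimate, se, ci_lo, ci_hi, p_raw, p_fdr), the
#'   derived `a1`, `phi1_deg`, `a1_se`, `a1_ci`, fit statistics `r2`, `f`,
#'   `p_model`, and metadata.
#' @export
fit_harmonic <- function(centered, method = c("ols", "robust"),
                         aligned = NULL, vcov = c("model", "cluster"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  vcov <- match.arg(vcov)
  stopifnot(is.data.frame(centered),
            all(c("subject", "phase_deg", "dcs") %in% names(centered)))
  aligned <- aligned %||% isTRUE(attr(centered, "aligned"))
  subjects <- unique(centered$subject)
  if (length(subjects) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  X <- harmonic_design(centered$phase_deg, aligned)
  dat <- cbind(X, dcs = centered$dcs)
  terms <- if (aligned) c("A0", "B1", "B2") else c("A0", "B1", "B2", "A2")
  n <- nrow(dat)
  p <- length(terms)
  if (qr(cbind(1, as.matrix(X)))$rank < p)
    stop("rank-deficient design", call. = FALSE)

  if (method == "ols") {
    fit <- stats::lm(dcs ~ ., data = dat)
    est <- stats::coef(fit)
    if (vcov == "cluster") {
      V <- sandwich::vcovCL(fit, cluster = factor(centered$subject))
      df <- length(subjects) - 1
    } else {
      V <- suppressWarnings(stats::vcov(fit))
      df <- fit$df.residual
    }
    r2 <- suppressWarnings(summary(fit)$r.squared)
    fitted_vals <- stats::fitted(fit)
  } else {
    if (vcov == "cluster")
      stop("cluster covariance is only available for method = 'ols'",
           call. = FALSE)
    sd0 <- stats::sd(stats::residuals(stats::lm(dcs ~ ., data = dat)))
    if (sd0 < 1e-10) {
      # exact fit: IRLS weights are degenerate, OLS solution is the MLE
      fit <- stats::lm(dcs ~ ., data = dat)
      est <- stats::coef(fit)
      V <- suppressWarnings(stats::vcov(fit))
      irls_w <- rep(1, n)
    } else {
      fit <- MASS::rlm(dcs ~ ., data = dat, psi = MASS::psi.bisquare,
                       scale.est = "MAD", maxit = 200, acc = 1e-8)
      est <- stats::coef(fit)
      sm <- summary(fit)
      V <- diag(sm$coefficients[, "Std. Error"]^2, nrow = p)
      dimnames(V) <- list(names(est), names(est))
      irls_w <- fit$w
    }
    df <- n - p
    fitted_vals <- stats::fitted(fit)
    r2 <- weighted_r2(fitted_vals, dat$dcs, irls_w)
  }

  se <- sqrt(diag(V))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  tval <- est / se
  p_raw <- 2 * stats::pt(-abs(tval), df)
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  coefs <- data.frame(term = terms, estimate = unname(est),
                      se = unname(se),
                      ci_lo = unname(est - tq * se),
                      ci_hi = unname(est + tq * se),
                      p_raw = unname(p_raw), p_fdr = unname(p_fdr))

  b1 <- est[["sphi"]]; b2 <- est[["cphi"]]
  ap <- amplitude_phase(b1, b2)
  a1_se <- if (ap$a1 > 0) {
    g <- c(b1, b2) / ap$a1
    Vbb <- V[c("sphi", "cphi"), c("sphi", "cphi")]
    sqrt(drop(t(g) %*% Vbb %*% g))
  } else NA_real_
  a1_ci <- if (is.na(a1_se)) c(NA_real_, NA_real_)
           else c(ap$a1 - tq * a1_se, ap$a1 + tq * a1_se)

  f <- if (r2 < 1) r2 / (1 - r2) * (n - p) / (p - 1) else Inf
  p_model <- stats::pf(f, p - 1, n - p, lower.tail = FALSE)

  structure(list(
    coefficients = coefs, a1 = ap$a1, phi1_deg = ap$phi1_deg,
    a1_se = a1_se, a1_ci = a1_ci, r2 = r2, f = f, p_model = p_model,
    df_num = p - 1, df_den = n - p, method = method, aligned = aligned,
    vcov_type = vcov, conf_level = conf_level, n_obs = n,
    n_subjects = length(subjects), source = attr(centered, "source")),
    class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Harmonic fit (%s%s)%s: %d subjects, %d observations\n",
              x$method, if (x$vcov_type == "cluster") ", cluster vcov" else "",
              if (x$aligned) ", best-phase aligned" else "",
              x$n_subjects, x$n_obs))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, digits)
  tab$ci <- sprintf("[%s, %s]", signif(tab$ci_lo, digits),
                    signif(tab$ci_hi, digits))
  tab$p_fdr <- signif(tab$p_fdr, 2)
  print(tab[, c("term", "estimate", "ci", "p_fdr")], row.names = FALSE)
  cat(sprintf("A1 = %s%%, phi1 = %s deg;  F = %s, p = %s, r2 = %s\n",
              signif(x$a1, digits), signif(x$phi1_deg, digits),
              signif(x$f, digits), signif(x$p_model, 2), signif(x$r2, digits)))
  invisible(x)
}

#' Align scores to each subject's best phase
#'
#' For each subject, finds the phase with the highest comprehension score
#' (ties broken toward the lowest phase) and re-indexes the remaining three
#' phases relative to it (`(phase - best) mod 360`). The deviations `dcs`
#' keep their values from the four-phase centering; only the phase labels
#' change and the best phase itself is removed. The resulting data feed the
#' three-parameter aligned model (no 180-degree term).
#'
#' @inheritParams center_scores
#' @return A `centered_scores` data frame with relative phases 90/180/270,
#'   attribute `aligned = TRUE`, a `best_phases` attribute (named vector of
#'   each subject's best phase) and an `n_ties` attribute.
#' @export
align_to_best_phase <- function(scores, source = c("target", "distractor")) {
  source <- match.arg(source)
  centered <- center_scores(scores, source)
  n_ties <- 0L
  best <- numeric(0)
  out <- do.call(rbind, lapply(split(centered, centered$subject),
                               function(ds) {
    ds <- ds[order(ds$phase_deg), ]
    mx <- max(ds$cs)
    idx <- which(ds$cs == mx)
    if (length(idx) > 1) n_ties <<- n_ties + 1L
    b <- ds$phase_deg[idx[1]]
    best[as.character(ds$subject[1])] <<- b
    keep <- ds[ds$phase_deg != b, , drop = FALSE]
    keep$phase_deg <- wrap_deg(keep$phase_deg - b)
    keep[order(keep$phase_deg), ]
  }))
  rownames(out) <- NULL
  structure(out, class = c("centered_scores", "data.frame"),
            source = source, aligned = TRUE, best_phases = best,
            n_ties = n_ties)
}

refit_r2_pair <- function(X1, y, subj_rows, boot_subjects, r2_method) {
  rows <- unlist(subj_rows[boot_subjects], use.names = FALSE)
  Xb <- X1[rows, , drop = FALSE]
  yb <- y[rows]
  ols <- stats::lm.fit(Xb, yb)
  if (ols$rank < ncol(Xb)) return(NULL)
  fit_ols <- drop(Xb %*% ols$coefficients)
  r2_ols <- weighted_r2(fit_ols, yb)
  res_sd <- stats::sd(yb - fit_ols)
  if (res_sd < 1e-10) {
    r2_rob <- r2_ols
  } else {
    rob <- tryCatch(
      suppressWarnings(
        MASS::rlm(Xb, yb, psi = MASS::psi.bisquare, scale.est = "MAD",
                  maxit = 200, acc = 1e-8)),
      error = function(e) NULL)
    if (is.null(rob)) return(NULL)
    fit_rob <- drop(Xb %*% stats::coef(rob))
    w <- if (r2_method == "weighted") rob$w else rep(1, length(yb))
    r2_rob <- weighted_r2(fit_rob, yb, w)
  }
  c(r2_ols, r2_rob)
}

#' Bootstrap comparison of standard and robust regression fits
#'
#' Draws bootstrap samples (by default resampling whole subjects with
#' replacement, preserving each subject's phase block), fits the harmonic
#' model by both ordinary and robust regression on every sample, records
#' the two `r^2` values, and compares them with a paired one-tailed
#' Student's t test for robust > standard. Degenerate resamples
#' (rank-deficient or failed IRLS) are skipped and counted.
#'
#' @param centered a `centered_scores` data frame.
#' @param n_boot number of bootstrap samples (the classical analysis used
#'   10,000).
#' @param seed integer seed; the result is reproducible given the seed.
#' @param unit resampling unit: `"subject"` (default) or `"row"`.
#' @param r2_method how the robust fit's `r^2` is computed: `"weighted"`
#'   (default) is the squared correlation between fitted and observed
#'   values weighted by the final IRLS weights, so outliers the robust
#'   estimator rejects do not count against its fit quality;
#'   `"correlation"` is the unweighted squared correlation, under which
#'   ordinary least squares is optimal by construction and can never be
#'   outperformed. The OLS `r^2` is always unweighted.
#' @return A list of class `bootstrap_r2` with per-sample `r2_ols`,
#'   `r2_robust`, the one-tailed `p`, `t`, `n_skipped` and `seed`.
#' @export
bootstrap_r2_compare <- function(centered, n_boot = 10000, seed = NULL,
                                 unit = c("subject", "row"),
                                 r2_method = c("weighted", "correlation")) {
  unit <- match.arg(unit)
  r2_method <- match.arg(r2_method)
  stopifnot(is.data.frame(centered), n_boot >= 2)
  aligned <- isTRUE(attr(centered, "aligned"))
  X <- as.matrix(harmonic_design(centered$phase_deg, aligned))
  X1 <- cbind(`(Intercept)` = 1, X)
  y <- centered$dcs
  subj <- as.character(centered$subject)
  subj_rows <- if (unit == "subject") split(seq_along(y), subj)
               else as.list(seq_along(y))
  n_units <- length(subj_rows)
  if (n_units < 2) stop("need at least 2 resampling units", call. = FALSE)
  res <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      pick <- sample.int(n_units, n_units, replace = TRUE)
      rr <- refit_r2_pair(X1, y, subj_rows, pick, r2_method)
      if (!is.null(rr)) out[b, ] <- rr
    }
    out
  })
  ok <- stats::complete.cases(res)
  r2_ols <- res[ok, 1]; r2_rob <- res[ok, 2]
  d <- r2_rob - r2_ols
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = if (mean(d) > 0) Inf else 0),
               p.value = if (mean(d) > 0) 0 else 1)
  } else {
    tt <- stats::t.test(r2_rob, r2_ols, paired = TRUE,
                        alternative = "greater")
  }
  structure(list(r2_ols = r2_ols, r2_robust = r2_rob,
                 t = unname(tt$statistic), p = tt$p.value,
                 n_boot = n_boot, n_skipped = sum(!ok), unit = unit,
                 seed = seed),
            class = "bootstrap_r2")
}

#' @export
print.bootstrap_r2 <- function(x, ...) {
  cat(sprintf("Bootstrap r2 comparison (%d samples, unit = %s): mean r2 ols = %.3f, robust = %.3f, one-tailed p = %.3g\n",
              length(x$r2_ols), x$unit, mean(x$r2_ols), mean(x$r2_robust),
              x$p))
  invisible(x)
}

#' Compare first-harmonic amplitudes between two stimulation sources
#'
#' Tests whether the modulation amplitude `A1` differs between two sources
#' (e.g. target-envelope versus distractor-envelope stimulation) fitted on
#' the same cohort. Subjects are resampled jointly for both sources (paired
#' bootstrap); the two-tailed p value comes from a normal approximation
#' using the bootstrap standard error of the amplitude difference. If the
#' difference is exactly degenerate (identical data), `p = 1`.
#'
#' @param scores cohort scores data frame containing both sources.
#' @param source_a,source_b the two sources to compare.
#' @param method regression method used for the amplitude estimates
#'   (default `"robust"`, as in the headline comparison).
#' @param n_boot number of paired bootstrap samples.
#' @param seed integer seed.
#' @return A list of class `amplitude_comparison` with the observed
#'   amplitudes, their difference, bootstrap SE and two-tailed `p`.
#' @export
compare_amplitudes <- function(scores, source_a = "target",
                               source_b = "distractor",
                               method = c("robust", "ols"),
                               n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  ca <- center_scores(scores, source_a)
  cb <- center_scores(scores, source_b)
  subj_a <- sort(unique(ca$subject)); subj_b <- sort(unique(cb$subject))
  if (!identical(as.character(subj_a), as.character(subj_b)))
    stop("the two sources must cover the same subjects (paired design)",
         call. = FALSE)
  fit_a <- fit_harmonic(ca, method = method)
  fit_b <- fit_harmonic(cb, method = method)
  obs_diff <- fit_a$a1 - fit_b$a1

  a1_of <- function(centered, pick, subj_rows, X1) {
    rows <- unlist(subj_rows[pick], use.names = FALSE)
    Xb <- X1[rows, , drop = FALSE]; yb <- centered$dcs[rows]
    cf <- if (method == "ols" ||
              stats::sd(stats::lm.fit(Xb, yb)$residuals) < 1e-10) {
      stats::lm.fit(Xb, yb)$coefficients
    } else {
      stats::coef(suppressWarnings(
        MASS::rlm(Xb, yb, psi = MASS::psi.bisquare, scale.est = "MAD",
                  maxit = 200, acc = 1e-8)))
    }
    sqrt(cf[["sphi"]]^2 + cf[["cphi"]]^2)
  }
  Xa <- cbind(1, as.matrix(harmonic_design(ca$phase_deg, FALSE)))
  Xb <- cbind(1, as.matrix(harmonic_design(cb$phase_deg, FALSE)))
  colnames(Xa) <- colnames(Xb) <- c("(Intercept)", "sphi", "cphi", "c2phi")
  rows_a <- split(seq_len(nrow(ca)), as.character(ca$subject))
  rows_b <- split(seq_len(nrow(cb)), as.character(cb$subject))
  rows_b <- rows_b[names(rows_a)]
  n_s <- length(rows_a)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(n_s, n_s, replace = TRUE)
      tryCatch(a1_of(ca, pick, rows_a, Xa) - a1_of(cb, pick, rows_b, Xb),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  diffs <- diffs[is.finite(diffs)]
  se <- stats::sd(diffs)
  p <- if (se == 0) {
    if (abs(obs_diff) < 1e-12) 1 else 0
  } else {
    2 * stats::pnorm(-abs(obs_diff) / se)
  }
  structure(list(a1_a = fit_a$a1, a1_b = fit_b$a1, diff = obs_diff,
                 se_boot = se, p = p, method = method,
                 n_boot = length(diffs), seed = seed,
                 source_a = source_a, source_b = source_b),
            class = "amplitude_comparison")
}

#' @export
print.amplitude_comparison <- function(x, ...) {
  cat(sprintf("A1 %s = %.2f%%, %s = %.2f%%, diff = %.2f%% (boot SE %.2f), two-tailed p = %.3g\n",
              x$source_a, x$a1_a, x$source_b, x$a1_b, x$diff, x$se_boot,
              x$p))
  invisible(x)
}

#' Compare best-phase stimulation conditions to sham
#'
#' One-way ANOVA of the comprehension scores in three conditions on the
#' same subjects: target-envelope stimulation at its best phase, distractor
#' envelope at its best phase, and sham.
#'
#' @param scores cohort scores data frame containing `target`,
#'   `distractor` and `sham` rows.
#' @param target_phase,distractor_phase the best phases to extract
#'   (defaults 0 and 180 degrees).
#' @return A list of class `sham_anova` with `f`, `df`, `df_resid`, `p`
#'   and the three group means.
#' @export
compare_to_sham <- function(scores, target_phase = 0,
                            distractor_phase = 180) {
  stopifnot(is.data.frame(scores))
  grab <- function(src, ph) {
    d <- scores[scores$source == src &
                  (is.na(ph) | scores$phase_deg %in% ph), , drop = FALSE]
    d[order(as.character(d$subject)), c("subject", "cs")]
  }
  tg <- grab("target", target_phase)
  ds <- grab("distractor", distractor_phase)
  sh <- scores[scores$source == "sham", , drop = FALSE]
  sh <- sh[order(as.character(sh$subject)), c("subject", "cs")]
  if (nrow(tg) == 0 || nrow(ds) == 0 || nrow(sh) == 0)
    stop("need target, distractor and sham scores", call. = FALSE)
  if (!(identical(as.character(tg$subject), as.character(sh$subject)) &&
        identical(as.character(ds$subject), as.character(sh$subject))))
    stop("unequal or mismatched groups: the design is paired by subject",
         call. = FALSE)
  df <- data.frame(
    cs = c(tg$cs, ds$cs, sh$cs),
    group = factor(rep(c("target_best", "distractor_best", "sham"),
                       each = nrow(sh))))
  av <- summary(stats::aov(cs ~ group, data = df))[[1]]
  structure(list(f = av[1, "F value"], df = av[1, "Df"],
                 df_resid = av[2, "Df"], p = av[1, "Pr(>F)"],
                 group_means = tapply(df$cs, df$group, mean)),
            class = "sham_anova")
}

#' @export
print.sham_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA vs sham: F(%d, %d) = %.3g, p = %.3g\n",
              x$df, x$df_resid, x$f, x$p))
  invisible(x)
}
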