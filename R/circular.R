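# Circular statistics for per-subject best stimulation phases: summary
# statistics, the Rayleigh uniformity test, maximum-likelihood von Mises
# fitting with a Watson U2 goodness-of-fit test, and a two-sample
# concentration homogeneity test. Angles are degrees at the interface and
# radians internally.

#' Best stimulation phase per subject
#'
#' For each subject, the phase shift (0/90/180/270 degrees) with the
#' highest comprehension score for the given source. Ties are broken
#' toward the lowest phase.
#'
#' @inheritParams center_scores
#' @return A named numeric vector of class `phase_sample` (degrees, one
#'   entry per subject), with an `n_ties` attribute.
#' @export
best_phase_per_subject <- function(scores, source = c("target",
                                                      "distractor")) {
  source <- match.arg(source)
  centered <- center_scores(scores, source)
  n_ties <- 0L
  best <- vapply(split(centered, centered$subject), function(ds) {
    ds <- ds[order(ds$phase_deg), ]
    idx <- which(ds$cs == max(ds$cs))
    if (length(idx) > 1) n_ties <<- n_ties + 1L
    ds$phase_deg[idx[1]]
  }, numeric(1))
  structure(wrap_deg(best), class = "phase_sample", n_ties = n_ties)
}

#' Circular summary statistics
#'
#' Mean direction, resultant vector length and angular deviation of a
#' sample of angles. The mean direction is the angle of the mean unit
#' vector, `R` its length, and the angular deviation is
#' `sqrt(2 (1 - R))` in radians (0 for perfect concentration, `sqrt(2)`
#' for a balanced sample).
#'
#' @param angles_deg numeric vector of angles in degrees (reduced mod 360).
#' @return A list of class `circular_summary` with `mean_deg`, `R`,
#'   `ang_dev_rad` and `n`.
#' @export
circular_summary <- function(angles_deg) {
  check_finite_numeric(angles_deg, "angles_deg")
  th <- deg2rad(wrap_deg(angles_deg))
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mean_deg <- if (R > .Machine$double.eps) wrap_deg(rad2deg(atan2(S, C)))
              else NA_real_
  structure(list(mean_deg = mean_deg, R = R,
                 ang_dev_rad = sqrt(2 * (1 - R)), n = length(th)),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Circular summary (n = %d): mean = %.1f deg, R = %.3f, angular deviation = %.3f rad\n",
              x$n, x$mean_deg, x$R, x$ang_dev_rad))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis of a uniform circular distribution using the
#' statistic `Z = n R^2` with the standard finite-sample correction
#' `p = exp(-Z) [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4) /
#' (288 n^2)]`. For very small samples (`n < 4`), where the asymptotic
#' correction is unreliable, a Monte-Carlo p value is substituted with a
#' warning.
#'
#' @param angles_deg angles in degrees.
#' @param n_mc Monte-Carlo draws for the small-sample fallback.
#' @param seed seed for the fallback.
#' @return A list of class `rayleigh_test` with `R`, `z` and `p`.
#' @export
rayleigh_test <- function(angles_deg, n_mc = 100000, seed = NULL) {
  cs <- circular_summary(angles_deg)
  n <- cs$n
  z <- n * cs$R^2
  if (n < 4) {
    warning("n < 4: using Monte-Carlo null for the Rayleigh test")
    p <- with_seed(seed, {
      r_null <- vapply(seq_len(n_mc), function(i) {
        th <- stats::runif(n, 0, 2 * pi)
        sqrt(mean(cos(th))^2 + mean(sin(th))^2)
      }, numeric(1))
      (1 + sum(r_null >= cs$R)) / (n_mc + 1)
    })
  } else {
    p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                      (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) /
                        (288 * n^2))
    p <- min(max(p, 0), 1)
  }
  structure(list(R = cs$R, z = z, n = n, p = p), class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, R = %.3f, Z = %.3f, p = %.3g\n",
              x$n, x$R, x$z, x$p))
  invisible(x)
}

# Ratio of modified Bessel functions A(kappa) = I1(kappa)/I0(kappa),
# the mean resultant length of a von Mises distribution.
bessel_ratio <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# Invert A(kappa) = R by bisection/uniroot; exact to ~1e-10.
kappa_from_R <- function(R, kappa_max = 1e3) {
  if (R <= 0) return(0)
  if (bessel_ratio(kappa_max) <= R) return(kappa_max)
  stats::uniroot(function(k) bessel_ratio(k) - R, c(1e-12, kappa_max),
                 tol = 1e-12)$root
}

# von Mises density and CDF (CDF by cumulative trapezoid on a fine grid,
# measured from mu - pi).
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

pvonmises <- function(theta, mu, kappa, n_grid = 4096) {
  x <- (theta - mu + pi) %% (2 * pi)  # position in [0, 2pi) from mu - pi
  grid <- seq(0, 2 * pi, length.out = n_grid)
  dens <- dvonmises(grid + mu - pi, mu, kappa)
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(grid)))
  cdf <- cdf / cdf[n_grid]
  stats::approx(grid, cdf, xout = x, rule = 2)$y
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to the uniform
#' distribution.
#'
#' @param n number of draws.
#' @param mu_deg location in degrees.
#' @param kappa concentration (>= 0).
#' @param seed integer seed.
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa, seed = NULL) {
  stopifnot(n >= 1, kappa >= 0)
  mu <- deg2rad(mu_deg)
  with_seed(seed, {
    if (kappa == 0) return(wrap_deg(rad2deg(stats::runif(n, 0, 2 * pi))))
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u <- stats::runif(3)
        z <- cos(pi * u[1])
        f <- (1 + r * z) / (r + z)
        c_ <- kappa * (r - f)
        if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
          out[i] <- mu + sign(u[3] - 0.5) * acos(f)
          break
        }
      }
    }
    wrap_deg(rad2deg(out))
  })
}

# Watson's U2 statistic for probability-integral-transformed values u.
watson_u2_stat <- function(u) {
  n <- length(u)
  u <- sort(u)
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

#' Fit a von Mises distribution with a Watson goodness-of-fit test
#'
#' Maximum-likelihood fit: the location `mu` is the circular mean and the
#' concentration `kappa` solves `A(kappa) = R` (ratio of modified Bessel
#' functions, inverted numerically to `1e-10`). Goodness of fit is
#' assessed with Watson's one-sample U2 statistic on the fitted
#' distribution's probability integral transform; because the parameters
#' are estimated, the null distribution of U2 is obtained by a parametric
#' bootstrap that refits on every simulated sample.
#'
#' With samples concentrated at `R = 1` (all angles identical), `kappa` is
#' capped and flagged.
#'
#' @param angles_deg angles in degrees (n >= 4).
#' @param n_sim parametric-bootstrap samples for the Watson p value; set
#'   to 0 to skip the test.
#' @param seed integer seed for the bootstrap.
#' @param kappa_max cap for the concentration estimate.
#' @return A list of class `von_mises_fit` with `mu_deg`, `kappa`, `R`,
#'   `watson_u2`, `watson_p`, `kappa_capped` and `n`.
#' @export
fit_von_mises <- function(angles_deg, n_sim = 999, seed = NULL,
                          kappa_max = 1e3) {
  check_finite_numeric(angles_deg, "angles_deg")
  if (length(angles_deg) < 4)
    stop("need at least 4 angles to fit a von Mises distribution",
         call. = FALSE)
  cs <- circular_summary(angles_deg)
  kappa <- kappa_from_R(cs$R, kappa_max)
  capped <- cs$R >= bessel_ratio(kappa_max)
  mu <- cs$mean_deg %||% 0
  if (is.na(mu)) mu <- 0
  u2 <- watson_u2_stat(pvonmises(deg2rad(angles_deg), deg2rad(mu), kappa))
  p <- NA_real_
  if (n_sim > 0 && !capped) {
    n <- length(angles_deg)
    u2_null <- with_seed(seed, {
      vapply(seq_len(n_sim), function(b) {
        th <- rvonmises_deg(n, mu, kappa)
        cs_b <- circular_summary(th)
        mu_b <- if (is.na(cs_b$mean_deg)) 0 else cs_b$mean_deg
        k_b <- kappa_from_R(cs_b$R, kappa_max)
        watson_u2_stat(pvonmises(deg2rad(th), deg2rad(mu_b), k_b))
      }, numeric(1))
    })
    p <- (1 + sum(u2_null >= u2)) / (n_sim + 1)
  }
  structure(list(mu_deg = mu, kappa = kappa, R = cs$R, watson_u2 = u2,
                 watson_p = p, kappa_capped = capped,
                 n = length(angles_deg)),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf("von Mises fit (n = %d): mu = %.1f deg, kappa = %.3f%s, Watson U2 = %.4f, p = %.3g\n",
              x$n, x$mu_deg, x$kappa,
              if (x$kappa_capped) " (capped)" else "", x$watson_u2,
              x$watson_p))
  invisible(x)
}

#' Two-sample concentration homogeneity test
#'
#' Permutation test of equal concentration for two circular samples. Each
#' sample is first rotated to a common mean direction (removing location
#' differences); the statistic is the larger ratio of the two sample
#' circular variances (`1 - R`), and the null distribution is generated by
#' permuting the pooled, centered angles between groups.
#'
#' @param angles_a_deg,angles_b_deg the two samples, in degrees.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A list of class `concentration_test` with the observed variance
#'   ratio, per-sample `R`, and the permutation `p`.
#' @export
concentration_homogeneity <- function(angles_a_deg, angles_b_deg,
                                      n_perm = 1999, seed = NULL) {
  check_finite_numeric(angles_a_deg, "angles_a_deg")
  check_finite_numeric(angles_b_deg, "angles_b_deg")
  center <- function(a) {
    cs <- circular_summary(a)
    m <- if (is.na(cs$mean_deg)) 0 else cs$mean_deg
    wrap_deg(a - m)
  }
  circ_var <- function(a) 1 - circular_summary(a)$R
  a <- center(angles_a_deg); b <- center(angles_b_deg)
  na <- length(a); nb <- length(b)
  ratio <- function(x, y) {
    vx <- circ_var(x); vy <- circ_var(y)
    if (vx == 0 && vy == 0) return(1)
    if (vx == 0 || vy == 0) return(Inf)
    max(vx / vy, vy / vx)
  }
  obs <- ratio(a, b)
  pool <- c(a, b)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(na + nb, na)
      ratio(pool[idx], pool[-idx])
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  structure(list(ratio = obs, R_a = circular_summary(angles_a_deg)$R,
                 R_b = circular_summary(angles_b_deg)$R, p = p,
                 n_perm = n_perm, seed = seed),
            class = "concentration_test")
}

#' @export
print.concentration_test <- function(x, ...) {
  cat(sprintf("Concentration homogeneity (permutation): R = %.3f vs %.3f, variance ratio = %.3f, p = %.3g\n",
              x$R_a, x$R_b, x$ratio, x$p))
  invisible(x)
}
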