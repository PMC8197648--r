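# Mean-centering, Fourier decomposition, harmonic regression (standard
# and robust), amplitude/phase extraction, best-phase alignment, bootstrap
# model comparison and the group-level tests.

test_that("centering removes each subject's mean across the four phases", {
  cen <- center_scores(tiny_scores(), "target")
  a <- cen[cen$subject == "a", ]
  expect_equal(a$cs_bar, rep(50, 4))
  expect_equal(a$dcs, c(0, 5, -2, -3))

  cen2 <- center_scores(tiny_scores(cs_a = rep(50, 4)), "target")
  expect_equal(cen2$dcs[cen2$subject == "a"], rep(0, 4))

  # per-subject deviations always sum to zero
  sc <- generate_cohort(seed = 3)
  cen3 <- center_scores(sc, "distractor")
  expect_lt(max(abs(tapply(cen3$dcs, cen3$subject, sum))), 1e-10)

  # missing phase -> incomplete design
  broken <- tiny_scores()[-2, ]
  expect_error(center_scores(broken, "target"), "four phases")
})

test_that("discrete Fourier coefficients match the closed-form examples", {
  d <- dft_coefficients(c(3, 0, -3, 0))
  expect_equal(d$a0, 0)
  expect_equal(d$a1, complex(real = 1.5, imaginary = 0))
  expect_equal(d$a2, 0)
  expect_equal(d$A1, 3)
  expect_equal(d$phi1_deg, 0)

  expect_equal(unclass(dft_coefficients(rep(0, 4)))[c("a0", "A1", "A2")],
               list(a0 = 0, A1 = 0, A2 = 0))

  d2 <- dft_coefficients(c(1, 2, -1, -2))
  expect_equal(d2$a1, complex(real = 0.5, imaginary = -1))
  expect_equal(d2$a2, 0)
  expect_equal(d2$A1, 2 * Mod(d2$a1))
  expect_equal(d2$B1, 2)
  expect_equal(d2$B2, 1)
  # conjugate symmetry for real input
  expect_equal(d2$a3, Conj(d2$a1))

  # the inverse relation reproduces the input
  delta <- c(2.5, -1, 0.5, -2)
  dd <- dft_coefficients(delta)
  phases <- c(0, 90, 180, 270)
  recon <- dd$A0 + dd$A1 * cos(pi / 180 * (phases - dd$phi1_deg)) +
    dd$A2 * cos(2 * pi / 180 * phases)
  expect_equal(recon, delta)

  expect_error(dft_coefficients(1:3), "exactly 4")
})

test_that("amplitude/phase mapping reproduces the sine-cosine expansion", {
  expect_equal(amplitude_phase(0, 3), list(a1 = 3, phi1_deg = 0))
  expect_equal(amplitude_phase(0, -1.6), list(a1 = 1.6, phi1_deg = 180))
  ap <- amplitude_phase(2, 1)
  expect_equal(ap$a1, sqrt(5))
  expect_equal(ap$phi1_deg, 180 / pi * atan2(2, 1))
  # A1 cos(phi - phi1) interpolates (1, 2, -1, -2) at the four phases
  phases <- c(0, 90, 180, 270)
  expect_equal(ap$a1 * cos(pi / 180 * (phases - ap$phi1_deg)),
               c(1, 2, -1, -2))
})

test_that("harmonic regression recovers noiseless cohorts exactly", {
  # pure 360-degree cosine
  f <- fit_harmonic(center_scores(noiseless_cohort(c(3, 0, -3, 0)),
                                  "target"), "ols")
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(est, c(A0 = 0, B1 = 0, B2 = 3, A2 = 0), tolerance = 1e-10)
  expect_equal(f$r2, 1)
  expect_equal(f$a1, 3)
  expect_equal(f$phi1_deg, 0)

  # mixed profile, matches the DFT mapping
  f2 <- fit_harmonic(center_scores(noiseless_cohort(c(1, 2, -1, -2)),
                                   "target"), "ols")
  est2 <- setNames(f2$coefficients$estimate, f2$coefficients$term)
  expect_equal(est2, c(A0 = 0, B1 = 2, B2 = 1, A2 = 0), tolerance = 1e-10)

  # robust on an exact fit agrees
  f3 <- fit_harmonic(center_scores(noiseless_cohort(c(1, 2, -1, -2)),
                                   "target"), "robust")
  expect_equal(f3$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("OLS coefficients equal the DFT of per-phase mean deviations", {
  for (seed in 1:10) {
    sc <- generate_cohort(n_subjects = 10, seed = seed)
    cen <- center_scores(sc, "target")
    f <- fit_harmonic(cen, "ols")
    m <- tapply(cen$dcs, cen$phase_deg, mean)[c("0", "90", "180", "270")]
    d <- dft_coefficients(as.numeric(m))
    est <- setNames(f$coefficients$estimate, f$coefficients$term)
    expect_equal(est[["A0"]], d$a0, tolerance = 1e-10)
    expect_equal(est[["B1"]], -2 * Im(d$a1), tolerance = 1e-10)
    expect_equal(est[["B2"]], 2 * Re(d$a1), tolerance = 1e-10)
    expect_equal(est[["A2"]], d$a2, tolerance = 1e-10)
  }
})

test_that("a single subject's four-parameter fit interpolates exactly", {
  one <- data.frame(subject = rep(c("a", "b"), each = 4), source = "target",
                    phase_deg = rep(c(0, 90, 180, 270), 2), n_keywords = 130,
                    n_correct = NA, cs = 50 + c(2, -1, 1, -2, 2, -1, 1, -2))
  f <- fit_harmonic(center_scores(one, "target"), "ols")
  expect_equal(f$r2, 1)
  ph <- pi / 180 * c(0, 90, 180, 270)
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  fitted_vals <- est[["A0"]] + est[["B1"]] * sin(ph) +
    est[["B2"]] * cos(ph) + est[["A2"]] * cos(2 * ph)
  expect_equal(unname(fitted_vals), c(2, -1, 1, -2), tolerance = 1e-10)
})

test_that("intercept vanishes on centered balanced cohorts and FDR is monotone", {
  sc <- generate_cohort(seed = 21)
  f <- fit_harmonic(center_scores(sc, "target"), "ols")
  tb <- f$coefficients
  expect_lt(abs(tb$estimate[tb$term == "A0"]), 1e-10)
  expect_true(all(tb$p_fdr >= tb$p_raw))
  # monotone: sorted by raw p, the adjusted values never decrease
  expect_true(all(diff(tb$p_fdr[order(tb$p_raw)]) >= -1e-15))
})

test_that("robust and OLS agree on outlier-free Gaussian data", {
  set.seed(31)
  sc <- do.call(rbind, lapply(1:18, function(s) {
    data.frame(subject = sprintf("S%02d", s), source = "target",
               phase_deg = c(0, 90, 180, 270), n_keywords = 130,
               n_correct = NA,
               cs = 50 + 3 * cospi(c(0, 90, 180, 270) / 180) + rnorm(4, 0, 2))
  }))
  cen <- center_scores(sc, "target")
  fo <- fit_harmonic(cen, "ols")
  fr <- fit_harmonic(cen, "robust")
  expect_lt(max(abs(fo$coefficients$estimate - fr$coefficients$estimate)),
            0.1)
})

test_that("best-phase alignment re-indexes phases and preserves deviations", {
  al <- align_to_best_phase(tiny_scores(), "target")
  a <- al[al$subject == "a", ]
  expect_equal(a$phase_deg, c(90, 180, 270))
  expect_equal(a$dcs, c(-2, -3, 0))
  expect_equal(unname(attr(al, "best_phases")["a"]), 90)

  # flat scores: tie broken to 0 degrees
  alf <- align_to_best_phase(tiny_scores(cs_a = rep(50, 4)), "target")
  expect_equal(unname(attr(alf, "best_phases")["a"]), 0)
  expect_equal(attr(alf, "n_ties"), 2L)

  # phase-locked cohort: every subject peaks at its own phase with a
  # common shape; the aligned fit recovers it exactly
  shape <- c(4, 1, -2, -3)  # relative phases 0, 90, 180, 270
  sc <- do.call(rbind, lapply(1:8, function(s) {
    best <- c(0, 90, 180, 270)[(s %% 4) + 1]
    ph <- c(0, 90, 180, 270)
    rel <- ((ph - best) %% 360) / 90 + 1
    data.frame(subject = sprintf("S%02d", s), source = "target",
               phase_deg = ph, n_keywords = 130, n_correct = NA,
               cs = 50 + shape[rel])
  }))
  fa <- fit_harmonic(align_to_best_phase(sc, "target"))
  expect_equal(fa$r2, 1, tolerance = 1e-10)
})

test_that("per-subject best phases follow the argmax with low-phase ties", {
  bp <- best_phase_per_subject(tiny_scores(), "target")
  expect_equal(unname(bp["a"]), 90)
  # strong modulation, little noise: the best-phase histogram peaks at
  # the true phase
  sc <- generate_cohort(seed = 8, n_sentences = 2000, subject_sd = 1,
                        a1_true = c(target = 3, distractor = 3),
                        phi1_true_deg = c(target = 0, distractor = 180))
  bp2 <- best_phase_per_subject(sc, "distractor")
  tab <- table(factor(bp2, levels = c(0, 90, 180, 270)))
  expect_equal(names(which.max(tab)), "180")
  expect_gt(tab[["180"]], 14)
})

test_that("bootstrap r2 comparison is seeded and favors robust under outliers", {
  sc <- generate_cohort(seed = 41)
  cen <- center_scores(sc, "target")
  set.seed(42)
  idx <- sample(nrow(cen), round(0.1 * nrow(cen)))
  cen$dcs[idx] <- cen$dcs[idx] + sample(c(-30, 30), length(idx),
                                        replace = TRUE)
  b1 <- bootstrap_r2_compare(cen, n_boot = 300, seed = 7)
  b2 <- bootstrap_r2_compare(cen, n_boot = 300, seed = 7)
  expect_identical(b1$p, b2$p)
  expect_lt(b1$p, 0.01)
  expect_gt(mean(b1$r2_robust), mean(b1$r2_ols))

  # outlier-free data under the unweighted-correlation definition:
  # the two r2 distributions nearly coincide and OLS is optimal, so the
  # one-tailed p for robust > standard is not extreme
  cen0 <- center_scores(generate_cohort(seed = 43), "target")
  b0 <- bootstrap_r2_compare(cen0, n_boot = 300, seed = 9,
                             r2_method = "correlation")
  expect_gt(b0$p, 0.001)
  expect_lt(mean(abs(b0$r2_robust - b0$r2_ols)), 0.05)
  # the weighted definition's systematic advantage on clean data is small
  bw <- bootstrap_r2_compare(cen0, n_boot = 300, seed = 9)
  expect_lt(mean(bw$r2_robust - bw$r2_ols), 0.1)
})

test_that("amplitude comparison is degenerate-safe and recovers true differences", {
  sc <- generate_cohort(seed = 51)
  # identical data in both slots -> zero difference, p = 1
  dup <- sc
  dup$source[dup$source == "distractor"] <- "tmp"
  tg <- sc[sc$source == "target", ]
  tg$source <- "distractor"
  same <- rbind(sc[sc$source == "target", ], tg)
  cmp0 <- compare_amplitudes(same, n_boot = 100, seed = 5)
  expect_equal(cmp0$diff, 0)
  expect_equal(cmp0$p, 1)

  # known truth: difference estimate within 2 bootstrap SE of 1.4 points
  cmp <- compare_amplitudes(sc, n_boot = 400, seed = 6)
  expect_lt(abs(cmp$diff - 1.4), 2 * cmp$se_boot)
})

test_that("sham ANOVA behaves at the extremes and errors on broken designs", {
  sc <- generate_cohort(seed = 61, subject_sd = 0)
  res <- compare_to_sham(sc)
  expect_equal(res$df, 2)
  expect_true(res$p >= 0 && res$p <= 1)

  # identical groups -> F ~ 0
  base <- data.frame(subject = sprintf("S%02d", 1:10), cs = rep(50, 10))
  sc0 <- rbind(
    transform(base, source = "target", phase_deg = 0),
    transform(base, source = "distractor", phase_deg = 180),
    transform(base, source = "sham", phase_deg = NA))
  sc0$cs <- sc0$cs + rep(rnorm(10, 0, 1e-8), 3)
  expect_lt(compare_to_sham(sc0)$f, 1e-6)

  # strong separation -> tiny p
  sc1 <- sc0
  sc1$cs[sc1$source == "sham"] <- 70 + rnorm(10, 0, 0.1)
  sc1$cs[sc1$source != "sham"] <- 50 + rnorm(20, 0, 0.1)
  expect_lt(compare_to_sham(sc1)$p, 1e-6)

  # mismatched subjects -> paired-design error
  broken <- sc0[-1, ]
  expect_error(compare_to_sham(broken), "paired")
})
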