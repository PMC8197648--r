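# Circular summaries, Rayleigh uniformity test, von Mises fitting with
# Watson goodness of fit, and the concentration homogeneity test.

test_that("circular summary matches closed forms and is rotation-equivariant", {
  s1 <- circular_summary(rep(90, 12))
  expect_equal(s1$mean_deg, 90)
  expect_equal(s1$R, 1)
  expect_equal(s1$ang_dev_rad, 0)

  s2 <- circular_summary(c(0, 90, 180, 270))
  expect_equal(s2$R, 0, tolerance = 1e-12)
  expect_equal(s2$ang_dev_rad, sqrt(2), tolerance = 1e-6)

  # angular deviation from the resultant length alone
  expect_equal(sqrt(2 * (1 - 0.57)), 0.93, tolerance = 0.005)

  # global rotation: R invariant, mean equivariant
  set.seed(14)
  a <- runif(25, 0, 360)
  s <- circular_summary(a)
  sr <- circular_summary(a + 40)
  expect_equal(sr$R, s$R)
  expect_circ_close(sr$mean_deg, s$mean_deg + 40, 1e-8)
})

test_that("Rayleigh test is calibrated and monotone in concentration", {
  expect_lt(rayleigh_test(rep(45, 18))$p, 1e-6)
  expect_gt(rayleigh_test(rep(c(0, 90, 180, 270), 4))$p, 0.9)

  # p decreases as R grows at fixed n
  ps <- sapply(c(0.2, 0.4, 0.6, 0.8), function(R) {
    # an 18-sample configuration with prescribed R: two opposite clusters
    n <- 18
    k <- round(n * (1 + R) / 2)
    rayleigh_test(c(rep(0, k), rep(180, n - k)))$p
  })
  expect_true(all(diff(ps) < 0))

  # agreement with a Monte-Carlo null for n = 18, R = 0.5
  n <- 18
  z <- n * 0.5^2
  p_analytic <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                             (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) /
                               (288 * n^2))
  set.seed(15)
  r_null <- replicate(20000, {
    th <- runif(n, 0, 2 * pi)
    sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  })
  p_mc <- mean(r_null >= 0.5)
  expect_lt(abs(p_analytic / p_mc - 1), 0.2)
})

test_that("von Mises fitting recovers parameters and inverts A(kappa) exactly", {
  # uniform limit: kappa near zero
  u <- rvonmises_deg(1000, 0, 0, seed = 16)
  expect_lt(fit_von_mises(u, n_sim = 0)$kappa, 0.1)

  # recovery at n = 1000
  x <- rvonmises_deg(1000, 180, 2, seed = 17)
  vm <- fit_von_mises(x, n_sim = 0)
  expect_circ_close(vm$mu_deg, 180, 10)
  expect_lt(abs(vm$kappa / 2 - 1), 0.15)

  # kappa inversion reproduces the sample R to 1e-6
  expect_lt(abs(tacsphase:::bessel_ratio(vm$kappa) - vm$R), 1e-6)

  # all angles equal: kappa capped and flagged
  cap <- fit_von_mises(rep(90, 10), n_sim = 0)
  expect_true(cap$kappa_capped)

  expect_error(fit_von_mises(c(0, 90, 180)), "at least 4")
})

test_that("Watson goodness-of-fit p values are sane under the correct model", {
  ps <- sapply(1:6, function(i)
    fit_von_mises(rvonmises_deg(18, 90, 2, seed = 300 + i),
                  n_sim = 99, seed = 400 + i)$watson_p)
  expect_true(all(ps >= 0 & ps <= 1))
  # under a correctly specified model, p should rarely be extreme
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("concentration homogeneity separates unequal concentrations", {
  # identical samples -> p near 1
  x <- rvonmises_deg(40, 0, 2, seed = 18)
  expect_gt(concentration_homogeneity(x, x, n_perm = 499, seed = 19)$p, 0.9)

  # strong difference -> small p
  a <- rvonmises_deg(50, 0, 8, seed = 20)
  b <- rvonmises_deg(50, 0, 0.5, seed = 21)
  expect_lt(concentration_homogeneity(a, b, n_perm = 999, seed = 22)$p,
            0.01)

  # same-distribution null: p roughly uniform over seeds
  ps <- sapply(1:10, function(i) {
    aa <- rvonmises_deg(20, 0, 2, seed = 500 + 2 * i)
    bb <- rvonmises_deg(20, 0, 2, seed = 501 + 2 * i)
    concentration_homogeneity(aa, bb, n_perm = 199, seed = 600 + i)$p
  })
  expect_gt(mean(ps > 0.05), 0.5)
  expect_gt(min(ps), 0.001)
})
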