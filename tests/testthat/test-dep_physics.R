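test_that("complex permittivity follows eps - j sigma/omega", {
  # zero conductivity: purely real
  expect_equal(complex_permittivity(dielectric_body(80, 0), 1e6),
               complex(real = 80 * eps0, imaginary = 0))
  # hand arithmetic at the device buffer (50 uS/cm) and 12 MHz
  ep <- complex_permittivity(dielectric_body(80, 0.005), 12e6)
  expect_equal(Re(ep), 80 * eps0)
  expect_equal(Im(ep), -0.005 / (2 * pi * 1.2e7))
  # sigma/omega vanishes at high frequency; imaginary part always <= 0
  expect_lt(abs(Im(complex_permittivity(dielectric_body(80, 1), 1e15))), 1e-15)
  expect_lte(Im(complex_permittivity(dielectric_body(5, 3), 1e3)), 0)
  expect_error(complex_permittivity(dielectric_body(80, 1), 0), "positive")
  expect_error(complex_permittivity(dielectric_body(80, 1), -5), "positive")
})

test_that("dielectric body validation rejects unphysical parameters", {
  expect_error(dielectric_body(0, 1), "eps_rel")
  expect_error(dielectric_body(-2, 1), "eps_rel")
  expect_error(dielectric_body(80, -1), "sigma")
  expect_error(dielectric_body(80, 1, radius = 0), "radius")
})

test_that("CM factor matches its frequency limits and vanishes for identical bodies", {
  p <- body_cell(); m <- body_buffer()
  same <- dielectric_body(p$eps_rel, p$sigma)
  expect_equal(cm_factor(p, same, 1e6), 0 + 0i)
  # high-frequency limit: permittivity-only closed form
  hi <- (p$eps_rel - m$eps_rel) / (p$eps_rel + 2 * m$eps_rel)
  expect_equal(Re(cm_factor(p, m, 1e15)), hi, tolerance = 1e-9)
  # low-frequency limit: conductivity-only closed form
  lo <- (p$sigma - m$sigma) / (p$sigma + 2 * m$sigma)
  expect_equal(Re(cm_factor(p, m, 1e-3)), lo, tolerance = 1e-9)
})

test_that("Re(fcm) stays within [-0.5, 1] over random physical parameters", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_body(); m <- random_body()
    f <- 10^runif(1, 0, 10)
    re <- Re(cm_factor(p, m, f))
    expect_gte(re, -0.5)
    expect_lte(re, 1)
  }
})

test_that("DEP regime classification follows the sign of Re(fcm)", {
  m <- body_buffer()
  same <- dielectric_body(m$eps_rel, m$sigma)
  expect_equal(dep_regime(same, m, 1e6), "null")
  # sigma_p > sigma_m and eps_p > eps_m: positive at all frequencies
  p_hi <- dielectric_body(90, 0.02)
  freqs <- 10^seq(1, 10, length.out = 60)
  expect_true(all(dep_regime(p_hi, m, freqs) == "positive"))
  # sigma_p < sigma_m, eps_p > eps_m: negative low, positive high
  p_mix <- dielectric_body(90, 0.001)
  regimes <- dep_regime(p_mix, m, freqs)
  expect_equal(regimes[1], "negative")
  expect_equal(regimes[length(regimes)], "positive")
  # one switch only along the scan
  expect_equal(sum(regimes[-1] != regimes[-length(regimes)]), 1)
})

test_that("crossover frequency agrees with a bisection oracle", {
  set.seed(202)
  found <- 0
  for (i in 1:60) {
    p <- random_body(); m <- random_body()
    fc <- crossover_frequency(p, m)
    re_at <- function(f) Re(cm_factor(p, m, f))
    if (is.na(fc)) {
      # scan oracle: no sign change over a wide dense grid
      res <- re_at(10^seq(-2, 12, length.out = 400))
      expect_true(all(res >= -1e-15) || all(res <= 1e-15))
    } else {
      found <- found + 1
      # bisection oracle on Re(fcm), independent of the closed form
      lo <- 1e-2; hi <- 1e12
      s_lo <- sign(re_at(lo))
      for (k in 1:200) {
        mid <- sqrt(lo * hi)
        if (sign(re_at(mid)) == s_lo) lo <- mid else hi <- mid
      }
      expect_equal(fc, sqrt(lo * hi), tolerance = 1e-6)
    }
  }
  expect_gt(found, 5)  # the sweep exercises both branches
})

test_that("crossover is absent for identical bodies", {
  p <- body_cell()
  expect_true(is.na(crossover_frequency(p, dielectric_body(p$eps_rel, p$sigma))))
})

test_that("DEP force obeys its scaling laws", {
  m <- body_buffer()
  p1 <- dielectric_body(60, 0.01, radius = 5e-6)
  p2 <- dielectric_body(60, 0.01, radius = 1e-5)
  f1 <- dep_force(p1, m, 12e6, 1e15)
  f2 <- dep_force(p2, m, 12e6, 1e15)
  expect_equal(f2 / f1, 8)                       # cubic in r
  expect_equal(dep_force(p1, m, 12e6, 4e15), 4 * f1)  # linear in grad E^2
  # direct product oracle
  re_fcm <- Re(cm_factor(p1, m, 12e6))
  expect_equal(f1, 2 * pi * (5e-6)^3 * 78 * eps0 * re_fcm * 1e15)
  # null CM factor gives zero force
  same <- dielectric_body(m$eps_rel, m$sigma, radius = 5e-6)
  expect_equal(dep_force(same, m, 1e6, 1e15), 0)
  expect_error(dep_force(dielectric_body(60, 0.01), m, 12e6, 1e15), "radius")
})

test_that("DEP stress and Young's modulus compose correctly", {
  m <- body_buffer()
  # n = 0: uniform field exerts no stretching stress
  expect_equal(dep_stress(stress_parameters(0, 1e5, m, 12e6), body_cell()), 0)
  # n = 1, Re(fcm) = 1 limit: stress = eps_m E0^2 exactly
  metal_like <- dielectric_body(1e6, 1e6)
  vac_like <- dielectric_body(1, 1e-9)
  s <- dep_stress(stress_parameters(1, 1e5, vac_like, 1e3), metal_like)
  expect_equal(s, 1 * eps0 * 1e10, tolerance = 1e-5)
  # ratio invariance of the modulus
  expect_equal(youngs_modulus(2 * 17.6, 2 * 0.0864),
               youngs_modulus(17.6, 0.0864))
  expect_error(youngs_modulus(17.6, 0), "unmeasurable")
  expect_error(youngs_modulus(17.6, -0.1), "unmeasurable")
})

test_that("modulus worked examples reproduce the reference pairs", {
  expect_equal(round(youngs_modulus(17.59968, 0.0864), 1), 203.7)
  expect_equal(round(youngs_modulus(17.59932, 0.0901), 1), 195.3)
})

test_that("spectrum table carries the crossover and respects bounds", {
  p <- dielectric_body(90, 0.001); m <- body_buffer()
  sp <- cm_spectrum(p, m)
  expect_named(sp, c("freq_hz", "re_fcm", "im_fcm"))
  fc <- attr(sp, "crossover_hz")
  expect_false(is.na(fc))
  expect_lt(abs(Re(cm_factor(p, m, fc))), 1e-12)
  expect_true(all(sp$re_fcm >= -0.5 & sp$re_fcm <= 1))
})
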