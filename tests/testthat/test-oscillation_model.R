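test_that("parameter validation enforces the model's domain", {
  expect_error(model_params(a = -1, b = 1, c = 1, p = 0.5), "non-negative")
  expect_error(model_params(a = 1, b = 1, c = 1, p = 1.2), "\\[0, 1\\]")
  expect_error(model_params(a = 1, b = 1, c = 1, p = 0.5, omega = 0),
               "positive")
  expect_error(model_params(a = NA, b = 1, c = 1, p = 0.5), "finite")
  pr <- model_params(a = 1, b = 1, c = 1, p = 0.5, alpha1 = 7)
  expect_true(pr$alpha1 >= 0 && pr$alpha1 < 2 * pi)
})

test_that("isoform waveform matches hand-derived cases", {
  # b - pa = -2 with all phases zero: n1 = -2 cos(t) = 2 cos(t + pi)
  w <- isoform_waveform(model_params(a = 3, b = 1, c = 1, p = 1, omega = 1),
                        "long")
  expect_equal(w$amplitude, 2)
  expect_equal(w$phase, pi)
  # b = 0: only the production term -(pa/w)cos(wt + alpha1) survives
  w2 <- isoform_waveform(
    model_params(a = 2, b = 0, c = 1, p = 0.5, omega = 1, alpha1 = pi / 3),
    "long")
  expect_equal(w2$amplitude, 1)
  expect_equal(w2$phase, pi / 3 + pi)
})

test_that("waveforms agree with the Fourier-projection oracle", {
  for (seed in 1:20) {
    pr <- random_params(seed)
    t <- period_grid(pr$omega)
    for (iso in c("long", "short")) {
      y <- if (iso == "long") oracle_n1(pr, t) else oracle_n2(pr, t)
      ref <- oracle_wave(y, t, pr$omega)
      w <- isoform_waveform(pr, iso)
      expect_equal(w$amplitude, ref$amplitude, tolerance = 1e-8)
      if (w$amplitude > 1e-8) {
        dphi <- abs(((w$phase - ref$phase + pi) %% (2 * pi)) - pi)
        expect_lt(dphi, 1e-8)
      }
    }
  }
})

test_that("degenerate zero-amplitude waves are flagged with phase 0", {
  # pa and b cancel exactly: pa = b, alpha1 = alpha2
  pr <- model_params(a = 2, b = 1, c = 0.5, p = 0.5, omega = 1)
  w <- isoform_waveform(pr, "long")
  expect_true(w$degenerate)
  expect_equal(w$amplitude, 0)
  expect_equal(w$phase, 0)
  expect_error(phase_difference(pr), "phase undefined")
})

test_that("phase difference covers symmetric, counter-phase and generic cases", {
  # identical equations for the two isoforms: difference exactly 0
  expect_equal(phase_difference(
    model_params(a = 1, b = 1, c = 1, p = 0.5, omega = 1,
                 alpha2 = 0.3, alpha3 = 0.3)), 0)
  # rectifier family: exact counter-phase
  expect_equal(phase_difference(rectifier_params()), pi)
  # definitional consistency with the two waveform phases
  for (seed in 21:30) {
    pr <- random_params(seed)
    w1 <- isoform_waveform(pr, "long")
    w2 <- isoform_waveform(pr, "short")
    d <- ((w2$phase - w1$phase + pi) %% (2 * pi)) - pi
    if (d <= -pi) d <- d + 2 * pi
    expect_equal(phase_difference(pr), d)
  }
})

test_that("analytic evaluation matches direct formula and edge cases", {
  t <- seq(0, 48, by = 0.5)
  pr0 <- model_params(a = 0, b = 0, c = 0, p = 0.5, m1 = 5, m2 = 7)
  tr0 <- evaluate_analytic(pr0, t)
  expect_true(all(tr0$n1 == 5) && all(tr0$n2 == 7))
  # rectifier: the summed trajectory is exactly flat at zero
  trr <- evaluate_analytic(rectifier_params(), t)
  expect_lt(max(abs(trr$total)), 1e-12)
  for (seed in 31:35) {
    pr <- random_params(seed)
    tr <- evaluate_analytic(pr, t)
    expect_equal(tr$n1, oracle_n1(pr, t))
    expect_equal(tr$n2, oracle_n2(pr, t))
  }
  expect_error(evaluate_analytic(pr0, numeric(0)), "empty")
  expect_error(evaluate_analytic(pr0, c(1, 1, 2)), "increasing")
})

test_that("analytic time-derivative matches the model right-hand side", {
  pr <- random_params(36)
  rhs <- function(t) {
    pr$p * pr$a * sin(pr$omega * t + pr$alpha1) -
      pr$b * sin(pr$omega * t + pr$alpha2)
  }
  err_at <- function(h) {
    t <- seq(0, 24, by = h)
    n1 <- evaluate_analytic(pr, t)$n1
    k <- 2:(length(t) - 1)
    max(abs((n1[k + 1] - n1[k - 1]) / (2 * h) - rhs(t[k])))
  }
  e1 <- err_at(0.01)
  e2 <- err_at(0.001)
  expect_lt(e1, 1e-4)
  expect_lt(e2 * 50, e1) # second-order convergence of the central difference
})

test_that("RK4 integration reproduces the analytic solution", {
  t <- seq(0, 48, by = 1)
  for (seed in 41:50) {
    pr <- random_params(seed)
    ana <- evaluate_analytic(pr, t)
    ode <- integrate_ode(pr, t, init = c(ana$n1[1], ana$n2[1]))
    expect_lt(max(abs(ode$n1 - ana$n1), abs(ode$n2 - ana$n2)), 1e-6)
  }
  # zero rates: trajectories stay at the initial abundances
  still <- integrate_ode(model_params(a = 0, b = 0, c = 0, p = 0.5),
                         t, init = c(5, 7))
  expect_true(all(still$n1 == 5) && all(still$n2 == 7))
  # rectification corollary: the integrated sum does not oscillate
  pr <- rectifier_params()
  ana <- evaluate_analytic(pr, seq(0, 24, by = 0.25))
  ode <- integrate_ode(pr, seq(0, 24, by = 0.25),
                       init = c(ana$n1[1], ana$n2[1]))
  expect_lt(var(ode$total), 1e-10)
})

test_that("sum amplitude matches the cosine-sum identity and a trajectory oracle", {
  expect_equal(sum_amplitude(rectifier_params()), 0)
  # one isoform absent: sum amplitude is the remaining wave's amplitude
  pr1 <- model_params(a = 2, b = 1, c = 0, p = 1, omega = 1, alpha2 = 1)
  expect_equal(sum_amplitude(pr1), isoform_waveform(pr1, "long")$amplitude)
  for (seed in 51:55) {
    pr <- random_params(seed)
    t <- period_grid(pr$omega, n = 2e5) # dense: sampled extrema are O(dt^2)
    tot <- oracle_n1(pr, t) + oracle_n2(pr, t)
    expect_equal(sum_amplitude(pr), (max(tot) - min(tot)) / 2,
                 tolerance = 1e-8)
  }
})

test_that("model symmetries hold: isoform swap and amplitude scaling", {
  for (seed in 61:65) {
    pr <- random_params(seed)
    swapped <- model_params(a = pr$a, b = pr$c, c = pr$b, p = 1 - pr$p,
                            omega = pr$omega, alpha1 = pr$alpha1,
                            alpha2 = pr$alpha3, alpha3 = pr$alpha2)
    wl <- isoform_waveform(pr, "long")
    ws <- isoform_waveform(swapped, "short")
    expect_equal(wl$amplitude, ws$amplitude)
    expect_equal(wl$phase, ws$phase)
    lam <- 2.7
    scaled <- model_params(a = lam * pr$a, b = lam * pr$b, c = lam * pr$c,
                           p = pr$p, omega = pr$omega, alpha1 = pr$alpha1,
                           alpha2 = pr$alpha2, alpha3 = pr$alpha3)
    expect_equal(isoform_waveform(scaled, "long")$amplitude,
                 lam * wl$amplitude)
    expect_equal(isoform_waveform(scaled, "long")$phase, wl$phase)
  }
})
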