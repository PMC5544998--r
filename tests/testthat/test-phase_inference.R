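test_that("maximum-entropy bootstrap handles degenerate and short input", {
  e <- me_bootstrap(c(5, 5, 5, 5), replicates = 10, seed = 1)
  expect_true(all(e$replicates == 5))
  expect_error(me_bootstrap(c(1, 2), replicates = 5, seed = 1), "length >= 3")
  expect_error(me_bootstrap(c(1, 2, 3), replicates = 0, seed = 1), ">= 1")
})

test_that("bootstrap ensemble preserves the sample mean and is deterministic", {
  s <- c(4, 12, 36, 20, 8) # sample mean 16
  e <- me_bootstrap(s, replicates = 1000, seed = 7)
  expect_lt(abs(mean(e$replicates) - 16), 0.5)
  e2 <- me_bootstrap(s, replicates = 1000, seed = 7)
  expect_identical(e$replicates, e2$replicates)
})

test_that("every bootstrap replicate keeps the original rank ordering", {
  set.seed(14)
  for (k in 1:10) {
    s <- rnorm(9)
    e <- me_bootstrap(s, replicates = 20, seed = k)
    for (r in seq_len(nrow(e$replicates))) {
      expect_identical(order(e$replicates[r, ]), order(s))
    }
  }
})

test_that("phase estimation recovers pure cosine templates", {
  t <- mouse_times()
  est <- estimate_phase(10 + 3 * cos(2 * pi * (t - 8) / 24), t)
  expect_equal(est$phi_h, 8, tolerance = 1e-9)
  expect_equal(est$class, 2L)
  expect_equal(est$strength, 1, tolerance = 1e-12)
  # negated series: antiphase peak at 20 h
  est2 <- estimate_phase(-cos(2 * pi * (t - 8) / 24), t)
  expect_equal(est2$phi_h, 20, tolerance = 1e-9)
  expect_equal(est2$class, 5L)
  expect_error(estimate_phase(rep(1, length(t)), t), "phase undefined")
  expect_error(estimate_phase(1:3, c(0, 4, 8)), ">= 4 distinct")
})

test_that("phase estimation is shift-equivariant modulo the period", {
  t <- mouse_times()
  set.seed(2)
  base_phi <- runif(5, 0, 24)
  for (phi in base_phi) {
    for (delta in c(2, 4.5, 13, 23)) {
      e0 <- estimate_phase(cos(2 * pi * (t - phi) / 24), t)$phi_h
      e1 <- estimate_phase(cos(2 * pi * (t - phi - delta) / 24), t)$phi_h
      expect_equal((e1 - e0) %% 24, delta %% 24, tolerance = 1e-6)
    }
  }
})

test_that("class recovery stays above 95% at 10% relative noise", {
  panel <- generate_panel(make_design("mouse"), n_genes = 500,
                          probes_per_gene = c(1), frac_rhythmic = 1,
                          noise_frac = 0.1, seed = 31)
  t <- panel$expression$samples$time_h
  hit <- vapply(seq_len(500), function(i) {
    estimate_phase(panel$expression$values[i, ], t)$class ==
      planted_class(panel$truth$phase_h[i])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("rhythmicity p-value hits its floor on noiseless cosines", {
  t <- mouse_times()
  p <- rhythmicity_pvalue(cos(2 * pi * t / 24), t, n_perm = 999, seed = 3)
  expect_equal(p, 1 / 1000)
  expect_equal(rhythmicity_pvalue(rep(2, length(t)), t, seed = 1), 1)
})

test_that("rhythmicity p-values are uniform under white noise", {
  t <- mouse_times()
  set.seed(5)
  ps <- vapply(1:500, function(i) {
    rhythmicity_pvalue(rnorm(length(t)), t, n_perm = 199, seed = i)
  }, numeric(1))
  ks <- max(abs(seq_along(ps) / length(ps) - sort(ps)))
  expect_lt(ks, 0.05)
})

test_that("phase confidence reflects replicate agreement", {
  t <- seq(0, 24, by = 4)
  # noiseless cosine: every bootstrap replicate lands in the planted class
  s <- 10 + 3 * cos(2 * pi * (t - 8) / 24)
  ens <- me_bootstrap(s, replicates = 300, seed = 9)
  conf <- phase_confidence(ens, t)
  expect_equal(conf$class, 2L)
  expect_equal(conf$modal_fraction, 1)
  expect_equal(conf$p_phase, 0)
  expect_lt(conf$ci_width_h, 2)
  # crafted 50/50 split between two classes: confidence p-value 0.5
  half <- rbind(
    matrix(rep(cos(2 * pi * (t - 8) / 24), 50), 50, byrow = TRUE),
    matrix(rep(cos(2 * pi * (t - 12) / 24), 50), 50, byrow = TRUE))
  ens2 <- structure(list(replicates = half, series = half[1, ], seed = 0),
                    class = "bootstrap_ensemble")
  conf2 <- phase_confidence(ens2, t)
  expect_equal(conf2$p_phase, 0.5)
  # all-constant replicates: no phase anywhere
  ens3 <- structure(list(replicates = matrix(1, 5, length(t)),
                         series = rep(1, length(t)), seed = 0),
                    class = "bootstrap_ensemble")
  expect_error(phase_confidence(ens3, t), "undefined")
})

test_that("probes passing the confidence filter are almost always classed right", {
  panel <- generate_panel(make_design("mouse"), n_genes = 300,
                          probes_per_gene = c(1), frac_rhythmic = 1,
                          noise_frac = 0.3, seed = 99)
  calls <- call_phases(panel$expression, seed = 99,
                       bootstrap_replicates = 100, n_perm = 49)
  m <- dplyr::inner_join(calls, panel$truth, by = "probe_id")
  pass <- m$p_phase <= 0.1
  expect_gt(mean(pass), 0.5) # the filter keeps a usable fraction
  acc <- mean((m$phase_class == planted_class(m$phase_h))[pass])
  expect_gte(acc, 0.99)
})

test_that("call_phases is reproducible and flags undefined probes", {
  panel <- generate_panel(make_design("mouse"), n_genes = 30, seed = 17,
                          noise_frac = 0)
  calls <- call_phases(panel$expression, seed = 17,
                       bootstrap_replicates = 50, n_perm = 49)
  calls2 <- call_phases(panel$expression, seed = 17,
                        bootstrap_replicates = 50, n_perm = 49)
  expect_identical(calls, calls2)
  expect_equal(nrow(calls), nrow(panel$truth))
  # noiseless flat probes are constant: flagged, not dropped
  flat <- panel$truth$probe_id[!panel$truth$rhythmic]
  expect_true(all(!calls$phase_defined[calls$probe_id %in% flat]))
  # noiseless rhythmic probes recover their planted class exactly
  m <- dplyr::inner_join(calls, panel$truth, by = "probe_id")
  mr <- dplyr::filter(m, rhythmic)
  expect_true(all(mr$phase_class == planted_class(mr$phase_h)))
})

test_that("rhythmicity test separates planted from flat probes", {
  panel <- generate_panel(make_design("mouse"), n_genes = 400,
                          probes_per_gene = c(1), frac_rhythmic = 0.2,
                          noise_frac = 0.15, seed = 55)
  calls <- call_phases(panel$expression, seed = 55,
                       bootstrap_replicates = 50, n_perm = 199)
  m <- dplyr::inner_join(calls, panel$truth, by = "probe_id")
  sens <- mean(m$p_rhythm[m$rhythmic] <= 0.05)
  fpr <- mean(m$p_rhythm[!m$rhythmic] <= 0.05)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.1)
})
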