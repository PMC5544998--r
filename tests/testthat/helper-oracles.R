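# Independent oracles used across the test files. These recompute expected
# quantities from first principles (direct formula evaluation, Fourier
# projection, finite differences) without calling the code paths they check.

# direct evaluation of the integrated model solution, written out literally
oracle_n1 <- function(pr, t) {
  -(pr$p * pr$a / pr$omega) * cos(pr$omega * t + pr$alpha1) +
    (pr$b / pr$omega) * cos(pr$omega * t + pr$alpha2) + pr$m1
}
oracle_n2 <- function(pr, t) {
  -((1 - pr$p) * pr$a / pr$omega) * cos(pr$omega * t + pr$alpha1) +
    (pr$c / pr$omega) * cos(pr$omega * t + pr$alpha3) + pr$m2
}

# amplitude/phase of a sampled harmonic by Fourier projection over whole
# periods: for y = A cos(w t + beta), (2/N) sum y exp(-i w t) = A exp(i beta)
oracle_wave <- function(y, t, omega) {
  coef <- 2 * mean(y * exp(-1i * omega * t))
  list(amplitude = Mod(coef), phase = Arg(coef) %% (2 * pi))
}

# dense grid covering exactly one period (endpoint excluded)
period_grid <- function(omega, n = 4096) {
  seq(0, 2 * pi / omega, length.out = n + 1)[-(n + 1)]
}

random_params <- function(seed) {
  set.seed(seed)
  model_params(a = runif(1, 0.5, 4), b = runif(1, 0.1, 3),
               c = runif(1, 0.1, 3), p = runif(1, 0.05, 0.95),
               omega = runif(1, 0.1, 1),
               alpha1 = runif(1, 0, 2 * pi), alpha2 = runif(1, 0, 2 * pi),
               alpha3 = runif(1, 0, 2 * pi))
}

planted_class <- function(phase_h, period_h = 24) {
  as.integer(round(phase_h / (period_h / 6)) %% 6)
}

mouse_times <- function() rep(seq(0, 24, by = 4), each = 2)

# count within-gene probe pairs whose planted phases are 12 h apart; this
# includes pairs of a counter-phase member with a concordant gene-mate
truth_bin6_pairs <- function(truth) {
  sum(vapply(split(truth$phase_h[truth$rhythmic], truth$gene[truth$rhythmic]),
             function(ph) {
               if (length(ph) < 2) return(0L)
               idx <- utils::combn(length(ph), 2)
               sum((abs(ph[idx[1, ]] - ph[idx[2, ]]) %% 24) == 12)
             }, integer(1)))
}
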