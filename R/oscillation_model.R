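#' Parameters of the two-isoform transcription/decay model
#'
#' The model describes a gene transcribed into two alternatively
#' polyadenylated isoforms. A fraction `p` of nascent transcripts becomes the
#' long isoform (n1) and `1 - p` the short isoform (n2). Production and the
#' two decay processes are sinusoidal rates sharing one angular frequency:
#'
#' \deqn{dn_1/dt = p\,a\sin(\omega t+\alpha_1) - b\sin(\omega t+\alpha_2)}
#' \deqn{dn_2/dt = (1-p)\,a\sin(\omega t+\alpha_1) - c\sin(\omega t+\alpha_3)}
#'
#' The decay terms are pure sinusoidal rates, not proportional to abundance;
#' this abstracts (for example) rhythmic miRNA-mediated turnover of the long
#' isoform into the amplitude `b`. The common biological regime has `b > c`
#' (the long isoform, carrying miRNA target sites, turns over faster); this
#' is not enforced because the algebra does not require it.
#'
#' @param a Production-oscillation amplitude (abundance/h), `>= 0`.
#' @param b Decay-oscillation amplitude of the long isoform (abundance/h).
#' @param c Decay-oscillation amplitude of the short isoform (abundance/h).
#' @param p Probability that a transcript is the long isoform, in `[0, 1]`.
#' @param omega Angular frequency in rad/h; defaults to a 24 h period.
#' @param alpha1,alpha2,alpha3 Phases (radians) of the production wave and of
#'   the long- and short-isoform decay waves; stored reduced to `[0, 2*pi)`.
#' @param m1,m2 Constant baseline offsets added to n1 and n2 (the constants
#'   of integration, 0 by default).
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' rectifier_params() # equal isoform amplitudes, counter-phase
#' @export
model_params <- function(a, b, c, p, omega = 2 * pi / 24,
                         alpha1 = 0, alpha2 = 0, alpha3 = 0,
                         m1 = 0, m2 = 0) {
  vals <- c(a = a, b = b, c = c, p = p, omega = omega,
            alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            m1 = m1, m2 = m2)
  if (!all(is.finite(vals))) {
    stop("all model parameters must be finite", call. = FALSE)
  }
  if (a < 0 || b < 0 || c < 0) {
    stop("amplitudes 'a', 'b', 'c' must be non-negative", call. = FALSE)
  }
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]", call. = FALSE)
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  out <- list(a = a, b = b, c = c, p = p, omega = omega,
              alpha1 = wrap_2pi(alpha1), alpha2 = wrap_2pi(alpha2),
              alpha3 = wrap_2pi(alpha3), m1 = m1, m2 = m2)
  structure(out, class = "model_params")
}

#' Canonical rectifier parameter set
#'
#' The symmetric parameter choice for which the two isoform waves have equal
#' amplitude and opposite phase, so their sum is constant in time: the
#' "molecular rectifier" regime.
#'
#' @param omega Angular frequency (rad/h), default a 24 h period.
#' @return A `model_params` object with `a = 2`, `p = 0.5`, `b = 1.5`,
#'   `c = 0.5` and all phase angles zero.
#' @export
rectifier_params <- function(omega = 2 * pi / 24) {
  model_params(a = 2, b = 1.5, c = 0.5, p = 0.5, omega = omega)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-isoform oscillation model parameters\n")
  cat(sprintf("  a = %g, b = %g, c = %g, p = %g\n", x$a, x$b, x$c, x$p))
  cat(sprintf("  omega = %g rad/h (period %.3g h)\n", x$omega, 2 * pi / x$omega))
  cat(sprintf("  alpha = (%.4g, %.4g, %.4g) rad; offsets m = (%g, %g)\n",
              x$alpha1, x$alpha2, x$alpha3, x$m1, x$m2))
  invisible(x)
}

wrap_2pi <- function(x) x %% (2 * pi)

# wrap to (-pi, pi]
wrap_pi <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Analytic waveform of one isoform
#'
#' Each isoform's abundance is a single harmonic, e.g. for the long isoform
#' \eqn{n_1(t) = A\cos(\omega t + \beta_1)} with
#' \deqn{A = \sqrt{(pa/\omega)^2 + (b/\omega)^2 -
#'   (2pab/\omega^2)\cos(\alpha_1-\alpha_2)}}
#' \deqn{\tan\beta_1 = \frac{b\sin\alpha_2 - pa\sin\alpha_1}
#'   {b\cos\alpha_2 - pa\cos\alpha_1}}
#' The phase is extracted quadrant-correctly with the two-argument
#' arctangent applied to the (numerator, denominator) pair, so the resulting
#' wave matches the rotating-vector geometric construction for every sign
#' combination. The short isoform uses `(1-p)a`, `c`, `alpha3` in place of
#' `pa`, `b`, `alpha2`.
#'
#' @param params A [model_params()] object.
#' @param isoform `"long"` (n1) or `"short"` (n2).
#' @return A `harmonic_wave`: list with `amplitude` (>= 0), `phase`
#'   (radians in `[0, 2*pi)`) and `degenerate` (`TRUE` when the amplitude is
#'   zero, in which case the phase is defined as 0).
#' @examples
#' isoform_waveform(rectifier_params(), "long")
#' @export
isoform_waveform <- function(params, isoform = c("long", "short")) {
  stopifnot(inherits(params, "model_params"))
  isoform <- match.arg(isoform)
  w <- params$omega
  if (isoform == "long") {
    prod_amp <- params$p * params$a
    dec_amp <- params$b
    dec_alpha <- params$alpha2
  } else {
    prod_amp <- (1 - params$p) * params$a
    dec_amp <- params$c
    dec_alpha <- params$alpha3
  }
  num <- dec_amp * sin(dec_alpha) - prod_amp * sin(params$alpha1)
  den <- dec_amp * cos(dec_alpha) - prod_amp * cos(params$alpha1)
  amp2 <- (prod_amp / w)^2 + (dec_amp / w)^2 -
    2 * prod_amp * dec_amp / w^2 * cos(params$alpha1 - dec_alpha)
  amplitude <- sqrt(max(amp2, 0))
  tol <- 1e-12 * max(1, prod_amp, dec_amp)
  degenerate <- abs(num) < tol && abs(den) < tol
  phase <- if (degenerate) 0 else wrap_2pi(atan2(num, den))
  structure(list(amplitude = amplitude, phase = phase, degenerate = degenerate),
            class = "harmonic_wave")
}

#' @export
print.harmonic_wave <- function(x, ...) {
  cat(sprintf("Harmonic wave: amplitude %.6g, phase %.6g rad%s\n",
              x$amplitude, x$phase,
              if (x$degenerate) " (degenerate, zero amplitude)" else ""))
  invisible(x)
}

#' Phase difference between the two isoform waves
#'
#' Returns \eqn{\beta_2 - \beta_1}, the phase lag of the short isoform behind
#' the long one, wrapped to `(-pi, pi]`. A value of `pi` is the counter-phase
#' (rectifier) regime in which the summed abundance is constant.
#'
#' @param params A [model_params()] object.
#' @return Phase difference in radians, in `(-pi, pi]`.
#' @examples
#' phase_difference(rectifier_params()) # pi
#' @export
phase_difference <- function(params) {
  w1 <- isoform_waveform(params, "long")
  w2 <- isoform_waveform(params, "short")
  if (w1$degenerate || w2$degenerate) {
    stop("phase undefined: an isoform wave has zero amplitude", call. = FALSE)
  }
  wrap_pi(w2$phase - w1$phase)
}

#' Amplitude of the summed isoform abundance
#'
#' The sum n1 + n2 of two harmonics with amplitudes A, B and phase lag
#' \eqn{\Delta\beta} is itself a harmonic with amplitude
#' \eqn{\sqrt{A^2 + B^2 + 2AB\cos\Delta\beta}}. When the amplitudes are
#' equal and the lag is \eqn{\pi}, the summed amplitude is zero: oscillatory
#' transcription yields a steady total transcript level.
#'
#' @param params A [model_params()] object.
#' @return Non-negative scalar amplitude of n1(t) + n2(t).
#' @examples
#' sum_amplitude(rectifier_params()) # 0
#' @export
sum_amplitude <- function(params) {
  w1 <- isoform_waveform(params, "long")
  w2 <- isoform_waveform(params, "short")
  A <- w1$amplitude
  B <- w2$amplitude
  dphi <- w2$phase - w1$phase
  sqrt(max(A^2 + B^2 + 2 * A * B * cos(dphi), 0))
}

#' Evaluate the analytic solution on a time grid
#'
#' The closed-form solution of the model is
#' \deqn{n_1(t) = -(pa/\omega)\cos(\omega t+\alpha_1) +
#'   (b/\omega)\cos(\omega t+\alpha_2) + m_1}
#' and analogously for n2 with `(1-p)a`, `c`, `alpha3`, `m2`.
#'
#' @param params A [model_params()] object.
#' @param times Numeric vector of time points (hours), strictly increasing.
#' @return A tibble with columns `time_h`, `n1`, `n2`, `total`.
#' @examples
#' evaluate_analytic(rectifier_params(), seq(0, 48, by = 0.5))
#' @export
evaluate_analytic <- function(params, times) {
  stopifnot(inherits(params, "model_params"))
  check_time_grid(times)
  w <- params$omega
  n1 <- -(params$p * params$a / w) * cos(w * times + params$alpha1) +
    (params$b / w) * cos(w * times + params$alpha2) + params$m1
  n2 <- -((1 - params$p) * params$a / w) * cos(w * times + params$alpha1) +
    (params$c / w) * cos(w * times + params$alpha3) + params$m2
  tibble(time_h = as.numeric(times), n1 = n1, n2 = n2, total = n1 + n2)
}

check_time_grid <- function(times) {
  if (length(times) < 1L) stop("time grid is empty", call. = FALSE)
  if (!all(is.finite(times))) stop("time grid must be finite", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  invisible(times)
}

#' Numerically integrate the model ODE
#'
#' Integrates the two rate equations with the classical fixed-step
#' fourth-order Runge-Kutta scheme, subdividing each output interval so no
#' internal step exceeds `max_step` hours. This integrator serves as an
#' independent numerical oracle for [evaluate_analytic()]; the right-hand
#' side does not depend on the state, so the problem is a quadrature and RK4
#' is accurate far below the default tolerances used in testing.
#'
#' @param params A [model_params()] object.
#' @param times Output time grid (hours), strictly increasing.
#' @param init Length-2 numeric: initial abundances `c(n1, n2)` at `times[1]`.
#' @param max_step Maximum internal step (hours), default 0.05.
#' @return A tibble with columns `time_h`, `n1`, `n2`, `total`.
#' @export
integrate_ode <- function(params, times, init = c(0, 0), max_step = 0.05) {
  stopifnot(inherits(params, "model_params"))
  check_time_grid(times)
  if (length(init) != 2L || !all(is.finite(init))) {
    stop("'init' must be two finite abundances", call. = FALSE)
  }
  deriv <- function(t) {
    c(params$p * params$a * sin(params$omega * t + params$alpha1) -
        params$b * sin(params$omega * t + params$alpha2),
      (1 - params$p) * params$a * sin(params$omega * t + params$alpha1) -
        params$c * sin(params$omega * t + params$alpha3))
  }
  n_out <- length(times)
  out <- matrix(NA_real_, n_out, 2L)
  out[1L, ] <- init
  y <- init
  if (n_out > 1L) {
    for (i in seq_len(n_out - 1L)) {
      t0 <- times[i]
      dt <- times[i + 1L] - t0
      n_sub <- max(1L, ceiling(dt / max_step))
      h <- dt / n_sub
      for (s in seq_len(n_sub)) {
        tt <- t0 + (s - 1L) * h
        k1 <- deriv(tt)
        k2 <- deriv(tt + h / 2)
        k3 <- k2 # state-independent RHS: k3 evaluates at the same time as k2
        k4 <- deriv(tt + h)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      out[i + 1L, ] <- y
    }
  }
  tibble(time_h = as.numeric(times), n1 = out[, 1L], n2 = out[, 2L],
         total = out[, 1L] + out[, 2L])
}
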