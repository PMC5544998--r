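#' Maximum-entropy bootstrap of a time series
#'
#' Generates bootstrap replicates of a short, possibly non-stationary time
#' series by the maximum-entropy construction: sort the series, form the
#' intermediate points (midpoints of adjacent order statistics, with end
#' intervals extended by a trimmed mean of the absolute first differences),
#' draw sorted uniforms and map them through the piecewise-linear
#' maximum-entropy quantile function whose interval means are adjusted to
#' preserve the sample mean, then restore the original time ordering by
#' rank. Every replicate therefore shares the original series' rank
#' ordering, and the ensemble grand mean converges to the sample mean.
#'
#' @param series Numeric vector (length >= 3), one value per time point in
#'   time order.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param trim Trim fraction for the mean absolute difference that extends
#'   the end intervals; default 0.10.
#' @param seed Integer seed; the ensemble is deterministic given the seed.
#' @return A `bootstrap_ensemble`: list with `replicates` (matrix, one row
#'   per replicate), `series`, and `seed`.
#' @examples
#' me_bootstrap(c(4, 12, 36, 20, 8), replicates = 5, seed = 1)$replicates
#' @export
me_bootstrap <- function(series, replicates, trim = 0.10, seed) {
  n <- length(series)
  if (n < 3L) stop("series must have length >= 3", call. = FALSE)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)

  if (diff(range(series)) == 0) {
    reps <- matrix(series[1L], nrow = replicates, ncol = n)
    return(structure(list(replicates = reps, series = series, seed = seed),
                     class = "bootstrap_ensemble"))
  }

  ord <- order(series)
  xs <- series[ord]
  # interval limits: midpoints, with trimmed-mean-extended ends
  m_trm <- mean(abs(diff(series)), trim = trim)
  z <- c(xs[1L] - m_trm, (xs[-n] + xs[-1L]) / 2, xs[n] + m_trm)
  # desired interval means, preserving the overall mean
  des <- c(0.75 * xs[1L] + 0.25 * xs[2L],
           if (n > 2L) 0.25 * xs[1:(n - 2L)] + 0.5 * xs[2:(n - 1L)] +
             0.25 * xs[3:n],
           0.25 * xs[n - 1L] + 0.75 * xs[n])
  shift <- des - (z[-(n + 1L)] + z[-1L]) / 2

  reps <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = replicates, ncol = n)
    for (r in seq_len(replicates)) {
      u <- runif(n)
      j <- pmin(floor(u * n) + 1L, n)
      frac <- u * n - (j - 1L)
      q <- z[j] + frac * (z[j + 1L] - z[j]) + shift[j]
      # sorting before rank placement makes rank preservation structural
      # even where the mean-preserving shifts dent monotonicity locally
      out[r, ord] <- sort(q)
    }
    out
  })
  structure(list(replicates = reps, series = series, seed = seed),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("Maximum-entropy bootstrap ensemble: %d replicates of length %d (seed %s)\n",
              nrow(x$replicates), ncol(x$replicates), format(x$seed)))
  invisible(x)
}

# average replicate samples taken at the same nominal time
average_replicates <- function(series, times) {
  ut <- sort(unique(times))
  list(times = ut,
       values = vapply(ut, function(t) mean(series[times == t]), numeric(1)))
}

# first-harmonic least-squares fit for a matrix of series (rows) on a common
# time grid; returns phi (hours), class, and variance fraction captured
harmonic_fit_many <- function(mat, times, period_h) {
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * times), sin(w * times))
  P <- solve(crossprod(X), t(X)) # 3 x n projector onto the harmonic basis
  coefs <- P %*% t(mat)          # rows: intercept, cos, sin
  fitted <- X %*% coefs
  resid2 <- colSums((t(mat) - fitted)^2)
  tot2 <- colSums((t(mat) - rep(colMeans(t(mat)), each = length(times)))^2)
  phi <- (atan2(coefs[3L, ], coefs[2L, ]) / w) %% period_h
  strength <- ifelse(tot2 > 0, pmax(0, 1 - resid2 / tot2), NA_real_)
  n_class <- round(period_h / 4)
  list(phi_h = phi,
       class = as.integer(round(phi / (period_h / n_class)) %% n_class),
       strength = strength)
}

#' Estimate the circadian phase of one series
#'
#' Fits the first harmonic at the circadian frequency by least squares
#' (replicate samples at the same nominal time are averaged first) and
#' reports the peak time of the fitted cosine as the continuous phase
#' `phi_h` in `[0, period_h)` hours, the discrete phase class
#' `round(phi_h / 4) mod 6` (six 4 h classes over the 24 h cycle), and the
#' fraction of variance captured by the harmonic (`strength`).
#'
#' @param series Numeric values, one per sample.
#' @param times Sampling times in hours, same length as `series`.
#' @param period_h Oscillation period in hours (default 24).
#' @return A list with `phi_h`, `class`, `strength`.
#' @examples
#' t <- rep(seq(0, 24, 4), each = 2)
#' estimate_phase(10 + 3 * cos(2 * pi * (t - 8) / 24), t)
#' @export
estimate_phase <- function(series, times, period_h = 24) {
  stopifnot(length(series) == length(times))
  avg <- average_replicates(series, times)
  if (length(avg$times) < 4L) {
    stop("need >= 4 distinct time points", call. = FALSE)
  }
  if (diff(range(avg$values)) == 0) {
    stop("phase undefined: constant series", call. = FALSE)
  }
  fit <- harmonic_fit_many(matrix(avg$values, nrow = 1L), avg$times, period_h)
  list(phi_h = unname(fit$phi_h), class = unname(fit$class),
       strength = unname(fit$strength))
}

#' Permutation p-value for rhythmicity
#'
#' Tests whether a probe oscillates at the circadian frequency. The test
#' statistic is the fraction of sample variance captured by the first
#' harmonic at `1/period_h`; the null distribution is generated by randomly
#' permuting values across samples (destroying any time structure while
#' keeping the marginal distribution), and
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams estimate_phase
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A p-value in `(0, 1]`; constant series return 1.
#' @export
rhythmicity_pvalue <- function(series, times, period_h = 24, n_perm = 999,
                               seed) {
  stopifnot(length(series) == length(times))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (diff(range(series)) == 0) return(1)
  w <- 2 * pi / period_h
  X <- cbind(cos(w * times), sin(w * times))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  M <- Xc %*% solve(crossprod(Xc), t(Xc))
  stat <- function(ymat) {
    yc <- ymat - rep(colMeans(ymat), each = nrow(ymat))
    colSums(yc * (M %*% yc)) / colSums(yc^2)
  }
  obs <- stat(matrix(series, ncol = 1L))
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(series), series)
  })
  null_stats <- stat(perm)
  (1 + sum(null_stats >= obs)) / (n_perm + 1)
}

#' Bootstrap confidence of a phase assignment
#'
#' Re-estimates the phase on every maximum-entropy bootstrap replicate and
#' summarizes the stability of the assignment: the modal phase class across
#' replicates, a phase-confidence p-value defined as one minus the modal
#' class fraction (0 when every replicate agrees), and a central circular
#' percentile confidence interval for the continuous phase.
#'
#' @param ensemble A [me_bootstrap()] ensemble built from the
#'   replicate-averaged series, in time order.
#' @param times Distinct sampling times (hours) matching the ensemble's
#'   series length.
#' @param period_h Oscillation period in hours (default 24).
#' @param level Coverage of the percentile interval (default 0.90).
#' @return A list with `class` (modal), `modal_fraction`, `p_phase`,
#'   `ci_lo_h`, `ci_hi_h`, `ci_width_h`.
#' @export
phase_confidence <- function(ensemble, times, period_h = 24, level = 0.90) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  mat <- ensemble$replicates
  stopifnot(ncol(mat) == length(times))
  ok <- apply(mat, 1L, function(r) diff(range(r)) > 0)
  if (!any(ok)) stop("phase undefined on every replicate", call. = FALSE)
  fit <- harmonic_fit_many(mat[ok, , drop = FALSE], times, period_h)
  tab <- table(fit$class)
  modal <- as.integer(names(tab)[which.max(tab)])
  modal_frac <- max(tab) / sum(tab)
  # circular percentile interval, centred on the circular mean
  w <- 2 * pi / period_h
  mu <- (atan2(mean(sin(w * fit$phi_h)), mean(cos(w * fit$phi_h))) / w) %%
    period_h
  dev <- ((fit$phi_h - mu + period_h / 2) %% period_h) - period_h / 2
  qs <- quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  list(class = modal, modal_fraction = unname(modal_frac),
       p_phase = unname(1 - modal_frac),
       ci_lo_h = (mu + qs[1]) %% period_h,
       ci_hi_h = (mu + qs[2]) %% period_h,
       ci_width_h = qs[2] - qs[1])
}

#' Assign phases to every probe of an expression panel
#'
#' Per-probe orchestration of the phase-assignment pipeline: estimate the
#' continuous phase and phase class from the first harmonic, compute a
#' permutation rhythmicity p-value, and quantify phase stability with a
#' maximum-entropy bootstrap confidence p-value and percentile interval.
#' Probes whose (replicate-averaged) series is constant have no defined
#' phase; they are flagged (`phase_defined = FALSE`), never dropped
#' silently. Per-probe random substreams are derived deterministically from
#' the master seed, so results are reproducible and independent of probe
#' order of evaluation.
#'
#' @param x An [expr_ts()] panel (or the `expression` element of
#'   [generate_panel()] output).
#' @param period_h Oscillation period in hours (default 24).
#' @param bootstrap_replicates Maximum-entropy bootstrap replicates per
#'   probe (default 200).
#' @param n_perm Permutations for the rhythmicity test (default 199).
#' @param seed Master integer seed.
#' @return A tibble with one row per probe: `probe_id`, `phi_h`,
#'   `phase_class`, `strength`, `p_rhythm`, `p_phase`, `ci_lo_h`, `ci_hi_h`,
#'   `phase_defined`.
#' @examples
#' panel <- generate_panel(make_design("mouse"), n_genes = 5, seed = 1)
#' call_phases(panel$expression, seed = 1, bootstrap_replicates = 50,
#'             n_perm = 99)
#' @export
call_phases <- function(x, period_h = 24, bootstrap_replicates = 200,
                        n_perm = 199, seed) {
  stopifnot(inherits(x, "expr_ts"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  times <- x$samples$time_h
  if (is.null(times) || !all(is.finite(times))) {
    stop("sample sheet lacks usable time metadata", call. = FALSE)
  }
  probes <- rownames(x$values)
  purrr::map_dfr(seq_along(probes), function(i) {
    series <- x$values[i, ]
    sub <- substream_seed(seed, i)
    avg <- average_replicates(series, times)
    if (diff(range(avg$values)) == 0) {
      return(tibble(probe_id = probes[i], phi_h = NA_real_,
                    phase_class = NA_integer_, strength = NA_real_,
                    p_rhythm = 1, p_phase = NA_real_, ci_lo_h = NA_real_,
                    ci_hi_h = NA_real_, phase_defined = FALSE))
    }
    est <- estimate_phase(series, times, period_h)
    p_rhythm <- rhythmicity_pvalue(series, times, period_h, n_perm, seed = sub)
    ens <- me_bootstrap(avg$values, bootstrap_replicates, seed = sub + 1L)
    conf <- phase_confidence(ens, avg$times, period_h)
    tibble(probe_id = probes[i], phi_h = est$phi_h,
           phase_class = est$class, strength = est$strength,
           p_rhythm = p_rhythm, p_phase = conf$p_phase,
           ci_lo_h = conf$ci_lo_h, ci_hi_h = conf$ci_hi_h,
           phase_defined = TRUE)
  })
}
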