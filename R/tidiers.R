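#' Tidy a Poisson goodness-of-fit object
#'
#' One row per difference bin with observed and expected counts and the
#' Pearson residual `(O - E) / sqrt(E)`; large positive residuals in bin 6
#' are the counter-phase excess.
#'
#' @param x A [poisson_gof()] object.
#' @param ... Unused.
#' @return A tibble with columns `bin`, `observed`, `expected`, `residual`.
#' @export
tidy.poisson_gof <- function(x, ...) {
  tibble(bin = x$bins, observed = x$observed, expected = x$expected,
         residual = (x$observed - x$expected) / sqrt(x$expected))
}

#' Glance at a Poisson goodness-of-fit object
#'
#' @param x A [poisson_gof()] object.
#' @param ... Unused.
#' @return A one-row tibble: `lambda`, `n_pairs`, `statistic`, `df`,
#'   `p.value` (asymptotic), `p.value.mc`, `mc_reps`.
#' @export
glance.poisson_gof <- function(x, ...) {
  tibble(lambda = x$lambda, n_pairs = x$total, statistic = x$X2, df = x$df,
         p.value = x$p_asym,
         p.value.mc = if (is.null(x$p_mc)) NA_real_ else x$p_mc,
         mc_reps = x$mc_reps)
}

#' Glance at a pipeline result
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return A one-row tibble mirroring the summary table: `dataset`,
#'   `n_probes`, `n_retained`, `n_pairs`, `lambda`, `statistic`, `p.value`,
#'   `p.value.mc`.
#' @export
glance.pipeline_result <- function(x, ...) {
  n <- setNames(x$log$n, x$log$stage)
  g <- x$gof
  tibble(dataset = x$config$dataset,
         n_probes = unname(n["probes_total"]),
         n_retained = unname(n["retained"]),
         n_pairs = unname(n["pairs"]),
         lambda = if (is.null(g)) NA_real_ else g$lambda,
         statistic = if (is.null(g)) NA_real_ else g$X2,
         p.value = if (is.null(g)) NA_real_ else g$p_asym,
         p.value.mc = if (is.null(g) || is.null(g$p_mc)) NA_real_ else g$p_mc)
}
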