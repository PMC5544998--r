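#' Configuration for the end-to-end pipeline
#'
#' Bundles input paths and tuning parameters for [run_pipeline_files()] (and
#' the bundled command-line script). All stochastic stages draw from the
#' single master `seed`, which is recorded in every output artifact.
#'
#' @param matrix_path,samples_path,annotation_path Input file paths.
#' @param period_h Oscillation period in hours (default 24).
#' @param bootstrap_replicates Maximum-entropy bootstrap replicates per
#'   probe.
#' @param n_perm Permutations for the rhythmicity test.
#' @param p_threshold Confidence filter for pairing (default 0.1).
#' @param p_column `"p_phase"` (default) or `"p_rhythm"`.
#' @param mc_reps Monte Carlo repetitions for the goodness-of-fit test.
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if needed), or `NULL`.
#' @param dataset Label used in reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path, samples_path, annotation_path,
                            period_h = 24, bootstrap_replicates = 200,
                            n_perm = 199, p_threshold = 0.1,
                            p_column = c("p_phase", "p_rhythm"),
                            mc_reps = 1000, seed, out_dir = NULL,
                            dataset = "dataset") {
  p_column <- match.arg(p_column)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  counts <- c(period_h = period_h,
              bootstrap_replicates = bootstrap_replicates,
              n_perm = n_perm, mc_reps = mc_reps)
  if (any(counts <= 0)) {
    stop("counts and period must be positive", call. = FALSE)
  }
  if (p_threshold <= 0 || p_threshold > 1) {
    stop("'p_threshold' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(matrix_path = matrix_path, samples_path = samples_path,
                 annotation_path = annotation_path, period_h = period_h,
                 bootstrap_replicates = bootstrap_replicates,
                 n_perm = n_perm, p_threshold = p_threshold,
                 p_column = p_column, mc_reps = mc_reps,
                 seed = as.integer(seed), out_dir = out_dir,
                 dataset = dataset),
            class = "pipeline_config")
}

#' Run the full counter-phase mining pipeline
#'
#' Chains the analysis end to end: per-probe phase assignment
#' ([call_phases()]), probe grouping by gene ([group_probes()]), within-gene
#' pair differences under the confidence filter ([pair_differences()]), the
#' 7-bin difference histogram ([difference_histogram()]), and the Poisson
#' stochastic-decay test ([poisson_gof()]). The returned log accounts for
#' every probe: total = phase-undefined + filtered + retained.
#'
#' @param expression An [expr_ts()] panel.
#' @param annotation Annotation tibble (see [read_annotation()] /
#'   [group_probes()]).
#' @param group_mode `"auto"` (from the annotation's columns), `"symbol"`,
#'   or `"any_field"`.
#' @param period_h,bootstrap_replicates,n_perm,p_threshold,p_column,mc_reps
#'   See [pipeline_config()].
#' @param seed Master integer seed.
#' @param dataset Label recorded in the report.
#' @param out_dir If non-`NULL`, artifacts are written there via
#'   [write_report()].
#' @return A `pipeline_result` list: `calls`, `groups`, `pairs`,
#'   `histogram`, `gof` (`NULL` when no pairs survive), `log`, `config`.
#' @export
run_pipeline <- function(expression, annotation, group_mode = "auto",
                         period_h = 24, bootstrap_replicates = 200,
                         n_perm = 199, p_threshold = 0.1,
                         p_column = c("p_phase", "p_rhythm"),
                         mc_reps = 1000, seed, dataset = "dataset",
                         out_dir = NULL) {
  p_column <- match.arg(p_column)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(inherits(expression, "expr_ts"))
  annotation <- as_tibble(annotation)
  if (group_mode == "auto") {
    group_mode <- attr(annotation, "mode") %||%
      if ("symbol" %in% names(annotation)) "symbol" else "any_field"
  }

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  calls <- stage("call_phases",
    call_phases(expression, period_h = period_h,
                bootstrap_replicates = bootstrap_replicates,
                n_perm = n_perm, seed = seed))
  groups <- stage("group_probes", group_probes(annotation, group_mode))
  pairs <- stage("pair_differences",
    pair_differences(calls, groups, p_threshold = p_threshold,
                     p_column = p_column, period_h = period_h))
  histogram <- stage("difference_histogram",
    difference_histogram(pairs, dataset = dataset))
  gof <- if (attr(histogram, "total") > 0) {
    stage("poisson_gof",
      poisson_gof(histogram, mc_reps = mc_reps, seed = seed))
  } else {
    NULL
  }

  n_total <- nrow(calls)
  n_undef <- sum(!calls$phase_defined)
  n_kept <- sum(calls$phase_defined & calls[[p_column]] <= p_threshold)
  log <- tibble(
    stage = c("probes_total", "phase_undefined", "filtered_by_p",
              "retained", "pairs", "histogram_total"),
    n = c(n_total, n_undef, n_total - n_undef - n_kept, n_kept,
          nrow(pairs), attr(histogram, "total"))
  )

  result <- structure(
    list(calls = calls, groups = groups, pairs = pairs,
         histogram = histogram, gof = gof, log = log,
         config = list(group_mode = group_mode, period_h = period_h,
                       bootstrap_replicates = bootstrap_replicates,
                       n_perm = n_perm, p_threshold = p_threshold,
                       p_column = p_column, mc_reps = mc_reps,
                       seed = as.integer(seed), dataset = dataset)),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Counter-phase mining pipeline result\n")
  cat(sprintf("  dataset: %s (seed %d)\n", x$config$dataset, x$config$seed))
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-16s %d\n", x$log$stage[i], x$log$n[i]))
  }
  if (!is.null(x$gof)) {
    cat(sprintf("  lambda = %.3f, X2 = %.2f, p = %.3g\n",
                x$gof$lambda, x$gof$X2, x$gof$p_asym))
  } else {
    cat("  no pairs retained; goodness-of-fit test not run\n")
  }
  invisible(x)
}

#' Run the pipeline from files
#'
#' Reads the expression matrix, sample sheet and annotation named in a
#' [pipeline_config()], runs [run_pipeline()], and writes the report if the
#' config names an output directory.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`.
#' @export
run_pipeline_files <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  expression <- read_expression(config$matrix_path, config$samples_path)
  annotation <- read_annotation(config$annotation_path)
  run_pipeline(expression, annotation,
               period_h = config$period_h,
               bootstrap_replicates = config$bootstrap_replicates,
               n_perm = config$n_perm, p_threshold = config$p_threshold,
               p_column = config$p_column, mc_reps = config$mc_reps,
               seed = config$seed, dataset = config$dataset,
               out_dir = config$out_dir)
}

#' Write pipeline artifacts
#'
#' Writes the phase-call table, pair table, histogram and a JSON report to
#' `out_dir`, plus a one-row summary table with columns `dataset`, `lambda`,
#' `X_squared`, `p_value`. Runs are fully determined by config and seed, so
#' repeated runs produce byte-identical artifacts. An empty histogram is
#' written with an explicit `zero_pairs` marker in the JSON report.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory ", out_dir, call. = FALSE)
    }
  }
  paths <- file.path(out_dir, c("phase_calls.tsv", "pairs.tsv",
                                "histogram.tsv", "summary.tsv",
                                "report.json"))
  names(paths) <- c("calls", "pairs", "histogram", "summary", "report")
  readr::write_tsv(result$calls, paths["calls"])
  readr::write_tsv(result$pairs, paths["pairs"])
  readr::write_tsv(as_tibble(result$histogram), paths["histogram"])
  gof <- result$gof
  summary_row <- tibble(
    dataset = result$config$dataset,
    lambda = if (is.null(gof)) NA_real_ else gof$lambda,
    X_squared = if (is.null(gof)) NA_real_ else gof$X2,
    p_value = if (is.null(gof)) NA_real_ else gof$p_asym
  )
  readr::write_tsv(summary_row, paths["summary"])
  report <- list(
    dataset = result$config$dataset,
    config = result$config,
    log = as.list(setNames(result$log$n, result$log$stage)),
    histogram = as.list(setNames(result$histogram$count,
                                 paste0("bin", result$histogram$bin))),
    zero_pairs = attr(result$histogram, "total") == 0,
    gof = if (is.null(gof)) NULL else list(
      lambda = gof$lambda, X2 = gof$X2, df = gof$df,
      p_asym = gof$p_asym, p_mc = gof$p_mc, mc_reps = gof$mc_reps,
      seed = result$config$seed)
  )
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
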