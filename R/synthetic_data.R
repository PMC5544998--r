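#' Sampling design of a circadian expression time course
#'
#' Two canonical designs are built in. `"mouse"` mirrors a tissue panel
#' harvested at 4 h intervals in duplicate over a 24 h period (7 nominal time
#' points including both endpoints, 14 arrays). `"arabidopsis"` mirrors
#' seedlings in constant light harvested every 4 h over 44 h (12 time points,
#' single arrays). Both assume a 24 h oscillation period.
#'
#' @param kind `"mouse"`, `"arabidopsis"`, or `"custom"` with the remaining
#'   arguments supplied explicitly.
#' @param span_h Total duration in hours (first sample at 0 h).
#' @param step_h Sampling interval in hours; must divide `span_h`.
#' @param replicates Arrays per time point (>= 1).
#' @param period_h Oscillation period in hours (> 0).
#' @return A `design_spec` object (named list).
#' @examples
#' make_design("mouse")
#' make_design("custom", span_h = 24, step_h = 12, replicates = 1)
#' @export
make_design <- function(kind = c("mouse", "arabidopsis", "custom"),
                        span_h = NULL, step_h = 4, replicates = 1,
                        period_h = 24) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    mouse = list(span_h = 24, step_h = 4, replicates = 2, period_h = 24),
    arabidopsis = list(span_h = 44, step_h = 4, replicates = 1, period_h = 24),
    custom = list(span_h = span_h, step_h = step_h,
                  replicates = replicates, period_h = period_h)
  )
  if (is.null(spec$span_h) || !is.finite(spec$span_h) || spec$span_h <= 0) {
    stop("'span_h' must be a positive number", call. = FALSE)
  }
  if (spec$step_h <= 0 || abs(spec$span_h / spec$step_h -
                              round(spec$span_h / spec$step_h)) > 1e-9) {
    stop("'step_h' must be positive and divide 'span_h'", call. = FALSE)
  }
  if (spec$replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  if (spec$period_h <= 0) stop("'period_h' must be positive", call. = FALSE)
  structure(c(spec, list(kind = kind)), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  st <- design_samples(x)
  cat(sprintf(
    "Time-course design (%s): 0-%g h every %g h, %d replicate(s), period %g h\n",
    x$kind, x$span_h, x$step_h, x$replicates, x$period_h))
  cat(sprintf("  %d time points, %d samples\n",
              length(unique(st$time_h)), nrow(st)))
  invisible(x)
}

#' Sample sheet implied by a design
#'
#' @param design A [make_design()] object.
#' @return A tibble with columns `sample_id`, `time_h`, `replicate`.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  tp <- seq(0, design$span_h, by = design$step_h)
  grid <- tidyr::expand_grid(time_h = tp, replicate = seq_len(design$replicates))
  dplyr::mutate(grid,
                sample_id = sprintf("T%02g_R%d", .data$time_h, .data$replicate),
                .before = 1L)
}

#' Expression time-series container
#'
#' A light container pairing a probes-by-samples value matrix with its sample
#' sheet. Most package functions accept and return it; use
#' [tibble::as_tibble()] for a long (probe, sample, value) view.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample_id`, `time_h`, `replicate`,
#'   one row per matrix column.
#' @return An `expr_ts` object.
#' @export
expr_ts <- function(values, samples) {
  values <- as.matrix(values)
  samples <- as_tibble(samples)
  need <- c("sample_id", "time_h", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry probe rownames and sample colnames",
         call. = FALSE)
  }
  if (!setequal(colnames(values), samples$sample_id) ||
      ncol(values) != nrow(samples)) {
    missing_ids <- setdiff(colnames(values), samples$sample_id)
    extra_ids <- setdiff(samples$sample_id, colnames(values))
    stop("matrix columns and sample sheet disagree; missing from sheet: [",
         paste(missing_ids, collapse = ", "), "]; missing from matrix: [",
         paste(extra_ids, collapse = ", "), "]", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at probe '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  structure(list(values = values, samples = samples), class = "expr_ts")
}

#' @export
print.expr_ts <- function(x, ...) {
  cat(sprintf("Expression time series: %d probes x %d samples (%d time points)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$time_h))))
  invisible(x)
}

#' @export
dim.expr_ts <- function(x) dim(x$values)

#' @export
as_tibble.expr_ts <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "probe_id")
  long <- tidyr::pivot_longer(long, -"probe_id",
                              names_to = "sample_id", values_to = "value")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-unit substream seed below 2^31
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) + 999983 * as.numeric(index)) %% 2147483629)
}

#' Generate a synthetic circadian expression panel
#'
#' Simulates a probes-by-samples intensity matrix with known ground truth,
#' emulating the statistical structure that the phase-difference datamining
#' assumes: a rhythmic fraction of genes following 24 h cosines, several
#' probe sets per gene, a planted subset of within-gene probe pairs in exact
#' counter-phase (peaks 12 h apart), additive Gaussian noise on the
#' normalized intensities, and a non-rhythmic background.
#'
#' Rhythmic probe values are
#' `baseline + amplitude * cos(2*pi*(t - phase)/period) + noise`; flat probes
#' are `baseline + noise`. Baselines are drawn log-uniformly over
#' `baseline_range`; amplitudes are a uniform fraction (`amp_frac_range`) of
#' the probe's baseline; the noise standard deviation is `noise_frac` times
#' the probe amplitude (for flat probes, times a typical amplitude at that
#' baseline, so rhythmic and flat probes have comparable noise).
#'
#' Among rhythmic genes carrying at least two probes, a fraction
#' `frac_counterphase` is planted as a counter-phase pair (first two probes
#' 12 h apart); all other multi-probe rhythmic genes are concordant (all
#' probes share the gene phase). Planted phases sit by default on the 4 h
#' grid of phase-class centres (0, 4, ..., 20 h), the only grid on which
#' discrete class recovery is exact: phases planted on class boundaries
#' (odd multiples of 2 h) are intrinsically ambiguous between two classes
#' under any perturbation. Pass `phase_grid_h = 2` for boundary-including
#' planting or `phase_grid_h = NULL` for continuous phases.
#'
#' @param design A [make_design()] object.
#' @param n_genes Number of genes.
#' @param probes_per_gene Probability weights for 1, 2, ... probes per gene.
#' @param frac_rhythmic Fraction of genes that oscillate.
#' @param frac_counterphase Fraction of multi-probe rhythmic genes planted as
#'   counter-phase pairs.
#' @param amp_frac_range Range of amplitude as a fraction of baseline.
#' @param noise_frac Noise sd as a fraction of amplitude (0 = noiseless).
#' @param baseline_range Range of baseline intensities (log-uniform draw).
#' @param phase_grid_h Grid spacing for planted phases in hours, or `NULL`
#'   for continuous phases.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @return A list with elements `expression` (an [expr_ts()]), `annotation`
#'   (tibble `probe_id`, `symbol`) and `truth` (tibble with per-probe gene,
#'   rhythmic flag, planted phase/amplitude/baseline/noise sd and pair role).
#' @examples
#' panel <- generate_panel(make_design("mouse"), n_genes = 20, seed = 1)
#' panel$truth
#' @export
generate_panel <- function(design,
                           n_genes = 200,
                           probes_per_gene = c(0.5, 0.35, 0.15),
                           frac_rhythmic = 0.3,
                           frac_counterphase = 0.15,
                           amp_frac_range = c(0.2, 0.5),
                           noise_frac = 0.1,
                           baseline_range = c(50, 500),
                           phase_grid_h = 4,
                           seed) {
  stopifnot(inherits(design, "design_spec"))
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (frac_rhythmic < 0 || frac_rhythmic > 1 ||
      frac_counterphase < 0 || frac_counterphase > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(probes_per_gene) < 1 || any(probes_per_gene < 0) ||
      sum(probes_per_gene) <= 0) {
    stop("'probes_per_gene' must be non-negative weights for >= 1 probe",
         call. = FALSE)
  }
  samples <- design_samples(design)
  period <- design$period_h

  with_seed(seed, {
    n_probes_gene <- sample.int(length(probes_per_gene), n_genes,
                                replace = TRUE, prob = probes_per_gene)
    gene_id <- sprintf("G%04d", seq_len(n_genes))
    rhythmic_gene <- runif(n_genes) < frac_rhythmic
    phase_gene <- if (is.null(phase_grid_h)) {
      runif(n_genes, 0, period)
    } else {
      phase_grid_h * sample.int(round(period / phase_grid_h), n_genes,
                                replace = TRUE) - phase_grid_h
    }
    eligible <- rhythmic_gene & n_probes_gene >= 2L
    counter_gene <- eligible & runif(n_genes) < frac_counterphase

    truth <- purrr::map_dfr(seq_len(n_genes), function(g) {
      k <- n_probes_gene[g]
      probe_id <- sprintf("%s_p%d", gene_id[g], seq_len(k))
      baseline <- exp(runif(k, log(baseline_range[1]), log(baseline_range[2])))
      amp_frac <- runif(k, amp_frac_range[1], amp_frac_range[2])
      rhythmic <- rep(rhythmic_gene[g], k)
      amplitude <- ifelse(rhythmic, baseline * amp_frac, 0)
      phase <- rep(NA_real_, k)
      role <- rep("none", k)
      if (rhythmic_gene[g]) {
        phase <- rep(phase_gene[g], k)
        if (counter_gene[g]) {
          phase[2L] <- (phase_gene[g] + period / 2) %% period
          role[1:2] <- "counterphase"
          if (k > 2L) role[3:k] <- "concordant"
        } else if (k >= 2L) {
          role[] <- "concordant"
        }
      }
      noise_sd <- ifelse(rhythmic, noise_frac * amplitude,
                         noise_frac * mean(amp_frac_range) * baseline)
      tibble(probe_id = probe_id, gene = gene_id[g], rhythmic = rhythmic,
             phase_h = phase, amplitude = amplitude, baseline = baseline,
             noise_sd = noise_sd, pair_role = role)
    })

    n_p <- nrow(truth)
    n_s <- nrow(samples)
    t_h <- samples$time_h
    signal <- matrix(truth$baseline, n_p, n_s)
    is_r <- truth$rhythmic
    if (any(is_r)) {
      phase_mat <- outer(truth$phase_h[is_r], t_h, function(ph, t) {
        cos(2 * pi * (t - ph) / period)
      })
      signal[is_r, ] <- signal[is_r, , drop = FALSE] +
        truth$amplitude[is_r] * phase_mat
    }
    noise <- matrix(rnorm(n_p * n_s), n_p, n_s) * truth$noise_sd
    values <- signal + noise
    dimnames(values) <- list(truth$probe_id, samples$sample_id)

    list(
      expression = expr_ts(values, samples),
      annotation = tibble(probe_id = truth$probe_id, symbol = truth$gene),
      truth = truth
    )
  })
}

#' Build a multi-identifier annotation table
#'
#' Arabidopsis array annotations identify a gene through several partially
#' filled fields (RefSeq transcript id, AGI locus, Entrez gene id); two probe
#' sets belong to the same gene whenever any field matches. This constructor
#' assembles such a table from per-probe records, joining multi-valued fields
#' with the conventional `"///"` delimiter, for use with
#' [group_probes()] in `"any_field"` mode.
#'
#' @param records A data frame (or list coercible to one) with column
#'   `probe_id` and any of `refseq`, `agi`, `entrez`; fields may be `NA` or
#'   character vectors in list-columns.
#' @return A tibble with columns `probe_id`, `refseq`, `agi`, `entrez`.
#' @examples
#' make_arabidopsis_annotation(data.frame(
#'   probe_id = c("a", "b"), agi = c("AT1G01010", "AT1G01010")))
#' @export
make_arabidopsis_annotation <- function(records) {
  records <- as_tibble(records)
  if (!"probe_id" %in% names(records)) {
    stop("'records' needs a probe_id column", call. = FALSE)
  }
  flatten_field <- function(col) {
    if (is.null(col)) return(rep(NA_character_, nrow(records)))
    purrr::map_chr(col, function(v) {
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v) == 0) NA_character_ else paste(v, collapse = " /// ")
    })
  }
  tibble(
    probe_id = as.character(records$probe_id),
    refseq = flatten_field(records[["refseq"]]),
    agi = flatten_field(records[["agi"]]),
    entrez = flatten_field(records[["entrez"]])
  )
}
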