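#' Group probes into per-gene probe sets
#'
#' Multiple probe sets on an expression array frequently interrogate the
#' same gene — an unintended redundancy that makes alternative
#' polyadenylation visible. In `"symbol"` mode probes are partitioned by
#' exact gene-symbol match (mouse-style annotations). In `"any_field"` mode
#' (Arabidopsis-style annotations with RefSeq transcript, AGI locus and
#' Entrez gene columns), probes belong together whenever *any* non-missing
#' identifier value is shared; groups are the connected components of the
#' probe-identifier graph, so chains A~B (AGI), B~C (Entrez) merge into one
#' group. Multi-valued fields use the `"///"` delimiter.
#'
#' @param annotation A data frame with column `probe_id` plus `symbol`
#'   (symbol mode) or any of `refseq`, `agi`, `entrez` (any-field mode).
#' @param mode `"symbol"` or `"any_field"`.
#' @return A tibble with columns `probe_id`, `gene` (group key). Probes with
#'   no usable identifier become singleton groups.
#' @examples
#' ann <- data.frame(probe_id = c("p1", "p2"), symbol = "Socs3")
#' group_probes(ann, "symbol")
#' @export
group_probes <- function(annotation, mode = c("symbol", "any_field")) {
  mode <- match.arg(mode)
  annotation <- as_tibble(annotation)
  if (!"probe_id" %in% names(annotation)) {
    stop("annotation needs a probe_id column", call. = FALSE)
  }
  probes <- as.character(annotation$probe_id)
  if (anyDuplicated(probes)) {
    stop("duplicate probe ids in annotation: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "),
         call. = FALSE)
  }
  if (mode == "symbol") {
    if (!"symbol" %in% names(annotation)) {
      stop("symbol mode needs a 'symbol' column", call. = FALSE)
    }
    sym <- as.character(annotation$symbol)
    gene <- ifelse(is.na(sym) | !nzchar(sym),
                   paste0("singleton:", probes), sym)
    return(tibble(probe_id = probes, gene = gene))
  }
  fields <- intersect(c("refseq", "agi", "entrez"), names(annotation))
  if (length(fields) == 0) {
    stop("any_field mode needs at least one of: refseq, agi, entrez",
         call. = FALSE)
  }
  # bipartite graph probe -- "field:value"; probe groups are components
  edges <- purrr::map_dfr(fields, function(f) {
    vals <- as.character(annotation[[f]])
    tibble(probe = probes, value = vals) |>
      dplyr::filter(!is.na(.data$value) & nzchar(.data$value)) |>
      dplyr::mutate(value = strsplit(.data$value, "\\s*///\\s*")) |>
      tidyr::unnest("value") |>
      dplyr::filter(nzchar(.data$value)) |>
      dplyr::mutate(value = paste0(f, ":", .data$value))
  })
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = unique(c(probes, edges$value)))
  )
  comp <- igraph::components(g)$membership
  member <- comp[probes]
  # name each group by its first member probe for stable, readable keys
  first <- tapply(probes, member, function(p) p[1L])
  tibble(probe_id = probes,
         gene = paste0("grp:", unname(first[as.character(member)])))
}

#' Within-gene probe-pair phase differences
#'
#' Applies the confidence filter (keep probes with a defined phase and
#' `p <= p_threshold`), then enumerates all unordered probe pairs within
#' each gene group and computes each pair's absolute circular phase
#' difference `d = min(|phi_i - phi_j|, period - |phi_i - phi_j|)` in
#' `[0, period/2]` hours, binned into 2 h-wide difference classes
#' `bin = round(d / 2)` (0..6 for a 24 h period). Differences are taken on
#' the continuous phases, not the coarse classes, so odd bins are reachable
#' under 4 h sampling.
#'
#' @param calls Phase-call tibble from [call_phases()].
#' @param groups Grouping tibble from [group_probes()].
#' @param p_threshold Confidence filter threshold (default 0.1); the
#'   comparison is `<=`, so ties at the threshold are retained.
#' @param p_column Which p-value drives the filter: the bootstrap
#'   phase-confidence p (`"p_phase"`, default) or the permutation
#'   rhythmicity p (`"p_rhythm"`).
#' @param period_h Oscillation period in hours (default 24).
#' @return A tibble with columns `gene`, `probe_i`, `probe_j`, `phi_i`,
#'   `phi_j`, `diff_h`, `bin`.
#' @export
pair_differences <- function(calls, groups, p_threshold = 0.1,
                             p_column = c("p_phase", "p_rhythm"),
                             period_h = 24) {
  p_column <- match.arg(p_column)
  if (p_threshold <= 0 || p_threshold > 1) {
    stop("'p_threshold' must lie in (0, 1]", call. = FALSE)
  }
  calls <- as_tibble(calls)
  kept <- calls |>
    dplyr::filter(.data$phase_defined, .data[[p_column]] <= p_threshold) |>
    dplyr::inner_join(as_tibble(groups), by = "probe_id")
  half <- period_h / 2
  multi <- split(kept, kept$gene)
  multi <- multi[vapply(multi, nrow, integer(1)) >= 2L]
  out <- if (length(multi) == 0L) {
    tibble(gene = character(), probe_i = character(), probe_j = character(),
           phi_i = numeric(), phi_j = numeric())
  } else {
    purrr::map_dfr(multi, function(g) {
      idx <- utils::combn(nrow(g), 2L)
      tibble(gene = g$gene[1L],
             probe_i = g$probe_id[idx[1L, ]],
             probe_j = g$probe_id[idx[2L, ]],
             phi_i = g$phi_h[idx[1L, ]],
             phi_j = g$phi_h[idx[2L, ]])
    })
  }
  out <- dplyr::mutate(
    out,
    diff_h = pmin(abs(.data$phi_i - .data$phi_j),
                  period_h - abs(.data$phi_i - .data$phi_j)),
    bin = as.integer(round(.data$diff_h / (half / 6)))
  )
  attr(out, "p_threshold") <- p_threshold
  attr(out, "period_h") <- period_h
  out
}

#' Histogram of probe-pair phase differences
#'
#' Tallies pair differences into the 7 ordered bins (0 h plus one bin per
#' pi/6 cyclic shift, i.e. 2 h steps of circular difference folded to
#' `[0, 12]` h). Bin 6 is the counter-phase bin; an excess there relative to
#' a stochastic-decay (Poisson) profile signals genuinely counter-phase
#' probe pairs.
#'
#' @param pairs Pair tibble from [pair_differences()] (may be empty).
#' @param dataset Optional label recorded in the histogram's provenance.
#' @return A `diff_histogram`: tibble with columns `bin` (0..6) and `count`,
#'   with attributes `total`, `p_threshold`, `dataset`.
#' @export
difference_histogram <- function(pairs, dataset = NULL) {
  bins <- 0:6
  counts <- if (is.null(pairs) || nrow(pairs) == 0L) {
    rep(0L, 7L)
  } else {
    as.integer(table(factor(pairs$bin, levels = bins)))
  }
  out <- tibble(bin = bins, count = counts)
  attr(out, "total") <- sum(counts)
  attr(out, "p_threshold") <- attr(pairs, "p_threshold")
  attr(out, "dataset") <- dataset
  class(out) <- c("diff_histogram", class(out))
  out
}

#' @export
print.diff_histogram <- function(x, ...) {
  lbl <- attr(x, "dataset")
  cat(sprintf("Phase-difference histogram%s: %d pairs\n",
              if (!is.null(lbl)) paste0(" (", lbl, ")") else "",
              attr(x, "total")))
  NextMethod()
}
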