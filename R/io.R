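read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

write_delim_auto <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is TSV or CSV (by extension) with probe ids in the first
#' column and one column per sample; the sample sheet provides `sample_id`,
#' `time_h` and `replicate` for every matrix column. Ids are cross-checked
#' and mismatches reported by name. Non-numeric or missing cells are an
#' error (with coordinates) unless `impute = TRUE`, in which case missing
#' cells are filled with the probe's mean.
#'
#' @param matrix_path Path to the expression matrix (probes x samples).
#' @param samples_path Path to the sample sheet.
#' @param impute Fill missing cells with the probe mean (default `FALSE`).
#' @return An [expr_ts()] object.
#' @export
read_expression <- function(matrix_path, samples_path, impute = FALSE) {
  mat_df <- read_delim_auto(matrix_path)
  samples <- read_delim_auto(samples_path)
  probe_col <- names(mat_df)[1L]
  probes <- as.character(mat_df[[probe_col]])
  vals <- mat_df[-1L]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                     probes[bad[1L]], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- probes
  if (anyNA(m)) {
    if (impute) {
      for (i in which(rowSums(is.na(m)) > 0)) {
        m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
      }
    } else {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at probe '%s', sample '%s' (use impute = TRUE to fill)",
                   rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
    }
  }
  expr_ts(m, samples)
}

#' Write an expression panel to disk
#'
#' @param x An [expr_ts()] object.
#' @param matrix_path,samples_path Output paths (TSV unless `.csv`).
#' @return The input, invisibly.
#' @export
write_expression <- function(x, matrix_path, samples_path) {
  stopifnot(inherits(x, "expr_ts"))
  wide <- as_tibble(x$values, rownames = "probe_id")
  write_delim_auto(wide, matrix_path)
  write_delim_auto(x$samples, samples_path)
  invisible(x)
}

#' Read a probe annotation table
#'
#' Accepts a mouse-style table (`probe_id`, `symbol`) or an
#' Arabidopsis-style multi-identifier table (`probe_id` plus any of
#' `refseq`, `agi`, `entrez`; `"///"`-delimited multi-values are preserved
#' for [group_probes()] to split). Column names are matched
#' case-insensitively with common aliases (e.g. `Gene Symbol`,
#' `RefSeq Transcript ID`, `Entrez Gene`, `AGI`).
#'
#' @param path Path to a TSV/CSV annotation file.
#' @return A tibble whose columns determine the grouping mode: `symbol`, or
#'   identifier columns for any-field grouping. Attribute `mode` records
#'   which was detected.
#' @export
read_annotation <- function(path) {
  raw <- read_delim_auto(path)
  nm <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(raw))))
  canon <- c(probe_id = "probe_id", probe = "probe_id",
             probe_set_id = "probe_id", probeset_id = "probe_id",
             symbol = "symbol", gene_symbol = "symbol",
             refseq = "refseq", refseq_transcript_id = "refseq",
             agi = "agi", entrez = "entrez", entrez_gene = "entrez")
  names(raw) <- ifelse(nm %in% names(canon), canon[nm], nm)
  if (!"probe_id" %in% names(raw)) {
    stop("no probe id column recognized in ", path, call. = FALSE)
  }
  if (anyDuplicated(raw$probe_id)) {
    stop("duplicate probe ids in annotation: ",
         paste(unique(raw$probe_id[duplicated(raw$probe_id)]), collapse = ", "),
         call. = FALSE)
  }
  has_any <- any(c("refseq", "agi", "entrez") %in% names(raw))
  if (!has_any && !"symbol" %in% names(raw)) {
    stop("no recognizable identifier column (symbol, refseq, agi, entrez) in ",
         path, call. = FALSE)
  }
  out <- as_tibble(raw)
  attr(out, "mode") <- if (has_any) "any_field" else "symbol"
  out
}

#' Read a phase-difference histogram
#'
#' @param path TSV/CSV with columns `bin`, `count`.
#' @param dataset Optional label for the histogram's provenance.
#' @return A `diff_histogram`.
#' @export
read_histogram <- function(path, dataset = NULL) {
  raw <- read_delim_auto(path)
  if (!all(c("bin", "count") %in% names(raw))) {
    stop("histogram file needs 'bin' and 'count' columns", call. = FALSE)
  }
  out <- tibble(bin = as.integer(raw$bin), count = as.integer(raw$count))
  attr(out, "total") <- sum(out$count)
  attr(out, "dataset") <- dataset
  class(out) <- c("diff_histogram", class(out))
  out
}
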