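#' Construct a cohort
#'
#' A cohort couples a genes-by-samples expression matrix with a per-sample
#' right-censored survival table. Construction validates and aligns the two
#' components: samples are intersected, ordered identically, gene rows with
#' any missing value are dropped (and counted in a message), and duplicate
#' gene symbols or invalid survival records are rejected.
#'
#' Survival times are taken as-is (days or months); all cohorts analysed
#' together must share the same unit.
#'
#' @param cohort_id Short identifier for the cohort.
#' @param expression Numeric matrix, rows = gene symbols, columns = sample
#'   identifiers.
#' @param survival Data frame with columns `sample_id`, `time`
#'   (non-negative) and `event` (1 = death observed, 0 = censored).
#' @param quiet Suppress the dropped-row/sample message.
#'
#' @return A `cohort` object: list with elements `cohort_id`, `expression`
#'   and `survival` (tibble), samples aligned across both.
#' @export
new_cohort <- function(cohort_id, expression, survival, quiet = FALSE) {
  stopifnot(is.matrix(expression))
  storage.mode(expression) <- "double"
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    abort("Expression matrix needs gene rownames and sample colnames.",
          class = "pascrosstalk_input_error")
  }
  if (anyDuplicated(rownames(expression))) {
    dup <- unique(rownames(expression)[duplicated(rownames(expression))])
    abort(paste0("Duplicate gene symbol(s) in expression matrix: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "pascrosstalk_input_error")
  }
  if (anyDuplicated(colnames(expression))) {
    abort("Duplicate sample identifiers in expression matrix.",
          class = "pascrosstalk_input_error")
  }
  survival <- as_tibble(survival)
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(survival))) {
    abort("Survival table needs columns sample_id, time, event.",
          class = "pascrosstalk_input_error")
  }
  survival <- select(survival, dplyr::all_of(req))
  survival$sample_id <- as.character(survival$sample_id)
  if (anyDuplicated(survival$sample_id)) {
    abort("Duplicate sample identifiers in survival table.",
          class = "pascrosstalk_input_error")
  }
  if (any(is.na(survival$time)) || any(survival$time < 0)) {
    abort("Survival time must be non-negative and non-missing.",
          class = "pascrosstalk_input_error")
  }
  if (!all(survival$event %in% c(0, 1))) {
    abort("Survival event must be 0 (censored) or 1 (death observed).",
          class = "pascrosstalk_input_error")
  }

  shared <- intersect(colnames(expression), survival$sample_id)
  if (length(shared) == 0) {
    abort("No overlapping samples between expression and survival.",
          class = "pascrosstalk_input_error")
  }
  n_expr_drop <- ncol(expression) - length(shared)
  n_surv_drop <- nrow(survival) - length(shared)
  expression <- expression[, shared, drop = FALSE]
  survival <- survival[match(shared, survival$sample_id), ]

  incomplete <- rowSums(is.na(expression)) > 0
  n_gene_drop <- sum(incomplete)
  expression <- expression[!incomplete, , drop = FALSE]
  if (nrow(expression) == 0) {
    abort("No complete gene rows left after dropping missing values.",
          class = "pascrosstalk_input_error")
  }

  if (!quiet && (n_expr_drop + n_surv_drop + n_gene_drop > 0)) {
    inform(sprintf(
      "Cohort %s: dropped %d expression-only sample(s), %d survival-only sample(s), %d gene row(s) with missing values.",
      cohort_id, n_expr_drop, n_surv_drop, n_gene_drop))
  }

  structure(
    list(cohort_id = as.character(cohort_id),
         expression = expression,
         survival = survival),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort %s: %d genes x %d samples, %d events / %d samples>\n",
              x$cohort_id, nrow(x$expression), ncol(x$expression),
              sum(x$survival$event), nrow(x$survival)))
  invisible(x)
}

#' Read a cohort from tab-separated files
#'
#' The expression file is a tab-separated matrix whose first column (named
#' `gene`) holds gene symbols and whose header row holds sample identifiers.
#' The survival file is tab-separated with header
#' `sample_id<TAB>time<TAB>event`. Samples are intersected and aligned; a
#' message reports how many samples and gene rows were dropped.
#'
#' @param expr_path Path to the expression matrix file.
#' @param surv_path Path to the survival table file.
#' @param cohort_id Identifier to attach to the cohort.
#' @inheritParams new_cohort
#' @return A [new_cohort()] object.
#' @export
read_cohort <- function(expr_path, surv_path, cohort_id, quiet = FALSE) {
  for (p in c(expr_path, surv_path)) {
    if (!file.exists(p)) {
      abort(paste0("File not found: ", p), class = "pascrosstalk_io_error")
    }
  }
  expr_df <- readr::read_tsv(expr_path, show_col_types = FALSE,
                             progress = FALSE)
  if (ncol(expr_df) < 2) {
    abort("Expression file needs a gene column plus at least one sample.",
          class = "pascrosstalk_input_error")
  }
  genes <- as.character(expr_df[[1]])
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- genes
  survival <- readr::read_tsv(surv_path, show_col_types = FALSE,
                              progress = FALSE)
  new_cohort(cohort_id, expression, survival, quiet = quiet)
}

#' Write a cohort to tab-separated files
#'
#' Inverse of [read_cohort()]: writes the expression matrix (first column
#' `gene`) and survival table in the package's tab-separated layout.
#'
#' @param cohort A `cohort`.
#' @param expr_path,surv_path Output file paths.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, expr_path, surv_path) {
  expr_df <- tibble(gene = rownames(cohort$expression))
  expr_df <- dplyr::bind_cols(expr_df, as_tibble(cohort$expression))
  readr::write_tsv(expr_df, expr_path, progress = FALSE)
  readr::write_tsv(cohort$survival, surv_path, progress = FALSE)
  invisible(cohort)
}
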