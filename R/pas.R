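#' Median-split gene votes
#'
#' The elementary rank-based score: within a cohort, samples whose
#' expression of a gene is strictly greater than that gene's median are
#' scored +1 ("high" group), all other samples — including any sample tied
#' with the median — are scored -1. A constant gene therefore votes -1 for
#' every sample. Because the split depends only on within-cohort ranks, any
#' strictly increasing transform of the expression vector (platform or
#' scale effects) leaves the votes unchanged.
#'
#' @param expression_row Numeric vector of one gene's expression across the
#'   cohort's samples (length >= 2).
#' @return Numeric vector of votes in `{-1, +1}`, same names as the input.
#' @export
#' @examples
#' gene_votes(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
gene_votes <- function(expression_row) {
  if (length(expression_row) < 2) {
    abort("gene_votes needs at least 2 samples.",
          class = "pascrosstalk_input_error")
  }
  ifelse(expression_row > median(expression_row), 1, -1)
}

vote_matrix <- function(expression) {
  med <- apply(expression, 1, median)
  votes <- matrix(-1, nrow(expression), ncol(expression),
                  dimnames = dimnames(expression))
  votes[expression > med] <- 1
  votes
}

new_pas_matrix <- function(values, cohort_id, n_genes_used) {
  structure(values, class = c("pas_matrix", "matrix"),
            cohort_id = cohort_id, n_genes_used = n_genes_used)
}

pas_from_sets <- function(cohort, sets, what = "pathway") {
  measured <- map(sets, function(g) intersect(g, rownames(cohort$expression)))
  keep <- lengths(measured) > 0
  if (any(!keep)) {
    inform(sprintf("Cohort %s: dropped %d %s(s) with no measured genes.",
                   cohort$cohort_id, sum(!keep), what))
  }
  if (!any(keep)) {
    abort(paste0("All ", what, "s were dropped: no genes measured in cohort ",
                 cohort$cohort_id, "."),
          class = "pascrosstalk_empty_result")
  }
  measured <- measured[keep]
  votes <- vote_matrix(
    cohort$expression[unique(unlist(measured, use.names = FALSE)), ,
                      drop = FALSE])
  values <- do.call(rbind, map(measured, function(g) {
    colMeans(votes[g, , drop = FALSE])
  }))
  rownames(values) <- names(measured)
  new_pas_matrix(values, cohort$cohort_id,
                 setNames(lengths(measured), names(measured)))
}

#' Compute per-sample pathway activity scores
#'
#' For each pathway, the PAS of a sample is the mean of [gene_votes()] over
#' the pathway's genes that are measured in the cohort; unmeasured genes
#' are excluded from the average (never treated as zero), and pathways with
#' no measured gene are dropped with a message. All scores lie in
#' `[-1, +1]`; +1 means every measured pathway gene is in its
#' high-expression half for that sample.
#'
#' @param cohort A [new_cohort()].
#' @param collection A [gene_set_collection()].
#' @return A `pas_matrix`: pathways x samples numeric matrix with
#'   attributes `cohort_id` and `n_genes_used` (measured genes per row).
#' @export
compute_pas <- function(cohort, collection) {
  collection <- as_gene_set_collection(collection)
  if (nrow(collection) == 0) {
    abort("Empty gene-set collection.", class = "pascrosstalk_input_error")
  }
  pas_from_sets(cohort, gene_sets(collection), what = "pathway")
}

#' Recompute PAS on derived sub-pathways
#'
#' Applies the identical median-split scoring rule to the derived gene sets
#' of a sub-pathway decomposition; rows are sub-pathway ids.
#'
#' @param cohort A [new_cohort()].
#' @param subpaths A `subpathway_set` from [decompose_crosstalk()] (every
#'   set must have >= 3 genes).
#' @return A `pas_matrix` with sub-pathway ids as rows.
#' @export
subpathway_pas <- function(cohort, subpaths) {
  stopifnot(inherits(subpaths, "subpathway_set"))
  if (any(lengths(subpaths$genes) < 3)) {
    abort("Every sub-pathway must have at least 3 genes.",
          class = "pascrosstalk_input_error")
  }
  pas_from_sets(cohort, setNames(subpaths$genes, subpaths$subpathway_id),
                what = "sub-pathway")
}

#' @export
print.pas_matrix <- function(x, ...) {
  cat(sprintf("<pas_matrix cohort %s: %d gene sets x %d samples>\n",
              attr(x, "cohort_id"), nrow(x), ncol(x)))
  invisible(x)
}

#' Tidy a PAS matrix into long form
#'
#' @param x A `pas_matrix`.
#' @param ... Ignored.
#' @return Tibble with columns `pathway_id`, `sample_id`, `pas`.
#' @export
as_tibble.pas_matrix <- function(x, ...) {
  tibble(pathway_id = rep(rownames(x), times = ncol(x)),
         sample_id = rep(colnames(x), each = nrow(x)),
         pas = as.vector(x))
}

#' Heatmap of a PAS matrix
#'
#' @param object A `pas_matrix`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pas_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$pathway_id,
                                   fill = .data$pas)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "sample", y = "gene set", fill = "PAS",
                  title = paste("Pathway activity,", attr(object, "cohort_id"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Write a PAS matrix to a tab-separated file
#'
#' Rows are gene-set ids (first column `pathway_id`), header holds sample
#' ids.
#'
#' @param pas A `pas_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pas <- function(pas, path) {
  df <- dplyr::bind_cols(tibble(pathway_id = rownames(pas)),
                         as_tibble(unclass(pas)[, , drop = FALSE]))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
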